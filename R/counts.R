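#' Read counts at one SNP in one replicate
#'
#' The elementary observation of the framework: at a SNP distinguishing the
#' two grafted genotypes, `total_reads` (N) reads cover the position and
#' `distal_reads` (n) of them carry the base of the distal genotype, i.e. the
#' genotype of the grafted partner that was *not* sampled.
#'
#' @param total_reads total read count N (single non-negative integer).
#' @param distal_reads reads mapping to the distal genotype, 0 <= n <= N.
#' @param snp_id,replicate_id opaque identifiers (optional).
#' @param tissue sampled tissue, `"scion"` or `"stock"` (optional).
#' @param genotype genotype of the sampled tissue (optional).
#' @return An object of class `"snp_counts"`.
#' @examples
#' snp_counts(100, 3, snp_id = "s1")
#' @export
snp_counts <- function(total_reads, distal_reads, snp_id = NA_character_,
                       replicate_id = NA_character_, tissue = NA_character_,
                       genotype = NA_character_) {
  if (length(total_reads) != 1L || length(distal_reads) != 1L)
    stop("snp_counts() holds a single observation; use a count table for many")
  if (!is_count(total_reads) || !is_count(distal_reads))
    stop("total_reads and distal_reads must be non-negative integers")
  if (distal_reads > total_reads)
    stop("distal_reads (", distal_reads, ") exceeds total_reads (",
         total_reads, ")")
  if (!is.na(tissue)) tissue <- match.arg(tissue, c("scion", "stock"))
  structure(
    list(snp_id = as.character(snp_id),
         replicate_id = as.character(replicate_id),
         tissue = as.character(tissue), genotype = as.character(genotype),
         total_reads = as.integer(total_reads),
         distal_reads = as.integer(distal_reads)),
    class = "snp_counts")
}

#' @export
print.snp_counts <- function(x, ...) {
  cat(sprintf("<snp_counts> snp=%s rep=%s N=%d n=%d\n",
              x$snp_id, x$replicate_id, x$total_reads, x$distal_reads))
  invisible(x)
}

# Coerce a snp_counts object, single-row data.frame or list to snp_counts.
as_snp_counts <- function(x) {
  if (inherits(x, "snp_counts")) return(x)
  if (is.data.frame(x)) {
    if (nrow(x) != 1L) stop("expected a single observation")
    x <- as.list(x)
  }
  if (!is.list(x) || is.null(x$total_reads) || is.null(x$distal_reads))
    stop("cannot interpret input as SNP counts (need total_reads, distal_reads)")
  snp_counts(x$total_reads, x$distal_reads,
             snp_id = x$snp_id %||% NA_character_,
             replicate_id = x$replicate_id %||% NA_character_,
             tissue = x$tissue %||% NA_character_,
             genotype = (x$genotype %||% x$genotype_sampled) %||% NA_character_)
}

count_table_columns <- c("transcript_id", "snp_id", "replicate_id",
                         "total_reads", "distal_reads")

#' Validate a count table
#'
#' A count table is a data frame with one row per (transcript, SNP,
#' replicate) carrying `total_reads` and `distal_reads`; `tissue` and
#' `genotype_sampled` columns are optional metadata.  Violations are
#' reported with their row numbers.
#'
#' @param x data frame to check.
#' @param context label used in error messages (e.g. a file name).
#' @return `x`, invisibly, after passing all checks.
#' @export
validate_count_table <- function(x, context = "count table") {
  if (!is.data.frame(x)) stop(context, ": not a data frame")
  missing_cols <- setdiff(count_table_columns, names(x))
  if (length(missing_cols))
    stop(context, ": missing required columns: ",
         paste(missing_cols, collapse = ", "))
  if (nrow(x) == 0L) {
    warning(context, ": table is empty")
    return(invisible(x))
  }
  bad_rows <- function(flag, what) {
    if (any(flag))
      stop(context, ": ", what, " in rows ",
           paste(utils::head(which(flag), 20L), collapse = ", "))
  }
  for (col in c("total_reads", "distal_reads")) {
    v <- x[[col]]
    if (!is.numeric(v)) stop(context, ": column ", col, " is not numeric")
    bad_rows(is.na(v) | v < 0 | v != floor(v),
             paste0("non-integer or negative ", col))
  }
  bad_rows(x$distal_reads > x$total_reads, "distal_reads > total_reads")
  key <- paste(x$transcript_id, x$snp_id, x$replicate_id, sep = "\r")
  bad_rows(duplicated(key), "duplicate (transcript, snp, replicate) key")
  invisible(x)
}

#' Read a count table from delimited text
#'
#' @param path file path; a header row is required.
#' @param dialect `"auto"` (default) sniffs tab versus comma from the header
#'   line, or force `"tsv"` / `"csv"`.
#' @return A validated data frame.
#' @export
read_count_table <- function(path, dialect = c("auto", "tsv", "csv")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  if (dialect == "auto") {
    header <- readLines(path, n = 1L)
    if (length(header) == 0L) stop(path, ": empty file, no header row")
    dialect <- if (grepl("\t", header, fixed = TRUE)) "tsv" else "csv"
  }
  sep <- if (dialect == "tsv") "\t" else ","
  x <- utils::read.table(path, header = TRUE, sep = sep,
                         stringsAsFactors = FALSE, check.names = FALSE)
  validate_count_table(x, context = path)
  x
}

#' Write a count table as delimited text
#'
#' @param x count table (validated before writing).
#' @param path output path.
#' @param dialect `"tsv"` (default) or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_count_table <- function(x, path, dialect = c("tsv", "csv")) {
  dialect <- match.arg(dialect)
  if (nrow(x) > 0L) validate_count_table(x)
  utils::write.table(x, path, sep = if (dialect == "tsv") "\t" else ",",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
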