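#' Configuration for the threshold baselines
#'
#' @param read_threshold distal reads must be strictly above this count for
#'   a replicate to qualify (default 3).
#' @param min_replicates number of qualifying replicates required (default
#'   2 of 3).
#' @param n_replicates expected replicates per SNP (default 3); missing
#'   replicates count as non-qualifying.
#' @return An object of class `"threshold_config"`.
#' @export
threshold_config <- function(read_threshold = 3L, min_replicates = 2L,
                             n_replicates = 3L) {
  if (!is_count(read_threshold)) stop("read_threshold must be a count")
  if (!is_count(min_replicates) || !is_count(n_replicates) ||
      min_replicates < 1 || min_replicates > n_replicates)
    stop("need 1 <= min_replicates <= n_replicates")
  structure(list(read_threshold = as.integer(read_threshold),
                 min_replicates = as.integer(min_replicates),
                 n_replicates = as.integer(n_replicates)),
            class = "threshold_config")
}

#' Method A: absolute read-count threshold baseline
#'
#' A replicate qualifies when its distal read count is strictly above the
#' threshold; a SNP is called when it qualifies in at least
#' `min_replicates` replicates; the transcript is called mobile when any of
#' its SNPs is called (option `aggregate = "all"` requires every SNP).
#' With `unit = "transcript"` the distal counts are first summed over SNPs
#' within each replicate and the rule applied to the sums.
#'
#' @param het_counts count table rows for one transcript (`snp_id`,
#'   `replicate_id`, `distal_reads`).
#' @param config a [threshold_config()].
#' @param aggregate SNP-to-transcript rule, `"any"` (default) or `"all"`.
#' @param unit apply the rule per `"snp"` (default) or to per-replicate
#'   sums over SNPs (`"transcript"`).
#' @return `"mobile"` or `"non-mobile"`.
#' @examples
#' tab <- data.frame(snp_id = "s1", replicate_id = c("R1", "R2", "R3"),
#'                   distal_reads = c(4, 4, 0))
#' method_a(tab)  # qualifies in two of three replicates -> mobile
#' @export
method_a <- function(het_counts, config = threshold_config(),
                     aggregate = c("any", "all"),
                     unit = c("snp", "transcript")) {
  aggregate <- match.arg(aggregate)
  unit <- match.arg(unit)
  stopifnot(inherits(config, "threshold_config"))
  if (nrow(het_counts) == 0L) return("non-mobile")
  if (unit == "transcript") {
    rid <- factor(het_counts$replicate_id)
    sums <- tapply(het_counts$distal_reads, rid, sum)
    het_counts <- data.frame(snp_id = "all",
                             replicate_id = levels(rid),
                             distal_reads = as.numeric(sums),
                             stringsAsFactors = FALSE)
  }
  sid <- factor(het_counts$snp_id)
  n_reps_seen <- tapply(het_counts$replicate_id, sid,
                        function(r) length(unique(r)))
  if (any(n_reps_seen < config$n_replicates))
    message("SNP(s) with fewer than ", config$n_replicates,
            " replicates: missing replicates treated as non-qualifying")
  qualifies <- het_counts$distal_reads > config$read_threshold
  called <- tapply(qualifies, sid, sum) >= config$min_replicates
  hit <- if (aggregate == "any") any(called) else all(called)
  if (hit) "mobile" else "non-mobile"
}

#' Method B: Method A on error-free SNPs only
#'
#' First removes every SNP with any distal read in the (pooled) local
#' homograft data, then applies [method_a()] to the survivors.  SNPs present
#' in the heterograft but absent from the homograft table are excluded.
#' With realistic error rates and read depths the filter removes most SNPs,
#' making the method conservative to the point of missing true mobility.
#'
#' @param hom_counts local homograft rows for the same SNPs (`snp_id`,
#'   `distal_reads`; replicates pooled).
#' @inheritParams method_a
#' @return `"mobile"` or `"non-mobile"`.
#' @export
method_b <- function(hom_counts, het_counts, config = threshold_config(),
                     aggregate = c("any", "all"),
                     unit = c("snp", "transcript")) {
  stopifnot(inherits(config, "threshold_config"))
  if (nrow(het_counts) == 0L) return("non-mobile")
  hom_err <- tapply(hom_counts$distal_reads, hom_counts$snp_id, sum)
  clean <- names(hom_err)[hom_err == 0]
  missing <- setdiff(unique(het_counts$snp_id), names(hom_err))
  if (length(missing))
    message("SNP(s) absent from the homograft table excluded: ",
            paste(missing, collapse = ", "))
  keep <- het_counts$snp_id %in% clean
  if (!any(keep)) return("non-mobile")
  method_a(het_counts[keep, , drop = FALSE], config,
           aggregate = aggregate, unit = unit)
}

# Vectorised whole-table drivers used by the sweeps and the CLI ------------

#' Classify every transcript of a count table with Method A or B
#'
#' @param het heterograft count table.
#' @param hom local homograft count table (Method B only).
#' @param config a [threshold_config()].
#' @param ... passed on to [method_a()] / [method_b()].
#' @return Data frame with `transcript_id`, `label` and `method`, sorted by
#'   transcript.
#' @export
classify_method_a <- function(het, config = threshold_config(), ...) {
  validate_count_table(het, "heterograft table")
  out <- vapply(split(het, het$transcript_id), method_a, character(1),
                config = config, ...)
  data.frame(transcript_id = names(out), label = unname(out),
             method = "method_a", stringsAsFactors = FALSE)
}

#' @rdname classify_method_a
#' @export
classify_method_b <- function(het, hom, config = threshold_config(), ...) {
  validate_count_table(het, "heterograft table")
  validate_count_table(hom, "homograft table")
  hom_split <- split(hom[c("snp_id", "distal_reads")], hom$transcript_id)
  out <- vapply(split(het, het$transcript_id), function(h) {
    hm <- hom_split[[h$transcript_id[1L]]]
    if (is.null(hm))
      hm <- data.frame(snp_id = character(), distal_reads = integer())
    method_b(hm, h, config = config, ...)
  }, character(1))
  data.frame(transcript_id = names(out), label = unname(out),
             method = "method_b", stringsAsFactors = FALSE)
}
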