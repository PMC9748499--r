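#' Configuration for blending two homograft count tables
#'
#' @param blend_proportion p in \[0, 1\]: fraction of the distal table's
#'   distal-genotype reads titrated into the local table, with the local
#'   reads down-sampled to (1 - p) of their depth.
#' @param depth_tolerance maximum allowed factor between the total depths of
#'   a SNP in the two tables for it to be considered comparable (default 2).
#' @param n_bins number of adaptive read-depth bins for downstream
#'   stratified evaluation (default 1 = no stratification).
#' @param seed integer seed for the hypergeometric down-sampling.
#' @return An object of class `"blend_config"`.
#' @export
blend_config <- function(blend_proportion = 0.1, depth_tolerance = 2,
                         n_bins = 1L, seed = 1L) {
  if (!is.numeric(blend_proportion) || blend_proportion < 0 ||
      blend_proportion > 1)
    stop("blend_proportion must be in [0, 1]")
  if (!is.numeric(depth_tolerance) || depth_tolerance < 1)
    stop("depth_tolerance must be >= 1")
  if (!is_count(n_bins) || n_bins < 1) stop("n_bins must be >= 1")
  structure(list(blend_proportion = blend_proportion,
                 depth_tolerance = depth_tolerance,
                 n_bins = as.integer(n_bins), seed = as.integer(seed)),
            class = "blend_config")
}

#' Blend a distal homograft table into a local one
#'
#' Emulates a labelled heterograft built from two real (or synthetic)
#' homograft experiments: for every SNP present in both tables with
#' comparable depth, the local observation is down-sampled to
#' `round((1 - p) * N_local)` reads (hypergeometric subsampling so the
#' distal error counts follow), and `round(p * n_distal)` of the distal
#' table's distal-genotype reads are added as graft-mobile reads.  A
#' transcript is labelled mobile when at least one of its observations
#' received an added read.
#'
#' Rows are matched on `(snp_id, replicate_id)`.  SNPs whose total depths
#' differ by more than `depth_tolerance`-fold are dropped, mirroring the
#' selection of SNPs with comparable read depth between accessions.
#'
#' @param local_table count table providing the background (errors-only)
#'   reads.
#' @param distal_table count table of the other genotype; its
#'   `distal_reads` column holds the reads that map to *its* distal
#'   genotype, i.e. genuine distal-genotype material from the local table's
#'   point of view.
#' @param config a [blend_config()].
#' @return A list with `table` (the blended heterograft count table, plus
#'   an `added_reads` column), `labels` (per transcript) and `config`.
#' @export
blend_datasets <- function(local_table, distal_table,
                           config = blend_config()) {
  stopifnot(inherits(config, "blend_config"))
  validate_count_table(local_table, "local table")
  validate_count_table(distal_table, "distal table")
  key <- function(x) paste(x$snp_id, x$replicate_id, sep = "\r")
  i <- match(key(local_table), key(distal_table))
  keep <- !is.na(i)
  if (!any(keep))
    stop("no shared (snp_id, replicate_id) keys between the two tables")
  loc <- local_table[keep, , drop = FALSE]
  dis <- distal_table[i[keep], , drop = FALSE]

  ratio <- pmax(loc$total_reads, dis$total_reads) /
    pmax(1, pmin(loc$total_reads, dis$total_reads))
  comparable <- ratio <= config$depth_tolerance
  if (!any(comparable))
    stop("no SNPs with comparable read depth (tolerance factor ",
         config$depth_tolerance, ")")
  loc <- loc[comparable, , drop = FALSE]
  dis <- dis[comparable, , drop = FALSE]

  set.seed(config$seed)
  p <- config$blend_proportion
  new_total_local <- as.integer(round_half_away((1 - p) * loc$total_reads))
  # subsample the local reads; the distal (error) reads among the kept ones
  # follow a hypergeometric draw
  kept_distal <- mapply(function(n_dist, n_loc, k) {
    if (k >= n_dist + n_loc) n_dist else rhyper(1L, n_dist, n_loc, k)
  }, loc$distal_reads, loc$total_reads - loc$distal_reads, new_total_local)
  added <- as.integer(round_half_away(p * dis$distal_reads))

  out <- loc
  out$total_reads <- new_total_local + added
  out$distal_reads <- as.integer(kept_distal) + added
  out$added_reads <- added
  rownames(out) <- NULL

  tid <- factor(out$transcript_id)
  labels <- data.frame(
    transcript_id = levels(tid),
    label = ifelse(as.numeric(tapply(added, tid, max)) >= 1,
                   "mobile", "non-mobile"),
    added_reads = as.integer(tapply(added, tid, sum)),
    stringsAsFactors = FALSE)

  list(table = out, labels = labels, config = config)
}

#' Adaptive read-depth binning
#'
#' Splits observations into `n_bins` groups of approximately equal size by
#' total read depth, keeping tied depths in the same bin (so with heavy
#' ties the bin sizes can deviate from equality).
#'
#' @param rows a count table (uses its `total_reads` column) or a numeric
#'   vector of depths.
#' @param n_bins number of bins; must not exceed the number of distinct
#'   depth values.
#' @return Integer vector of bin indices (1 = shallowest), same length and
#'   order as the input.
#' @export
bin_by_depth <- function(rows, n_bins) {
  depths <- if (is.data.frame(rows)) rows$total_reads else rows
  if (!is.numeric(depths) || length(depths) == 0L)
    stop("no depths to bin")
  if (!is_count(n_bins) || length(n_bins) != 1L || n_bins < 1)
    stop("n_bins must be a positive integer")
  vals <- sort(unique(depths))
  if (n_bins > length(vals))
    stop("n_bins (", n_bins, ") exceeds the number of distinct depths (",
         length(vals), ")")
  counts <- tabulate(match(depths, vals))
  bin_of_val <- integer(length(vals))
  bin <- 1L
  filled <- 0L
  remaining <- length(depths)
  for (v in seq_along(vals)) {
    bin_of_val[v] <- bin
    filled <- filled + counts[v]
    remaining <- remaining - counts[v]
    # close the bin once it reached its fair share of what is left
    if (bin < n_bins &&
        filled >= remaining / (n_bins - bin) &&
        (length(vals) - v) >= (n_bins - bin)) {
      bin <- bin + 1L
      filled <- 0L
    }
  }
  bin_of_val[match(depths, vals)]
}
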