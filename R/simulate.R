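#' Configuration for the binomial read-count simulator
#'
#' Describes one simulated grafting experiment: homograft reference tables
#' for both genotypes and a heterograft table in which half the transcripts
#' carry `mobile_reads` distal-origin reads per SNP and replicate.
#'
#' @param error_rate q, the per-read probability of being observed as the
#'   other genotype (sequencing plus mapping error), in \[0, 1\].
#' @param homograft_depth reads per SNP per replicate in the homograft
#'   reference tables (N_hom).
#' @param heterograft_depth local-origin reads per SNP per replicate in the
#'   heterograft table (N); mobile reads are added on top, so a mobile
#'   transcript's total depth is N + N2.
#' @param mobile_reads N2, the number of distal-origin reads added per SNP
#'   and replicate for transcripts in the mobile arm.
#' @param snps_per_transcript,replicates,n_transcripts cohort dimensions.
#' @param seed integer seed recorded in all outputs.
#' @param mobile_reads_with_errors if `TRUE`, the added mobile reads are
#'   themselves subject to the error rate (a mobile read is observed as
#'   local with probability q), for use with the two-rate inference model.
#'   The default `FALSE` observes mobile reads as distal, error-free.
#' @return An object of class `"simulation_config"`.
#' @export
simulation_config <- function(error_rate = 0.01, homograft_depth = 1000,
                              heterograft_depth = 1000, mobile_reads = 10,
                              snps_per_transcript = 3, replicates = 3,
                              n_transcripts = 100, seed = 1L,
                              mobile_reads_with_errors = FALSE) {
  if (!is.numeric(error_rate) || error_rate < 0 || error_rate > 1)
    stop("error_rate must be in [0, 1]")
  counts <- c(homograft_depth, heterograft_depth, mobile_reads,
              snps_per_transcript, replicates, n_transcripts)
  if (!is_count(counts)) stop("all counts must be non-negative integers")
  if (snps_per_transcript < 1 || replicates < 1 || n_transcripts < 1)
    stop("snps_per_transcript, replicates and n_transcripts must be >= 1")
  structure(list(error_rate = error_rate,
                 homograft_depth = as.integer(homograft_depth),
                 heterograft_depth = as.integer(heterograft_depth),
                 mobile_reads = as.integer(mobile_reads),
                 snps_per_transcript = as.integer(snps_per_transcript),
                 replicates = as.integer(replicates),
                 n_transcripts = as.integer(n_transcripts),
                 seed = as.integer(seed),
                 mobile_reads_with_errors = isTRUE(mobile_reads_with_errors)),
            class = "simulation_config")
}

# One binomial draw realised read by read: a uniform number per read, the
# read is assigned to the local genotype when the draw exceeds q, otherwise
# to the distal genotype.
draw_distal_errors <- function(N, q) {
  if (N == 0L) return(0L)
  sum(runif(N) <= q)
}

#' Simulate one homograft SNP
#'
#' Every read is an independent two-outcome event: with probability q it is
#' mis-assigned to the other genotype.  Uses the R random number generator;
#' set a seed (or pass `seed`) for reproducibility.
#'
#' @param N read depth.
#' @param q error rate in \[0, 1\].
#' @param seed optional integer seed applied before drawing.
#' @param ... metadata passed to [snp_counts()].
#' @return A [snp_counts()] observation with `distal_reads ~ Binomial(N, q)`.
#' @export
simulate_homograft_snp <- function(N, q, seed = NULL, ...) {
  if (!is.numeric(q) || length(q) != 1L || is.na(q) || q < 0 || q > 1)
    stop("q must be in [0, 1]")
  if (!is_count(N)) stop("N must be a non-negative integer")
  if (!is.null(seed)) set.seed(seed)
  snp_counts(N, draw_distal_errors(N, q), ...)
}

#' Simulate one heterograft SNP
#'
#' As [simulate_homograft_snp()], with `N2` further reads from the distal
#' genotype added on top: total depth `N + N2`, distal count
#' `Binomial(N, q) + N2` (or `Binomial(N, q) + N2 - Binomial(N2, q)` when
#' mobile reads are themselves subject to errors).
#'
#' @inheritParams simulate_homograft_snp
#' @param N2 number of distal-origin (mobile) reads added.
#' @param mobile_reads_with_errors see [simulation_config()].
#' @return A [snp_counts()] observation.
#' @export
simulate_heterograft_snp <- function(N, q, N2, seed = NULL,
                                     mobile_reads_with_errors = FALSE, ...) {
  if (!is_count(N2)) stop("N2 must be a non-negative integer")
  if (!is.numeric(q) || length(q) != 1L || is.na(q) || q < 0 || q > 1)
    stop("q must be in [0, 1]")
  if (!is_count(N)) stop("N must be a non-negative integer")
  if (!is.null(seed)) set.seed(seed)
  n_err <- draw_distal_errors(N, q)
  n_mobile <- if (mobile_reads_with_errors) N2 - draw_distal_errors(N2, q)
              else N2
  snp_counts(N + N2, n_err + n_mobile, ...)
}

#' Simulate a labelled homograft/heterograft cohort
#'
#' Generates the three count tables of a grafting experiment with known
#' truth: homograft references for the local genotype ("A") and the distal
#' genotype ("B"), and a heterograft table sampled from genotype A tissue in
#' which exactly half of the transcripts carry `mobile_reads` distal reads
#' per SNP and replicate (balanced positive/negative arms).  All tables
#' share SNP identifiers, and the seed makes the cohort bit-reproducible.
#'
#' @param config a [simulation_config()]; `n_transcripts` must be even.
#' @return A list of class `"graft_cohort"` with elements `heterograft`,
#'   `homograft_local`, `homograft_distal` (count tables), `truth`
#'   (`transcript_id`, `label`, `N2`) and `config`.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  if (config$n_transcripts %% 2L != 0L)
    stop("n_transcripts must be even for a balanced cohort")
  set.seed(config$seed)

  nt <- config$n_transcripts
  tids <- sprintf("T%05d", seq_len(nt))
  mobile <- rep(c(TRUE, FALSE), each = nt %/% 2L)
  n2 <- ifelse(mobile, config$mobile_reads, 0L)

  grid <- expand.grid(
    replicate_id = sprintf("R%d", seq_len(config$replicates)),
    snp = seq_len(config$snps_per_transcript),
    t = seq_len(nt), KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid$transcript_id <- tids[grid$t]
  grid$snp_id <- sprintf("%s_S%d", grid$transcript_id, grid$snp)
  grid$N2 <- n2[grid$t]
  nr <- nrow(grid)
  q <- config$error_rate

  hom_table <- function(genotype) {
    data.frame(
      transcript_id = grid$transcript_id, snp_id = grid$snp_id,
      replicate_id = grid$replicate_id, tissue = "scion",
      genotype_sampled = genotype,
      total_reads = rep(config$homograft_depth, nr),
      distal_reads = vapply(seq_len(nr), function(i)
        draw_distal_errors(config$homograft_depth, q), integer(1)),
      stringsAsFactors = FALSE)
  }
  hom_local <- hom_table("A")
  hom_distal <- hom_table("B")

  n_err <- vapply(seq_len(nr), function(i)
    draw_distal_errors(config$heterograft_depth, q), integer(1))
  n_mob <- if (config$mobile_reads_with_errors) {
    grid$N2 - vapply(seq_len(nr), function(i)
      draw_distal_errors(grid$N2[i], q), integer(1))
  } else grid$N2
  het <- data.frame(
    transcript_id = grid$transcript_id, snp_id = grid$snp_id,
    replicate_id = grid$replicate_id, tissue = "scion",
    genotype_sampled = "A",
    total_reads = config$heterograft_depth + grid$N2,
    distal_reads = n_err + n_mob, stringsAsFactors = FALSE)

  truth <- data.frame(
    transcript_id = tids,
    label = ifelse(mobile, "mobile", "non-mobile"),
    N2 = n2, seed = config$seed, stringsAsFactors = FALSE)

  structure(list(heterograft = het, homograft_local = hom_local,
                 homograft_distal = hom_distal, truth = truth,
                 config = config),
            class = "graft_cohort")
}

#' @export
print.graft_cohort <- function(x, ...) {
  cat(sprintf(
    "<graft_cohort> %d transcripts (balanced), %d SNP(s) x %d replicate(s); q=%g, N_hom=%d, N=%d, N2=%d, seed=%d\n",
    x$config$n_transcripts, x$config$snps_per_transcript,
    x$config$replicates, x$config$error_rate, x$config$homograft_depth,
    x$config$heterograft_depth, x$config$mobile_reads, x$config$seed))
  invisible(x)
}
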