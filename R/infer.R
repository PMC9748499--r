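#' Score every transcript in a heterograft count table
#'
#' The table-level driver: pools homograft replicates into one error-rate
#' posterior per SNP, computes the per-SNP, per-replicate log10 Bayes factor
#' for every heterograft observation, and sums the evidence per transcript.
#' With both homograft references the two-error-rate model is used (errors
#' in the local reads *and* back-errors in the distal reads); without a
#' distal reference the single-rate model applies and a warning is issued.
#'
#' SNPs present in the heterograft but absent from a homograft reference
#' fall back to the prior-only posterior (with a warning): they contribute
#' weak evidence rather than silently disappearing.  Zero-depth rows
#' contribute a log BF of exactly 0.
#'
#' @param het heterograft count table (see [validate_count_table()]).
#' @param hom_local homograft count table of the sampled (local) genotype,
#'   same tissue.
#' @param hom_distal homograft count table of the distal genotype, same
#'   tissue, or `NULL` for the single-error-rate model.
#' @param prior [prior_hyperparameters()] for the error rates.
#' @param threshold log10 BF classification threshold (default 1).
#' @return A data frame, one row per transcript sorted by `transcript_id`,
#'   with `n_snps`, `n_obs`, `total_log_bf`, `mean_expected_n2`, `mean_r2`
#'   (averages over SNP/replicate observations) and `label`.  The per-SNP
#'   contributions are attached as `attr(, "contributions")`.
#' @export
infer_mobility <- function(het, hom_local, hom_distal = NULL,
                           prior = prior_hyperparameters(), threshold = 1) {
  validate_count_table(het, "heterograft table")
  validate_count_table(hom_local, "local homograft table")
  two_rate <- !is.null(hom_distal)
  if (two_rate) {
    validate_count_table(hom_distal, "distal homograft table")
  } else {
    warning("no distal homograft reference supplied: ",
            "falling back to the single-error-rate model")
  }
  if (nrow(het) == 0L) stop("heterograft table has no rows")

  loc <- pool_by_snp(hom_local, prior)
  dist <- if (two_rate) pool_by_snp(hom_distal, prior) else NULL

  i_loc <- match(het$snp_id, loc$snp_id)
  if (anyNA(i_loc))
    warning("SNP(s) missing from the local homograft reference, ",
            "using the prior alone: ",
            paste(unique(het$snp_id[is.na(i_loc)]), collapse = ", "))
  a1 <- ifelse(is.na(i_loc), prior$u1, loc$alpha[i_loc])
  b1 <- ifelse(is.na(i_loc), prior$u2, loc$beta[i_loc])
  if (two_rate) {
    i_dist <- match(het$snp_id, dist$snp_id)
    if (anyNA(i_dist))
      warning("SNP(s) missing from the distal homograft reference, ",
              "using the prior alone: ",
              paste(unique(het$snp_id[is.na(i_dist)]), collapse = ", "))
    a2 <- ifelse(is.na(i_dist), prior$u1, dist$alpha[i_dist])
    b2 <- ifelse(is.na(i_dist), prior$u2, dist$beta[i_dist])
  }

  nr <- nrow(het)
  log_bf <- expected_n2 <- r2 <- numeric(nr)
  for (i in seq_len(nr)) {
    ev <- snp_evidence_counts(het$total_reads[i], het$distal_reads[i],
                              a1[i], b1[i],
                              if (two_rate) a2[i] else NULL,
                              if (two_rate) b2[i] else NULL)
    log_bf[i] <- ev[["log_bf"]]
    expected_n2[i] <- ev[["expected_n2"]]
    r2[i] <- ev[["r2"]]
  }
  if (any(het$total_reads == 0L))
    message(sum(het$total_reads == 0L),
            " zero-depth observation(s) contribute log BF 0")

  contributions <- data.frame(
    transcript_id = het$transcript_id, snp_id = het$snp_id,
    replicate_id = het$replicate_id, total_reads = het$total_reads,
    distal_reads = het$distal_reads, log_bf = log_bf,
    expected_n2 = expected_n2, r2 = r2, stringsAsFactors = FALSE)

  tid <- factor(het$transcript_id)
  out <- data.frame(
    transcript_id = levels(tid),
    n_snps = as.integer(tapply(het$snp_id, tid,
                               function(s) length(unique(s)))),
    n_obs = as.integer(table(tid)),
    total_log_bf = as.numeric(tapply(log_bf, tid, sum)),
    mean_expected_n2 = as.numeric(tapply(expected_n2, tid, mean)),
    mean_r2 = as.numeric(tapply(r2, tid, mean)),
    stringsAsFactors = FALSE)
  out$label <- ifelse(out$total_log_bf >= threshold, "mobile", "non-mobile")
  out <- out[order(out$transcript_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "contributions") <- contributions
  attr(out, "threshold") <- threshold
  attr(out, "model") <- if (two_rate) "two_rate" else "single_rate"
  out
}

# One pooled Beta posterior per SNP (replicates add their counts).
pool_by_snp <- function(tab, prior) {
  if (nrow(tab) == 0L)
    return(data.frame(snp_id = character(), alpha = numeric(),
                      beta = numeric(), stringsAsFactors = FALSE))
  sid <- factor(tab$snp_id)
  n_sum <- as.numeric(tapply(tab$distal_reads, sid, sum))
  N_sum <- as.numeric(tapply(tab$total_reads, sid, sum))
  data.frame(snp_id = levels(sid),
             alpha = prior$u1 + n_sum,
             beta = prior$u2 + (N_sum - n_sum),
             stringsAsFactors = FALSE)
}
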