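#' Prior hyperparameters for the error-rate Beta prior
#'
#' The per-SNP error rate theta (probability that a read from the local
#' genotype is observed as distal) gets a conjugate Beta(u1, u2) prior.  The
#' default u1 = u2 = 1 is the flat, non-informative choice; with growing
#' homograft read depth the prior loses relevance.
#'
#' @param u1,u2 positive shape hyperparameters.
#' @return An object of class `"prior_hyperparameters"`.
#' @export
prior_hyperparameters <- function(u1 = 1, u2 = 1) {
  if (!is.numeric(u1) || !is.numeric(u2) || length(u1) != 1L ||
      length(u2) != 1L || is.na(u1) || is.na(u2) || u1 <= 0 || u2 <= 0)
    stop("u1 and u2 must be positive reals")
  structure(list(u1 = as.numeric(u1), u2 = as.numeric(u2)),
            class = "prior_hyperparameters")
}

#' Construct an error-rate posterior directly from shape parameters
#'
#' Mostly useful for tests and for replaying published configurations; in an
#' analysis the posterior comes from [fit_error_posterior()].
#'
#' @param alpha,beta positive Beta shape parameters of the posterior.
#' @param snp_id,tissue,genotype optional provenance metadata.
#' @param prior the [prior_hyperparameters()] the posterior was built from.
#' @return An object of class `"error_posterior"` with elements `alpha`,
#'   `beta`, `snp_id`, `tissue`, `genotype` and `prior`.
#' @export
error_posterior <- function(alpha, beta, snp_id = NA_character_,
                            tissue = NA_character_, genotype = NA_character_,
                            prior = prior_hyperparameters()) {
  if (!is.numeric(alpha) || !is.numeric(beta) || alpha <= 0 || beta <= 0)
    stop("alpha and beta must be positive")
  if (alpha < prior$u1 || beta < prior$u2)
    stop("posterior shapes cannot be below the prior hyperparameters ",
         "(counts only add)")
  if (!is.na(tissue)) tissue <- match.arg(tissue, c("scion", "stock"))
  structure(
    list(snp_id = as.character(snp_id), tissue = as.character(tissue),
         genotype = as.character(genotype),
         alpha = as.numeric(alpha), beta = as.numeric(beta), prior = prior),
    class = "error_posterior")
}

#' @export
print.error_posterior <- function(x, ...) {
  cat(sprintf(
    "<error_posterior> Beta(%.6g, %.6g)  mean=%.4g  snp=%s tissue=%s genotype=%s\n",
    x$alpha, x$beta, posterior_mean(x), x$snp_id, x$tissue, x$genotype))
  invisible(x)
}

#' Posterior mean of an error-rate posterior
#'
#' @param x an `error_posterior`.
#' @return `alpha / (alpha + beta)`, the expected error rate `<theta>`.
#' @export
posterior_mean <- function(x) {
  stopifnot(inherits(x, "error_posterior"))
  x$alpha / (x$alpha + x$beta)
}

#' Infer a SNP-specific error-rate posterior from homograft counts
#'
#' In a homograft every read mapping to the other genotype is an error, so
#' the distal counts are binomial draws with the unknown error rate theta.
#' Conjugate updating of the Beta prior gives the exact posterior
#' `Beta(u1 + sum(n), u2 + sum(N - n))`.  Replicates simply add their counts:
#' the result does not depend on how the data are split or ordered.
#'
#' @param counts data frame with columns `total_reads` and `distal_reads`
#'   (one row per replicate), a single [snp_counts()] object, or a list of
#'   them.  All rows must belong to one SNP; if a `snp_id` column is present
#'   this is enforced.  An empty input is allowed and returns the prior with
#'   a low-information warning.
#' @param prior [prior_hyperparameters()]; flat Beta(1, 1) by default.
#' @param snp_id,tissue,genotype metadata for the returned posterior; taken
#'   from `counts` when available.
#' @return An [error_posterior()].
#' @examples
#' fit_error_posterior(data.frame(total_reads = 100, distal_reads = 3))
#' # identical to two replicates carrying the same pooled counts:
#' fit_error_posterior(data.frame(total_reads = c(50, 50), distal_reads = c(1, 2)))
#' @export
fit_error_posterior <- function(counts, prior = prior_hyperparameters(),
                                snp_id = NULL, tissue = NA_character_,
                                genotype = NA_character_) {
  if (inherits(counts, "snp_counts")) counts <- list(counts)
  if (is.list(counts) && !is.data.frame(counts) &&
      all(vapply(counts, inherits, logical(1), "snp_counts"))) {
    counts <- data.frame(
      snp_id = vapply(counts, `[[`, character(1), "snp_id"),
      total_reads = vapply(counts, `[[`, integer(1), "total_reads"),
      distal_reads = vapply(counts, `[[`, integer(1), "distal_reads"),
      stringsAsFactors = FALSE)
  }
  if (!is.data.frame(counts))
    stop("counts must be a data frame or snp_counts object(s)")
  if (nrow(counts) == 0L) {
    warning("no homograft observations: posterior equals the prior ",
            "(low information)")
    return(error_posterior(prior$u1, prior$u2, snp_id = snp_id %||% NA,
                           tissue = tissue, genotype = genotype,
                           prior = prior))
  }
  if (!is_count(counts$total_reads) || !is_count(counts$distal_reads) ||
      any(counts$distal_reads > counts$total_reads))
    stop("invalid counts: need integer 0 <= distal_reads <= total_reads")
  if (!is.null(counts$snp_id)) {
    ids <- unique(counts$snp_id)
    if (length(ids) > 1L)
      stop("counts span multiple SNPs: ", paste(ids, collapse = ", "))
    snp_id <- snp_id %||% ids
  }
  error_posterior(prior$u1 + sum(counts$distal_reads),
                  prior$u2 + sum(counts$total_reads - counts$distal_reads),
                  snp_id = snp_id %||% NA, tissue = tissue,
                  genotype = genotype, prior = prior)
}

#' Beta-binomial log probability mass
#'
#' Marginal probability of `k` successes in `m` binomial trials when the
#' success probability is Beta(alpha, beta) distributed:
#' `C(m, k) * B(k + alpha, m - k + beta) / B(alpha, beta)`, computed via
#' log-gamma.  Vectorised over `k` and `m`.
#'
#' @param k successes, `0 <= k <= m`.
#' @param m number of trials.
#' @param alpha,beta positive shape parameters.
#' @return log probability (base e).
#' @export
log_beta_binomial <- function(k, m, alpha, beta) {
  if (!is_count(k) || !is_count(m) || any(k > m))
    stop("require integer 0 <= k <= m")
  if (any(alpha <= 0) || any(beta <= 0)) stop("alpha, beta must be > 0")
  lchoose(m, k) + lbeta(k + alpha, m - k + beta) - lbeta(alpha, beta)
}

#' Posterior over the number of distal-origin reads at one SNP
#'
#' Of the N reads covering a heterograft SNP, an unknown number N2 genuinely
#' originate from distal-genotype transcripts.  Under a uniform prior on
#' N2 in \{0, ..., N\} the posterior is the normalised likelihood
#' `P(n | N2)`, where the observed distal count n is the sum of errors among
#' the N - N2 local reads (rate theta1, Beta-distributed per the local
#' homograft posterior) and of distal reads observed as distal.  With a
#' distal error posterior supplied (the default two-rate model inside
#' [infer_mobility()]), a distal read is observed as distal with probability
#' 1 - theta2 and the likelihood is a convolution of two beta-binomial
#' terms; without one, distal reads are always observed as distal
#' (theta2 = 0), mirroring the simulator in [simulate_heterograft_snp()].
#'
#' @param het heterograft observation: a [snp_counts()] object or anything
#'   coercible (a single-row data frame or a list with `total_reads` and
#'   `distal_reads`).
#' @param local_error [error_posterior()] of the sampled (local) genotype,
#'   matching tissue.
#' @param distal_error optional [error_posterior()] of the distal genotype,
#'   matching tissue; `NULL` selects the single-error-rate model.
#' @return An object of class `"mobile_posterior"`: `probabilities` (vector
#'   over N2 = 0..N), `log_probabilities`, `expected_n2` (`<N2>`), `ratio_r2`
#'   (`<N2>/N`), `total_reads`, `distal_reads`, `model`.
#' @examples
#' post <- posterior_over_n2(snp_counts(2, 1), error_posterior(1, 1))
#' post$probabilities              # 2/5, 3/5, 0
#' snp_log_bf(post)                # log10(1.5)
#' @export
posterior_over_n2 <- function(het, local_error, distal_error = NULL) {
  het <- as_snp_counts(het)
  stopifnot(inherits(local_error, "error_posterior"))
  two_rate <- !is.null(distal_error)
  if (two_rate) {
    stopifnot(inherits(distal_error, "error_posterior"))
    check_pairing(het, local_error, distal_error)
  } else {
    check_pairing(het, local_error, NULL)
  }
  N <- het$total_reads
  n <- het$distal_reads
  if (N == 0L) {
    warning("SNP ", het$snp_id, ": zero read depth, degenerate posterior ",
            "P(N2 = 0) = 1")
    ll <- 0
  } else {
    ll <- .bb_n2_loglik(N, n, local_error$alpha, local_error$beta,
                        if (two_rate) distal_error$alpha else 1,
                        if (two_rate) distal_error$beta else 1,
                        two_rate)
  }
  lp <- ll - log_sum_exp(ll)
  probs <- exp(lp)
  n2 <- seq_along(probs) - 1
  expected_n2 <- sum(n2 * probs)
  structure(
    list(probabilities = probs, log_probabilities = lp,
         expected_n2 = expected_n2,
         ratio_r2 = if (N > 0) expected_n2 / N else 0,
         total_reads = N, distal_reads = n,
         model = if (two_rate) "two_rate" else "single_rate",
         snp_id = het$snp_id, replicate_id = het$replicate_id),
    class = "mobile_posterior")
}

# Reject mismatched tissue/genotype combinations between the heterograft
# observation and the homograft posteriors.  Fields left NA are not checked.
check_pairing <- function(het, local_error, distal_error) {
  chk <- function(cond, msg) if (isTRUE(cond)) stop(msg)
  if (!is.na(het$tissue) && !is.na(local_error$tissue))
    chk(het$tissue != local_error$tissue,
        "local error posterior tissue does not match the heterograft sample")
  if (!is.na(het$genotype) && !is.na(local_error$genotype))
    chk(het$genotype != local_error$genotype,
        "local error posterior genotype does not match the sampled genotype")
  if (!is.na(het$snp_id) && !is.na(local_error$snp_id))
    chk(het$snp_id != local_error$snp_id,
        "local error posterior belongs to a different SNP")
  if (!is.null(distal_error)) {
    if (!is.na(het$tissue) && !is.na(distal_error$tissue))
      chk(het$tissue != distal_error$tissue,
          "distal error posterior tissue does not match the heterograft sample")
    if (!is.na(distal_error$genotype) && !is.na(local_error$genotype))
      chk(distal_error$genotype == local_error$genotype,
          "local and distal error posteriors share a genotype")
    if (!is.na(het$snp_id) && !is.na(distal_error$snp_id))
      chk(het$snp_id != distal_error$snp_id,
          "distal error posterior belongs to a different SNP")
  }
  invisible(TRUE)
}

#' @export
print.mobile_posterior <- function(x, ...) {
  cat(sprintf(
    "<mobile_posterior> N=%d n=%d model=%s  <N2>=%.4g  r2=%.4g\n",
    x$total_reads, x$distal_reads, x$model, x$expected_n2, x$ratio_r2))
  invisible(x)
}

#' Per-SNP log10 Bayes factor for graft mobility
#'
#' Under a uniform prior every value of N2 has the same prior mass, so the
#' posterior odds of the best-supported mobile explanation against the
#' errors-only explanation equal the Bayes factor:
#' `log10( max_{N2 > 0} P(N2 | D) / P(N2 = 0 | D) )`.  Positive values
#' favour the presence of distal-origin reads, negative values favour
#' errors only; a zero read depth carries no evidence either way.  If the
#' maximum over N2 > 0 exactly ties P(N2 = 0 | D) the function returns 0.
#'
#' @param post a [posterior_over_n2()] result.
#' @return log10 Bayes factor (may be `-Inf` under the single-rate model
#'   when n = 0, where any N2 > 0 is impossible).
#' @export
snp_log_bf <- function(post) {
  stopifnot(inherits(post, "mobile_posterior"))
  lp <- post$log_probabilities
  if (length(lp) == 1L) return(0)      # N = 0: no evidence either way
  if (!is.finite(lp[1L]))
    stop("invalid posterior: P(N2 = 0) must be strictly positive")
  best <- max(lp[-1L])
  if (best == lp[1L]) return(0)
  (best - lp[1L]) / log(10)
}

# Fast path used by infer_mobility(): log10 BF, <N2> and r2 straight from
# counts and shape parameters, skipping object construction.
snp_evidence_counts <- function(N, n, a1, b1, a2 = NULL, b2 = NULL) {
  if (N == 0L)
    return(c(log_bf = 0, expected_n2 = 0, r2 = 0))
  two_rate <- !is.null(a2)
  ll <- .bb_n2_loglik(N, n, a1, b1, a2 %||% 1, b2 %||% 1, two_rate)
  lp <- ll - log_sum_exp(ll)
  probs <- exp(lp)
  en2 <- sum((seq_along(probs) - 1) * probs)
  best <- max(lp[-1L])
  lbf <- if (best == lp[1L]) 0 else (best - lp[1L]) / log(10)
  c(log_bf = lbf, expected_n2 = en2, r2 = en2 / N)
}

#' Combine per-SNP, per-replicate evidence into a transcript call
#'
#' Independence of the parameters across SNPs lets the transcript-level
#' Bayes factor factorise: the total log10 BF is the plain sum of the
#' per-SNP (and per-replicate) contributions.  A transcript is labelled
#' mobile when the total reaches the threshold (default 1, i.e. 10:1 odds,
#' "substantial" evidence); totals at or below minus the threshold are
#' additionally flagged as confidently non-mobile.
#'
#' @param contributions named numeric vector of per-(SNP, replicate) log10
#'   Bayes factors; must be non-empty (a transcript with no SNP data is
#'   unclassifiable, not non-mobile).
#' @param threshold classification threshold on the total log10 BF.
#' @param transcript_id optional identifier.
#' @return An object of class `"transcript_evidence"` with `contributions`,
#'   `total_log_bf`, `label` (`"mobile"`/`"non-mobile"`) and
#'   `confident_non_mobile`.
#' @examples
#' transcript_log_bf(c(s1 = 0.5, s2 = 0.7))   # total 1.2 -> mobile
#' transcript_log_bf(c(s1 = 1.5, s2 = -2.0))  # one deviant SNP outvoted
#' @export
transcript_log_bf <- function(contributions, threshold = 1,
                              transcript_id = NA_character_) {
  if (length(contributions) == 0L)
    stop("no contributions: a transcript without SNP data is unclassifiable")
  if (!is.numeric(contributions) || anyNA(contributions))
    stop("contributions must be numeric and non-missing")
  total <- sum(contributions)
  structure(
    list(transcript_id = as.character(transcript_id),
         contributions = contributions, total_log_bf = total,
         threshold = threshold,
         label = if (total >= threshold) "mobile" else "non-mobile",
         confident_non_mobile = total <= -threshold),
    class = "transcript_evidence")
}

#' @export
print.transcript_evidence <- function(x, ...) {
  cat(sprintf("<transcript_evidence> %s: total log10 BF = %.4f over %d SNP/replicate terms -> %s\n",
              x$transcript_id, x$total_log_bf, length(x$contributions),
              x$label))
  invisible(x)
}
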