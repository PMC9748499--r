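#' Confusion table for a labelled cohort
#'
#' Compares predicted against true mobility labels transcript by
#' transcript.  Rates with an empty denominator are reported as `NA`
#' (not applicable), never as 0.
#'
#' @param truth,predicted data frames with `transcript_id` and `label`
#'   columns (`"mobile"`/`"non-mobile"`, or logicals), or named
#'   logical/character vectors keyed by transcript.  The two key sets must
#'   match exactly.
#' @return An object of class `"confusion_table"` with counts `tp`, `fp`,
#'   `tn`, `fn` and rates `tpr` = TP/(TP+FN), `fpr` = FP/(FP+TN),
#'   `accuracy` = (TP+TN)/(TP+TN+FP+FN).
#' @examples
#' truth <- data.frame(transcript_id = c("t1", "t2"),
#'                     label = c("mobile", "non-mobile"))
#' confusion(truth, truth)  # perfect
#' @export
confusion <- function(truth, predicted) {
  tr <- as_label_vector(truth, "truth")
  pr <- as_label_vector(predicted, "predicted")
  only_tr <- setdiff(names(tr), names(pr))
  only_pr <- setdiff(names(pr), names(tr))
  if (length(only_tr) || length(only_pr))
    stop("transcript keys differ between truth and predictions; ",
         "only in truth: {", paste(utils::head(only_tr, 10), collapse = ", "),
         "}; only in predictions: {",
         paste(utils::head(only_pr, 10), collapse = ", "), "}")
  pr <- pr[names(tr)]
  tp <- sum(tr & pr); fn <- sum(tr & !pr)
  fp <- sum(!tr & pr); tn <- sum(!tr & !pr)
  rate <- function(num, den) if (den > 0) num / den else NA_real_
  structure(list(tp = tp, fp = fp, tn = tn, fn = fn,
                 tpr = rate(tp, tp + fn), fpr = rate(fp, fp + tn),
                 accuracy = rate(tp + tn, tp + tn + fp + fn)),
            class = "confusion_table")
}

# Accept labelled data frames or named vectors; return named logical.
as_label_vector <- function(x, what) {
  if (is.data.frame(x)) {
    if (is.null(x$transcript_id) || is.null(x$label))
      stop(what, ": need transcript_id and label columns")
    v <- x$label
    names(v) <- x$transcript_id
    x <- v
  }
  if (is.null(names(x)) || anyNA(names(x)))
    stop(what, ": labels must be keyed by transcript_id")
  if (anyDuplicated(names(x)))
    stop(what, ": duplicate transcript keys")
  if (is.character(x) || is.factor(x)) {
    nm <- names(x)
    x <- as.character(x)
    bad <- !x %in% c("mobile", "non-mobile")
    if (any(bad)) stop(what, ": labels must be 'mobile' or 'non-mobile'")
    out <- x == "mobile"
    names(out) <- nm
    return(out)
  }
  if (is.logical(x)) return(x)
  stop(what, ": cannot interpret labels")
}

#' @export
print.confusion_table <- function(x, ...) {
  cat(sprintf(
    "<confusion_table> TP=%d FP=%d TN=%d FN=%d | TPR=%s FPR=%s accuracy=%s\n",
    x$tp, x$fp, x$tn, x$fn, fmt_rate(x$tpr), fmt_rate(x$fpr),
    fmt_rate(x$accuracy)))
  invisible(x)
}

fmt_rate <- function(r) if (is.na(r)) "n/a" else sprintf("%.4f", r)

confusion_row <- function(ct) {
  data.frame(tp = ct$tp, fp = ct$fp, tn = ct$tn, fn = ct$fn,
             tpr = ct$tpr, fpr = ct$fpr, accuracy = ct$accuracy)
}

# Run one simulated cohort through the requested classifiers.
classify_cohort <- function(cohort, methods, threshold = 1,
                            thr_config = threshold_config()) {
  out <- list()
  for (m in methods) {
    pred <- switch(
      m,
      bayes = {
        res <- infer_mobility(cohort$heterograft, cohort$homograft_local,
                              cohort$homograft_distal, threshold = threshold)
        data.frame(transcript_id = res$transcript_id, label = res$label,
                   stringsAsFactors = FALSE)
      },
      method_a = classify_method_a(cohort$heterograft, thr_config),
      method_b = classify_method_b(cohort$heterograft,
                                   cohort$homograft_local, thr_config),
      stop("unknown method: ", m))
    out[[m]] <- confusion(cohort$truth, pred)
  }
  out
}

#' Benchmark sweep over read depth
#'
#' For each depth in the grid, simulates a balanced cohort and scores each
#' classifier, recording one confusion table per (method, depth).  Both
#' panels of the depth-dependence benchmark are covered: homograft depth
#' tracking the heterograft depth (`hom_depth = NULL`, default) or held
#' fixed (`hom_depth = 1000`).  A failing grid point is recorded with `NA`
#' metrics and the sweep continues.
#'
#' @param depths integer vector of heterograft read depths N.
#' @param config base [simulation_config()]; its depths are overridden per
#'   grid point and its seed is the master seed from which per-point seeds
#'   are derived deterministically.
#' @param methods subset of `c("bayes", "method_a", "method_b")`.
#' @param hom_depth fixed homograft depth, or `NULL` for N_hom = N.
#' @param mobile_reads per-point N2: a fixed count, or a function of N
#'   (e.g. `function(N) round(5 * 0.01 * N)`); `NULL` keeps
#'   `config$mobile_reads`.
#' @param threshold log10 BF threshold for the Bayesian classifier.
#' @param thr_config [threshold_config()] for the baselines.
#' @return Tidy data frame: method, N, N_hom, q, N2, n_transcripts, tp, fp,
#'   tn, fn, tpr, fpr, accuracy, seed.
#' @export
run_depth_sweep <- function(depths, config = simulation_config(),
                            methods = c("bayes", "method_a", "method_b"),
                            hom_depth = NULL, mobile_reads = NULL,
                            threshold = 1,
                            thr_config = threshold_config()) {
  if (length(depths) == 0L) stop("empty depth grid")
  rows <- list()
  for (i in seq_along(depths)) {
    N <- as.integer(depths[i])
    n2 <- if (is.null(mobile_reads)) config$mobile_reads
          else if (is.function(mobile_reads)) as.integer(mobile_reads(N))
          else as.integer(mobile_reads)
    cfg <- simulation_config(
      error_rate = config$error_rate,
      homograft_depth = if (is.null(hom_depth)) N else as.integer(hom_depth),
      heterograft_depth = N, mobile_reads = n2,
      snps_per_transcript = config$snps_per_transcript,
      replicates = config$replicates,
      n_transcripts = config$n_transcripts,
      seed = derive_seed(config$seed, i),
      mobile_reads_with_errors = config$mobile_reads_with_errors)
    point <- tryCatch({
      cohort <- simulate_cohort(cfg)
      cts <- classify_cohort(cohort, methods, threshold, thr_config)
      do.call(rbind, lapply(names(cts), function(m)
        cbind(data.frame(method = m, stringsAsFactors = FALSE),
              confusion_row(cts[[m]]))))
    }, error = function(e) {
      warning("grid point N=", N, " failed: ", conditionMessage(e))
      data.frame(method = methods, tp = NA_integer_, fp = NA_integer_,
                 tn = NA_integer_, fn = NA_integer_, tpr = NA_real_,
                 fpr = NA_real_, accuracy = NA_real_)
    })
    point <- cbind(point[, "method", drop = FALSE],
                   N = N, N_hom = cfg$homograft_depth, q = cfg$error_rate,
                   N2 = n2, n_transcripts = cfg$n_transcripts,
                   point[, setdiff(names(point), "method"), drop = FALSE],
                   seed = cfg$seed)
    rows[[i]] <- point
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Benchmark sweep over the number of SNPs per transcript
#'
#' Classification performance of the Bayesian classifier as evidence is
#' summed over an increasing number of SNPs, at fixed depth and error rate.
#'
#' @param snp_counts integer vector of SNPs-per-transcript values (>= 1).
#' @param config base [simulation_config()] (its `snps_per_transcript` is
#'   overridden; the seed is the master seed).
#' @param threshold log10 BF threshold.
#' @return Tidy data frame: n_snps, q, N_hom, N, N2, n_transcripts, tp, fp,
#'   tn, fn, tpr, fpr, accuracy, seed.
#' @export
run_snp_sweep <- function(snp_counts, config = simulation_config(),
                          threshold = 1) {
  if (length(snp_counts) == 0L || any(snp_counts < 1))
    stop("snp_counts must contain positive integers")
  rows <- list()
  for (i in seq_along(snp_counts)) {
    k <- as.integer(snp_counts[i])
    cfg <- simulation_config(
      error_rate = config$error_rate,
      homograft_depth = config$homograft_depth,
      heterograft_depth = config$heterograft_depth,
      mobile_reads = config$mobile_reads,
      snps_per_transcript = k, replicates = config$replicates,
      n_transcripts = config$n_transcripts,
      seed = derive_seed(config$seed, i),
      mobile_reads_with_errors = config$mobile_reads_with_errors)
    point <- tryCatch({
      cohort <- simulate_cohort(cfg)
      ct <- classify_cohort(cohort, "bayes", threshold)$bayes
      confusion_row(ct)
    }, error = function(e) {
      warning("grid point n_snps=", k, " failed: ", conditionMessage(e))
      data.frame(tp = NA_integer_, fp = NA_integer_, tn = NA_integer_,
                 fn = NA_integer_, tpr = NA_real_, fpr = NA_real_,
                 accuracy = NA_real_)
    })
    rows[[i]] <- cbind(
      data.frame(n_snps = k, q = cfg$error_rate, N_hom = cfg$homograft_depth,
                 N = cfg$heterograft_depth, N2 = cfg$mobile_reads,
                 n_transcripts = cfg$n_transcripts),
      point, seed = cfg$seed)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
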