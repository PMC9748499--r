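# Independent oracles used to freeze expected values.  They integrate the
# error-rate(s) out by adaptive quadrature over the Beta density and
# enumerate read-origin configurations explicitly -- no code shared with the
# log-space kernels they check.

# marginal P(k successes | m trials, rate ~ Beta(a, b)) by quadrature
oracle_bb <- function(k, m, a, b) {
  if (m == 0) return(as.numeric(k == 0))
  stats::integrate(function(th) stats::dbinom(k, m, th) * stats::dbeta(th, a, b),
                   0, 1, rel.tol = 1e-10, abs.tol = 1e-13)$value
}

# posterior over N2 (uniform prior) for one heterograft observation
oracle_n2_posterior <- function(N, n, a1, b1, a2 = NULL, b2 = NULL) {
  lik <- vapply(0:N, function(N2) {
    M <- N - N2
    if (is.null(a2)) {
      # distal reads always observed as distal
      k <- n - N2
      if (k < 0 || k > M) return(0)
      return(oracle_bb(k, M, a1, b1))
    }
    js <- max(0, n - N2):min(n, M)
    sum(vapply(js, function(j) {
      # j errors among local reads, n - j distal reads kept as distal;
      # a distal read is observed distal with probability 1 - theta2
      p_loc <- oracle_bb(j, M, a1, b1)
      p_dist <- if (N2 == 0) as.numeric(n - j == 0) else
        stats::integrate(function(th) stats::dbinom(n - j, N2, 1 - th) *
                           stats::dbeta(th, a2, b2),
                         0, 1, rel.tol = 1e-10, abs.tol = 1e-13)$value
      p_loc * p_dist
    }, numeric(1)))
  }, numeric(1))
  lik / sum(lik)
}

# small valid count table for io / baseline tests
make_table <- function(n_transcripts = 2, snps = 2, reps = 2,
                       total = 100L, distal = 0L) {
  g <- expand.grid(replicate_id = sprintf("R%d", seq_len(reps)),
                   s = seq_len(snps), t = seq_len(n_transcripts),
                   stringsAsFactors = FALSE)
  data.frame(transcript_id = sprintf("T%02d", g$t),
             snp_id = sprintf("T%02d_S%d", g$t, g$s),
             replicate_id = g$replicate_id,
             tissue = "scion", genotype_sampled = "A",
             total_reads = total, distal_reads = distal,
             stringsAsFactors = FALSE)
}
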