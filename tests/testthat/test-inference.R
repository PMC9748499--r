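# Core Bayesian machinery: conjugate error posteriors, beta-binomial
# marginals, the posterior over N2 and the Bayes factors built from it.

test_that("fit_error_posterior performs exact conjugate updates", {
  ep <- fit_error_posterior(data.frame(total_reads = 100, distal_reads = 3))
  expect_equal(ep$alpha, 4)
  expect_equal(ep$beta, 98)
  expect_equal(posterior_mean(ep), 4 / 102)

  # replicate splits pool to the identical posterior, bit for bit
  split2 <- fit_error_posterior(
    data.frame(total_reads = c(50, 50), distal_reads = c(1, 2)))
  expect_identical(c(split2$alpha, split2$beta), c(ep$alpha, ep$beta))
  split4 <- fit_error_posterior(
    data.frame(total_reads = c(10, 40, 25, 25), distal_reads = c(0, 2, 1, 0)))
  expect_identical(c(split4$alpha, split4$beta), c(ep$alpha, ep$beta))

  # posterior mean matches (u1 + sum n) / (u1 + u2 + sum N) for other priors
  pr <- prior_hyperparameters(0.5, 2)
  ep2 <- fit_error_posterior(
    data.frame(total_reads = c(30, 70), distal_reads = c(2, 5)), prior = pr)
  expect_equal(posterior_mean(ep2), (0.5 + 7) / (0.5 + 2 + 100))
})

test_that("fit_error_posterior handles empty and invalid input", {
  expect_warning(ep <- fit_error_posterior(
    data.frame(total_reads = integer(), distal_reads = integer())),
    "low information")
  expect_equal(c(ep$alpha, ep$beta), c(1, 1))
  expect_error(fit_error_posterior(
    data.frame(total_reads = 10, distal_reads = 11)), "invalid counts")
  expect_error(fit_error_posterior(
    data.frame(snp_id = c("a", "b"), total_reads = c(5, 5),
               distal_reads = c(0, 0))), "multiple SNPs")
  expect_error(prior_hyperparameters(0, 1), "positive")
})

test_that("log_beta_binomial matches closed forms and the quadrature oracle", {
  # flat prior: uniform marginal over k
  m <- 17
  expect_equal(log_beta_binomial(0:m, m, 1, 1), rep(log(1 / (m + 1)), m + 1))
  # empty trial has probability one
  expect_equal(log_beta_binomial(0, 0, 3.2, 0.7), 0)
  # quadrature oracle
  expect_equal(log_beta_binomial(2, 10, 4, 98), log(oracle_bb(2, 10, 4, 98)),
               tolerance = 1e-6)
  for (case in list(c(5, 12, 0.5, 0.5), c(0, 8, 2, 30), c(7, 7, 1.5, 4))) {
    expect_equal(exp(log_beta_binomial(case[1], case[2], case[3], case[4])),
                 oracle_bb(case[1], case[2], case[3], case[4]),
                 tolerance = 1e-8)
  }
  # the pmf sums to one
  for (shapes in list(c(1, 1), c(4, 98), c(0.3, 7))) {
    expect_equal(sum(exp(log_beta_binomial(0:25, 25, shapes[1], shapes[2]))),
                 1, tolerance = 1e-9)
  }
  expect_error(log_beta_binomial(5, 3, 1, 1), "0 <= k <= m")
  expect_error(log_beta_binomial(1, 3, -1, 1), "> 0")
})

test_that("posterior_over_n2 reproduces the hand-checked small cases", {
  # N2 = 1 would force n >= 1 under the single-rate model
  p <- posterior_over_n2(snp_counts(1, 0), error_posterior(1, 1))
  expect_equal(unname(p$probabilities[1]), 1)
  # the oracle-confirmed flat-prior case
  p <- posterior_over_n2(snp_counts(2, 1), error_posterior(1, 1))
  expect_equal(unname(p$probabilities), c(2, 3, 0) / 5, tolerance = 1e-12)
  expect_equal(p$expected_n2, 0.6)
  expect_equal(p$ratio_r2, 0.3)
  expect_equal(unname(p$probabilities),
               oracle_n2_posterior(2, 1, 1, 1), tolerance = 1e-9)
})

test_that("posterior_over_n2 matches the enumeration oracle for N <= 6", {
  # spot-check grid here; the exhaustive scan lives in test-acceptance.R
  for (N in c(3L, 5L)) for (n in 0:N) {
    p1 <- posterior_over_n2(snp_counts(N, n), error_posterior(2, 5))
    expect_equal(unname(p1$probabilities), oracle_n2_posterior(N, n, 2, 5),
                 tolerance = 1e-6, label = sprintf("single N=%d n=%d", N, n))
    p2 <- posterior_over_n2(snp_counts(N, n), error_posterior(2, 5),
                            error_posterior(1, 3, genotype = "B"))
    expect_equal(unname(p2$probabilities),
                 oracle_n2_posterior(N, n, 2, 5, 1, 3),
                 tolerance = 1e-6, label = sprintf("two-rate N=%d n=%d", N, n))
  }
})

test_that("posterior_over_n2 normalises for randomised valid inputs", {
  set.seed(42)
  for (i in 1:40) {
    N <- sample(1:400, 1)
    n <- sample(0:N, 1)
    a1 <- runif(1, 0.2, 50); b1 <- runif(1, 0.2, 500)
    two <- i %% 2 == 0
    pr <- prior_hyperparameters(0.2, 0.2)
    p <- posterior_over_n2(
      snp_counts(N, n), error_posterior(a1, b1, prior = pr),
      if (two) error_posterior(runif(1, 0.2, 20), runif(1, 0.2, 200),
                               prior = pr))
    expect_equal(sum(p$probabilities), 1, tolerance = 1e-9)
    expect_true(all(p$probabilities >= 0))
    expect_gt(p$probabilities[1], 0)
    expect_equal(p$expected_n2,
                 sum((seq_along(p$probabilities) - 1) * p$probabilities))
    expect_true(p$expected_n2 >= 0 && p$expected_n2 <= N)
  }
})

test_that("posterior_over_n2 handles degenerate and mismatched input", {
  expect_warning(p <- posterior_over_n2(snp_counts(0, 0),
                                        error_posterior(1, 1)),
                 "zero read depth")
  expect_equal(unname(p$probabilities), 1)
  expect_equal(snp_log_bf(p), 0)

  loc <- error_posterior(4, 98, tissue = "scion", genotype = "A")
  dist_bad <- error_posterior(3, 99, tissue = "stock", genotype = "B")
  het <- snp_counts(10, 1, tissue = "scion", genotype = "A")
  expect_error(posterior_over_n2(het, loc, dist_bad), "tissue")
  same_geno <- error_posterior(3, 99, tissue = "scion", genotype = "A")
  expect_error(posterior_over_n2(het, loc, same_geno), "share a genotype")
  expect_error(posterior_over_n2(snp_counts(10, 1, tissue = "stock"), loc),
               "tissue")
})

test_that("snp_log_bf follows the maximum posterior odds form", {
  p <- posterior_over_n2(snp_counts(2, 1), error_posterior(1, 1))
  expect_equal(snp_log_bf(p), log10(1.5))
  # P(N2 = 0) the unique maximum -> negative evidence
  p <- posterior_over_n2(snp_counts(1000, 2), error_posterior(101, 9901))
  expect_lt(snp_log_bf(p), 0)
  # n below the expected error count qN: evidence against mobility
  p <- posterior_over_n2(snp_counts(1000, 7), error_posterior(101, 9901))
  expect_lt(snp_log_bf(p), 0)
})

test_that("evidence is monotone in n and increasing from n=0 to n=N", {
  loc <- error_posterior(11, 991)   # <theta> ~ 0.011
  N <- 120L
  bf <- vapply(0:N, function(n)
    snp_log_bf(posterior_over_n2(snp_counts(N, n), loc,
                                 error_posterior(6, 500, genotype = "B"))),
    numeric(1))
  from <- ceiling(posterior_mean(loc) * N)
  expect_true(all(diff(bf[(from + 1):(N + 1)]) >= -1e-9))
  expect_gt(bf[N + 1], bf[1])
})

test_that("transcript_log_bf sums contributions and applies the threshold", {
  ev <- transcript_log_bf(c(s1 = 0.5))
  expect_equal(ev$total_log_bf, 0.5)
  expect_equal(ev$label, "non-mobile")

  ev <- transcript_log_bf(c(0.5, 0.7))
  expect_equal(ev$total_log_bf, 1.2, tolerance = 1e-9)
  expect_equal(ev$label, "mobile")

  # one deviant SNP outvoted by evidence against
  ev <- transcript_log_bf(c(1.5, -2.0))
  expect_equal(ev$total_log_bf, -0.5)
  expect_equal(ev$label, "non-mobile")
  expect_false(ev$confident_non_mobile)
  expect_true(transcript_log_bf(c(-0.6, -0.6))$confident_non_mobile)

  # totals exactly at the threshold are mobile
  expect_equal(transcript_log_bf(c(0.4, 0.6))$label, "mobile")
  expect_error(transcript_log_bf(numeric()), "unclassifiable")
})
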