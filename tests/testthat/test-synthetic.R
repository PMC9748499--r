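# Simulator and blending generator.

test_that("simulate_homograft_snp realises Binomial(N, q) per read", {
  expect_equal(simulate_homograft_snp(100, 0, seed = 1)$distal_reads, 0L)
  expect_equal(simulate_homograft_snp(100, 1, seed = 1)$distal_reads, 100L)
  expect_error(simulate_homograft_snp(100, 1.5), "0, 1")

  # binomial moments: mean of n over many draws near q * N
  set.seed(11)
  reps <- 2000L
  draws <- vapply(seq_len(reps),
                  function(i) simulate_homograft_snp(1000, 0.01)$distal_reads,
                  integer(1))
  se <- sqrt(0.01 * 0.99 * 1000 / reps)
  expect_lt(abs(mean(draws) - 10), 3 * se)
})

test_that("homograft draws pass a chi-square test against Binomial(N, q)", {
  set.seed(7)
  N <- 50L; q <- 0.1
  draws <- vapply(seq_len(10000L),
                  function(i) simulate_homograft_snp(N, q)$distal_reads,
                  integer(1))
  # bin the upper tail so expected counts stay above 5
  probs <- dbinom(0:N, N, q)
  cut_at <- max(which(probs * 10000 >= 5))
  obs <- c(tabulate(pmin(draws, cut_at) + 1L, nbins = cut_at + 1L))
  exp_p <- c(probs[1:cut_at], sum(probs[(cut_at + 1):(N + 1)]))
  test <- suppressWarnings(stats::chisq.test(obs, p = exp_p))
  expect_gt(test$p.value, 0.01)
})

test_that("simulate_heterograft_snp adds N2 distal reads on top", {
  x <- simulate_heterograft_snp(100, 0, 5, seed = 3)
  expect_equal(x$total_reads, 105L)
  expect_equal(x$distal_reads, 5L)

  # reduces to the homograft generator when N2 = 0
  expect_identical(simulate_heterograft_snp(100, 0.02, 0, seed = 9)$distal_reads,
                   simulate_homograft_snp(100, 0.02, seed = 9)$distal_reads)

  # mean distal count ~ qN + N2 by linearity
  set.seed(21)
  draws <- vapply(seq_len(2000L), function(i)
    simulate_heterograft_snp(1000, 0.01, 50)$distal_reads, integer(1))
  expect_lt(abs(mean(draws) - 60), 3 * sqrt(0.01 * 0.99 * 1000 / 2000))

  # optional error process on the mobile reads reduces the distal count
  set.seed(22)
  y <- vapply(seq_len(500L), function(i)
    simulate_heterograft_snp(0, 0.5, 100, mobile_reads_with_errors = TRUE)$distal_reads,
    integer(1))
  expect_lt(abs(mean(y) - 50), 3 * sqrt(0.25 * 100 / 500))
})

test_that("simulate_cohort builds a balanced, reproducible labelled cohort", {
  cfg <- simulation_config(n_transcripts = 10, snps_per_transcript = 3,
                           replicates = 3, heterograft_depth = 50,
                           homograft_depth = 50, mobile_reads = 5, seed = 5)
  cohort <- simulate_cohort(cfg)
  expect_equal(sum(cohort$truth$label == "mobile"), 5)
  expect_equal(sum(cohort$truth$label == "non-mobile"), 5)
  expect_equal(nrow(cohort$heterograft), 90)          # 10 * 3 * 3
  expect_equal(nrow(cohort$homograft_local), 90)
  validate_count_table(cohort$heterograft)
  validate_count_table(cohort$homograft_distal)

  # mobile transcripts carry N + N2 total reads, non-mobile N
  tot <- tapply(cohort$heterograft$total_reads,
                cohort$heterograft$transcript_id, unique)
  mob <- cohort$truth$transcript_id[cohort$truth$label == "mobile"]
  expect_true(all(tot[mob] == 55))
  expect_true(all(tot[setdiff(names(tot), mob)] == 50))

  # same seed, byte-identical output; different seed differs
  again <- simulate_cohort(cfg)
  expect_identical(cohort$heterograft, again$heterograft)
  expect_identical(cohort$homograft_local, again$homograft_local)
  cfg2 <- simulation_config(n_transcripts = 10, snps_per_transcript = 3,
                            replicates = 3, heterograft_depth = 50,
                            homograft_depth = 50, mobile_reads = 5, seed = 6)
  expect_false(identical(simulate_cohort(cfg2)$heterograft,
                         cohort$heterograft))

  expect_error(simulate_cohort(
    simulation_config(n_transcripts = 7)), "even")
})

test_that("blend_datasets titrates distal reads per the blending proportion", {
  local <- data.frame(transcript_id = "T1", snp_id = "s1",
                      replicate_id = "R1", total_reads = 200L,
                      distal_reads = 2L, stringsAsFactors = FALSE)
  distal <- data.frame(transcript_id = "T1", snp_id = "s1",
                       replicate_id = "R1", total_reads = 180L,
                       distal_reads = 100L, stringsAsFactors = FALSE)
  res <- blend_datasets(local, distal, blend_config(blend_proportion = 0.1))
  expect_equal(res$table$added_reads, 10L)   # 10% of 100 distal reads
  expect_equal(res$table$total_reads, 180L + 10L)  # round(0.9 * 200) + 10
  expect_equal(res$labels$label, "mobile")

  # p = 0: depth-filtered local table unchanged, all labels negative
  res0 <- blend_datasets(local, distal, blend_config(blend_proportion = 0))
  expect_equal(res0$table$total_reads, 200L)
  expect_equal(res0$table$distal_reads, 2L)
  expect_equal(res0$labels$label, "non-mobile")

  # p = 1: local contribution removed entirely
  res1 <- blend_datasets(local, distal, blend_config(blend_proportion = 1))
  expect_equal(res1$table$total_reads, 100L)
  expect_equal(res1$table$distal_reads, 100L)
})

test_that("blend_datasets filters on depth comparability and shared SNPs", {
  local <- make_table(n_transcripts = 2, snps = 1, reps = 1, total = 100L,
                      distal = 1L)
  distal <- make_table(n_transcripts = 2, snps = 1, reps = 1, total = 100L,
                       distal = 10L)
  distal$total_reads <- c(100L, 2000L)   # second SNP 20x deeper
  res <- blend_datasets(local, distal, blend_config(blend_proportion = 0.5))
  expect_equal(nrow(res$table), 1L)
  expect_equal(res$table$snp_id, "T01_S1")

  distal$snp_id <- c("other_1", "other_2")
  expect_error(blend_datasets(local, distal), "no shared")
})

test_that("blending never adds more reads than the distal table holds", {
  set.seed(13)
  local <- make_table(n_transcripts = 5, snps = 2, reps = 2, total = 300L)
  local$distal_reads <- rbinom(nrow(local), 10, 0.3)
  distal <- make_table(n_transcripts = 5, snps = 2, reps = 2, total = 310L)
  distal$distal_reads <- rbinom(nrow(distal), 300, 0.5)
  for (p in c(0.1, 0.37, 0.9)) {
    res <- blend_datasets(local, distal, blend_config(blend_proportion = p,
                                                      seed = 99))
    expect_true(all(res$table$added_reads <= distal$distal_reads))
    expect_true(all(res$table$distal_reads <= res$table$total_reads))
    again <- blend_datasets(local, distal, blend_config(blend_proportion = p,
                                                        seed = 99))
    expect_identical(res$table, again$table)
  }
})

test_that("bin_by_depth makes near-equal bins and keeps ties together", {
  expect_equal(unname(table(bin_by_depth(1:100, 4))), rep(25L, 4),
               ignore_attr = TRUE)
  expect_equal(bin_by_depth(c(5, 1, 9), 1), rep(1L, 3))

  # heavy ties stay in one bin
  depths <- c(rep(10, 7), rep(20, 3))
  bins <- bin_by_depth(depths, 2)
  expect_equal(unique(bins[depths == 10]), 1L)
  expect_equal(unique(bins[depths == 20]), 2L)

  # matches a reference quantile computation on distinct values
  set.seed(3)
  x <- sample(1000, 200)
  bins <- bin_by_depth(x, 4)
  qs <- quantile(x, c(0.25, 0.5, 0.75), type = 1)
  ref <- findInterval(x, qs + 0.5) + 1L
  expect_equal(bins, ref)

  expect_error(bin_by_depth(c(1, 1, 2), 3), "distinct")
})
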