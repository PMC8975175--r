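test_that("random sequence generation is uniform, closed and reproducible", {
  expect_identical(unclass(generate_random_sequence(0))[1], "")
  s1 <- generate_random_sequence(10, seed = 4)
  s2 <- generate_random_sequence(10, seed = 4)
  expect_identical(s1, s2)
  expect_true(grepl("^[ACGT]{10}$", s1))
  expect_error(generate_random_sequence(-1), "non-negative")

  # base frequencies within 3 binomial sd of 0.25 at n = 1e5
  n <- 1e5
  big <- generate_random_sequence(n, seed = 11)
  counts <- table(strsplit(big, "")[[1]])
  sd3 <- 3 * sqrt(n * 0.25 * 0.75)
  expect_true(all(abs(counts - n / 4) < sd3))
})

test_that("indel lengths follow the truncated Zipfian", {
  m1 <- mutation_model(0, 0.1, max_indel = 1)
  expect_true(all(sample_indel_length(m1, 50) == 1L))

  # untruncated s = 2: P(l = 1) = 6 / pi^2
  set.seed(21)
  mu <- mutation_model(0, 0.1, zipf_s = 2, max_indel = Inf)
  draws <- sample_indel_length(mu, 1e5)
  p1 <- 6 / pi^2
  expect_lt(abs(mean(draws == 1) - p1), 3 * sqrt(p1 * (1 - p1) / 1e5))

  # s = 2 truncated at 3: ratios 1 : 1/4 : 1/9
  set.seed(22)
  m3 <- mutation_model(0, 0.1, zipf_s = 2, max_indel = 3)
  d3 <- sample_indel_length(m3, 1e5)
  probs <- zipf_pmf(2, 3)
  expect_equal(probs / probs[1], c(1, 1 / 4, 1 / 9))
  for (l in 1:3) {
    expect_lt(abs(mean(d3 == l) - probs[l]),
              3 * sqrt(probs[l] * (1 - probs[l]) / 1e5))
  }
})

test_that("mutation respects its model and the event log replays exactly", {
  s <- generate_random_sequence(200, seed = 31)
  none <- mutate_sequence(s, mutation_model(0, 0))
  expect_identical(unclass(none$seq)[1], unclass(s)[1])
  expect_identical(nrow(none$events), 0L)

  all_sub <- mutate_sequence(s, mutation_model(1, 0), seed = 32)
  expect_true(all(strsplit(all_sub$seq, "")[[1]] != strsplit(s, "")[[1]]))

  # realized substitution rate within 3 binomial sd at n = 1e5
  big <- generate_random_sequence(1e5, seed = 33)
  mut <- mutate_sequence(big, mutation_model(0.1, 0), seed = 34)
  frac <- mean(strsplit(mut$seq, "")[[1]] != strsplit(big, "")[[1]])
  expect_lt(abs(frac - 0.1), 3 * sqrt(0.1 * 0.9 / 1e5))

  # event-log soundness over random trials
  set.seed(35)
  for (i in 1:20) {
    src <- generate_random_sequence(80)
    r <- mutate_sequence(src, mutation_model(0.1, 0.05, max_indel = 4))
    expect_identical(replay_events(src, r$events), unclass(r$seq)[1])
  }
})

test_that("environment pairs are consistent and length drift is bounded", {
  zero <- make_environment_pair(mutation_model(0, 0), 50, seed = 41)
  expect_identical(unclass(zero$S2)[1], unclass(zero$S1)[1])
  expect_identical(unclass(zero$S2_eval)[1], unclass(zero$S1_eval)[1])

  pair <- make_environment_pair(mutation_model(0.05, 0.02, max_indel = 5),
                                100, seed = 42)
  expect_identical(replay_events(pair$S1, pair$events), unclass(pair$S2)[1])
  expect_identical(replay_events(pair$S1_eval, pair$events_eval),
                   unclass(pair$S2_eval)[1])

  # mean |length drift| bounded by p_indel * length * E[l]
  set.seed(43)
  m <- mutation_model(0, 0.02, zipf_s = 1.5, max_indel = 5)
  el <- sum((1:5) * zipf_pmf(1.5, 5))
  drifts <- replicate(200, {
    p <- make_environment_pair(m, 200)
    nchar(p$S2) - nchar(p$S1)
  })
  bound <- 0.02 * 200 * el
  expect_lt(abs(mean(drifts)), 3 * stats::sd(drifts) / sqrt(200))
  expect_lt(mean(abs(drifts)), bound + 3 * stats::sd(abs(drifts)) / sqrt(200))
})

test_that("simulator distributions pass chi-squared goodness of fit", {
  # substitution count, indel count and indel-length histogram at n = 1e5
  n <- 1e5
  m <- mutation_model(0.08, 0.01, zipf_s = 1.5, max_indel = 6)
  src <- generate_random_sequence(n, seed = 51)
  set.seed(52)
  r <- mutate_sequence(src, m)
  n_sub <- sum(r$events$kind == "substitution")
  expect_gt(stats::chisq.test(c(n_sub, n - n_sub),
                              p = c(0.08, 0.92))$p.value, 0.01)
  n_ind <- sum(r$events$kind != "substitution")
  expect_gt(stats::chisq.test(c(n_ind, n - n_ind),
                              p = c(0.01, 0.99))$p.value, 0.01)

  set.seed(53)
  lens <- sample_indel_length(m, n)
  expect_gt(stats::chisq.test(tabulate(lens, 6),
                              p = zipf_pmf(1.5, 6))$p.value, 0.01)
})

test_that("FASTA round trip preserves records and rejects bad symbols", {
  tmp <- withr::local_tempfile(fileext = ".fasta")
  seqs <- c(a = generate_random_sequence(80, seed = 61),
            b = generate_random_sequence(35, seed = 62),
            c = "ACGTN")
  write_fasta(seqs, tmp)
  back <- read_fasta(tmp)
  expect_identical(names(back), c("a", "b", "c"))
  expect_identical(unname(vapply(back, unclass, character(1))),
                   unname(vapply(seqs, unclass, character(1))))

  empty <- withr::local_tempfile(fileext = ".fasta")
  file.create(empty)
  expect_length(read_fasta(empty), 0)

  lc <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">low", "acgt"), lc)
  expect_identical(unname(read_fasta(lc)), "ACGT")

  bad <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">ok", "ACGT", ">oops", "ACXT"), bad)
  expect_error(read_fasta(bad), "oops")
})
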