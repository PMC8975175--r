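test_that("seed finding: self-match merging, absence, and n-hit filtering", {
  set.seed(11)
  S <- generate_random_sequence(200)
  s <- find_seeds(S, S, k = 12)
  d0 <- s[s$diag == 0, ]
  expect_equal(nrow(d0), 1)
  expect_equal(d0$x, 0)
  expect_equal(d0$length, 200)

  A <- generate_random_sequence(300, seed = 12)
  B <- generate_random_sequence(300, seed = 13)
  expect_equal(nrow(find_seeds(A, B, k = 12)), 0)

  # two co-diagonal hits at distance 50 survive n = 2 within d = 100;
  # a lone hit on another diagonal is dropped
  word1 <- "ACGTACGGTTCA"
  word2 <- "TTGACCAGGATC"
  lone <- "CAGTTACCGGAT"
  pad <- function(n, seed) generate_random_sequence(n, seed = seed)
  S1 <- paste0(word1, pad(38, 21), word2, pad(40, 22), lone)
  S2 <- paste0(word1, pad(38, 23), word2, pad(33, 24), lone)
  s2 <- find_seeds(S1, S2, k = 12, n_hit = 2, hit_window = 100)
  expect_true(any(s2$diag == 0 & s2$x == 0))
  expect_true(any(s2$diag == 0 & s2$x == 50))
  expect_false(any(s2$diag != 0))

  expect_equal(nrow(find_seeds("ACGT", "ACGT", k = 12)), 0)
})

test_that("policy-driven x-drop extension follows the while-rule exactly", {
  params <- xdrop_params(X = 4, W = 4)
  S <- "ACGTACGTACGTACGT"

  # forced forward on identical sequences never x-drops
  r <- dqn_xdrop_extend(S, S, c(0, 0), policy_fixed("forward"),
                        xdrop_params(X = 5, W = 4))
  expect_identical(r$terminated_by, "seqend")
  expect_equal(r$best, nchar(S) * 1)
  expect_equal(r$best_prefix_len, nchar(S))

  # gaps after 5 matches with gap = -2, X = 4: exactly 2 gap steps taken
  pol <- policy_script(c(rep("forward", 5), rep("insertion", 20)))
  r2 <- dqn_xdrop_extend(S, S, c(0, 0), pol, params)
  expect_identical(r2$path, c(rep("M", 5), "I", "I"))
  expect_equal(r2$best, 5)
  expect_equal(r2$best_prefix_len, 5)
  expect_equal(r2$score, 1)   # 5 - 2*2 = best - X
  expect_identical(r2$terminated_by, "xdrop")

  # start at a sequence end gives the empty extension
  r3 <- dqn_xdrop_extend(S, S, c(nchar(S), 0), policy_fixed("forward"), params)
  expect_equal(r3$steps, 0)
  expect_equal(r3$score, 0)

  # conservation: recomputed best-prefix score equals best, many policies
  set.seed(31)
  for (i in 1:30) {
    S1 <- generate_random_sequence(60)
    S2 <- mutate_sequence(S1, mutation_model(0.1, 0.03))$seq
    pol <- list(policy_heuristic(), policy_fixed("forward"),
                make_test_net(W = 6))[[1 + i %% 3]]
    r <- dqn_xdrop_extend(S1, S2, c(0, 0), pol, xdrop_params(X = 10, W = 6))
    expect_equal(score_columns(r$path[seq_len(r$best_prefix_len)],
                               scoring_scheme()), r$best)
    expect_true(isTRUE(verify_xdrop(r, xdrop_params(X = 10, W = 6))))
  }
})

test_that("greedy x-drop equals the exhaustive DP oracle at X = Inf", {
  set.seed(41)
  for (i in 1:200) {
    l1 <- sample(5:30, 1)
    l2 <- sample(5:30, 1)
    S1 <- generate_random_sequence(l1)
    S2 <- if (i %% 2 == 0) generate_random_sequence(l2)
          else mutate_sequence(S1, mutation_model(0.15, 0.05))$seq
    g <- greedy_xdrop_extend(S1, S2, c(0, 0), xdrop_params(X = Inf))
    expect_identical(g$best, brute_force_extension(S1, S2))
    expect_equal(score_columns(g$path, scoring_scheme()), g$best)
  }
})

test_that("greedy x-drop on identical sequences is the pure diagonal", {
  S <- generate_random_sequence(50, seed = 42)
  g <- greedy_xdrop_extend(S, S, c(0, 0), xdrop_params(X = 20))
  expect_equal(g$best, 50)
  expect_identical(g$path, rep("M", 50))
  expect_identical(g$terminated_by, "seqend")
})

test_that("bidirectional extension assembles coordinates, score and identity", {
  # seed spanning both full identical sequences
  S <- generate_random_sequence(80, seed = 51)
  al <- extend_bidirectional(S, S, list(x = 0, y = 0, length = 80),
                             xdrop_params(X = 20), "greedy")
  expect_equal(al$identity, 1)
  expect_equal(al$coverage1, 1)
  expect_equal(al$coverage2, 1)
  expect_equal(al$score, 80)

  # seed at (0,0): upstream part empty
  S1 <- generate_random_sequence(100, seed = 52)
  S2 <- mutate_sequence(S1, mutation_model(0.05, 0))$seq
  al2 <- extend_bidirectional(S1, S2, list(x = 0, y = 0, length = 12),
                              xdrop_params(X = 30), "greedy")
  expect_equal(al2$start1, 0)
  expect_equal(al2$start2, 0)

  # additivity: total score = up.best + k * match + down.best
  sd <- list(x = 40, y = 40, length = 12)
  up <- greedy_xdrop_extend(rev(dna_codes(substr(S1, 1, 40))),
                            rev(dna_codes(substr(S2, 1, 40))),
                            c(0, 0), xdrop_params(X = 30))
  down <- greedy_xdrop_extend(substring(S1, 53), substring(S2, 53),
                              c(0, 0), xdrop_params(X = 30))
  al3 <- extend_bidirectional(S1, S2, sd, xdrop_params(X = 30), "greedy")
  expect_equal(al3$score, up$best + 12 + down$best)

  # per-sequence residue spans match the columns' consumption
  cons1 <- sum(al3$columns %in% c("M", "X", "D"))
  cons2 <- sum(al3$columns %in% c("M", "X", "I"))
  expect_equal(al3$end1 - al3$start1, cons1)
  expect_equal(al3$end2 - al3$start2, cons2)
})

test_that("pair alignment pipeline reports sorted, consistent alignments", {
  S <- generate_random_sequence(300, seed = 61)
  als <- align_pair(S, S, xdrop_params(X = 50, W = 6))
  expect_equal(length(als), 1)
  expect_equal(als[[1]]$identity, 1)
  expect_equal(als[[1]]$coverage1, 1)

  # unrelated sequences: no seeds survive, empty output
  A <- generate_random_sequence(500, seed = 62)
  B <- generate_random_sequence(500, seed = 63)
  expect_length(align_pair(A, B), 0)

  # two homologous blocks -> scores non-ascending, identity consistent
  set.seed(64)
  core1 <- generate_random_sequence(120)
  core2 <- generate_random_sequence(60)
  S1 <- paste0(core1, generate_random_sequence(50), core2)
  S2 <- paste0(mutate_sequence(core1, mutation_model(0.03, 0))$seq,
               generate_random_sequence(55),
               mutate_sequence(core2, mutation_model(0.03, 0))$seq)
  als2 <- align_pair(S1, S2, xdrop_params(X = 20, W = 6), k = 12)
  expect_gt(length(als2), 0)
  scores <- vapply(als2, `[[`, numeric(1), "score")
  expect_true(all(diff(scores) <= 0))
  for (a in als2) {
    expect_equal(round(a$identity * length(a$columns)),
                 sum(a$columns == "M"))
    expect_equal(score_columns(a$columns, scoring_scheme()), a$score)
  }
})

test_that("the policy interface makes the extender policy-agnostic", {
  S1 <- generate_random_sequence(60, seed = 71)
  S2 <- mutate_sequence(S1, mutation_model(0.05, 0.01))$seq
  params <- xdrop_params(X = 20, W = 6)
  for (pol in list(policy_fixed("forward"), policy_heuristic(),
                   make_test_net())) {
    r <- dqn_xdrop_extend(S1, S2, c(0, 0), pol, params)
    expect_s3_class(r, "extension_result")
    expect_true(isTRUE(verify_xdrop(r, params)))
  }
})
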