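test_that("q_values satisfy the dueling decomposition and determinism", {
  for (variant in c("separable", "standard")) {
    net <- make_test_net(variant)
    S1 <- generate_random_sequence(30, seed = 1)
    S2 <- generate_random_sequence(30, seed = 2)
    st <- extract_state(S1, S2, c(3, 5), 6)
    q <- q_values(net, st)
    expect_length(q, 3)
    expect_true(all(is.finite(q)))
    expect_named(q, c("forward", "insertion", "deletion"))
    expect_identical(q, q_values(net, st))

    # dueling: mean_a (Q_a - V) = 0
    fw <- dqnxdrop:::net_forward(net, matrix(st$enc, nrow = 1))
    expect_equal(mean(fw$Q - as.vector(fw$V)), 0, tolerance = 1e-12)
  }

  # window mismatch is a contract error
  net <- make_test_net(W = 6)
  st8 <- extract_state("ACGTACGTAC", "ACGTACGTAC", c(0, 0), 8)
  expect_error(q_values(net, st8), "window")
})

test_that("variants are drop-in interchangeable; separable has fewer parameters", {
  sep <- make_test_net("separable")
  std <- make_test_net("standard")
  st <- extract_state(generate_random_sequence(20, seed = 3),
                      generate_random_sequence(20, seed = 4), c(0, 0), 6)
  expect_identical(dim(dqnxdrop:::net_forward(sep, matrix(st$enc, 1))$Q),
                   dim(dqnxdrop:::net_forward(std, matrix(st$enc, 1))$Q))
  expect_lt(n_parameters(sep), n_parameters(std))
})

test_that("epsilon-greedy selection: argmax, tie order, uniform exploration", {
  q <- c(forward = 2, insertion = 1, deletion = 0)
  expect_identical(select_action(q, 0), "forward")
  expect_identical(select_action(c(forward = 1, insertion = 1, deletion = 0), 0),
                   "forward")
  expect_identical(select_action(c(forward = 0, insertion = 1, deletion = 1), 0),
                   "insertion")

  set.seed(5)
  draws <- replicate(30000, select_action(q, 1))
  freq <- table(draws) / 30000
  sd3 <- 3 * sqrt((1 / 3) * (2 / 3) / 30000)
  expect_true(all(abs(freq - 1 / 3) < sd3))
})

test_that("double-DQN targets implement the stated backup", {
  net <- make_test_net()
  tgt <- make_test_net(seed = 43)
  buf <- fill_buffer(64)
  batch <- buffer_sample(buf, 16, 6)

  # gamma = 0: target is the reward for every item
  expect_equal(double_dqn_target(batch, 0, net, tgt), batch$rewards)

  # terminal items keep target = r at any gamma
  batch$done[] <- TRUE
  expect_equal(double_dqn_target(batch, 0.9, net, tgt), batch$rewards)

  # hand computation: gamma = 0.9, r = 1, Q_target(s') known, argmax from main
  batch$done[] <- FALSE
  t1 <- double_dqn_target(batch, 0.9, net, tgt)
  Qm <- dqnxdrop:::q_matrix(net, batch$S2)
  Qt <- dqnxdrop:::q_matrix(tgt, batch$S2)
  astar <- max.col(Qm, ties.method = "first")
  expect_equal(t1, batch$rewards +
                 0.9 * Qt[cbind(seq_len(16), astar)])

  # the literal variant takes the argmax under the target network
  t2 <- double_dqn_target(batch, 0.9, net, tgt, action_from = "target")
  astar2 <- max.col(Qt, ties.method = "first")
  expect_equal(t2, batch$rewards + 0.9 * Qt[cbind(seq_len(16), astar2)])
})

test_that("soft target update is a convex parameter blend", {
  main <- make_test_net()
  tgt <- make_test_net(seed = 99)
  copy <- soft_update_target(main, tgt, 1)
  expect_equal(copy$params, main$params)
  same <- soft_update_target(main, tgt, 0)
  expect_equal(same$params, tgt$params)
  mid <- soft_update_target(main, tgt, 0.3)
  lo <- pmin(main$params$dense$W, tgt$params$dense$W)
  hi <- pmax(main$params$dense$W, tgt$params$dense$W)
  expect_true(all(mid$params$dense$W >= lo - 1e-12 &
                    mid$params$dense$W <= hi + 1e-12))

  other <- dqn_network(network_config(window = 8, channels = c(4, 4),
                                      hidden = 16))
  expect_error(soft_update_target(main, other, 0.5), "architectures differ")
})

test_that("training reduces the loss on a frozen batch, deterministically", {
  for (variant in c("separable", "standard")) {
    net <- make_test_net(variant)
    tgt <- net
    buf <- fill_buffer(64)
    set.seed(6)
    batch <- buffer_sample(buf, 16, 6)
    losses <- numeric(100)
    n2 <- net
    for (i in 1:100) {
      ts <- train_step(n2, tgt, batch)
      n2 <- ts$net
      losses[i] <- ts$loss
    }
    expect_lt(mean(tail(losses, 10)), mean(head(losses, 10)))
    expect_lt(losses[100], losses[1] * 0.5)

    # identical trajectory on re-run
    n3 <- net
    losses2 <- numeric(100)
    for (i in 1:100) {
      ts <- train_step(n3, tgt, batch)
      n3 <- ts$net
      losses2[i] <- ts$loss
    }
    expect_identical(losses, losses2)
  }

  # a batch whose targets already equal Q(s, a) has ~zero loss
  net <- make_test_net()
  buf <- fill_buffer(64)
  set.seed(7)
  batch <- buffer_sample(buf, 16, 6)
  Q <- dqnxdrop:::q_matrix(net, batch$S)
  batch$rewards <- Q[cbind(1:16, batch$actions)]
  batch$done[] <- TRUE
  ts <- train_step(net, net, batch)
  expect_equal(ts$loss, 0, tolerance = 1e-20)
})

test_that("replay buffer is a bounded FIFO with guarded sampling", {
  buf <- replay_buffer(8)
  expect_error(buffer_sample(buf, 4, 6), "holds 0")
  filled <- fill_buffer(20, seed = 8)
  expect_equal(buffer_size(filled), 20)
  small <- replay_buffer(8)
  st <- extract_state("ACGTACGT", "ACGTACGT", c(0, 0), 6)
  for (i in 1:12) buffer_add(small, st, "forward", i, st, FALSE)
  expect_equal(buffer_size(small), 8)
  rewards <- vapply(small$store, `[[`, numeric(1), "r")
  expect_setequal(rewards, 5:12)
})

test_that("checkpoint round trip reproduces bit-identical Q-values", {
  net <- make_test_net()
  path <- withr::local_tempfile(fileext = ".ckpt")
  save_checkpoint(net, path)
  back <- load_checkpoint(path)
  probe <- lapply(1:5, function(i) {
    extract_state(generate_random_sequence(20, seed = i),
                  generate_random_sequence(20, seed = i + 50), c(0, 0), 6)
  })
  for (st in probe) expect_identical(q_values(net, st), q_values(back, st))
  expect_identical(back$config, net$config)
})
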