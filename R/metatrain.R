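# Meta-training: an outer loop over a distribution of mutation environments,
# an inner DQN training loop per environment, held-out evaluation whose
# trajectories feed an outer replay buffer, and final fine-tuning on
# user-supplied sequences.

#' Distribution of training environments
#'
#' Mutation-model parameters are drawn independently and uniformly from the
#' given ranges: one draw defines one training environment.
#'
#' @param p_snp Range (length-2 numeric) of the substitution probability.
#' @param p_indel Range of the indel-initiation probability.
#' @param max_indel Range of the maximum indel length (integers).
#' @param zipf_s Fixed Zipfian exponent of indel lengths.
#' @return Object of class `environment_distribution`.
#' @export
environment_distribution <- function(p_snp = c(0, 0.3),
                                     p_indel = c(0, 0.1),
                                     max_indel = c(1, 10),
                                     zipf_s = 1.5) {
  stopifnot(length(p_snp) == 2, length(p_indel) == 2, length(max_indel) == 2,
            all(p_snp >= 0), all(p_snp <= 1), all(p_indel >= 0),
            all(p_indel <= 1), all(max_indel >= 1), zipf_s > 1)
  structure(list(p_snp = sort(p_snp), p_indel = sort(p_indel),
                 max_indel = sort(max_indel), zipf_s = zipf_s),
            class = "environment_distribution")
}

#' Sample one environment (mutation model) from a distribution
#'
#' @param dist An [environment_distribution()].
#' @return A [mutation_model()].
#' @export
sample_environment <- function(dist) {
  stopifnot(inherits(dist, "environment_distribution"))
  mutation_model(
    p_snp = stats::runif(1, dist$p_snp[1], dist$p_snp[2]),
    p_indel = stats::runif(1, dist$p_indel[1], dist$p_indel[2]),
    zipf_s = dist$zipf_s,
    max_indel = sample(seq(dist$max_indel[1], dist$max_indel[2]), 1))
}

#' Meta-training configuration
#'
#' @param M Outer iterations (environments visited).
#' @param N Inner training steps per environment.
#' @param seq_length Ancestral sequence length per generated pair.
#' @param outer_updates Gradient steps on the outer network per outer
#'   iteration, sampled from the outer buffer.
#' @param eval_episodes Held-out evaluation rollouts per environment.
#' @param inner_buffer,outer_buffer Replay capacities.
#' @param scoring A [scoring_scheme()].
#' @param seed Root seed; all streams derive from it.
#' @return Object of class `meta_config`.
#' @export
meta_config <- function(M, N, seq_length = 1000, outer_updates = 50,
                        eval_episodes = 1, inner_buffer = 10000,
                        outer_buffer = 50000, scoring = scoring_scheme(),
                        seed = NULL) {
  stopifnot(M >= 1, N >= 0, seq_length > 0)
  structure(list(M = as.integer(M), N = as.integer(N),
                 seq_length = as.integer(seq_length),
                 outer_updates = as.integer(outer_updates),
                 eval_episodes = as.integer(eval_episodes),
                 inner_buffer = as.integer(inner_buffer),
                 outer_buffer = as.integer(outer_buffer),
                 scoring = scoring, seed = seed),
            class = "meta_config")
}

# one environment step on coded sequences; returns updated pos, reward,
# column and terminal flag (terminal = a pointer reached a sequence end
# after the move)
step_codes <- function(c1, c2, x, y, act, sc) {
  if (act == 1L) {
    is_match <- c1[x + 1L] == c2[y + 1L] && c1[x + 1L] <= 4L
    r <- if (is_match) sc$match else sc$mismatch
    x <- x + 1L; y <- y + 1L
  } else if (act == 2L) {
    r <- sc$gap; y <- y + 1L
  } else {
    r <- sc$gap; x <- x + 1L
  }
  list(x = x, y = y, r = r,
       terminal = x >= length(c1) || y >= length(c2))
}

#' Inner-loop DQN training on one environment pair
#'
#' Copies the initial network and trains it for `N` epsilon-greedy steps on
#' the pair `(S1, S2)`, recording every transition in a fresh inner replay
#' buffer and taking one [train_step()] per environment step once the buffer
#' can fill a batch. Episodes that hit a sequence end restart at `(0, 0)` on
#' a freshly simulated pair from the same environment. The initial network
#' is not modified (the trained copy is returned).
#'
#' @param net Initial `dqn_net`.
#' @param env_pair An `environment_pair` from [make_environment_pair()].
#' @param N Number of inner steps.
#' @param scoring A [scoring_scheme()].
#' @param eps_fun Function mapping global step index to epsilon; default is
#'   the linear schedule of the network config over `N` steps.
#' @param step_offset Global step offset fed to `eps_fun`.
#' @return List: `net` (trained copy), `buffer` (inner replay buffer),
#'   `target` (final target network), `steps` (= `N`).
#' @export
inner_loop_train <- function(net, env_pair, N, scoring = scoring_scheme(),
                             eps_fun = NULL, step_offset = 0) {
  stopifnot(inherits(env_pair, "environment_pair"), N >= 0)
  cfg <- net$config
  if (is.null(eps_fun)) eps_fun <- linear_eps(cfg, N)
  buffer <- replay_buffer(min(cfg$buffer_capacity, max(N, 1)))
  target <- net
  W <- cfg$window
  c1 <- dna_codes(env_pair$S1); c2 <- dna_codes(env_pair$S2)
  x <- 0L; y <- 0L
  for (t in seq_len(N)) {
    if (x >= length(c1) || y >= length(c2)) {
      anc <- generate_random_sequence(nchar(env_pair$S1))
      mut <- mutate_sequence(anc, env_pair$model)
      c1 <- dna_codes(anc); c2 <- dna_codes(mut$seq)
      x <- 0L; y <- 0L
    }
    w1 <- window_codes(c1, x, W); w2 <- window_codes(c2, y, W)
    st <- structure(list(codes1 = w1, codes2 = w2, W = W,
                         enc = encode_windows(w1, w2, W)),
                    class = "window_state")
    q <- as.vector(net_forward(net, matrix(st$enc, nrow = 1))$Q)
    eps <- eps_fun(step_offset + t)
    act <- match(select_action(q, eps), ACTIONS)
    mv <- step_codes(c1, c2, x, y, act, scoring)
    x <- mv$x; y <- mv$y
    nw1 <- window_codes(c1, x, W); nw2 <- window_codes(c2, y, W)
    nst <- structure(list(codes1 = nw1, codes2 = nw2, W = W, enc = NULL),
                     class = "window_state")
    buffer_add(buffer, st, act, mv$r, nst, mv$terminal)
    if (buffer_size(buffer) >= cfg$batch_size) {
      ts <- train_step(net, target, buffer, cfg)
      net <- ts$net
      target <- soft_update_target(net, target, cfg$tau)
    }
  }
  list(net = net, buffer = buffer, target = target, steps = N)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# linear epsilon schedule from a network config over `total` steps
linear_eps <- function(cfg, total) {
  decay_steps <- max(1, cfg$eps_decay_frac * total)
  function(t) {
    max(cfg$eps_end,
        cfg$eps_start - (cfg$eps_start - cfg$eps_end) * t / decay_steps)
  }
}

#' Greedy evaluation rollout of a policy on a sequence pair
#'
#' Rolls the policy out greedily (epsilon = 0) from `(0, 0)` until a
#' sequence end, recording the trajectory.
#'
#' @param policy Any `alignment_policy` (typically a `dqn_net`).
#' @param S1,S2 Sequences.
#' @param scoring A [scoring_scheme()].
#' @param W Window size (defaults to the network's).
#' @return List: `trajectory` (list of transition records), `reward` (summed),
#'   `identity` (matches / columns), `steps`, `columns`.
#' @export
evaluate_policy <- function(policy, S1, S2, scoring = scoring_scheme(),
                            W = policy$config$window) {
  c1 <- dna_codes(S1); c2 <- dna_codes(S2)
  x <- 0L; y <- 0L
  needs_enc <- inherits(policy, "dqn_net")
  n_max <- length(c1) + length(c2)
  traj <- vector("list", n_max)
  cols <- character(n_max)
  total <- 0; nstep <- 0L
  while (x < length(c1) && y < length(c2)) {
    w1 <- window_codes(c1, x, W); w2 <- window_codes(c2, y, W)
    st <- structure(list(codes1 = w1, codes2 = w2, W = W,
                         enc = if (needs_enc) encode_windows(w1, w2, W)),
                    class = "window_state")
    q <- q_values(policy, st)
    act <- which.max(q)
    mv <- step_codes(c1, c2, x, y, act, scoring)
    x <- mv$x; y <- mv$y
    nstep <- nstep + 1L
    cols[nstep] <- if (act == 1L) {
      if (mv$r == scoring$match) "M" else "X"
    } else if (act == 2L) "I" else "D"
    total <- total + mv$r
    traj[[nstep]] <- list(c1 = w1, c2 = w2, a = act, r = mv$r,
                          n1 = window_codes(c1, x, W),
                          n2 = window_codes(c2, y, W),
                          done = mv$terminal)
  }
  cols <- cols[seq_len(nstep)]
  list(trajectory = traj[seq_len(nstep)], reward = total,
       identity = if (nstep > 0) sum(cols == "M") / nstep else NA_real_,
       steps = nstep, columns = cols)
}

#' Meta-train a Q-network over a distribution of environments
#'
#' For each of `M` outer iterations: sample a mutation environment, simulate
#' a training pair and a held-out pair, train a copy of the outer network for
#' `N` inner steps on the training pair, evaluate the trained copy greedily
#' on the held-out pair (no gradient steps touch the held-out pair), append
#' the evaluation trajectories to the outer replay buffer, and update the
#' outer network with `outer_updates` gradient steps sampled from that
#' buffer. Epsilon decays linearly across the `M * N` total inner steps.
#'
#' @param dist An [environment_distribution()].
#' @param meta A [meta_config()].
#' @param netcfg A [network_config()].
#' @param verbose Print one summary line per outer iteration.
#' @return The final `dqn_net` (outer network after `M` iterations).
#' @export
meta_train <- function(dist, meta, netcfg = network_config(),
                       verbose = FALSE) {
  if (!is.null(meta$seed)) set.seed(meta$seed)
  net <- dqn_network(netcfg)
  outer_target <- net
  outer_buf <- replay_buffer(meta$outer_buffer)
  total <- meta$M * max(meta$N, 1)
  eps_fun <- linear_eps(netcfg, total)
  for (outer in seq_len(meta$M)) {
    model <- sample_environment(dist)
    pair <- make_environment_pair(model, meta$seq_length)
    inner <- inner_loop_train(net, pair, meta$N, meta$scoring,
                              eps_fun = eps_fun,
                              step_offset = (outer - 1) * meta$N)
    ev <- NULL
    for (ep in seq_len(meta$eval_episodes)) {
      ev <- evaluate_policy(inner$net, pair$S1_eval, pair$S2_eval,
                            meta$scoring)
      for (tr in ev$trajectory) {
        outer_buf$pos <- (outer_buf$pos %% outer_buf$capacity) + 1L
        outer_buf$store[[outer_buf$pos]] <- tr
        outer_buf$size <- min(outer_buf$size + 1L, outer_buf$capacity)
      }
    }
    for (u in seq_len(meta$outer_updates)) {
      if (buffer_size(outer_buf) < netcfg$batch_size) break
      ts <- train_step(net, outer_target, outer_buf, netcfg)
      net <- ts$net
      outer_target <- soft_update_target(net, outer_target, netcfg$tau)
    }
    if (verbose && !is.null(ev)) {
      message(sprintf(
        "outer %d/%d: p_snp=%.3f p_indel=%.3f maxI=%d eval_reward=%g eval_identity=%.3f buffer=%d",
        outer, meta$M, model$p_snp, model$p_indel, model$max_indel,
        ev$reward, ev$identity, buffer_size(outer_buf)))
    }
  }
  net$meta$root_seed <- meta$seed
  net
}

#' Fine-tune a trained network on user-supplied sequences
#'
#' Continues DQN training using pairs drawn from the given sequences (all
#' unordered pairs, cycled), with the same update rule as the inner loop and
#' a constant exploration rate `eps_end`.
#'
#' @param net A trained `dqn_net`.
#' @param seqs Character vector of at least two sequences.
#' @param steps Number of training steps.
#' @param scoring A [scoring_scheme()].
#' @param seed Optional seed.
#' @return The fine-tuned network.
#' @export
fine_tune <- function(net, seqs, steps, scoring = scoring_scheme(),
                      seed = NULL) {
  if (length(seqs) < 2) stop("fine-tuning requires at least 2 sequences")
  if (steps == 0) return(net)
  if (!is.null(seed)) set.seed(seed)
  cfg <- net$config
  W <- cfg$window
  pairs <- utils::combn(length(seqs), 2)
  buffer <- replay_buffer(min(cfg$buffer_capacity, max(steps, 1)))
  target <- net
  pi <- 0L
  codes <- lapply(seqs, dna_codes)
  c1 <- NULL; c2 <- NULL; x <- 0L; y <- 0L
  for (t in seq_len(steps)) {
    if (is.null(c1) || x >= length(c1) || y >= length(c2)) {
      pi <- (pi %% ncol(pairs)) + 1L
      c1 <- codes[[pairs[1, pi]]]; c2 <- codes[[pairs[2, pi]]]
      x <- 0L; y <- 0L
    }
    w1 <- window_codes(c1, x, W); w2 <- window_codes(c2, y, W)
    st <- structure(list(codes1 = w1, codes2 = w2, W = W,
                         enc = encode_windows(w1, w2, W)),
                    class = "window_state")
    q <- as.vector(net_forward(net, matrix(st$enc, nrow = 1))$Q)
    act <- match(select_action(q, cfg$eps_end), ACTIONS)
    mv <- step_codes(c1, c2, x, y, act, scoring)
    x <- mv$x; y <- mv$y
    nst <- structure(list(codes1 = window_codes(c1, x, W),
                          codes2 = window_codes(c2, y, W), W = W, enc = NULL),
                     class = "window_state")
    buffer_add(buffer, st, act, mv$r, nst, mv$terminal)
    if (buffer_size(buffer) >= cfg$batch_size) {
      ts <- train_step(net, target, buffer, cfg)
      net <- ts$net
      target <- soft_update_target(net, target, cfg$tau)
    }
  }
  net
}
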