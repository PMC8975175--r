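# Q-function over window states: dueling double DQN with a standard-
# convolution variant and a separable-convolution variant, plus replay
# buffer, epsilon-greedy selection, regression targets and training step.

#' Q-network configuration
#'
#' @param window Window size `W` observed at each step (must match the
#'   environment's window).
#' @param conv_variant `"separable"` (depthwise-then-pointwise convolutions,
#'   the cheaper default) or `"standard"`.
#' @param channels Integer vector of output channels per convolutional block.
#' @param kernel Odd kernel width of every convolution.
#' @param hidden Width of the fully connected layer feeding the dueling heads.
#' @param gamma Discount factor in `[0, 1]`.
#' @param lr Adam learning rate.
#' @param tau Polyak rate of the soft target update, per training step.
#' @param eps_start,eps_end,eps_decay_frac Linear epsilon-greedy schedule:
#'   epsilon decays from `eps_start` to `eps_end` over the first
#'   `eps_decay_frac` fraction of total training steps.
#' @param batch_size Minibatch size sampled from the replay buffer.
#' @param buffer_capacity Replay-buffer capacity (FIFO).
#' @param clip_norm Global gradient-norm clip.
#' @param double_action_from `"main"` (standard double DQN: the argmax action
#'   comes from the main network and is valued by the target network) or
#'   `"target"` (both from the target network).
#' @return Object of class `network_config`.
#' @export
network_config <- function(window = 10, conv_variant = c("separable", "standard"),
                           channels = c(16, 16), kernel = 3, hidden = 64,
                           gamma = 0.99, lr = 1e-3, tau = 0.001,
                           eps_start = 1.0, eps_end = 0.05,
                           eps_decay_frac = 0.5,
                           batch_size = 32, buffer_capacity = 1e5,
                           clip_norm = 10,
                           double_action_from = c("main", "target")) {
  conv_variant <- match.arg(conv_variant)
  double_action_from <- match.arg(double_action_from)
  stopifnot(window >= 1, kernel %% 2 == 1, gamma >= 0, gamma <= 1,
            length(channels) >= 1, all(channels >= 1), hidden >= 1)
  structure(list(window = as.integer(window), conv_variant = conv_variant,
                 channels = as.integer(channels), kernel = as.integer(kernel),
                 hidden = as.integer(hidden), gamma = gamma, lr = lr,
                 tau = tau, eps_start = eps_start, eps_end = eps_end,
                 eps_decay_frac = eps_decay_frac,
                 batch_size = as.integer(batch_size),
                 buffer_capacity = as.integer(buffer_capacity),
                 clip_norm = clip_norm,
                 double_action_from = double_action_from),
            class = "network_config")
}

#' Build a Q-network
#'
#' Initializes a dueling DQN over `2 x W x 5` one-hot window states
#' (He-style initialization). Deterministic given the RNG state; pass `seed`
#' for local reproducibility.
#'
#' @param config A [network_config()].
#' @param seed Optional integer seed for weight initialization.
#' @return Object of class `dqn_net`.
#' @export
dqn_network <- function(config = network_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  k <- config$kernel
  in_ch <- 10L
  conv <- list()
  for (bi in seq_along(config$channels)) {
    out_ch <- config$channels[bi]
    if (config$conv_variant == "standard") {
      Wt <- lapply(seq_len(k), function(i)
        matrix(stats::rnorm(in_ch * out_ch, sd = sqrt(2 / (k * in_ch))),
               in_ch, out_ch))
      conv[[bi]] <- list(type = "standard", Wt = Wt, b = numeric(out_ch))
    } else {
      conv[[bi]] <- list(
        type = "separable",
        Dw = matrix(stats::rnorm(k * in_ch, sd = sqrt(2 / k)), k, in_ch),
        P = matrix(stats::rnorm(in_ch * out_ch, sd = sqrt(2 / in_ch)),
                   in_ch, out_ch),
        b = numeric(out_ch))
    }
    in_ch <- out_ch
  }
  flat <- config$window * in_ch
  params <- list(
    conv = conv,
    dense = list(W = matrix(stats::rnorm(flat * config$hidden,
                                         sd = sqrt(2 / flat)),
                            flat, config$hidden),
                 b = numeric(config$hidden)),
    v = list(W = matrix(stats::rnorm(config$hidden, sd = sqrt(1 / config$hidden)),
                        config$hidden, 1),
             b = 0),
    a = list(W = matrix(stats::rnorm(config$hidden * 3,
                                     sd = sqrt(1 / config$hidden)),
                        config$hidden, 3),
             b = numeric(3)))
  zeros <- param_map1(params, function(x) x * 0)
  structure(list(config = config, params = params,
                 taps = seq_len(k) - (k + 1L) %/% 2L,
                 opt = list(t = 0, m = zeros, v = zeros),
                 meta = list(trained_steps = 0L, seed = seed)),
            class = c("dqn_net", "alignment_policy"))
}

#' Number of trainable parameters of a network
#'
#' The separable variant has strictly fewer parameters than the standard
#' variant at equal channel widths.
#'
#' @param net A `dqn_net`.
#' @return Integer parameter count.
#' @export
n_parameters <- function(net) {
  param_reduce(net$params, function(acc, x) acc + length(x))
}

#' Q-values of a policy for a window state
#'
#' Generic over policies: any object implementing `q_values()` can drive the
#' x-drop extender, so deterministic stub policies are drop-in replacements
#' for trained networks.
#'
#' @param policy A `dqn_net` or any `alignment_policy`.
#' @param state A `window_state` from [extract_state()].
#' @return Named numeric of length 3: `forward`, `insertion`, `deletion`.
#' @export
q_values <- function(policy, state) UseMethod("q_values")

#' @export
q_values.dqn_net <- function(policy, state) {
  stopifnot(inherits(state, "window_state"))
  if (state$W != policy$config$window)
    stop("state window size ", state$W, " does not match network window ",
         policy$config$window)
  out <- net_forward(policy, matrix(state$enc, nrow = 1))
  q <- as.vector(out$Q)
  names(q) <- ACTIONS
  q
}

# batch Q-matrix for encoded states (rows); internal fast path
q_matrix <- function(net, X) net_forward(net, X)$Q

#' Epsilon-greedy action selection
#'
#' With probability `1 - epsilon` returns the argmax action, ties broken in
#' fixed order forward > insertion > deletion; with probability `epsilon` a
#' uniform random action.
#'
#' @param q Named Q-value vector (order forward, insertion, deletion).
#' @param epsilon Exploration probability in `[0, 1]`.
#' @return One of `"forward"`, `"insertion"`, `"deletion"`.
#' @export
select_action <- function(q, epsilon = 0) {
  if (epsilon > 0 && stats::runif(1) < epsilon)
    return(ACTIONS[sample.int(3L, 1L)])
  ACTIONS[which.max(q)]
}

#' Create a replay buffer
#'
#' Bounded FIFO of transitions with uniform sampling. Stores integer-coded
#' windows (not one-hot encodings) and encodes on sampling.
#'
#' @param capacity Maximum number of stored transitions.
#' @return Object of class `replay_buffer` (mutable environment).
#' @export
replay_buffer <- function(capacity = 1e5) {
  buf <- new.env(parent = emptyenv())
  buf$capacity <- as.integer(capacity)
  buf$store <- vector("list", as.integer(capacity))
  buf$size <- 0L
  buf$pos <- 0L
  class(buf) <- "replay_buffer"
  buf
}

#' @export
print.replay_buffer <- function(x, ...) {
  cat(sprintf("replay buffer: %d / %d transitions\n", x$size, x$capacity))
  invisible(x)
}

#' Append a transition to a replay buffer
#'
#' @param buf A [replay_buffer()].
#' @param state,next_state `window_state` objects.
#' @param action Action taken (name or index).
#' @param reward Scalar reward.
#' @param terminal Did the episode end at `next_state`?
#' @return The buffer, invisibly.
#' @export
buffer_add <- function(buf, state, action, reward, next_state, terminal) {
  if (is.character(action)) action <- match(action, ACTIONS)
  buf$pos <- (buf$pos %% buf$capacity) + 1L
  buf$store[[buf$pos]] <- list(
    c1 = state$codes1, c2 = state$codes2,
    a = as.integer(action), r = reward,
    n1 = next_state$codes1, n2 = next_state$codes2,
    done = isTRUE(terminal))
  buf$size <- min(buf$size + 1L, buf$capacity)
  invisible(buf)
}

#' Number of stored transitions
#' @param buf A [replay_buffer()].
#' @return Integer size.
#' @export
buffer_size <- function(buf) buf$size

#' Sample a uniform minibatch from a replay buffer
#'
#' @param buf A [replay_buffer()].
#' @param n Batch size (requires `buffer_size(buf) >= n`).
#' @param W Window size (for encoding).
#' @return List with matrices `S`, `S2` (`n x (W*10)` encodings), integer
#'   `actions`, numeric `rewards`, logical `done`.
#' @export
buffer_sample <- function(buf, n, W) {
  if (buf$size < n) stop("replay buffer holds ", buf$size,
                         " transitions; need ", n)
  idx <- sample.int(buf$size, n)
  encode_batch(buf$store[idx], W)
}

encode_batch <- function(exps, W) {
  n <- length(exps)
  S <- matrix(0, n, W * 10L)
  S2 <- matrix(0, n, W * 10L)
  for (i in seq_len(n)) {
    e <- exps[[i]]
    S[i, ] <- encode_windows(e$c1, e$c2, W)
    S2[i, ] <- encode_windows(e$n1, e$n2, W)
  }
  list(S = S, S2 = S2,
       actions = vapply(exps, `[[`, integer(1), "a"),
       rewards = vapply(exps, `[[`, numeric(1), "r"),
       done = vapply(exps, `[[`, logical(1), "done"))
}

#' Double-DQN regression targets for a minibatch
#'
#' `target = r` for terminal transitions, else
#' `r + gamma * Q_target(s', a*)` where `a*` is the argmax action under the
#' main network (standard double-DQN decoupling; set
#' `double_action_from = "target"` in the config to take the argmax under the
#' target network instead).
#'
#' @param batch A minibatch from [buffer_sample()].
#' @param gamma Discount factor.
#' @param main_net,target_net `dqn_net` objects of identical architecture.
#' @param action_from `"main"` or `"target"`.
#' @return Numeric vector of per-item targets.
#' @export
double_dqn_target <- function(batch, gamma, main_net, target_net,
                              action_from = main_net$config$double_action_from) {
  n <- length(batch$rewards)
  tgt <- batch$rewards
  live <- !batch$done
  if (gamma > 0 && any(live)) {
    S2 <- batch$S2[live, , drop = FALSE]
    Qt <- q_matrix(target_net, S2)
    Qsel <- if (identical(action_from, "target")) Qt else q_matrix(main_net, S2)
    astar <- max.col(Qsel, ties.method = "first")
    tgt[live] <- tgt[live] + gamma * Qt[cbind(seq_len(nrow(Qt)), astar)]
  }
  tgt
}

#' Polyak (soft) target-network update
#'
#' Every parameter of the target network moves toward the main network:
#' `theta_t <- tau * theta_m + (1 - tau) * theta_t`.
#'
#' @param main_net,target_net `dqn_net` objects of identical architecture.
#' @param tau Blend rate in `[0, 1]`.
#' @return The updated target network.
#' @export
soft_update_target <- function(main_net, target_net, tau) {
  if (!identical(main_net$config[c("window", "conv_variant", "channels",
                                   "kernel", "hidden")],
                 target_net$config[c("window", "conv_variant", "channels",
                                     "kernel", "hidden")]))
    stop("main and target network architectures differ")
  target_net$params <- param_map2(main_net$params, target_net$params,
                                  function(m, t) tau * m + (1 - tau) * t)
  target_net
}

#' One DQN training step
#'
#' Samples a minibatch, computes double-DQN targets, takes one Adam step on
#' the squared error between `Q(s, a)` and the targets (gradient-norm
#' clipped), and returns the pre-step loss. If the buffer holds fewer than
#' `batch_size` transitions, no step is taken and loss is `NA`.
#'
#' @param main_net,target_net `dqn_net` objects.
#' @param buffer A [replay_buffer()] (or a pre-sampled minibatch from
#'   [buffer_sample()], for training repeatedly on a frozen batch).
#' @param config A [network_config()]; defaults to the main network's.
#' @return List with `net` (updated main network) and `loss`.
#' @export
train_step <- function(main_net, target_net, buffer,
                       config = main_net$config) {
  if (inherits(buffer, "replay_buffer")) {
    if (buffer_size(buffer) < config$batch_size)
      return(list(net = main_net, loss = NA_real_))
    batch <- buffer_sample(buffer, config$batch_size, config$window)
  } else batch <- buffer
  tgt <- double_dqn_target(batch, config$gamma, main_net, target_net)
  fw <- net_forward(main_net, batch$S, want_cache = TRUE)
  n <- nrow(batch$S)
  sel <- cbind(seq_len(n), batch$actions)
  err <- fw$Q[sel] - tgt
  loss <- mean(err^2)
  dQ <- matrix(0, n, 3)
  dQ[sel] <- 2 * err / n
  grads <- net_backward(main_net, fw$cache, dQ)
  main_net <- adam_step(main_net, grads, config$lr, config$clip_norm)
  main_net$meta$trained_steps <- main_net$meta$trained_steps + 1L
  list(net = main_net, loss = loss)
}

CHECKPOINT_FORMAT <- "dqnxdrop-checkpoint/1"

#' Save / load a network checkpoint
#'
#' Single-file serialized weights plus configuration and training metadata,
#' with a version tag. A save/load round trip reproduces bit-identical
#' Q-values.
#'
#' @param net A `dqn_net`.
#' @param path File path.
#' @return `save_checkpoint`: `path`, invisibly. `load_checkpoint`: the
#'   restored `dqn_net`.
#' @export
save_checkpoint <- function(net, path) {
  saveRDS(list(format = CHECKPOINT_FORMAT, config = net$config,
               params = net$params, taps = net$taps, opt = net$opt,
               meta = net$meta), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, CHECKPOINT_FORMAT))
    stop("unrecognized checkpoint format: ", obj$format)
  structure(obj[c("config", "params", "taps", "opt", "meta")],
            class = c("dqn_net", "alignment_policy"))
}

#' @export
print.dqn_net <- function(x, ...) {
  cat(sprintf("dqn_net: W=%d %s conv [%s] hidden=%d, %d parameters, %d trained steps\n",
              x$config$window, x$config$conv_variant,
              paste(x$config$channels, collapse = ","), x$config$hidden,
              n_parameters(x), x$meta$trained_steps))
  invisible(x)
}
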