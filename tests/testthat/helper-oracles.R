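# Independent oracles and small fixture builders shared across tests.

# Exhaustive full-matrix extension DP (global start at (0,0), free end):
# the brute-force oracle for greedy x-drop extension with X = Inf.
brute_force_extension <- function(S1, S2, sc = scoring_scheme()) {
  a <- dna_codes(S1)
  b <- dna_codes(S2)
  m <- length(a)
  n <- length(b)
  H <- matrix(-Inf, m + 1, n + 1)
  H[1, 1] <- 0
  for (i in 0:m) {
    for (j in 0:n) {
      if (i == 0 && j == 0) next
      v <- -Inf
      if (i > 0 && j > 0)
        v <- max(v, H[i, j] +
                   if (a[i] == b[j] && a[i] <= 4) sc$match else sc$mismatch)
      if (i > 0) v <- max(v, H[i, j + 1] + sc$gap)
      if (j > 0) v <- max(v, H[i + 1, j] + sc$gap)
      H[i + 1, j + 1] <- v
    }
  }
  max(H)
}

# direct truncated-Zipf pmf on 1..max_indel
zipf_pmf <- function(s, max_indel) {
  p <- (1:max_indel)^(-s)
  p / sum(p)
}

# a tiny network + filled buffer for qnet tests
make_test_net <- function(variant = "separable", W = 6, seed = 42) {
  cfg <- network_config(window = W, conv_variant = variant,
                        channels = c(4, 4), hidden = 16, batch_size = 8)
  dqn_network(cfg, seed = seed)
}

fill_buffer <- function(n, W = 6, seed = 1) {
  set.seed(seed)
  buf <- replay_buffer(max(n, 64))
  sc <- scoring_scheme()
  S1 <- generate_random_sequence(200)
  S2 <- mutate_sequence(S1, mutation_model(0.1, 0.02))$seq
  pos <- c(0, 0)
  for (i in seq_len(n)) {
    if (episode_terminal(S1, S2, pos)) pos <- c(0, 0)
    st <- extract_state(S1, S2, pos, W)
    act <- sample(c("forward", "insertion", "deletion"), 1)
    mv <- apply_action(S1, S2, pos, act, sc)
    if (mv$terminal) { pos <- c(0, 0); next }
    nst <- extract_state(S1, S2, mv$pos, W)
    buffer_add(buf, st, act, mv$reward,
               nst, episode_terminal(S1, S2, mv$pos))
    pos <- mv$pos
  }
  buf
}
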