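DNA_BASES <- c("A", "C", "G", "T")

#' Mutation model for sequence-pair simulation
#'
#' Defines the evolution model used to derive one sequence from another:
#' independent per-base substitutions (SNPs) plus indels whose lengths follow
#' a truncated Zipfian (power-law) distribution. A mutation model is both a
#' training environment for the aligner and a fixture generator for tests.
#'
#' @param p_snp Per-base substitution probability in `[0, 1]`.
#' @param p_indel Per-base indel-initiation probability in `[0, 1]`.
#' @param zipf_s Zipfian exponent `s > 1` of the indel-length distribution.
#' @param max_indel Maximum indel length (positive integer, or `Inf` for the
#'   untruncated distribution).
#' @param p_insertion Probability that an initiated indel is an insertion
#'   (the remainder are deletions).
#' @return An object of class `mutation_model`.
#' @examples
#' m <- mutation_model(p_snp = 0.05, p_indel = 0.01)
#' @export
mutation_model <- function(p_snp, p_indel, zipf_s = 1.5, max_indel = 10,
                           p_insertion = 0.5) {
  stopifnot(is.numeric(p_snp), length(p_snp) == 1, p_snp >= 0, p_snp <= 1)
  stopifnot(is.numeric(p_indel), length(p_indel) == 1, p_indel >= 0, p_indel <= 1)
  stopifnot(is.numeric(zipf_s), length(zipf_s) == 1, zipf_s > 1)
  stopifnot(length(max_indel) == 1, max_indel >= 1)
  stopifnot(p_insertion >= 0, p_insertion <= 1)
  structure(list(p_snp = p_snp, p_indel = p_indel, zipf_s = zipf_s,
                 max_indel = max_indel, p_insertion = p_insertion),
            class = "mutation_model")
}

#' @export
print.mutation_model <- function(x, ...) {
  cat(sprintf(
    "mutation model: p_snp=%g p_indel=%g zipf_s=%g max_indel=%s p_insertion=%g\n",
    x$p_snp, x$p_indel, x$zipf_s, format(x$max_indel), x$p_insertion))
  invisible(x)
}

#' Generate a uniform random DNA sequence
#'
#' Bases are i.i.d. uniform over `{A, C, G, T}`. Reproducible under
#' `set.seed()`; pass `seed` to set the RNG locally.
#'
#' @param length Non-negative sequence length.
#' @param id Identifier attached as the `id` attribute.
#' @param seed Optional integer seed.
#' @return A single character string of `length` bases with attribute `id`.
#' @export
generate_random_sequence <- function(length, id = "random", seed = NULL) {
  if (!is.numeric(length) || length(length) != 1 || is.na(length) || length < 0)
    stop("`length` must be a single non-negative number")
  if (!is.null(seed)) set.seed(seed)
  s <- if (length == 0) "" else
    paste(DNA_BASES[sample.int(4L, length, replace = TRUE)], collapse = "")
  attr(s, "id") <- id
  s
}

# Truncated-Zipf probability vector over 1..max_indel; max_indel = Inf is
# truncated internally at 1e6 (residual tail mass < 1e-6 for s > 1.3).
zipf_probs <- function(s, max_indel) {
  top <- if (is.infinite(max_indel)) 1e6L else as.integer(max_indel)
  p <- (1:top)^(-s)
  p / sum(p)
}

#' Sample indel lengths from the model's truncated Zipfian
#'
#' Lengths `l` are drawn with probability proportional to `1 / l^s`,
#' renormalized on `1..max_indel`.
#'
#' @param model A [mutation_model()].
#' @param n Number of draws.
#' @return Integer vector of `n` lengths in `1..max_indel`.
#' @export
sample_indel_length <- function(model, n = 1) {
  stopifnot(inherits(model, "mutation_model"), n >= 0)
  if (n == 0) return(integer(0))
  if (model$max_indel == 1) return(rep(1L, n))
  p <- zipf_probs(model$zipf_s, model$max_indel)
  sample.int(length(p), n, replace = TRUE, prob = p)
}

#' Replay a mutation event log
#'
#' Applies a list of mutation events (as produced by [mutate_sequence()]) to a
#' source sequence. Substitutions are applied first; indels are then applied
#' from right to left so that source coordinates remain valid. An insertion at
#' position `p` (0-based) inserts its payload immediately before the source
#' base at index `p`; a deletion at `p` removes bases `p .. p+length-1`.
#'
#' @param seq Source sequence (character string).
#' @param events Data frame with columns `kind`, `position`, `length`, `payload`.
#' @return The mutated sequence (character string).
#' @export
replay_events <- function(seq, events) {
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  if (nrow(events) == 0) return(paste(ch, collapse = ""))
  subs <- events[events$kind == "substitution", , drop = FALSE]
  if (nrow(subs) > 0) ch[subs$position + 1L] <- subs$payload
  ind <- events[events$kind != "substitution", , drop = FALSE]
  if (nrow(ind) > 0) {
    ind <- ind[order(ind$position, decreasing = TRUE), , drop = FALSE]
    pieces <- ch
    for (r in seq_len(nrow(ind))) {
      p <- ind$position[r]
      if (ind$kind[r] == "insertion") {
        ins <- strsplit(ind$payload[r], "", fixed = TRUE)[[1]]
        pieces <- append(pieces, ins, after = p)
      } else {
        drop_idx <- (p + 1L):(p + ind$length[r])
        pieces <- pieces[-drop_idx]
      }
    }
    ch <- pieces
  }
  paste(ch, collapse = "")
}

#' Mutate a sequence under a mutation model
#'
#' Each base is substituted independently with probability `p_snp`, always to
#' one of the three other bases (so `p_snp` is the realized divergence rate).
#' At each position an indel initiates with probability `p_indel`; it is an
#' insertion with probability `p_insertion`, otherwise a deletion, with length
#' drawn from the truncated Zipfian. Indels initiating inside an earlier
#' deletion's span are dropped; deletions are truncated at the sequence end.
#' The returned event log replays exactly from source to output via
#' [replay_events()].
#'
#' @param seq Source sequence (non-empty character string).
#' @param model A [mutation_model()].
#' @param seed Optional integer seed.
#' @return List with elements `seq` (mutated sequence) and `events`
#'   (data frame log with columns `kind`, `position`, `length`, `payload`).
#' @export
mutate_sequence <- function(seq, model, seed = NULL) {
  stopifnot(inherits(model, "mutation_model"), nchar(seq) > 0)
  if (!is.null(seed)) set.seed(seed)
  n <- nchar(seq)
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]

  ev_kind <- character(0); ev_pos <- integer(0)
  ev_len <- integer(0); ev_pay <- character(0)

  sub_mask <- stats::runif(n) < model$p_snp
  sub_pos <- which(sub_mask)
  if (length(sub_pos) > 0) {
    code <- match(ch[sub_pos], DNA_BASES)
    off <- sample.int(3L, length(sub_pos), replace = TRUE)
    new_base <- DNA_BASES[((code - 1L + off) %% 4L) + 1L]
    ev_kind <- c(ev_kind, rep("substitution", length(sub_pos)))
    ev_pos <- c(ev_pos, sub_pos - 1L)
    ev_len <- c(ev_len, rep(1L, length(sub_pos)))
    ev_pay <- c(ev_pay, new_base)
  }

  ind_pos <- which(stats::runif(n) < model$p_indel)
  if (length(ind_pos) > 0) {
    is_ins <- stats::runif(length(ind_pos)) < model$p_insertion
    lens <- sample_indel_length(model, length(ind_pos))
    blocked_until <- -1L   # 0-based source index covered by a previous deletion
    for (i in seq_along(ind_pos)) {
      p0 <- ind_pos[i] - 1L              # 0-based
      if (p0 <= blocked_until) next      # inside an earlier deletion
      if (is_ins[i]) {
        pay <- paste(DNA_BASES[sample.int(4L, lens[i], replace = TRUE)],
                     collapse = "")
        ev_kind <- c(ev_kind, "insertion"); ev_pos <- c(ev_pos, p0)
        ev_len <- c(ev_len, lens[i]); ev_pay <- c(ev_pay, pay)
      } else {
        len <- min(lens[i], n - p0)      # truncate at sequence end
        ev_kind <- c(ev_kind, "deletion"); ev_pos <- c(ev_pos, p0)
        ev_len <- c(ev_len, as.integer(len)); ev_pay <- c(ev_pay, "")
        blocked_until <- p0 + as.integer(len) - 1L
      }
    }
  }

  events <- data.frame(kind = ev_kind, position = ev_pos, length = ev_len,
                       payload = ev_pay, stringsAsFactors = FALSE)
  events <- events[order(events$position, events$kind), , drop = FALSE]
  rownames(events) <- NULL
  out <- replay_events(seq, events)
  attr(out, "id") <- paste0(attr(seq, "id"), "_mut")
  list(seq = out, events = events)
}

#' Generate one training environment: two ancestral/mutated sequence pairs
#'
#' Draws two independent ancestral sequences and mutates each under the same
#' model. The first pair `(S1, S2)` is intended for inner-loop training; the
#' held-out pair `(S1_eval, S2_eval)` for post-training evaluation.
#'
#' @param model A [mutation_model()].
#' @param length Ancestral sequence length (> 0).
#' @param seed Optional integer seed.
#' @return List of class `environment_pair` with `S1`, `S2`, `events`,
#'   `S1_eval`, `S2_eval`, `events_eval`, and the generating `model`.
#' @export
make_environment_pair <- function(model, length, seed = NULL) {
  stopifnot(length > 0)
  if (!is.null(seed)) set.seed(seed)
  S1 <- generate_random_sequence(length, id = "S1")
  m1 <- mutate_sequence(S1, model)
  S1e <- generate_random_sequence(length, id = "S1_eval")
  m2 <- mutate_sequence(S1e, model)
  structure(list(S1 = S1, S2 = m1$seq, events = m1$events,
                 S1_eval = S1e, S2_eval = m2$seq, events_eval = m2$events,
                 model = model),
            class = "environment_pair")
}

#' Derive a reproducible sub-seed from a root seed
#'
#' Components of a larger run (simulator, network init, training, benchmark)
#' draw from independent streams derived from one root seed, so each piece is
#' reproducible in isolation. Kept below 2^31 - 1.
#'
#' @param root Integer root seed.
#' @param salt Integer stream label.
#' @return A single integer seed.
#' @export
derive_seed <- function(root, salt) {
  as.integer((as.numeric(root) * 48271 + as.numeric(salt) * 1103) %% 2147483629)
}
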