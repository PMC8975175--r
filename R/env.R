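# Alignment MDP: windowed observations over two sequences, three actions
# (forward / insertion / deletion), scoring-scheme rewards.
#
# Conventions, fixed package-wide:
#  - coordinates are 0-based half-open; position (x, y) means x bases of S1
#    and y bases of S2 have been consumed;
#  - FORWARD advances both pointers by one column (match or mismatch);
#  - INSERTION opens a gap in S1 and consumes one base of S2;
#  - DELETION opens a gap in S2 and consumes one base of S1;
#  - base codes: A=1 C=2 G=3 T=4 N=5, PAD=0. N never matches anything.

ACTIONS <- c("forward", "insertion", "deletion")

#' Alignment scoring scheme
#'
#' Match/mismatch/gap scores drive both the RL reward and the alignment score.
#' Gaps are linear (a single per-column gap score; no affine opening cost).
#'
#' @param match Score of a matching column (> 0).
#' @param mismatch Score of a mismatching column (< match).
#' @param gap Score of a gap column (< 0).
#' @return Object of class `scoring_scheme`.
#' @export
scoring_scheme <- function(match = 1, mismatch = -1, gap = -2) {
  stopifnot(match > 0, gap < 0, match > mismatch)
  structure(list(match = match, mismatch = mismatch, gap = gap),
            class = "scoring_scheme")
}

#' Convert a DNA character string to integer codes
#'
#' @param seq Character string over `{A,C,G,T,N}` (or an already-coded
#'   integer vector, returned unchanged).
#' @return Integer vector: A=1, C=2, G=3, T=4, N=5.
#' @export
dna_codes <- function(seq) {
  if (is.integer(seq) || is.numeric(seq)) return(as.integer(seq))
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  code <- match(ch, c("A", "C", "G", "T", "N"))
  if (anyNA(code)) stop("sequence contains symbols outside {A,C,G,T,N}")
  code
}

# window of W codes starting at 0-based pos; 0 = PAD past the end
window_codes <- function(codes, pos, W) {
  n <- length(codes)
  idx <- (pos + 1L):(pos + W)
  out <- integer(W)
  real <- idx <= n
  out[real] <- codes[idx[real]]
  out
}

# One-hot encoding of a (window1, window2) code pair: numeric vector of
# length W*10, position-major with 10 channels per position (5 for each
# window: A,C,G,T,PAD; N encodes as all-zeros so the net sees "unknown").
# channel by code 0..5: PAD->5, A..T->1..4, N->NA (all-zero row)
CHMAP <- c(5L, 1L, 2L, 3L, 4L, NA_integer_)

encode_windows <- function(c1, c2, W = length(c1)) {
  enc <- numeric(W * 10L)
  w10 <- (seq_len(W) - 1L) * 10L
  i1 <- w10 + CHMAP[c1 + 1L]
  i2 <- w10 + 5L + CHMAP[c2 + 1L]
  enc[c(i1[!is.na(i1)], i2[!is.na(i2)])] <- 1
  enc
}

#' Extract the windowed RL state at an alignment position
#'
#' The state observed by the Q-network: the next `W` symbols of each sequence
#' starting at the current position, PAD-filled past either end, one-hot
#' encoded over `{A,C,G,T,PAD}` per window (an `N` row is all-zeros).
#'
#' @param S1,S2 Sequences (character strings or [dna_codes()] vectors).
#' @param pos Numeric `c(x, y)`, 0-based counts of consumed bases.
#' @param W Window size (>= 1).
#' @return Object of class `window_state`: list with `codes1`, `codes2`
#'   (length-`W` integer windows, 0 = PAD), `W`, and `enc` (numeric
#'   length `W*10`, the flattened 2 x W x 5 one-hot array).
#' @export
extract_state <- function(S1, S2, pos, W) {
  stopifnot(W >= 1)
  c1 <- dna_codes(S1); c2 <- dna_codes(S2)
  x <- as.integer(pos[1]); y <- as.integer(pos[2])
  stopifnot(x >= 0, y >= 0, x <= length(c1), y <= length(c2))
  w1 <- window_codes(c1, x, W)
  w2 <- window_codes(c2, y, W)
  structure(list(codes1 = w1, codes2 = w2, W = W,
                 enc = encode_windows(w1, w2, W)),
            class = "window_state")
}

#' Has the alignment episode reached a sequence end?
#'
#' @inheritParams extract_state
#' @return `TRUE` iff `x == nchar(S1)` or `y == nchar(S2)`.
#' @export
episode_terminal <- function(S1, S2, pos) {
  n1 <- if (is.character(S1)) nchar(S1) else length(S1)
  n2 <- if (is.character(S2)) nchar(S2) else length(S2)
  pos[1] >= n1 || pos[2] >= n2
}

#' Apply an alignment action at a position
#'
#' `forward` consumes one base of each sequence and yields the match score if
#' they agree (`N` never matches) else the mismatch score, emitting column
#' `M` or `X`. `insertion` consumes one base of S2 (column `I`), `deletion`
#' one base of S1 (column `D`); both yield the gap score. An action that
#' would consume past a sequence end returns `terminal = TRUE` with no state
#' change.
#'
#' @inheritParams extract_state
#' @param action One of `"forward"`, `"insertion"`, `"deletion"` (or index 1:3).
#' @param scoring A [scoring_scheme()].
#' @return List with `pos` (updated), `reward`, `column` (one of
#'   `"M","X","I","D"`, or `NA` if terminal), and `terminal`.
#' @export
apply_action <- function(S1, S2, pos, action, scoring) {
  c1 <- dna_codes(S1); c2 <- dna_codes(S2)
  if (is.numeric(action)) action <- ACTIONS[action]
  action <- match.arg(action, ACTIONS)
  x <- as.integer(pos[1]); y <- as.integer(pos[2])
  n1 <- length(c1); n2 <- length(c2)
  need1 <- action %in% c("forward", "deletion")
  need2 <- action %in% c("forward", "insertion")
  if ((need1 && x >= n1) || (need2 && y >= n2)) {
    return(list(pos = c(x, y), reward = 0, column = NA_character_,
                terminal = TRUE))
  }
  if (action == "forward") {
    is_match <- c1[x + 1L] == c2[y + 1L] && c1[x + 1L] <= 4L
    list(pos = c(x + 1L, y + 1L),
         reward = if (is_match) scoring$match else scoring$mismatch,
         column = if (is_match) "M" else "X",
         terminal = FALSE)
  } else if (action == "insertion") {
    list(pos = c(x, y + 1L), reward = scoring$gap, column = "I",
         terminal = FALSE)
  } else {
    list(pos = c(x + 1L, y), reward = scoring$gap, column = "D",
         terminal = FALSE)
  }
}

#' Recompute an alignment score from its columns
#'
#' @param columns Character vector over `{M, X, I, D}`.
#' @param scoring A [scoring_scheme()].
#' @return The summed column score.
#' @export
score_columns <- function(columns, scoring) {
  if (length(columns) == 0) return(0)
  sum(c(M = scoring$match, X = scoring$mismatch, I = scoring$gap,
        D = scoring$gap)[columns])
}

# Per-sequence base consumption of a column vector.
columns_consumed <- function(columns) {
  c(s1 = sum(columns %in% c("M", "X", "D")),
    s2 = sum(columns %in% c("M", "X", "I")))
}
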