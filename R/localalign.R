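# Seed-and-extend local alignment: exact k-mer seeding with n-hit diagonal
# filtering, x-drop gapped extension in both directions (policy-driven
# single-path extender or the classical greedy DP baseline), and alignment
# assembly and reporting.

#' X-drop extension parameters
#'
#' @param X Positive drop threshold: extension terminates when the running
#'   score falls to `best - X` or below.
#' @param W Window size observed by the policy-driven extender. The
#'   larger-scale experiments behind this method favour `W` around 100;
#'   the desk-scale default here is 10.
#' @param scoring A [scoring_scheme()]; defaults to match/mismatch/gap =
#'   (1, -1, -2).
#' @return Object of class `xdrop_params`.
#' @export
xdrop_params <- function(X = 100, W = 10, scoring = scoring_scheme()) {
  stopifnot(X > 0, W >= 1, inherits(scoring, "scoring_scheme"))
  structure(list(X = X, W = as.integer(W), scoring = scoring),
            class = "xdrop_params")
}

empty_extension <- function(terminated_by = "seqend") {
  structure(list(path = character(0), score = 0, best = 0,
                 best_prefix_len = 0L, steps = 0L,
                 terminated_by = terminated_by),
            class = "extension_result")
}

#' @export
print.extension_result <- function(x, ...) {
  cat(sprintf("x-drop extension: best=%g over %d columns (%d steps, %s)\n",
              x$best, x$best_prefix_len, x$steps, x$terminated_by))
  invisible(x)
}

#' Policy-driven x-drop extension
#'
#' Extends an alignment from a start position by repeatedly observing the
#' window state, taking the policy's greedy action, and applying it, while
#' the running score stays above `best - X`. The best-scoring prefix of the
#' path is the returned alignment. Any object implementing [q_values()] can
#' serve as the policy, including a trained `dqn_net` and the stub policies.
#'
#' @param S1,S2 Sequences (character strings or code vectors).
#' @param start Numeric `c(x, y)`: 0-based start position of the extension.
#' @param policy An `alignment_policy` (e.g. a `dqn_net`).
#' @param params An [xdrop_params()]; for a `dqn_net` policy, `params$W`
#'   must equal the network's window size.
#' @return An `extension_result`: `path` (all emitted columns), `score`
#'   (running score at termination), `best`, `best_prefix_len`, `steps`,
#'   `terminated_by` (`"xdrop"` or `"seqend"`).
#' @export
dqn_xdrop_extend <- function(S1, S2, start = c(0, 0), policy,
                             params = xdrop_params()) {
  c1 <- dna_codes(S1); c2 <- dna_codes(S2)
  x <- as.integer(start[1]); y <- as.integer(start[2])
  n1 <- length(c1); n2 <- length(c2)
  stopifnot(x >= 0, y >= 0, x <= n1, y <= n2)
  if (inherits(policy, "dqn_net") && policy$config$window != params$W)
    stop("params$W (", params$W, ") does not match the network window (",
         policy$config$window, ")")
  if (x >= n1 || y >= n2) return(empty_extension("seqend"))
  W <- params$W
  sc <- params$scoring
  needs_enc <- inherits(policy, "dqn_net")
  maxsteps <- (n1 - x) + (n2 - y)
  path <- character(maxsteps)
  score <- 0; best <- 0; best_len <- 0L; steps <- 0L
  terminated <- "xdrop"
  while (score > best - params$X) {
    if (x >= n1 || y >= n2) { terminated <- "seqend"; break }
    w1 <- window_codes(c1, x, W)
    w2 <- window_codes(c2, y, W)
    state <- structure(list(codes1 = w1, codes2 = w2, W = W,
                            enc = if (needs_enc) encode_windows(w1, w2, W)),
                       class = "window_state")
    q <- q_values(policy, state)
    act <- which.max(q)   # ties: forward > insertion > deletion
    steps <- steps + 1L
    if (act == 1L) {
      is_match <- c1[x + 1L] == c2[y + 1L] && c1[x + 1L] <= 4L
      score <- score + if (is_match) sc$match else sc$mismatch
      path[steps] <- if (is_match) "M" else "X"
      x <- x + 1L; y <- y + 1L
    } else if (act == 2L) {
      score <- score + sc$gap; path[steps] <- "I"; y <- y + 1L
    } else {
      score <- score + sc$gap; path[steps] <- "D"; x <- x + 1L
    }
    if (score > best) { best <- score; best_len <- steps }
  }
  structure(list(path = path[seq_len(steps)], score = score, best = best,
                 best_prefix_len = best_len, steps = steps,
                 terminated_by = terminated),
            class = "extension_result")
}

# safe lookup into an antidiagonal score vector stored with offset `lo`
adiag_get <- function(H, lo, i) {
  v <- rep(-Inf, length(i))
  idx <- i - lo + 1L
  ok <- idx >= 1L & idx <= length(H)
  v[ok] <- H[idx[ok]]
  v
}

#' Greedy x-drop extension (pruned dynamic programming baseline)
#'
#' The classical extension baseline: a Smith-Waterman-style extension DP with
#' linear gap penalty, evaluated in antidiagonal order, where a cell is
#' pruned as soon as its score drops to `best - X` or below, and the
#' extension terminates when an antidiagonal has no live cells. With
#' `X = Inf` this is the exhaustive extension DP. `steps` counts DP cells
#' evaluated, the hardware-independent complexity observable.
#'
#' @inheritParams dqn_xdrop_extend
#' @param traceback Compute the alignment path (set `FALSE` to benchmark
#'   only scores and cell counts).
#' @return An `extension_result` (see [dqn_xdrop_extend()]); `path` is the
#'   traceback of the best cell.
#' @export
greedy_xdrop_extend <- function(S1, S2, start = c(0, 0),
                                params = xdrop_params(), traceback = TRUE) {
  c1 <- dna_codes(S1); c2 <- dna_codes(S2)
  x0 <- as.integer(start[1]); y0 <- as.integer(start[2])
  stopifnot(x0 >= 0, y0 >= 0, x0 <= length(c1), y0 <= length(c2))
  a <- if (x0 < length(c1)) c1[(x0 + 1L):length(c1)] else integer(0)
  b <- if (y0 < length(c2)) c2[(y0 + 1L):length(c2)] else integer(0)
  na <- length(a); nb <- length(b)
  if (na == 0 || nb == 0) return(empty_extension("seqend"))
  sc <- params$scoring
  X <- params$X
  lo_l <- vector("list", na + nb + 1L)
  H_l <- vector("list", na + nb + 1L)
  lo_l[[1]] <- 0L; H_l[[1]] <- 0
  best <- 0; best_i <- 0L; best_d <- 0L
  cells <- 1L
  terminated <- "seqend"
  for (d in seq_len(na + nb)) {
    lo1 <- lo_l[[d]]; H1 <- H_l[[d]]
    if (is.null(H1) || length(H1) == 0) { terminated <- "xdrop"; break }
    hi1 <- lo1 + length(H1) - 1L
    if (d >= 2 && !is.null(H_l[[d - 1L]])) {
      lo2 <- lo_l[[d - 1L]]; H2 <- H_l[[d - 1L]]
      hi2 <- lo2 + length(H2) - 1L
    } else { lo2 <- NA_integer_; H2 <- NULL; hi2 <- NA_integer_ }
    cand_lo <- max(0L, d - nb, min(lo1, if (!is.na(lo2)) lo2 + 1L else lo1))
    cand_hi <- min(na, d, max(hi1 + 1L, if (!is.na(hi2)) hi2 + 1L else hi1 + 1L))
    if (cand_lo > cand_hi) next
    i_vec <- cand_lo:cand_hi
    j_vec <- d - i_vec
    up <- adiag_get(H1, lo1, i_vec - 1L) + sc$gap
    left <- adiag_get(H1, lo1, i_vec) + sc$gap
    diagv <- rep(-Inf, length(i_vec))
    dg_ok <- i_vec >= 1L & j_vec >= 1L
    if (!is.null(H2) && any(dg_ok)) {
      ai <- a[i_vec[dg_ok]]; bj <- b[j_vec[dg_ok]]
      sub <- ifelse(ai == bj & ai <= 4L, sc$match, sc$mismatch)
      diagv[dg_ok] <- adiag_get(H2, lo2, i_vec[dg_ok] - 1L) + sub
    }
    Hc <- pmax(diagv, up, left)
    cells <- cells + length(i_vec)
    m <- max(Hc)
    if (m > best) {
      best <- m
      best_i <- i_vec[which.max(Hc)]
      best_d <- d
    }
    Hc[Hc <= best - X] <- -Inf
    keep <- which(is.finite(Hc))
    if (length(keep) == 0) { terminated <- "xdrop"; break }
    rng <- keep[1]:keep[length(keep)]
    lo_l[[d + 1L]] <- i_vec[keep[1]]
    H_l[[d + 1L]] <- Hc[rng]
  }
  path <- character(0)
  if (traceback && best_d > 0) {
    ops <- character(best_d)
    nop <- 0L
    i <- best_i; d <- best_d
    v <- adiag_get(H_l[[d + 1L]], lo_l[[d + 1L]], i)
    while (d > 0L) {
      j <- d - i
      moved <- FALSE
      if (i >= 1L && j >= 1L && d >= 2L && !is.null(H_l[[d - 1L]])) {
        vd <- adiag_get(H_l[[d - 1L]], lo_l[[d - 1L]], i - 1L)
        sub <- if (a[i] == b[j] && a[i] <= 4L) sc$match else sc$mismatch
        if (is.finite(vd) && vd + sub == v) {
          nop <- nop + 1L
          ops[nop] <- if (sub == sc$match) "M" else "X"
          i <- i - 1L; d <- d - 2L; v <- vd; moved <- TRUE
        }
      }
      if (!moved && i >= 1L && !is.null(H_l[[d]])) {
        vu <- adiag_get(H_l[[d]], lo_l[[d]], i - 1L)
        if (is.finite(vu) && vu + sc$gap == v) {
          nop <- nop + 1L; ops[nop] <- "D"
          i <- i - 1L; d <- d - 1L; v <- vu; moved <- TRUE
        }
      }
      if (!moved) {
        vl <- adiag_get(H_l[[d]], lo_l[[d]], i)
        if (!is.finite(vl) || vl + sc$gap != v)
          stop("internal error: greedy x-drop traceback lost the path")
        nop <- nop + 1L; ops[nop] <- "I"
        d <- d - 1L; v <- vl
      }
    }
    path <- rev(ops[seq_len(nop)])
  }
  structure(list(path = path, score = best, best = best,
                 best_prefix_len = length(path), steps = cells,
                 terminated_by = terminated),
            class = "extension_result")
}

#' Verify the x-drop soundness of an extension result
#'
#' Re-simulates a policy extender's recorded path and checks that (i) the
#' while-condition `score > best - X` held before every retained step,
#' (ii) the recomputed running/best scores match the reported ones, and
#' (iii) the best-prefix score equals `best`.
#'
#' @param result An `extension_result` from [dqn_xdrop_extend()].
#' @param params The [xdrop_params()] used.
#' @return `TRUE` if sound, otherwise `FALSE` with a `reason` attribute.
#' @export
verify_xdrop <- function(result, params) {
  sc <- params$scoring
  score <- 0; best <- 0; best_len <- 0L
  for (i in seq_along(result$path)) {
    if (!(score > best - params$X))
      return(structure(FALSE, reason = paste0("step ", i,
        " taken although score <= best - X")))
    score <- score + switch(result$path[i], M = sc$match, X = sc$mismatch,
                            I = sc$gap, D = sc$gap)
    if (score > best) { best <- score; best_len <- i }
  }
  if (score != result$score)
    return(structure(FALSE, reason = "running score mismatch"))
  if (best != result$best)
    return(structure(FALSE, reason = "best score mismatch"))
  if (best_len != result$best_prefix_len)
    return(structure(FALSE, reason = "best prefix length mismatch"))
  pref <- result$path[seq_len(result$best_prefix_len)]
  if (score_columns(pref, sc) != result$best)
    return(structure(FALSE, reason = "best prefix does not score best"))
  if (result$terminated_by == "xdrop" && score > best - params$X)
    return(structure(FALSE, reason = "reported x-drop but condition held"))
  TRUE
}

#' Find exact k-mer seed matches with n-hit diagonal filtering
#'
#' All exact k-mer matches between `S1` and `S2` are located by hashing the
#' k-mers of `S1` and probing with those of `S2`. A hit is retained only if
#' at least `n_hit` hits (itself included) fall on its diagonal within
#' `hit_window` bases; retained overlapping or abutting same-diagonal hits
#' are merged into one longer seed.
#'
#' @param S1,S2 Sequences (character strings).
#' @param k K-mer length (>= 4).
#' @param n_hit Minimum number of co-diagonal hits within the window.
#' @param hit_window Diagonal distance window (bases).
#' @return Data frame with 0-based columns `x`, `y`, `length`, `diag`
#'   (`diag = x - y`), sorted by decreasing `length`.
#' @export
find_seeds <- function(S1, S2, k = 12, n_hit = 2, hit_window = 100) {
  stopifnot(k >= 4)
  L1 <- nchar(S1); L2 <- nchar(S2)
  empty <- data.frame(x = integer(0), y = integer(0), length = integer(0),
                      diag = integer(0))
  if (k > L1 || k > L2) return(empty)
  km1 <- substring(S1, 1:(L1 - k + 1), k:L1)
  km2 <- substring(S2, 1:(L2 - k + 1), k:L2)
  pos1 <- split(0:(L1 - k), km1)
  matched <- pos1[km2]
  nh <- lengths(matched)
  if (sum(nh) == 0) return(empty)
  xs <- unlist(matched, use.names = FALSE)
  ys <- rep(0:(L2 - k), nh)
  dg <- xs - ys
  out_x <- integer(0); out_y <- integer(0); out_len <- integer(0)
  out_dg <- integer(0)
  for (dgv in unique(dg)) {
    xd <- sort(xs[dg == dgv])
    n_near <- findInterval(xd + hit_window, xd) -
      findInterval(xd - hit_window - 1L, xd)
    xd <- xd[n_near >= n_hit]
    if (length(xd) == 0) next
    run_start <- c(TRUE, xd[-1] > xd[-length(xd)] + k)
    grp <- cumsum(run_start)
    first <- tapply(xd, grp, min)
    last <- tapply(xd, grp, max)
    out_x <- c(out_x, as.integer(first))
    out_y <- c(out_y, as.integer(first) - dgv)
    out_len <- c(out_len, as.integer(last) + k - as.integer(first))
    out_dg <- c(out_dg, rep(dgv, length(first)))
  }
  res <- data.frame(x = out_x, y = out_y, length = out_len, diag = out_dg)
  res[order(-res$length, res$x), , drop = FALSE]
}

#' Bidirectional x-drop extension around a seed
#'
#' Extends downstream from the seed end and upstream from the seed start
#' (on the reversed prefixes, with the same policy — the extension procedure
#' is direction-agnostic), then merges upstream + seed + downstream into a
#' local alignment with coordinates, score, identity and coverage.
#'
#' @inheritParams dqn_xdrop_extend
#' @param seed One row of [find_seeds()] output (list or data frame row with
#'   `x`, `y`, `length`).
#' @param extender `"greedy"` or `"dqn"` (policy-driven).
#' @return Object of class `local_alignment`: 0-based half-open coordinates
#'   `start1`, `end1`, `start2`, `end2`; `columns`; `score`; `identity`;
#'   `coverage1`; `coverage2`; `steps`; `terminated_by` (up/down).
#' @export
extend_bidirectional <- function(S1, S2, seed, params = xdrop_params(),
                                 extender = c("greedy", "dqn"),
                                 policy = NULL) {
  extender <- match.arg(extender)
  c1 <- dna_codes(S1); c2 <- dna_codes(S2)
  n1 <- length(c1); n2 <- length(c2)
  x <- as.integer(seed$x); y <- as.integer(seed$y); k <- as.integer(seed$length)
  stopifnot(x >= 0, y >= 0, k >= 1, x + k <= n1, y + k <= n2)
  run_ext <- function(ca, cb) {
    if (extender == "greedy")
      greedy_xdrop_extend(ca, cb, c(0, 0), params)
    else dqn_xdrop_extend(ca, cb, c(0, 0), policy, params)
  }
  down <- run_ext(c1[seq_len(n1) > x + k], c2[seq_len(n2) > y + k])
  up <- run_ext(rev(c1[seq_len(n1) <= x]), rev(c2[seq_len(n2) <= y]))
  up_cols <- rev(up$path[seq_len(up$best_prefix_len)])
  down_cols <- down$path[seq_len(down$best_prefix_len)]
  up_use <- columns_consumed(up_cols)
  down_use <- columns_consumed(down_cols)
  columns <- c(up_cols, rep("M", k), down_cols)
  start1 <- x - up_use[["s1"]]; end1 <- x + k + down_use[["s1"]]
  start2 <- y - up_use[["s2"]]; end2 <- y + k + down_use[["s2"]]
  score <- up$best + k * params$scoring$match + down$best
  structure(list(start1 = start1, end1 = end1, start2 = start2, end2 = end2,
                 columns = columns, score = score,
                 identity = sum(columns == "M") / length(columns),
                 coverage1 = (end1 - start1) / n1,
                 coverage2 = (end2 - start2) / n2,
                 steps = up$steps + down$steps,
                 terminated_by = c(up = up$terminated_by,
                                   down = down$terminated_by)),
            class = "local_alignment")
}

#' @export
print.local_alignment <- function(x, ...) {
  cat(sprintf(
    "local alignment: S1[%d,%d) S2[%d,%d) score=%g identity=%.3f cov=(%.3f,%.3f)\n",
    x$start1, x$end1, x$start2, x$end2, x$score, x$identity,
    x$coverage1, x$coverage2))
  invisible(x)
}

#' Align a pair of sequences (seed, filter, extend, report)
#'
#' Finds filtered seeds, visits them by decreasing merged length, skips any
#' seed with at least half of its S1 span already inside an accepted
#' alignment, extends the rest bidirectionally, and returns the alignments
#' sorted by score.
#'
#' @inheritParams extend_bidirectional
#' @param k,n_hit,hit_window Seeding parameters (see [find_seeds()]).
#' @return List of `local_alignment` objects, non-ascending in score.
#' @export
align_pair <- function(S1, S2, params = xdrop_params(),
                       extender = c("greedy", "dqn"), policy = NULL,
                       k = 12, n_hit = 2, hit_window = 100) {
  extender <- match.arg(extender)
  seeds <- find_seeds(S1, S2, k = k, n_hit = n_hit, hit_window = hit_window)
  out <- list()
  accepted <- matrix(numeric(0), ncol = 2)   # [start1, end1) intervals
  for (si in seq_len(nrow(seeds))) {
    sd <- seeds[si, ]
    span <- c(sd$x, sd$x + sd$length)
    if (nrow(accepted) > 0) {
      ov <- pmin(accepted[, 2], span[2]) - pmax(accepted[, 1], span[1])
      if (sum(pmax(ov, 0)) >= 0.5 * (span[2] - span[1])) next
    }
    al <- extend_bidirectional(S1, S2, sd, params, extender, policy)
    out[[length(out) + 1L]] <- al
    accepted <- rbind(accepted, c(al$start1, al$end1))
  }
  if (length(out) > 1)
    out <- out[order(vapply(out, `[[`, numeric(1), "score"),
                     decreasing = TRUE)]
  out
}

#' Tabulate local alignments
#'
#' One row per alignment, BLAST-tabular style: 0-based half-open coordinates,
#' score, identity, per-sequence coverage, extension steps and termination
#' reasons.
#'
#' @param alignments List of `local_alignment` objects (from [align_pair()]).
#' @param query_id,subject_id Identifier columns.
#' @return A data frame.
#' @export
alignments_to_df <- function(alignments, query_id = "query",
                             subject_id = "subject") {
  if (length(alignments) == 0) {
    return(data.frame(query_id = query_id, subject_id = subject_id,
                      q_start = NA_integer_, q_end = NA_integer_,
                      s_start = NA_integer_, s_end = NA_integer_,
                      score = 0, identity = 0, coverage_q = 0,
                      coverage_s = 0, steps = 0L,
                      terminated_by = "no_seed",
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, lapply(alignments, function(a) {
    data.frame(query_id = query_id, subject_id = subject_id,
               q_start = a$start1, q_end = a$end1,
               s_start = a$start2, s_end = a$end2,
               score = a$score, identity = a$identity,
               coverage_q = a$coverage1, coverage_s = a$coverage2,
               steps = a$steps,
               terminated_by = paste(a$terminated_by, collapse = "/"),
               stringsAsFactors = FALSE)
  }))
}

#' All-vs-all pairwise alignment of a sequence set
#'
#' Aligns every unordered pair and reports the best alignment per pair (a
#' `no_seed` row with zero score/identity/coverage when no seed survives
#' filtering), giving `n*(n-1)/2` rows for `n` sequences.
#'
#' @param seqs Named character vector of sequences.
#' @inheritParams align_pair
#' @return Data frame as in [alignments_to_df()], one row per pair.
#' @export
align_all <- function(seqs, params = xdrop_params(),
                      extender = c("greedy", "dqn"), policy = NULL,
                      k = 12, n_hit = 2, hit_window = 100) {
  extender <- match.arg(extender)
  n <- length(seqs)
  ids <- names(seqs)
  if (is.null(ids)) ids <- paste0("seq_", seq_len(n))
  rows <- list()
  for (i in seq_len(max(n - 1, 0))) {
    for (j in (i + 1):n) {
      als <- align_pair(seqs[[i]], seqs[[j]], params, extender, policy,
                        k = k, n_hit = n_hit, hit_window = hit_window)
      rows[[length(rows) + 1L]] <-
        alignments_to_df(als[seq_len(min(1, length(als)))],
                         query_id = ids[i], subject_id = ids[j])
    }
  }
  if (length(rows) == 0) return(alignments_to_df(list())[0, ])
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write an alignment table as TSV
#'
#' @param df Data frame from [alignments_to_df()] or [align_all()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_hits_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
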