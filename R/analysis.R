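# Numerical evaluators for the method's step-error / complexity analysis and
# the desk-scale benchmark harness (step counts, identity, coverage).

#' Gumbel (Karlin-Altschul) parameters of a scoring scheme
#'
#' `K` and `lambda` govern the extreme-value statistics of high-scoring
#' segments. They are user-supplied; the defaults `K = 0.711`,
#' `lambda = 1.33` are commonly tabulated values for ungapped unit-match DNA
#' scoring, provided as a convenience, not derived here.
#'
#' @param K Positive real.
#' @param lambda Positive real.
#' @return Object of class `gumbel_params`.
#' @export
gumbel_params <- function(K = 0.711, lambda = 1.33) {
  stopifnot(K > 0, lambda > 0)
  structure(list(K = K, lambda = lambda), class = "gumbel_params")
}

#' Per-step error probability of windowed greedy path selection
#'
#' Evaluates the step-error bound of the window-driven extender: the
#' probability that the locally best move within a window of size `W`
#' deviates from the globally optimal path,
#' \deqn{P_e = \left(p_{indel} K (e^{\lambda g} + \tfrac14 e^{\lambda m} +
#'   \tfrac34 e^{\lambda x}) + 2 p_{SNP} K e^{\lambda g}\right)
#'   \frac{W^2}{e^{\lambda W \bar s}}}
#' with `m`, `x`, `g` the match/mismatch/gap scores and `\bar s` the average
#' per-column score of the pair. The bound vanishes as `W` grows whenever
#' `score_avg > 0`.
#'
#' @param p_snp,p_indel Mutation probabilities of the pair's evolution model.
#' @param scoring A [scoring_scheme()].
#' @param score_avg Expected per-column score of the pair (> 0); see
#'   [average_pair_score()].
#' @param W Window size.
#' @param g A [gumbel_params()].
#' @return The step-error probability bound (non-negative real).
#' @export
step_error_probability <- function(p_snp, p_indel, scoring, score_avg, W,
                                   g = gumbel_params()) {
  stopifnot(p_snp >= 0, p_snp <= 1, p_indel >= 0, p_indel <= 1, W >= 1)
  if (score_avg <= 0)
    stop("step_error_probability requires score_avg > 0 (the bound diverges)")
  lam <- g$lambda
  pref <- p_indel * g$K * (exp(lam * scoring$gap) +
                             0.25 * exp(lam * scoring$match) +
                             0.75 * exp(lam * scoring$mismatch)) +
    2 * p_snp * g$K * exp(lam * scoring$gap)
  pref * W^2 / exp(lam * W * score_avg)
}

#' Expected per-column score of a diverged pair
#'
#' The default `score_avg` used in [step_error_probability()]: columns match
#' with probability `1 - p_snp` under the substitution-only view of the
#' pair's divergence.
#'
#' @param p_snp Substitution divergence of the pair.
#' @param scoring A [scoring_scheme()].
#' @return `(1 - p_snp) * match + p_snp * mismatch`.
#' @export
average_pair_score <- function(p_snp, scoring = scoring_scheme()) {
  (1 - p_snp) * scoring$match + p_snp * scoring$mismatch
}

#' Riemann zeta function
#'
#' Normalization constant of the Zipfian indel-length distribution.
#'
#' @param s Exponent, `s > 1`.
#' @return `zeta(s)` to better than 1e-10 relative error.
#' @export
zipf_zeta <- function(s) {
  if (s <= 1) stop("zeta(s) diverges for s <= 1")
  pracma::zeta(s)
}

#' Upper bound on the expected x-drop extension length
#'
#' With Zipfian indel lengths, the extension is unconditionally terminated by
#' an indel of length at least `X_g = ceiling(X / |score_gap|)` (each gap
#' column costs `|score_gap|`, so such an indel drops the score by at least
#' `X`). The expected distance to such an indel bounds the extension length:
#' `L(X) < X_g^s * zeta(s) / p_indel`. The magnitude of the gap score is
#' used, treating `X_g` as a positive count.
#'
#' @param X X-drop parameter.
#' @param scoring A [scoring_scheme()].
#' @param p_indel Indel initiation probability (> 0 for a finite bound; 0
#'   returns `Inf`).
#' @param s Zipf exponent (> 1).
#' @return The length bound (real; `Inf` when `p_indel = 0`).
#' @export
expected_length_bound <- function(X, scoring, p_indel, s) {
  stopifnot(X > 0, s > 1, p_indel >= 0, p_indel <= 1)
  if (p_indel == 0) return(Inf)
  Xg <- ceiling(X / abs(scoring$gap))
  Xg^s * zipf_zeta(s) / p_indel
}

#' Window size required for a given x-drop parameter
#'
#' The window-size relation `W = (s/B) ln X_g + alpha
#' = (s/B) ln X - (s/B) ln |score_gap| + alpha`, under which the total path
#' error vanishes for large `X`; the constants `B` and `alpha` are the
#' exponential rate and offset absorbed from the step-error bound and are
#' user-supplied (the relation is exposed parametrically). Implies
#' `W(eX) - W(X) = s/B`.
#'
#' @param X X-drop parameter (> 0).
#' @param s Zipf exponent.
#' @param B,alpha Positive constants.
#' @param score_gap Gap score (its magnitude is used).
#' @return The required window size (real).
#' @export
required_window <- function(X, s, B, alpha, score_gap = -2) {
  stopifnot(all(X > 0), B > 0, alpha >= 0)
  (s / B) * log(X) - (s / B) * log(abs(score_gap)) + alpha
}

#' Benchmark extension step counts, identity and coverage versus X
#'
#' For each x-drop parameter and replicate, simulates a pair with a
#' homologous core (a mutated copy under `model`) followed by unrelated
#' random flanks (length `4X + 50`, enough for the post-homology termination
#' phase), extends from the core start with both the greedy DP baseline
#' (steps = DP cells) and the policy-driven extender (steps = decisions),
#' and fits per-aligner log-log slopes of mean steps versus X.
#'
#' @param Xs Numeric vector of x-drop parameters.
#' @param model A [mutation_model()] for the homologous core.
#' @param core_length Length of the homologous core.
#' @param reps Replicates per X.
#' @param policy Policy for the windowed extender.
#' @param W Window size for the windowed extender.
#' @param scoring A [scoring_scheme()].
#' @param flank Flank length; `NULL` (default) scales it as `4X + 50`. Use 0
#'   to benchmark pure homologous pairs with no termination phase.
#' @param seed Optional root seed.
#' @return List with `records` (one row per aligner/X/rep: aligner, X, W,
#'   length, steps, identity, coverage) and `slopes` (named numeric log-log
#'   slopes per aligner).
#' @export
run_benchmark <- function(Xs = c(25, 50, 100, 200, 400),
                          model = mutation_model(p_snp = 0.1, p_indel = 0.01,
                                                 max_indel = 5),
                          core_length = 100, reps = 3,
                          policy = policy_heuristic(), W = 10,
                          scoring = scoring_scheme(), flank = NULL,
                          seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  rows <- list()
  for (X in Xs) {
    params <- xdrop_params(X = X, W = W, scoring = scoring)
    fl <- if (is.null(flank)) ceiling(4 * X) + 50 else flank
    for (r in seq_len(reps)) {
      anc <- generate_random_sequence(core_length)
      mut <- mutate_sequence(anc, model)$seq
      S1 <- paste0(anc, generate_random_sequence(fl))
      S2 <- paste0(mut, generate_random_sequence(fl))
      for (aligner in c("greedy", "dqn")) {
        ext <- if (aligner == "greedy")
          greedy_xdrop_extend(S1, S2, c(0, 0), params, traceback = TRUE)
        else dqn_xdrop_extend(S1, S2, c(0, 0), policy, params)
        cols <- ext$path[seq_len(ext$best_prefix_len)]
        use <- columns_consumed(cols)
        rows[[length(rows) + 1L]] <- data.frame(
          aligner = aligner, X = X, W = W, length = core_length,
          steps = ext$steps,
          identity = if (length(cols) > 0) sum(cols == "M") / length(cols)
                     else 0,
          coverage = use[["s1"]] / nchar(S1),
          stringsAsFactors = FALSE)
      }
    }
  }
  records <- do.call(rbind, rows)
  rownames(records) <- NULL
  slopes <- vapply(c("greedy", "dqn"), function(al) {
    sub <- records[records$aligner == al, ]
    mean_steps <- tapply(sub$steps, sub$X, mean)
    xs <- as.numeric(names(mean_steps))
    unname(stats::coef(stats::lm(log(mean_steps) ~ log(xs)))[2])
  }, numeric(1))
  list(records = records, slopes = slopes)
}

#' Write benchmark records as CSV
#'
#' @param bench Result of [run_benchmark()].
#' @param path Output path.
#' @param seed Seed recorded in the metadata comment line.
#' @return `path`, invisibly.
#' @export
write_benchmark_csv <- function(bench, path, seed = NA) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# dqnxdrop benchmark v%s seed=%s",
                     as.character(utils::packageVersion("dqnxdrop")),
                     format(seed)), con)
  utils::write.csv(bench$records, con, row.names = FALSE)
  invisible(path)
}

#' Identity / coverage distribution summaries for pairwise alignments
#'
#' Summarizes the best-alignment identity and coverage over all sequence
#' pairs (as produced by [align_all()]), overall and per pair group. If
#' per-sequence `groups` labels are given, a pair is `"intra"` when both
#' members share a label and `"inter"` otherwise.
#'
#' @param hits Data frame from [align_all()] (one row per pair).
#' @param groups Optional named character vector: sequence id -> group label.
#' @param breaks Histogram bin edges on `[0, 1]`.
#' @return List with `summary` (group x metric mean/median/n) and
#'   `histogram` (group, metric, bin_lo, bin_hi, count).
#' @export
pairwise_stats <- function(hits, groups = NULL, breaks = seq(0, 1, 0.1)) {
  stopifnot(is.data.frame(hits), nrow(hits) >= 1)
  grp <- rep("all", nrow(hits))
  if (!is.null(groups)) {
    gq <- groups[hits$query_id]; gs <- groups[hits$subject_id]
    grp <- ifelse(!is.na(gq) & !is.na(gs) & gq == gs, "intra", "inter")
  }
  metrics <- list(identity = hits$identity,
                  coverage = pmin(hits$coverage_q, hits$coverage_s))
  sum_rows <- list(); hist_rows <- list()
  for (g in unique(grp)) {
    for (mn in names(metrics)) {
      v <- metrics[[mn]][grp == g]
      sum_rows[[length(sum_rows) + 1L]] <- data.frame(
        group = g, metric = mn, mean = mean(v), median = stats::median(v),
        n = length(v), stringsAsFactors = FALSE)
      h <- graphics::hist(pmin(pmax(v, 0), 1), breaks = breaks, plot = FALSE)
      hist_rows[[length(hist_rows) + 1L]] <- data.frame(
        group = g, metric = mn, bin_lo = h$breaks[-length(h$breaks)],
        bin_hi = h$breaks[-1], count = h$counts, stringsAsFactors = FALSE)
    }
  }
  list(summary = do.call(rbind, sum_rows),
       histogram = do.call(rbind, hist_rows))
}
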