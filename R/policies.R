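# Stub policies implementing the q_values() interface. They make every
# branch of the x-drop extender deterministic and testable without any
# training, and the window-similarity heuristic is a reasonable
# network-free extender in its own right.

#' Fixed-action stub policy
#'
#' Always prefers the given action (Q = 1 for it, 0 elsewhere).
#'
#' @param action `"forward"`, `"insertion"`, or `"deletion"`.
#' @return An `alignment_policy`.
#' @export
policy_fixed <- function(action = "forward") {
  action <- match.arg(action, ACTIONS)
  structure(list(action = action),
            class = c("policy_fixed", "alignment_policy"))
}

#' @export
q_values.policy_fixed <- function(policy, state) {
  q <- c(forward = 0, insertion = 0, deletion = 0)
  q[policy$action] <- 1
  q
}

#' Scripted stub policy
#'
#' Emits a predetermined sequence of actions (repeating the last one once the
#' script is exhausted). Stateful: each `q_values()` call consumes one entry.
#'
#' @param actions Character vector of actions.
#' @return An `alignment_policy`.
#' @export
policy_script <- function(actions) {
  stopifnot(length(actions) >= 1, all(actions %in% ACTIONS))
  st <- new.env(parent = emptyenv())
  st$i <- 0L
  structure(list(actions = actions, st = st),
            class = c("policy_script", "alignment_policy"))
}

#' @export
q_values.policy_script <- function(policy, state) {
  policy$st$i <- policy$st$i + 1L
  a <- policy$actions[min(policy$st$i, length(policy$actions))]
  q <- c(forward = 0, insertion = 0, deletion = 0)
  q[a] <- 1
  q
}

#' Window-similarity heuristic policy
#'
#' A network-free extender policy: scores each action by the fraction of
#' matching positions between the two windows after the corresponding
#' pointer move (forward compares the windows in register; insertion and
#' deletion compare them shifted by one). A small forward bonus breaks the
#' symmetry so ungapped extension is preferred when in register.
#'
#' @param forward_bonus Additive preference for forward at equal similarity.
#' @return An `alignment_policy`.
#' @export
policy_heuristic <- function(forward_bonus = 0.05) {
  structure(list(forward_bonus = forward_bonus),
            class = c("policy_heuristic", "alignment_policy"))
}

#' @export
q_values.policy_heuristic <- function(policy, state) {
  c1 <- state$codes1; c2 <- state$codes2
  W <- state$W
  sim <- function(a, b) {
    ok <- a != 0L & b != 0L
    if (!any(ok)) return(0)
    mean(a[ok] == b[ok] & a[ok] <= 4L)
  }
  q_for <- sim(c1, c2) + policy$forward_bonus
  q_ins <- if (W > 1) sim(c1[1:(W - 1)], c2[2:W]) else 0
  q_del <- if (W > 1) sim(c1[2:W], c2[1:(W - 1)]) else 0
  c(forward = q_for, insertion = q_ins, deletion = q_del)
}
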