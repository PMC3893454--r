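#' Hybrid agent parameters
#'
#' Parameter set of the hybrid reinforcement-learning agent that mixes
#' model-free SARSA(lambda) values with one-step model-based (Bellman)
#' values computed from the true transition structure. `w = 0` gives the
#' pure model-free agent, `w = 1` the pure model-based agent.
#'
#' @param alpha1,alpha2 Learning rates for stage 1 and stage 2, in `[0, 1]`.
#' @param lam Eligibility-trace parameter in `[0, 1]`: fraction of the
#'   stage-2 prediction error passed back to the stage-1 value.
#' @param beta1,beta2 Softmax inverse temperatures (>= 0) for the two stages.
#' @param w Model-based weight in `[0, 1]`.
#' @param rho Choice-perseveration bonus added to the net value of the
#'   previously chosen first-stage option (any real; 0 disables it).
#' @return An object of class `hybrid_params`.
#' @examples
#' hybrid_params(w = 1)         # pure model-based agent
#' hybrid_params(w = 0, rho = 0) # pure model-free agent, no perseveration
#' @export
hybrid_params <- function(alpha1 = 0.4, alpha2 = 0.4, lam = 0.6,
                          beta1 = 5, beta2 = 5, w = 0.5, rho = 0.2) {
  chk01 <- function(x, nm) {
    if (length(x) != 1L || is.na(x) || x < 0 || x > 1)
      stop(sprintf("`%s` must be a scalar in [0, 1]", nm), call. = FALSE)
  }
  chk01(alpha1, "alpha1"); chk01(alpha2, "alpha2")
  chk01(lam, "lam"); chk01(w, "w")
  if (beta1 < 0 || beta2 < 0)
    stop("inverse temperatures must be non-negative", call. = FALSE)
  structure(
    list(alpha1 = alpha1, alpha2 = alpha2, lam = lam,
         beta1 = beta1, beta2 = beta2, w = w, rho = rho),
    class = "hybrid_params"
  )
}

#' Initial agent state
#'
#' All values start at zero (rewards are 0/1, so zero is the symmetric,
#' uninformative starting point); no previous choice.
#'
#' @return An `agent_state`: list with `q1_mf` (2 stage-1 values), `q2`
#'   (2 x 2 matrix of state x option values) and `prev_choice1`
#'   (`NA` before the first trial).
#' @export
agent_state <- function() {
  structure(
    list(q1_mf = c(0, 0), q2 = matrix(0, 2L, 2L), prev_choice1 = NA_integer_),
    class = "agent_state"
  )
}

#' Model-based stage-1 values
#'
#' One-step Bellman values under the true transition structure: the value of
#' first-stage option `a` is the `p_common`-weighted mixture of the best
#' attainable second-stage value in its common and its rare state.
#'
#' @param q2 2 x 2 matrix of second-stage values (`q2[state, option]`,
#'   1-based rows/cols for 0-based state/option ids).
#' @param config A [task_config()] (supplies `p_common`).
#' @return Numeric vector of two stage-1 values (options 0 and 1).
#' @examples
#' q2 <- rbind(c(0.8, 0.1), c(0.4, 0.2))
#' mb_stage1_values(q2, task_config()) # c(0.68, 0.52)
#' @export
mb_stage1_values <- function(q2, config = task_config()) {
  stopifnot(is.matrix(q2), all(dim(q2) == c(2L, 2L)), all(is.finite(q2)))
  p <- config$p_common
  m <- c(max(q2[1L, ]), max(q2[2L, ]))
  c(p * m[1L] + (1 - p) * m[2L],
    p * m[2L] + (1 - p) * m[1L])
}

#' Model-free SARSA(lambda) update
#'
#' Updates the agent's cached values from one completed trial:
#' the stage-1 value of the chosen option moves toward the visited
#' second-stage value (prediction error `delta1`), the visited second-stage
#' value moves toward the reward (`delta2`), and a fraction `lam` of
#' `delta2` is also credited back to the stage-1 choice (eligibility trace).
#' Only entries indexed by the experienced `(choice1, state2, choice2)`
#' change. Missed trials leave the state untouched.
#'
#' @param state An [agent_state()].
#' @param trial A single-trial record: list or one-row data.frame with
#'   `choice1`, `state2`, `choice2`, `reward`, `missed`.
#' @param params A [hybrid_params()].
#' @return The updated `agent_state` (with `prev_choice1` set to the trial's
#'   first-stage choice).
#' @export
mf_update <- function(state, trial, params) {
  if (isTRUE(as.logical(trial$missed))) return(state)
  c1 <- trial$choice1 + 1L; s2 <- trial$state2 + 1L; c2 <- trial$choice2 + 1L
  d1 <- state$q2[s2, c2] - state$q1_mf[c1]
  state$q1_mf[c1] <- state$q1_mf[c1] + params$alpha1 * d1
  d2 <- trial$reward - state$q2[s2, c2]
  state$q2[s2, c2] <- state$q2[s2, c2] + params$alpha2 * d2
  state$q1_mf[c1] <- state$q1_mf[c1] + params$alpha1 * params$lam * d2
  state$prev_choice1 <- as.integer(trial$choice1)
  state
}

softmax2 <- function(v, beta) {
  z <- beta * v
  p0 <- 1 / (1 + exp(z[2L] - z[1L]))
  c(p0, 1 - p0)
}

#' First-stage choice probabilities of the hybrid agent
#'
#' Softmax over the net value
#' `Qnet(a) = w * Qmb(a) + (1 - w) * Qmf(a) + rho * [a == previous choice]`
#' with inverse temperature `beta1`.
#'
#' @inheritParams mf_update
#' @param config A [task_config()].
#' @return Probabilities for options 0 and 1 (sum to 1).
#' @export
stage1_choice_probs <- function(state, params, config = task_config()) {
  qmb <- mb_stage1_values(state$q2, config)
  qnet <- params$w * qmb + (1 - params$w) * state$q1_mf
  if (!is.na(state$prev_choice1))
    qnet[state$prev_choice1 + 1L] <- qnet[state$prev_choice1 + 1L] + params$rho
  softmax2(qnet, params$beta1)
}

#' Second-stage choice probabilities
#'
#' Softmax with inverse temperature `beta2` over the cached values of the
#' two options available in the visited second-stage state.
#'
#' @inheritParams mf_update
#' @param state2 Visited second-stage state, 0 or 1.
#' @return Probabilities for options 0 and 1.
#' @export
stage2_choice_probs <- function(state, state2, params) {
  softmax2(state$q2[state2 + 1L, ], params$beta2)
}
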