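#' Screening criterion for candidate reward walks
#'
#' A candidate walk is accepted when pure model-free agents simulated on it
#' show no spurious reward-by-transition interaction: the normal-approximation
#' confidence interval of the mean interaction must cover zero AND its
#' absolute mean must fall below a magnitude guard.
#'
#' @param max_abs_interaction Magnitude guard in stay-probability units
#'   (default 0.05).
#' @param ci_level Confidence level of the interval (default 0.95).
#' @return A `screen_criterion` list.
#' @export
screen_criterion <- function(max_abs_interaction = 0.05, ci_level = 0.95) {
  stopifnot(max_abs_interaction > 0, ci_level > 0, ci_level < 1)
  structure(list(max_abs_interaction = max_abs_interaction,
                 ci_level = ci_level),
            class = "screen_criterion")
}

#' Screen a candidate reward walk with pure model-free agents
#'
#' Certain walks — e.g. ones where a single second-stage option stays near
#' the upper bound, making the optimal strategy static — induce a
#' reward-by-transition interaction even in a purely model-free agent,
#' through the 1-back structure of the stay/switch analysis. This screen
#' simulates `n_agents` independent model-free sessions (`w = 0` enforced)
#' on the candidate walk, computes each agent's effect indices, and accepts
#' the walk only if the mean interaction is statistically and practically
#' indistinguishable from zero.
#'
#' @param walk A `reward_walk`.
#' @param params A [hybrid_params()] with `w = 0`; defaults to the
#'   model-free screening agent (no perseveration).
#' @param n_agents Number of simulated agents (default 500).
#' @param seed Integer seed; the report is deterministic given all inputs.
#' @param criterion A [screen_criterion()].
#' @param config A [task_config()].
#' @param walk_id Identifier copied into the report.
#' @return A `screen_report`: list with `walk_id`, `n_agents` (agents with a
#'   valid stay table), `mean_interaction`, `interaction_ci` (2-vector),
#'   `mean_reward_effect`, `accepted`, `criterion`, and `metric`
#'   (`"stay_probability_contrast"`, recording which quantification was
#'   used).
#' @export
screen_walk <- function(walk,
                        params = hybrid_params(w = 0, rho = 0),
                        n_agents = 500L, seed = NULL,
                        criterion = screen_criterion(),
                        config = task_config(), walk_id = "walk") {
  if (params$w != 0)
    stop("walk screening is defined for pure model-free agents (w = 0)",
         call. = FALSE)
  if (n_agents < 2L) stop("`n_agents` must be at least 2", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  mb <- mf <- rep(NA_real_, n_agents)
  for (i in seq_len(n_agents)) {
    s <- run_session(params, walk, config)
    tab <- stay_table(lag_session(s))
    if (tab$valid) {
      idx <- effect_indices(tab)
      mb[i] <- idx$mb_effect
      mf[i] <- idx$mf_effect
    }
  }
  ok <- !is.na(mb)
  m <- mean(mb[ok])
  se <- stats::sd(mb[ok]) / sqrt(sum(ok))
  zq <- stats::qnorm(1 - (1 - criterion$ci_level) / 2)
  ci <- c(m - zq * se, m + zq * se)
  accepted <- (ci[1L] <= 0 && ci[2L] >= 0) &&
    abs(m) < criterion$max_abs_interaction
  structure(
    list(walk_id = walk_id, n_agents = sum(ok), mean_interaction = m,
         interaction_ci = ci, mean_reward_effect = mean(mf[ok]),
         accepted = accepted, criterion = criterion,
         metric = "stay_probability_contrast"),
    class = "screen_report"
  )
}

#' Generate walks that pass the model-free screen
#'
#' Repeatedly draws candidate walks from [generate_walk()] and screens each
#' with [screen_walk()] until `n_required` have been accepted.
#'
#' @param config A [task_config()].
#' @param n_required Number of accepted walks needed.
#' @param seed Integer seed controlling both walk generation and screening.
#' @param n_agents Agents per screen (default 500).
#' @param criterion A [screen_criterion()].
#' @param max_candidates Abort with an error after this many candidates
#'   (default 50 per required walk).
#' @return A list with `walks` (list of accepted `reward_walk`s), `reports`
#'   (their `screen_report`s) and `n_rejected`.
#' @export
generate_screened_walks <- function(config = task_config(), n_required = 3L,
                                    seed = NULL, n_agents = 500L,
                                    criterion = screen_criterion(),
                                    max_candidates = 50L * n_required) {
  if (n_required < 1L) stop("`n_required` must be >= 1", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  walks <- list(); reports <- list(); rejected <- 0L; tried <- 0L
  while (length(walks) < n_required) {
    tried <- tried + 1L
    if (tried > max_candidates)
      stop(sprintf(
        "no %d acceptable walks among %d candidates under the criterion",
        n_required, max_candidates), call. = FALSE)
    w <- generate_walk(config)
    rep_i <- screen_walk(w, n_agents = n_agents, criterion = criterion,
                         config = config,
                         walk_id = sprintf("candidate_%03d", tried))
    if (rep_i$accepted) {
      walks[[length(walks) + 1L]] <- w
      reports[[length(reports) + 1L]] <- rep_i
    } else {
      rejected <- rejected + 1L
    }
  }
  list(walks = walks, reports = reports, n_rejected = rejected)
}
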