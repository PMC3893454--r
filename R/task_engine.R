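#' Task configuration for the two-step sequential decision task
#'
#' Bundles the constants of the task environment: number of trials, the
#' common-transition probability linking first-stage choices to second-stage
#' states, and the bounded Gaussian random walk that drives the four
#' second-stage reward probabilities.
#'
#' @param n_trials Number of trials per session (default 201).
#' @param n_practice Number of practice trials (not simulated; carried for
#'   completeness of the task description).
#' @param p_common Probability that a first-stage choice leads to its common
#'   second-stage state (default 0.7).
#' @param walk_sd Standard deviation of the Gaussian increments of the reward
#'   probability walks (default 0.025).
#' @param walk_lo,walk_hi Lower and upper bounds of the reward probability
#'   walks (defaults 0.2 and 0.8). Excursions are folded back by reflection.
#' @param walk_init_rule Either `"uniform_in_bounds"` (each trajectory starts
#'   at an independent uniform draw within the bounds) or `"fixed"` (all start
#'   at `walk_init_value`).
#' @param walk_init_value Starting value when `walk_init_rule = "fixed"`.
#'
#' @return An object of class `task_config` (a named list).
#' @examples
#' cfg <- task_config()
#' cfg$p_common
#' @export
task_config <- function(n_trials = 201L,
                        n_practice = 50L,
                        p_common = 0.7,
                        walk_sd = 0.025,
                        walk_lo = 0.2,
                        walk_hi = 0.8,
                        walk_init_rule = c("uniform_in_bounds", "fixed"),
                        walk_init_value = 0.5) {
  walk_init_rule <- match.arg(walk_init_rule)
  if (length(n_trials) != 1L || is.na(n_trials) || n_trials < 1)
    stop("`n_trials` must be a positive integer", call. = FALSE)
  if (!(p_common > 0 && p_common < 1))
    stop("`p_common` must lie strictly in (0, 1)", call. = FALSE)
  if (!(walk_lo < walk_hi) || walk_lo <= 0 || walk_hi >= 1)
    stop("walk bounds must satisfy 0 < walk_lo < walk_hi < 1", call. = FALSE)
  if (walk_sd < 0) stop("`walk_sd` must be non-negative", call. = FALSE)
  structure(
    list(
      n_trials = as.integer(n_trials),
      n_practice = as.integer(n_practice),
      p_common = p_common,
      walk_sd = walk_sd,
      walk_lo = walk_lo,
      walk_hi = walk_hi,
      walk_init_rule = walk_init_rule,
      walk_init_value = walk_init_value,
      n_stage2_states = 2L,
      n_options = 2L
    ),
    class = "task_config"
  )
}

# Fold a value back into [lo, hi] by repeated reflection at the bounds.
# With increments a small fraction of the band width a single fold suffices,
# but the loop makes the operation total.
reflect_into <- function(x, lo, hi) {
  width <- hi - lo
  while (x < lo || x > hi) {
    if (x > hi) x <- 2 * hi - x
    if (x < lo) x <- 2 * lo - x
    # pathological overshoot beyond a full band: wrap into range first
    if (x < lo - 2 * width || x > hi + 2 * width) {
      x <- lo + abs((x - lo) %% (2 * width))
      if (x > hi) x <- 2 * hi - x
    }
  }
  x
}

#' Generate bounded random-walk reward probabilities
#'
#' Each of the four second-stage options (two states x two options) gets an
#' independent trajectory: Gaussian increments of scale `walk_sd`, reflected
#' at `walk_lo` and `walk_hi` so every probability stays inside the band.
#'
#' @param config A [task_config()].
#' @param seed Integer seed; the walk is reproducible given the seed.
#' @return A `reward_walk`: an `n_trials` x 4 numeric matrix with columns
#'   `p_s0_o0, p_s0_o1, p_s1_o0, p_s1_o1` (state x option, 0-based labels).
#'   The raw pre-reflection increments are attached as attribute
#'   `"increments"` (an `(n_trials - 1)` x 4 matrix) for diagnostics.
#' @examples
#' w <- generate_walk(task_config(), seed = 1)
#' range(w) # within [0.2, 0.8]
#' @export
generate_walk <- function(config = task_config(), seed = NULL) {
  stopifnot(inherits(config, "task_config"))
  if (!is.null(seed)) set.seed(seed)
  n <- config$n_trials
  p <- matrix(NA_real_, nrow = n, ncol = 4L,
              dimnames = list(NULL, c("p_s0_o0", "p_s0_o1", "p_s1_o0", "p_s1_o1")))
  inc <- matrix(NA_real_, nrow = max(n - 1L, 0L), ncol = 4L)
  for (j in seq_len(4L)) {
    x <- switch(config$walk_init_rule,
      uniform_in_bounds = stats::runif(1L, config$walk_lo, config$walk_hi),
      fixed = config$walk_init_value
    )
    p[1L, j] <- x
    if (n > 1L) {
      steps <- stats::rnorm(n - 1L, mean = 0, sd = config$walk_sd)
      inc[, j] <- steps
      for (t in seq_len(n - 1L)) {
        x <- reflect_into(x + steps[t], config$walk_lo, config$walk_hi)
        p[t + 1L, j] <- x
      }
    }
  }
  structure(p, increments = inc, class = c("reward_walk", "matrix", "array"))
}

#' Sample a second-stage state given a first-stage choice
#'
#' The transition structure is fixed: choice `k` leads to state `k` with
#' probability `p_common` (the "common" transition) and to the other state
#' otherwise ("rare").
#'
#' @param choice1 First-stage choice, 0 or 1.
#' @param config A [task_config()].
#' @return A list with `state2` (0/1) and `transition` (`"common"`/`"rare"`).
#'   Consumes one uniform draw from the current RNG stream.
#' @export
sample_transition <- function(choice1, config = task_config()) {
  if (!choice1 %in% c(0L, 1L)) stop("`choice1` must be 0 or 1", call. = FALSE)
  common <- stats::runif(1L) < config$p_common
  state2 <- if (common) choice1 else 1L - choice1
  list(state2 = as.integer(state2),
       transition = if (common) "common" else "rare")
}

#' Simulate one agent-environment session
#'
#' Runs a hybrid agent (see [hybrid_params()]) through `config$n_trials`
#' trials of the two-step task on a given reward-probability walk. On each
#' trial the agent makes a softmax first-stage choice, transitions
#' probabilistically to a second-stage state, makes a softmax second-stage
#' choice, is rewarded with the walk's current probability for that option,
#' and updates its values.
#'
#' @param params A [hybrid_params()] parameter set.
#' @param walk A `reward_walk` from [generate_walk()] with at least
#'   `config$n_trials` rows.
#' @param config A [task_config()].
#' @param seed Integer seed; the session is bit-reproducible given the seed.
#' @param subject_id,condition Labels copied into the output.
#' @return A `data.frame` (one row per trial) with columns `subject`,
#'   `condition`, `trial` (0-based), `choice1`, `transition`, `state2`,
#'   `choice2`, `reward`, `missed`.
#' @examples
#' w <- generate_walk(task_config(), seed = 2)
#' s <- run_session(hybrid_params(w = 0.5), w, seed = 3)
#' head(s)
#' @export
run_session <- function(params, walk, config = task_config(), seed = NULL,
                        subject_id = "s1", condition = "vertex") {
  stopifnot(inherits(params, "hybrid_params"))
  n <- config$n_trials
  if (nrow(walk) < n)
    stop("walk has fewer rows than `config$n_trials`", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)

  sim <- .sim_session_cpp(unclass(walk), n, config$p_common,
                          params$alpha1, params$alpha2, params$lam,
                          params$beta1, params$beta2, params$w, params$rho)

  structure(
    list(
      subject = rep.int(subject_id, n),
      condition = rep.int(condition, n),
      trial = 0:(n - 1L),
      choice1 = sim$choice1,
      transition = c("rare", "common")[sim$common + 1L],
      state2 = sim$state2,
      choice2 = sim$choice2,
      reward = sim$reward,
      missed = rep.int(FALSE, n)
    ),
    class = "data.frame", row.names = c(NA_integer_, -n)
  )
}

#' Read/write reward walks and trial tables as CSV
#'
#' Walks are stored with a leading 0-based `trial` column and the four
#' probability columns; sessions use the long per-trial format produced by
#' [run_session()].
#'
#' @param walk A `reward_walk` matrix.
#' @param path File path.
#' @return `read_walk_csv()` returns a `reward_walk`; `read_sessions_csv()`
#'   a trial `data.frame`.
#' @export
write_walk_csv <- function(walk, path) {
  df <- data.frame(trial = 0:(nrow(walk) - 1L), unclass(walk)[, , drop = FALSE])
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_walk_csv
#' @export
read_walk_csv <- function(path) {
  df <- utils::read.csv(path)
  m <- as.matrix(df[, c("p_s0_o0", "p_s0_o1", "p_s1_o0", "p_s1_o1")])
  dimnames(m) <- list(NULL, colnames(m))
  structure(m, class = c("reward_walk", "matrix", "array"))
}

#' @rdname write_walk_csv
#' @param sessions A trial `data.frame` (rows from one or more sessions).
#' @export
write_sessions_csv <- function(sessions, path) {
  cols <- c("subject", "condition", "trial", "choice1", "transition",
            "state2", "choice2", "reward", "missed")
  utils::write.csv(sessions[, cols], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_walk_csv
#' @export
read_sessions_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$missed <- as.logical(df$missed)
  df
}
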