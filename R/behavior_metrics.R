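#' Build 1-back lagged trials from a session
#'
#' For each consecutive pair of valid trials (t-1, t) produces one row with
#' the outcome `stay` (did the first-stage choice repeat?) and the previous
#' trial's reward and transition type — the predictors of the 1-back
#' stay/switch analysis. Pairs in which either trial is missed are dropped,
#' as is the first trial (no predecessor).
#'
#' @param session A per-trial `data.frame` as produced by [run_session()],
#'   ordered by `trial`.
#' @return A `data.frame` with columns `subject`, `condition`, `trial`
#'   (the later trial of the pair, 0-based), `stay` (0/1), `prev_reward`
#'   (0/1), `prev_transition` (`"common"`/`"rare"`). Zero rows if fewer than
#'   two valid trials.
#' @examples
#' w <- generate_walk(task_config(), seed = 1)
#' s <- run_session(hybrid_params(), w, seed = 1)
#' nrow(lag_session(s)) # 200 for a 201-trial session without misses
#' @export
lag_session <- function(session) {
  stopifnot(all(c("trial", "choice1", "transition", "reward", "missed")
                %in% names(session)))
  session <- session[order(session$trial), , drop = FALSE]
  n <- nrow(session)
  empty <- data.frame(subject = character(), condition = character(),
                      trial = integer(), stay = integer(),
                      prev_reward = integer(), prev_transition = character(),
                      stringsAsFactors = FALSE)
  if (n < 2L) return(empty)
  prev <- seq_len(n - 1L); cur <- prev + 1L
  ok <- !(session$missed[prev] | session$missed[cur]) &
    (session$trial[cur] == session$trial[prev] + 1L)
  if (!any(ok)) return(empty)
  prev <- prev[ok]; cur <- cur[ok]
  structure(
    list(
      subject = session$subject[cur],
      condition = session$condition[cur],
      trial = session$trial[cur],
      stay = as.integer(session$choice1[cur] == session$choice1[prev]),
      prev_reward = as.integer(session$reward[prev]),
      prev_transition = session$transition[prev]
    ),
    class = "data.frame", row.names = c(NA_integer_, -length(cur))
  )
}

#' 2 x 2 stay-probability table
#'
#' Mean stay probability in each of the four cells defined by the previous
#' trial's reward (0/1) and transition type (common/rare), with cell counts.
#'
#' @param lagged A lagged-trial `data.frame` from [lag_session()].
#' @return A `stay_table`: list with `p_stay` and `n`, both 2 x 2 matrices
#'   with rows `reward0`/`reward1` and columns `common`/`rare`, and `valid`
#'   (`FALSE` if any cell is empty; empty cells hold `NA`).
#' @export
stay_table <- function(lagged) {
  if (nrow(lagged) == 0L) stop("no lagged trials", call. = FALSE)
  cell <- 2L * lagged$prev_reward + (lagged$prev_transition == "rare") + 1L
  nm0 <- tabulate(cell, nbins = 4L)
  st0 <- vapply(1:4, function(k) sum(lagged$stay[cell == k]), numeric(1))
  p <- matrix(ifelse(nm0 > 0, st0 / nm0, NA_real_), 2L, 2L, byrow = TRUE,
              dimnames = list(c("reward0", "reward1"), c("common", "rare")))
  nm <- matrix(as.numeric(nm0), 2L, 2L, byrow = TRUE, dimnames = dimnames(p))
  structure(list(p_stay = p, n = nm, valid = !anyNA(p)), class = "stay_table")
}

#' Model-free / model-based effect indices from a stay table
#'
#' The canonical main-effect and interaction contrasts of the 2 x 2 table:
#' \itemize{
#'   \item `mf_effect` — main effect of previous reward on staying, averaged
#'     over transition type (the model-free signature);
#'   \item `mb_effect` — reward-by-transition interaction, the double
#'     difference `(p[r1,common] - p[r1,rare]) - (p[r0,common] - p[r0,rare])`
#'     (the model-based signature);
#'   \item `balance` — `mb_effect - mf_effect`, positive when model-based
#'     control dominates.
#' }
#'
#' @param table A valid [stay_table()] (no empty cells).
#' @return Named list `mf_effect`, `mb_effect`, `balance` (stay-probability
#'   units).
#' @examples
#' lag <- data.frame(
#'   stay = c(1, 1, 0, 0, 1, 0, 1, 1),
#'   prev_reward = c(1, 1, 0, 0, 1, 0, 1, 0),
#'   prev_transition = c("common", "common", "common", "common",
#'                       "rare", "rare", "rare", "rare")
#' )
#' effect_indices(stay_table(lag))
#' @export
effect_indices <- function(table) {
  stopifnot(inherits(table, "stay_table"))
  if (!table$valid)
    stop("stay table has empty cells; indices are undefined", call. = FALSE)
  p <- table$p_stay
  mf <- mean(p["reward1", ] - p["reward0", ])
  mb <- (p["reward1", "common"] - p["reward1", "rare"]) -
        (p["reward0", "common"] - p["reward0", "rare"])
  list(mf_effect = mf, mb_effect = mb, balance = mb - mf)
}

#' Per-subject, per-condition effect indices
#'
#' Convenience wrapper: splits a multi-session trial table by subject and
#' condition, lags each session and computes [effect_indices()].
#'
#' @param sessions Trial `data.frame` holding one or more sessions.
#' @return A `data.frame` with columns `subject`, `condition`, `mf_effect`,
#'   `mb_effect`, `balance`. Sessions whose stay table has empty cells yield
#'   `NA` indices.
#' @export
subject_indices <- function(sessions) {
  parts <- split(sessions, list(sessions$subject, sessions$condition),
                 drop = TRUE)
  out <- lapply(parts, function(s) {
    tab <- stay_table(lag_session(s))
    idx <- if (tab$valid) effect_indices(tab) else
      list(mf_effect = NA_real_, mb_effect = NA_real_, balance = NA_real_)
    data.frame(subject = s$subject[1L], condition = s$condition[1L],
               mf_effect = idx$mf_effect, mb_effect = idx$mb_effect,
               balance = idx$balance, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$subject, res$condition), , drop = FALSE]
}
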