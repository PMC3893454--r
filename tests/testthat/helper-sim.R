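# Simulate lagged-trial designs directly from the logistic generating model:
# per-subject coefficients are the population betas plus independent normal
# random effects; rows carry the centered reward/transition coding used by
# build_design(). Serves as ground truth for parameter-recovery checks.
sim_logit_design <- function(n_subj = 25, n_rows = 200, beta = NULL,
                             re_sd = 0.3, seed = 1) {
  set.seed(seed)
  regs <- design_regressors()
  b0 <- stats::setNames(rep(0, length(regs)), regs)
  b0["intercept"] <- 1
  if (!is.null(beta)) b0[names(beta)] <- beta
  rows <- vector("list", n_subj * 3L)
  k <- 0L
  for (i in seq_len(n_subj)) {
    b_i <- b0 + stats::rnorm(length(regs), 0, re_sd)
    for (cond in c("vertex", "left_dlpfc", "right_dlpfc")) {
      rew <- sample(c(-0.5, 0.5), n_rows, TRUE)
      trans <- sample(c(-0.5, 0.5), n_rows, TRUE, prob = c(0.3, 0.7))
      left <- as.numeric(cond == "left_dlpfc")
      right <- as.numeric(cond == "right_dlpfc")
      vert <- as.numeric(cond == "vertex")
      X <- cbind(intercept = 1, site_left = left, site_right = right,
                 rew_left = rew * left, rew_right = rew * right,
                 rew_vertex = rew * vert,
                 trans_left = trans * left, trans_right = trans * right,
                 trans_vertex = trans * vert,
                 rxt_left = rew * trans * left,
                 rxt_right = rew * trans * right,
                 rxt_vertex = rew * trans * vert)
      stay <- stats::rbinom(n_rows, 1, stats::plogis(drop(X %*% b_i)))
      k <- k + 1L
      rows[[k]] <- data.frame(stay = stay, subject = sprintf("s%02d", i), X,
                              stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

# Hand-built session data.frame from parallel vectors (0-based trials).
make_session <- function(choice1, reward, transition,
                         state2 = NULL, choice2 = NULL, missed = NULL,
                         subject = "s1", condition = "vertex") {
  n <- length(choice1)
  data.frame(
    subject = subject, condition = condition, trial = 0:(n - 1L),
    choice1 = choice1,
    transition = transition,
    state2 = if (is.null(state2)) rep(0L, n) else state2,
    choice2 = if (is.null(choice2)) rep(0L, n) else choice2,
    reward = reward,
    missed = if (is.null(missed)) rep(FALSE, n) else missed,
    stringsAsFactors = FALSE
  )
}

# Lagged rows with exact per-cell stay counts, for table/index oracles.
make_lagged <- function(n_stay, n_total) {
  # n_stay / n_total: 2x2 matrices, rows reward 0/1, cols common/rare
  rows <- list()
  for (r in 0:1) for (tr in c("common", "rare")) {
    ns <- n_stay[r + 1L, if (tr == "common") 1L else 2L]
    nt <- n_total[r + 1L, if (tr == "common") 1L else 2L]
    if (nt > 0)
      rows[[length(rows) + 1L]] <- data.frame(
        stay = c(rep(1L, ns), rep(0L, nt - ns)),
        prev_reward = r, prev_transition = tr, stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}
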