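#' Specification of a synthetic study cohort
#'
#' Defines the generating model of a full synthetic study: each subject has
#' a working-memory capacity K and a baseline model-based weight `w`;
#' stimulation of right dlPFC lowers `w` by a constant, stimulation of left
#' dlPFC lowers `w` by an amount that shrinks with K
#' (`max(0, delta_w_left_max * (1 - K / k_max))`), and the vertex condition
#' leaves `w` at baseline. This is the testable structure of the
#' behavioral hypotheses: a site effect on model-based control, and a
#' WM-dependent site effect.
#'
#' @param n_subjects Number of subjects (default 25).
#' @param n_trials Trials per session (default 201).
#' @param w_baseline_mean,w_baseline_sd Distribution of the subject-level
#'   baseline model-based weight (defaults 0.6 and 0.15; clipped to
#'   `[0, 1]`).
#' @param delta_w_right Reduction of `w` under right-dlPFC stimulation
#'   (default 0.3).
#' @param delta_w_left_max Maximum reduction of `w` under left-dlPFC
#'   stimulation, attained at K = 0 and decaying linearly to 0 at
#'   K = `k_max` (default 0.8: a subject with no working-memory capacity
#'   loses nearly all model-based control).
#' @param wm_mean,wm_sd Distribution of K (defaults 3.0 and 1.2; clipped to
#'   `[0, k_max]`).
#' @param k_max Upper bound of the K scale (default 5, the set size of the
#'   change-detection task).
#' @param agent A [hybrid_params()] set providing every parameter except
#'   `w`.
#' @param config A [task_config()].
#' @param screen_n_agents Agents per walk screen (default 500).
#' @param seed Integer seed for the whole study.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_subjects = 25L, n_trials = 201L,
                        w_baseline_mean = 0.6, w_baseline_sd = 0.15,
                        delta_w_right = 0.3, delta_w_left_max = 0.8,
                        wm_mean = 3.0, wm_sd = 1.2, k_max = 5,
                        agent = hybrid_params(),
                        config = task_config(n_trials = n_trials),
                        screen_n_agents = 500L,
                        seed = 1L) {
  if (n_subjects < 2L) stop("`n_subjects` must be >= 2", call. = FALSE)
  structure(
    list(n_subjects = as.integer(n_subjects),
         conditions = c("vertex", "left_dlpfc", "right_dlpfc"),
         w_baseline_mean = w_baseline_mean, w_baseline_sd = w_baseline_sd,
         delta_w_right = delta_w_right, delta_w_left_max = delta_w_left_max,
         wm_mean = wm_mean, wm_sd = wm_sd, k_max = k_max,
         agent = agent, config = config,
         screen_n_agents = as.integer(screen_n_agents),
         seed = as.integer(seed)),
    class = "cohort_spec"
  )
}

# Balanced session orders: all 6 permutations of the 3 conditions, cycled
# over the first 24 subjects; the odd 25th subject gets a random order.
counterbalanced_orders <- function(n_subjects, conditions) {
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  n_bal <- (n_subjects %/% length(perms)) * length(perms)
  orders <- vector("list", n_subjects)
  for (i in seq_len(n_subjects)) {
    ord <- if (i <= n_bal) perms[[(i - 1L) %% length(perms) + 1L]]
           else sample(3L)
    orders[[i]] <- conditions[ord]
  }
  orders
}

#' Generate a full synthetic study
#'
#' Draws per-subject working-memory capacity and baseline model-based
#' weight, sets the condition-specific weights per the [cohort_spec()]
#' generating model, pre-screens three reward walks with pure model-free
#' agents ([generate_screened_walks()]), assigns walks randomly to each
#' subject's sessions, counterbalances condition order, and simulates every
#' session with the hybrid agent. Out-of-bounds weights are clipped to
#' `[0, 1]` with a warning.
#'
#' @param spec A [cohort_spec()].
#' @return A `synthetic_study`: list with `sessions` (one long trial
#'   `data.frame`, `n_subjects * 3` sessions), `wm` (`data.frame` subject,
#'   `k`), `truth` (`data.frame` of every generating parameter per subject x
#'   condition, incl. the session order and walk assignment) and `walks`
#'   (the three screened walks). Bit-reproducible given `spec$seed`.
#' @export
generate_cohort <- function(spec = cohort_spec()) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  ns <- spec$n_subjects
  k <- pmin(spec$k_max, pmax(0, stats::rnorm(ns, spec$wm_mean, spec$wm_sd)))
  w_base <- stats::rnorm(ns, spec$w_baseline_mean, spec$w_baseline_sd)
  if (any(w_base < 0 | w_base > 1)) {
    warning("baseline w outside [0, 1] clipped", call. = FALSE)
    w_base <- pmin(1, pmax(0, w_base))
  }
  screened <- generate_screened_walks(spec$config, n_required = 3L,
                                      n_agents = spec$screen_n_agents)
  orders <- counterbalanced_orders(ns, spec$conditions)

  subj_ids <- sprintf("s%02d", seq_len(ns))
  sessions <- vector("list", ns * 3L)
  truth <- vector("list", ns * 3L)
  idx <- 0L
  for (i in seq_len(ns)) {
    walk_perm <- sample(3L)  # random walk-to-session assignment
    for (sess in 1:3) {
      cond <- orders[[i]][sess]
      w_cond <- switch(cond,
        vertex = w_base[i],
        right_dlpfc = w_base[i] - spec$delta_w_right,
        left_dlpfc = w_base[i] -
          max(0, spec$delta_w_left_max * (1 - k[i] / spec$k_max))
      )
      if (w_cond < 0 || w_cond > 1) {
        warning("condition-level w outside [0, 1] clipped", call. = FALSE)
        w_cond <- min(1, max(0, w_cond))
      }
      par_i <- spec$agent
      par_i$w <- w_cond
      wid <- walk_perm[sess]
      idx <- idx + 1L
      sessions[[idx]] <- run_session(par_i, screened$walks[[wid]],
                                     spec$config,
                                     subject_id = subj_ids[i],
                                     condition = cond)
      truth[[idx]] <- data.frame(
        subject = subj_ids[i], condition = cond, session = sess,
        walk_id = wid, k = k[i], w_baseline = w_base[i], w = w_cond,
        alpha1 = par_i$alpha1, alpha2 = par_i$alpha2, lam = par_i$lam,
        beta1 = par_i$beta1, beta2 = par_i$beta2, rho = par_i$rho,
        stringsAsFactors = FALSE)
    }
  }
  structure(
    list(sessions = do.call(rbind, sessions),
         wm = data.frame(subject = subj_ids, k = k, stringsAsFactors = FALSE),
         truth = do.call(rbind, truth),
         walks = screened$walks,
         spec = spec),
    class = "synthetic_study"
  )
}

#' Run the full analysis pipeline on a study
#'
#' Per-subject effect indices, the hierarchical logistic regression with the
#' standard site contrasts, WM correlations of the balance index per
#' condition, and the pairwise permutation tests between conditions.
#'
#' @param sessions Long trial `data.frame` (all subjects x conditions).
#' @param wm `data.frame` with `subject` and `k`.
#' @param n_perm Permutations for the pairwise correlation tests.
#' @param perm_seed Seed for the permutation tests.
#' @return List with `indices`, `fit`, `contrasts`, `correlations`
#'   (per-condition r and cor.test p of K vs balance), `perm_tests`
#'   (pairwise `perm_result`s on the balance index).
#' @export
analyze_study <- function(sessions, wm, n_perm = 1e4L, perm_seed = 1L) {
  indices <- subject_indices(sessions)
  design <- build_design(sessions)
  fit <- fit_hier_logit(design)
  contrasts <- site_contrasts(fit)

  conds <- sort(unique(indices$condition))
  bal <- lapply(conds, function(cn) {
    b <- indices[indices$condition == cn, c("subject", "balance")]
    stats::setNames(b$balance, b$subject)[wm$subject]
  })
  names(bal) <- conds
  correlations <- do.call(rbind, lapply(conds, function(cn) {
    ct <- stats::cor.test(wm$k, bal[[cn]])
    data.frame(condition = cn, r = unname(ct$estimate), p = ct$p.value,
               stringsAsFactors = FALSE)
  }))
  pairs <- utils::combn(conds, 2L, simplify = FALSE)
  perm_tests <- lapply(pairs, function(pr) {
    perm_corr_diff(wm$k, bal[[pr[1L]]], bal[[pr[2L]]], n_perm = n_perm,
                   seed = perm_seed)
  })
  names(perm_tests) <- vapply(pairs, paste, character(1L), collapse = "_vs_")
  list(indices = indices, fit = fit, contrasts = contrasts,
       correlations = correlations, perm_tests = perm_tests)
}

#' Recovery report: does the analysis recover the generating structure?
#'
#' Runs [analyze_study()] on a synthetic study and tabulates how well the
#' pipeline recovers the generating model: the sign of the
#' right-vs-vertex interaction contrast (the generator reduces `w` under
#' right dlPFC), the correlation between K and the left-dlPFC balance (the
#' generator couples them), the vertex balance-K correlation (null by
#' construction), the rank correlation between generating `w` and estimated
#' interaction index across all sessions, and the left-vs-right permutation
#' test.
#'
#' @param study A `synthetic_study`.
#' @param n_perm Permutations for the pairwise tests.
#' @return List with `analysis` (the full [analyze_study()] output) and
#'   `recovery` (named list of the summary quantities above).
#' @export
recovery_report <- function(study, n_perm = 1e4L) {
  stopifnot(inherits(study, "synthetic_study"))
  an <- analyze_study(study$sessions, study$wm, n_perm = n_perm,
                      perm_seed = study$spec$seed)
  ctr <- an$contrasts
  rv <- ctr[ctr$effect == "interaction" & ctr$contrast == "right_vs_vertex", ]
  corr <- an$correlations
  merged <- merge(an$indices, study$truth[, c("subject", "condition", "w")],
                  by = c("subject", "condition"))
  recovery <- list(
    right_vs_vertex_interaction = rv$estimate,
    right_vs_vertex_interaction_p = rv$p,
    left_wm_balance_r = corr$r[corr$condition == "left_dlpfc"],
    left_wm_balance_p = corr$p[corr$condition == "left_dlpfc"],
    vertex_wm_balance_r = corr$r[corr$condition == "vertex"],
    vertex_wm_balance_p = corr$p[corr$condition == "vertex"],
    w_mb_rank_r = stats::cor(merged$w, merged$mb_effect, method = "spearman"),
    left_vs_right_perm_p = an$perm_tests[["left_dlpfc_vs_right_dlpfc"]]$p
  )
  list(analysis = an, recovery = recovery)
}
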