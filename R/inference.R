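#' Regressor names of the hierarchical stay/switch design
#'
#' The 12 regressors of the population model: an intercept (which absorbs
#' the vertex main effect), dummies for the two dlPFC sites, and
#' site-specific reward, transition, and reward-by-transition terms.
#' @return Character vector of length 12.
#' @export
design_regressors <- function() {
  c("intercept", "site_left", "site_right",
    "rew_left", "rew_right", "rew_vertex",
    "trans_left", "trans_right", "trans_vertex",
    "rxt_left", "rxt_right", "rxt_vertex")
}

#' Build the hierarchical stay/switch design matrix
#'
#' Lags every session (see [lag_session()]) and codes the 12 regressors:
#' previous reward as -0.5/+0.5, previous transition as +0.5 (common) /
#' -0.5 (rare) — centered so the interaction is orthogonal to the main
#' effects — and one indicator per stimulation site. Site-specific terms are
#' the products of the coded predictor and the site indicator, so exactly
#' one regressor of each site triple is active on any row. The vertex main
#' effect is absorbed by the intercept.
#'
#' @param sessions Trial `data.frame` covering one or more subjects and
#'   conditions; condition labels must come from
#'   `c("vertex", "left_dlpfc", "right_dlpfc")`.
#' @return A `data.frame` with `stay`, `subject`, and the 12 regressor
#'   columns of [design_regressors()].
#' @export
build_design <- function(sessions) {
  valid <- c("vertex", "left_dlpfc", "right_dlpfc")
  bad <- setdiff(unique(sessions$condition), valid)
  if (length(bad))
    stop("unknown condition label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  parts <- split(sessions, list(sessions$subject, sessions$condition),
                 drop = TRUE)
  lagged <- do.call(rbind, lapply(parts, lag_session))
  if (is.null(lagged) || nrow(lagged) == 0L)
    stop("no lagged trials in input", call. = FALSE)
  rew <- ifelse(lagged$prev_reward == 1L, 0.5, -0.5)
  trans <- ifelse(lagged$prev_transition == "common", 0.5, -0.5)
  left <- as.numeric(lagged$condition == "left_dlpfc")
  right <- as.numeric(lagged$condition == "right_dlpfc")
  vertex <- as.numeric(lagged$condition == "vertex")
  d <- data.frame(
    stay = lagged$stay,
    subject = lagged$subject,
    intercept = 1,
    site_left = left,
    site_right = right,
    rew_left = rew * left,
    rew_right = rew * right,
    rew_vertex = rew * vertex,
    trans_left = trans * left,
    trans_right = trans * right,
    trans_vertex = trans * vertex,
    rxt_left = rew * trans * left,
    rxt_right = rew * trans * right,
    rxt_vertex = rew * trans * vertex,
    stringsAsFactors = FALSE
  )
  rownames(d) <- NULL
  d
}

#' Fit the hierarchical logistic regression on stay/switch
#'
#' Logistic mixed model for staying with the previous first-stage choice,
#' with all 12 regressors as fixed effects and, per subject, independent
#' (diagonal-covariance) random effects on every coefficient. Estimated by
#' Laplace-approximated marginal maximum likelihood via [lme4::glmer()].
#'
#' With `random_effects = FALSE` the random-effect variances are fixed at
#' zero inside the same mixed-model deviance machinery and only the fixed
#' effects are optimized, which collapses the model to an ordinary pooled
#' logistic regression — useful as a degenerate-case check.
#'
#' @param design A `data.frame` from [build_design()].
#' @param random_effects If `FALSE`, constrain all random-effect variances
#'   to zero (see above).
#' @return A `hier_fit`: list with `fixed_effects` (named, log-odds scale),
#'   `vcov` (12 x 12), `re_variances` (named, on the variance scale),
#'   `loglik`, `converged`, and `model` (the underlying fit object).
#' @export
fit_hier_logit <- function(design, random_effects = TRUE) {
  regs <- design_regressors()
  stopifnot(all(c("stay", "subject", regs) %in% names(design)))
  if (length(unique(design$subject)) < 2L)
    stop("at least 2 subjects are required", call. = FALSE)
  if (!all(design$stay %in% c(0L, 1L)))
    stop("`stay` must be 0/1", call. = FALSE)
  rhs <- paste(regs, collapse = " + ")
  form <- stats::as.formula(sprintf(
    "stay ~ 0 + %s + (0 + %s || subject)", rhs, rhs))

  if (random_effects) {
    fit <- lme4::glmer(form, data = design, family = stats::binomial(),
                       control = lme4::glmerControl(optimizer = "bobyqa",
                                                    calc.derivs = FALSE))
    beta <- lme4::fixef(fit)[regs]
    V <- as.matrix(stats::vcov(fit))[regs, regs]
    vc <- lme4::VarCorr(fit)
    rev <- vapply(vc, function(m) as.numeric(m[1L, 1L]), numeric(1L))
    names(rev) <- vapply(vc, function(m) rownames(m)[1L], character(1L))
    rev <- rev[regs]
    conv <- length(fit@optinfo$conv$lme4) == 0L &&
      isTRUE(fit@optinfo$conv$opt == 0L)
    structure(list(fixed_effects = beta, vcov = V, re_variances = rev,
                   loglik = as.numeric(stats::logLik(fit)),
                   converged = conv, model = fit),
              class = "hier_fit")
  } else {
    # evaluate the glmer deviance with theta pinned at 0; optimize beta only
    gf <- lme4::glFormula(form, data = design, family = stats::binomial())
    devfun <- do.call(lme4::mkGlmerDevfun, gf)
    devfun2 <- lme4::updateGlmerDevfun(devfun, gf$reTrms)
    ntheta <- length(gf$reTrms$theta)
    start <- stats::coef(stats::glm(
      stats::as.formula(paste("stay ~ 0 +", rhs)),
      data = design, family = stats::binomial()))
    obj <- function(beta) devfun2(c(rep(0, ntheta), beta))
    opt <- stats::optim(start, obj, method = "BFGS", hessian = TRUE,
                        control = list(maxit = 500, reltol = 1e-12))
    beta <- opt$par
    names(beta) <- regs
    V <- 2 * solve(opt$hessian)  # devfun is on the deviance (-2 logLik) scale
    dimnames(V) <- list(regs, regs)
    structure(list(fixed_effects = beta, vcov = V,
                   re_variances = stats::setNames(rep(0, length(regs)), regs),
                   loglik = -opt$value / 2,
                   converged = opt$convergence == 0L, model = opt),
              class = "hier_fit")
  }
}

#' Wald chi-square contrast on the fixed effects
#'
#' Linear contrast `t(weights) %*% beta` with a 1-df chi-square test,
#' `chi2 = estimate^2 / (t(w) V w)` — the classic contrast test on mixed
#' model population coefficients.
#'
#' @param fit A `hier_fit`.
#' @param weights Numeric vector of length 12, or a named vector whose names
#'   are a subset of [design_regressors()] (unnamed regressors get weight 0).
#' @return A `contrast_result`: list `estimate`, `se`, `chi2`, `df` (1),
#'   `p`.
#' @examples
#' \dontrun{
#' wald_contrast(fit, c(rxt_right = 1, rxt_vertex = -1))
#' }
#' @export
wald_contrast <- function(fit, weights) {
  stopifnot(inherits(fit, "hier_fit"))
  if (!fit$converged)
    stop("contrast on a non-converged fit", call. = FALSE)
  regs <- design_regressors()
  if (!is.null(names(weights))) {
    bad <- setdiff(names(weights), regs)
    if (length(bad))
      stop("unknown regressor(s) in weights: ", paste(bad, collapse = ", "),
           call. = FALSE)
    w <- stats::setNames(rep(0, length(regs)), regs)
    w[names(weights)] <- weights
  } else {
    if (length(weights) != length(regs))
      stop("`weights` must have length 12", call. = FALSE)
    w <- stats::setNames(as.numeric(weights), regs)
  }
  est <- sum(w * fit$fixed_effects)
  v <- drop(t(w) %*% fit$vcov %*% w)
  if (all(w == 0))
    return(structure(list(estimate = 0, se = 0, chi2 = 0, df = 1L, p = 1),
                     class = "contrast_result"))
  if (v <= 0) stop("zero-variance contrast", call. = FALSE)
  chi2 <- est^2 / v
  structure(list(estimate = est, se = sqrt(v), chi2 = chi2, df = 1L,
                 p = stats::pchisq(chi2, df = 1L, lower.tail = FALSE)),
            class = "contrast_result")
}

#' Standard site-contrast table
#'
#' All pairwise site comparisons (left - vertex, right - vertex,
#' left - right) for model-free control (reward), model-based control
#' (reward x transition), and their balance (interaction minus reward).
#'
#' @param fit A `hier_fit`.
#' @return A `data.frame` with one row per contrast: `effect`, `contrast`,
#'   `estimate`, `se`, `chi2`, `df`, `p`.
#' @export
site_contrasts <- function(fit) {
  triples <- list(reward = c("rew_left", "rew_right", "rew_vertex"),
                  interaction = c("rxt_left", "rxt_right", "rxt_vertex"))
  pairs <- list(left_vs_vertex = c(1L, 3L), right_vs_vertex = c(2L, 3L),
                left_vs_right = c(1L, 2L))
  rows <- list()
  for (eff in names(triples)) {
    tr <- triples[[eff]]
    for (cn in names(pairs)) {
      idx <- pairs[[cn]]
      w <- stats::setNames(c(1, -1), tr[idx])
      res <- wald_contrast(fit, w)
      rows[[length(rows) + 1L]] <- data.frame(
        effect = eff, contrast = cn, estimate = res$estimate, se = res$se,
        chi2 = res$chi2, df = res$df, p = res$p, stringsAsFactors = FALSE)
    }
  }
  # balance = interaction - reward, compared across sites
  bal <- list(left = c(rxt_left = 1, rew_left = -1),
              right = c(rxt_right = 1, rew_right = -1),
              vertex = c(rxt_vertex = 1, rew_vertex = -1))
  for (cn in names(pairs)) {
    idx <- pairs[[cn]]
    sites <- c("left", "right", "vertex")[idx]
    w <- c(bal[[sites[1L]]], -bal[[sites[2L]]])
    res <- wald_contrast(fit, w)
    rows[[length(rows) + 1L]] <- data.frame(
      effect = "balance", contrast = cn, estimate = res$estimate,
      se = res$se, chi2 = res$chi2, df = res$df, p = res$p,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Pearson product-moment correlation
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return The correlation coefficient.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop("length mismatch", call. = FALSE)
  if (length(x) < 3L) stop("need at least 3 pairs", call. = FALSE)
  stats::cor(x, y, method = "pearson")
}

#' Paired permutation test for a difference between dependent correlations
#'
#' Tests whether a covariate (e.g. working-memory capacity) correlates more
#' strongly with a per-subject measure in condition A than in condition B,
#' for the same subjects. The observed statistic is
#' `r(wm, a) - r(wm, b)`. Under the null the condition labels are
#' exchangeable within subject, so the null distribution is built by
#' independently swapping each subject's (a, b) pair with probability 1/2
#' per permutation; the two-sided p-value is
#' `(1 + #{|null| >= |observed|}) / (n_perm + 1)`.
#'
#' @param wm Per-subject covariate.
#' @param balance_a,balance_b Per-subject measures in the two conditions,
#'   aligned with `wm`.
#' @param n_perm Number of permutations (default 1e5).
#' @param seed Integer seed.
#' @return A `perm_result`: list `observed_diff`, `n_perm`, `p`, `seed`.
#' @export
perm_corr_diff <- function(wm, balance_a, balance_b, n_perm = 1e5L,
                           seed = NULL) {
  n <- length(wm)
  if (length(balance_a) != n || length(balance_b) != n)
    stop("length mismatch", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  obs <- pearson_r(wm, balance_a) - pearson_r(wm, balance_b)
  wmc <- wm - mean(wm)
  sw <- sqrt(sum(wmc^2))
  n_ge <- 0L
  chunk <- 20000L
  done <- 0L
  col_r <- function(M) {
    Mc <- sweep(M, 2L, colMeans(M))
    colSums(wmc * Mc) / (sw * sqrt(colSums(Mc^2)))
  }
  while (done < n_perm) {
    k <- min(chunk, n_perm - done)
    S <- matrix(stats::runif(n * k) < 0.5, n, k)
    A <- ifelse(S, balance_b, balance_a)
    B <- ifelse(S, balance_a, balance_b)
    d <- col_r(A) - col_r(B)
    n_ge <- n_ge + sum(abs(d) >= abs(obs))
    done <- done + k
  }
  structure(list(observed_diff = obs, n_perm = as.integer(n_perm),
                 p = (1 + n_ge) / (n_perm + 1),
                 seed = if (is.null(seed)) NA_integer_ else as.integer(seed)),
            class = "perm_result")
}

#' Working-memory capacity K from change detection
#'
#' Cowan's K for a single-probe change-detection task:
#' `K = set_size * (hit_rate - false_alarm_rate)`, clipped below at zero —
#' the estimated number of items held in visuospatial working memory.
#'
#' @param set_size Number of items presented (> 0).
#' @param hit_rate,fa_rate Hit and false-alarm rates in `[0, 1]`.
#' @return K (same length as the rate inputs).
#' @examples
#' cowan_k(5, 0.8, 0.2) # 3
#' @export
cowan_k <- function(set_size, hit_rate, fa_rate) {
  if (any(set_size <= 0)) stop("`set_size` must be positive", call. = FALSE)
  if (any(hit_rate < 0 | hit_rate > 1 | fa_rate < 0 | fa_rate > 1))
    stop("rates must be in [0, 1]", call. = FALSE)
  pmax(0, set_size * (hit_rate - fa_rate))
}
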