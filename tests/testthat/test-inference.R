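test_that("the design matrix has the Table-1 structure", {
  cfg <- task_config(n_trials = 50L)
  w <- generate_walk(cfg, seed = 1)
  set.seed(2)
  sessions <- rbind(
    run_session(hybrid_params(), w, cfg, subject_id = "a",
                condition = "vertex"),
    run_session(hybrid_params(), w, cfg, subject_id = "a",
                condition = "left_dlpfc"),
    run_session(hybrid_params(), w, cfg, subject_id = "b",
                condition = "right_dlpfc")
  )
  d <- build_design(sessions)
  expect_setequal(setdiff(names(d), c("stay", "subject")),
                  design_regressors())
  expect_equal(length(design_regressors()), 12L)
  expect_true(all(d$intercept == 1))
  # each row activates exactly one regressor of each site triple
  expect_true(all(rowSums(abs(d[, c("rew_left", "rew_right",
                                    "rew_vertex")]) > 0) == 1))
  expect_true(all(rowSums(abs(d[, c("rxt_left", "rxt_right",
                                    "rxt_vertex")]) > 0) == 1))
  # centered +-0.5 coding
  expect_setequal(unique(d$rew_vertex[d$rew_vertex != 0]), c(-0.5, 0.5))
  expect_setequal(unique(d$trans_left[d$trans_left != 0]), c(-0.5, 0.5))
})

test_that("a vertex-only subject activates only the vertex columns", {
  cfg <- task_config(n_trials = 40L)
  w <- generate_walk(cfg, seed = 3)
  s <- run_session(hybrid_params(), w, cfg, subject_id = "a",
                   condition = "vertex")
  d <- build_design(s)
  for (col in c("site_left", "site_right", "rew_left", "rew_right",
                "trans_left", "trans_right", "rxt_left", "rxt_right"))
    expect_true(all(d[[col]] == 0))
  for (col in c("rew_vertex", "trans_vertex", "rxt_vertex"))
    expect_gt(stats::sd(d[[col]]), 0)
})

test_that("design rows encode the lagged predictors exactly", {
  s <- make_session(choice1 = c(0L, 0L, 1L, 1L),
                    reward = c(1L, 0L, 1L, 0L),
                    transition = c("common", "rare", "common", "common"),
                    condition = "left_dlpfc")
  d <- build_design(s)
  expect_equal(nrow(d), 3L)
  expect_equal(d$stay, c(1L, 0L, 1L))
  expect_equal(d$rew_left, c(0.5, -0.5, 0.5))
  expect_equal(d$trans_left, c(0.5, -0.5, 0.5))
  expect_equal(d$rxt_left, c(0.25, 0.25, 0.25))
  expect_true(all(d$rew_vertex == 0))
  expect_error(build_design(transform(s, condition = "sham")),
               "unknown condition")
})

test_that("the hierarchical fit recovers generating coefficients", {
  # simulate straight from the logistic mixed model at the study's scale
  truth <- c(rew_vertex = 0.8, rxt_right = -0.5, rxt_vertex = 0.4)
  d <- sim_logit_design(n_subj = 25, n_rows = 200, beta = truth,
                        re_sd = 0.3, seed = 41)
  fit <- fit_hier_logit(d)
  expect_true(fit$converged)
  se <- sqrt(diag(fit$vcov))
  full_truth <- stats::setNames(rep(0, 12), design_regressors())
  full_truth["intercept"] <- 1
  full_truth[names(truth)] <- truth
  for (r in design_regressors())
    expect_lt(abs(fit$fixed_effects[r] - full_truth[r]), 3 * se[r])
  # the planted positive effect is clearly detected
  expect_gt(fit$fixed_effects["rew_vertex"] / se["rew_vertex"], 2)
  expect_true(all(fit$re_variances >= 0))
  expect_true(isSymmetric(fit$vcov, tol = 1e-8))
})

test_that("zero random-effect variance collapses to pooled logistic", {
  d <- sim_logit_design(n_subj = 8, n_rows = 50, re_sd = 0.3, seed = 42)
  f0 <- fit_hier_logit(d, random_effects = FALSE)
  g <- stats::glm(stay ~ 0 + intercept + site_left + site_right +
                    rew_left + rew_right + rew_vertex + trans_left +
                    trans_right + trans_vertex + rxt_left + rxt_right +
                    rxt_vertex,
                  data = d, family = stats::binomial())
  expect_lt(max(abs(f0$fixed_effects - stats::coef(g))), 1e-4)
  expect_true(all(f0$re_variances == 0))
  expect_equal(unname(f0$loglik), as.numeric(stats::logLik(g)),
               tolerance = 1e-6)
})

test_that("Wald contrasts behave as stated", {
  d <- sim_logit_design(n_subj = 10, n_rows = 60, re_sd = 0.2, seed = 43)
  fit <- fit_hier_logit(d)

  # all-zero weights: trivial contrast
  z <- wald_contrast(fit, rep(0, 12))
  expect_equal(z$estimate, 0)
  expect_equal(z$chi2, 0)
  expect_equal(z$p, 1)

  # unit vector reproduces the coefficient's own z-squared p-value
  se <- sqrt(diag(fit$vcov))
  for (r in c("intercept", "rxt_vertex")) {
    u <- stats::setNames(1, r)
    res <- wald_contrast(fit, u)
    expect_equal(res$estimate, unname(fit$fixed_effects[r]))
    zval <- fit$fixed_effects[r] / se[r]
    expect_equal(res$chi2, unname(zval^2), tolerance = 1e-10)
    expect_equal(res$p, unname(2 * stats::pnorm(-abs(zval))),
                 tolerance = 1e-10)
  }
  expect_error(wald_contrast(fit, stats::setNames(1, "nonsense")),
               "unknown regressor")

  # site_contrasts covers 3 effects x 3 pairwise comparisons
  tab <- site_contrasts(fit)
  expect_equal(nrow(tab), 9L)
  expect_setequal(tab$effect, c("reward", "interaction", "balance"))
  expect_true(all(tab$p >= 0 & tab$p <= 1))
  # balance contrast = interaction contrast - reward contrast
  for (cn in unique(tab$contrast)) {
    sub <- tab[tab$contrast == cn, ]
    expect_equal(sub$estimate[sub$effect == "balance"],
                 sub$estimate[sub$effect == "interaction"] -
                   sub$estimate[sub$effect == "reward"],
                 tolerance = 1e-10)
  }
})

test_that("a planted site difference is detected by its contrast", {
  # generator reduces the right-site interaction relative to vertex
  d <- sim_logit_design(n_subj = 25, n_rows = 200,
                        beta = c(rxt_vertex = 0.6, rxt_left = 0.6,
                                 rxt_right = -0.2),
                        re_sd = 0.3, seed = 44)
  fit <- fit_hier_logit(d)
  res <- wald_contrast(fit, c(rxt_right = 1, rxt_vertex = -1))
  expect_lt(res$estimate, 0)
  expect_lt(res$p, 0.05)
})

test_that("pearson_r matches hand-computed values", {
  expect_equal(pearson_r(1:5, 1:5), 1)
  expect_equal(pearson_r(1:5, -(1:5)), -1)
  expect_equal(pearson_r(c(1, 2, 3), c(2, 4, 7)), 5 / sqrt(2 * 38 / 3),
               tolerance = 1e-12)
  expect_equal(pearson_r(c(1, 2, 3), c(2, 4, 7)), 0.9934, tolerance = 1e-4)
  expect_error(pearson_r(1:3, 1:4), "length")
  expect_error(pearson_r(1:2, 1:2), "at least 3")
})

test_that("the paired permutation test has the stated trivial cases", {
  set.seed(51)
  wm <- rnorm(20)
  a <- rnorm(20)
  r1 <- perm_corr_diff(wm, a, a, n_perm = 500L, seed = 1)
  expect_equal(r1$observed_diff, 0)
  expect_equal(r1$p, 1)

  b <- rnorm(20)
  r_ab <- perm_corr_diff(wm, a, b, n_perm = 2000L, seed = 2)
  r_ba <- perm_corr_diff(wm, b, a, n_perm = 2000L, seed = 2)
  expect_equal(r_ab$observed_diff, -r_ba$observed_diff)
  expect_equal(r_ab$p, r_ba$p)   # |diff| is label-symmetric
  expect_gte(r_ab$p, 1 / 2001)
  expect_error(perm_corr_diff(wm, a, b[-1], n_perm = 10L), "length")
})

test_that("a strong constructed correlation difference is detected", {
  set.seed(52)
  n <- 25
  wm <- rnorm(n)
  bal_a <- 0.9 * wm + sqrt(1 - 0.81) * rnorm(n)  # r ~ 0.9 by construction
  bal_b <- rnorm(n)                              # r ~ 0
  res <- perm_corr_diff(wm, bal_a, bal_b, n_perm = 10000L, seed = 3)
  expect_gt(res$observed_diff, 0.5)
  expect_lt(res$p, 0.01)
})

test_that("Cowan's K follows set_size * (hit - fa), clipped at zero", {
  expect_equal(cowan_k(5, 1, 0), 5)
  expect_equal(cowan_k(5, 0.4, 0.4), 0)
  expect_equal(cowan_k(5, 0.8, 0.2), 3)
  expect_equal(cowan_k(4, 0.1, 0.9), 0)  # below-chance clips to 0
  expect_equal(cowan_k(5, c(0.8, 1), c(0.2, 0)), c(3, 5))
  expect_error(cowan_k(0, 0.5, 0.5), "set_size")
  expect_error(cowan_k(5, 1.2, 0), "rates")
})
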