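sim_table <- function(..., seed = 1) {
  simulate_metric_table(lmm_sim_params(..., seed = seed))
}

test_that("zero group variance collapses the mixed fit to OLS", {
  d <- sim_table(sigma_int = 0, sigma_slope_day = 0, sigma_res = 0.05,
                 n_groups = 8, days = 1:6, intervals = 1:5, seed = 11)
  ft <- fit_lmm(model_spec("y"), d)
  ols <- lm(y ~ interval + day, d)
  expect_lt(ft$G["(Intercept)", "(Intercept)"], 1e-4)
  expect_equal(unname(ft$beta_hat), unname(coef(ols)), tolerance = 1e-3)
})

test_that("balanced one-way variance components match ANOVA closed forms", {
  set.seed(21)
  g <- rep(1:4, each = 10)
  y <- 2 + rnorm(4, 0, 0.8)[g] + rnorm(40, 0, 0.5)
  d <- data.frame(group = g, y = y, interval = 0, day = 0)
  sp <- model_spec("y", fixed = character(0), estimation = "REML")
  # intercept-only model: REML estimates equal the moment estimators
  ft <- fit_lmm(sp, d)
  oracle <- oracle_oneway_anova(y, g)
  expect_equal(ft$sigma2_res, unname(oracle["sigma2_res"]), tolerance = 1e-5)
  expect_equal(ft$G["(Intercept)", "(Intercept)"],
               unname(oracle["sigma2_int"]), tolerance = 1e-5)
})

test_that("variance components are recovered from the generating model", {
  truth <- c(int = 0.05, slope = 0.01, res = 0.05)
  est <- t(sapply(1:10, function(s) {
    d <- sim_table(sigma_int = 0.05, sigma_slope_day = 0.01, rho = 0,
                   sigma_res = 0.05, n_groups = 12, days = 1:12,
                   intervals = 1:5, seed = 4000 + s)
    ft <- fit_lmm(model_spec("y", random_slopes = "day"), d)
    c(sqrt(ft$G["(Intercept)", "(Intercept)"]), sqrt(ft$G["day", "day"]),
      sqrt(ft$sigma2_res))
  }))
  relerr <- abs(sweep(est, 2, truth, "/") - 1)
  expect_lt(mean(relerr[, 1]), 0.5)
  expect_lt(mean(relerr[, 2]), 0.5)
  expect_lt(mean(relerr[, 3]), 0.05)
})

test_that("cAIC reduces to fixed-effects AIC as group variance vanishes", {
  d <- sim_table(sigma_int = 0, sigma_slope_day = 0, sigma_res = 0.05,
                 n_groups = 6, days = 1:8, intervals = 1:5, seed = 31)
  ft <- fit_lmm(model_spec("y"), d)
  ca <- caic(ft)
  aic_fixed <- AIC(lm(y ~ interval + day, d))
  expect_lt(abs(ca$value - aic_fixed), 0.1)
})

test_that("cAIC effective df equals the Henderson-equation hat-matrix trace", {
  d <- sim_table(sigma_int = 0.2, sigma_slope_day = 0, sigma_res = 0.1,
                 n_groups = 4, days = 1:3, intervals = 1:2, seed = 41)
  ft <- fit_lmm(model_spec("y"), d)
  ca <- caic(ft)
  # independent route: hat matrix from Henderson's mixed-model equations,
  # H = W (W'W + diag(0_p, sigma2 G^-1))^-1 W'
  m <- ft$fit
  X <- lme4::getME(m, "X")
  Z <- as.matrix(lme4::getME(m, "Z"))
  W <- cbind(X, Z)
  p <- ncol(X); q <- ncol(Z)
  Ginv <- diag(q) / ft$G["(Intercept)", "(Intercept)"]
  pen <- rbind(cbind(matrix(0, p, p), matrix(0, p, q)),
               cbind(matrix(0, q, p), ft$sigma2_res * Ginv))
  H <- W %*% solve(crossprod(W) + pen, t(W))
  expect_equal(ca$effective_df, sum(diag(H)) + 1, tolerance = 1e-6)
  # trace bounds: between the fixed-effect count and its random extension
  expect_gte(ca$effective_df, p + 1 - 1e-8)
  expect_lte(ca$effective_df, p + q + 1 + 1e-8)
})

test_that("AICc follows its formula and limits", {
  expect_equal(aicc(-100, 3, 50), 200 + 6 + 24 / 46)
  expect_equal(aicc(-100, 0, 50), 200)
  expect_equal(aicc(-50, 4, 1e9), -2 * -50 + 8, tolerance = 1e-6)
  expect_error(aicc(-10, 5, 6), "n > k")
})

test_that("ML log-likelihood is monotone over nested random structures", {
  d <- sim_table(sigma_int = 0.05, sigma_slope_day = 0.01,
                 n_groups = 12, days = 1:8, intervals = 1:5, seed = 51)
  ll0 <- fit_lmm(model_spec("y", random_intercept = FALSE), d)$loglik_marginal
  ll1 <- fit_lmm(model_spec("y"), d)$loglik_marginal
  ll2 <- fit_lmm(model_spec("y", random_slopes = "day"), d)$loglik_marginal
  expect_gte(ll1, ll0 - 1e-6)
  expect_gte(ll2, ll1 - 1e-6)
})

test_that("REML and ML variance estimates converge at large n", {
  d <- sim_table(sigma_int = 0.05, sigma_slope_day = 0.01,
                 n_groups = 50, days = 1:20, intervals = 1:5, seed = 61)
  sp_ml <- model_spec("y", random_slopes = "day", estimation = "ML")
  sp_reml <- model_spec("y", random_slopes = "day", estimation = "REML")
  v_ml <- sqrt(diag(fit_lmm(sp_ml, d)$G))
  v_reml <- sqrt(diag(fit_lmm(sp_reml, d)$G))
  expect_equal(unname(v_ml), unname(v_reml), tolerance = 0.02)
})

test_that("model comparison flags degenerate correlations and ranks the rest", {
  d <- sim_table(sigma_int = 0.05, sigma_slope_day = 0.01,
                 sigma_slope_interval = 0, n_groups = 12, days = 1:12,
                 intervals = 1:5, seed = 3)
  cand <- list(model_spec("y", random_intercept = FALSE),
               model_spec("y"),
               model_spec("y", random_slopes = "interval"),
               model_spec("y", random_slopes = "day"))
  tab <- compare_models(cand, d)
  expect_s3_class(tab, "model_comparison_table")
  expect_equal(tab$criterion, c("AICc", "cAIC", "cAIC", "cAIC"))
  # the true generating structure (day slope) wins here
  expect_equal(attr(tab, "best"), "group identity / day")
  # the interval-slope model overfits: estimated correlation at the boundary
  expect_false(tab$reliable[3])
  expect_true(is.na(tab$value[3]) && is.na(tab$rank[3]))
  # deltas of reliable rows are >= 0 with exactly one rank-1 row
  expect_true(all(tab$delta[tab$reliable] >= 0))
  expect_equal(sum(tab$rank == 1, na.rm = TRUE), 1L)
})

test_that("Satterthwaite p-values are calibrated under the null", {
  pvals <- sapply(1:150, function(s) {
    d <- sim_table(beta_day = 0, sigma_int = 0.05, sigma_slope_day = 0,
                   sigma_res = 0.05, n_groups = 12, days = 1:12,
                   intervals = 1:5, seed = 7000 + s)
    ft <- fit_lmm(model_spec("y"), d)
    fixed_effect_tests(ft)$p[2]
  })
  expect_gt(ks.test(pvals, "punif")$p.value, 0.01)
  # and powerful under a strong true slope
  p_alt <- sapply(1:40, function(s) {
    d <- sim_table(beta_day = -0.015, sigma_int = 0.05, sigma_slope_day = 0,
                   sigma_res = 0.05, n_groups = 12, days = 1:12,
                   intervals = 1:5, seed = 8000 + s)
    fixed_effect_tests(fit_lmm(model_spec("y"), d))$p[2]
  })
  expect_gte(mean(p_alt < 0.001), 0.95)
})

test_that("duplicated covariates are rejected as rank-deficient", {
  d <- sim_table(n_groups = 6, days = 1:6, intervals = 1:5, seed = 71)
  d$day2 <- d$day
  ft <- try(fit_lmm(model_spec("y", fixed = c("interval", "day", "day2")), d),
            silent = TRUE)
  # lmer drops the aliased column; the fit must not silently report it
  if (!inherits(ft, "try-error"))
    expect_false("day2" %in% names(ft$beta_hat))
})

test_that("between-group variance follows its quadratic closed form", {
  fake <- structure(list(
    spec = model_spec("y", random_slopes = "day"),
    G = matrix(c(1, 0, 0, 0.25), 2, 2,
               dimnames = list(c("(Intercept)", "day"), c("(Intercept)", "day")))),
    class = "model_fit")
  vt <- variance_at_covariate(fake, "day", c(0, 2, 4), nboot = 0)
  expect_equal(vt$variance, c(1, 2, 5))
  # monotone in |c| when the intercept-slope covariance is zero
  expect_true(all(diff(vt$variance) > 0))
  expect_error(variance_at_covariate(fake, "interval", 1, nboot = 0),
               "no random slope")
})

test_that("closed-form variance equals the re-centred refit", {
  d <- sim_table(sigma_int = 0.05, sigma_slope_day = 0.012, rho = 0.3,
                 n_groups = 12, days = 1:12, intervals = 1:5, seed = 81)
  ft <- fit_lmm(model_spec("y", random_slopes = "day"), d)
  for (cen in c(4, 10)) {
    vt <- variance_at_covariate(ft, "day", cen, nboot = 0)
    d2 <- d; d2$day <- d2$day - cen
    ft2 <- fit_lmm(model_spec("y", random_slopes = "day"), d2)
    expect_equal(vt$variance, ft2$G["(Intercept)", "(Intercept)"],
                 tolerance = 1e-4)
  }
})

test_that("bootstrap intervals cover the true between-group variance", {
  truth_var_at <- function(c_) 0.05^2 + c_^2 * 0.012^2
  hits <- sapply(1:100, function(s) {
    d <- sim_table(sigma_int = 0.05, sigma_slope_day = 0.012, rho = 0,
                   sigma_res = 0.05, n_groups = 12, days = 1:12,
                   intervals = 1:2, seed = 9000 + s)
    # REML point fits: ML variance bias would centre the bootstrap too low
    ft <- fit_lmm(model_spec("y", random_slopes = "day",
                             estimation = "REML"), d)
    vt <- variance_at_covariate(ft, "day", 4, nboot = 200, seed = s)
    vt$lower <= truth_var_at(4) && truth_var_at(4) <= vt$upper
  })
  expect_gte(mean(hits), 0.85)
})

test_that("reaction-norm predictions respect BLUP geometry", {
  d <- sim_table(sigma_int = 0.08, sigma_slope_day = 0, sigma_res = 0.05,
                 n_groups = 10, days = 1:10, intervals = 1:5, seed = 91)
  ft <- fit_lmm(model_spec("y"), d)
  rn <- predict_reaction_norms(ft, "day", at = c(1, 5, 10))
  wide <- matrix(rn$predicted, nrow = 10)   # groups x at-values
  # intercept-only random structure: all group lines are parallel
  offsets <- sweep(wide, 2, colMeans(wide))
  expect_lt(max(abs(offsets - offsets[, 1])), 1e-8)
  # balanced design: the mean of the group lines tracks the fixed-effect line
  pop <- ft$beta_hat["(Intercept)"] + ft$beta_hat["interval"] * mean(d$interval) +
    ft$beta_hat["day"] * c(1, 5, 10)
  expect_equal(unname(colMeans(wide)), unname(pop), tolerance = 1e-6)
  expect_error(predict_reaction_norms(ft, "weight"), "unknown covariate")
})
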