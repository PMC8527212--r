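#' Specify a reaction-norm mixed model
#'
#' Describes one candidate model for an interval-level metric: fixed effects
#' of within-trial interval and day (both treated as continuous), optionally
#' a random intercept for group identity (collective personality) and random
#' slopes of interval and/or day (collective plasticity).
#'
#' @param response name of the response column in the metric table.
#' @param transform `"none"` or `"sqrt"` (convex hull area is square-root
#'   transformed to meet parametric assumptions).
#' @param family `"gaussian"` or `"beta"` (leadership switch rate, a
#'   proportion-like rate in (0,1), uses a beta family with logit link).
#' @param fixed character vector of fixed-effect covariates
#'   (default `c("interval", "day")`).
#' @param random_intercept include a group-identity random intercept?
#' @param random_slopes character subset of `fixed` given group-specific
#'   random slopes; requires `random_intercept = TRUE`.
#' @param estimation `"ML"` or `"REML"`. Model comparison requires ML;
#'   REML is conventional for reporting a single Gaussian fit.
#' @return A list of class `model_spec`.
#' @export
model_spec <- function(response, transform = c("none", "sqrt"),
                       family = c("gaussian", "beta"),
                       fixed = c("interval", "day"),
                       random_intercept = TRUE, random_slopes = character(),
                       estimation = c("ML", "REML")) {
  transform <- match.arg(transform)
  family <- match.arg(family)
  estimation <- match.arg(estimation)
  if (length(random_slopes) && !random_intercept)
    stop("random slopes require a random intercept")
  if (length(setdiff(random_slopes, fixed)))
    stop("random slopes must be a subset of the fixed covariates")
  structure(list(response = response, transform = transform, family = family,
                 fixed = fixed, random_intercept = random_intercept,
                 random_slopes = random_slopes, estimation = estimation),
            class = "model_spec")
}

spec_label <- function(spec) {
  ri <- if (spec$random_intercept) "group identity" else "none"
  rs <- if (length(spec$random_slopes)) paste(spec$random_slopes, collapse = "+")
        else "none"
  paste0(ri, " / ", rs)
}

spec_formula <- function(spec) {
  rhs <- if (length(spec$fixed)) paste(spec$fixed, collapse = " + ") else "1"
  if (spec$random_intercept) {
    re <- if (length(spec$random_slopes))
      paste("1 +", paste(spec$random_slopes, collapse = " + "))
    else "1"
    rhs <- paste0(rhs, " + (", re, " | group)")
  }
  stats::as.formula(paste(".response ~", rhs))
}

prepare_model_frame <- function(spec, data) {
  need <- c(spec$fixed, "group", spec$response)
  missing_cols <- setdiff(need, names(data))
  if (length(missing_cols))
    stop("metric table is missing columns: ", paste(missing_cols, collapse = ", "))
  d <- data[stats::complete.cases(data[c(spec$response, spec$fixed)]), , drop = FALSE]
  y <- d[[spec$response]]
  if (spec$transform == "sqrt") {
    if (any(y < 0)) stop("sqrt transform requires a non-negative response")
    y <- sqrt(y)
  }
  d$.response <- y
  d$group <- factor(d$group)
  d
}

#' Fit a Gaussian reaction-norm mixed model
#'
#' Fits `y = Xb + Zu + e` with group random effects by (restricted) maximum
#' likelihood, and derives the quantities the model-selection layer needs:
#' marginal and conditional log-likelihoods, the random-effect covariance,
#' boundary and degenerate-correlation diagnostics. Specifications without a
#' random intercept are fitted by ordinary least squares.
#'
#' @param spec a [model_spec()] with `family = "gaussian"`.
#' @param data metric table with columns `group`, the fixed covariates and
#'   the response.
#' @return An object of class `model_fit`: list with `spec`, `fit` (the
#'   underlying `lmerMod`/`lm`), `beta_hat`, `G` (random-effect covariance
#'   matrix, `NULL` for fixed-effects fits), `sigma2_res`,
#'   `loglik_marginal`, `loglik_conditional`, `n_obs`, `n_groups`,
#'   `converged`, `boundary_flags`, `corr_degenerate`.
#' @export
fit_lmm <- function(spec, data) {
  stopifnot(inherits(spec, "model_spec"))
  if (spec$family != "gaussian")
    stop("`fit_lmm` fits Gaussian models; use `fit_beta_glmm` for the beta family")
  d <- prepare_model_frame(spec, data)
  if (nlevels(d$group) < 2L && spec$random_intercept)
    stop("need at least 2 groups to estimate between-group variance")
  f <- spec_formula(spec)
  if (!spec$random_intercept) {
    fit <- stats::lm(f, data = d)
    ll <- as.numeric(stats::logLik(fit))
    return(structure(list(
      spec = spec, fit = fit, data = d,
      beta_hat = stats::coef(fit), G = NULL,
      sigma2_res = sum(stats::residuals(fit)^2) / stats::nobs(fit),
      loglik_marginal = ll, loglik_conditional = ll,
      n_obs = stats::nobs(fit), n_groups = nlevels(d$group),
      converged = TRUE, boundary_flags = logical(), corr_degenerate = FALSE),
      class = "model_fit"))
  }
  fit <- suppressMessages(suppressWarnings(
    lmerTest::lmer(f, data = d, REML = spec$estimation == "REML",
                   control = lme4::lmerControl(calc.derivs = FALSE))))
  vc <- lme4::VarCorr(fit)$group
  G <- matrix(as.numeric(vc), nrow(vc), ncol(vc), dimnames = dimnames(vc))
  sigma2 <- stats::sigma(fit)^2
  y <- d$.response
  cll <- sum(stats::dnorm(y, stats::fitted(fit), sqrt(sigma2), log = TRUE))
  corr <- attr(vc, "correlation")
  off <- corr[upper.tri(corr)]
  # a correlation at the boundary, or unestimable because a variance
  # collapsed, marks an overfitted random structure
  corr_degenerate <- length(off) > 0 && any(!is.finite(off) | abs(off) > 0.999)
  opt_msgs <- fit@optinfo$conv$lme4$messages
  boundary <- diag(G) < 1e-8 * max(diag(G), sigma2, 1e-12)
  structure(list(
    spec = spec, fit = fit, data = d,
    beta_hat = lme4::fixef(fit), G = G, sigma2_res = sigma2,
    loglik_marginal = as.numeric(stats::logLik(fit)),
    loglik_conditional = cll,
    n_obs = stats::nobs(fit), n_groups = nlevels(d$group),
    converged = fit@optinfo$conv$opt == 0 && is.null(opt_msgs),
    boundary_flags = boundary, corr_degenerate = corr_degenerate),
    class = "model_fit")
}

#' @export
print.model_fit <- function(x, ...) {
  cat(sprintf("<model_fit> %s on '%s'%s, family %s, %s\n",
              spec_label(x$spec), x$spec$response,
              if (x$spec$transform == "sqrt") " (sqrt)" else "",
              x$spec$family, x$spec$estimation))
  cat(sprintf("  n = %d obs, %d groups; marginal logLik = %.3f\n",
              x$n_obs, x$n_groups, x$loglik_marginal))
  if (!is.null(x$G)) {
    cat("  random-effect SDs:",
        paste(sprintf("%s %.4g", rownames(x$G), sqrt(diag(x$G))), collapse = ", "),
        "\n")
  }
  if (x$corr_degenerate)
    cat("  WARNING: degenerate random-effect correlation (overfitting)\n")
  invisible(x)
}

#' Conditional AIC of a Gaussian mixed model
#'
#' Conditional AIC evaluates a mixed model on its conditional (given the
#' predicted random effects) likelihood and charges it the effective degrees
#' of freedom `rho` of the shrinkage estimator: the trace of the hat matrix
#' mapping the observations to the fitted values at the estimated variance
#' parameters, plus one for the residual variance
#' (Vaida & Blanchard 2005 form). As the between-group variance shrinks to
#' zero, `rho` falls to the fixed-effect count and cAIC approaches the AIC of
#' the fixed-effects model.
#'
#' @param fit a `model_fit` from [fit_lmm()] with random effects.
#' @return A list with `value` (the cAIC) and `effective_df`
#'   (`rho + 1`, reported like a comparison table's d.f. column).
#' @export
caic <- function(fit) {
  stopifnot(inherits(fit, "model_fit"))
  if (is.null(fit$G))
    stop("cAIC is defined for mixed models; use `aicc` for fixed-effects models")
  if (is.null(fit$loglik_conditional))
    stop("conditional log-likelihood unavailable")
  m <- fit$fit
  n <- fit$n_obs
  Z <- as.matrix(lme4::getME(m, "Z"))
  L <- as.matrix(lme4::getME(m, "Lambda"))
  X <- lme4::getME(m, "X")
  sigma2 <- fit$sigma2_res
  # V = sigma2 (I + M M') with M = Z Lambda; Woodbury keeps everything at
  # the random-effect dimension q << n
  M <- Z %*% L
  A <- diag(ncol(M)) + crossprod(M)
  MtX <- crossprod(M, X)
  tr_vi <- (n - sum(diag(solve(A, crossprod(M))))) / sigma2
  ViX <- (X - M %*% solve(A, MtX)) / sigma2
  XtViX <- crossprod(X, ViX)
  tr_vip <- sum(diag(solve(XtViX, crossprod(ViX))))
  rho <- n - sigma2 * (tr_vi - tr_vip)
  list(value = -2 * fit$loglik_conditional + 2 * (rho + 1),
       effective_df = rho + 1)
}

#' Small-sample corrected AIC
#'
#' @param loglik maximized log-likelihood.
#' @param k number of estimated parameters (including any variance/precision
#'   parameters).
#' @param n number of observations; must exceed `k + 1`.
#' @return `-2 loglik + 2k + 2k(k+1)/(n-k-1)`.
#' @export
aicc <- function(loglik, k, n) {
  if (n <= k + 1) stop("AICc requires n > k + 1")
  -2 * loglik + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

n_params <- function(fit) {
  p <- length(fit$beta_hat)
  if (inherits(fit$fit, "lm")) return(p + 1L)              # + residual variance
  if (fit$spec$family == "beta")
    return(p + 1L + as.integer(fit$spec$random_intercept)) # + phi (+ sigma)
  q <- nrow(fit$G)
  p + q * (q + 1) / 2 + 1L                                  # + G + residual
}

#' Compare candidate random-effect structures
#'
#' Fits every candidate by maximum likelihood and builds a comparison table:
#' mixed Gaussian models are scored by conditional AIC, models without random
#' effects (and all beta-family models, for which cAIC is unavailable) by
#' AICc. Fits with an estimated random-effect correlation at the +/-1
#' boundary are overfitted, their criterion unreliable: they are flagged
#' `reliable = FALSE`, reported without a criterion value and excluded from
#' ranking. Support for a structure is declared when a competitor sits more
#' than `delta_support` criterion units above the best model.
#'
#' @param candidates list of [model_spec()]; must share response, transform
#'   and fixed effects.
#' @param data metric table.
#' @param delta_support support threshold on the criterion difference
#'   (default 2).
#' @return A data.frame of class `model_comparison_table` with one row per
#'   candidate: `label`, `random_intercept`, `random_slope`, `criterion`,
#'   `value`, `effective_df`, `delta`, `rank`, `reliable`, plus attributes
#'   `fits` (the fitted models) and `best` (label of the rank-1 model).
#' @export
compare_models <- function(candidates, data, delta_support = 2) {
  stopifnot(length(candidates) >= 2L)
  base <- candidates[[1L]]
  for (sp in candidates)
    if (!identical(sp$response, base$response) ||
        !identical(sp$transform, base$transform) ||
        !identical(sp$fixed, base$fixed))
      stop("all candidates must share response, transform and fixed effects")
  fits <- lapply(candidates, function(sp) {
    sp$estimation <- "ML"
    if (sp$family == "beta") fit_beta_glmm(sp, data) else fit_lmm(sp, data)
  })
  rows <- lapply(fits, function(ft) {
    sp <- ft$spec
    if (sp$family == "beta" || !sp$random_intercept) {
      crit <- "AICc"; k <- n_params(ft)
      val <- aicc(ft$loglik_marginal, k, ft$n_obs); edf <- k
    } else {
      crit <- "cAIC"
      ca <- caic(ft); val <- ca$value; edf <- ca$effective_df
    }
    data.frame(label = spec_label(sp),
               random_intercept = sp$random_intercept,
               random_slope = if (length(sp$random_slopes))
                 paste(sp$random_slopes, collapse = "+") else "none",
               criterion = crit, value = val, effective_df = edf,
               reliable = !ft$corr_degenerate, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  tab$value[!tab$reliable] <- NA_real_
  tab$effective_df[!tab$reliable] <- NA_real_
  if (!any(tab$reliable)) stop("all candidate models are unreliable (overfitted)")
  best <- min(tab$value[tab$reliable])
  tab$delta <- tab$value - best
  tab$rank <- NA_integer_
  tab$rank[tab$reliable] <- rank(tab$value[tab$reliable], ties.method = "first")
  attr(tab, "fits") <- fits
  attr(tab, "best") <- tab$label[which(tab$reliable & tab$rank == 1L)]
  attr(tab, "support_threshold") <- delta_support
  class(tab) <- c("model_comparison_table", "data.frame")
  tab
}

#' Tests of the fixed time effects
#'
#' Gaussian mixed models: F-tests with Satterthwaite-approximated denominator
#' degrees of freedom. Fixed-effects (lm) fits: standard F-tests. Beta
#' models: likelihood-ratio chi-square tests against the model dropping the
#' covariate.
#'
#' @param fit a `model_fit`.
#' @return A data.frame with one row per fixed covariate: `covariate`,
#'   `statistic`, `df`, `ddf` (denominator df; `NA` for LRT), `p`.
#' @export
fixed_effect_tests <- function(fit) {
  stopifnot(inherits(fit, "model_fit"))
  sp <- fit$spec
  if (sp$family == "beta") {
    rows <- lapply(sp$fixed, function(cv) {
      sub <- sp; sub$fixed <- setdiff(sp$fixed, cv)
      sub$random_slopes <- intersect(sp$random_slopes, sub$fixed)
      if (!length(sub$random_slopes)) sub$random_slopes <- character()
      f0 <- fit_beta_glmm(sub, fit$data)
      lr <- 2 * (fit$loglik_marginal - f0$loglik_marginal)
      data.frame(covariate = cv, statistic = lr, df = 1, ddf = NA_real_,
                 p = stats::pchisq(lr, 1, lower.tail = FALSE))
    })
    return(do.call(rbind, rows))
  }
  if (inherits(fit$fit, "lm")) {
    a <- stats::drop1(fit$fit, test = "F")
    idx <- match(sp$fixed, rownames(a))
    return(data.frame(covariate = sp$fixed, statistic = a$`F value`[idx],
                      df = a$Df[idx], ddf = stats::df.residual(fit$fit),
                      p = a$`Pr(>F)`[idx]))
  }
  a <- suppressMessages(stats::anova(fit$fit, ddf = "Satterthwaite"))
  idx <- match(sp$fixed, rownames(a))
  data.frame(covariate = sp$fixed, statistic = a$`F value`[idx],
             df = a$NumDF[idx], ddf = a$DenDF[idx], p = a$`Pr(>F)`[idx])
}

# Intercept/slope covariance entries for one covariate's random slope.
slope_vc <- function(fit, covariate) {
  G <- fit$G
  if (is.null(G) || !covariate %in% rownames(G))
    stop("fit has no random slope on '", covariate, "'")
  list(v_int = G["(Intercept)", "(Intercept)"],
       v_slope = G[covariate, covariate],
       c_is = G["(Intercept)", covariate])
}

#' Between-group variance along a covariate
#'
#' With a random slope, the between-group variance is not a single number:
#' re-centring the covariate at `c` moves it to
#' `Var(a_g + s_g c) = s2_int + 2 c Cov(a, s) + c^2 s2_slope`, the variance
#' the random intercept would take if the model were refitted with the
#' covariate centred at `c`. Evaluating it along the covariate shows whether
#' group differences grow or shrink over time. Confidence intervals come from
#' a parametric bootstrap: responses are simulated from the fitted model,
#' the model is refitted and the variance recomputed.
#'
#' @param fit a `model_fit` with a random slope on `covariate`.
#' @param covariate covariate name (e.g. `"day"`).
#' @param centers numeric vector of covariate values at which to evaluate.
#' @param nboot number of parametric-bootstrap replicates (default 1000; 0
#'   skips the CIs).
#' @param level confidence level (default 0.95).
#' @param seed integer seed for the bootstrap.
#' @return A data.frame with `center`, `variance`, `lower`, `upper`,
#'   and attribute `nboot`.
#' @export
variance_at_covariate <- function(fit, covariate, centers, nboot = 1000,
                                  level = 0.95, seed = 1L) {
  stopifnot(inherits(fit, "model_fit"))
  vc <- slope_vc(fit, covariate)
  var_at <- function(v, cen) v$v_int + 2 * cen * v$c_is + cen^2 * v$v_slope
  est <- var_at(vc, centers)
  lower <- upper <- rep(NA_real_, length(centers))
  if (nboot > 0) {
    set.seed(seed)
    sims <- stats::simulate(fit$fit, nsim = nboot)
    boot <- matrix(NA_real_, nboot, length(centers))
    for (b in seq_len(nboot)) {
      rf <- tryCatch(
        suppressMessages(suppressWarnings(lme4::refit(fit$fit, sims[[b]]))),
        error = function(e) NULL)
      if (is.null(rf)) next
      vcb <- lme4::VarCorr(rf)$group
      if (!covariate %in% rownames(vcb)) next
      vb <- list(v_int = vcb["(Intercept)", "(Intercept)"],
                 v_slope = vcb[covariate, covariate],
                 c_is = vcb["(Intercept)", covariate])
      boot[b, ] <- var_at(vb, centers)
    }
    alpha <- (1 - level) / 2
    qs <- apply(boot, 2L, stats::quantile, probs = c(alpha, 1 - alpha),
                na.rm = TRUE)
    lower <- qs[1L, ]; upper <- qs[2L, ]
  }
  out <- data.frame(center = centers, variance = est,
                    lower = lower, upper = upper)
  attr(out, "nboot") <- nboot
  out
}

#' Per-group predicted reaction norms
#'
#' Conditional predictions (fixed effects plus the group's predicted random
#' effects, i.e. BLUPs) along one covariate, with the other covariates held
#' at supplied values (conventionally their mean). With an intercept-only
#' random structure the group lines are parallel; random slopes let them fan
#' out or converge.
#'
#' @param fit a converged `model_fit` with group random effects.
#' @param covariate covariate to sweep.
#' @param held named list/vector of values for the remaining fixed
#'   covariates; defaults to their means in the training data.
#' @param at values of `covariate` at which to predict; defaults to the
#'   sorted unique values observed.
#' @return A data.frame with `group`, `covariate` value and `predicted`
#'   (response on the model scale, i.e. after any transform).
#' @export
predict_reaction_norms <- function(fit, covariate, held = NULL, at = NULL) {
  stopifnot(inherits(fit, "model_fit"))
  if (is.null(fit$G)) stop("fit has no group random effects")
  if (!covariate %in% fit$spec$fixed) stop("unknown covariate '", covariate, "'")
  d <- fit$data
  if (is.null(at)) at <- sort(unique(d[[covariate]]))
  others <- setdiff(fit$spec$fixed, covariate)
  grid <- expand.grid(group = levels(d$group), .v = at)
  names(grid)[2L] <- covariate
  for (o in others)
    grid[[o]] <- if (!is.null(held) && o %in% names(held)) held[[o]]
                 else mean(d[[o]])
  grid$predicted <- stats::predict(fit$fit, newdata = grid)
  grid[c("group", covariate, "predicted")]
}
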