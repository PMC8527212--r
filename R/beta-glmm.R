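#' Gauss-Hermite nodes and weights
#'
#' Nodes and weights for n-point Gauss-Hermite quadrature with weight
#' function `exp(-x^2)`, computed by the Golub-Welsch eigenvalue method on
#' the Jacobi matrix of the Hermite recurrence.
#'
#' @param n number of nodes.
#' @return List with `nodes` (ascending) and `weights`.
#' @keywords internal
gauss_hermite <- function(n) {
  if (n == 1L) return(list(nodes = 0, weights = sqrt(pi)))
  J <- matrix(0, n, n)
  off <- sqrt(seq_len(n - 1L) / 2)
  J[cbind(seq_len(n - 1L), seq_len(n - 1L) + 1L)] <- off
  J[cbind(seq_len(n - 1L) + 1L, seq_len(n - 1L))] <- off
  e <- eigen(J, symmetric = TRUE)
  ord <- order(e$values)
  list(nodes = e$values[ord], weights = sqrt(pi) * e$vectors[1L, ord]^2)
}

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# log Beta(y; mu, phi) under the mean/precision parameterization:
# shape1 = mu*phi, shape2 = (1-mu)*phi.
dbeta_mu_phi <- function(y, mu, phi) {
  stats::dbeta(y, mu * phi, (1 - mu) * phi, log = TRUE)
}

#' Beta-family mixed model by adaptive Gauss-Hermite quadrature
#'
#' Fits a beta regression with logit link and, optionally, a group-identity
#' random intercept: `y | b ~ Beta(mu * phi, (1 - mu) * phi)` with
#' `logit(mu) = X beta + b_g`, `b_g ~ N(0, sigma^2)`. Suitable for
#' rate-like responses strictly inside (0, 1), such as the leadership switch
#' rate. The marginal likelihood integrates the random intercept out by
#' adaptive Gauss-Hermite quadrature: each group's integrand is re-centred at
#' its posterior mode and re-scaled by its curvature before applying the
#' quadrature rule, so modest node counts suffice. All estimation is by
#' maximum likelihood.
#'
#' @param spec a [model_spec()] with `family = "beta"`; random slopes are not
#'   supported for this family (a single 1-D random intercept is
#'   integrated).
#' @param data metric table; the response must be strictly in (0, 1).
#' @param n_quad number of quadrature nodes (default 15).
#' @return A `model_fit` with `phi` (precision), `G` a 1x1 matrix holding
#'   `sigma^2` (or `NULL` without a random intercept) and `blups` (posterior
#'   modes of the group effects).
#' @export
fit_beta_glmm <- function(spec, data, n_quad = 15L) {
  stopifnot(inherits(spec, "model_spec"))
  if (spec$family != "beta") stop("`fit_beta_glmm` requires a beta-family spec")
  if (length(spec$random_slopes))
    stop("random slopes are not supported for the beta family")
  d <- prepare_model_frame(spec, data)
  y <- d$.response
  bad <- which(y <= 0 | y >= 1)
  if (length(bad))
    stop("beta-family response must be strictly in (0, 1); offending rows: ",
         paste(utils::head(bad, 10L), collapse = ", "))
  rhs <- if (length(spec$fixed)) paste(spec$fixed, collapse = " + ") else "1"
  X <- stats::model.matrix(stats::as.formula(paste("~", rhs)), d)
  p <- ncol(X)
  grp <- as.integer(d$group)
  n_g <- max(grp)
  gh <- gauss_hermite(n_quad)
  lw <- log(gh$weights) + gh$nodes^2

  group_rows <- split(seq_along(y), grp)

  # log joint density of one group's data and random effect b
  h_fun <- function(rows, eta_fix, b, phi, sigma) {
    mu <- stats::plogis(eta_fix[rows] + b)
    sum(dbeta_mu_phi(y[rows], mu, phi)) +
      stats::dnorm(b, 0, sigma, log = TRUE)
  }

  # AGQ marginal log-likelihood and posterior modes at given parameters
  marginal <- function(par, return_modes = FALSE) {
    beta <- par[seq_len(p)]
    phi <- exp(par[p + 1L])
    eta_fix <- drop(X %*% beta)
    if (!spec$random_intercept) {
      mu <- stats::plogis(eta_fix)
      ll <- sum(dbeta_mu_phi(y, mu, phi))
      return(if (return_modes) list(ll = ll, modes = NULL) else ll)
    }
    sigma <- exp(par[p + 2L])
    modes <- numeric(n_g)
    ll <- 0
    for (g in seq_len(n_g)) {
      rows <- group_rows[[g]]
      opt <- stats::optimize(function(b) h_fun(rows, eta_fix, b, phi, sigma),
                             interval = c(-30, 30), maximum = TRUE,
                             tol = 1e-9)
      b_hat <- opt$maximum
      step <- 1e-4 * (1 + abs(b_hat))
      hpp <- (h_fun(rows, eta_fix, b_hat + step, phi, sigma) -
              2 * opt$objective +
              h_fun(rows, eta_fix, b_hat - step, phi, sigma)) / step^2
      sd_h <- if (is.finite(hpp) && hpp < 0) 1 / sqrt(-hpp) else sigma
      hv <- vapply(gh$nodes, function(x)
        h_fun(rows, eta_fix, b_hat + sqrt(2) * sd_h * x, phi, sigma),
        numeric(1))
      ll <- ll + log(sqrt(2) * sd_h) + logsumexp(lw + hv)
      modes[g] <- b_hat
    }
    if (return_modes) list(ll = ll, modes = modes) else ll
  }

  # starting values: OLS on the empirical logit; precision by moments
  ylogit <- stats::qlogis(y)
  b0 <- stats::coef(stats::lm.fit(X, ylogit))
  mu0 <- stats::plogis(drop(X %*% b0))
  phi0 <- max(mean(mu0 * (1 - mu0)) / max(stats::var(y - mu0 + mean(mu0)), 1e-8) - 1, 2)
  par0 <- c(b0, log(phi0))
  if (spec$random_intercept) {
    gm <- tapply(ylogit - drop(X %*% b0), grp, mean)
    par0 <- c(par0, log(max(stats::sd(gm), 1e-3)))
  }
  # dbeta warns (and returns -Inf/NaN) on parameter excursions the line
  # search immediately rejects; those are expected, not diagnostics
  opt <- suppressWarnings(
    stats::optim(par0, function(par) {
      val <- -marginal(par)
      if (is.finite(val)) val else 1e10
    }, method = "BFGS", control = list(maxit = 500, reltol = 1e-12)))
  res <- marginal(opt$par, return_modes = TRUE)
  beta_hat <- opt$par[seq_len(p)]
  names(beta_hat) <- colnames(X)
  phi_hat <- exp(opt$par[p + 1L])
  sigma2 <- if (spec$random_intercept) exp(opt$par[p + 2L])^2 else NULL
  cll <- if (spec$random_intercept) {
    eta <- drop(X %*% beta_hat) + res$modes[grp]
    sum(dbeta_mu_phi(y, stats::plogis(eta), phi_hat))
  } else res$ll
  G <- if (spec$random_intercept)
    matrix(sigma2, 1, 1, dimnames = list("(Intercept)", "(Intercept)"))
  else NULL
  structure(list(
    spec = spec, fit = NULL, data = d,
    beta_hat = beta_hat, G = G, sigma2_res = NA_real_, phi = phi_hat,
    loglik_marginal = res$ll, loglik_conditional = cll,
    blups = res$modes, n_quad = n_quad,
    n_obs = length(y), n_groups = n_g,
    converged = opt$convergence == 0,
    boundary_flags = if (is.null(sigma2)) logical() else sigma2 < 1e-8,
    corr_degenerate = FALSE),
    class = "model_fit")
}

#' Marginal log-likelihood of a fitted beta GLMM at a different node count
#'
#' Re-evaluates the adaptive-quadrature marginal log-likelihood of a fitted
#' beta mixed model at its estimates with `n_quad` nodes; used to check that
#' the quadrature has converged in the node count.
#'
#' @param fit a `model_fit` from [fit_beta_glmm()].
#' @param n_quad node count for the re-evaluation.
#' @return The marginal log-likelihood.
#' @export
beta_glmm_loglik <- function(fit, n_quad) {
  stopifnot(inherits(fit, "model_fit"), fit$spec$family == "beta")
  sp <- fit$spec
  par <- c(fit$beta_hat, log(fit$phi))
  if (sp$random_intercept) par <- c(par, log(sqrt(fit$G[1, 1])))
  refit <- fit_beta_glmm_loglik_only(sp, fit$data, par, n_quad)
  refit
}

# internal: evaluate the AGQ log-likelihood at fixed parameters
fit_beta_glmm_loglik_only <- function(spec, d, par, n_quad) {
  y <- d$.response
  rhs <- if (length(spec$fixed)) paste(spec$fixed, collapse = " + ") else "1"
  X <- stats::model.matrix(stats::as.formula(paste("~", rhs)), d)
  p <- ncol(X)
  grp <- as.integer(d$group)
  gh <- gauss_hermite(n_quad)
  lw <- log(gh$weights) + gh$nodes^2
  beta <- par[seq_len(p)]
  phi <- exp(par[p + 1L])
  eta_fix <- drop(X %*% beta)
  if (!spec$random_intercept)
    return(sum(dbeta_mu_phi(y, stats::plogis(eta_fix), phi)))
  sigma <- exp(par[p + 2L])
  ll <- 0
  for (rows in split(seq_along(y), grp)) {
    h <- function(b) sum(dbeta_mu_phi(y[rows], stats::plogis(eta_fix[rows] + b), phi)) +
      stats::dnorm(b, 0, sigma, log = TRUE)
    opt <- stats::optimize(h, c(-30, 30), maximum = TRUE, tol = 1e-9)
    b_hat <- opt$maximum
    step <- 1e-4 * (1 + abs(b_hat))
    hpp <- (h(b_hat + step) - 2 * opt$objective + h(b_hat - step)) / step^2
    sd_h <- if (is.finite(hpp) && hpp < 0) 1 / sqrt(-hpp) else sigma
    hv <- vapply(gh$nodes, function(x) h(b_hat + sqrt(2) * sd_h * x), numeric(1))
    ll <- ll + log(sqrt(2) * sd_h) + logsumexp(lw + hv)
  }
  ll
}
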