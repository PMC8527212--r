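# Independent brute-force oracles. These deliberately share no code with the
# package: hull by gift wrapping, correlations by explicit sums, switch and
# transition counts by literal per-frame loops.

# Convex hull area: Jarvis gift-wrapping march + shoelace on the resulting
# polygon. O(n * h), no shortcuts.
oracle_hull_area <- function(pts) {
  pts <- unique(pts[stats::complete.cases(pts), , drop = FALSE])
  n <- nrow(pts)
  if (n < 3L) return(0)
  cross3 <- function(o, a, b)
    (a[1] - o[1]) * (b[2] - o[2]) - (a[2] - o[2]) * (b[1] - o[1])
  start <- which.min(pts[, 1] + 1e-12 * pts[, 2])
  hull <- integer()
  p <- start
  repeat {
    hull <- c(hull, p)
    q <- if (p == 1L) 2L else 1L
    for (r in seq_len(n)) {
      if (r == p || r == q) next
      cr <- cross3(pts[p, ], pts[q, ], pts[r, ])
      if (cr < 0 ||
          (cr == 0 && sum((pts[r, ] - pts[p, ])^2) > sum((pts[q, ] - pts[p, ])^2)))
        q <- r
    }
    p <- q
    if (p == start) break
  }
  if (length(hull) < 3L) return(0)
  x <- pts[hull, 1]; y <- pts[hull, 2]
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}

# Max Pearson cross-correlation over lags, by explicit sums per lag.
oracle_max_xcorr <- function(v, w, max_lag) {
  n <- length(v)
  best <- -Inf
  for (L in -max_lag:max_lag) {
    a <- c(); b <- c()
    for (t in seq_len(n)) {
      if (t + L >= 1 && t + L <= n) { a <- c(a, v[t]); b <- c(b, w[t + L]) }
    }
    m <- length(a)
    if (m < 3L) next
    ma <- sum(a) / m; mb <- sum(b) / m
    sa <- sqrt(sum((a - ma)^2) / (m - 1)); sb <- sqrt(sum((b - mb)^2) / (m - 1))
    if (sa == 0 || sb == 0) next
    r <- sum((a - ma) * (b - mb)) / ((m - 1) * sa * sb)
    if (r > best) best <- r
  }
  if (is.infinite(best)) NA_real_ else best
}

# Transition count and rate by a literal loop over valid frames.
oracle_transition <- function(P, thr) {
  ok <- which(is.finite(P))
  if (length(ok) < 2L) return(NA_real_)
  count <- 0L
  prev <- P[ok[1]] > thr
  for (j in ok[-1]) {
    cur <- P[j] > thr
    if (cur != prev) count <- count + 1L
    prev <- cur
  }
  count / length(ok)
}

# Leadership switch rate by per-frame recount: polarization by direct formula
# over defined headings, direction from centroid displacement, ranks by
# sorting projections.
oracle_leadership <- function(block, thr = 0.65, min_speed = 1e-6) {
  Tn <- block$n_frames; N <- block$n_individuals
  cen <- apply(block$positions, c(1, 3), mean)
  lead <- matrix(NA, Tn, N)
  for (t in seq_len(Tn)) {
    if (!block$frame_valid[t]) next
    hx <- hy <- c()
    for (i in seq_len(N)) {
      sp <- sqrt(block$velocities[t, i, 1]^2 + block$velocities[t, i, 2]^2)
      if (is.finite(sp) && sp >= min_speed) {
        hx <- c(hx, block$velocities[t, i, 1] / sp)
        hy <- c(hy, block$velocities[t, i, 2] / sp)
      }
    }
    if (length(hx) < 2L) next
    P <- sqrt(mean(hx)^2 + mean(hy)^2)
    if (P <= thr) next
    if (t < Tn && block$frame_valid[t + 1]) dir <- cen[t + 1, ] - cen[t, ]
    else if (t > 1 && block$frame_valid[t - 1]) dir <- cen[t, ] - cen[t - 1, ]
    else next
    nd <- sqrt(sum(dir^2))
    if (nd == 0) next
    proj <- numeric(N)
    for (i in seq_len(N))
      proj[i] <- sum((block$positions[t, i, ] - cen[t, ]) * dir) / nd
    lead[t, ] <- seq_len(N) == which.max(proj)
  }
  pairs <- 0L
  switches <- integer(N)
  for (t in seq_len(Tn - 1)) {
    if (anyNA(lead[t, ]) || anyNA(lead[t + 1, ])) next
    pairs <- pairs + 1L
    for (i in seq_len(N))
      if (lead[t, i] != lead[t + 1, i]) switches[i] <- switches[i] + 1L
  }
  if (pairs == 0L) return(NA_real_)
  mean(switches / pairs)
}

# Closed-form REML variance components for a balanced one-way layout.
oracle_oneway_anova <- function(y, group) {
  g <- length(unique(group))
  n <- length(y) / g
  gm <- tapply(y, group, mean)
  msw <- sum((y - gm[group])^2) / (length(y) - g)
  msb <- n * sum((gm - mean(y))^2) / (g - 1)
  c(sigma2_res = msw, sigma2_int = max(0, (msb - msw) / n))
}

# Direct fixed-effects beta-regression MLE (logit link), no shared code with
# the package's quadrature path.
oracle_beta_mle <- function(y, X) {
  nll <- function(par) {
    p <- ncol(X)
    mu <- 1 / (1 + exp(-drop(X %*% par[1:p])))
    phi <- exp(par[p + 1])
    -sum(lgamma(phi) - lgamma(mu * phi) - lgamma((1 - mu) * phi) +
           (mu * phi - 1) * log(y) + ((1 - mu) * phi - 1) * log(1 - y))
  }
  start <- c(stats::coef(stats::lm.fit(X, stats::qlogis(y))), log(10))
  opt <- stats::optim(start, nll, method = "BFGS",
                      control = list(maxit = 1000, reltol = 1e-14))
  list(beta = opt$par[seq_len(ncol(X))], phi = exp(opt$par[ncol(X) + 1]),
       loglik = -opt$value)
}
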