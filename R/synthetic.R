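#' Configuration for the zonal schooling simulator
#'
#' An agent-based model of a small fish shoal in an elliptical arena, used to
#' generate trajectory data with known group structure. Each agent carries a
#' heading and constant-magnitude step; every frame it reacts to neighbours
#' in three concentric zones — repulsion (collision avoidance, overriding),
#' alignment (copy neighbours' headings) and attraction (move towards distant
#' neighbours) — with the social (alignment + attraction) response weighted
#' by an effective sociability
#' `w_g(day, interval) = w0 + a_g + (day_slope + b_g)(day - 1) +
#' interval_slope (interval - 1)`,
#' where `a_g` and `b_g` are group-specific intercepts and day slopes. This
#' gives groups both a baseline collective personality and group-specific
#' temporal plasticity, the structure the reaction-norm models are designed
#' to detect. Preferred speed declines over days via `speed_day_slope`.
#'
#' @param n_groups number of groups (default 12).
#' @param n_fish individuals per group (default 8).
#' @param fps frames per second (default 25).
#' @param arena_a,arena_b ellipse half-axes in mm (default 667.5 x 360,
#'   a 133.5 x 72 cm oval arena).
#' @param r_repulsion,r_align,r_attract zone radii in mm, strictly ordered.
#' @param speed preferred displacement per frame in mm (default 4, i.e.
#'   100 mm/s at 25 fps).
#' @param turn_limit maximum turn per frame in radians.
#' @param angular_noise_sd wrapped-normal heading noise SD in radians.
#' @param sociability_base baseline sociability `w0`.
#' @param group_intercept_sd SD of the group sociability intercepts `a_g`.
#' @param day_slope mean change in sociability per day (negative:
#'   habituation, groups become less social).
#' @param group_slope_sd SD of group-specific day slopes `b_g`.
#' @param interval_slope change in sociability per within-trial interval.
#' @param speed_day_slope proportional change in preferred speed per day.
#' @param speed_noise_sd SD of the per-frame innovation of each fish's AR(1)
#'   speed fluctuation, as a fraction of the preferred speed.
#' @param speed_ar autocorrelation of the speed fluctuation.
#' @param speed_coupling strength of speed matching to the nearest
#'   neighbour; the realized coupling is `sociability * speed_coupling`, so
#'   less social groups also transfer speed information more weakly.
#' @param wall_zone fraction of the ellipse (in normalized radius) treated as
#'   boundary layer, inside which agents steer along the wall tangent.
#' @param seed base integer seed; all randomness derives from it.
#' @return A list of class `school_sim_config`.
#' @export
school_sim_config <- function(n_groups = 12L, n_fish = 8L, fps = 25,
                              arena_a = 667.5, arena_b = 360,
                              r_repulsion = 30, r_align = 150, r_attract = 450,
                              speed = 4, turn_limit = 0.4,
                              angular_noise_sd = 0.55,
                              sociability_base = 0.27,
                              group_intercept_sd = 0.04,
                              day_slope = -0.008, group_slope_sd = 0.004,
                              interval_slope = -0.004,
                              speed_day_slope = -0.02,
                              speed_noise_sd = 0.15, speed_ar = 0.9,
                              speed_coupling = 2.5,
                              wall_zone = 0.85, seed = 1L) {
  if (!(r_repulsion < r_align && r_align < r_attract))
    stop("zone radii must satisfy r_repulsion < r_align < r_attract")
  if (angular_noise_sd < 0) stop("`angular_noise_sd` must be >= 0")
  if (arena_a <= 0 || arena_b <= 0) stop("arena half-axes must be positive")
  if (n_fish < 1L) stop("need at least one fish")
  structure(as.list(environment()), class = "school_sim_config")
}

# deterministic per-block seed below 2^31
block_seed <- function(seed, group, day, interval) {
  as.integer((abs(seed) %% 65536) * 32749 + group * 7919 + day * 173 +
             interval) %% 2147483647L
}

# group-level sociability intercepts and day slopes, deterministic in seed
group_effects <- function(cfg) {
  set.seed(block_seed(cfg$seed, 0L, 0L, 0L))
  data.frame(group = seq_len(cfg$n_groups),
             a_g = stats::rnorm(cfg$n_groups, 0, cfg$group_intercept_sd),
             b_g = stats::rnorm(cfg$n_groups, 0, cfg$group_slope_sd))
}

#' Simulate one interval of schooling for one group
#'
#' Runs the zonal model for `n_frames` frames. Deterministic given the
#' config seed and the (group, day, interval) coordinates.
#'
#' @param cfg a [school_sim_config()].
#' @param group group index (1-based).
#' @param day day of testing (1-based; drives the sociability and speed
#'   drift).
#' @param interval within-trial interval (1-based; drives the within-trial
#'   sociability drift).
#' @param n_frames number of frames to simulate.
#' @param a_g,b_g the group's sociability intercept and day slope; defaults
#'   draw them from the config's group-effect distribution (deterministic in
#'   the seed).
#' @return A `trajectory_dataset` in mm with attribute `"interval_index"`.
#' @export
simulate_school <- function(cfg, group = 1L, day = 1L, interval = 1L,
                            n_frames = 1500L, a_g = NULL, b_g = NULL) {
  stopifnot(inherits(cfg, "school_sim_config"))
  if (n_frames < 1L) stop("`n_frames` must be positive")
  N <- cfg$n_fish
  if (N < 1L) stop("need at least one fish")
  if (is.null(a_g) || is.null(b_g)) {
    ge <- group_effects(cfg)
    if (group > nrow(ge)) stop("group index exceeds n_groups")
    a_g <- ge$a_g[group]; b_g <- ge$b_g[group]
  }
  w <- cfg$sociability_base + a_g +
    (cfg$day_slope + b_g) * (day - 1) + cfg$interval_slope * (interval - 1)
  w <- min(1, max(0, w))
  spd <- cfg$speed * max(0.2, 1 + cfg$speed_day_slope * (day - 1))
  set.seed(block_seed(cfg$seed, group, day, interval))
  a <- cfg$arena_a; b <- cfg$arena_b
  pos <- cbind(stats::rnorm(N, 0, 60), stats::rnorm(N, 0, 60))
  th0 <- stats::runif(1, 0, 2 * pi)
  # initial heading spread scales with the process noise, so the noiseless
  # model starts (and stays) perfectly aligned
  theta <- th0 + stats::rnorm(N, 0, min(0.5, 2 * cfg$angular_noise_sd))
  out <- array(NA_real_, c(n_frames, N, 2L))
  noise <- matrix(stats::rnorm(n_frames * N, 0, cfg$angular_noise_sd),
                  n_frames, N)
  snoise <- matrix(stats::rnorm(n_frames * N, 0, cfg$speed_noise_sd * spd),
                   n_frames, N)
  sdev <- numeric(N)                # AR(1) speed fluctuation around spd
  cpl <- min(1, w * cfg$speed_coupling)
  for (t in seq_len(n_frames)) {
    ct <- cos(theta); st <- sin(theta)
    dx <- outer(pos[, 1L], pos[, 1L], `-`)   # dx[i,j] = x_i - x_j
    dy <- outer(pos[, 2L], pos[, 2L], `-`)
    dd <- sqrt(dx^2 + dy^2)
    diag(dd) <- Inf
    des_x <- ct; des_y <- st
    for (i in seq_len(N)) {
      rep_j <- which(dd[i, ] < cfg$r_repulsion)
      if (length(rep_j)) {
        # move directly away from too-close neighbours; overrides everything
        vx <- sum(dx[i, rep_j] / dd[i, rep_j])
        vy <- sum(dy[i, rep_j] / dd[i, rep_j])
        nv <- sqrt(vx^2 + vy^2)
        if (nv > 0) { des_x[i] <- vx / nv; des_y[i] <- vy / nv }
        next
      }
      al_j <- which(dd[i, ] < cfg$r_align)
      at_j <- which(dd[i, ] >= cfg$r_align & dd[i, ] < cfg$r_attract)
      sx <- sy <- 0
      if (length(al_j)) {
        vx <- sum(ct[al_j]); vy <- sum(st[al_j])
        nv <- sqrt(vx^2 + vy^2)
        if (nv > 0) { sx <- sx + vx / nv; sy <- sy + vy / nv }
      }
      if (length(at_j)) {
        vx <- sum(-dx[i, at_j] / dd[i, at_j])
        vy <- sum(-dy[i, at_j] / dd[i, at_j])
        nv <- sqrt(vx^2 + vy^2)
        if (nv > 0) { sx <- sx + vx / nv; sy <- sy + vy / nv }
      }
      nv <- sqrt(sx^2 + sy^2)
      if (nv > 0) {
        bx <- (1 - w) * ct[i] + w * sx / nv
        by <- (1 - w) * st[i] + w * sy / nv
        nb <- sqrt(bx^2 + by^2)
        if (nb > 0) { des_x[i] <- bx / nb; des_y[i] <- by / nb }
      }
    }
    # boundary layer: steer along the ellipse tangent instead of reflecting
    e <- sqrt((pos[, 1L] / a)^2 + (pos[, 2L] / b)^2)
    near <- which(e > cfg$wall_zone)
    for (i in near) {
      nx <- pos[i, 1L] / a^2; ny <- pos[i, 2L] / b^2
      nn <- sqrt(nx^2 + ny^2); nx <- nx / nn; ny <- ny / nn
      outward <- des_x[i] * nx + des_y[i] * ny
      if (outward > 0) {
        depth <- (e[i] - cfg$wall_zone) / (1 - cfg$wall_zone)
        tx <- des_x[i] - outward * nx; ty <- des_y[i] - outward * ny
        tx <- tx - depth * nx; ty <- ty - depth * ny
        nv <- sqrt(tx^2 + ty^2)
        if (nv > 1e-9) { des_x[i] <- tx / nv; des_y[i] <- ty / nv }
        else { des_x[i] <- -nx; des_y[i] <- -ny }
      }
    }
    # bounded turn towards the desired direction, plus wrapped-normal noise
    dtheta <- atan2(des_y, des_x) - theta
    dtheta <- atan2(sin(dtheta), cos(dtheta))
    dtheta <- pmin(cfg$turn_limit, pmax(-cfg$turn_limit, dtheta))
    theta <- theta + dtheta + noise[t, ]
    # speed fluctuations, partially matched to the nearest neighbour's
    nn <- apply(dd, 1L, which.min)
    sdev <- cfg$speed_ar * sdev + cpl * (sdev[nn] - sdev) + snoise[t, ]
    step <- pmax(0.2 * spd, spd + sdev)
    pos <- pos + step * cbind(cos(theta), sin(theta))
    # hard containment: project back just inside the ellipse
    e2 <- sqrt((pos[, 1L] / a)^2 + (pos[, 2L] / b)^2)
    outp <- e2 >= 1
    if (any(outp)) pos[outp, ] <- pos[outp, ] * (0.995 / e2[outp])
    out[t, , ] <- pos
  }
  ds <- trajectory_dataset(out, fps = cfg$fps, px_per_mm = 2.7,
                           group_id = sprintf("g%02d", group), day = day,
                           trial_id = sprintf("d%02d", day))
  attr(ds, "interval_index") <- as.integer(interval)
  ds
}

#' Simulate a full repeated-measures study design
#'
#' Full factorial of groups x days x intervals of schooling blocks, plus the
#' ground-truth group effects, for end-to-end validation of the analysis
#' chain: groups with lower effective sociability should show lower median
#' polarization, and group-specific day slopes should be recoverable as
#' random-slope variance downstream.
#'
#' @param cfg a [school_sim_config()].
#' @param days integer vector of test days (default `1:12`).
#' @param intervals integer vector of within-trial intervals (default `1:5`).
#' @param n_frames frames per interval block (default 1500).
#' @return A list with `datasets` (list of `trajectory_dataset`, one per
#'   group x day x interval) and `truth` (data.frame of `group`, `a_g`,
#'   `b_g`).
#' @export
simulate_study <- function(cfg, days = 1:12, intervals = 1:5,
                           n_frames = 1500L) {
  stopifnot(inherits(cfg, "school_sim_config"))
  ge <- group_effects(cfg)
  datasets <- list()
  for (g in seq_len(cfg$n_groups))
    for (d in days)
      for (iv in intervals)
        datasets[[length(datasets) + 1L]] <-
          simulate_school(cfg, g, d, iv, n_frames,
                          a_g = ge$a_g[g], b_g = ge$b_g[g])
  list(datasets = datasets, truth = ge)
}

#' Parameters of the metric-level reaction-norm generator
#'
#' @param beta0,beta_interval,beta_day fixed-effect coefficients.
#' @param sigma_int SD of group random intercepts.
#' @param sigma_slope_day,sigma_slope_interval SDs of group-specific slopes.
#' @param rho correlation between the random intercept and the day slope.
#' @param sigma_res residual SD.
#' @param n_groups,days,intervals design.
#' @param link `"identity"` (Gaussian residuals) or `"logit"` (beta-family
#'   response with precision `phi`, no Gaussian residual).
#' @param phi beta precision when `link = "logit"`.
#' @param seed integer seed.
#' @return A list of class `lmm_sim_params`.
#' @export
lmm_sim_params <- function(beta0 = 0.7, beta_interval = -0.01,
                           beta_day = -0.015, sigma_int = 0.05,
                           sigma_slope_day = 0.01,
                           sigma_slope_interval = 0, rho = 0,
                           sigma_res = 0.05, n_groups = 12L, days = 1:12,
                           intervals = 1:5, link = c("identity", "logit"),
                           phi = 200, seed = 1L) {
  link <- match.arg(link)
  if (abs(rho) > 1) stop("|rho| must be <= 1")
  if (any(c(sigma_int, sigma_slope_day, sigma_slope_interval, sigma_res) < 0))
    stop("all SDs must be >= 0")
  if (n_groups < 2L) stop("need at least 2 groups for a mixed-model design")
  structure(as.list(environment()), class = "lmm_sim_params")
}

#' Draw a metric table directly from the reaction-norm model
#'
#' Generates interval-level responses
#' `y = beta0 + beta_interval i + beta_day d + a_g + s_g d + t_g i + e`
#' with `(a_g, s_g)` bivariate normal (SDs `sigma_int`, `sigma_slope_day`,
#' correlation `rho`), independent interval slopes `t_g`, and Gaussian
#' residuals — or, with `link = "logit"`, beta-distributed responses around
#' the inverse-logit of the linear predictor. This is the generating model
#' the mixed-model layer assumes, so it provides exact ground truth for
#' parameter-recovery and model-selection calibration.
#'
#' @param params an [lmm_sim_params()].
#' @return A data.frame with columns `group`, `day`, `interval`, `y` and the
#'   realized `a_g`, `s_g`, `t_g` as attribute `"truth"`.
#' @export
simulate_metric_table <- function(params) {
  stopifnot(inherits(params, "lmm_sim_params"))
  set.seed(params$seed)
  ng <- params$n_groups
  a <- stats::rnorm(ng)
  z <- stats::rnorm(ng)
  a_g <- params$sigma_int * a
  s_g <- params$sigma_slope_day * (params$rho * a + sqrt(1 - params$rho^2) * z)
  t_g <- stats::rnorm(ng, 0, params$sigma_slope_interval)
  des <- expand.grid(interval = params$intervals, day = params$days,
                     group = seq_len(ng))
  eta <- params$beta0 + params$beta_interval * des$interval +
    params$beta_day * des$day + a_g[des$group] + s_g[des$group] * des$day +
    t_g[des$group] * des$interval
  y <- if (params$link == "identity")
    eta + stats::rnorm(nrow(des), 0, params$sigma_res)
  else {
    mu <- stats::plogis(eta)
    stats::rbeta(nrow(des), mu * params$phi, (1 - mu) * params$phi)
  }
  out <- data.frame(group = sprintf("g%02d", des$group), day = des$day,
                    interval = des$interval, y = y,
                    stringsAsFactors = FALSE)
  attr(out, "truth") <- data.frame(group = sprintf("g%02d", seq_len(ng)),
                                   a_g = a_g, s_g = s_g, t_g = t_g)
  out
}
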