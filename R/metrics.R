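#' Metric configuration
#'
#' @param polarization_threshold polarization value above which the group is
#'   classified as polarized (default 0.65); a frame at exactly the threshold
#'   counts as unpolarized.
#' @param max_lag_frames maximum lag, in frames, for the speed
#'   cross-correlation (default 300, i.e. 12 s at 25 fps).
#' @param min_heading_speed minimum speed (mm/frame) for an individual's
#'   heading to be defined; below it the fish is effectively stationary and
#'   its velocity direction is numerical noise (default 1e-6).
#' @param leadership_direction how the direction of group motion is defined
#'   for leadership ranking: `"centroid"` (displacement of the group centroid
#'   to the next frame; default) or `"mean_heading"` (mean of individual
#'   headings).
#' @return A list of class `metric_config`.
#' @export
metric_config <- function(polarization_threshold = 0.65, max_lag_frames = 300L,
                          min_heading_speed = 1e-6,
                          leadership_direction = c("centroid", "mean_heading")) {
  if (polarization_threshold <= 0 || polarization_threshold >= 1)
    stop("`polarization_threshold` must be in (0, 1)")
  if (max_lag_frames < 1L) stop("`max_lag_frames` must be >= 1")
  structure(list(polarization_threshold = polarization_threshold,
                 max_lag_frames = as.integer(max_lag_frames),
                 min_heading_speed = min_heading_speed,
                 leadership_direction = match.arg(leadership_direction)),
            class = "metric_config")
}

#' Polarization order parameter of one frame
#'
#' The norm of the mean unit heading vector: 0 when headings cancel (no
#' alignment), 1 when all individuals share a heading (complete alignment).
#'
#' @param headings an `n x 2` matrix of unit heading vectors for the
#'   individuals whose heading is defined at this frame.
#' @return Polarization in `[0, 1]`, or `NA` if fewer than 2 headings are
#'   defined.
#' @export
frame_polarization <- function(headings) {
  headings <- headings[stats::complete.cases(headings), , drop = FALSE]
  if (nrow(headings) < 2L) return(NA_real_)
  min(1, sqrt(sum(colMeans(headings)^2)))
}

# Unit headings per frame: T x N x 2, NA where speed below threshold or
# velocity missing.
block_headings <- function(block, cfg) {
  sp <- block$speeds
  ok <- is.finite(sp) & sp >= cfg$min_heading_speed
  h <- block$velocities / rep(sp, 2L)
  h[!rep(ok, 2L)] <- NA_real_
  h
}

# Per-frame polarization series for a block (NA at frames where undefined or
# group-invalid).
polarization_series <- function(block, cfg = metric_config()) {
  h <- block_headings(block, cfg)
  P <- vapply(seq_len(block$n_frames), function(t)
    frame_polarization(h[t, , ]), numeric(1))
  P[!block$frame_valid] <- NA_real_
  P
}

#' Per-frame centroid speed series
#'
#' Speed of the group's mean position, in mm/s, based on the distance
#' travelled since the previous frame. Defined only for pairs of consecutive
#' group-valid frames.
#'
#' @param block an `interval_block`.
#' @return Numeric vector of length `n_frames`; entry `t` is the centroid
#'   speed between frames `t-1` and `t`, `NA` where undefined (including
#'   frame 1).
#' @export
centroid_speed_series <- function(block) {
  cen <- apply(block$positions, c(1L, 3L), mean)
  s <- rep(NA_real_, block$n_frames)
  if (block$n_frames < 2L) return(s)
  pair_ok <- block$frame_valid[-1L] & block$frame_valid[-block$n_frames]
  d <- sqrt(diff(cen[, 1L])^2 + diff(cen[, 2L])^2)
  s[-1L][pair_ok] <- d[pair_ok] * block$fps
  s
}

#' Convex hull area of a set of points
#'
#' Area in mm^2 of the smallest convex polygon containing the group; a proxy
#' for (inverse) cohesion. Degenerate sets (fewer than 3 distinct points, or
#' all collinear) have area 0.
#'
#' @param points an `n x 2` matrix of positions in mm.
#' @return Area in mm^2.
#' @export
convex_hull_area <- function(points) {
  points <- points[stats::complete.cases(points), , drop = FALSE]
  pts <- unique(points)
  if (nrow(pts) < 3L) return(0)
  h <- grDevices::chull(pts)
  x <- pts[h, 1L]; y <- pts[h, 2L]
  # shoelace formula on the hull vertices (chull returns them in order)
  abs(sum(x * c(y[-1L], y[1L]) - c(x[-1L], x[1L]) * y)) / 2
}

# Per-frame hull area series (NA at group-invalid frames).
hull_area_series <- function(block) {
  a <- vapply(seq_len(block$n_frames), function(t)
    convex_hull_area(block$positions[t, , ]), numeric(1))
  a[!block$frame_valid] <- NA_real_
  a
}

#' Rate of transitions between polarized and unpolarized states
#'
#' Counts the state changes of the group between polarized (polarization
#' above the threshold) and unpolarized states across consecutive valid
#' frames, divided by the number of valid frames in the interval.
#'
#' @param P per-frame polarization series (`NA` = missing/invalid frame).
#' @param threshold polarization threshold (default 0.65).
#' @return Transitions per frame, or `NA` if fewer than 2 valid frames.
#' @export
transition_rate <- function(P, threshold = 0.65) {
  ok <- which(is.finite(P))
  if (length(ok) < 2L) return(NA_real_)
  state <- P[ok] > threshold
  sum(state[-1L] != state[-length(state)]) / length(ok)
}

# Pearson cross-correlation of two series over lags -max_lag..max_lag;
# returns the maximum. Correlation at lag L uses the overlapping segment
# cor(v[t], w[t + L]).
max_xcorr <- function(v, w, max_lag) {
  n <- length(v)
  best <- -Inf
  max_lag <- min(max_lag, n - 3L)
  if (max_lag < 0L) return(NA_real_)
  for (L in -max_lag:max_lag) {
    if (L >= 0) { a <- v[seq_len(n - L)]; b <- w[seq_len(n - L) + L] }
    else { a <- v[seq_len(n + L) - L]; b <- w[seq_len(n + L)] }
    if (length(a) < 3L) next
    sa <- stats::sd(a); sb <- stats::sd(b)
    if (sa == 0 || sb == 0) next
    r <- stats::cor(a, b)
    if (r > best) best <- r
  }
  if (is.infinite(best)) NA_real_ else best
}

#' Mean maximum speed cross-correlation to the nearest neighbour
#'
#' For each focal individual, the frame-wise speed series is cross-correlated
#' (Pearson, over the overlapping segment at each lag in
#' `-max_lag..+max_lag`) with the speed of its nearest neighbour, recomputed
#' every frame; the maximum over lags is taken and the mean over individuals
#' returned. High values indicate rapid transfer of speed changes between
#' neighbours. Series are built on the longest contiguous run of valid
#' frames, avoiding spurious correlation across tracking gaps.
#'
#' @param block an `interval_block`.
#' @param cfg a [metric_config()].
#' @return Mean maximum cross-correlation in `[-1, 1]`; individuals with
#'   zero-variance speed series are excluded from the mean. `NA` if no
#'   individual yields a defined value.
#' @export
max_speed_crosscorr <- function(block, cfg = metric_config()) {
  run <- longest_valid_run(block$frame_valid)
  if (length(run) < 3L) return(NA_real_)
  N <- block$n_individuals
  pos <- block$positions[run, , , drop = FALSE]
  sp <- block$speeds[run, , drop = FALSE]
  Tn <- length(run)
  nn_speed <- matrix(NA_real_, Tn, N)
  for (t in seq_len(Tn)) {
    d <- as.matrix(stats::dist(pos[t, , ]))
    diag(d) <- Inf
    # ties broken by the lowest individual id (which.min's convention)
    nn <- apply(d, 1L, which.min)
    nn_speed[t, ] <- sp[t, nn]
  }
  vals <- vapply(seq_len(N), function(i)
    max_xcorr(sp[, i], nn_speed[, i], cfg$max_lag_frames), numeric(1))
  if (all(is.na(vals))) NA_real_ else mean(vals, na.rm = TRUE)
}

longest_valid_run <- function(fv) {
  runs <- valid_runs(fv)
  if (!length(runs)) return(integer())
  runs[[which.max(lengths(runs))]]
}

# Leader flags: T x N logical, TRUE where the individual holds rank 1
# (largest projection of centroid-relative position onto the direction of
# group motion). NA rows where direction or polarization is undefined or the
# group is not polarized.
leader_flags <- function(block, cfg) {
  Tn <- block$n_frames; N <- block$n_individuals
  cen <- apply(block$positions, c(1L, 3L), mean)
  P <- polarization_series(block, cfg)
  polarized <- is.finite(P) & P > cfg$polarization_threshold & block$frame_valid
  lead <- matrix(NA, Tn, N)
  for (t in seq_len(Tn)) {
    if (!polarized[t]) next
    if (cfg$leadership_direction == "centroid") {
      # direction of the centroid's displacement to the next frame; at the
      # end of a valid run, from the previous frame
      if (t < Tn && block$frame_valid[t + 1L]) dir <- cen[t + 1L, ] - cen[t, ]
      else if (t > 1L && block$frame_valid[t - 1L]) dir <- cen[t, ] - cen[t - 1L, ]
      else next
    } else {
      h <- block_headings(block, cfg)[t, , ]
      dir <- colMeans(h, na.rm = TRUE)
    }
    nd <- sqrt(sum(dir^2))
    if (!is.finite(nd) || nd == 0) next
    proj <- (block$positions[t, , 1L] - cen[t, 1L]) * dir[1L] / nd +
            (block$positions[t, , 2L] - cen[t, 2L]) * dir[2L] / nd
    lead[t, ] <- seq_len(N) == which.max(proj)
  }
  lead
}

#' Mean rate of leadership switches
#'
#' A leadership switch is a change, between consecutive polarized frames, in
#' whether an individual holds the front-most rank along the direction of
#' group motion. Each individual's switch count is divided by the number of
#' polarized consecutive frame pairs, and the mean over individuals is
#' returned.
#'
#' @param block an `interval_block`.
#' @param cfg a [metric_config()].
#' @return Mean switches per polarized frame pair, in `[0, 1]`; `NA` when
#'   there is no polarized frame pair.
#' @export
leadership_switch_rate <- function(block, cfg = metric_config()) {
  lead <- leader_flags(block, cfg)
  Tn <- nrow(lead)
  if (Tn < 2L) return(NA_real_)
  ok <- stats::complete.cases(lead)
  pair <- ok[-1L] & ok[-Tn]
  n_pairs <- sum(pair)
  if (n_pairs == 0L) return(NA_real_)
  switches <- colSums(lead[-1L, , drop = FALSE][pair, , drop = FALSE] !=
                      lead[-Tn, , drop = FALSE][pair, , drop = FALSE])
  mean(switches / n_pairs)
}

#' All six collective-motion statistics for one interval
#'
#' Computes the interval-level summary used as one analysis row: medians
#' (over frames) of polarization, centroid speed and convex hull area
#' (medians because the per-frame distributions are right-skewed), the
#' polarized-state transition rate, the mean maximum speed cross-correlation
#' to the nearest neighbour, and the mean leadership switch rate.
#'
#' @param block an `interval_block` that passed quality control.
#' @param cfg a [metric_config()].
#' @return A one-row data.frame with columns `group`, `day`, `trial`,
#'   `interval`, `polarization`, `centroid_speed` (mm/s), `hull_area`
#'   (mm^2), `transition_rate` (1/frames), `max_speed_xcorr`,
#'   `leadership_switch_rate` (1/frames), `n_valid_frames`, `qc_ok`.
#'   Undefined components are `NA` with `qc_ok = FALSE`.
#' @export
compute_interval_metrics <- function(block, cfg = metric_config()) {
  stopifnot(inherits(block, "interval_block"))
  P <- polarization_series(block, cfg)
  s <- centroid_speed_series(block)
  a <- hull_area_series(block)
  res <- data.frame(
    group = block$group_id, day = block$day, trial = block$trial_id,
    interval = block$interval_index,
    polarization = stats::median(P, na.rm = TRUE),
    centroid_speed = stats::median(s, na.rm = TRUE),
    hull_area = stats::median(a, na.rm = TRUE),
    transition_rate = transition_rate(P, cfg$polarization_threshold),
    max_speed_xcorr = max_speed_crosscorr(block, cfg),
    leadership_switch_rate = leadership_switch_rate(block, cfg),
    n_valid_frames = block$n_valid_frames,
    stringsAsFactors = FALSE)
  res[vapply(res, function(x) is.numeric(x) && !is.finite(x), logical(1))] <- NA
  res$qc_ok <- !anyNA(res[c("polarization", "centroid_speed", "hull_area",
                            "transition_rate", "max_speed_xcorr",
                            "leadership_switch_rate")])
  res
}

#' Metric table for a list of interval blocks
#'
#' @param blocks list of `interval_block` objects.
#' @param cfg a [metric_config()].
#' @return A tidy data.frame, one row per (group, day, trial, interval) —
#'   the input format of the modelling layer.
#' @export
metrics_table <- function(blocks, cfg = metric_config()) {
  do.call(rbind, lapply(blocks, compute_interval_metrics, cfg = cfg))
}
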