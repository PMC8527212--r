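#' Preprocessing configuration
#'
#' Bundles the quality-filtering and smoothing parameters applied to raw
#' tracked trajectories before any collective-motion statistic is computed.
#'
#' @param max_speed_px_per_frame speed-outlier threshold in pixels/frame
#'   (default 50, about 46 cm/s at 2.7 px/mm and 25 fps): frames where any
#'   individual moves faster are treated as tracking errors.
#' @param sg_window Savitzky-Golay window length in frames; must be odd and
#'   greater than `sg_degree` (default 13 frames, about 0.5 s at 25 fps).
#' @param sg_degree Savitzky-Golay polynomial degree (default 3).
#' @param min_interval_s minimum seconds of usable trajectory for an interval
#'   to be retained (default 30).
#' @param interval_length_s nominal interval length in seconds (default 150,
#'   i.e. 2.5 min).
#' @return A list of class `preprocess_config`.
#' @export
preprocess_config <- function(max_speed_px_per_frame = 50, sg_window = 13L,
                              sg_degree = 3L, min_interval_s = 30,
                              interval_length_s = 150) {
  sg_window <- as.integer(sg_window)
  sg_degree <- as.integer(sg_degree)
  if (sg_window %% 2L == 0L || sg_window <= sg_degree)
    stop("`sg_window` must be odd and greater than `sg_degree`")
  if (min_interval_s > interval_length_s)
    stop("`min_interval_s` cannot exceed `interval_length_s`")
  structure(list(max_speed_px_per_frame = max_speed_px_per_frame,
                 sg_window = sg_window, sg_degree = sg_degree,
                 min_interval_s = min_interval_s,
                 interval_length_s = interval_length_s),
            class = "preprocess_config")
}

#' Mark frames with complete trajectory information
#'
#' A frame is usable for group-level statistics only when every individual in
#' the group was tracked at it. Individual data at incomplete frames are
#' retained but masked out of group-level computation via `frame_valid`.
#'
#' @param ds a `trajectory_dataset`.
#' @return The dataset with `frame_valid[t]` set to `TRUE` iff all
#'   individuals are valid at frame `t` (intersected with any pre-existing
#'   frame validity).
#' @export
filter_complete_frames <- function(ds) {
  stopifnot(inherits(ds, "trajectory_dataset"))
  complete <- rowSums(ds$valid) == ds$n_individuals
  ds$frame_valid <- if (is.null(ds$frame_valid)) complete else ds$frame_valid & complete
  ds
}

#' Exclude frames containing speed outliers
#'
#' Frames where the raw (pre-smoothing) per-frame displacement of any
#' individual exceeds `max_speed` pixels/frame are marked group-invalid:
#' inspection of tracking output shows such jumps are almost always identity
#' or detection errors, not locomotion. Displacement is measured from the
#' individual's previous valid frame, divided by the frame gap; the first
#' valid frame of a track has no predecessor and is never excluded by this
#' rule.
#'
#' @param ds a `trajectory_dataset` (raw positions).
#' @param max_speed threshold in pixels per frame (default 50).
#' @param px_per_mm pixel scale used to express the threshold in mm/frame;
#'   defaults to the dataset's own `px_per_mm`.
#' @return The dataset with offending frames removed from `frame_valid`.
#' @export
filter_speed_outliers <- function(ds, max_speed = 50, px_per_mm = ds$px_per_mm) {
  stopifnot(inherits(ds, "trajectory_dataset"))
  if (is.na(px_per_mm) || px_per_mm <= 0)
    stop("`px_per_mm` must be supplied to express the px/frame threshold in mm")
  thr_mm <- max_speed / px_per_mm
  T_ <- ds$n_frames; N <- ds$n_individuals
  ok <- rep(TRUE, T_)
  for (i in seq_len(N)) {
    vt <- which(ds$valid[, i])
    if (length(vt) < 2L) next
    d <- sqrt(diff(ds$positions[vt, i, 1L])^2 + diff(ds$positions[vt, i, 2L])^2)
    gap <- diff(vt)
    fast <- d / gap > thr_mm
    ok[vt[-1L][fast]] <- FALSE
  }
  ds$frame_valid <- if (is.null(ds$frame_valid)) ok else ds$frame_valid & ok
  ds
}

# Central Savitzky-Golay coefficients for one full window.
sg_coef <- function(degree, window) {
  m <- (window - 1L) %/% 2L
  A <- outer(-m:m, 0:degree, `^`)
  (solve(crossprod(A), t(A)))[1L, ]
}

#' Smooth trajectories with a Savitzky-Golay filter
#'
#' Applies a Savitzky-Golay polynomial filter per individual and coordinate,
#' over contiguous runs of valid frames only, so no values are fabricated
#' across tracking gaps. Only interior points of a run (those with a full
#' window of valid neighbours) are replaced; run edges, and runs shorter than
#' the window, pass through unsmoothed. Velocities are computed from the
#' smoothed positions by central first differences (one-sided at run edges)
#' and stored on the dataset in mm/frame.
#'
#' @param ds a `trajectory_dataset`.
#' @param cfg a [preprocess_config()].
#' @return The dataset with smoothed `positions` and added `velocities`
#'   (`T x N x 2`, mm/frame) and `speeds` (`T x N`, mm/frame). The validity
#'   masks are never altered by smoothing.
#' @export
smooth_trajectories <- function(ds, cfg = preprocess_config()) {
  stopifnot(inherits(ds, "trajectory_dataset"))
  w <- cfg$sg_window
  m <- (w - 1L) %/% 2L
  cf <- sg_coef(cfg$sg_degree, w)
  T_ <- ds$n_frames; N <- ds$n_individuals
  vel <- array(NA_real_, c(T_, N, 2L))
  for (i in seq_len(N)) {
    runs <- valid_runs(ds$valid[, i])
    for (r in runs) {
      len <- length(r)
      for (k in 1:2) {
        x <- ds$positions[r, i, k]
        if (len >= w) {
          sm <- stats::filter(x, cf, sides = 2)
          x[(m + 1L):(len - m)] <- sm[(m + 1L):(len - m)]
          ds$positions[r, i, k] <- x
        }
        if (len >= 2L) {
          v <- numeric(len)
          v[1L] <- x[2L] - x[1L]
          v[len] <- x[len] - x[len - 1L]
          if (len > 2L) v[2:(len - 1L)] <- (x[3:len] - x[1:(len - 2L)]) / 2
          vel[r, i, k] <- v
        }
      }
    }
  }
  ds$velocities <- vel
  ds$speeds <- sqrt(vel[, , 1L]^2 + vel[, , 2L]^2)
  ds
}

# Contiguous runs of TRUE in a logical vector, as a list of index vectors.
valid_runs <- function(v) {
  r <- rle(v)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  lapply(keep, function(j) starts[j]:ends[j])
}

#' One analysis-ready within-trial interval
#'
#' @param ds a preprocessed `trajectory_dataset` slice.
#' @param interval_index 1-based interval number within the trial.
#' @keywords internal
interval_block <- function(positions, velocities, speeds, frame_valid,
                           fps, group_id, day, trial_id, interval_index) {
  structure(list(positions = positions, velocities = velocities,
                 speeds = speeds, frame_valid = frame_valid, fps = fps,
                 group_id = group_id, day = as.integer(day),
                 trial_id = trial_id, interval_index = as.integer(interval_index),
                 n_individuals = dim(positions)[2],
                 n_frames = dim(positions)[1],
                 n_valid_frames = sum(frame_valid)),
            class = "interval_block")
}

#' @export
print.interval_block <- function(x, ...) {
  cat(sprintf(
    "<interval_block> group %s, day %d, trial %s, interval %d: %d/%d valid frames\n",
    x$group_id, x$day, x$trial_id, x$interval_index, x$n_valid_frames,
    x$n_frames))
  invisible(x)
}

#' Segment a trial into analysis intervals
#'
#' Cuts the recording into the configured time windows (by default five
#' consecutive 2.5-min intervals) and drops windows with too little usable
#' trajectory. A dropped window is recorded, with its reason, in the
#' `"dropped"` attribute of the result.
#'
#' @param ds a `trajectory_dataset`, already filtered and smoothed.
#' @param windows list (or 2-column matrix) of `(start_s, end_s)` windows,
#'   non-overlapping and in order; frame `t` belongs to a window when
#'   `start_s <= t/fps < end_s`.
#' @param cfg a [preprocess_config()]; `min_interval_s` sets the retention
#'   threshold.
#' @return A list of `interval_block` objects with `interval_index` equal to
#'   the window's position in `windows`; attribute `"dropped"` is a
#'   data.frame of dropped windows with reason codes.
#' @export
segment_intervals <- function(ds, windows, cfg = preprocess_config()) {
  stopifnot(inherits(ds, "trajectory_dataset"))
  if (is.matrix(windows)) windows <- asplit(windows, 1)
  if (length(windows) == 0L) stop("`windows` must contain at least one window")
  if (is.null(ds$frame_valid)) ds <- filter_complete_frames(ds)
  if (is.null(ds$velocities)) ds <- smooth_trajectories(ds, cfg)
  t_s <- ds$frames / ds$fps
  min_frames <- cfg$min_interval_s * ds$fps
  blocks <- list()
  dropped <- data.frame(interval_index = integer(), reason = character())
  for (j in seq_along(windows)) {
    w <- windows[[j]]
    sel <- which(t_s >= w[1] & t_s < w[2])
    nv <- if (length(sel)) sum(ds$frame_valid[sel]) else 0L
    if (nv < min_frames) {
      dropped <- rbind(dropped, data.frame(
        interval_index = j,
        reason = if (nv == 0L) "no-valid-frames" else "below-min-duration"))
      next
    }
    blocks[[length(blocks) + 1L]] <- interval_block(
      positions = ds$positions[sel, , , drop = FALSE],
      velocities = ds$velocities[sel, , , drop = FALSE],
      speeds = ds$speeds[sel, , drop = FALSE],
      frame_valid = ds$frame_valid[sel], fps = ds$fps,
      group_id = ds$group_id, day = ds$day, trial_id = ds$trial_id,
      interval_index = j)
  }
  attr(blocks, "dropped") <- dropped
  blocks
}

#' Run the full preprocessing chain on one trial
#'
#' Applies, in fixed order: the complete-frame filter, the speed-outlier
#' filter (on raw positions), Savitzky-Golay smoothing, and interval
#' segmentation. The order matters: the outlier test must see raw
#' displacements, and smoothing must not leak across excluded frames.
#'
#' @param ds a raw `trajectory_dataset`.
#' @param cfg a [preprocess_config()].
#' @param windows interval windows in seconds; defaults to contiguous windows
#'   of `cfg$interval_length_s` covering the recording (at most five).
#' @param px_per_mm pixel scale for the speed threshold; defaults to the
#'   dataset's.
#' @return As [segment_intervals()].
#' @export
preprocess_trajectories <- function(ds, cfg = preprocess_config(),
                                    windows = NULL, px_per_mm = ds$px_per_mm) {
  if (is.null(windows)) {
    dur <- ds$n_frames / ds$fps
    n_win <- min(5L, max(1L, floor(dur / cfg$interval_length_s)))
    windows <- lapply(seq_len(n_win), function(j)
      c((j - 1) * cfg$interval_length_s, j * cfg$interval_length_s))
  }
  ds <- filter_complete_frames(ds)
  ds <- filter_speed_outliers(ds, cfg$max_speed_px_per_frame, px_per_mm)
  ds <- smooth_trajectories(ds, cfg)
  segment_intervals(ds, windows, cfg)
}
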