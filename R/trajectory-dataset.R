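#' Per-frame trajectory data for one group and trial
#'
#' A `trajectory_dataset` holds the tracked 2-D positions of all `N`
#' individuals of one group across the frames of one trial (or one
#' within-trial interval). Positions are stored in millimetres; time is
#' indexed by 0-based frame number at a fixed frame rate.
#'
#' @param positions numeric `T x N x 2` array of coordinates in mm.
#' @param valid logical `T x N` matrix; `TRUE` where the individual's position
#'   was observed at that frame. Defaults to all observed.
#' @param fps frames per second (> 0).
#' @param px_per_mm pixel scale used when converting from pixel input (> 0);
#'   retained as metadata.
#' @param group_id,trial_id labels for the group and trial.
#' @param day integer day of testing (1-based).
#' @param frames integer vector of 0-based frame indices; must be contiguous.
#' @param frame_valid optional logical vector of group-level frame validity
#'   (all individuals observed, no speed outlier). Computed by the
#'   preprocessing filters; defaults to `NULL` (not yet assessed).
#'
#' @return An object of class `trajectory_dataset`: a list with elements
#'   `positions`, `valid`, `frame_valid`, `fps`, `px_per_mm`, `group_id`,
#'   `day`, `trial_id`, `frames`, `n_individuals`, `n_frames`.
#' @export
trajectory_dataset <- function(positions, valid = NULL, fps, px_per_mm = NA_real_,
                               group_id = "g1", day = 1L, trial_id = "t1",
                               frames = NULL, frame_valid = NULL) {
  if (length(dim(positions)) != 3L || dim(positions)[3] != 2L)
    stop("`positions` must be a T x N x 2 array")
  T_ <- dim(positions)[1]
  N <- dim(positions)[2]
  if (N < 2L) stop("a trajectory dataset needs at least 2 individuals")
  if (!is.numeric(fps) || length(fps) != 1L || fps <= 0)
    stop("`fps` must be a single positive number")
  if (is.null(valid)) valid <- matrix(TRUE, T_, N)
  valid <- valid & apply(is.finite(positions), c(1, 2), all)
  if (!identical(dim(valid), c(T_, N)))
    stop("`valid` must be a T x N logical matrix")
  if (is.null(frames)) frames <- seq_len(T_) - 1L
  frames <- as.integer(frames)
  if (length(frames) != T_ || (T_ > 1L && any(diff(frames) != 1L)))
    stop("`frames` must be contiguous, strictly increasing frame indices")
  if (any(!is.finite(positions[rep(valid, 2L)])))
    stop("positions must be finite wherever `valid` is TRUE")
  if (!is.null(frame_valid) && length(frame_valid) != T_)
    stop("`frame_valid` must have one entry per frame")
  structure(
    list(positions = positions, valid = valid, frame_valid = frame_valid,
         fps = fps, px_per_mm = px_per_mm, group_id = group_id,
         day = as.integer(day), trial_id = trial_id, frames = frames,
         n_individuals = N, n_frames = T_),
    class = "trajectory_dataset"
  )
}

#' @export
print.trajectory_dataset <- function(x, ...) {
  cat(sprintf(
    "<trajectory_dataset> group %s, day %d, trial %s: %d frames x %d individuals @ %g fps\n",
    x$group_id, x$day, x$trial_id, x$n_frames, x$n_individuals, x$fps))
  cat(sprintf("  individual positions observed: %.1f%%",
              100 * mean(x$valid)))
  if (!is.null(x$frame_valid))
    cat(sprintf("; group-valid frames: %d", sum(x$frame_valid)))
  cat("\n")
  invisible(x)
}

#' Read trajectory data from a long-format CSV
#'
#' The canonical on-disk format is a long CSV with columns
#' `group, day, trial, frame, id, x, y`. Coordinates may be in pixels or
#' millimetres, declared in `config$units`; pixel input is converted to mm
#' using `config$px_per_mm`. Missing `(frame, id)` rows become unobserved
#' (`valid = FALSE`) entries, so every returned dataset covers the full frame
#' range of its trial.
#'
#' @param path path to the CSV file.
#' @param config list with at least `fps` (frames/s) and `units` (`"px"` or
#'   `"mm"`); `px_per_mm` is required when `units == "px"`.
#' @return A list of `trajectory_dataset` objects, one per `(group, day,
#'   trial)` combination present in the file, in file order of first
#'   appearance.
#' @export
read_trajectories <- function(path, config) {
  units <- config$units %||% "mm"
  if (!units %in% c("px", "mm"))
    stop("unknown units '", units, "': must be 'px' or 'mm'")
  scale <- 1
  if (units == "px") {
    if (is.null(config$px_per_mm) || config$px_per_mm <= 0)
      stop("`config$px_per_mm` must be a positive number for pixel input")
    scale <- 1 / config$px_per_mm
  }
  fps <- config$fps
  if (is.null(fps) || fps <= 0) stop("`config$fps` must be a positive number")
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("group", "day", "trial", "frame", "id", "x", "y")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols))
    stop("CSV is missing columns: ", paste(missing_cols, collapse = ", "))
  key <- interaction(df$group, df$day, df$trial, drop = TRUE, lex.order = TRUE)
  out <- lapply(split(df, key), function(d) {
    dup <- duplicated(d[c("frame", "id")])
    if (any(dup))
      stop("duplicate (frame, id) rows in group ", d$group[1],
           " trial ", d$trial[1])
    ids <- sort(unique(d$id))
    fr_range <- range(d$frame)
    frames <- seq.int(fr_range[1], fr_range[2])
    T_ <- length(frames)
    N <- length(ids)
    pos <- array(NA_real_, c(T_, N, 2L))
    valid <- matrix(FALSE, T_, N)
    ti <- match(d$frame, frames)
    ii <- match(d$id, ids)
    if (any(is.na(ti)))
      stop("non-integer or non-monotone frame indices in group ", d$group[1])
    pos[cbind(ti, ii, 1L)] <- d$x * scale
    pos[cbind(ti, ii, 2L)] <- d$y * scale
    valid[cbind(ti, ii)] <- TRUE
    trajectory_dataset(pos, valid, fps = fps,
                       px_per_mm = if (units == "px") config$px_per_mm else NA_real_,
                       group_id = as.character(d$group[1]),
                       day = as.integer(d$day[1]),
                       trial_id = as.character(d$trial[1]),
                       frames = frames)
  })
  unname(out)
}

#' Write trajectory data to the canonical long CSV
#'
#' Writes only observed (valid) positions, in mm, in the same dialect read by
#' [read_trajectories()], so that read -> write -> read is the identity on
#' `(positions, valid)`.
#'
#' @param datasets a `trajectory_dataset` or list of them.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_trajectories <- function(datasets, path) {
  if (inherits(datasets, "trajectory_dataset")) datasets <- list(datasets)
  rows <- lapply(datasets, function(ds) {
    idx <- which(ds$valid, arr.ind = TRUE)
    data.frame(group = ds$group_id, day = ds$day, trial = ds$trial_id,
               frame = ds$frames[idx[, 1]], id = idx[, 2],
               x = ds$positions[cbind(idx, 1L)],
               y = ds$positions[cbind(idx, 2L)])
  })
  df <- do.call(rbind, rows)
  df <- df[order(df$group, df$day, df$trial, df$frame, df$id), ]
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Convert a per-frame pixel speed to cm/s
#'
#' Video-tracking speeds are naturally expressed in pixels per frame; analyses
#' and quality thresholds are stated in cm/s. At 2.7 px/mm and 25 fps the
#' conversion maps the 50 px/frame tracking-error threshold to about 46 cm/s.
#'
#' @param v speed in pixels per frame (> 0).
#' @param px_per_mm pixel scale in pixels per mm (> 0).
#' @param fps frame rate in frames per second (> 0).
#' @return speed in cm/s: `v / px_per_mm * fps / 10`.
#' @export
px_per_frame_to_cm_per_s <- function(v, px_per_mm, fps) {
  if (any(v <= 0) || any(px_per_mm <= 0) || any(fps <= 0))
    stop("all arguments must be positive")
  v / px_per_mm * fps / 10
}

#' Convert a frame count to seconds
#'
#' @param k number of frames (>= 0).
#' @param fps frame rate in frames per second (> 0).
#' @return duration in seconds, `k / fps`.
#' @export
frames_to_seconds <- function(k, fps) {
  if (any(k < 0)) stop("`k` must be non-negative")
  if (any(fps <= 0)) stop("`fps` must be positive")
  k / fps
}

`%||%` <- function(a, b) if (is.null(a)) b else a
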