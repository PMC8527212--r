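# Fixture builders used across the test files.

# Interval block built directly from a positions array (smoothing skipped:
# velocities by central differences, all frames valid unless masked).
make_block <- function(positions, fps = 25, frame_valid = NULL,
                       group_id = "g01", day = 1L, interval = 1L) {
  T_ <- dim(positions)[1]; N <- dim(positions)[2]
  vel <- array(NA_real_, dim(positions))
  for (i in seq_len(N)) {
    for (k in 1:2) {
      x <- positions[, i, k]
      v <- numeric(T_)
      v[1] <- x[2] - x[1]
      v[T_] <- x[T_] - x[T_ - 1]
      if (T_ > 2) v[2:(T_ - 1)] <- (x[3:T_] - x[1:(T_ - 2)]) / 2
      vel[, i, k] <- v
    }
  }
  if (is.null(frame_valid)) frame_valid <- rep(TRUE, T_)
  shoalmotion:::interval_block(
    positions = positions, velocities = vel,
    speeds = sqrt(vel[, , 1]^2 + vel[, , 2]^2),
    frame_valid = frame_valid, fps = fps, group_id = group_id, day = day,
    trial_id = "t1", interval_index = interval)
}

# Correlated-random-walk block: N individuals drifting together with noise,
# adversarial enough to exercise every metric.
random_block <- function(seed, T_ = 120, N = 8, fps = 25) {
  set.seed(seed)
  pos <- array(NA_real_, c(T_, N, 2))
  base <- matrix(rnorm(N * 2, 0, 40), N, 2)
  ang <- runif(1, 0, 2 * pi)
  for (t in seq_len(T_)) {
    ang <- ang + rnorm(1, 0, 0.3)
    drift <- c(cos(ang), sin(ang)) * 3
    base <- base + rep(drift, each = N) + matrix(rnorm(N * 2, 0, 1.5), N, 2)
    pos[t, , ] <- base
  }
  make_block(pos, fps = fps)
}

# Long CSV for two fish over a few frames, in declared units.
write_tiny_csv <- function(path, units = "mm", drop_row = NULL) {
  df <- expand.grid(frame = 0:3, id = 1:2)
  df$group <- "gA"; df$day <- 1; df$trial <- "t1"
  df$x <- 10 * df$frame + df$id
  df$y <- 5 + df$id
  df <- df[c("group", "day", "trial", "frame", "id", "x", "y")]
  if (!is.null(drop_row)) df <- df[-drop_row, ]
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  df
}
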