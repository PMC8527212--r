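test_that("polarization hits its analytic anchor points", {
  u <- matrix(rep(c(1, 0), each = 8), 8, 2)
  expect_identical(frame_polarization(u), 1)
  expect_equal(frame_polarization(rbind(c(1, 0), c(-1, 0))), 0)
  sym4 <- rbind(c(1, 0), c(0, 1), c(-1, 0), c(0, -1))
  expect_equal(frame_polarization(sym4), 0)
  expect_true(is.na(frame_polarization(matrix(c(1, 0), 1, 2))))
})

test_that("polarization is invariant to global rotation", {
  set.seed(2)
  for (rep in 1:10) {
    th <- runif(8, 0, 2 * pi)
    u <- cbind(cos(th), sin(th))
    phi <- runif(1, 0, 2 * pi)
    R <- matrix(c(cos(phi), sin(phi), -sin(phi), cos(phi)), 2, 2)
    expect_equal(frame_polarization(u %*% t(R)), frame_polarization(u),
                 tolerance = 1e-12)
  }
})

test_that("centroid speed follows displacement arithmetic", {
  pos <- array(0, c(2, 4, 2))
  pos[2, , 1] <- 3; pos[2, , 2] <- 4          # centroid moves (3,4) mm
  bl <- make_block(pos, fps = 25)
  expect_equal(centroid_speed_series(bl)[2], 125)  # 5 mm * 25 fps

  pos0 <- array(1, c(5, 4, 2))
  bl0 <- make_block(pos0)
  expect_true(all(centroid_speed_series(bl0)[-1] == 0))

  # speed scales linearly under spatial scaling
  bl2 <- random_block(3, T_ = 50)
  bl3 <- bl2; bl3$positions <- bl2$positions * 2.5
  expect_equal(centroid_speed_series(bl3)[-1],
               2.5 * centroid_speed_series(bl2)[-1], tolerance = 1e-10)
})

test_that("convex hull area matches geometry anchors and the oracle", {
  square <- rbind(c(0, 0), c(10, 0), c(10, 10), c(0, 10),
                  c(3, 3), c(5, 5), c(7, 2), c(2, 8))
  expect_equal(convex_hull_area(square), 100)
  collinear <- cbind(1:8, 2 * (1:8))
  expect_equal(convex_hull_area(collinear), 0)
  set.seed(4)
  for (rep in 1:25) {
    pts <- matrix(rnorm(16, 0, 30), 8, 2)
    expect_equal(convex_hull_area(pts), oracle_hull_area(pts),
                 tolerance = 1e-10)
  }
  # rotation invariance, quadratic scaling
  pts <- matrix(rnorm(16), 8, 2)
  phi <- 0.7
  R <- matrix(c(cos(phi), sin(phi), -sin(phi), cos(phi)), 2, 2)
  expect_equal(convex_hull_area(pts %*% t(R)), convex_hull_area(pts),
               tolerance = 1e-10)
  expect_equal(convex_hull_area(3 * pts), 9 * convex_hull_area(pts),
               tolerance = 1e-10)
})

test_that("transition rate counts threshold crossings over valid frames", {
  expect_equal(transition_rate(c(0.7, 0.6, 0.7, 0.7), 0.65), 0.5)
  expect_equal(transition_rate(rep(0.9, 100), 0.65), 0)
  Tn <- 30
  alt <- rep(c(0.9, 0.3), Tn / 2)
  expect_equal(transition_rate(alt, 0.65), (Tn - 1) / Tn)
  # an NA gap: states on either side of the gap are still compared
  expect_equal(transition_rate(c(0.9, NA, 0.3, 0.3), 0.65), 1 / 3)
  expect_true(is.na(transition_rate(c(NA, 0.5, NA), 0.65)))
  # degenerate thresholds see no crossings for series inside (0,1)
  s <- runif(50, 0.05, 0.95)
  expect_equal(transition_rate(s, 1 - 1e-12), 0)
  expect_equal(transition_rate(s, 1e-12), 0)
})

test_that("speed cross-correlation has the shift and self properties", {
  set.seed(5)
  v <- abs(rnorm(200)) + 0.5
  expect_equal(shoalmotion:::max_xcorr(v, v, 50), 1, tolerance = 1e-12)
  w <- c(rep(mean(v), 40), v[1:160])   # v delayed by 40 frames
  expect_gt(shoalmotion:::max_xcorr(v, w, 50), 0.95)
  # symmetry under series exchange (lag sign flips, maximum unchanged)
  w2 <- abs(rnorm(200)) + 0.5
  expect_equal(shoalmotion:::max_xcorr(v, w2, 30),
               shoalmotion:::max_xcorr(w2, v, 30), tolerance = 1e-12)
})

test_that("cross-correlation matches the explicit-sum oracle", {
  set.seed(6)
  for (rep in 1:10) {
    v <- rnorm(60); w <- rnorm(60)
    expect_equal(shoalmotion:::max_xcorr(v, w, 15), oracle_max_xcorr(v, w, 15),
                 tolerance = 1e-10)
  }
})

test_that("leadership switches count front-rank changes while polarized", {
  # two fish moving +x; A ahead for one frame, then B ahead
  pos <- array(0, c(3, 2, 2))
  pos[, 1, 1] <- c(1, 2, 6)    # fish 1: jumps ahead at frame 3
  pos[, 2, 1] <- c(0, 3, 4)    # fish 2: ahead at frame 2
  pos[, , 2] <- 0.01 * pos[, , 1]
  bl <- make_block(pos)
  r <- leadership_switch_rate(bl)
  expect_equal(r, 1)           # both fish switch in every frame pair

  # fixed spatial order: no switches
  pos2 <- array(0, c(50, 4, 2))
  for (i in 1:4) pos2[, i, 1] <- seq_len(50) + i * 10
  bl2 <- make_block(pos2)
  expect_equal(leadership_switch_rate(bl2), 0)
})

test_that("leadership switch rate matches the per-frame recount oracle", {
  set.seed(8)
  for (rep in 1:10) {
    bl <- random_block(rep + 100, T_ = 80)
    expect_equal(leadership_switch_rate(bl), oracle_leadership(bl),
                 tolerance = 1e-10)
  }
})

test_that("a perfectly aligned constant-velocity school is degenerate", {
  pos <- array(0, c(100, 8, 2))
  offs <- matrix(rnorm(16, 0, 20), 8, 2)
  for (t in 1:100) pos[t, , ] <- offs + (t - 1) * 2
  bl <- make_block(pos)
  m <- compute_interval_metrics(bl)
  expect_equal(m$polarization, 1)
  expect_equal(m$transition_rate, 0)
  expect_equal(m$leadership_switch_rate, 0)
  expect_equal(m$centroid_speed, 2 * sqrt(2) * 25, tolerance = 1e-10)
  expect_true(m$qc_ok)
})

test_that("interval metrics are medians/means of their per-frame series", {
  bl <- random_block(42, T_ = 150)
  m <- compute_interval_metrics(bl)
  P <- shoalmotion:::polarization_series(bl, metric_config())
  expect_equal(m$polarization, median(P, na.rm = TRUE))
  expect_equal(m$centroid_speed, median(centroid_speed_series(bl), na.rm = TRUE))
  expect_equal(m$hull_area, median(shoalmotion:::hull_area_series(bl), na.rm = TRUE))
  expect_equal(m$transition_rate, transition_rate(P, 0.65))
  expect_equal(m$n_valid_frames, 150L)
})

test_that("metrics are invariant to translation and rotation of the arena", {
  bl <- random_block(9, T_ = 100)
  phi <- 1.1
  R <- matrix(c(cos(phi), sin(phi), -sin(phi), cos(phi)), 2, 2)
  bl2 <- bl
  for (t in 1:bl$n_frames) {
    bl2$positions[t, , ] <- bl$positions[t, , ] %*% t(R) + rep(c(500, -200), each = 8)
    bl2$velocities[t, , ] <- bl$velocities[t, , ] %*% t(R)
  }
  m1 <- compute_interval_metrics(bl)
  m2 <- compute_interval_metrics(bl2)
  expect_equal(m2$polarization, m1$polarization, tolerance = 1e-10)
  expect_equal(m2$hull_area, m1$hull_area, tolerance = 1e-8)
  expect_equal(m2$centroid_speed, m1$centroid_speed, tolerance = 1e-10)
  expect_equal(m2$transition_rate, m1$transition_rate)
})
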