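# kymograph construction and slope velocimetry

# single-channel time-lapse from a frame-builder function
build_tl <- function(n_frames, ny, nx, fill, pixel_size = 1,
                     frame_interval = 60) {
  arr <- array(0L, c(n_frames, 1, ny, nx))
  for (t in seq_len(n_frames)) arr[t, 1, , ] <- as.integer(round(fill(t)))
  timelapse(arr, "x", pixel_size, frame_interval)
}

# frames with a vertical step edge at micrometre position x_t
edge_tl <- function(n_frames, nx, x_of_t, frame_interval = 60) {
  build_tl(n_frames, 21, nx, function(t) {
    xs <- (seq_len(nx) - 0.5)
    matrix(rep(ifelse(xs < x_of_t(t), 1000, 100), each = 21), 21, nx)
  }, frame_interval = frame_interval)
}

# frames with a bright vertical band (Gaussian ridge) centered at x_t
ridge_tl <- function(n_frames, nx, x_of_t, frame_interval = 60) {
  build_tl(n_frames, 21, nx, function(t) {
    xs <- (seq_len(nx) - 0.5)
    matrix(rep(100 + 900 * exp(-(xs - x_of_t(t))^2 / 8), each = 21), 21, nx)
  }, frame_interval = frame_interval)
}

h_line <- function(nx, width = 1) line_spec(c(0.5, 10), c(nx - 0.5, 10),
                                            width = width)

test_that("uniform stacks give constant kymographs of the right shape", {
  tl <- build_tl(4, 21, 50, function(t) matrix(777, 21, 50))
  k <- build_kymograph(tl, "x", h_line(50, 3))
  expect_true(all(k$matrix == 777))
  expect_equal(ncol(k$matrix), 4)
  # row count x um/row covers the line length within one pixel
  expect_lt(abs((nrow(k$matrix) - 1) * k$um_per_row - 49), 1)
})

test_that("a feature moving 1 px/frame traces a unit-slope diagonal", {
  tl <- ridge_tl(10, 60, function(t) 10 + (t - 1))
  k <- build_kymograph(tl, "x", h_line(60))
  ridge <- apply(k$matrix, 2, which.max)
  expect_equal(diff(ridge), rep(1, 9), ignore_attr = TRUE)
})

test_that("width averaging is exact on width-uniform patterns", {
  tl <- ridge_tl(3, 60, function(t) 25)
  k1 <- build_kymograph(tl, "x", h_line(60, 1))
  k3 <- build_kymograph(tl, "x", h_line(60, 3))
  expect_equal(k1$matrix, k3$matrix)
})

test_that("lines exiting the image are rejected", {
  tl <- ridge_tl(2, 30, function(t) 10)
  expect_error(build_kymograph(tl, "x", line_spec(c(-20, 10), c(50, 10))),
               "exits")
})

test_that("edge-mode slope recovers a constructed clearance speed", {
  # 0.5 um/min at 60 s frames = 0.5 px/frame
  tl <- edge_tl(30, 80, function(t) 20 + 0.5 * (t - 1))
  k <- build_kymograph(tl, "x", h_line(80))
  v <- extract_slope(k, mode = "edge")
  expect_equal(v$speed, 0.5, tolerance = 0.05)
  expect_gt(v$fit_quality, 0.98)
  # static edge: zero within numerical tolerance
  tls <- edge_tl(10, 80, function(t) 33.3)
  vs <- extract_slope(build_kymograph(tls, "x", h_line(80)), mode = "edge")
  expect_lt(abs(vs$speed), 1e-6)
})

test_that("ridge-mode slope recovers speed and reverses under time reversal", {
  tl <- ridge_tl(30, 80, function(t) 15 + 0.5 * (t - 1))
  k <- build_kymograph(tl, "x", h_line(80))
  v <- extract_slope(k, mode = "ridge")
  expect_equal(v$speed, 0.5, tolerance = 0.05)
  kr <- k
  kr$matrix <- k$matrix[, ncol(k$matrix):1]
  vr <- extract_slope(kr, mode = "ridge")
  expect_equal(vr$speed, -v$speed, tolerance = 1e-9)
})

test_that("slope estimates are equivariant in the time calibration", {
  tl1 <- ridge_tl(30, 80, function(t) 15 + 0.5 * (t - 1), frame_interval = 60)
  tl2 <- ridge_tl(30, 80, function(t) 15 + 0.5 * (t - 1), frame_interval = 30)
  v1 <- extract_slope(build_kymograph(tl1, "x", h_line(80)), mode = "ridge")
  v2 <- extract_slope(build_kymograph(tl2, "x", h_line(80)), mode = "ridge")
  expect_equal(v2$speed, 2 * v1$speed, tolerance = 1e-6)
})

test_that("degenerate kymographs are rejected", {
  tl <- build_tl(4, 21, 40, function(t) matrix(5, 21, 40))
  k <- build_kymograph(tl, "x", h_line(40))
  expect_error(extract_slope(k, mode = "edge"), "feature absent")
  expect_error(extract_slope(k, roi = list(cols = 1:99)), "roi outside")
})

test_that("flow_profile places trajectory slopes at normalized positions", {
  nx <- 200
  tl <- build_tl(30, 21, nx, function(t) {
    xs <- (seq_len(nx) - 0.5)
    row <- 100 + 900 * exp(-(xs - (20 + 1.0 * (t - 1)))^2 / 8) +
                 900 * exp(-(xs - (160 + 0.2 * (t - 1)))^2 / 8)
    matrix(rep(row, each = 21), 21, nx)
  })
  k <- build_kymograph(tl, "x", h_line(nx))
  traj <- data.frame(position_um = c(20, 160), frame_start = 1,
                     frame_end = 30, window_um = 8)
  prof <- flow_profile(k, traj)
  expect_equal(prof$speed_um_min, c(1.0, 0.2), tolerance = 0.05)
  expect_equal(prof$norm_position, c(20, 160) / ((nrow(k$matrix) - 1) *
                                                   k$um_per_row),
               tolerance = 0.01)
  # single static feature reports zero speed
  tls <- ridge_tl(10, 80, function(t) 40)
  ks <- build_kymograph(tls, "x", h_line(80))
  ps <- flow_profile(ks, data.frame(position_um = 40, frame_start = 1,
                                    frame_end = 10, window_um = 8))
  expect_lt(abs(ps$speed_um_min), 1e-6)
})

test_that("wave_speed recovers a constructed onset front", {
  # onset sweeping at 4 um/min across 100 um
  nx <- 100
  tl <- build_tl(30, 11, nx, function(t) {
    xs <- seq_len(nx) - 0.5
    on <- xs <= 4 * (t - 1)  # front position after t-1 minutes
    matrix(rep(ifelse(on, 1000, 50), each = 11), 11, nx)
  })
  k <- build_kymograph(tl, "x", line_spec(c(0.5, 5), c(nx - 0.5, 5)))
  expect_equal(wave_speed(k), 4, tolerance = 0.05)
  # simultaneous onset: infinite-speed sentinel
  tl2 <- build_tl(6, 11, 40, function(t)
    matrix(if (t < 3) 50 else 1000, 11, 40))
  k2 <- build_kymograph(tl2, "x", line_spec(c(0.5, 5), c(39.5, 5)))
  expect_warning(v <- wave_speed(k2), "simultaneous|Inf")
  expect_true(is.infinite(v))
  # no front at all
  tl3 <- build_tl(6, 11, 40, function(t) matrix(50, 11, 40))
  k3 <- build_kymograph(tl3, "x", line_spec(c(0.5, 5), c(39.5, 5)))
  expect_error(wave_speed(k3, threshold = 900), "no onset front")
})

test_that("circumferential arcs sample at the requested radius", {
  # bright ring at radius 20: arc kymograph along the ring is bright,
  # an arc at half that radius is dark
  side <- 64
  img <- matrix(0, side, side)
  d <- sqrt(outer(((1:side) - 32.5)^2, ((1:side) - 32.5)^2, "+"))
  img[abs(d - 20) < 1.5] <- 1000
  arr <- array(0L, c(1, 1, side, side)); arr[1, 1, , ] <- as.integer(img)
  tl <- timelapse(arr, "x", 1, 60)
  arc <- list(center = c(32, 32), radius = 20, theta = c(0, 2 * pi * 0.9))
  k <- build_kymograph(tl, "x", arc)
  expect_gt(min(k$matrix), 500)
  arc2 <- list(center = c(32, 32), radius = 10, theta = c(0, 2 * pi * 0.9))
  expect_lt(max(build_kymograph(tl, "x", arc2)$matrix), 100)
})
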