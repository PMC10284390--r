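# oocyte geometry, radial profiles, ROI series, voxel volume

disk_mask <- function(side, cx, cy, r) {
  oomat:::paint_disk(matrix(0, side, side), cx, cy, r, 1, 1) > 0
}

test_that("geometry of a perfect disk: radius within 1 px, center centered", {
  m <- disk_mask(140, 70, 70, 60)
  geo <- fit_geometry(m, pixel_size = 1)
  expect_equal(length(geo$radius_by_angle), 72)
  expect_true(all(abs(geo$radius_by_angle - 60) <= 1))
  expect_true(all(abs(geo$center - 70) <= 0.5))
})

test_that("geometry of an ellipse matches the analytic polar radius", {
  side <- 140; a <- 60; b <- 45
  xs <- (seq_len(side) - 0.5) - 70
  m <- outer(xs^2 / b^2, xs^2 / a^2, "+") <= 1   # rows y, cols x
  geo <- fit_geometry(m, pixel_size = 1)
  th <- geo$angles_deg * pi / 180
  # direction (sin th, -cos th): x half-axis a, y half-axis b
  analytic <- 1 / sqrt((sin(th) / a)^2 + (cos(th) / b)^2)
  expect_true(all(abs(geo$radius_by_angle - analytic) <= 1))
})

test_that("non-star-shaped input and empty masks raise errors", {
  expect_error(fit_geometry(matrix(FALSE, 10, 10)), "empty")
  ring <- disk_mask(60, 30, 30, 25) & !disk_mask(60, 30, 30, 15)
  expect_error(fit_geometry(ring), "ray missed")
})

test_that("phase fractions match brute-force per-pixel binning to 1e-9", {
  side <- 128; R <- 50
  oo_mask <- disk_mask(side, 64, 64, R)
  geo <- fit_geometry(oo_mask, pixel_size = 1)
  # constructed annulus of cortical phase at r/R(theta) in [0.8, 0.9],
  # built from the fitted geometry so bin membership is unambiguous
  ii <- row(oo_mask); jj <- col(oo_mask)
  xs <- jj - 0.5; ys <- ii - 0.5
  dd <- sqrt((xs - geo$center[1])^2 + (ys - geo$center[2])^2)
  th <- atan2(xs - geo$center[1], -(ys - geo$center[2])) %% (2 * pi)
  Rth <- matrix(approx(c(geo$angles_deg * pi / 180, 2 * pi),
                       c(geo$radius_by_angle, geo$radius_by_angle[1]),
                       xout = as.vector(th), rule = 2)$y, side, side)
  rn <- dd / Rth
  cortical <- oo_mask & rn >= 0.8 & rn < 0.9
  yolk <- oo_mask & !cortical
  ooplasm <- matrix(FALSE, side, side)
  prof <- phase_fractions(list(ooplasm = ooplasm, yolk = yolk,
                               cortical = cortical), geo, n_bins = 20)
  # brute-force oracle: loop over phase pixels, bin by r/R(theta)
  oracle <- matrix(0, 20, 3)
  phases <- list(ooplasm, yolk, cortical)
  for (k in 1:3) {
    idx <- which(phases[[k]])
    if (!length(idx)) next
    i <- (idx - 1) %% side + 1; j <- (idx - 1) %/% side + 1
    x <- j - 0.5; y <- i - 0.5
    dd <- sqrt((x - geo$center[1])^2 + (y - geo$center[2])^2)
    ang <- atan2(x - geo$center[1], -(y - geo$center[2])) %% (2 * pi)
    Rth <- approx(c(geo$angles_deg * pi / 180, 2 * pi),
                  c(geo$radius_by_angle, geo$radius_by_angle[1]),
                  xout = ang, rule = 2)$y
    bin <- pmin(pmax(floor(dd / Rth * 20) + 1, 1), 20)
    oracle[, k] <- oracle[, k] + tabulate(bin, nbins = 20)
  }
  frac_oracle <- oracle / rowSums(oracle)
  occ <- rowSums(oracle)
  expect_equal(prof$fraction[occ > 0, ], frac_oracle[occ > 0, ],
               tolerance = 1e-9, ignore_attr = TRUE)
  # annulus bins are purely cortical, others not at all
  mid_r <- (prof$edges[-1] + prof$edges[-21]) / 2
  ann <- mid_r > 0.8 & mid_r < 0.9
  expect_true(all(prof$fraction[ann, "cortical"] == 1))
  expect_true(all(prof$fraction[!ann & occ > 0, "cortical"] == 0))
})

test_that("occupied-bin fractions always sum to 1; empty bins are NA", {
  run <- mini_run_clean()
  tl <- run$timelapse
  fr <- 20
  chs <- frame_channels(tl, fr, c("ooplasm", "lysotracker"))
  mask <- segment_oocyte(chs$ooplasm, 1)
  geo <- fit_geometry(mask, 1)
  ylab <- segment_granules(chs, "yolk", 1, oocyte_mask = mask)
  clab <- segment_granules(chs, "cortical", 1, oocyte_mask = mask)
  phases <- list(yolk = ylab$labels > 0, cortical = clab$labels > 0,
                 ooplasm = mask & ylab$labels == 0 & clab$labels == 0)
  prof <- phase_fractions(phases, geo, n_bins = 20)
  s <- rowSums(prof$fraction)
  expect_true(all(abs(s[prof$occupancy > 0] - 1) < 1e-9))
  expect_true(all(is.na(prof$fraction[prof$occupancy == 0, ])))
  expect_error(phase_fractions(list(ooplasm = matrix(FALSE, 4, 4),
                                    yolk = matrix(FALSE, 4, 4),
                                    cortical = matrix(FALSE, 4, 4)),
                               geo), "all-background")
})

test_that("delta_phase is zero on identity and antisymmetric", {
  m <- disk_mask(64, 32, 32, 25)
  geo <- fit_geometry(m, 1)
  d <- sqrt(outer(((1:64) - 32.5)^2, ((1:64) - 32.5)^2, "+"))
  pa <- list(ooplasm = m & d < 12, yolk = m & d >= 12 & d < 20,
             cortical = m & d >= 20)
  pb <- list(ooplasm = m & d < 15, yolk = m & d >= 15 & d < 20,
             cortical = m & d >= 20)
  profa <- phase_fractions(pa, geo); profb <- phase_fractions(pb, geo)
  z <- delta_phase(profa, profa)
  expect_true(all(z[!is.na(z)] == 0))
  ab <- delta_phase(profa, profb); ba <- delta_phase(profb, profa)
  expect_equal(ab, -ba)
  profc <- phase_fractions(pa, geo, n_bins = 10)
  expect_error(delta_phase(profa, profc), "binning")
})

test_that("radial histogram bins granule centroids; density is exact", {
  side <- 200; R <- 90
  mask <- disk_mask(side, 100, 100, R)
  geo <- fit_geometry(mask, 1)
  lab <- matrix(0, side, side)
  # 10 granules at r/R = 0.72, disjoint angles
  for (k in 1:10) {
    th <- 2 * pi * k / 10
    lab <- oomat:::paint_disk(lab, 100 + 0.72 * R * sin(th),
                              100 - 0.72 * R * cos(th), 3, k, 1)
  }
  lf <- structure(list(labels = matrix(as.integer(lab), side, side),
                       class = "cortical", frame_index = 1L,
                       pixel_size = 1), class = "oo_label_frame")
  dp <- radial_histogram(lf, geo, bin_width = 0.05)
  expect_equal(sum(dp$counts), 10)
  b <- which(dp$breaks >= 0.70)[1]  # bin [0.70, 0.75)
  expect_equal(dp$counts[b], 10L)
  # density against brute-force pixel counting over the labelled pixels
  expect_equal(dp$surface_density,
               sum(lab > 0) / sum(mask), tolerance = 1e-2)
  # empty input
  lf0 <- structure(list(labels = matrix(0L, side, side), class = "cortical",
                        frame_index = 1L, pixel_size = 1),
                   class = "oo_label_frame")
  dp0 <- radial_histogram(lf0, geo)
  expect_equal(dp0$surface_density, 0)
  expect_equal(sum(dp0$counts), 0)
})

test_that("roi_intensity series and normalizations behave as defined", {
  arr <- array(0L, c(3, 1, 20, 20))
  arr[1, 1, , ] <- 2L; arr[2, 1, , ] <- 4L; arr[3, 1, , ] <- 6L
  tl <- timelapse(arr, "x", 1, 60)
  expect_equal(roi_intensity(tl, "x", c(2, 2, 10, 10)), c(2, 4, 6))
  expect_equal(roi_intensity(tl, "x", c(2, 2, 10, 10), "to_first"),
               c(1, 2, 3))
  expect_equal(roi_intensity(tl, "x", c(2, 2, 10, 10),
                             "to_reference_frame", reference_frame = 2),
               c(0.5, 1, 1.5))
  expect_error(roi_intensity(tl, "x", c(-5, 2, 10, 10)), "outside")
})

test_that("band profile peaks at 1.0 at the constructed peak position", {
  ny <- 30; nx <- 100
  arr <- array(0L, c(2, 1, ny, nx))
  arr[1, 1, , ] <- 100L
  peak <- 100 + 400 * exp(-((1:nx) - 20)^2 / 50)  # peak at x = 20
  arr[2, 1, , ] <- matrix(rep(round(peak), each = ny), ny, nx)
  tl <- timelapse(arr, "x", 1, 60)
  ln <- line_spec(c(0.5, 15), c(99.5, 15), width = 5)
  prof <- roi_intensity(tl, "x", ln, "subtract_baseline_then_peak",
                        reference_frame = 1)
  expect_equal(max(prof[, 2]), 1.0)
  pos <- attr(prof, "positions_um")
  expect_lt(abs(pos[which.max(prof[, 2])] - 19.5), 1.5)
})

test_that("voxel volume: unit voxel, digitized ball, empty, validation", {
  one <- array(0, c(3, 3, 3)); one[2, 2, 2] <- 1
  expect_equal(voxel_volume(one, 1, 2), 2)
  # digitized ball of radius 50 um at 2 um voxels within 2% of (4/3) pi r^3
  vx <- 2; n <- 56
  xs <- ((seq_len(n) - 0.5) * vx - n * vx / 2)^2
  ball <- array(FALSE, c(n, n, n))
  pl <- outer(xs, xs, "+")
  for (k in seq_len(n)) ball[, , k] <- pl + xs[k] <= 50^2
  expect_equal(voxel_volume(ball, vx, vx), 4 / 3 * pi * 50^3,
               tolerance = 0.02)
  expect_equal(voxel_volume(array(0, c(4, 4, 4)), 1, 1), 0)
  bad <- array(0.5, c(2, 2, 2))
  expect_error(voxel_volume(bad, 1, 1), "binary")
})
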