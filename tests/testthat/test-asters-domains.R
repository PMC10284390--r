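# aster blob detection, counts, projections, Voronoi contraction domains

gauss_spots <- function(side, centers, amp = 0.5, sigma = 4, bg = 0.1,
                        noise_sd = 0) {
  m <- matrix(bg, side, side)
  for (k in seq_len(nrow(centers)))
    m <- oomat:::add_gaussian_spot(m, centers[k, 1], centers[k, 2], amp,
                                   sigma, 1)
  if (noise_sd > 0) m <- m + matrix(rnorm(side^2, 0, noise_sd), side, side)
  m
}

test_that("LoG detection finds k well-separated spots to sub-pixel error", {
  centers <- cbind(c(20, 60, 95, 40), c(25, 70, 30, 90))
  set.seed(1)
  m <- gauss_spots(120, centers, noise_sd = 0.05)  # SNR ~ 10
  sp <- detect_asters(m, min_sigma = 3, max_sigma = 6, threshold = 0.3)
  expect_equal(nrow(sp), 4)
  d <- sapply(seq_len(4), function(k)
    min(sqrt((sp$x - centers[k, 1])^2 + (sp$y - centers[k, 2])^2)))
  expect_true(all(d < 1))
})

test_that("blank frames give zero detections", {
  expect_equal(nrow(detect_asters(matrix(0.2, 50, 50))), 0)
})

test_that("detections are invariant to intensity rescaling", {
  centers <- cbind(c(20, 50), c(30, 55))
  m <- gauss_spots(80, centers)
  a <- detect_asters(m, min_sigma = 3, max_sigma = 6)
  b <- detect_asters(0.37 * m, min_sigma = 3, max_sigma = 6)
  expect_equal(a[, c("x", "y")], b[, c("x", "y")])
})

test_that("aster density halves when the oocyte area doubles", {
  centers <- cbind(c(20, 50, 75), c(30, 55, 20))
  m <- gauss_spots(100, centers)
  arr <- array(0L, c(2, 1, 100, 100))
  arr[1, 1, , ] <- arr[2, 1, , ] <- as.integer(round(m * 65535))
  tl <- timelapse(arr, "microtubule", 1, 60)
  at1 <- aster_counts(tl, "microtubule", oocyte_area = 1e4,
                      min_sigma = 3, max_sigma = 6)
  at2 <- aster_counts(tl, "microtubule", oocyte_area = 2e4,
                      min_sigma = 3, max_sigma = 6)
  expect_equal(at1$count, at2$count)
  expect_equal(at2$density, at1$density / 2)
  expect_error(aster_counts(tl, "microtubule", oocyte_area = c(1, 2, 3)),
               "length mismatch")
})

test_that("scripted aster counts are recovered exactly, clean and at
           default noise", {
  for (noise in c(FALSE, TRUE)) {
    p <- mini_params(seed = 7, noise = noise, aster_density_peak = 60,
                     aster_sigma = 5, n_frames = 40)
    run <- generate_timelapse(p)
    mask <- segment_oocyte(tl_frame(run$timelapse, 1, "ooplasm"), 1)
    at <- aster_counts(run$timelapse, "microtubule",
                       min_sigma = 4, max_sigma = 7, threshold = 0.25,
                       mask = mask)
    gt <- run$truth$aster_tracks
    gt_counts <- vapply(seq_len(40), function(f) sum(gt$frame == f),
                        numeric(1))
    expect_gte(max(gt_counts), 3)
    expect_equal(at$count, as.integer(gt_counts))
    # the scheduled curve rises after GVBD and decays at the end
    expect_equal(gt_counts[1], 0)
    expect_gt(max(gt_counts), tail(gt_counts, 1))
  }
})

test_that("temporal projection dominates frames; tmax tracks brightening", {
  arr <- array(0L, c(3, 1, 8, 8))
  arr[1, 1, , ] <- 10L; arr[2, 1, , ] <- 20L; arr[3, 1, , ] <- 30L
  arr[2, 1, 4, 4] <- 500L
  tl <- timelapse(arr, "x", 1, 60)
  tp <- temporal_projection(tl, "x")
  expect_true(all(tp$projection >= tl_frame(tl, 1, "x")))
  expect_true(all(tp$projection >= tl_frame(tl, 3, "x")))
  expect_equal(tp$tmax[4, 4], 2)
  expect_equal(tp$tmax[1, 1], 3)  # monotone brightening elsewhere
  one <- temporal_projection(tl, "x", range = 2)
  expect_equal(one$projection, tl_frame(tl, 2, "x"))
  expect_error(temporal_projection(tl, "x", range = 0:2), "range")
})

test_that("Voronoi assignment equals brute-force nearest-cluster search", {
  set.seed(42)
  side <- 48
  init <- matrix(runif(side^2) < 0.25, side, side)
  fin <- matrix(0L, side, side)
  fin[5:9, 6:10] <- 1L; fin[30:35, 8:12] <- 2L; fin[20:24, 38:43] <- 3L
  cd <- contraction_domains(init, fin, pixel_size = 1)
  # brute force: distance from every initial pixel to every cluster pixel
  tgt <- which(fin > 0)
  ti <- (tgt - 1) %% side + 1; tj <- (tgt - 1) %/% side + 1
  tlab <- fin[tgt]
  src <- which(init)
  for (s in src) {
    si <- (s - 1) %% side + 1; sj <- (s - 1) %/% side + 1
    d2 <- (ti - si)^2 + (tj - sj)^2
    best <- min(d2)
    # the assigned cluster must attain the true minimum distance
    got <- cd$domain_labels[s]
    expect_equal(min(d2[tlab == got]), best)
  }
  # labels partition the initial mask
  expect_true(all((cd$domain_labels > 0) == init))
})

test_that("a 3x3 grid of clusters yields nine ~L/3 domains", {
  side <- 90
  init <- matrix(TRUE, side, side)
  fin <- matrix(0L, side, side)
  k <- 0L
  for (gy in 1:3) for (gx in 1:3) {
    k <- k + 1L
    fin[(gy * 30 - 16):(gy * 30 - 14), (gx * 30 - 16):(gx * 30 - 14)] <- k
  }
  cd <- contraction_domains(init, fin, pixel_size = 1)
  expect_equal(length(cd$domain_sizes), 9)
  expect_true(all(abs(cd$domain_sizes - 30) <= 2))
  expect_lt(cd$xi1 / cd$xi2, 1.1)
  expect_equal(cd$mode, "local")
})

test_that("a single cluster under a full mask reports the system size", {
  side <- 60
  init <- matrix(TRUE, side, side)
  fin <- matrix(0L, side, side); fin[28:32, 28:32] <- 1L
  cd <- contraction_domains(init, fin, pixel_size = 1)
  expect_equal(cd$xi1, 60)
  expect_equal(cd$xi2, cd$xi1)
  expect_equal(cd$mode, "large_scale")
})

test_that("domain sizes are invariant under relabeling of clusters", {
  set.seed(3)
  side <- 40
  init <- matrix(runif(side^2) < 0.3, side, side)
  fin <- matrix(0L, side, side)
  fin[4:7, 4:7] <- 1L; fin[30:34, 28:33] <- 2L
  fin2 <- ifelse(fin == 1L, 2L, ifelse(fin == 2L, 1L, 0L))
  a <- contraction_domains(init, fin, 1)
  b <- contraction_domains(init, fin2, 1)
  expect_equal(a$domain_sizes, b$domain_sizes)
})

test_that("classification boundary is closed at 0.7 x field size", {
  d <- structure(list(domain_labels = matrix(1L, 2, 2),
                      domain_sizes = c(70, 30), xi1 = 70, xi2 = 30,
                      field_size = 100, mode = NA),
                 class = "oo_contraction_domains")
  expect_equal(classify_contraction(d), "large_scale")
  d$xi1 <- 69.9
  expect_equal(classify_contraction(d), "local")
})

test_that("degenerate domain inputs raise errors", {
  expect_error(contraction_domains(matrix(FALSE, 4, 4),
                                   matrix(0L, 4, 4)), "empty initial")
  expect_error(contraction_domains(matrix(TRUE, 4, 4),
                                   matrix(0L, 4, 4)), "no final clusters")
  expect_error(contraction_domains(matrix(TRUE, 4, 4),
                                   matrix(0L, 5, 5)), "shape")
})

test_that("contraction generator: modes, partition, focus separation", {
  p <- scene_params(field_size = 90, n_frames = 8, psf_sigma = 0,
                    noise_model = list(photon_rate = 0, read_sigma = 0),
                    seed = 5)
  g <- generate_contraction_series(p, mode = "global")
  expect_equal(max(g$truth$domain_map), 1)
  l <- generate_contraction_series(p, mode = "local", n_foci = 9)
  expect_equal(sort(unique(as.vector(l$truth$domain_map[
    l$truth$domain_map > 0]))), 1:9)
  expect_error(generate_contraction_series(p, mode = "local", n_foci = 400),
               "separate")
  # final frame of the global series holds exactly one cluster
  lastf <- tl_frame(g$timelapse, 8, "network")
  bw <- lastf > 0.5 * max(lastf)
  expect_equal(max(EBImage::bwlabel(EBImage::Image(bw * 1))), 1)
})
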