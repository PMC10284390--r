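# internal helpers: seeded RNG, geometry, sampling, rasterization

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  force(code)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Unit vector at angle theta (radians): 0 = animal pole ("up", -y in image
# coordinates with y increasing downward), increasing clockwise on screen.
angle_unit <- function(theta) cbind(x = sin(theta), y = -cos(theta))

# Angle of points (x, y) relative to `center`, same convention, in [0, 2*pi).
point_angle <- function(x, y, center) {
  (atan2(x - center[1], -(y - center[2]))) %% (2 * pi)
}

# Matrices are [row = y, col = x]; pixel (i, j) has center
# ((j - 0.5) * px, (i - 0.5) * px) in micrometres.
pixel_centers_x <- function(ncol_, px) (seq_len(ncol_) - 0.5) * px
pixel_centers_y <- function(nrow_, px) (seq_len(nrow_) - 0.5) * px

# Set all pixels whose center lies within `r` of (cx, cy) to `value`.
paint_disk <- function(mat, cx, cy, r, value, px) {
  nr <- nrow(mat); nc <- ncol(mat)
  j0 <- max(1L, floor((cx - r) / px + 0.5)); j1 <- min(nc, ceiling((cx + r) / px + 0.5))
  i0 <- max(1L, floor((cy - r) / px + 0.5)); i1 <- min(nr, ceiling((cy + r) / px + 0.5))
  if (j0 > j1 || i0 > i1) return(mat)
  xs <- (j0:j1 - 0.5) * px - cx
  ys <- (i0:i1 - 0.5) * px - cy
  m <- outer(ys^2, xs^2, "+") <= r^2
  sub <- mat[i0:i1, j0:j1, drop = FALSE]
  sub[m] <- value
  mat[i0:i1, j0:j1] <- sub
  mat
}

# Set all pixels whose center falls in the annulus r0 <= d < r1 around
# (cx, cy) to `value` (granule membrane rims).
paint_ring <- function(mat, cx, cy, r0, r1, value, px) {
  nr <- nrow(mat); nc <- ncol(mat)
  j0 <- max(1L, floor((cx - r1) / px + 0.5)); j1 <- min(nc, ceiling((cx + r1) / px + 0.5))
  i0 <- max(1L, floor((cy - r1) / px + 0.5)); i1 <- min(nr, ceiling((cy + r1) / px + 0.5))
  if (j0 > j1 || i0 > i1) return(mat)
  xs <- (j0:j1 - 0.5) * px - cx
  ys <- (i0:i1 - 0.5) * px - cy
  d2 <- outer(ys^2, xs^2, "+")
  m <- d2 >= r0^2 & d2 < r1^2
  sub <- mat[i0:i1, j0:j1, drop = FALSE]
  sub[m] <- value
  mat[i0:i1, j0:j1] <- sub
  mat
}

# Add a radially symmetric Gaussian of amplitude `amp` and s.d. `sigma` (um).
add_gaussian_spot <- function(mat, cx, cy, amp, sigma, px, extent = 4) {
  nr <- nrow(mat); nc <- ncol(mat)
  r <- extent * sigma
  j0 <- max(1L, floor((cx - r) / px + 0.5)); j1 <- min(nc, ceiling((cx + r) / px + 0.5))
  i0 <- max(1L, floor((cy - r) / px + 0.5)); i1 <- min(nr, ceiling((cy + r) / px + 0.5))
  if (j0 > j1 || i0 > i1) return(mat)
  xs <- (j0:j1 - 0.5) * px - cx
  ys <- (i0:i1 - 0.5) * px - cy
  g <- amp * exp(-outer(ys^2, xs^2, "+") / (2 * sigma^2))
  mat[i0:i1, j0:j1] <- mat[i0:i1, j0:j1] + g
  mat
}

# Bilinear interpolation of matrix `mat` at micrometre coordinates (x, y).
# Points outside the image are clamped to the border pixel.
bilinear <- function(mat, x, y, px) {
  nr <- nrow(mat); nc <- ncol(mat)
  cj <- clamp(x / px + 0.5, 1, nc)   # fractional column index
  ci <- clamp(y / px + 0.5, 1, nr)
  j0 <- clamp(floor(cj), 1, nc); j1 <- clamp(j0 + 1, 1, nc)
  i0 <- clamp(floor(ci), 1, nr); i1 <- clamp(i0 + 1, 1, nr)
  fx <- cj - j0; fy <- ci - i0
  v00 <- mat[cbind(i0, j0)]; v01 <- mat[cbind(i0, j1)]
  v10 <- mat[cbind(i1, j0)]; v11 <- mat[cbind(i1, j1)]
  (1 - fy) * ((1 - fx) * v00 + fx * v01) + fy * ((1 - fx) * v10 + fx * v11)
}

# Convert float intensities in [0, 1] to 16-bit integer counts and back.
to_uint16 <- function(mat) {
  storage.mode(mat) <- "double"
  m <- round(clamp(mat, 0, 1) * 65535)
  storage.mode(m) <- "integer"
  m
}

stopifnot_scalar <- function(x, name, positive = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a finite numeric scalar", name), call. = FALSE)
  if (positive && x <= 0)
    stop(sprintf("'%s' must be > 0", name), call. = FALSE)
  invisible(x)
}

# Siegel repeated-median slope estimator; robust to a minority of outlier
# feature localizations in a kymograph column series.
repeated_median_fit <- function(x, y) {
  n <- length(x)
  slopes_i <- vapply(seq_len(n), function(i) {
    dx <- x - x[i]; dy <- y - y[i]
    ok <- dx != 0
    if (!any(ok)) return(NA_real_)
    median(dy[ok] / dx[ok])
  }, numeric(1))
  slope <- median(slopes_i, na.rm = TRUE)
  intercept <- median(y - slope * x)
  list(slope = slope, intercept = intercept)
}
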