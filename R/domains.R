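#' Binary network mask from a single-channel frame
#'
#' Otsu threshold on the normalized intensities; the standard first step
#' for both the initial filament-network mask and the final cluster mask
#' of a contraction series.
#'
#' @param frame Y x X numeric matrix.
#' @return Logical matrix.
#' @export
network_mask <- function(frame) {
  m <- normalize01(frame)
  m > EBImage::otsu(EBImage::Image(clamp(m, 0, 1)))
}

#' Label the microtubule clusters of a (final) network frame
#'
#' Threshold plus connected-component labelling with a minimum-area
#' filter - the clusters "detectable at the final time point" that seed
#' the Voronoi domain analysis.
#'
#' @param frame Y x X numeric matrix.
#' @param pixel_size um per pixel.
#' @param min_area minimum cluster area, um^2.
#' @return Integer label matrix (background 0).
#' @export
segment_network_clusters <- function(frame, pixel_size = 1, min_area = 3) {
  bw <- network_mask(frame)
  lab <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(bw * 1)))
  storage.mode(lab) <- "integer"
  if (max(lab) == 0L) return(lab)
  areas <- tabulate(lab[lab > 0]) * pixel_size^2
  keep <- which(areas >= min_area)
  remap <- integer(max(lab))
  remap[keep] <- seq_along(keep)
  out <- matrix(0L, nrow(lab), ncol(lab))
  nz <- lab > 0
  out[nz] <- remap[lab[nz]]
  out
}

#' Voronoi contraction-domain analysis (xi1, xi2)
#'
#' Identifies the network domain that gives rise to each microtubule
#' cluster present at the final time point of a contraction: every pixel
#' of the initial network mask is assigned to the nearest final cluster
#' (Euclidean distance to cluster pixels - the Voronoi partition), and the
#' linear size xi of each domain is measured on the domain restricted to
#' the initial mask. xi1 >= xi2 are the two largest; with a single domain
#' xi2 = xi1 by convention. In the percolation-theory reading, local
#' contractions give xi1 of the same order as xi2, while large-scale
#' contractions push xi1 towards the system size.
#'
#' The linear size is the maximum caliper extent measured along the image
#' axes (the larger of the domain's x- and y-extent). A domain that spans
#' the whole square patch therefore reports the system size itself, which
#' is the length xi1 is compared against.
#'
#' @param initial_mask logical matrix: the network at the start of the
#'   contraction (e.g. the first frame segmented, or a temporal-projection
#'   mask).
#' @param final_clusters logical or integer matrix, same shape: the
#'   clusters detectable at the final time point (binary masks are
#'   labelled internally; use the granule segmentation machinery to
#'   produce them).
#' @param pixel_size um per pixel.
#' @param field_size system size in um; defaults to the larger image side.
#' @return An `oo_contraction_domains`: list with `domain_labels` (integer
#'   matrix over the initial mask, 0 elsewhere), `domain_sizes` (um,
#'   descending), `xi1`, `xi2`, `field_size`, and `mode` from
#'   [classify_contraction()].
#' @export
contraction_domains <- function(initial_mask, final_clusters,
                                pixel_size = 1, field_size = NULL) {
  if (!any(initial_mask)) stop("empty initial mask")
  if (!identical(dim(initial_mask), dim(final_clusters)))
    stop("mask shapes differ")
  if (is.logical(final_clusters) ||
      all(unique(as.vector(final_clusters)) %in% c(0, 1))) {
    final_labels <- EBImage::imageData(
      EBImage::bwlabel(EBImage::Image(final_clusters * 1)))
    storage.mode(final_labels) <- "integer"
  } else {
    final_labels <- final_clusters
    storage.mode(final_labels) <- "integer"
  }
  if (max(final_labels) < 1L) stop("no final clusters detected")
  if (is.null(field_size))
    field_size <- max(dim(initial_mask)) * pixel_size

  nr <- nrow(initial_mask)
  tgt <- which(final_labels > 0L)
  ti <- (tgt - 1L) %% nr + 1L
  tj <- (tgt - 1L) %/% nr + 1L
  src <- which(initial_mask)
  si <- (src - 1L) %% nr + 1L
  sj <- (src - 1L) %/% nr + 1L

  assigned <- if (max(final_labels) == 1L) {
    rep(1L, length(src))
  } else {
    # exact nearest cluster pixel (Euclidean) via 1-NN classification
    as.integer(as.character(class::knn1(
      train = cbind(ti, tj), test = cbind(si, sj),
      cl = factor(final_labels[tgt]))))
  }

  dlab <- matrix(0L, nr, ncol(initial_mask))
  dlab[src] <- assigned

  sizes <- vapply(sort(unique(assigned)), function(l) {
    sel <- assigned == l
    max(diff(range(si[sel])) + 1L, diff(range(sj[sel])) + 1L) * pixel_size
  }, numeric(1))
  sizes <- sort(sizes, decreasing = TRUE)
  xi1 <- sizes[1]
  xi2 <- if (length(sizes) >= 2) sizes[2] else xi1

  out <- structure(list(domain_labels = dlab, domain_sizes = sizes,
                        xi1 = xi1, xi2 = xi2, field_size = field_size,
                        mode = NA_character_),
                   class = "oo_contraction_domains")
  out$mode <- classify_contraction(out)
  out
}

#' @export
print.oo_contraction_domains <- function(x, ...) {
  cat(sprintf("contraction domains: %d domain(s), xi1 = %.1f um, xi2 = %.1f um\n",
              length(x$domain_sizes), x$xi1, x$xi2))
  cat(sprintf("  field %.0f um -> %s contraction\n", x$field_size, x$mode))
  invisible(x)
}

#' Classify a contraction as local or large-scale
#'
#' Large-scale when xi1 reaches at least 70% of the system size (a closed
#' boundary: xi1 exactly at the threshold classifies as large-scale),
#' otherwise local. The numeric (xi1, xi2) pair always travels with the
#' result, so the sensitivity of the call to the 0.7 threshold can be
#' judged directly.
#'
#' @param d an `oo_contraction_domains`.
#' @param threshold fraction of the field size (default 0.7).
#' @return `"large_scale"` or `"local"`.
#' @export
classify_contraction <- function(d, threshold = 0.7) {
  if (!inherits(d, "oo_contraction_domains"))
    stop("'d' must be an oo_contraction_domains")
  if (d$xi1 >= threshold * d$field_size) "large_scale" else "local"
}
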