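# Eleven morphological descriptors of a segmented lesion mask.

# Chain-code perimeter of the traced boundary with the Kulpa correction
# (0.948 per axial step, 1.340 per diagonal step), which removes the
# systematic overestimate of raw 8-connected chain length.
.chainPerimeter <- function(bnd) {
  steps <- diff(rbind(bnd, bnd[1, , drop = FALSE]))
  diag <- abs(steps[, 1]) > 0 & abs(steps[, 2]) > 0
  # steps longer than one pixel (rare contour jumps) fall back on Euclidean
  long <- pmax(abs(steps[, 1]), abs(steps[, 2])) > 1
  len <- sqrt(rowSums(steps^2))
  sum(0.948 * (!diag & !long)) + sum(1.340 * (diag & !long)) + sum(len[long])
}

#' Radial length profile of a mask
#'
#' Distances from the mask centroid to each traced boundary pixel, in
#' boundary order, normalised by the maximum.
#'
#' @param mask non-empty logical matrix.
#' @return numeric vector in (0, 1\], one value per boundary pixel, with
#'   attribute `"centroidInside"` (FALSE flags a centroid outside the mask).
#' @export
radialLengthProfile <- function(mask) {
  if (!any(mask)) stop("empty mask")
  w <- which(mask, arr.ind = TRUE)
  ctr <- colMeans(w)
  bnd <- maskBoundary(mask)
  d <- sqrt((bnd[, 1] - ctr[1])^2 + (bnd[, 2] - ctr[2])^2)
  p <- d / max(d)
  attr(p, "centroidInside") <- mask[round(ctr[1]), round(ctr[2])]
  p
}

#' Box-counting dimension of a boundary pixel set
#'
#' Counts occupied boxes at each scale on a grid anchored at the point set's
#' minimum corner and fits the least-squares slope of `log N(eps)` against
#' `log(1/eps)`.
#'
#' @param pts n x 2 matrix of boundary pixel coordinates.
#' @param scales dyadic box sizes in pixels (at least two).
#' @return the fitted dimension (clamped to \[1, 2\], the attainable range for
#'   a connected planar boundary); attribute `"counts"` holds N(eps).
#' @export
boxCountingDimension <- function(pts, scales = c(1, 2, 4, 8, 16)) {
  if (length(scales) < 2) stop("need at least 2 scales")
  x <- pts[, 1] - min(pts[, 1]); y <- pts[, 2] - min(pts[, 2])
  xr <- max(x) - x; yr <- max(y) - y
  counts <- vapply(scales, function(s) {
    nBox <- function(a, b) {
      ba <- floor(a / s); bb <- floor(b / s)
      length(unique(ba * (max(bb) + 2) + bb))
    }
    # averaged over the four axis orientations so grid anchoring does not
    # break exact invariance under 90-degree rotations and reflections
    (nBox(x, y) + nBox(x, yr) + nBox(xr, y) + nBox(xr, yr)) / 4
  }, numeric(1))
  keep <- counts > 0
  if (sum(keep) < 2) stop("fewer than 2 non-empty scales")
  fit <- stats::lm.fit(cbind(1, log(1 / scales[keep])), log(counts[keep]))
  dim <- unname(fit$coefficients[2])
  structure(min(max(dim, 1), 2), counts = counts)
}

#' Compute the 11 morphological features
#'
#' Definitions: `circularity = 4 pi A / P^2` and `compactness` its reciprocal
#' (corrected chain-code perimeter `P`); `elongation` = minor/major axis ratio
#' of the second-moment ellipse and `eccentricity` its ellipse eccentricity;
#' `extent` = area over bounding-box area; `solidity` = area over convex-hull
#' area; `spiculation` = mean absolute cyclic first difference of the
#' normalised radial-length profile times its number of derivative sign
#' changes, per boundary pixel; `radial_length_entropy` = base-2 Shannon
#' entropy of the 10-bin radial-length histogram; `fractal_dimension` by box
#' counting on boundary pixels at scales 1-16 px; `heterogeneity` = squared
#' coefficient of variation of the intensity inside the mask; `area` in mm^2.
#'
#' @param mask non-empty logical matrix, a single connected component.
#' @param intensity matrix on the same grid (first post-contrast frame);
#'   used only by `heterogeneity`.
#' @param spacing pixel size in mm.
#' @return named numeric vector of the 11 features, with attribute
#'   `"borderTouching"` flagging masks clipped by the image border.
#' @export
computeMorphology <- function(mask, intensity, spacing = 1) {
  if (!any(mask)) stop("empty mask")
  lab <- EBImage::bwlabel(matrix(as.integer(mask), nrow(mask)))
  if (max(lab) > 1L) stop("mask must be a single connected component")
  w <- which(mask, arr.ind = TRUE)
  border <- any(w[, 1] %in% c(1L, nrow(mask))) || any(w[, 2] %in% c(1L, ncol(mask)))

  A <- nrow(w)                          # pixel count
  areaMm2 <- A * spacing^2
  bnd <- maskBoundary(mask)
  P <- .chainPerimeter(bnd)
  # not clamped at 1: the corrected digital perimeter can undershoot the
  # continuous one by a percent or two, and clamping would collapse the
  # feature to a constant across near-circular lesions
  circ <- 4 * pi * A / P^2
  comp <- 1 / circ

  # second-moment ellipse
  cv <- stats::cov(w) + diag(2) / 12    # per-pixel variance correction
  ev <- eigen(cv, symmetric = TRUE, only.values = TRUE)$values
  ratio2 <- max(ev[2], 0) / ev[1]
  elong <- sqrt(ratio2)
  ecc <- sqrt(max(1 - ratio2, 0))

  bbox <- (diff(range(w[, 1])) + 1) * (diff(range(w[, 2])) + 1)
  extent <- A / bbox
  hullIdx <- chull(bnd)
  hullArea <- polygonArea(bnd[hullIdx, , drop = FALSE]) + P / 2 + 1
  solidity <- min(A / hullArea, 1)

  p <- radialLengthProfile(mask)
  # spiculation on a circularly smoothed profile (5-point moving average),
  # so pixel-level jitter of the digital boundary does not register as spikes
  np <- length(p)
  ps <- p
  if (np >= 5) {
    ext <- c(tail(p, 2), p, head(p, 2))
    ps <- vapply(seq_len(np), function(i) mean(ext[i:(i + 4)]), numeric(1))
  }
  dcyc <- diff(c(ps, ps[1]))            # cyclic first difference
  # derivative zero-crossings with a prominence floor: count reversals
  # between cyclically adjacent profile extrema whose amplitude exceeds 2%
  # of the maximum radius (residual jitter would otherwise dominate)
  nz <- which(dcyc != 0)
  crossings <- 0
  if (length(nz) > 1) {
    sgn <- sign(dcyc[nz])
    extIdx <- nz[sgn != c(sgn[-1], sgn[1])]
    if (length(extIdx) > 1) {
      ev <- ps[extIdx]
      crossings <- sum(abs(ev - c(ev[-1], ev[1])) > 0.02)
    }
  }
  spic <- mean(abs(dcyc)) * crossings / np
  h <- tabulate(pmin(floor(p * 10) + 1, 10), nbins = 10)
  rle <- entropyBits(h / sum(h))
  fd <- as.numeric(boxCountingDimension(bnd))

  inten <- intensity[mask]
  het <- var(inten) / mean(inten)^2

  out <- c(compactness = comp, spiculation = spic, extent = extent,
           elongation = elong, solidity = solidity, circularity = circ,
           radial_length_entropy = rle, fractal_dimension = fd,
           heterogeneity = het, area = areaMm2, eccentricity = ecc)
  attr(out, "borderTouching") <- border
  out
}
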