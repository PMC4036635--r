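# Gray-level co-occurrence matrix and the 13 Haralick texture statistics.

#' Build a gray-level co-occurrence matrix over a mask
#'
#' Pixel pairs are counted only when both pixels lie inside the mask, over all
#' requested offsets, optionally symmetrised (each pair counted in both
#' directions), then normalised to joint probabilities. Intensities that are
#' already non-negative integers below `ng` are used as gray levels directly;
#' otherwise they are min-max scaled over the masked pixels onto
#' `0 .. ng - 1`.
#'
#' @param img numeric matrix.
#' @param mask logical matrix; defaults to the full image.
#' @param ng number of gray levels (default 256, i.e. fine binning).
#' @param offsets list of `c(dr, dc)` displacement vectors; default distance-1
#'   in the four principal directions, accumulated into one matrix.
#' @param symmetric symmetrise before normalising.
#' @return a `GLCM` list: `p` (ng x ng probabilities), `ng`, `offsets`,
#'   `symmetric`, `nPairs`.
#' @examples
#' g <- buildGLCM(matrix(c(0, 1, 0, 1), 2), ng = 2, offsets = list(c(0, 1)))
#' g$p
#' @export
buildGLCM <- function(img, mask = NULL, ng = 256L,
                      offsets = list(c(0L, 1L), c(1L, 0L), c(1L, 1L), c(1L, -1L)),
                      symmetric = TRUE) {
  if (is.null(mask)) mask <- matrix(TRUE, nrow(img), ncol(img))
  if (!any(mask)) stop("mask is empty")
  if (ng < 2L) stop("need at least 2 gray levels")
  vals <- img[mask]
  if (all(vals >= 0 & vals <= ng - 1 & vals == floor(vals))) {
    lev <- matrix(NA_integer_, nrow(img), ncol(img))
    lev[mask] <- as.integer(img[mask])
  } else {
    rng <- range(vals)
    span <- diff(rng)
    lev <- matrix(NA_integer_, nrow(img), ncol(img))
    lev[mask] <- if (span > 0) {
      pmin(as.integer(floor((img[mask] - rng[1]) / span * ng)), ng - 1L)
    } else 0L
  }
  counts <- matrix(0, ng, ng)
  nr <- nrow(img); nc <- ncol(img)
  for (off in offsets) {
    dr <- off[1]; dc <- off[2]
    if (max(1, 1 - dr) > min(nr, nr - dr) ||
        max(1, 1 - dc) > min(nc, nc - dc)) next  # offset exceeds the image
    r1 <- max(1, 1 - dr):min(nr, nr - dr)
    c1 <- max(1, 1 - dc):min(nc, nc - dc)
    a <- lev[r1, c1, drop = FALSE]
    b <- lev[r1 + dr, c1 + dc, drop = FALSE]
    ok <- !is.na(a) & !is.na(b)
    if (!any(ok)) next
    tab <- tabulate(a[ok] * ng + b[ok] + 1L, nbins = ng * ng)
    counts <- counts + matrix(tab, ng, ng, byrow = TRUE)
  }
  nPairs <- sum(counts)
  if (nPairs == 0) stop("no valid pixel pair inside the mask (mask too thin)")
  if (symmetric) counts <- counts + t(counts)
  structure(list(p = counts / sum(counts), ng = ng, offsets = offsets,
                 symmetric = symmetric, nPairs = nPairs), class = "GLCM")
}

#' The 13 Haralick features of a GLCM
#'
#' Entropies are in bits (log base 2) with the `0 log 0 = 0` convention.
#' Gray levels are 0-based, so sum-marginal indices run over `0 .. 2(Ng-1)`
#' and difference-marginal indices over `0 .. Ng-1`. `sum_variance` is
#' centred on `sum_average`; `difference_variance` is the variance of the
#' difference marginal; the two information measures of correlation are
#' `IMC1 = (HXY - HXY1) / max(HX, HY)` and
#' `IMC2 = sqrt(1 - exp(-2 (HXY2 - HXY)))`.
#'
#' @param glcm a `GLCM` from [buildGLCM()].
#' @return named numeric vector of the 13 texture features
#'   (`featureNames("texture")`).
#' @export
haralickFeatures <- function(glcm) {
  p <- glcm$p
  if (abs(sum(p) - 1) > 1e-6 || any(p < 0))
    stop("GLCM is not a normalized probability matrix")
  ng <- glcm$ng
  i <- matrix(0:(ng - 1), ng, ng)               # row level
  j <- t(i)                                     # column level
  px <- rowSums(p); py <- colSums(p)
  mux <- sum((0:(ng - 1)) * px); muy <- sum((0:(ng - 1)) * py)
  sx <- sqrt(sum(((0:(ng - 1)) - mux)^2 * px))
  sy <- sqrt(sum(((0:(ng - 1)) - muy)^2 * py))

  asm <- sum(p^2)
  inertia <- sum((i - j)^2 * p)
  correlation <- if (sx * sy > 0) (sum(i * j * p) - mux * muy) / (sx * sy) else 0
  idm <- sum(p / (1 + (i - j)^2))

  # sum and difference marginals
  psum <- as.vector(rowsum(as.vector(p), factor(as.vector(i + j), levels = 0:(2 * ng - 2))))
  psum[is.na(psum)] <- 0
  pdif <- as.vector(rowsum(as.vector(p), factor(as.vector(abs(i - j)), levels = 0:(ng - 1))))
  pdif[is.na(pdif)] <- 0
  ks <- 0:(2 * ng - 2); kd <- 0:(ng - 1)
  sumAvg <- sum(ks * psum)
  sumVar <- sum((ks - sumAvg)^2 * psum)
  sumEnt <- entropyBits(psum)
  ent <- entropyBits(p)
  difAvg <- sum(kd * pdif)
  difVar <- sum((kd - difAvg)^2 * pdif)
  difEnt <- entropyBits(pdif)

  hx <- entropyBits(px); hy <- entropyBits(py)
  pxpy <- outer(px, py)
  pos <- p > 0
  hxy1 <- -sum(p[pos] * log2(pxpy[pos]))
  posm <- pxpy > 0
  hxy2 <- -sum(pxpy[posm] * log2(pxpy[posm]))
  imc1 <- if (max(hx, hy) > 0) (ent - hxy1) / max(hx, hy) else 0
  imc2 <- sqrt(max(1 - exp(-2 * (hxy2 - ent)), 0))

  c(asm = asm, inertia = inertia, correlation = correlation,
    inverse_difference_moment = idm, sum_average = sumAvg,
    sum_variance = sumVar, sum_entropy = sumEnt, entropy = ent,
    difference_average = difAvg, difference_variance = difVar,
    difference_entropy = difEnt, info_correlation_1 = imc1,
    info_correlation_2 = imc2)
}
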