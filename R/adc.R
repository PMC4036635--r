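# Apparent diffusion coefficient from the two-b-value DWI pair.

#' Compute the per-pixel ADC map
#'
#' Two-point log-ratio estimate, exact for mono-exponential decay:
#' `ADC = ln(S_b0 / S_bhigh) / (b_high - b_low)`, reported in units of
#' 10^-3 mm^2/s. Pixels with a non-positive signal in either frame are
#' excluded from the valid mask rather than raising an error.
#'
#' @param b0,b800 numeric matrices on one grid (low- and high-b signal).
#' @param bValues the two b-values in s/mm^2, strictly increasing.
#' @return an `ADCMap` list: `adc` (matrix, NA outside `validMask`),
#'   `validMask`, `bValues`.
#' @examples
#' m <- computeADCMap(matrix(1000), matrix(449.329), c(0, 800))
#' m$adc  # ~1.0 x 10^-3 mm^2/s
#' @export
computeADCMap <- function(b0, b800, bValues = c(0, 800)) {
  if (!all(dim(b0) == dim(b800))) stop("DWI frames are not co-registered")
  if (diff(bValues) <= 0) stop("bValues must be strictly increasing")
  valid <- b0 > 0 & b800 > 0
  adc <- matrix(NA_real_, nrow(b0), ncol(b0))
  adc[valid] <- log(b0[valid] / b800[valid]) / diff(bValues) * 1000
  structure(list(adc = adc, validMask = valid, bValues = bValues),
            class = "ADCMap")
}

#' Dichotomize the high-b DWI signal inside a lesion
#'
#' Splits the lesion into high- and low-signal parts by an Otsu threshold
#' computed over the lesion plus a surrounding background ring (the mask
#' dilated by `ringWidth` pixels, minus the mask), and returns the
#' high-signal subset of the mask.
#'
#' @param b800 high-b DWI frame.
#' @param mask non-empty logical lesion mask.
#' @param ringWidth ring radius in pixels.
#' @return logical matrix (subset of `mask`); attribute `"flagged"` is TRUE
#'   when the intensities carried no contrast and the whole mask was
#'   returned.
#' @export
dichotomizeDWI <- function(b800, mask, ringWidth = 5L) {
  if (!any(mask)) stop("empty mask")
  brush <- EBImage::makeBrush(2L * as.integer(ringWidth) + 1L, shape = "disc")
  dil <- EBImage::dilate(matrix(as.integer(mask), nrow(mask)), brush) > 0
  ring <- dil & !mask
  if (!any(ring)) stop("background ring is empty (mask fills the image)")
  vals <- b800[mask | ring]
  rng <- range(vals)
  if (diff(rng) < .Machine$double.eps * (abs(rng[2]) + 1)) {
    out <- mask
    attr(out, "flagged") <- TRUE
    return(out)
  }
  svals <- (vals - rng[1]) / diff(rng)
  thr <- EBImage::otsu(EBImage::Image(matrix(svals, ncol = 1)), range = c(0, 1))
  scaled <- (b800 - rng[1]) / diff(rng)
  out <- mask & scaled > thr
  if (!any(out)) out <- mask  # threshold above the whole lesion: keep it all
  attr(out, "flagged") <- FALSE
  out
}

#' Mean ADC over the high-signal lesion core
#'
#' @param adcMap an `ADCMap` from [computeADCMap()].
#' @param highSubset logical matrix (e.g. from [dichotomizeDWI()]).
#' @return mean ADC (10^-3 mm^2/s) over `highSubset` intersected with the
#'   map's valid mask.
#' @export
adcFeature <- function(adcMap, highSubset) {
  sel <- highSubset & adcMap$validMask
  if (!any(sel)) stop("no valid pixel in the selected subset")
  mean(adcMap$adc[sel])
}
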