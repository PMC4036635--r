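# Enhancement-kinetic features of the DCE time series.

#' Extract the lesion kinetic curve
#'
#' Mean intensity over the mask for every DCE frame.
#'
#' @param dce numeric array `h x w x frames` (frame 1 pre-contrast).
#' @param mask non-empty logical matrix.
#' @return a `KineticCurve` list: `fullCurve` (one mean per frame), `I0`
#'   (pre-contrast), `Iinit` (first post-contrast), `Ilast` (last frame).
#' @export
extractCurve <- function(dce, mask) {
  if (!any(mask)) stop("empty mask")
  nf <- dim(dce)[3]
  cur <- vapply(seq_len(nf), function(k) mean(dce[, , k][mask]), numeric(1))
  structure(list(fullCurve = cur, I0 = cur[1], Iinit = cur[2],
                 Ilast = cur[nf]), class = "KineticCurve")
}

#' Early-phase enhancement (percent)
#'
#' `EPE = (Iinit - I0) / I0 x 100`: the relative signal rise from the
#' pre-contrast to the first post-contrast frame. Negative values
#' (de-enhancement) are allowed.
#'
#' @param curve a `KineticCurve`.
#' @return EPE in percent.
#' @examples
#' kineticEPE(structure(list(I0 = 100, Iinit = 180, Ilast = 140),
#'                      class = "KineticCurve"))  # 80
#' @export
kineticEPE <- function(curve) {
  if (curve$I0 <= 0) stop("pre-contrast intensity must be positive")
  (curve$Iinit - curve$I0) / curve$I0 * 100
}

#' Signal enhancement ratio
#'
#' `SER = (Iinit - I0) / (Ilast - I0)`: early enhancement relative to late
#' enhancement. With `Iinit > I0`, SER > 1 indicates washout and SER < 1
#' persistent enhancement.
#'
#' @param curve a `KineticCurve`.
#' @param eps relative tolerance below which `Ilast - I0` is treated as zero.
#' @return the ratio.
#' @examples
#' kineticSER(structure(list(I0 = 100, Iinit = 180, Ilast = 140),
#'                      class = "KineticCurve"))  # 2 (washout)
#' @export
kineticSER <- function(curve, eps = 1e-8) {
  denom <- curve$Ilast - curve$I0
  if (abs(denom) < eps * (abs(curve$I0) + 1))
    stop("SER undefined: last-frame intensity equals pre-contrast intensity")
  (curve$Iinit - curve$I0) / denom
}
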