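# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's stream afterwards. Keeps per-lesion streams independent of call order.
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}

# Derive a child seed from a parent seed and a counter; stays below 2^31.
childSeed <- function(seed, counter) {
  as.integer((as.double(seed) * 48271 + as.double(counter) * 9973) %% 2147483629)
}

# -Σ p log2 p with the 0·log0 = 0 convention.
entropyBits <- function(p) {
  p <- p[p > 0]
  if (!length(p)) return(0)
  -sum(p * log2(p))
}

# Shift a matrix by (dr, dc) with replicated (Neumann) borders.
shiftMat <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  ri <- pmin(pmax(seq_len(nr) + dr, 1L), nr)
  ci <- pmin(pmax(seq_len(nc) + dc, 1L), nc)
  m[ri, ci, drop = FALSE]
}

# 5-point Laplacian with replicated borders.
laplacianMat <- function(m) {
  shiftMat(m, 1L, 0L) + shiftMat(m, -1L, 0L) +
    shiftMat(m, 0L, 1L) + shiftMat(m, 0L, -1L) - 4 * m
}

# Central-difference gradient; returns list(dr, dc).
gradientMat <- function(m) {
  list(dr = (shiftMat(m, 1L, 0L) - shiftMat(m, -1L, 0L)) / 2,
       dc = (shiftMat(m, 0L, 1L) - shiftMat(m, 0L, -1L)) / 2)
}

# Bilinear interpolation of matrix `m` at (row, col) positions (1-based, may
# be fractional); positions are clamped to the grid.
bilinearAt <- function(m, r, c) {
  nr <- nrow(m); nc <- ncol(m)
  r <- pmin(pmax(r, 1), nr); c <- pmin(pmax(c, 1), nc)
  r0 <- pmin(floor(r), nr - 1L); c0 <- pmin(floor(c), nc - 1L)
  fr <- r - r0; fc <- c - c0
  m[cbind(r0, c0)] * (1 - fr) * (1 - fc) +
    m[cbind(r0 + 1, c0)] * fr * (1 - fc) +
    m[cbind(r0, c0 + 1)] * (1 - fr) * fc +
    m[cbind(r0 + 1, c0 + 1)] * fr * fc
}

#' Dice overlap between two binary masks
#'
#' @param a,b logical matrices of the same dimension.
#' @return Dice similarity coefficient in \[0, 1\].
#' @export
diceCoefficient <- function(a, b) {
  a <- as.logical(a); b <- as.logical(b)
  stopifnot(length(a) == length(b))
  denom <- sum(a) + sum(b)
  if (denom == 0) return(1)
  2 * sum(a & b) / denom
}

# Shoelace area of a closed polygon given as n x 2 (x, y) vertices
# (first vertex not repeated).
polygonArea <- function(v) {
  x <- v[, 1]; y <- v[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  abs(sum(x * yn - xn * y)) / 2
}

# Rasterize a closed polygon (n x 2, columns = (row, col), 1-based pixel
# coordinates) onto a logical matrix of dimension `dm`; pixel centers inside
# the polygon (even-odd rule) are TRUE.
rasterizePolygon <- function(v, dm) {
  bnd <- rbind(v, v[1, , drop = FALSE])
  rr <- seq_len(dm[1]); cc <- seq_len(dm[2])
  # restrict the point-in-polygon test to the polygon's bounding box
  rkeep <- rr[rr >= floor(min(v[, 1])) & rr <= ceiling(max(v[, 1]))]
  ckeep <- cc[cc >= floor(min(v[, 2])) & cc <= ceiling(max(v[, 2]))]
  out <- matrix(FALSE, dm[1], dm[2])
  if (!length(rkeep) || !length(ckeep)) return(out)
  grid <- cbind(rep(rkeep, times = length(ckeep)),
                rep(ckeep, each = length(rkeep)))
  inside <- mgcv::in.out(bnd, grid)
  out[grid[inside, , drop = FALSE]] <- TRUE
  out
}

# Offset a closed polygon outward by `d` along per-vertex normals (oriented
# away from the centroid). Compensates the half-pixel gap between a polygon
# through boundary-pixel centers and the pixel-area boundary.
outwardOffset <- function(v, d = 0.5) {
  n <- nrow(v)
  prv <- v[c(n, seq_len(n - 1)), , drop = FALSE]
  nxt <- v[c(seq_len(n)[-1], 1), , drop = FALSE]
  tg <- nxt - prv
  len <- sqrt(rowSums(tg^2)); len[len == 0] <- 1
  nrm <- cbind(tg[, 2], -tg[, 1]) / len
  ctr <- colMeans(v)
  sgn <- sign(rowSums(nrm * sweep(v, 2, ctr)))
  sgn[sgn == 0] <- 1
  v + d * nrm * sgn
}

# Ordered outer boundary polygon of a binary mask as an n x 2 matrix of
# (row, col) 1-based pixel-center coordinates.
maskBoundary <- function(mask) {
  oc <- EBImage::ocontour(matrix(as.integer(mask), nrow(mask), ncol(mask)))
  if (!length(oc)) stop("mask has no boundary (empty mask)")
  v <- oc[[1]] + 1  # EBImage contours are 0-based; column 1 is the row index
  colnames(v) <- c("row", "col")
  v
}

# TRUE when the closed polygon (n x 2) has no self-intersection.
isSimplePolygon <- function(v) {
  n <- nrow(v)
  if (n < 3) return(FALSE)
  seg <- cbind(v, rbind(v[-1, , drop = FALSE], v[1, , drop = FALSE]))
  cross <- function(ox, oy, ax, ay, bx, by) (ax - ox) * (by - oy) - (ay - oy) * (bx - ox)
  for (i in seq_len(n - 2)) {
    js <- (i + 2):n
    js <- js[!(i == 1 & js == n)]  # skip segments sharing a vertex
    if (!length(js)) next
    p1 <- seg[i, 1:2]; p2 <- seg[i, 3:4]
    q1 <- seg[js, 1:2, drop = FALSE]; q2 <- seg[js, 3:4, drop = FALSE]
    d1 <- cross(p1[1], p1[2], p2[1], p2[2], q1[, 1], q1[, 2])
    d2 <- cross(p1[1], p1[2], p2[1], p2[2], q2[, 1], q2[, 2])
    d3 <- cross(q1[, 1], q1[, 2], q2[, 1], q2[, 2], p1[1], p1[2])
    d4 <- cross(q1[, 1], q1[, 2], q2[, 1], q2[, 2], p2[1], p2[2])
    if (any(d1 * d2 < 0 & d3 * d4 < 0)) return(FALSE)
  }
  TRUE
}
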