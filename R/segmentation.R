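# Two-step lesion segmentation: fuzzy c-means initialisation refined by a
# gradient-vector-flow (GVF) active contour.

#' Fuzzy c-means clustering of intensities
#'
#' Standard FCM with fuzziness exponent `m`: memberships
#' `u_ik = 1 / sum_l (d_ik/d_il)^(2/(m-1))`, centroids
#' `c_k = sum_i u_ik^m x_i / sum_i u_ik^m`, objective
#' `J = sum_ik u_ik^m d_ik^2`. Centroids are initialised at evenly spaced
#' quantiles (deterministic) unless `seed` is given, in which case they start
#' from a random sample of distinct values.
#'
#' @param x numeric vector (or matrix, flattened) of intensities.
#' @param centers number of clusters (>= 2).
#' @param m fuzziness exponent (> 1).
#' @param tol stop when the largest centroid shift falls below `tol` times the
#'   intensity range.
#' @param maxIter iteration cap.
#' @param seed optional seed for random initialisation.
#' @return an `FCMResult` list: `membership` (n x c, rows sum to 1),
#'   `centroids` (ascending), `nIter`, `converged`, `objective` (per-iteration
#'   trace), `degenerate`.
#' @examples
#' r <- fcmCluster(c(rep(10, 60), rep(200, 40)), centers = 2)
#' round(r$centroids)
#' @export
fcmCluster <- function(x, centers = 3L, m = 2, tol = 1e-4, maxIter = 100L,
                       seed = NULL) {
  x <- as.numeric(x)
  if (!length(x)) stop("empty input")
  if (centers < 2L) stop("need at least 2 clusters")
  if (m <= 1) stop("fuzziness exponent must exceed 1")
  rng <- diff(range(x))
  if (rng < .Machine$double.eps * (abs(mean(x)) + 1)) {
    # constant image: a single effective cluster
    u <- matrix(1 / centers, length(x), centers)
    return(structure(list(membership = u, centroids = rep(x[1], centers),
                          nIter = 0L, converged = FALSE,
                          objective = numeric(0), degenerate = TRUE),
                     class = "FCMResult"))
  }
  cen <- if (is.null(seed)) {
    as.numeric(quantile(x, probs = (seq_len(centers) - 0.5) / centers))
  } else {
    withSeed(seed, sort(sample(unique(x), centers)))
  }
  n <- length(x)
  obj <- numeric(0)
  converged <- FALSE
  iter <- 0L
  eps <- .Machine$double.eps
  for (iter in seq_len(maxIter)) {
    d2 <- outer(x, cen, function(a, b) (a - b)^2) + eps
    u <- d2^(-1 / (m - 1))
    u <- u / rowSums(u)
    um <- u^m
    cenNew <- colSums(um * x) / colSums(um)
    obj <- c(obj, sum(um * (outer(x, cenNew, function(a, b) (a - b)^2))))
    shift <- max(abs(cenNew - cen))
    cen <- cenNew
    if (shift < tol * rng) { converged <- TRUE; break }
  }
  ord <- order(cen)
  d2 <- outer(x, cen[ord], function(a, b) (a - b)^2) + eps
  u <- d2^(-1 / (m - 1)); u <- u / rowSums(u)
  structure(list(membership = u, centroids = cen[ord], nIter = iter,
                 converged = converged, objective = obj, degenerate = FALSE),
            class = "FCMResult")
}

#' Gradient vector flow field of an edge map
#'
#' Iterates the Xu-Prince diffusion update
#' `v <- v + mu * laplacian(v) - (v - grad f) * |grad f|^2`
#' (unit time step) from `v = grad f`, where `f` is the edge map normalised to
#' \[0, 1\]. Near strong edges the field approximates `grad f`; in homogeneous
#' regions it diffuses edge information inward.
#'
#' @param edgeMap non-negative matrix (e.g. gradient magnitude).
#' @param mu regularisation weight; stability requires `mu <= 0.25` at unit
#'   time step.
#' @param nIter diffusion iterations.
#' @return list with components `dr`, `dc` (row/column force components).
#' @export
gvfField <- function(edgeMap, mu = 0.2, nIter = 80L) {
  if (any(!is.finite(edgeMap))) stop("non-finite edge map")
  if (any(edgeMap < 0)) stop("edge map must be non-negative")
  f <- edgeMap
  mx <- max(f)
  if (mx > 0) f <- f / mx
  g <- gradientMat(f)
  b <- g$dr^2 + g$dc^2
  u <- g$dr; v <- g$dc
  for (i in seq_len(nIter)) {
    u <- u + mu * laplacianMat(u) - b * (u - g$dr)
    v <- v + mu * laplacianMat(v) - b * (v - g$dc)
  }
  list(dr = u, dc = v)
}

# Resample a closed polygon to n vertices at uniform arc length.
resampleContour <- function(v, n) {
  closed <- rbind(v, v[1, , drop = FALSE])
  seg <- sqrt(rowSums(diff(closed)^2))
  s <- c(0, cumsum(seg))
  total <- s[length(s)]
  if (total <= 0) return(matrix(rep(v[1, ], each = n), n, 2))
  at <- seq(0, total, length.out = n + 1)[-(n + 1)]
  idx <- findInterval(at, s, rightmost.closed = TRUE)
  idx <- pmin(idx, nrow(closed) - 1L)
  frac <- (at - s[idx]) / pmax(seg[idx], .Machine$double.eps)
  closed[idx, , drop = FALSE] +
    (closed[idx + 1L, , drop = FALSE] - closed[idx, , drop = FALSE]) * frac
}

# Discrete snake energy: internal membrane/thin-plate terms plus external
# potential -edgeMap sampled at the vertices.
.snakeEnergy <- function(v, alpha, beta, edgeMap) {
  d1 <- diff(rbind(v, v[1, , drop = FALSE]))
  vp <- rbind(v[nrow(v), , drop = FALSE], v, v[1, , drop = FALSE])
  d2 <- vp[3:(nrow(v) + 2), , drop = FALSE] - 2 * vp[2:(nrow(v) + 1), , drop = FALSE] +
    vp[1:nrow(v), , drop = FALSE]
  e <- alpha * sum(d1^2) + beta * sum(d2^2)
  if (!is.null(edgeMap))
    e <- e - sum(bilinearAt(edgeMap, v[, 1], v[, 2]))
  e
}

#' Evolve an active contour under a GVF force field
#'
#' Semi-implicit iteration `x <- solve(I + gamma A, x + gamma F(x))` where `A`
#' is the cyclic pentadiagonal internal-energy matrix built from `alpha`
#' (tension) and `beta` (rigidity). After each step the contour is resampled
#' to uniform arc length. A step is accepted only if the discrete snake
#' energy does not increase; otherwise the step size is halved (backtracking),
#' so the recorded energy trace is non-increasing.
#'
#' @param init n x 2 matrix of (row, col) vertices of a closed polygon
#'   (first vertex not repeated), inside the image.
#' @param field GVF field from [gvfField()].
#' @param alpha,beta,gamma positive tension, rigidity and step size.
#' @param maxIter iteration cap.
#' @param tol stop when mean vertex displacement per iteration drops below
#'   `tol` pixels.
#' @param nVertices number of vertices after resampling.
#' @param edgeMap optional edge map used in the external energy term of the
#'   trace (defaults to the field magnitude potential being omitted).
#' @return a `SnakeContour` list: `vertices`, `energyTrace`, `converged`,
#'   `nIter`.
#' @export
evolveSnake <- function(init, field, alpha = 0.1, beta = 0.1, gamma = 1,
                        maxIter = 200L, tol = 0.05, nVertices = 100L,
                        edgeMap = NULL) {
  if (alpha <= 0 || beta <= 0 || gamma <= 0)
    stop("alpha, beta and gamma must be positive")
  dm <- dim(field$dr)
  if (any(init[, 1] < 1 | init[, 1] > dm[1] | init[, 2] < 1 | init[, 2] > dm[2]))
    stop("initial contour leaves the image")
  x <- resampleContour(init, nVertices)
  n <- nVertices
  # cyclic pentadiagonal internal-force matrix
  A <- matrix(0, n, n)
  idx <- function(i) ((i - 1) %% n) + 1
  for (i in seq_len(n)) {
    A[i, idx(i - 2)] <- A[i, idx(i - 2)] + beta
    A[i, idx(i - 1)] <- A[i, idx(i - 1)] - alpha - 4 * beta
    A[i, i] <- A[i, i] + 2 * alpha + 6 * beta
    A[i, idx(i + 1)] <- A[i, idx(i + 1)] - alpha - 4 * beta
    A[i, idx(i + 2)] <- A[i, idx(i + 2)] + beta
  }
  invCache <- new.env(parent = emptyenv())
  getInv <- function(g) {
    key <- format(g, digits = 12)
    if (is.null(invCache[[key]]))
      invCache[[key]] <- solve(diag(n) + g * A)
    invCache[[key]]
  }
  clampGrid <- function(v) {
    v[, 1] <- pmin(pmax(v[, 1], 1), dm[1])
    v[, 2] <- pmin(pmax(v[, 2], 1), dm[2])
    v
  }
  energy <- .snakeEnergy(x, alpha, beta, edgeMap)
  trace <- energy
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(maxIter)) {
    fr <- bilinearAt(field$dr, x[, 1], x[, 2])
    fc <- bilinearAt(field$dc, x[, 1], x[, 2])
    g <- gamma
    accepted <- FALSE
    for (bt in 1:20) {
      M <- getInv(g)
      cand <- cbind(M %*% (x[, 1] + g * fr), M %*% (x[, 2] + g * fc))
      cand <- clampGrid(resampleContour(cand, n))
      eNew <- .snakeEnergy(cand, alpha, beta, edgeMap)
      if (eNew <= energy + 1e-12 * (abs(energy) + 1)) { accepted <- TRUE; break }
      g <- g / 2
    }
    if (!accepted) { converged <- TRUE; break }   # local minimum of the energy
    disp <- mean(sqrt(rowSums((cand - x)^2)))
    x <- cand
    energy <- eNew
    trace <- c(trace, energy)
    if (polygonArea(x) < 4)
      stop("contour collapsed (area < 4 px^2) at iteration ", iter)
    if (disp < tol) { converged <- TRUE; break }
  }
  structure(list(vertices = x, energyTrace = trace, converged = converged,
                 nIter = iter), class = "SnakeContour")
}

#' Default segmentation parameters
#'
#' @return list of tunables: FCM (`centers = 3`, `m = 2` on the first
#'   post-contrast frame), edge map smoothing (`sigmaPx = 1`), GVF
#'   (`mu = 0.2`, `gvfIter = 80`), snake (`alpha = 0.1`, `beta = 0.1`,
#'   `gamma = 1`, `snakeIter = 200`, `nVertices = 100`), ROI margin and the
#'   minimum candidate area.
#' @export
defaultSegmentationConfig <- function() {
  list(centers = 3L, m = 2, fcmTol = 1e-4, fcmIter = 100L,
       sigmaPx = 1, mu = 0.2, gvfIter = 80L,
       alpha = 0.1, beta = 0.1, gamma = 1, snakeIter = 200L,
       snakeTol = 0.05, nVertices = 100L,
       roiMargin = 10L, minArea = 9L, minContrast = 0.5, useTruth = FALSE)
}

#' Segment a lesion from a study
#'
#' FCM (3 clusters) on the first post-contrast DCE frame inside the ROI; the
#' brightest cluster's largest connected component seeds a closed contour,
#' which a GVF snake refines against the gradient-magnitude edge map of the
#' Gaussian-smoothed frame; the final polygon is filled and returned as a
#' full-grid mask.
#'
#' @param study a [LesionStudy-class].
#' @param roi integer vector `c(row0, col0, row1, col1)`; defaults to the
#'   bounding box of `trueMask` padded by `config$roiMargin` (phantom mode).
#' @param config see [defaultSegmentationConfig()].
#' @return logical matrix (full grid), a single connected component, with
#'   attributes `"contour"` (the `SnakeContour`) and `"fcm"`.
#' @export
segmentLesion <- function(study, roi = NULL, config = defaultSegmentationConfig()) {
  dm <- dim(study@trueMask)
  if (is.null(roi)) {
    w <- which(study@trueMask, arr.ind = TRUE)
    m <- config$roiMargin
    roi <- c(max(min(w[, 1]) - m, 1), max(min(w[, 2]) - m, 1),
             min(max(w[, 1]) + m, dm[1]), min(max(w[, 2]) + m, dm[2]))
  }
  rr <- roi[1]:roi[3]; cc <- roi[2]:roi[4]
  win <- study@dce[rr, cc, 2]

  fcm <- fcmCluster(win, centers = config$centers, m = config$m,
                    tol = config$fcmTol, maxIter = config$fcmIter)
  if (fcm$degenerate) stop("empty brightest cluster: ROI has no contrast")
  contrast <- (max(fcm$centroids) - min(fcm$centroids)) /
    max(min(fcm$centroids), .Machine$double.eps)
  if (contrast < config$minContrast)
    stop("empty brightest cluster: ROI contrast ", signif(contrast, 3),
         " below the minimum of ", config$minContrast)
  hard <- max.col(fcm$membership)
  # enhancing candidate: every cluster whose centroid lies above the midpoint
  # between the background (darkest) and brightest centroids, so lesions
  # whose heterogeneous interior spans two clusters are not halved
  mid <- (min(fcm$centroids) + max(fcm$centroids)) / 2
  bright <- which(fcm$centroids > mid)
  cand <- matrix(hard %in% bright, length(rr), length(cc))
  lab <- EBImage::bwlabel(matrix(as.integer(cand), length(rr), length(cc)))
  sizes <- tabulate(as.integer(lab))
  if (!length(sizes) || max(sizes) < config$minArea)
    stop("empty brightest cluster: no candidate component of at least ",
         config$minArea, " px")
  comp <- lab == which.max(sizes)

  init <- maskBoundary(comp)
  sm <- as.matrix(EBImage::gblur(EBImage::Image(win), sigma = config$sigmaPx))
  g <- gradientMat(sm)
  edge <- sqrt(g$dr^2 + g$dc^2)
  field <- gvfField(edge, mu = config$mu, nIter = config$gvfIter)
  snk <- evolveSnake(init, field, alpha = config$alpha, beta = config$beta,
                     gamma = config$gamma, maxIter = config$snakeIter,
                     tol = config$snakeTol, nVertices = config$nVertices,
                     edgeMap = edge / max(max(edge), .Machine$double.eps))
  fillWin <- rasterizePolygon(outwardOffset(snk$vertices, 0.5),
                              c(length(rr), length(cc)))
  # keep the largest component of the filled polygon (robustness to grazing)
  lab2 <- EBImage::bwlabel(matrix(as.integer(fillWin), nrow(fillWin)))
  sz2 <- tabulate(as.integer(lab2))
  if (!length(sz2)) stop("snake produced an empty region")
  fillWin <- lab2 == which.max(sz2)
  mask <- matrix(FALSE, dm[1], dm[2])
  mask[rr, cc] <- fillWin
  attr(mask, "contour") <- snk
  attr(mask, "fcm") <- fcm
  mask
}
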