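# Local-hyperplane RELIEF (LHR) feature weighting.
#
# RELIEF-family margin weighting in which the nearest-hit and nearest-miss
# *points* are replaced by the orthogonal projections of each sample onto the
# local affine hyperplanes spanned by its K nearest same-class and
# other-class neighbours, computed in the current weighted metric.

#' Project a point onto the local hyperplane of its neighbours
#'
#' Finds the affine combination `sum_k alpha_k h_k` (with
#' `sum_k alpha_k = 1`) of the K neighbour rows of `H` minimising the
#' weighted squared distance to `x` plus a ridge penalty
#' `lambda * ||alpha||^2`, by solving the equality-constrained normal
#' equations.
#'
#' @param x numeric vector (one sample).
#' @param H K x p matrix of neighbours (rows).
#' @param lambda ridge penalty on the combination coefficients (>= 0).
#' @param w non-negative feature weights defining the diagonal metric;
#'   defaults to uniform.
#' @return list: `projection`, `distance` (in the weighted metric), `alpha`.
#' @export
localHyperplaneProjection <- function(x, H, lambda = 1, w = NULL) {
  H <- rbind(H)
  K <- nrow(H); p <- ncol(H)
  if (K < 1) stop("need at least one neighbour")
  if (lambda < 0) stop("lambda must be non-negative")
  if (is.null(w)) w <- rep(1, p)
  if (K == 1) {
    proj <- drop(H)
    return(list(projection = proj,
                distance = sqrt(sum(w * (x - proj)^2)), alpha = 1))
  }
  Hw <- sweep(H, 2, w, "*")
  G <- Hw %*% t(H) + lambda * diag(K)
  rhs <- drop(Hw %*% x)
  kkt <- rbind(cbind(G, 1), c(rep(1, K), 0))
  sol <- tryCatch(solve(kkt, c(rhs, 1)), error = function(e)
    stop("singular projection system; use lambda > 0"))
  alpha <- sol[seq_len(K)]
  proj <- drop(crossprod(H, alpha))
  list(projection = proj, distance = sqrt(sum(w * (x - proj)^2)),
       alpha = alpha)
}

#' Local-hyperplane RELIEF feature weights
#'
#' Iterative scheme: starting from uniform weights, for every sample find the
#' K nearest same-class (hit) and other-class (miss) neighbours under the
#' current weighted squared-Euclidean metric, project the sample onto the two
#' local hyperplanes, and accumulate the per-feature margin
#' `|x - proj_miss| - |x - proj_hit|`. New weights are the positive part of
#' the summed margins, L1-normalized; iteration stops when the largest weight
#' change falls below `tol`.
#'
#' @param X numeric matrix (samples x features), pre-normalized.
#' @param y two-class factor or character vector.
#' @param K neighbours per class (each class must have more than K samples).
#' @param lambda ridge penalty of the hyperplane projection.
#' @param nIter outer-iteration cap.
#' @param tol convergence tolerance on the weights.
#' @param m size of the selected subset recorded on the result.
#' @param zCut noise floor: a feature's summed margin is kept only when its
#'   z-score (sum over samples divided by `sd * sqrt(n)` of the per-sample
#'   contributions) exceeds `zCut`. Margins of uninformative features are
#'   zero-mean noise whose positive part would otherwise be renormalized into
#'   arbitrarily spiky weights; the floor denoises them.
#' @return a [FeatureWeights-class]. When no margin survives the noise floor
#'   the weights fall back to uniform and `degenerate` is TRUE. The attribute
#'   `"margins"` carries the raw (unthresholded) per-feature summed margins
#'   of the last iteration.
#' @export
lhrWeights <- function(X, y, K = 5L, lambda = 1.0, nIter = 50L, tol = 1e-4,
                       m = 5L, zCut = 2.5) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("f", seq_len(ncol(X)))
  y <- as.character(y)
  cls <- unique(y)
  if (length(cls) != 2) stop("need exactly two classes")
  if (min(table(y)) <= K)
    stop("each class needs more than K = ", K, " samples")
  n <- nrow(X); p <- ncol(X)
  w <- rep(1 / p, p)
  names(w) <- colnames(X)
  converged <- FALSE
  degenerate <- FALSE
  iter <- 0L
  margins <- numeric(p)
  alive <- rep(TRUE, p)   # monotone pruning: a feature failing the noise
                          # floor once stays out (no spurious re-entry once
                          # the metric has concentrated)
  for (iter in seq_len(nIter)) {
    contrib <- matrix(0, n, p)   # per-sample margin contributions
    # pairwise squared distances in the weighted metric
    Xw <- sweep(X, 2, sqrt(w), "*")
    sq <- rowSums(Xw^2)
    D <- outer(sq, sq, "+") - 2 * tcrossprod(Xw)
    diag(D) <- Inf
    for (i in seq_len(n)) {
      same <- which(y == y[i]); same <- same[same != i]
      other <- which(y != y[i])
      hits <- same[order(D[i, same])[seq_len(K)]]
      miss <- other[order(D[i, other])[seq_len(K)]]
      ph <- localHyperplaneProjection(X[i, ], X[hits, , drop = FALSE],
                                      lambda = lambda, w = w)
      pm <- localHyperplaneProjection(X[i, ], X[miss, , drop = FALSE],
                                      lambda = lambda, w = w)
      contrib[i, ] <- abs(X[i, ] - pm$projection) -
        abs(X[i, ] - ph$projection)
    }
    margins <- colSums(contrib)
    csd <- apply(contrib, 2, sd) * sqrt(n)
    z <- ifelse(csd > 0, margins / csd, 0)
    pos <- ifelse(alive & z > zCut, pmax(margins, 0), 0)
    if (sum(pos) <= 0) {
      if (iter == 1L) {            # nothing informative at all
        w <- rep(1 / p, p); names(w) <- colnames(X)
        degenerate <- TRUE
      } else converged <- TRUE     # keep the last informative weighting
      break
    }
    alive <- pos > 0
    wNew <- pos / sum(pos)
    names(wNew) <- colnames(X)
    delta <- max(abs(wNew - w))
    w <- wNew
    if (delta < tol) { converged <- TRUE; break }
  }
  ranking <- colnames(X)[order(-w, seq_len(p))]
  out <- new("FeatureWeights", weights = w, ranking = ranking,
             selected = ranking[seq_len(min(m, p))], nIter = iter,
             converged = converged, degenerate = degenerate)
  attr(out, "margins") <- setNames(margins, colnames(X))
  out
}

#' Select the top-m features by weight
#'
#' @param fw a [FeatureWeights-class].
#' @param m subset size, `1 <= m <=` number of features. Ties are already
#'   broken by the fixed feature order in the ranking.
#' @return character vector of the m selected feature names.
#' @export
selectSubset <- function(fw, m = 5L) {
  p <- length(fw@weights)
  if (m < 1 || m > p) stop("m must be between 1 and ", p)
  fw@ranking[seq_len(m)]
}
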