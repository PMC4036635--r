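# Shared fixtures: analytic shapes, toy studies and independent oracles.

diskMask <- function(r, dim = c(2 * r + 21, 2 * r + 21), ctr = dim / 2 + 0.5) {
  rows <- matrix(seq_len(dim[1]), dim[1], dim[2])
  cols <- matrix(seq_len(dim[2]), dim[1], dim[2], byrow = TRUE)
  sqrt((rows - ctr[1])^2 + (cols - ctr[2])^2) <= r
}

ellipseMask <- function(a, b, dim = c(2 * a + 21, 2 * a + 21)) {
  ctr <- dim / 2 + 0.5
  rows <- matrix(seq_len(dim[1]), dim[1], dim[2])
  cols <- matrix(seq_len(dim[2]), dim[1], dim[2], byrow = TRUE)
  ((rows - ctr[1]) / a)^2 + ((cols - ctr[2]) / b)^2 <= 1
}

starMask <- function(rMean, nPoints = 8, amp = 0.4, dim = c(101, 101)) {
  ctr <- dim / 2 + 0.5
  rows <- matrix(seq_len(dim[1]), dim[1], dim[2])
  cols <- matrix(seq_len(dim[2]), dim[1], dim[2], byrow = TRUE)
  th <- atan2(cols - ctr[2], rows - ctr[1])
  rr <- sqrt((rows - ctr[1])^2 + (cols - ctr[2])^2)
  rr <= rMean * (1 + amp * cos(nPoints * th))
}

# Vertex set of the 8-segment quadric Koch curve (von Koch "Minkowski
# sausage"); its similarity dimension is log(8)/log(4) = 1.5.
kochQuadricPoints <- function(depth = 4, step = 1) {
  # L-system: F -> F+F-F-FF+F+F-F (+ = left 90 deg, - = right 90 deg)
  s <- "F"
  for (i in seq_len(depth)) {
    s <- gsub("F", "f+f-f-ff+f+f-f", s, fixed = TRUE)
    s <- toupper(s)
  }
  moves <- strsplit(s, "")[[1]]
  dir <- 0
  x <- 0; y <- 0
  xs <- x; ys <- y
  for (mv in moves) {
    if (mv == "F") {
      x <- x + step * cos(dir); y <- y + step * sin(dir)
      xs <- c(xs, x); ys <- c(ys, y)
    } else if (mv == "+") dir <- dir + pi / 2
    else if (mv == "-") dir <- dir - pi / 2
  }
  cbind(round(xs), round(ys))
}

# A minimal in-memory study: homogeneous lesion on flat background.
mkToyStudy <- function(r = 15, dim = c(96, 96), epe = 0.8, ser = 2,
                       adc = 1.0, adcBg = 2.0, nPost = 9, label = "malignant") {
  mask <- diskMask(r, dim)
  I0 <- ifelse(mask, 150, 60)
  dce <- array(0, c(dim, 1 + nPost))
  dce[, , 1] <- I0
  for (j in seq_len(nPost)) {
    frac <- (j - 1) / (nPost - 1)
    enh <- ifelse(mask, epe * (1 + frac * (1 / ser - 1)), 0)
    dce[, , 1 + j] <- I0 * (1 + enh)
  }
  adcField <- ifelse(mask, adc, adcBg)
  b0 <- ifelse(mask, 550, 430)
  b800 <- b0 * exp(-800 * adcField * 1e-3)
  new("LesionStudy", dce = dce, dwiB0 = b0, dwiB800 = b800,
      bValues = c(0, 800), trueMask = mask, label = label,
      cohortTag = "train15T", studyId = "toy001", pixelSpacing = 1,
      params = list())
}

# ---------------------------------------------------------------------------
# Independent oracles

# Naive Haralick features computed by explicit loops straight from the
# textbook definitions (base-2 logs, 0-based levels).
naiveHaralick <- function(p) {
  ng <- nrow(p)
  lg <- function(v) ifelse(v > 0, log2(v), 0)
  px <- rowSums(p); py <- colSums(p)
  mux <- 0; muy <- 0
  for (i in 1:ng) { mux <- mux + (i - 1) * px[i]; muy <- muy + (i - 1) * py[i] }
  sx2 <- 0; sy2 <- 0
  for (i in 1:ng) { sx2 <- sx2 + (i - 1 - mux)^2 * px[i]
                    sy2 <- sy2 + (i - 1 - muy)^2 * py[i] }
  asm <- 0; con <- 0; cor <- 0; idm <- 0; ent <- 0
  for (i in 1:ng) for (j in 1:ng) {
    v <- p[i, j]
    asm <- asm + v^2
    con <- con + (i - j)^2 * v
    cor <- cor + (i - 1) * (j - 1) * v
    idm <- idm + v / (1 + (i - j)^2)
    ent <- ent - v * lg(v)
  }
  cor <- if (sx2 > 0 && sy2 > 0) (cor - mux * muy) / sqrt(sx2 * sy2) else 0
  psum <- numeric(2 * ng - 1)
  pdif <- numeric(ng)
  for (i in 1:ng) for (j in 1:ng) {
    psum[i + j - 1] <- psum[i + j - 1] + p[i, j]
    pdif[abs(i - j) + 1] <- pdif[abs(i - j) + 1] + p[i, j]
  }
  sa <- sum((0:(2 * ng - 2)) * psum)
  sv <- sum(((0:(2 * ng - 2)) - sa)^2 * psum)
  se <- -sum(psum * lg(psum))
  da <- sum((0:(ng - 1)) * pdif)
  dv <- sum(((0:(ng - 1)) - da)^2 * pdif)
  de <- -sum(pdif * lg(pdif))
  hx <- -sum(px * lg(px)); hy <- -sum(py * lg(py))
  hxy1 <- 0; hxy2 <- 0
  for (i in 1:ng) for (j in 1:ng) {
    hxy1 <- hxy1 - p[i, j] * lg(px[i] * py[j])
    hxy2 <- hxy2 - px[i] * py[j] * lg(px[i] * py[j])
  }
  imc1 <- if (max(hx, hy) > 0) (ent - hxy1) / max(hx, hy) else 0
  imc2 <- sqrt(max(1 - exp(-2 * (hxy2 - ent)), 0))
  c(asm = asm, inertia = con, correlation = cor,
    inverse_difference_moment = idm, sum_average = sa, sum_variance = sv,
    sum_entropy = se, entropy = ent, difference_average = da,
    difference_variance = dv, difference_entropy = de,
    info_correlation_1 = imc1, info_correlation_2 = imc2)
}

# Naive GLCM by looping over every pixel pair.
naiveGLCM <- function(img, mask, ng, offsets, symmetric = TRUE) {
  counts <- matrix(0, ng, ng)
  nr <- nrow(img); nc <- ncol(img)
  for (off in offsets) for (r in 1:nr) for (c in 1:nc) {
    r2 <- r + off[1]; c2 <- c + off[2]
    if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc) next
    if (!mask[r, c] || !mask[r2, c2]) next
    i <- img[r, c] + 1; j <- img[r2, c2] + 1
    counts[i, j] <- counts[i, j] + 1
  }
  if (symmetric) counts <- counts + t(counts)
  counts / sum(counts)
}

# Exhaustive best-cutoff search over every midpoint and both polarities.
bruteBestCutoff <- function(pos, neg) {
  u <- sort(unique(c(pos, neg)))
  cuts <- c(u[1] - 1, if (length(u) > 1) (u[-1] + u[-length(u)]) / 2,
            u[length(u)] + 1)
  best <- -Inf
  for (ct in cuts) for (dir in c("higher", "lower")) {
    sens <- if (dir == "higher") mean(pos > ct) else mean(pos < ct)
    spec <- if (dir == "higher") mean(neg <= ct) else mean(neg >= ct)
    best <- max(best, (sens + spec) / 2)
  }
  best
}

# Hand-coded classic RELIEF margins (nearest hit/miss points) in a weighted
# metric, one pass, for the K = 1 equivalence check.
handReliefMargins <- function(X, y, w) {
  n <- nrow(X); p <- ncol(X)
  m <- numeric(p)
  for (i in 1:n) {
    d <- colSums(w * (t(X) - X[i, ])^2)
    d[i] <- Inf
    hit <- which(y == y[i] & is.finite(d))
    mis <- which(y != y[i])
    h <- hit[which.min(d[hit])]
    s <- mis[which.min(d[mis])]
    m <- m + abs(X[i, ] - X[s, ]) - abs(X[i, ] - X[h, ])
  }
  m
}

# Small cached default-phantom cohort shared across test files.
.cohortCache <- new.env(parent = emptyenv())
sharedCohorts <- function() {
  if (is.null(.cohortCache$co)) {
    .cohortCache$co <- generateCohorts(
      defaultPhantomSpec("train15T", seed = 11, nBenign = 10, nMalignant = 10),
      defaultPhantomSpec("test30T", seed = 12, nBenign = 5, nMalignant = 5))
  }
  .cohortCache$co
}
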