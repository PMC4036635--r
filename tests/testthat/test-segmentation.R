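test_that("FCM separates a two-valued image and normalizes memberships", {
  x <- c(rep(10, 60), rep(200, 40))
  r <- fcmCluster(x, centers = 2)
  expect_equal(r$centroids, c(10, 200), tolerance = 1e-2)
  hard <- r$centroids[max.col(r$membership)]
  expect_equal(hard, ifelse(x < 100, r$centroids[1], r$centroids[2]))
  expect_equal(rowSums(r$membership), rep(1, length(x)), tolerance = 1e-9)
  expect_false(r$degenerate)
})

test_that("FCM objective is non-increasing and matches the e1071 solution", {
  set.seed(5)
  x <- c(rnorm(80, 10, 2), rnorm(60, 50, 4), rnorm(40, 120, 6))
  r <- fcmCluster(x, centers = 3, tol = 1e-8, maxIter = 200)
  expect_true(all(diff(r$objective) <= 1e-8 * abs(r$objective[-length(r$objective)])))
  ref <- e1071::cmeans(matrix(x), centers = matrix(sort(x)[c(30, 100, 160)]),
                       m = 2, iter.max = 300)
  expect_equal(sort(r$centroids), sort(as.numeric(ref$centers)),
               tolerance = 1e-2)
})

test_that("constant images raise the degenerate FCM flag", {
  r <- fcmCluster(rep(7, 50), centers = 3)
  expect_true(r$degenerate)
  expect_false(r$converged)
})

test_that("GVF field is zero for a flat edge map and points toward a ridge", {
  z <- gvfField(matrix(0, 16, 16))
  expect_equal(max(abs(z$dr)), 0)
  expect_equal(max(abs(z$dc)), 0)

  edge <- matrix(0, 32, 32); edge[, 16] <- 1   # vertical ridge at col 16
  f <- gvfField(edge, nIter = 200)
  expect_true(all(f$dc[, 5:14] > 0))    # left side pushes right
  expect_true(all(f$dc[, 18:27] < 0))   # right side pushes left
})

test_that("GVF diffusion reaches a stable fixed point", {
  set.seed(8)
  edge <- matrix(0, 24, 24)
  edge[8:16, 8:16] <- 1
  a <- gvfField(edge, nIter = 3000)
  b <- gvfField(edge, nIter = 3500)
  expect_lt(max(abs(a$dr - b$dr), abs(a$dc - b$dc)), 1e-6)
  expect_error(gvfField(matrix(NaN, 4, 4)), "non-finite")
})

test_that("snake locks onto a clean disk edge", {
  dim <- c(64, 64)
  disk <- diskMask(15, dim)
  img <- ifelse(disk, 200, 50)
  sm <- as.matrix(EBImage::gblur(EBImage::Image(img), sigma = 1))
  gr <- list(dr = (rbind(sm[-1, ], sm[64, ]) - rbind(sm[1, ], sm[-64, ])) / 2,
             dc = (cbind(sm[, -1], sm[, 64]) - cbind(sm[, 1], sm[, -64])) / 2)
  edge <- sqrt(gr$dr^2 + gr$dc^2)
  field <- gvfField(edge, nIter = 120)
  th <- seq(0, 2 * pi, length.out = 80)[-80]
  init <- cbind(32.5 + 20 * cos(th), 32.5 + 20 * sin(th))
  snk <- evolveSnake(init, field, edgeMap = edge / max(edge))
  rad <- sqrt(rowSums(sweep(snk$vertices, 2, c(32.5, 32.5))^2))
  expect_equal(mean(rad), 15, tolerance = 0.5)
  expect_true(isSimplePolygon(snk$vertices))
})

test_that("with no external force the snake shrinks and smooths", {
  field <- list(dr = matrix(0, 64, 64), dc = matrix(0, 64, 64))
  th <- seq(0, 2 * pi, length.out = 60)[-60]
  init <- cbind(32 + 18 * cos(th), 32 + 18 * sin(th))
  snk <- evolveSnake(init, field, maxIter = 50, tol = 1e-9)
  perim0 <- sum(sqrt(rowSums(diff(rbind(init, init[1, ]))^2)))
  v <- snk$vertices
  perim1 <- sum(sqrt(rowSums(diff(rbind(v, v[1, ]))^2)))
  expect_lt(perim1, perim0)
  expect_true(all(diff(snk$energyTrace) <= 1e-9))
})

test_that("segmentation recovers a noiseless homogeneous phantom disk", {
  sp <- defaultPhantomSpec("train15T", seed = 5)
  sp@fieldEffects$noiseSD <- 0
  for (cl in c("benign", "malignant")) {
    sp@classParams[[cl]]$irregularity <- 0
    sp@classParams[[cl]]$textureCV <- 0.01
  }
  s <- generateLesion(sp, "malignant", 1)
  m <- segmentLesion(s)
  expect_gte(diceCoefficient(m, s@trueMask), 0.95)
  lab <- EBImage::bwlabel(matrix(as.integer(m), nrow(m)))
  expect_equal(max(lab), 1)   # single connected component
})

test_that("an all-background ROI refuses to segment", {
  s <- sharedCohorts()$train[[1]]
  expect_error(segmentLesion(s, roi = c(2, 2, 30, 30)), "cluster|contrast")
})

test_that("snake energy decreases after burn-in on phantom segmentations", {
  for (s in sharedCohorts()$train[c(2, 12)]) {
    snk <- attr(segmentLesion(s), "contour")
    tr <- snk$energyTrace
    expect_gt(length(tr), 1)
    if (length(tr) > 5) {
      burned <- tr[-(1:5)]
      expect_true(all(diff(burned) <= 1e-9 * (abs(burned[-length(burned)]) + 1)))
    }
  }
})
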