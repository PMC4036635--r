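flatI <- function(mask) matrix(100, nrow(mask), ncol(mask))

test_that("a disk hits the circular limit values", {
  m <- diskMask(30)
  f <- computeMorphology(m, flatI(m), spacing = 1)
  expect_gte(f[["circularity"]], 0.95)
  expect_gte(f[["elongation"]], 0.95)
  expect_lte(f[["radial_length_entropy"]], 0.2)
  expect_equal(f[["fractal_dimension"]], 1.0, tolerance = 0.1)
  expect_equal(f[["compactness"]], 1 / f[["circularity"]])
  expect_gt(f[["solidity"]], 0.95)
  expect_equal(f[["area"]], sum(m))
  expect_lt(f[["eccentricity"]], 0.3)
  expect_equal(f[["heterogeneity"]], 0)
})

test_that("a 2:1 ellipse has elongation one half", {
  m <- ellipseMask(30, 15)
  f <- computeMorphology(m, flatI(m), spacing = 1)
  expect_equal(f[["elongation"]], 0.5, tolerance = 0.05)
  expect_equal(f[["eccentricity"]], sqrt(1 - 0.25), tolerance = 0.05)
})

test_that("a star is more spiculated and less compact than a disk", {
  star <- starMask(25)
  disk <- diskMask(round(sqrt(sum(star) / pi)))   # equal-area disk
  fs <- computeMorphology(star, flatI(star))
  fd <- computeMorphology(disk, flatI(disk))
  expect_gt(fs[["spiculation"]], fd[["spiculation"]])
  expect_gt(fs[["compactness"]], fd[["compactness"]])
  expect_gt(fs[["radial_length_entropy"]], fd[["radial_length_entropy"]])
})

test_that("radial profile is flat for a circle and halves for a 2:1 ellipse", {
  pc <- radialLengthProfile(diskMask(25))
  expect_true(all(pc > 0.9 & pc <= 1))
  expect_length(pc, nrow(maskBoundary(diskMask(25))))
  pe <- radialLengthProfile(ellipseMask(30, 15))
  expect_lt(abs(min(pe) / max(pe) - 0.5), 0.05)
})

test_that("box counting recovers known dimensions", {
  expect_equal(as.numeric(boxCountingDimension(cbind(1:256, 1))), 1.0,
               tolerance = 0.05)
  sq <- matrix(FALSE, 120, 120); sq[31:90, 31:90] <- TRUE
  bnd <- maskBoundary(sq)
  expect_equal(as.numeric(boxCountingDimension(bnd, c(1, 2, 4, 8))), 1.0,
               tolerance = 0.1)
  # quadric Koch curve, similarity dimension log(8)/log(4) = 1.5; counted at
  # scales coarse enough to sit inside the finite recursion's scaling window
  koch <- kochQuadricPoints(depth = 5)
  expect_equal(as.numeric(boxCountingDimension(koch, c(4, 8, 16, 32, 64))),
               1.5, tolerance = 0.1)
  expect_error(boxCountingDimension(cbind(1, 1), scales = 2), "2 scales")
})

test_that("features are invariant to translation and exact 90-degree rotation", {
  set.seed(3)
  m <- starMask(20, 7, 0.3)
  I <- matrix(runif(101 * 101, 50, 150), 101)
  a <- computeMorphology(m, I, 1)

  big <- matrix(FALSE, 130, 130); big[11:111, 16:116] <- m
  bigI <- matrix(0, 130, 130); bigI[11:111, 16:116] <- I
  expect_equal(computeMorphology(big, bigI, 1), a, tolerance = 1e-9,
               ignore_attr = TRUE)

  rotM <- t(m)[, ncol(m):1]
  rotI <- t(I)[, ncol(I):1]
  expect_equal(computeMorphology(rotM, rotI, 1), a, tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("area scales with spacing squared; shape features with size do not", {
  m1 <- diskMask(20); m2 <- diskMask(40)
  f1 <- computeMorphology(m1, flatI(m1), spacing = 2)
  f1b <- computeMorphology(m1, flatI(m1), spacing = 1)
  expect_equal(f1[["area"]], 4 * f1b[["area"]])
  f2 <- computeMorphology(m2, flatI(m2), spacing = 1)
  for (k in c("elongation", "solidity", "extent", "eccentricity", "circularity"))
    expect_equal(f2[[k]], f1b[[k]], tolerance = 0.05)
})

test_that("degenerate masks are rejected, border contact is flagged", {
  expect_error(computeMorphology(matrix(FALSE, 5, 5), matrix(0, 5, 5)), "empty")
  two <- matrix(FALSE, 20, 20); two[2:4, 2:4] <- TRUE; two[15:18, 15:18] <- TRUE
  expect_error(computeMorphology(two, matrix(0, 20, 20)), "single connected")
  edge <- matrix(FALSE, 20, 20); edge[1:6, 5:10] <- TRUE
  f <- computeMorphology(edge, matrix(1, 20, 20))
  expect_true(attr(f, "borderTouching"))
})
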