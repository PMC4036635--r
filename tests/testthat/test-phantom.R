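test_that("default specs encode the clinical class structure", {
  sp <- defaultPhantomSpec("train15T", seed = 1)
  expect_equal(sp@classParams$benign$radiusMeanMm, 6.5)  # half of 1.3 cm
  expect_lt(sp@classParams$malignant$adcMean, sp@classParams$benign$adcMean)
  expect_gt(sp@classParams$malignant$radiusMeanMm,
            sp@classParams$benign$radiusMeanMm)
  expect_gt(sp@classParams$malignant$irregularity,
            sp@classParams$benign$irregularity)
  expect_gt(sp@classParams$malignant$serMean, sp@classParams$benign$serMean)
  expect_identical(sp, defaultPhantomSpec("train15T", seed = 1))
  expect_error(defaultPhantomSpec("no-such-cohort"), "arg")
})

test_that("generated DWI inverts to the drawn ADC field when noise is off", {
  sp <- defaultPhantomSpec("train15T", seed = 2)
  sp@fieldEffects$noiseSD <- 0
  s <- generateLesion(sp, "benign", 3)
  amap <- computeADCMap(s@dwiB0, s@dwiB800, s@bValues)
  inside <- s@trueMask & amap$validMask
  relErr <- abs(amap$adc[inside] - s@params$adcField[inside]) /
    abs(s@params$adcField[inside])
  expect_lt(max(relErr), 1e-9)
})

test_that("zero irregularity gives a disk-like mask with elongation near 1", {
  sp <- defaultPhantomSpec("train15T", seed = 4)
  for (cl in c("benign", "malignant")) sp@classParams[[cl]]$irregularity <- 0
  s <- generateLesion(sp, "malignant", 2)
  f <- computeMorphology(s@trueMask, s@dce[, , 2], s@pixelSpacing)
  expect_gt(f[["elongation"]], 0.95)
  expect_gt(f[["circularity"]], 0.9)
})

test_that("lesion generation is deterministic and order-independent", {
  sp <- defaultPhantomSpec("train15T", seed = 9, nBenign = 2, nMalignant = 2)
  a <- generateLesion(sp, "malignant", 2)
  set.seed(777)  # stream derivation must shield against ambient RNG state
  b <- generateLesion(sp, "malignant", 2)
  expect_equal(a@dce, b@dce)
  expect_equal(a@dwiB800, b@dwiB800)
  expect_identical(a@trueMask, b@trueMask)
})

test_that("cohort generation keeps class counts and round-trips via NIfTI", {
  co <- sharedCohorts()
  expect_length(co$train, 20)
  expect_length(co$test, 10)
  expect_equal(sum(vapply(co$train, function(s) s@label, "") == "benign"), 10)

  dir1 <- file.path(tempfile("cohA"))
  dir2 <- file.path(tempfile("cohB"))
  writeCohort(co$test[1:3], dir1)
  writeCohort(co$test[1:3], dir2)
  expect_identical(readBin(file.path(dir1, "manifest.json"), "raw", 1e6),
                   readBin(file.path(dir2, "manifest.json"), "raw", 1e6))

  s <- co$test[[2]]
  back <- readStudy(dir1, s@studyId)
  expect_equal(back@dce, s@dce, tolerance = 1e-6)
  expect_equal(back@dwiB0, s@dwiB0, tolerance = 1e-6)
  expect_identical(back@trueMask, s@trueMask)
  expect_identical(back@label, s@label)
})

test_that("every emitted frame is finite and non-negative", {
  for (s in sharedCohorts()$test) {
    expect_true(all(is.finite(s@dce)) && all(s@dce >= 0))
    expect_true(all(is.finite(s@dwiB800)) && all(s@dwiB800 >= 0))
  }
})

test_that("field-strength gain shows up as the cohort intensity ratio", {
  n <- 25
  spTr <- defaultPhantomSpec("train15T", seed = 21, nBenign = n, nMalignant = n)
  spTe <- defaultPhantomSpec("test30T", seed = 22, nBenign = n, nMalignant = n)
  co <- generateCohorts(spTr, spTe)
  mTr <- mean(vapply(co$train, function(s) mean(s@dce[, , 1]), numeric(1)))
  mTe <- mean(vapply(co$test, function(s) mean(s@dce[, , 1]), numeric(1)))
  expect_equal(mTe / mTr, 1.4, tolerance = 0.06)
})

test_that("malignant phantoms have lower measured ADC (Welch p < 0.01)", {
  sp <- defaultPhantomSpec("train15T", seed = 31, nBenign = 50, nMalignant = 50)
  adcOf <- function(s) {
    amap <- computeADCMap(s@dwiB0, s@dwiB800, s@bValues)
    adcFeature(amap, dichotomizeDWI(s@dwiB800, s@trueMask))
  }
  ben <- vapply(1:50, function(i) adcOf(generateLesion(sp, "benign", i)), numeric(1))
  mal <- vapply(1:50, function(i) adcOf(generateLesion(sp, "malignant", i)), numeric(1))
  expect_lt(mean(mal), mean(ben))
  expect_lt(t.test(mal, ben)$p.value, 0.01)
})

test_that("class separation scales with the generating ADC gap", {
  smd <- function(gap) {
    sp <- defaultPhantomSpec("train15T", seed = 41, nBenign = 40, nMalignant = 40)
    sp@classParams$malignant$adcMean <- sp@classParams$benign$adcMean - gap
    draw <- function(lab) vapply(1:40, function(i)
      generateLesion(sp, lab, i)@params$adcMean, numeric(1))
    b <- draw("benign"); m <- draw("malignant")
    (mean(b) - mean(m)) / sqrt((var(b) + var(m)) / 2)
  }
  s1 <- smd(0.25); s2 <- smd(0.5)
  expect_equal(s2 / s1, 2, tolerance = 0.35)
})
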