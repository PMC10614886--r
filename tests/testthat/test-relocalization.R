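test_that("percent-length resampling reproduces linear structure exactly", {
  p <- mkProfile(rep(4.2, 56))
  r <- percentLengthResample(p)
  expect_equal(length(r@positions), 101)
  expect_true(all(r@values == 4.2))
  # linear ramp a -> b lands exactly on a + (b - a) t/100
  ramp <- mkProfile(seq(2, 10, length.out = 51))
  rr <- percentLengthResample(ramp)
  expect_equal(unname(rr@values[, 1]), 2 + 8 * (0:100) / 100,
               tolerance = 1e-12)
  # idempotent on an already-resampled profile
  expect_equal(percentLengthResample(rr)@values, rr@values,
               tolerance = 1e-12)
  expect_error(percentLengthResample(
    new("IntensityProfile", positions = c(0, 1),
        values = matrix(1:2, 2, 1, dimnames = list(NULL, "k")))),
    NA)
})

test_that("ratio identities hold exactly", {
  base <- percentLengthResample(mkProfile(
    5 + exp(-((0:80) * 0.1 - 4)^2)))
  same <- finalInitialRatio(base, base)
  expect_true(all(same@ratio == 1))
  expect_equal(same@auc, 100)
  expect_equal(same@deviationAuc, 0)
  doubled <- initialize(base, values = base@values * 2)
  r2 <- finalInitialRatio(base, doubled)
  expect_true(all(abs(r2@ratio - 2) < 1e-12))
  expect_equal(r2@auc, 200, tolerance = 1e-12)
  expect_equal(r2@deviationAuc, 100, tolerance = 1e-12)
})

test_that("AUC of simple shapes matches the trapezoid closed form", {
  grid <- mkProfile(rep(1, 101), spacing = 1)
  onGrid <- percentLengthResample(grid)
  zero <- finalInitialRatio(onGrid,
                            initialize(onGrid,
                                       values = onGrid@values * 0))
  expect_equal(zero@auc, 0)
  # linear ratio 0 -> 2: area of a triangle over [0, 100] is 100
  lin <- initialize(onGrid,
                    values = matrix(2 * (0:100) / 100, 101, 1,
                                    dimnames = list(NULL, "kinetochore")))
  r <- finalInitialRatio(onGrid, lin)
  expect_equal(r@auc, 100, tolerance = 1e-12)
})

test_that("masked positions are excluded, with a coverage threshold", {
  v <- rep(10, 101); v[40:45] <- 0        # dips below the 1% floor
  init <- percentLengthResample(mkProfile(v, spacing = 1))
  fin <- initialize(init, values = init@values)
  r <- finalInitialRatio(init, fin)
  expect_equal(sum(is.na(r@ratio)), 6)
  expect_equal(r@maskedFraction, 6 / 101, tolerance = 1e-12)
  # unmasked segments each contribute their exact trapezoid
  expect_equal(r@auc, 93, tolerance = 1e-12)
  expect_error(ratioAUC(r, minCoverage = 0.99), "coverage")
  v2 <- rep(0, 101); v2[1] <- 10
  init2 <- percentLengthResample(mkProfile(v2, spacing = 1))
  expect_warning(finalInitialRatio(init2, fin), "coverage")
})

test_that("an expanding-gap time-lapse drops mid-spindle ratio below 1", {
  tl <- generateTimelapse(cleanScene(), c(0, 1, 2, 3))
  r <- relocalizationAnalysis(tl$stack, polePxA, polePxB)
  mid <- r@ratio[46:56]
  edges <- r@ratio[c(2:6, 96:100)]
  expect_true(all(mid < 1))
  expect_true(all(edges > 1))
  expect_gt(r@deviationAuc, 0)
})

test_that("a no-gap control is the identity end to end", {
  tl <- generateTimelapse(cleanScene(), c(0, 0))
  r <- relocalizationAnalysis(tl$stack, polePxA, polePxB)
  expect_true(all(abs(r@ratio - 1) < 1e-12))
  expect_equal(r@auc, 100, tolerance = 1e-12)
  expect_equal(r@deviationAuc, 0, tolerance = 1e-12)
})

test_that("treated and control deviation AUCs separate under noise", {
  devAuc <- function(gaps, seed) {
    sc <- noisyScene(seed = seed)
    tl <- generateTimelapse(sc, gaps)
    relocalizationAnalysis(tl$stack, polePxA, polePxB)@deviationAuc
  }
  dmso <- vapply(1:5, function(s) devAuc(c(0, 0, 0, 0), 700 + s),
                 numeric(1))
  treated <- vapply(1:5, function(s) devAuc(c(0, 1, 2, 3), 800 + s),
                    numeric(1))
  expect_lt(max(dmso), min(treated))
})
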