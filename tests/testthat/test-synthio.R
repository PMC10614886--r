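test_that("noise-free render is the deterministic scene model", {
  sc <- SpindleScene(poleA = c(3, 6), poleB = c(14, 6),
                     channelAmplitudes = c(gamma_tubulin = 100,
                                           alpha_tubulin = 50,
                                           kinetochore = 80,
                                           kif18a = 60),
                     background = 10, shotNoise = FALSE, readSD = 0,
                     pixelSize = 0.1, imageShape = c(120L, 180L))
  img <- generateSpindleImage(sc)$image
  gam <- getChannel(img, "gamma_tubulin")
  # pole A sits exactly at pixel (row 60, col 30), 0-based
  expect_equal(gam[61, 31], 110, tolerance = 1e-9)
  # far corner is pure background in the gamma channel
  expect_equal(gam[1, 1], 10, tolerance = 1e-6)
})

test_that("noisy renders are bit-identical under one seed", {
  sc <- noisyScene(seed = 42)
  a <- generateSpindleImage(sc)$image
  b <- generateSpindleImage(sc)$image
  expect_identical(a@channels, b@channels)
  sc2 <- noisyScene(seed = 43)
  expect_false(identical(generateSpindleImage(sc2)$image@channels,
                         a@channels))
})

test_that("ground truth follows the scene in closed form", {
  res <- generateSpindleImage(cleanScene(kinetochoreSigma = 1.5))
  expect_equal(res$truth$true_fwhm, 2 * sqrt(2 * log(2)) * 1.5,
               tolerance = 1e-12)
  expect_equal(res$truth$true_fwhm, 3.532, tolerance = 1e-3)
  expect_equal(res$truth$true_spindle_length, 11)
  expect_equal(res$truth$true_peak_distance, 2)
})

test_that("scene invariants are enforced", {
  expect_error(SpindleScene(poleA = c(3, 6), poleB = c(3, 6)),
               "differ")
  expect_error(SpindleScene(kinetochoreSigma = -1), "kinetochoreSigma")
  expect_error(SpindleScene(kif18aPeakDistance = 8), "half")
  expect_error(SpindleScene(pixelSize = 0), "pixelSize")
  # poles too close to the border are rejected with the margin rule
  expect_error(generateSpindleImage(
    SpindleScene(poleA = c(1, 6), poleB = c(14, 6), pixelSize = 0.1,
                 imageShape = c(120L, 180L))), "margin")
})

test_that("zero-gap time-lapse frames all equal frame 0", {
  tl <- generateTimelapse(cleanScene(), gapHalfwidths = c(0, 0, 0))
  f1 <- getFrame(tl$stack, 1)
  for (i in 2:3)
    expect_identical(getFrame(tl$stack, i)@channels["kif18a"],
                     f1@channels["kif18a"])
})

test_that("expanding gap conserves KIF18A and empties the midzone", {
  gaps <- c(0, 0.8, 1.6, 2.4)
  tl <- generateTimelapse(cleanScene(), gapHalfwidths = gaps)
  sums <- vapply(seq_along(gaps), function(i)
    sum(getChannel(getFrame(tl$stack, i), "kif18a")), numeric(1))
  expect_true(all(abs(sums - sums[1]) / sums[1] < 0.01))
  # mean intensity in a mid-spindle strip strictly decreases
  midCols <- 81:100   # around x = 8.5 um, spindle midpoint
  midMeans <- vapply(seq_along(gaps), function(i)
    mean(getChannel(getFrame(tl$stack, i), "kif18a")[55:66, midCols]),
    numeric(1))
  expect_true(all(diff(midMeans) < 0))
})

test_that("decreasing gap schedules are rejected", {
  expect_error(generateTimelapse(cleanScene(), c(1, 0.5)),
               "non-decreasing")
  expect_error(generateTimelapse(cleanScene(), c(0, 6)), "half")
})

test_that("dose-response wells follow the 4PL model exactly at cv 0", {
  conc <- serialDilution(1000, 8, 4)
  expect_equal(conc, c(1000, 250, 62.5, 15.625, 3.90625, 0.9765625,
                       0.244140625, 0.06103515625))
  pl <- generateDoseResponse(trueIC50 = 15.625, hill = 1,
                             concentrations = conc, cv = 0, nReps = 1)
  pos <- mean(pl$signal[pl$role == "positive_control"])
  neg <- mean(pl$signal[pl$role == "negative_control"])
  atIC50 <- pl$signal[!is.na(pl$concentration_nM) &
                        pl$concentration_nM == 15.625]
  expect_equal(atIC50, (pos + neg) / 2, tolerance = 1e-12)
  # low-concentration limit approaches the positive-control level
  pl2 <- generateDoseResponse(100, 1, concentrations = 1e-6, cv = 0,
                              nReps = 1)
  expect_equal(pl2$signal[pl2$role == "sample"], pos, tolerance = 1e-6)
  expect_error(generateDoseResponse(10, concentrations = numeric(0)),
               "empty")
})

test_that("growth series double on schedule without noise", {
  g <- generateGrowthSeries(log(2) / 24, 100, c(0, 24, 48), noiseCV = 0)
  expect_equal(g$count, c(100, 200, 400), tolerance = 1e-12)
  expect_error(generateGrowthSeries(log(2) / 24, -5, c(0, 24)), "n0")
})

test_that("count tables are binomial with the requested fraction", {
  ct0 <- generateCountTable(10, 50, mitoticFraction = 0, seed = 1)
  expect_equal(sum(ct0@fields$mitotic_cells), 0)
  fracs <- vapply(1:200, function(s) {
    ct <- generateCountTable(20, 100, mitoticFraction = 0.1, seed = s)
    sum(ct@fields$mitotic_cells) / sum(ct@fields$total_cells)
  }, numeric(1))
  expect_lt(abs(mean(fracs) - 0.1), 0.01)
})
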