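mkCountTable <- function(total, mitotic, n_poles = integer(0)) {
  nf <- length(total)
  poles <- if (sum(mitotic) > 0)
    data.frame(field = rep(seq_len(nf), mitotic),
               cell = sequence(mitotic), n_poles = n_poles)
  else data.frame(field = integer(), cell = integer(),
                  n_poles = integer())
  new("CountTable",
      fields = data.frame(field = seq_len(nf), total_cells = total,
                          mitotic_cells = mitotic),
      poles = poles)
}

test_that("mitotic index pools fields and keeps per-field values", {
  ct <- mkCountTable(c(60, 40), c(3, 2), rep(2L, 5))
  mi <- mitoticIndex(ct)
  expect_equal(mi$percent, 5)
  expect_equal(mi$perField$percent, c(5, 5))
  expect_equal(mitoticIndex(mkCountTable(100, 0))$percent, 0)
})

test_that("multipolar fraction counts only cells with > 2 poles", {
  ct <- mkCountTable(100, 10, c(rep(2L, 6), 3L, 4L, 3L, 1L))
  expect_equal(multipolarFraction(ct), 30)  # monopolar not multipolar
  expect_equal(multipolarFraction(
    mkCountTable(50, 4, rep(2L, 4))), 0)
  expect_error(multipolarFraction(mkCountTable(50, 0)), "mitotic")
})

test_that("count-table validity rejects impossible counts", {
  expect_error(new("CountTable",
                   fields = data.frame(field = 1, total_cells = 5,
                                       mitotic_cells = 9),
                   poles = data.frame(field = integer(),
                                      cell = integer(),
                                      n_poles = integer())),
               "mitotic_cells")
})

test_that("mitotic index estimator sits inside the binomial band", {
  est <- vapply(1:200, function(s)
    mitoticIndex(generateCountTable(20, 100, 0.1, seed = s))$percent,
    numeric(1))
  # 95% interval for the mean of 200 estimates of a Binom(2000, .1) rate
  se <- 100 * sqrt(0.1 * 0.9 / 2000) / sqrt(200)
  expect_lt(abs(mean(est) - 10), 1.96 * se * 1.5)
})

test_that("fold change normalizes to the in-batch control mean", {
  t1 <- generateGrowthSeries(log(8) / 48, 100, c(0, 24, 48), 0,
                             "w1", "treated", "b1")
  c1 <- generateGrowthSeries(log(4) / 48, 100, c(0, 24, 48), 0,
                             "w2", "control", "b1")
  out <- normalizedFoldChange(rbind(t1, c1), "control")
  expect_equal(out$normalized_fold_change[out$condition == "treated"], 2)
  expect_equal(mean(
    out$normalized_fold_change[out$condition == "control"]), 1)
  expect_error(normalizedFoldChange(t1, "control"), "b1")
})

test_that("batch normalization is scale invariant", {
  mk <- function(mult)
    rbind(generateGrowthSeries(0.03, 100 * mult, c(0, 48, 96), 0,
                               "w1", "treated", "b"),
          generateGrowthSeries(0.02, 80 * mult, c(0, 48, 96), 0,
                               "w2", "control", "b"))
  a <- normalizedFoldChange(mk(1), "control")
  b <- normalizedFoldChange(mk(7), "control")
  expect_equal(a$normalized_fold_change, b$normalized_fold_change,
               tolerance = 1e-12)
})

test_that("slow growers land near the closed-form expectation", {
  wells <- do.call(rbind, c(
    lapply(1:6, function(i) generateGrowthSeries(
      log(2) / 48, 100, seq(0, 120, 12), 0.05,
      paste0("t", i), "treated", "b1", seed = 900 + i)),
    lapply(1:6, function(i) generateGrowthSeries(
      log(2) / 24, 100, seq(0, 120, 12), 0.05,
      paste0("c", i), "control", "b1", seed = 950 + i))))
  out <- normalizedFoldChange(wells, "control")
  medianTreated <- median(
    out$normalized_fold_change[out$condition == "treated"])
  expect_lt(abs(medianTreated - 2^(-2.5)) / 2^(-2.5), 0.15)
})

test_that("expression level subtracts background and normalizes", {
  m <- matrix(100, 40, 40)
  m[11:20, 11:20] <- 500
  img <- new("SpindleImage", channels = list(kif18a = m),
             pixelSize = 0.1)
  rec <- expressionLevel(img, c(10, 10, 19, 19), c(25, 25, 34, 34))
  expect_equal(rec$corrected, 400)
  # linearity: doubling intensities doubles the corrected value
  img2 <- new("SpindleImage", channels = list(kif18a = 2 * m),
              pixelSize = 0.1)
  rec2 <- expressionLevel(img2, c(10, 10, 19, 19), c(25, 25, 34, 34))
  expect_equal(rec2$corrected, 800)
  # control normalization maps the control mean to exactly 1
  recs <- rbind(cbind(rec, condition = "control"),
                cbind(rec2, condition = "treated"))
  nr <- normalizeExpression(recs, "control")
  expect_equal(mean(nr$normalized[nr$condition == "control"]), 1)
  expect_equal(nr$normalized[nr$condition == "treated"], 2)
  # overlapping ROIs are rejected; inverted background flagged
  expect_error(expressionLevel(img, c(10, 10, 19, 19),
                               c(15, 15, 30, 30)), "overlap")
  dim_img <- new("SpindleImage",
                 channels = list(kif18a = matrix(c(50, 10), 20, 20)),
                 pixelSize = 0.1)
  expect_warning(expressionLevel(img, c(25, 25, 34, 34),
                                 c(11, 11, 19, 19)), "background")
})
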