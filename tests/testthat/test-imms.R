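test_that("mass inference is exact on noiseless charge ladders", {
  # intact antibody-scale ladder
  lad <- makeChargeLadder(149328, 21:24)
  res <- inferMass(lad)
  expect_equal(res$mass, 149328, tolerance = 1e-8)
  expect_equal(res$charges, 21:24)
  # closed-form two-point case
  expect_equal(inferMass(makeChargeLadder(1000, c(1, 2)))$mass, 1000,
               tolerance = 1e-9)
  # property: exact over a wide mass range and charge counts
  for (mass in c(1e3, 5e4, 1e6)) {
    for (z0 in c(1L, 10L, 40L)) {
      res <- inferMass(makeChargeLadder(mass, z0:(z0 + 5)))
      expect_lt(abs(res$mass - mass) / mass, 1e-6)
    }
  }
})

test_that("mass inference rejects single peaks and inconsistent ladders", {
  expect_error(inferMass(data.frame(mz = 1001)), "two peaks")
  bad <- makeChargeLadder(50000, 10:13)
  bad$mz[2] <- bad$mz[2] * 1.01
  expect_error(inferMass(bad), "inconsistent")
})

test_that("charge-ladder generation follows the electrospray closed form", {
  out <- makeChargeLadder(1000, 1L)
  expect_equal(out$mz, 1001.00728)
  expect_error(makeChargeLadder(1000, integer()), "at least one")
  expect_error(makeChargeLadder(1000, c(0L, 2L)), "positive")
  expect_error(makeChargeLadder(1000, c(3L, 3L)), "distinct")
})

test_that("power-law calibration is recovered exactly from noiseless calibrants", {
  cal <- makeCalibrantSet(powerA = 2, powerB = 0.5, n = 6, noiseSd = 0)
  fit <- twimsCalibrate(cal)
  expect_equal(fit@A, 2, tolerance = 1e-9)
  expect_equal(fit@B, 0.5, tolerance = 1e-9)
  expect_lt(fit@residualRms, 1e-9)
})

test_that("calibration exponent is recovered within 5 % at 1 % drift-time noise", {
  cal <- makeCalibrantSet(powerA = 2, powerB = 0.5, n = 20, noiseSd = 0.01,
                          seed = 42)
  fit <- twimsCalibrate(cal)
  expect_lt(abs(fit@B - 0.5) / 0.5, 0.05)
})

test_that("calibration recovery is unbiased over seeded replicates", {
  bs <- vapply(1:100, function(s) {
    twimsCalibrate(makeCalibrantSet(2, 0.5, n = 20, noiseSd = 0.01,
                                    seed = s))@B
  }, numeric(1))
  expect_lt(abs(mean(bs) - 0.5) / 0.5, 0.01)
})

test_that("applying a calibration inverts the corrected-CCS transform", {
  cal <- makeCalibrantSet(powerA = 3.1, powerB = 0.62, n = 8, noiseSd = 0)
  fit <- twimsCalibrate(cal)
  back <- applyCalibration(fit, cal$drift, cal$mass, cal$charge)
  expect_equal(back, cal$ccs, tolerance = 1e-9)
  # monotone transform preserves the order of an arrival-time distribution
  t <- seq(1.2, 4, length.out = 25)
  ccsDist <- applyCalibration(fit, t, 150000, 21)
  expect_true(all(diff(ccsDist) > 0))
  expect_error(applyCalibration(fit, 0, 150000, 21), "dead time")
})

test_that("calibration input validation catches degenerate tables", {
  expect_error(makeCalibrantSet(2, 0.5, n = 1), "underdetermined")
  cal <- makeCalibrantSet(2, 0.5, n = 5)
  expect_error(twimsCalibrate(cal[1, , drop = FALSE]), "two calibrants")
  cal$drift[1] <- -1
  expect_error(twimsCalibrate(cal), "drift")
})

test_that("wave-velocity averaging uses the sample convention", {
  a <- averageOverWaves(c(6827, 6827, 6827))
  expect_equal(a$mean, 6827)
  expect_equal(a$sd, 0)
  b <- averageOverWaves(c(6746, 6827, 6908))
  expect_equal(b$mean, 6827)
  expect_equal(b$sd, sd(c(6746, 6827, 6908)))
  single <- averageOverWaves(7000)
  expect_equal(single$sd, 0)
  expect_true(single$singleValue)
})

test_that("model-vs-experiment comparison reports both conventions and the band", {
  eq <- compareToExperiment(7000, 7000)
  expect_equal(eq$relDiff, 0)
  expect_true(eq$withinBand)
  close <- compareToExperiment(7180, 7173)
  expect_equal(close$relDiff, (7180 - 7173) / 7173, tolerance = 1e-12)
  expect_lt(abs(close$relDiff), 0.002)  # the 0.1 % class of agreement
  expect_true(close$withinBand)
  far <- compareToExperiment(9532, 6827)
  expect_equal(far$relDiff, (9532 - 6827) / 6827)
  expect_equal(far$relDiffModelDenom, (9532 - 6827) / 9532)
  expect_false(far$withinBand)
})

test_that("the packaged IgG reference table is complete and self-consistent", {
  ref <- igGReference()
  expect_equal(ref$subclass, c("IgG1", "IgG2", "IgG3", "IgG4"))
  expect_true(all(ref$sampling_min_ccs < ref$initial_model_ccs))
  expect_true(all(ref$experimental_ccs < ref$sampling_min_ccs))
})
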