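test_that("the generator is deterministic for a fixed seed", {
  a <- smallAntibody(seed = 7L)
  b <- smallAntibody(seed = 7L)
  expect_identical(coords(a$structure), coords(b$structure))
  c <- smallAntibody(seed = 8L)
  expect_false(identical(coords(a$structure), coords(c$structure)))
})

test_that("the fixture topology is valid and its disulfides are detectable", {
  fx <- smallAntibody(m = 4L)
  expect_true(validObject(fx$topology))
  found <- detectDisulfides(fx$structure)
  expect_equal(nrow(found), nrow(fx$topology@disulfides))
  # flexible residues lie N-terminal of the most N-terminal hinge disulfide
  firstCys <- min(fx$topology@disulfides$resid_a)
  flexResid <- as.integer(sub("^[AB]:", "", unlist(fx$topology@flexibleResidues)))
  expect_true(all(flexResid < firstCys))
})

test_that("a zero-residue hinge yields a rigid fixture and a single conformer", {
  fx <- smallAntibody(m = 0L)
  expect_length(fx$topology@flexibleResidues$arm1, 0L)
  ens <- sampleEnsemble(fx$structure, fx$topology,
                        rrtParams(nSamples = 50L, seed = 3L,
                                  ccsOrientations = 30L, ccsPoints = 2000L),
                        fx$radii)
  expect_equal(nConformers(ens), 1L)
  expect_identical(ens@coordsList[[1]], coords(fx$structure))
})

test_that("no two beads overlap in the initial pose and impossible geometry errors", {
  fx <- smallAntibody(beads = 20L)
  a <- atoms(fx$structure)
  bb <- coords(fx$structure)[a$element == "BB", ]
  expect_gt(min(dist(bb)), 0.9 * 2 * fx$params$beadRadius)
  expect_error(
    makeSyntheticAntibody(syntheticAntibodyParams(
      beadsPerDomain = 30L, interArmAngle = 8, flexibleResiduesPerArm = 0L)),
    "overlap")
})

test_that("an IgG3-like hinge reaches farther than an IgG1-like hinge", {
  igg1 <- smallAntibody(m = 5L)
  igg3 <- smallAntibody(m = 12L)
  reach <- function(fx) {
    keys <- atomResidueKeys(fx$structure)
    fab <- colMeans(coords(fx$structure)[
      keys %in% fx$topology@rigidBodies$Fab1, , drop = FALSE])
    stem <- colMeans(coords(fx$structure)[
      keys %in% fx$topology@rigidBodies$Fc_core, , drop = FALSE])
    sqrt(sum((fab - stem)^2))
  }
  expect_gt(reach(igg3), reach(igg1))
})

test_that("fixture CCS grows monotonically with arm length", {
  vals <- vapply(c(40, 50, 60), function(al) {
    fx <- smallAntibody(armLength = al)
    ccs(projectionArea(fx$structure, fx$radii, nOrientations = 80,
                       nPoints = 8000, seed = 2))
  }, numeric(1))
  expect_true(all(diff(vals) > 0))
})

test_that("calibrant generation satisfies the power law by construction", {
  cal <- makeCalibrantSet(powerA = 2, powerB = 0.5, n = 6, noiseSd = 0)
  mu <- cal$mass * 28.006 / (cal$mass + 28.006)
  ccsPrime <- cal$ccs * sqrt(mu) / cal$charge
  expect_equal(ccsPrime, 2 * cal$drift^0.5, tolerance = 1e-12)
  # reproducible under a fixed seed
  expect_identical(makeCalibrantSet(2, 0.5, 10, 0.02, seed = 5),
                   makeCalibrantSet(2, 0.5, 10, 0.02, seed = 5))
})
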