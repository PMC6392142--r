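# sampler tests use small fixtures and reduced CCS settings; the scientific
# properties at the full study sizes are exercised in test-acceptance.R
quickParams <- function(n, seed, ...) {
  rrtParams(nSamples = n, seed = seed, ccsOrientations = 30L,
            ccsPoints = 2000L, ...)
}

test_that("clash test matches trivial configurations", {
  fx <- smallAntibody()
  expect_false(clashCheck(fx$structure, fx$radii, 0.7, fx$topology))
  # drop Fab1 onto Fab2: coincident beads from different bodies must clash
  s <- fx$structure
  keys <- atomResidueKeys(s)
  f1 <- which(keys %in% fx$topology@rigidBodies$Fab1)
  f2 <- which(keys %in% fx$topology@rigidBodies$Fab2)
  xyz <- coords(s)
  xyz[f1, ] <- xyz[f2[seq_along(f1)], ]
  coords(s) <- xyz
  expect_true(clashCheck(s, fx$radii, 0.7, fx$topology))
})

test_that("spatial-hash clash test agrees with the all-pairs oracle on random poses", {
  fx <- smallAntibody(m = 3L, beads = 10L)
  d <- length(measureDihedrals(fx$structure, fx$topology))
  agree <- 0L
  clashes <- 0L
  for (k in 1:50) {
    set.seed(1000 + k)
    pose <- applyDihedrals(fx$structure, fx$topology, runif(d, -180, 180))
    got <- clashCheck(pose, fx$radii, 0.7, fx$topology)
    want <- clashOracle(pose, fx$radii, 0.7, fx$topology)
    agree <- agree + as.integer(got == want)
    clashes <- clashes + as.integer(want)
  }
  expect_equal(agree, 50L)
  expect_gt(clashes, 0L)  # the pose set must actually exercise both verdicts
  expect_lt(clashes, 50L)
})

test_that("sampling is deterministic and extends prefix-stably with nSamples", {
  fx <- smallAntibody()
  e1 <- sampleEnsemble(fx$structure, fx$topology, quickParams(40L, 9L), fx$radii)
  e2 <- sampleEnsemble(fx$structure, fx$topology, quickParams(40L, 9L), fx$radii)
  expect_identical(ccs(e1), ccs(e2))
  expect_identical(e1@dihedrals, e2@dihedrals)
  e3 <- sampleEnsemble(fx$structure, fx$topology, quickParams(80L, 9L), fx$radii)
  expect_identical(ccs(e3)[1:40], ccs(e1))
  expect_lte(min(ccs(e3)), min(ccs(e1)))  # nested-run minimum is non-increasing
})

test_that("accepted conformers are clash-free with exactly preserved rigid bodies", {
  fx <- smallAntibody()
  ens <- sampleEnsemble(fx$structure, fx$topology, quickParams(30L, 4L),
                        fx$radii)
  keys <- atomResidueKeys(fx$structure)
  for (i in seq_len(nConformers(ens))) {
    s <- conformer(ens, i)
    expect_false(clashCheck(s, fx$radii, 0.7, fx$topology))
    for (b in c("Fab1", "Fab2", "Fc_core")) {
      idx <- which(keys %in% fx$topology@rigidBodies[[b]])
      expect_lt(superposedRmsd(coords(fx$structure)[idx, ],
                               coords(s)[idx, ]), 1e-6)
    }
  }
})

test_that("the attempt budget returns a truncated ensemble with a warning", {
  fx <- smallAntibody()
  expect_warning(
    ens <- sampleEnsemble(fx$structure, fx$topology,
                          quickParams(500L, 2L, maxExtensionAttempts = 20L),
                          fx$radii),
    "attempt budget")
  expect_true(ens@truncated)
  expect_lt(nConformers(ens), 500L)
})

test_that("compact selection takes the CCS minimum and respects diversity", {
  fx <- smallAntibody()
  ens <- sampleEnsemble(fx$structure, fx$topology, quickParams(60L, 12L),
                        fx$radii)
  sel <- selectCompact(ens, k = 3L, diversityRmsd = 0)
  # with no diversity constraint: exactly the 3 lowest CCS values
  expect_equal(sort(sel$ccs), sort(ccs(ens))[1:3])
  expect_equal(sel$indices[1], which.min(ccs(ens)))
  one <- selectCompact(ens, k = 1L)
  expect_equal(one$indices, which.min(ccs(ens)))
  expect_error(selectCompact(ens, k = nConformers(ens) + 1L), "exceeds")
})

test_that("near-duplicate low-CCS conformers are skipped for diversity", {
  fx <- smallAntibody()
  ens <- sampleEnsemble(fx$structure, fx$topology, quickParams(25L, 3L),
                        fx$radii)
  # construct an ensemble whose two lowest-CCS conformers are identical
  # coordinates: the second pick must skip to the next diverse conformer
  ord <- order(ens@ccsValues)
  i1 <- ord[1]; i2 <- ord[2]
  ens@coordsList[[i2]] <- ens@coordsList[[i1]]
  sel <- selectCompact(ens, k = 2L, diversityRmsd = 5)
  expect_equal(sel$indices[1], i1)
  expect_false(sel$indices[2] == i2)
  # exhaustive oracle: the second pick is the lowest-CCS conformer at
  # RMSD > 5 from the first
  nm <- trimws(atoms(fx$structure)$name)
  bb <- which(nm == "CA")
  rmsdTo1 <- vapply(seq_len(nConformers(ens)), function(j) {
    sqrt(mean(rowSums((ens@coordsList[[j]][bb, ] -
                         ens@coordsList[[i1]][bb, ])^2)))
  }, numeric(1))
  eligible <- which(rmsdTo1 > 5)
  expect_equal(sel$indices[2], eligible[which.min(ens@ccsValues[eligible])])
})

test_that("relaxing the diversity constraint fills the selection with a warning", {
  fx <- smallAntibody()
  ens <- sampleEnsemble(fx$structure, fx$topology, quickParams(5L, 8L),
                        fx$radii)
  expect_warning(sel <- selectCompact(ens, k = 4L, diversityRmsd = 1e6),
                 "relax")
  expect_length(sel$indices, 4L)
  expect_true(sel$relaxed)
})

test_that("ensemble summaries are consistent for degenerate and sampled ensembles", {
  fx <- smallAntibody(m = 0L)
  single <- sampleEnsemble(fx$structure, fx$topology, quickParams(5L, 2L),
                           fx$radii)
  s1 <- summariseEnsemble(single)
  expect_equal(s1$n, 1L)
  expect_equal(s1$deltaCcs, 0)
  expect_equal(s1$overlapFraction, 0)

  fx2 <- smallAntibody()
  ens <- sampleEnsemble(fx2$structure, fx2$topology, quickParams(40L, 2L),
                        fx2$radii)
  s2 <- summariseEnsemble(ens)
  expect_equal(s2$deltaCcs, max(ccs(ens)) - min(ccs(ens)))
  expect_equal(nrow(s2$fab1Cloud), nConformers(ens))
  expect_gte(s2$overlapFraction, 0)
  expect_lte(s2$overlapFraction, 1)
})
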