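# fast force-field settings for unit tests; the collapse physics at the
# standard study sizes is exercised in test-acceptance.R
quickFF <- function(nSteps, seed = 5L, ...) {
  forceFieldParams(nSteps = nSteps, reportStride = max(1L, nSteps %/% 10L),
                   seed = seed, ccsOrientations = 25L, ccsPoints = 2000L, ...)
}

test_that("zero net charge yields an empty, valid assignment", {
  fx <- smallAntibody()
  ch <- assignCharges(fx$structure, fx$topology, 0)
  expect_length(ch@sites, 0L)
  expect_equal(ch@netCharge, 0L)
})

test_that("surface spreading places the requested unit charges on distinct sites", {
  fx <- smallAntibody(beads = 30L)
  ch <- assignCharges(fx$structure, fx$topology, 21)
  expect_length(ch@sites, 21L)
  expect_equal(anyDuplicated(ch@sites), 0L)
  expect_equal(sum(ch@charges), 21L)
})

test_that("greedy farthest-point placement maximises the minimum distance stepwise", {
  # 10-site toy: verify each greedy pick against exhaustive search
  set.seed(21)
  pts <- matrix(runif(30, 0, 40), 10, 3)
  s <- structureFromAtoms(data.frame(
    name = "CA", element = "BB", resid = 1:10, chain = "A",
    x = pts[, 1], y = pts[, 2], z = pts[, 3]))
  topo <- new("AntibodyTopology",
              rigidBodies = list(Fab1 = residueKey("A", 1:10),
                                 Fab2 = character(), Fc_core = character()),
              flexibleResidues = list(arm1 = character(), arm2 = character()))
  ch <- assignCharges(s, topo, 4, shellRadius = 100)
  # with a shell radius covering everything, all 10 sites tie as eligible
  xyz <- coords(s)
  cent <- colMeans(xyz)
  expect_equal(ch@sites[1],
               which.max(rowSums(sweep(xyz, 2, cent)^2)))
  for (k in 2:4) {
    placed <- ch@sites[seq_len(k - 1)]
    best <- -Inf; bestSite <- NA
    for (cand in setdiff(1:10, placed)) {
      m <- min(sqrt(rowSums((xyz[placed, , drop = FALSE] -
                               matrix(xyz[cand, ], k - 1, 3, byrow = TRUE))^2)))
      if (m > best) { best <- m; bestSite <- cand }
    }
    expect_equal(ch@sites[k], bestSite)
  }
})

test_that("charge placement errors when sites run out", {
  fx <- smallAntibody(beads = 10L)
  expect_error(assignCharges(fx$structure, fx$topology, 10000), "eligible")
})

test_that("a zero-step simulation returns the initial frame and CCS", {
  fx <- smallAntibody()
  ch <- assignCharges(fx$structure, fx$topology, 5)
  tr <- simulateCollapse(fx$structure, fx$topology, ch, quickFF(0L),
                         fx$radii, reportStride = 1L)
  expect_equal(nConformers(tr), 1L)
  expect_equal(tr@finalWindowRange, 0)
  cg <- abgas:::.coarseGrain(fx$structure, fx$topology)
  expect_identical(tr@frames[[1]], coords(cg$beads))
})

test_that("collapse trajectories are bitwise reproducible for a fixed seed", {
  fx <- smallAntibody()
  ch <- assignCharges(fx$structure, fx$topology, 5)
  t1 <- simulateCollapse(fx$structure, fx$topology, ch, quickFF(2000L), fx$radii)
  t2 <- simulateCollapse(fx$structure, fx$topology, ch, quickFF(2000L), fx$radii)
  expect_identical(t1@frames, t2@frames)
  expect_identical(t1@ccsSeries, t2@ccsSeries)
  t3 <- simulateCollapse(fx$structure, fx$topology, ch, quickFF(2000L, seed = 6L),
                         fx$radii)
  expect_false(identical(t1@frames, t3@frames))
})

test_that("net charge is carried unchanged through the trajectory", {
  fx <- smallAntibody()
  ch <- assignCharges(fx$structure, fx$topology, 7)
  tr <- simulateCollapse(fx$structure, fx$topology, ch, quickFF(1000L), fx$radii)
  expect_equal(tr@netCharge, 7L)
})

test_that("numerical blow-up is reported with the step index", {
  fx <- smallAntibody()
  ch <- assignCharges(fx$structure, fx$topology, 5)
  expect_error(
    simulateCollapse(fx$structure, fx$topology, ch,
                     quickFF(5000L, dt = 50), fx$radii),
    "step.*reduce dt")
})

test_that("identical replicate inputs give zero spread; distinct seeds report it", {
  fx <- smallAntibody()
  same <- replicateCollapse(rep(list(fx$structure), 3), fx$topology, 5,
                            quickFF(1000L), fx$radii, seeds = c(4L, 4L, 4L))
  expect_equal(same$spreadPct, 0)
  diff <- replicateCollapse(rep(list(fx$structure), 2), fx$topology, 5,
                            quickFF(1000L), fx$radii, seeds = c(4L, 9L))
  expect_gt(diff$spreadPct, 0)
})

test_that("rigid-domain radii of gyration are preserved by the elastic network", {
  fx <- smallAntibody(beads = 16L)
  ch <- assignCharges(fx$structure, fx$topology, 5)
  tr <- simulateCollapse(fx$structure, fx$topology, ch, quickFF(5000L), fx$radii)
  keys <- atomResidueKeys(tr@template)
  rg <- function(m) sqrt(mean(rowSums(sweep(m, 2, colMeans(m))^2)))
  last <- tr@frames[[length(tr@frames)]]
  for (b in c("Fab1", "Fab2", "Fc_core")) {
    idx <- which(keys %in% fx$topology@rigidBodies[[b]])
    expect_lt(abs(rg(last[idx, ]) / rg(coords(tr@template)[idx, ]) - 1), 0.05)
  }
})
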