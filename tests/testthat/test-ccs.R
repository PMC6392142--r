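test_that("a single sphere has the closed-form projected area for any orientation count", {
  s <- structureFromAtoms(data.frame(name = "X", element = "C", resid = 1L,
                                     chain = "A", x = 0, y = 0, z = 0))
  r <- collisionRadii(c(C = 2.0), probe = 1.0)
  for (n in c(1L, 5L, 50L)) {
    res <- projectionArea(s, r, nOrientations = n, seed = 1)
    expect_equal(paArea(res), pi * 9, tolerance = 1e-12)
    expect_equal(ccs(res), 1.14 * pi * 9, tolerance = 1e-12)
    expect_equal(res@mcStandardError, 0)
  }
})

test_that("two far-apart atoms project additively within Monte-Carlo error", {
  s <- structureFromAtoms(data.frame(name = "X", element = "C", resid = 1:2,
                                     chain = "A", x = c(0, 100), y = 0, z = 0))
  r <- collisionRadii(c(C = 2.0), probe = 1.0)
  res <- projectionArea(s, r, nOrientations = 200, seed = 4)
  expect_lt(abs(paArea(res) - 2 * pi * 9), 3 * max(res@mcStandardError, 0.05))
})

test_that("the CCS scale factor is exactly 1.14 and paToCcs validates input", {
  expect_equal(paToCcs(100), 114)
  expect_identical(paToCcs(0), 0)
  expect_error(paToCcs(-1), "non-negative")
  # 9532 / 1.14 scales back up to 9532 within 0.1 %
  expect_equal(paToCcs(8361.4), 9532, tolerance = 1e-3)
  s <- randomCluster(20, seed = 8)
  res <- projectionArea(s, defaultRadii(), nOrientations = 30, seed = 2)
  expect_identical(ccs(res), 1.14 * paArea(res))
})

test_that("Monte-Carlo and grid estimators agree within 1 % on random clusters", {
  for (k in 1:5) {
    s <- randomCluster(30 + 5 * k, seed = 100 + k)
    mc <- projectionArea(s, defaultRadii(), nOrientations = 60, seed = k)
    gr <- projectionArea(s, defaultRadii(), nOrientations = 60,
                         sampler = "grid", cell = 0.2, seed = k)
    expect_lt(abs(paArea(mc) - paArea(gr)) / paArea(gr), 0.01)
  }
})

test_that("projected area is invariant under rigid rotation within MC error", {
  s <- randomCluster(40, seed = 31)
  a <- projectionArea(s, defaultRadii(), nOrientations = 150, seed = 7)
  sr <- s
  coords(sr) <- rotatePoints(coords(s), c(1, 2, 3), c(2, -1, 0.5), 63)
  b <- projectionArea(sr, defaultRadii(), nOrientations = 150, seed = 8)
  se <- sqrt(a@mcStandardError^2 + b@mcStandardError^2)
  expect_lt(abs(paArea(a) - paArea(b)), 2.5 * se)
})

test_that("adding a non-occluded atom never decreases the projected area", {
  s <- randomCluster(25, seed = 77)
  bigger <- structureFromAtoms(rbind(
    atoms(s),
    data.frame(serial = 26L, name = "X", element = "C", resname = "UNK",
               resid = 26L, ins = "", chain = "A",
               x = 60, y = 60, z = 60, het = FALSE)))
  a <- projectionArea(s, defaultRadii(), nOrientations = 80, seed = 5)
  b <- projectionArea(bigger, defaultRadii(), nOrientations = 80, seed = 5)
  expect_gt(paArea(b), paArea(a))
})

test_that("unknown elements and invalid orientation counts are rejected", {
  s <- structureFromAtoms(data.frame(name = "Q", element = "ZZ", resid = 1L,
                                     chain = "A", x = 0, y = 0, z = 0))
  expect_error(projectionArea(s, defaultRadii(), nOrientations = 10), "ZZ")
  expect_error(projectionArea(tinyStructure(), defaultRadii(),
                              nOrientations = 0), "nOrientations")
})

test_that("trajectory CCS handles single frames, identical frames and striding", {
  s <- randomCluster(15, seed = 3)
  one <- ccsTrajectory(list(s), nOrientations = 30, seed = 2)
  expect_length(one$ccs, 1L)
  expect_equal(one$finalWindowRange, 0)
  many <- ccsTrajectory(rep(list(s), 10), nOrientations = 30, seed = 2)
  expect_true(all(abs(many$ccs - many$ccs[1]) < 1e-12))  # shared seed: exact
  strided <- ccsTrajectory(rep(list(s), 10), stride = 3, nOrientations = 30,
                           seed = 2)
  expect_length(strided$ccs, 4L)
  expect_error(ccsTrajectory(list(), nOrientations = 10), "frame")
})
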