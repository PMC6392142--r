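# Shared fixtures and independent oracles used across the test files.
# Everything is generated in code; no binary data.

# tiny three-atom structure with known coordinates
tinyStructure <- function() {
  structureFromAtoms(data.frame(
    name = c("N", "CA", "C"), element = c("N", "C", "C"),
    resname = "GLY", resid = 1L, chain = "A",
    x = c(1.234, 2.345, 3.456), y = c(-0.5, 0.25, 1.125),
    z = c(10, 11.5, 12.75)))
}

# a pair of cysteines with a given SG-SG distance
cysPair <- function(sgDistance) {
  structureFromAtoms(data.frame(
    name = c("CA", "SG", "CA", "SG"), element = c("C", "S", "C", "S"),
    resname = "CYS", resid = c(1L, 1L, 2L, 2L), chain = c("A", "A", "B", "B"),
    x = c(0, 0, 5, sgDistance), y = 0, z = 0))
}

# small standard synthetic antibody used by sampler/collapse tests
smallAntibody <- function(m = 3L, beads = 12L, seed = 2L, ...) {
  makeSyntheticAntibody(syntheticAntibodyParams(
    beadsPerDomain = beads, flexibleResiduesPerArm = m, seed = seed, ...))
}

# random bead cluster for CCS estimator comparisons
randomCluster <- function(n, seed, sd = 7) {
  set.seed(seed)
  structureFromAtoms(data.frame(
    name = "CA", element = "C", resid = seq_len(n), chain = "A",
    x = rnorm(n, sd = sd), y = rnorm(n, sd = sd), z = rnorm(n, sd = sd)))
}

# O(N^2) all-pairs clash oracle mirroring the documented exemptions
clashOracle <- function(structure, radii, clashFactor, topology) {
  a <- atoms(structure)
  keys <- atomResidueKeys(structure)
  group <- integer(nrow(a))
  bodies <- names(topology@rigidBodies)
  for (b in seq_along(bodies))
    group[keys %in% topology@rigidBodies[[bodies[b]]]] <- b
  r <- radiusOf(collisionRadii(radii@radii, probe = 0), a$element)
  xyz <- coords(structure)
  n <- nrow(xyz)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (group[i] > 0 && group[i] == group[j]) next
      if (a$chain[i] == a$chain[j] && abs(a$resid[i] - a$resid[j]) <= 1) next
      if (sqrt(sum((xyz[i, ] - xyz[j, ])^2)) < clashFactor * (r[i] + r[j]))
        return(TRUE)
    }
  }
  FALSE
}

# independent dihedral oracle (explicit rotation matrix about an arbitrary
# axis), used to check the kinematics module from outside
rotationMatrixOracle <- function(axis, angleDeg) {
  u <- axis / sqrt(sum(axis^2))
  th <- angleDeg * pi / 180
  K <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0), 3, 3,
              byrow = TRUE)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}
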