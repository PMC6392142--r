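test_that("PDB round trip preserves coordinates at format precision", {
  s <- tinyStructure()
  f <- withr::local_tempfile(fileext = ".pdb")
  writePDB(s, f)
  s2 <- readPDB(f)
  expect_equal(nAtoms(s2), 3L)
  expect_lt(max(abs(coords(s2) - coords(s))), 0.001 + 1e-12)
  # idempotence: a second round trip is exact
  f2 <- withr::local_tempfile(fileext = ".pdb")
  writePDB(s2, f2)
  expect_identical(coords(readPDB(f2)), coords(s2))
})

test_that("altloc records keep only blank or 'A' and HETATM is flagged", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA AGLY A   1       0.000   0.000   0.000  0.50 10.00           C",
    "ATOM      2  CA BGLY A   1       1.000   0.000   0.000  0.50 10.00           C",
    "ATOM      3  CA  GLY A   2       3.800   0.000   0.000  1.00 10.00           C",
    "HETATM    4  C1  NAG A 901       8.000   1.000   0.000  1.00 10.00           C",
    "END"), f)
  s <- readPDB(f)
  expect_equal(nAtoms(s), 3L)   # altloc B dropped
  expect_equal(sum(atoms(s)$het), 1L)
  expect_true(s@metadata$hasHet)
})

test_that("unreadable and empty files raise informative errors", {
  expect_error(readPDB(file.path(tempdir(), "no-such-file.pdb")), "cannot read")
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines("REMARK nothing here", f)
  expect_error(readPDB(f), "PDB")
})

test_that("writePDB rejects multi-character chain identifiers", {
  s <- tinyStructure()
  s@atoms$chain <- "AB"
  f <- withr::local_tempfile(fileext = ".pdb")
  expect_error(writePDB(s, f), "AB")
})

test_that("disulfide detection pairs SG atoms greedily within the cutoff", {
  expect_equal(nrow(detectDisulfides(cysPair(2.05))), 1L)
  expect_equal(nrow(detectDisulfides(cysPair(4.0))), 0L)
  b <- detectDisulfides(cysPair(2.05))
  expect_equal(b$sg_distance, 2.05, tolerance = 1e-12)
})

test_that("disulfide detection is independent of atom ordering", {
  s <- cysPair(2.3)
  rev <- structureFromAtoms(atoms(s)[rev(seq_len(nAtoms(s))), ])
  expect_equal(detectDisulfides(s)[, 1:4], detectDisulfides(rev)[, 1:4])
})

test_that("each SG joins at most one bond under greedy nearest pairing", {
  # three cysteines in a row: SG spacing 2.1 and 2.2 - only one bond allowed
  # for the shared middle SG, and it takes the shorter pairing
  s <- structureFromAtoms(data.frame(
    name = "SG", element = "S", resname = "CYS",
    resid = c(1L, 2L, 3L), chain = "A",
    x = c(0, 2.1, 4.3), y = 0, z = 0))
  b <- detectDisulfides(s)
  expect_equal(nrow(b), 1L)
  expect_equal(b$resid_a, 1L)
  expect_equal(b$resid_b, 2L)
})

# small atomistic-style antibody with 2 heavy + 2 light chains for the
# partition: heavy chains H,I with hinge span 11..14 and hinge CYS 13;
# light chains L,M sit next to the heavy Fab portions
partitionFixture <- function() {
  mk <- function(chain, n, x0, y0) {
    data.frame(name = "CA", element = "C", resname = "GLY",
               resid = seq_len(n), chain = chain,
               x = x0 + seq_len(n) * 3.8, y = y0, z = 0)
  }
  h1 <- mk("H", 20, 0, 0); h1$resname[13] <- "CYS"
  h2 <- mk("I", 20, 0, 3); h2$resname[13] <- "CYS"
  sg <- data.frame(name = "SG", element = "S", resname = "CYS",
                   resid = 13L, chain = c("H", "I"),
                   x = 13 * 3.8, y = c(1.0, 2.0), z = 0)
  l1 <- mk("L", 8, 0, -4); l2 <- mk("M", 8, 0, 7)
  structureFromAtoms(rbind(h1, h2, sg, l1, l2))
}

test_that("antibody partition bounds the flexible set by the first hinge disulfide", {
  s <- partitionFixture()
  topo <- partitionAntibody(
    s, c(H = "heavy", I = "heavy", L = "light", M = "light"),
    hingeSpan = list(H = c(11, 14), I = c(11, 14)))
  # flexible: residues 11, 12 (13 is the first hinge cysteine, exclusive)
  expect_equal(topo@flexibleResidues$arm1, residueKey("H", 11:12))
  expect_equal(topo@flexibleResidues$arm2, residueKey("I", 11:12))
  # Fc core holds everything C-terminal of the cysteine
  expect_true(all(residueKey("H", 13:20) %in% topo@rigidBodies$Fc_core))
  # light chains joined their nearest heavy Fab portion
  expect_true(all(residueKey("L", 1:8) %in% topo@rigidBodies$Fab1))
  expect_true(all(residueKey("M", 1:8) %in% topo@rigidBodies$Fab2))
  # partition completeness: every residue in exactly one bucket
  keys <- unique(atomResidueKeys(s))
  buckets <- c(unlist(topo@rigidBodies), unlist(topo@flexibleResidues),
               topo@unassigned)
  expect_setequal(buckets, keys)
  expect_equal(anyDuplicated(buckets), 0L)
})

test_that("partition errors without a hinge disulfide and handles empty flexible sets", {
  s <- partitionFixture()
  expect_error(
    partitionAntibody(s, c(H = "heavy", I = "heavy", L = "light", M = "light"),
                      hingeSpan = list(H = c(2, 5), I = c(2, 5))),
    "disulfide")
  # hinge span starting at the cysteine itself: zero flexible residues is valid
  topo <- partitionAntibody(
    s, c(H = "heavy", I = "heavy", L = "light", M = "light"),
    hingeSpan = list(H = c(13, 14), I = c(13, 14)))
  expect_length(topo@flexibleResidues$arm1, 0L)
})

test_that("topology JSON round trip preserves the partition", {
  fx <- smallAntibody()
  f <- withr::local_tempfile(fileext = ".json")
  topologyToJSON(fx$topology, f)
  t2 <- readTopologyJSON(f)
  expect_equal(t2@rigidBodies, fx$topology@rigidBodies)
  expect_equal(t2@flexibleResidues, fx$topology@flexibleResidues)
  expect_equal(t2@disulfides$resid_a, fx$topology@disulfides$resid_a)
})
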