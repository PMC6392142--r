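#' @include AllClasses.R AllGenerics.R ccs.R sampler.R
NULL

#' Force-field and integrator parameters for the vacuum collapse simulation
#'
#' Coarse-grained (one bead per residue) vacuum Langevin dynamics: harmonic
#' bonds along each chain, an elastic network within each rigid body that
#' preserves domain shape, 12-6 Lennard-Jones attraction between non-bonded
#' beads (the compaction driver; no cutoff) and Coulomb repulsion between
#' charged beads at dielectric 1. Units: kJ/mol, Angstrom, Da, ps.
#'
#' @param bondK chain bond force constant, kJ/mol/A^2 (default 500).
#' @param bondR0 chain bond rest length in Angstrom; `NA` (default) takes
#'   each bond's initial length.
#' @param elasticNetworkCutoff intra-body elastic network cutoff, A
#'   (default 15, the usual residue-level anisotropic-network range).
#' @param elasticK elastic network force constant, kJ/mol/A^2 (default 50).
#' @param ljEpsilon Lennard-Jones well depth, kJ/mol (default 80). One bead
#'   stands for a whole residue and the bundled fixtures carry charge
#'   densities far above a real 150 kDa ion, so the per-pair cohesion is
#'   calibrated against two controls: a rigid cluster keeps its CCS within
#'   2 percent and the standard charged fixture collapses with a narrow
#'   final CCS window.
#' @param ljSigma Lennard-Jones diameter, A (default 6.6, the fixture bead
#'   diameter, so contact pairs sit at the potential minimum; use about 4.7
#'   for CA-trace inputs).
#' @param coulombConstant Coulomb prefactor, kJ/mol * A / e^2
#'   (default 1389.35, vacuum).
#' @param dielectric relative dielectric (1 for vacuum runs).
#' @param temperature thermostat temperature, K (default 300).
#' @param friction Langevin friction, 1/ps (default 0.05: in vacuum the
#'   thermostat coupling is weak; there is no solvent drag).
#' @param dt integration step, ps (default 0.01, i.e. 10 fs).
#' @param nSteps number of steps (default 200000).
#' @param reportStride record coordinates/CCS every this many steps
#'   (default 1000).
#' @param seed RNG seed.
#' @param beadMass bead mass, Da (default 110, an average residue).
#' @param minimizeSteps,minimizeMaxDisp capped-displacement steepest-descent
#'   steps run before dynamics (default 100 steps, 0.05 A per-coordinate
#'   cap): they relax steric overlaps — e.g. inter-domain contacts of
#'   compact conformers sitting inside the LJ wall — so the integrator
#'   starts from finite forces. The reported initial frame and CCS are the
#'   unminimised input.
#' @param ccsOrientations,ccsPoints reduced CCS settings for per-frame
#'   scoring.
#' @return named parameter list
#' @export
forceFieldParams <- function(bondK = 500, bondR0 = NA_real_,
                             elasticNetworkCutoff = 15, elasticK = 50,
                             ljEpsilon = 80, ljSigma = 6.6,
                             coulombConstant = 1389.35, dielectric = 1,
                             temperature = 300, friction = 0.05, dt = 0.01,
                             nSteps = 200000L, reportStride = 1000L,
                             seed = 1L, beadMass = 110,
                             minimizeSteps = 100L, minimizeMaxDisp = 0.05,
                             ccsOrientations = 60L, ccsPoints = 8000L) {
  stopifnot(bondK > 0, elasticNetworkCutoff > 0, elasticK > 0, ljEpsilon > 0,
            ljSigma > 0, coulombConstant > 0, dielectric > 0, temperature > 0,
            friction > 0, dt > 0, nSteps >= 0, reportStride >= 1)
  list(bondK = bondK, bondR0 = bondR0,
       elasticNetworkCutoff = elasticNetworkCutoff, elasticK = elasticK,
       ljEpsilon = ljEpsilon, ljSigma = ljSigma,
       coulombConstant = coulombConstant, dielectric = dielectric,
       temperature = temperature, friction = friction, dt = dt,
       nSteps = as.integer(nSteps), reportStride = as.integer(reportStride),
       seed = as.integer(seed), beadMass = beadMass,
       minimizeSteps = as.integer(minimizeSteps),
       minimizeMaxDisp = minimizeMaxDisp,
       ccsOrientations = as.integer(ccsOrientations),
       ccsPoints = as.integer(ccsPoints))
}

#' Assign integer charges to structure sites
#'
#' Places `netCharge` unit charges to mimic the lowest charge state observed
#' for the protein ion in native MS. `surface_spread` places charges on
#' solvent-exposed sites (exposure proxied by the neighbour count within
#' `shellRadius`: the less-buried half of the atoms are eligible) by greedy
#' farthest-point spreading: the first charge goes to the eligible site
#' farthest from the centroid; each next charge maximises the minimum
#' distance to the charges already placed. `basic_residues` first restricts
#' eligible sites to Arg/Lys/His side-chain tips. Deterministic given the
#' structure (ties resolved by lowest atom index).
#'
#' @param structure a [Structure]
#' @param topology an [AntibodyTopology] (reserved for site filtering)
#' @param netCharge total charge in elementary charges (>= 0)
#' @param rule `"surface_spread"` or `"basic_residues"`
#' @param shellRadius neighbour-count shell in Angstrom (default 10)
#' @return a [ChargeAssignment]
#' @export
assignCharges <- function(structure, topology, netCharge,
                          rule = c("surface_spread", "basic_residues"),
                          shellRadius = 10) {
  rule <- match.arg(rule)
  stopifnot(netCharge >= 0)
  if (netCharge == 0)
    return(new("ChargeAssignment", sites = integer(), charges = integer(),
               netCharge = 0L, rule = rule))
  a <- atoms(structure)
  xyz <- coords(structure)
  if (rule == "basic_residues") {
    eligible <- which(a$resname %in% c("ARG", "LYS", "HIS") &
                        trimws(a$name) %in% c("NZ", "NH1", "NH2", "NE2", "ND1"))
    if (!length(eligible))
      stop("no basic-residue side-chain sites present; use rule = 'surface_spread'")
  } else {
    d2 <- as.matrix(stats::dist(xyz))^2
    counts <- rowSums(d2 <= shellRadius^2) - 1
    eligible <- which(counts <= stats::quantile(counts, 0.5))
  }
  if (netCharge > length(eligible))
    stop("net charge ", netCharge, " exceeds the ", length(eligible),
         " eligible sites")
  cent <- colMeans(xyz)
  d0 <- rowSums((xyz[eligible, , drop = FALSE] -
                   matrix(cent, length(eligible), 3, byrow = TRUE))^2)
  chosen <- eligible[which.max(d0)]
  while (length(chosen) < netCharge) {
    rest <- setdiff(eligible, chosen)
    minD <- vapply(rest, function(i) {
      min(rowSums((xyz[chosen, , drop = FALSE] -
                     matrix(xyz[i, ], length(chosen), 3, byrow = TRUE))^2))
    }, numeric(1))
    chosen <- c(chosen, rest[which.max(minD)])
  }
  new("ChargeAssignment", sites = as.integer(chosen),
      charges = rep(1L, netCharge), netCharge = as.integer(netCharge),
      rule = rule)
}

# one bead per residue at CA (or residue centroid), carrying the residue's
# rigid-body membership; fixture beads keep element BB, others become CG
.coarseGrain <- function(structure, topology) {
  a <- atoms(structure)
  keys <- atomResidueKeys(structure)
  ukeys <- unique(keys)
  nm <- trimws(a$name)
  pos <- matrix(NA_real_, length(ukeys), 3)
  element <- chain <- character(length(ukeys))
  resid <- integer(length(ukeys))
  for (i in seq_along(ukeys)) {
    sel <- which(keys == ukeys[i])
    ca <- sel[nm[sel] == "CA"]
    pos[i, ] <- if (length(ca)) unlist(a[ca[1], c("x", "y", "z")]) else
      colMeans(coords(structure)[sel, , drop = FALSE])
    element[i] <- if (any(a$element[sel] == "BB")) "BB" else "CG"
    chain[i] <- a$chain[sel[1]]
    resid[i] <- a$resid[sel[1]]
  }
  group <- integer(length(ukeys))
  bodies <- names(topology@rigidBodies)
  for (b in seq_along(bodies))
    group[ukeys %in% topology@rigidBodies[[bodies[b]]]] <- b
  beads <- structureFromAtoms(data.frame(
    name = "CA", element = element, resname = "BEA", resid = resid,
    chain = chain, x = pos[, 1], y = pos[, 2], z = pos[, 3],
    stringsAsFactors = FALSE),
    metadata = list(source = "coarse-grained", parent = structure@metadata$source))
  list(beads = beads, keys = ukeys, group = group)
}

#' Simulate the gas-phase collapse of a charged conformer
#'
#' Coarse-grains the structure to one bead per residue, maps the charge
#' assignment onto the beads, and integrates vacuum Langevin dynamics (BAOAB
#' splitting) under the force field in `ff`. The CCS of every reported frame
#' is computed with the projection approximation; the final-window range is
#' the CCS range over the final 10 percent of reported frames.
#'
#' @param structure a clash-free [Structure] (e.g. a selected compact
#'   conformer)
#' @param topology an [AntibodyTopology]
#' @param charges a [ChargeAssignment] on the atoms of `structure`
#' @param ff parameters from [forceFieldParams()]
#' @param radii a [CollisionRadii] covering the bead elements
#' @param reportStride overrides `ff$reportStride` when given
#' @return a [CollapseTrajectory]
#' @export
simulateCollapse <- function(structure, topology, charges,
                             ff = forceFieldParams(), radii = defaultRadii(),
                             reportStride = NULL) {
  stride <- if (is.null(reportStride)) ff$reportStride else as.integer(reportStride)
  cg <- .coarseGrain(structure, topology)
  beads <- cg$beads
  n <- nAtoms(beads)
  xyz <- coords(beads)
  a <- atoms(beads)

  # map site charges onto residues' beads
  q <- numeric(n)
  if (length(charges@sites)) {
    siteKeys <- atomResidueKeys(structure)[charges@sites]
    for (i in seq_along(siteKeys)) {
      b <- match(siteKeys[i], cg$keys)
      q[b] <- q[b] + charges@charges[i]
    }
  }

  # chain bonds between consecutive residues (within a 10 A proximity guard
  # against true chain breaks)
  bonds <- NULL
  ord <- order(a$chain, a$resid)
  for (k in seq_len(n - 1)) {
    i <- ord[k]; j <- ord[k + 1]
    if (a$chain[i] != a$chain[j]) next
    if (a$resid[j] - a$resid[i] != 1) next
    r <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
    if (r < 10) bonds <- rbind(bonds, c(i, j, r))
  }
  if (is.null(bonds)) bonds <- matrix(numeric(0), 0, 3)
  bondR0 <- if (is.finite(ff$bondR0)) rep(ff$bondR0, nrow(bonds)) else bonds[, 3]

  # intra-body elastic network
  en <- NULL
  for (g in unique(cg$group[cg$group > 0])) {
    idx <- which(cg$group == g)
    if (length(idx) < 2) next
    D <- as.matrix(stats::dist(xyz[idx, , drop = FALSE]))
    pairs <- which(upper.tri(D) & D <= ff$elasticNetworkCutoff, arr.ind = TRUE)
    if (nrow(pairs))
      en <- rbind(en, cbind(idx[pairs[, 1]], idx[pairs[, 2]],
                            D[pairs]))
  }
  if (is.null(en)) en <- matrix(numeric(0), 0, 3)

  sim <- .langevin_cg(xyz, rep(ff$beadMass, n), q,
                      matrix(as.integer(bonds[, 1:2]), ncol = 2),
                      as.numeric(bondR0), ff$bondK,
                      matrix(as.integer(en[, 1:2]), ncol = 2),
                      as.numeric(en[, 3]), ff$elasticK,
                      ff$ljEpsilon, ff$ljSigma,
                      ff$coulombConstant / ff$dielectric,
                      ff$temperature, ff$friction, ff$dt,
                      ff$nSteps, stride, ff$seed,
                      ff$minimizeSteps, ff$minimizeMaxDisp)
  nf <- dim(sim$frames)[3]
  frames <- lapply(seq_len(nf), function(f) t(sim$frames[, , f]))

  rads <- radiusOf(radii, a$element)
  ccsv <- vapply(frames, function(fr) {
    1.14 * mean(.pa_orientations(fr, rads, ff$ccsOrientations, "monte_carlo",
                                 ff$ccsPoints, 0.5, ff$seed))
  }, numeric(1))
  nw <- max(1L, ceiling(0.1 * nf))
  w <- ccsv[(nf - nw + 1L):nf]
  new("CollapseTrajectory", template = beads, frames = frames,
      stepIndex = as.integer(sim$steps), ccsSeries = ccsv,
      finalCcs = ccsv[nf], finalWindowRange = max(w) - min(w),
      netCharge = charges@netCharge, seed = as.numeric(ff$seed), params = ff)
}

#' Replicate collapse simulations and report the cross-replicate spread
#'
#' Runs [simulateCollapse()] for each structure variant with its own seed
#' and reports the spread of final CCS values across replicates,
#' `100 * (max - min) / mean` percent.
#'
#' @param structures list of [Structure] variants (e.g. the selected compact
#'   conformers)
#' @param topology an [AntibodyTopology]
#' @param netCharge charge state applied to every variant
#' @param ff parameters from [forceFieldParams()]; each replicate r runs
#'   with seed `seeds[r]`.
#' @param radii a [CollisionRadii]
#' @param seeds one seed per variant (distinct for independent replicates)
#' @param rule charge placement rule, see [assignCharges()]
#' @return list with `trajectories`, `finalCcs` and `spreadPct`
#' @export
replicateCollapse <- function(structures, topology, netCharge,
                              ff = forceFieldParams(), radii = defaultRadii(),
                              seeds = seq_along(structures),
                              rule = "surface_spread") {
  stopifnot(length(structures) >= 1, length(seeds) == length(structures))
  trajs <- vector("list", length(structures))
  for (r in seq_along(structures)) {
    ffr <- ff
    ffr$seed <- as.integer(seeds[r])
    ch <- assignCharges(structures[[r]], topology, netCharge, rule = rule)
    trajs[[r]] <- simulateCollapse(structures[[r]], topology, ch, ffr, radii)
  }
  fin <- vapply(trajs, function(t) t@finalCcs, numeric(1))
  spread <- if (length(fin) > 1) 100 * (max(fin) - min(fin)) / mean(fin) else 0
  list(trajectories = trajs, finalCcs = fin, spreadPct = spread)
}
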