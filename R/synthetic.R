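#' @include AllClasses.R AllGenerics.R structure-io.R radii.R
NULL

#' Parameters for the synthetic Y-shaped antibody generator
#'
#' The generator builds a coarse-grained immunoglobulin analogue: two Fab
#' bead clusters and one Fc bead cluster joined at a hinge junction by
#' per-arm linkers of flexible three-atom (N/CA/C) residues at the 3.8
#' Angstrom CA-CA virtual bond spacing, so fixture "residue counts" compare
#' directly to upper-hinge residue counts of real IgG subclasses (5/3/12/7
#' for IgG1-4).
#'
#' @param beadsPerDomain beads per globular domain (default 40).
#' @param beadRadius bead radius in Angstrom (default 3).
#' @param armLength distance from the hinge junction to each Fab domain
#'   centre, Angstrom; `NULL` (default) derives the shortest geometrically
#'   consistent value from the linker length and domain radius, so reach
#'   grows with the flexible residue count.
#' @param stemLength distance from the hinge junction to the Fc domain
#'   centre; `NULL` derives it from the domain radius.
#' @param flexibleResiduesPerArm number of torsionally flexible upper-hinge
#'   residues per arm (>= 0; default 5, the IgG1 upper-hinge count).
#' @param coreHingeResidues number of disulfide-bonded core-hinge residue
#'   pairs zipping the two chains below the junction (>= 1; default 2, the
#'   IgG1 hinge disulfide count). Each pair carries a detectable SG-SG
#'   disulfide; the most N-terminal one bounds the flexible segment.
#' @param interArmAngle angle between the two arms in degrees (default 110).
#' @param linkerRise axial rise per linker residue in the initial pose, A
#'   (default 2.6). The CA-CA virtual bond stays 3.8 A; a rise below 3.8
#'   curls the linker into a zigzag, so the resting hinge stores extension
#'   headroom proportional to its residue count, as a peptide in a
#'   non-extended conformation does.
#' @param seed RNG seed for the small positional jitter on domain beads.
#' @return named parameter list
#' @export
syntheticAntibodyParams <- function(beadsPerDomain = 40L, beadRadius = 3,
                                    armLength = NULL, stemLength = NULL,
                                    flexibleResiduesPerArm = 5L,
                                    coreHingeResidues = 2L,
                                    interArmAngle = 110, linkerRise = 2.6,
                                    seed = 1L) {
  stopifnot(beadsPerDomain >= 1, beadRadius > 0, flexibleResiduesPerArm >= 0,
            coreHingeResidues >= 1, interArmAngle > 0, interArmAngle < 180,
            linkerRise > 0, linkerRise <= 3.8)
  if (!is.null(armLength)) stopifnot(armLength > 0)
  if (!is.null(stemLength)) stopifnot(stemLength > 0)
  list(beadsPerDomain = as.integer(beadsPerDomain), beadRadius = beadRadius,
       armLength = armLength, stemLength = stemLength,
       flexibleResiduesPerArm = as.integer(flexibleResiduesPerArm),
       coreHingeResidues = as.integer(coreHingeResidues),
       interArmAngle = interArmAngle, linkerRise = linkerRise,
       seed = as.integer(seed))
}

# deterministic uniform packing of n points in a ball: the n cubic-lattice
# sites (edge = `spacing`) closest to the origin, so nearest-neighbour
# distances equal `spacing` throughout; returns n x 3 matrix centred at 0
.ballPacking <- function(n, spacing) {
  if (n == 1) return(matrix(0, 1, 3))
  k <- ceiling((3 * n / (4 / 3 * pi))^(1 / 3)) + 1
  g <- seq(-k, k)
  lat <- as.matrix(expand.grid(x = g, y = g, z = g)) * spacing
  d2 <- rowSums(lat^2)
  ord <- order(d2, lat[, 1], lat[, 2], lat[, 3])
  pts <- lat[ord[seq_len(n)], , drop = FALSE]
  sweep(pts, 2, colMeans(pts))
}

#' Generate a synthetic Y-shaped antibody fixture
#'
#' Builds a [Structure] plus matching [AntibodyTopology]: rigid bodies
#' `Fab1`/`Fab2`/`Fc_core` (bead clusters, element `BB`) joined by per-arm
#' flexible linkers; a cysteine pair at the hinge junction provides a
#' detectable inter-chain disulfide bounding the flexible segment. The
#' initial pose is an open Y; no two beads of different components approach
#' below 0.9 bead diameters, otherwise generation fails. Deterministic for a
#' fixed seed.
#'
#' @param params from [syntheticAntibodyParams()]
#' @return list with `structure`, `topology`, `radii` (a [CollisionRadii]
#'   whose `BB` entry equals `beadRadius`) and `params`
#' @examples
#' fx <- makeSyntheticAntibody(syntheticAntibodyParams(beadsPerDomain = 10))
#' fx$structure
#' @export
makeSyntheticAntibody <- function(params = syntheticAntibodyParams()) {
  oldseed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(oldseed))
    assign(".Random.seed", oldseed, envir = globalenv()))
  set.seed(params$seed)

  nB <- params$beadsPerDomain
  rB <- params$beadRadius
  m <- params$flexibleResiduesPerArm
  cH <- params$coreHingeResidues
  rise <- params$linkerRise
  zig <- sqrt(3.8^2 - rise^2) / 2   # zigzag amplitude keeping CA-CA = 3.8 A
  spacing <- 2.2 * rB
  pack <- .ballPacking(nB, spacing)
  rDom <- if (nB > 1) max(sqrt(rowSums(pack^2))) else rB
  linkerSpan <- (m + 1) * rise
  armLen <- if (is.null(params$armLength)) linkerSpan + rDom + 2.5 else
    params$armLength
  stemLen <- if (is.null(params$stemLength)) cH * rise + rDom + 4 else
    params$stemLength

  alpha <- params$interArmAngle / 2 * pi / 180
  dirs <- list(A = c(-sin(alpha), 0, cos(alpha)),
               B = c(sin(alpha), 0, cos(alpha)))
  junction <- list(A = c(-0.8, 0, 0), B = c(0.8, 0, 0))
  perp <- c(0, 1, 0)

  rows <- list()
  addAtom <- function(name, element, resname, resid, chain, p) {
    rows[[length(rows) + 1]] <<- data.frame(
      name = name, element = element, resname = resname, resid = resid,
      chain = chain, x = p[1], y = p[2], z = p[3], stringsAsFactors = FALSE)
  }

  fabKeys <- list(); flexKeys <- list(); fcKeys <- character()
  stemBeads <- pack + matrix(c(0, 0, -stemLen), nB, 3, byrow = TRUE) +
    matrix(stats::rnorm(3 * nB, sd = 0.1), nB, 3)
  stemHalf <- split(seq_len(nB), rep(c("A", "B"), length.out = nB))
  components <- list()

  for (ch in c("A", "B")) {
    d <- dirs[[ch]]; J <- junction[[ch]]
    fabCenter <- J + d * armLen
    fab <- pack + matrix(fabCenter, nB, 3, byrow = TRUE) +
      matrix(stats::rnorm(3 * nB, sd = 0.1), nB, 3)
    components[[paste0("fab", ch)]] <- fab
    # Fab domain beads, one residue each
    for (i in seq_len(nB))
      addAtom("CA", "BB", "FAB", i, ch, fab[i, ])
    # Fab-side anchor residue (rigid, supplies the phi reference for the
    # first flexible residue)
    anchorCA <- J + d * linkerSpan + perp * zig
    pj <- perp * 0.45
    addAtom("N", "N", "GLY", nB + 1L, ch, anchorCA + 1.25 * d)
    addAtom("CA", "C", "GLY", nB + 1L, ch, anchorCA)
    addAtom("C", "C", "GLY", nB + 1L, ch, anchorCA - 1.25 * d + pj)
    fabKeys[[ch]] <- residueKey(ch, seq_len(nB + 1L))
    # flexible linker residues, Fab side first, on a zigzag with axial rise
    # `linkerRise` per residue and exact 3.8 A CA-CA spacing
    fk <- character(0)
    if (m > 0) {
      for (i in seq_len(m)) {
        resid <- nB + 1L + i
        ca <- J + d * ((m - i + 1) * rise) + perp * zig * (-1)^i
        pj <- perp * 0.45 * (-1)^i
        addAtom("N", "N", "GLY", resid, ch, ca + 1.25 * d + pj)
        addAtom("CA", "C", "GLY", resid, ch, ca)
        addAtom("C", "C", "GLY", resid, ch, ca - 1.25 * d + pj)
        fk <- c(fk, residueKey(ch, resid))
      }
    }
    flexKeys[[ch]] <- fk
    # core hinge: cysteine residues running down the stem axis, zipped to
    # the other chain by SG-SG disulfides; the first pair bounds the
    # flexible segment
    down <- c(0, 0, -1)
    resid <- nB + 1L + m
    for (j in seq_len(cH)) {
      resid <- resid + 1L
      ca <- J + down * (j * rise) + perp * zig * (-1)^(m + j)
      pj <- perp * 0.45 * (-1)^(m + j)
      addAtom("N", "N", "CYS", resid, ch, ca - 1.25 * down + pj)
      addAtom("CA", "C", "CYS", resid, ch, ca)
      addAtom("C", "C", "CYS", resid, ch, ca + 1.25 * down + pj)
      addAtom("SG", "S", "CYS", resid, ch,
              c(sign(J[1]) * 1.025, ca[2], ca[3] - 1.2))
      fcKeys <- c(fcKeys, residueKey(ch, resid))
    }
    # this chain's half of the Fc stem beads
    for (i in stemHalf[[ch]]) {
      resid <- resid + 1L
      addAtom("CA", "BB", "FCC", resid, ch, stemBeads[i, ])
      fcKeys <- c(fcKeys, residueKey(ch, resid))
    }
  }
  components$stem <- stemBeads

  # initial-pose overlap check between distinct components (bead centres)
  comp <- components
  for (i in seq_along(comp)) {
    for (j in seq_along(comp)) {
      if (j <= i) next
      d2 <- outer(rowSums(comp[[i]]^2), rowSums(comp[[j]]^2), `+`) -
        2 * comp[[i]] %*% t(comp[[j]])
      dmin <- sqrt(max(0, min(d2)))
      if (dmin < 0.9 * 2 * rB)
        stop("geometrically impossible parameters: components '",
             names(comp)[i], "' and '", names(comp)[j],
             "' overlap in the initial pose (min distance ",
             sprintf("%.2f", dmin), " A)")
    }
  }

  atoms <- do.call(rbind, rows)
  atoms$serial <- seq_len(nrow(atoms))
  structure <- structureFromAtoms(atoms, metadata = list(
    source = "synthetic", generator = "makeSyntheticAntibody",
    seed = params$seed))

  coreResid <- nB + 1L + m + seq_len(cH)
  disulfides <- data.frame(
    chain_a = "A", resid_a = coreResid, chain_b = "B", resid_b = coreResid,
    sg_distance = 2.05, stringsAsFactors = FALSE)
  topology <- new("AntibodyTopology",
                  rigidBodies = list(Fab1 = fabKeys$A, Fab2 = fabKeys$B,
                                     Fc_core = fcKeys),
                  flexibleResidues = list(arm1 = flexKeys$A, arm2 = flexKeys$B),
                  disulfides = disulfides, unassigned = character())

  radii <- collisionRadii(radii = c(H = 1.2, C = 1.7, N = 1.55, O = 1.52,
                                    S = 1.8, BB = rB, CG = 3.8))
  list(structure = structure, topology = topology, radii = radii,
       params = params)
}

#' Generate a synthetic TWIMS calibrant table
#'
#' Drift times are constructed so that the reduced-mass/charge-corrected CCS
#' obeys `CCS' = powerA * t'^powerB` exactly when `noiseSd = 0`; Gaussian
#' multiplicative noise of relative standard deviation `noiseSd` is applied
#' to the drift times otherwise.
#'
#' @param powerA,powerB power-law scale (> 0) and exponent of the generated
#'   relationship.
#' @param n number of calibrants (>= 2).
#' @param noiseSd relative noise standard deviation on drift times.
#' @param seed RNG seed.
#' @param gasMass drift-gas mass in Da (default nitrogen, 28.006).
#' @return data.frame with columns `ccs` (Angstrom^2), `drift` (corrected
#'   drift time), `mass` (Da), `charge`.
#' @export
makeCalibrantSet <- function(powerA, powerB, n, noiseSd = 0, seed = 1,
                             gasMass = 28.006) {
  if (n < 2) stop("calibration is underdetermined with fewer than 2 calibrants")
  stopifnot(powerA > 0)
  oldseed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(oldseed))
    assign(".Random.seed", oldseed, envir = globalenv()))
  set.seed(seed)
  mass <- seq(12000, 160000, length.out = n)
  charge <- pmax(1L, round(0.078 * sqrt(mass)))
  drift <- seq(1, 8, length.out = n)
  mu <- mass * gasMass / (mass + gasMass)
  ccsPrime <- powerA * drift^powerB
  ccsRef <- ccsPrime * charge / sqrt(mu)
  driftObs <- drift * (1 + stats::rnorm(n, sd = noiseSd))
  data.frame(ccs = ccsRef, drift = driftObs, mass = mass, charge = charge)
}

#' Generate an electrospray charge-ladder peak list
#'
#' m/z = (M + z * 1.00728) / z for each charge z (proton mass 1.00728 Da).
#'
#' @param mass neutral mass in Da (> 0)
#' @param charges vector of distinct positive integer charge states
#' @return data.frame with columns `mz` and `intensity`, sorted by m/z
#' @examples
#' makeChargeLadder(149328, 21:24)
#' @export
makeChargeLadder <- function(mass, charges) {
  if (length(charges) < 1) stop("at least one charge state required")
  if (any(charges <= 0) || anyDuplicated(charges))
    stop("charges must be distinct positive integers")
  stopifnot(mass > 0)
  mp <- 1.00728
  mz <- (mass + charges * mp) / charges
  out <- data.frame(mz = mz, intensity = 1)
  out[order(out$mz), , drop = FALSE]
}
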