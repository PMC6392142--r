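#' @include AllClasses.R AllGenerics.R ccs.R kinematics.R
NULL

#' Parameters for the rapidly-exploring random tree sampler
#'
#' @param nSamples number of accepted conformers, including the input
#'   conformation at the tree root (default 10000).
#' @param stepSize maximum extension per iteration, expressed in degrees per
#'   torsion (default 45): the extension norm in dihedral space is
#'   `stepSize * sqrt(d)` for `d` torsions, so per-joint exploration is
#'   comparable across hinge lengths; at the default the accepted nodes
#'   approach independent random hinge conformations, which is the intended
#'   energetically unweighted sampling.
#' @param clashFactor steric tolerance: a clash is any inter-body pair closer
#'   than `clashFactor * (r_i + r_j)` (default 0.7).
#' @param maxExtensionAttempts attempt budget; when exhausted a partial
#'   ensemble is returned with its `truncated` flag set (default
#'   `50 * nSamples`).
#' @param seed RNG seed.
#' @param ccsOrientations,ccsPoints reduced CCS settings used to score every
#'   conformer during sampling (selected conformers can be re-scored at full
#'   settings afterwards).
#' @return a named list of sampler parameters
#' @export
rrtParams <- function(nSamples = 10000L, stepSize = 45, clashFactor = 0.7,
                      maxExtensionAttempts = 50L * nSamples, seed = 1L,
                      ccsOrientations = 100L, ccsPoints = 5000L) {
  stopifnot(nSamples >= 1, clashFactor > 0, clashFactor <= 1, stepSize > 0)
  list(nSamples = as.integer(nSamples), stepSize = stepSize,
       clashFactor = clashFactor,
       maxExtensionAttempts = as.integer(maxExtensionAttempts),
       seed = as.integer(seed),
       ccsOrientations = as.integer(ccsOrientations),
       ccsPoints = as.integer(ccsPoints))
}

# static per-atom vectors for the clash kernel
.clashInfo <- function(structure, topology, radii) {
  a <- atoms(structure)
  keys <- atomResidueKeys(structure)
  group <- integer(nrow(a))
  bodies <- names(topology@rigidBodies)
  for (b in seq_along(bodies))
    group[keys %in% topology@rigidBodies[[bodies[b]]]] <- b
  list(r = radiusOf(radii, a$element), group = group,
       chain = as.integer(factor(a$chain)), resid = as.integer(a$resid))
}

#' Steric clash test between rigid bodies and flexible residues
#'
#' TRUE iff any non-exempt atom pair is closer than
#' `clashFactor * (r_i + r_j)` where the radii are element collision radii
#' (without the probe). Pairs within one rigid body, within one residue, or
#' between sequence-adjacent residues of a chain are exempt (covalent
#' neighbours). Implemented with a spatial hash.
#'
#' @param structure a [Structure]
#' @param radii a [CollisionRadii]
#' @param clashFactor fraction in (0, 1]
#' @param topology an [AntibodyTopology] supplying the rigid partition
#' @return logical
#' @export
clashCheck <- function(structure, radii, clashFactor, topology) {
  info <- .clashInfo(structure, topology, collisionRadii(radii@radii, probe = 0))
  .clash_check(coords(structure), info$r, info$group, info$chain, info$resid,
               clashFactor)
}

#' Sample clash-free conformations with a rapidly-exploring random tree
#'
#' Grows an RRT over the upper-hinge dihedral vector: the tree starts at the
#' input conformation; each iteration draws a uniform random target vector,
#' finds the nearest tree node under the wrapped-Euclidean metric (lowest
#' index on ties), extends toward the target by at most `stepSize`, poses the
#' structure and accepts the node iff it is clash-free. Sampling explores
#' reachable conformational space without energetic weighting. Every
#' accepted conformer is scored by projection-approximation CCS at the
#' reduced settings in `params`. Deterministic for a fixed seed; runs with
#' the same seed and a larger `nSamples` extend the smaller ensemble.
#'
#' @param structure a [Structure] (clash-free input pose)
#' @param topology an [AntibodyTopology]
#' @param params sampler parameters from [rrtParams()]
#' @param radii a [CollisionRadii]
#' @return a [ConformerEnsemble]; with zero flexible residues the ensemble
#'   contains exactly the input conformation.
#' @export
sampleEnsemble <- function(structure, topology, params = rrtParams(),
                           radii = defaultRadii()) {
  info <- .torsionInfo(structure, topology)
  d <- length(info)
  xyz0 <- coords(structure)
  a <- atoms(structure)
  keys <- atomResidueKeys(structure)
  fab1 <- which(keys %in% topology@rigidBodies$Fab1)
  fab2 <- which(keys %in% topology@rigidBodies$Fab2)
  cinfo <- .clashInfo(structure, topology, collisionRadii(radii@radii, probe = 0))
  rccs <- radiusOf(radii, a$element)

  scoreAll <- function(coordsList) {
    n <- length(coordsList)
    v <- numeric(n); se <- numeric(n)
    for (i in seq_len(n)) {
      areas <- .pa_orientations(coordsList[[i]], rccs, params$ccsOrientations,
                                "monte_carlo", params$ccsPoints, 0.5,
                                params$seed + i)
      v[i] <- 1.14 * mean(areas)
      se[i] <- if (length(areas) > 1) stats::sd(areas) / sqrt(length(areas)) else 0
    }
    list(ccs = v, se = se)
  }
  centroids <- function(coordsList, idx) {
    t(vapply(coordsList, function(m) colMeans(m[idx, , drop = FALSE]),
             numeric(3)))
  }

  if (d == 0) {
    sc <- scoreAll(list(xyz0))
    return(new("ConformerEnsemble", template = structure, topology = topology,
               dihedrals = matrix(numeric(0), nrow = 1, ncol = 0),
               coordsList = list(xyz0), ccsValues = sc$ccs, ccsSE = sc$se,
               fab1Centroids = centroids(list(xyz0), fab1),
               fab2Centroids = centroids(list(xyz0), fab2),
               seed = params$seed, params = params, truncated = FALSE))
  }

  oldseed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(oldseed))
    assign(".Random.seed", oldseed, envir = globalenv()))
  set.seed(params$seed)

  root <- measureDihedrals(structure, topology)
  root[is.na(root)] <- 0
  stepNorm <- params$stepSize * sqrt(d)
  arrays <- .torsionArrays(info)
  nodes <- matrix(NA_real_, nrow = params$nSamples, ncol = d)
  nodes[1, ] <- root
  coordsList <- vector("list", params$nSamples)
  coordsList[[1]] <- xyz0
  accepted <- 1L
  attempts <- 0L
  while (accepted < params$nSamples && attempts < params$maxExtensionAttempts) {
    attempts <- attempts + 1L
    target <- stats::runif(d, -180, 180)
    diff <- wrapAngle(sweep(nodes[seq_len(accepted), , drop = FALSE], 2,
                            target, function(n, t) t - n))
    near <- which.min(rowSums(diff^2))
    delta <- diff[near, ]
    nd <- sqrt(sum(delta^2))
    qnew <- if (nd > stepNorm)
      wrapAngle(nodes[near, ] + stepNorm * delta / nd) else
      wrapAngle(nodes[near, ] + delta)
    xyz <- .applyTorsionsCoords(xyz0, info, qnew, arrays)
    if (.clash_check(xyz, cinfo$r, cinfo$group, cinfo$chain, cinfo$resid,
                     params$clashFactor)) next
    accepted <- accepted + 1L
    nodes[accepted, ] <- qnew
    coordsList[[accepted]] <- xyz
  }
  truncated <- accepted < params$nSamples
  if (truncated)
    warning("attempt budget exhausted: ", accepted, " of ", params$nSamples,
            " conformers accepted")
  nodes <- nodes[seq_len(accepted), , drop = FALSE]
  coordsList <- coordsList[seq_len(accepted)]
  sc <- scoreAll(coordsList)
  new("ConformerEnsemble", template = structure, topology = topology,
      dihedrals = nodes, coordsList = coordsList,
      ccsValues = sc$ccs, ccsSE = sc$se,
      fab1Centroids = centroids(coordsList, fab1),
      fab2Centroids = centroids(coordsList, fab2),
      seed = params$seed, params = params, truncated = truncated)
}

#' Select compact, mutually diverse conformers
#'
#' The first pick is the global CCS minimum; each subsequent pick is the
#' next-lowest-CCS conformer whose backbone RMSD to every already-selected
#' conformer exceeds `diversityRmsd`. RMSD is computed on CA/bead atoms in
#' the shared Fc-fixed frame (no superposition), so arm reorientations count
#' as diversity. If the diversity constraint exhausts the ensemble the
#' constraint is relaxed with a warning.
#'
#' @param ensemble a [ConformerEnsemble]
#' @param k number of conformers to select (>= 1, <= ensemble size)
#' @param diversityRmsd minimum pairwise RMSD in Angstrom (default 5)
#' @return list with `indices`, `ccs` and `structures` (list of [Structure])
#' @export
selectCompact <- function(ensemble, k, diversityRmsd = 5) {
  n <- nConformers(ensemble)
  if (k < 1) stop("k must be >= 1")
  if (k > n) stop("k (", k, ") exceeds ensemble size (", n, ")")
  nm <- trimws(atoms(ensemble@template)$name)
  bb <- if (any(nm == "CA")) which(nm == "CA") else seq_along(nm)
  ord <- order(ensemble@ccsValues)
  chosen <- ord[1]
  relaxed <- FALSE
  for (i in ord[-1]) {
    if (length(chosen) >= k) break
    ok <- all(vapply(chosen, function(j) {
      A <- ensemble@coordsList[[i]][bb, , drop = FALSE]
      B <- ensemble@coordsList[[j]][bb, , drop = FALSE]
      sqrt(mean(rowSums((A - B)^2))) > diversityRmsd
    }, logical(1)))
    if (ok) chosen <- c(chosen, i)
  }
  if (length(chosen) < k) {
    relaxed <- TRUE
    warning("diversity constraint exhausted the ensemble; relaxing RMSD filter")
    chosen <- c(chosen, setdiff(ord, chosen)[seq_len(k - length(chosen))])
  }
  structures <- lapply(chosen, function(i) conformer(ensemble, i))
  list(indices = chosen, ccs = ensemble@ccsValues[chosen],
       structures = structures, relaxed = relaxed,
       diversityRmsd = diversityRmsd)
}

#' Summarise a conformer ensemble
#'
#' Reports the CCS extremes and range (the ensemble flexibility metric), the
#' per-arm Fab centroid clouds, and the fraction of shared arm space.
#' `overlapFraction` is the hemisphere-crossing fraction: the two clouds are
#' separated by the perpendicular bisector plane of their mean centroids,
#' and the statistic is the mean fraction of conformers whose Fab centroid
#' lies on the other arm's side. Arms restricted to their own hemispheres
#' score near 0; arms sharing space score higher. (A voxelised occupancy of
#' each cloud is also returned; the crossing fraction is used as the overlap
#' statistic because voxel-set ratios are not volume-normalisable across
#' ensembles of different spread.)
#'
#' @param ensemble a [ConformerEnsemble]
#' @param voxelSize voxel edge in Angstrom for the exported cloud occupancy
#'   (default 5)
#' @return list with `n`, `ccsMin`, `ccsMax`, `deltaCcs`, `fab1Cloud`,
#'   `fab2Cloud`, `fab1Voxels`, `fab2Voxels`, `overlapFraction`, `voxelSize`
#' @export
summariseEnsemble <- function(ensemble, voxelSize = 5) {
  v <- ensemble@ccsValues
  c1 <- ensemble@fab1Centroids
  c2 <- ensemble@fab2Centroids
  m1 <- colMeans(c1)
  m2 <- colMeans(c2)
  axis <- m2 - m1
  nrm <- sqrt(sum(axis^2))
  if (nrm < 1e-9) {
    overlap <- 1  # indistinguishable clouds share all space
  } else {
    axis <- axis / nrm
    mid <- (m1 + m2) / 2
    s1 <- drop(sweep(c1, 2, mid) %*% axis)  # > 0: on arm2's side
    s2 <- drop(sweep(c2, 2, mid) %*% axis)  # < 0: on arm1's side
    overlap <- (mean(s1 > 0) + mean(s2 < 0)) / 2
  }
  vox <- function(m) unique(paste(floor(m[, 1] / voxelSize),
                                  floor(m[, 2] / voxelSize),
                                  floor(m[, 3] / voxelSize)))
  list(n = nConformers(ensemble), ccsMin = min(v), ccsMax = max(v),
       deltaCcs = max(v) - min(v),
       fab1Cloud = c1, fab2Cloud = c2,
       fab1Voxels = vox(c1), fab2Voxels = vox(c2),
       overlapFraction = overlap, voxelSize = voxelSize)
}
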