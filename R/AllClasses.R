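#' @useDynLib abgas, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
NULL

#' Molecular structure container
#'
#' An ordered collection of atoms (or coarse-grained beads) with element,
#' Cartesian coordinates in Angstrom, and residue/chain identity. This is the
#' common currency passed between all workflow stages: PDB input, hinge
#' sampling, CCS scoring and the vacuum collapse simulation.
#'
#' @slot atoms data.frame with columns `serial` (integer), `name`, `element`,
#'   `resname` (character), `resid` (integer, 1-based as in PDB), `ins`
#'   (insertion code, `""` if none), `chain` (single character), `x`, `y`, `z`
#'   (numeric, Angstrom) and `het` (logical, HETATM flag).
#' @slot metadata free-form list (e.g. `title`, `source`).
#'
#' @seealso [readPDB()], [writePDB()], [coords()], [nAtoms()]
#' @export
setClass("Structure",
  representation(atoms = "data.frame", metadata = "list"),
  prototype(metadata = list())
)

setValidity("Structure", function(object) {
  a <- object@atoms
  need <- c("serial", "name", "element", "resname", "resid", "ins",
            "chain", "x", "y", "z", "het")
  if (!all(need %in% names(a)))
    return(paste("atoms must have columns:", paste(need, collapse = ", ")))
  if (nrow(a) < 1) return("a Structure must contain at least one atom")
  if (anyDuplicated(a$serial)) return("atom serial numbers must be unique")
  if (any(!nzchar(a$element))) return("every atom needs a non-empty element")
  if (!all(is.finite(c(a$x, a$y, a$z)))) return("coordinates must be finite")
  TRUE
})

#' Disulfide-aware rigid/flexible partition of an antibody
#'
#' Partitions a [Structure] into three rigid bodies (the two Fab arms and the
#' Fc plus disulfide-bonded core hinge) and, per arm, the ordered flexible
#' upper-hinge residues: the segment between the Fab domain and the most
#' N-terminal inter-heavy-chain hinge disulfide. Only these residues are
#' torsionally sampled.
#'
#' @slot rigidBodies named list (`Fab1`, `Fab2`, `Fc_core`) of residue keys
#'   (`"chain:resid"`); pairwise disjoint.
#' @slot flexibleResidues list of two character vectors (`arm1`, `arm2`),
#'   residue keys ordered N- to C-terminal (Fab side first).
#' @slot disulfides data.frame with columns `chain_a`, `resid_a`, `chain_b`,
#'   `resid_b`, `sg_distance`.
#' @slot unassigned residue keys belonging to no body and no flexible set.
#' @export
setClass("AntibodyTopology",
  representation(rigidBodies = "list", flexibleResidues = "list",
                 disulfides = "data.frame", unassigned = "character"),
  prototype(
    rigidBodies = list(Fab1 = character(), Fab2 = character(),
                       Fc_core = character()),
    flexibleResidues = list(arm1 = character(), arm2 = character()),
    disulfides = data.frame(chain_a = character(), resid_a = integer(),
                            chain_b = character(), resid_b = integer(),
                            sg_distance = numeric()),
    unassigned = character()
  )
)

setValidity("AntibodyTopology", function(object) {
  rb <- object@rigidBodies
  if (!all(c("Fab1", "Fab2", "Fc_core") %in% names(rb)))
    return("rigidBodies must contain Fab1, Fab2 and Fc_core")
  all_rb <- unlist(rb, use.names = FALSE)
  if (anyDuplicated(all_rb)) return("rigid bodies must be pairwise disjoint")
  fl <- unlist(object@flexibleResidues, use.names = FALSE)
  if (any(fl %in% all_rb))
    return("flexible residues may not belong to a rigid body")
  TRUE
})

#' Collision radii table
#'
#' Element-to-radius mapping (Angstrom) plus the probe radius added to every
#' atom when building projection disks. Coarse-grained bead elements (`BB` for
#' synthetic fixture beads, `CG` for one-bead-per-residue collapse models) sit
#' alongside the standard van der Waals set.
#'
#' @slot radii named numeric vector, Angstrom, all positive.
#' @slot probe probe radius in Angstrom (default 1.0).
#' @seealso [defaultRadii()]
#' @export
setClass("CollisionRadii",
  representation(radii = "numeric", probe = "numeric"),
  prototype(probe = 1.0)
)

setValidity("CollisionRadii", function(object) {
  if (is.null(names(object@radii)) || any(!nzchar(names(object@radii))))
    return("radii must be a named numeric vector")
  if (any(object@radii <= 0)) return("all radii must be positive")
  if (length(object@probe) != 1 || object@probe < 0)
    return("probe must be a single non-negative number")
  TRUE
})

#' Projection-approximation CCS result
#'
#' Orientation-averaged projected area (PA) of the union of collision disks,
#' and the model collision cross section CCS = PA x 1.14. The scale factor is
#' applied exactly; `mcStandardError` is the across-orientation Monte-Carlo
#' standard error on the PA.
#'
#' @slot paArea projected area, Angstrom^2.
#' @slot ccs scaled CCS, Angstrom^2 (exactly `1.14 * paArea`).
#' @slot mcStandardError Monte-Carlo standard error on `paArea`, Angstrom^2.
#' @slot nOrientations number of random orientations averaged.
#' @slot sampler `"monte_carlo"` or `"grid"`.
#' @slot seed RNG seed used for orientations (and points).
#' @export
setClass("CCSResult",
  representation(paArea = "numeric", ccs = "numeric",
                 mcStandardError = "numeric", nOrientations = "integer",
                 sampler = "character", seed = "numeric")
)

setValidity("CCSResult", function(object) {
  if (object@paArea < 0) return("paArea must be non-negative")
  if (object@mcStandardError < 0) return("mcStandardError must be non-negative")
  if (!identical(object@ccs, 1.14 * object@paArea))
    return("ccs must equal 1.14 * paArea exactly")
  TRUE
})

#' Ensemble of hinge-sampled conformers
#'
#' Output of the rapidly-exploring random tree (RRT) sampler: accepted
#' clash-free conformations of the whole antibody obtained by varying the
#' upper-hinge backbone dihedrals, each scored by projection-approximation
#' CCS. Conformer 1 is always the input conformation (the tree root).
#'
#' @slot template the input [Structure] (atom table shared by all conformers).
#' @slot topology the [AntibodyTopology] used.
#' @slot dihedrals n x d matrix of sampled dihedral vectors (degrees,
#'   wrapped to (-180, 180]); columns ordered arm1 phi/psi pairs then arm2.
#' @slot coordsList list of n coordinate matrices (atoms x 3).
#' @slot ccsValues per-conformer CCS, Angstrom^2.
#' @slot ccsSE per-conformer Monte-Carlo standard error on PA, Angstrom^2.
#' @slot fab1Centroids,fab2Centroids n x 3 matrices of Fab centroid positions.
#' @slot seed RRT seed.
#' @slot params the sampler parameter list used.
#' @slot truncated TRUE if the attempt budget ran out before `nSamples`.
#' @export
setClass("ConformerEnsemble",
  representation(template = "Structure", topology = "AntibodyTopology",
                 dihedrals = "matrix", coordsList = "list",
                 ccsValues = "numeric", ccsSE = "numeric",
                 fab1Centroids = "matrix", fab2Centroids = "matrix",
                 seed = "numeric", params = "list", truncated = "logical")
)

setValidity("ConformerEnsemble", function(object) {
  n <- length(object@coordsList)
  if (n < 1) return("an ensemble must contain at least one conformer")
  if (length(object@ccsValues) != n)
    return("ccsValues length must match the number of conformers")
  if (nrow(object@dihedrals) != n)
    return("dihedrals must have one row per conformer")
  TRUE
})

#' Charge assignment for gas-phase simulation
#'
#' Placement of integer elementary charges on structure sites, mimicking the
#' charge state observed for the protein ion in native MS. Charges are placed
#' by greedy farthest-point spreading over solvent-exposed sites (or over
#' basic residue side chains).
#'
#' @slot sites integer atom indices carrying a charge.
#' @slot charges integer charge per site (elementary charges).
#' @slot netCharge total charge; equals `sum(charges)`.
#' @slot rule placement rule used.
#' @export
setClass("ChargeAssignment",
  representation(sites = "integer", charges = "integer",
                 netCharge = "integer", rule = "character")
)

setValidity("ChargeAssignment", function(object) {
  if (length(object@sites) != length(object@charges))
    return("sites and charges must have equal length")
  if (sum(object@charges) != object@netCharge)
    return("site charges must sum to netCharge")
  TRUE
})

#' Vacuum-collapse trajectory
#'
#' Time series of coordinates and CCS from the coarse-grained charged vacuum
#' Langevin simulation, with final-window statistics: `finalWindowRange` is
#' the CCS range (max - min) over the final 10 percent of reported frames,
#' the trajectory analogue of a final-nanosecond range.
#'
#' @slot template one-bead-per-residue [Structure] the frames refer to.
#' @slot frames list of coordinate matrices (beads x 3), strided.
#' @slot stepIndex integration step of each frame.
#' @slot ccsSeries per-frame CCS, Angstrom^2.
#' @slot finalCcs CCS of the last frame.
#' @slot finalWindowRange CCS range over the final 10 percent of frames.
#' @slot netCharge total charge carried.
#' @slot seed simulation seed.
#' @slot params force-field parameter list used.
#' @export
setClass("CollapseTrajectory",
  representation(template = "Structure", frames = "list",
                 stepIndex = "integer", ccsSeries = "numeric",
                 finalCcs = "numeric", finalWindowRange = "numeric",
                 netCharge = "integer", seed = "numeric", params = "list")
)

setValidity("CollapseTrajectory", function(object) {
  if (length(object@frames) < 1) return("at least one frame required")
  if (length(object@ccsSeries) != length(object@frames))
    return("ccsSeries must match the number of frames")
  if (!isTRUE(all.equal(object@finalCcs,
                        object@ccsSeries[length(object@ccsSeries)])))
    return("finalCcs must equal the last element of ccsSeries")
  if (object@finalWindowRange < 0) return("finalWindowRange must be >= 0")
  TRUE
})

#' Travelling-wave IM calibration fit
#'
#' Power-law calibration `CCS' = A * t'^B` between reduced-mass/charge
#' corrected CCS and corrected drift time, fitted by least squares in log
#' space on a calibrant table.
#'
#' @slot A scale coefficient (positive).
#' @slot B exponent.
#' @slot residualRms RMS relative residual of the fit.
#' @slot nCalibrants number of calibrants used (>= 2).
#' @slot gasMass drift-gas mass used for the reduced-mass correction, Da.
#' @slot deadTime dead-time subtracted from drift times, same unit as input.
#' @export
setClass("CalibrationFit",
  representation(A = "numeric", B = "numeric", residualRms = "numeric",
                 nCalibrants = "integer", gasMass = "numeric",
                 deadTime = "numeric")
)

setValidity("CalibrationFit", function(object) {
  if (object@A <= 0) return("A must be positive")
  if (object@nCalibrants < 2) return("at least 2 calibrants required")
  TRUE
})

#' Stage-by-stage workflow report
#'
#' Summary of the integrative workflow: CCS of the initial model, the
#' minimum-CCS conformer after Fab-arm sampling, and the collapsed gas-phase
#' model, with percentage reductions between consecutive stages and (when an
#' experimental CCS is supplied) comparison verdicts.
#'
#' @slot stages named numeric: `initial`, `sampledMin`, `collapsedFinal`
#'   CCS values in Angstrom^2 (NA where a stage was not run).
#' @slot uncertainties named numeric uncertainties for the stages (MC
#'   standard error for model stages; final-window range for collapse).
#' @slot reductions named numeric percent reductions between stages, each
#'   relative to the preceding stage.
#' @slot comparison data.frame of model-vs-experiment verdicts (0 rows if no
#'   experimental value was supplied).
#' @slot replicates data.frame of per-replicate collapse results.
#' @slot provenance list: seeds, parameters, input identifiers.
#' @export
setClass("StageReport",
  representation(stages = "numeric", uncertainties = "numeric",
                 reductions = "numeric", comparison = "data.frame",
                 replicates = "data.frame", provenance = "list")
)
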