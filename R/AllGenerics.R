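#' @include AllClasses.R
NULL

#' Number of atoms in a structure
#' @param x a [Structure]
#' @return integer atom count
#' @export
setGeneric("nAtoms", function(x) standardGeneric("nAtoms"))

#' Atom table accessor
#' @param x a [Structure]
#' @return the atom data.frame
#' @export
setGeneric("atoms", function(x) standardGeneric("atoms"))

#' Coordinate matrix accessor
#' @param x a [Structure], [ConformerEnsemble] conformer, or similar
#' @param ... further arguments for methods
#' @return numeric matrix (atoms x 3), Angstrom
#' @export
setGeneric("coords", function(x, ...) standardGeneric("coords"))

#' Replace the coordinates of a structure
#' @param x a [Structure]
#' @param value numeric matrix (atoms x 3)
#' @return the modified object
#' @export
setGeneric("coords<-", function(x, value) standardGeneric("coords<-"))

#' Collision cross section accessor
#' @param x a [CCSResult], [ConformerEnsemble] or [CollapseTrajectory]
#' @param ... further arguments for methods
#' @return CCS value(s) in Angstrom^2
#' @export
setGeneric("ccs", function(x, ...) standardGeneric("ccs"))

#' Projected-area accessor
#' @param x a [CCSResult]
#' @return projected area in Angstrom^2
#' @export
setGeneric("paArea", function(x) standardGeneric("paArea"))

#' Number of conformers / frames
#' @param x a [ConformerEnsemble] or [CollapseTrajectory]
#' @return integer count
#' @export
setGeneric("nConformers", function(x) standardGeneric("nConformers"))

#' Extract one conformer as a Structure
#' @param x a [ConformerEnsemble]
#' @param i conformer index
#' @return a [Structure]
#' @export
setGeneric("conformer", function(x, i) standardGeneric("conformer"))

#' @rdname nAtoms
setMethod("nAtoms", "Structure", function(x) nrow(x@atoms))

#' @rdname atoms
setMethod("atoms", "Structure", function(x) x@atoms)

#' @rdname coords
setMethod("coords", "Structure", function(x, ...) {
  m <- as.matrix(x@atoms[, c("x", "y", "z")])
  dimnames(m) <- NULL
  m
})

#' @rdname coords-set
#' @name coords<-
setReplaceMethod("coords", "Structure", function(x, value) {
  stopifnot(is.matrix(value), nrow(value) == nAtoms(x), ncol(value) == 3)
  x@atoms$x <- value[, 1]
  x@atoms$y <- value[, 2]
  x@atoms$z <- value[, 3]
  x
})

#' @rdname ccs
setMethod("ccs", "CCSResult", function(x, ...) x@ccs)

#' @rdname paArea
setMethod("paArea", "CCSResult", function(x) x@paArea)

#' @rdname ccs
setMethod("ccs", "ConformerEnsemble", function(x, ...) x@ccsValues)

#' @rdname ccs
setMethod("ccs", "CollapseTrajectory", function(x, ...) x@ccsSeries)

#' @rdname nConformers
setMethod("nConformers", "ConformerEnsemble", function(x) length(x@coordsList))

#' @rdname nConformers
setMethod("nConformers", "CollapseTrajectory", function(x) length(x@frames))

#' @rdname conformer
setMethod("conformer", "ConformerEnsemble", function(x, i) {
  stopifnot(length(i) == 1, i >= 1, i <= nConformers(x))
  s <- x@template
  coords(s) <- x@coordsList[[i]]
  s
})

setMethod("show", "Structure", function(object) {
  a <- object@atoms
  cat("Structure:", nrow(a), "atoms,",
      length(unique(paste(a$chain, a$resid, a$ins))), "residues,",
      length(unique(a$chain)), "chain(s)\n")
  if (!is.null(object@metadata$source))
    cat("  source:", object@metadata$source, "\n")
  cat("  elements:", paste(sort(unique(a$element)), collapse = " "), "\n")
})

setMethod("show", "AntibodyTopology", function(object) {
  cat("AntibodyTopology\n")
  for (nm in names(object@rigidBodies))
    cat(sprintf("  %-8s %d residues\n", nm, length(object@rigidBodies[[nm]])))
  cat(sprintf("  flexible: %d + %d upper-hinge residues (arm1 + arm2)\n",
              length(object@flexibleResidues$arm1),
              length(object@flexibleResidues$arm2)))
  cat(sprintf("  disulfides: %d\n", nrow(object@disulfides)))
})

setMethod("show", "CCSResult", function(object) {
  cat(sprintf("CCSResult: PA %.2f A^2, CCS %.2f A^2 (MC SE %.2f, %d orientations, %s)\n",
              object@paArea, object@ccs, object@mcStandardError,
              object@nOrientations, object@sampler))
})

setMethod("show", "ConformerEnsemble", function(object) {
  cat(sprintf("ConformerEnsemble: %d conformers, CCS [%.1f, %.1f] A^2 (dCCS %.1f)\n",
              nConformers(object), min(object@ccsValues), max(object@ccsValues),
              max(object@ccsValues) - min(object@ccsValues)))
  if (isTRUE(object@truncated))
    cat("  note: attempt budget exhausted before requested sample count\n")
})

setMethod("show", "CollapseTrajectory", function(object) {
  cat(sprintf(
    "CollapseTrajectory: %d frames, CCS %.1f -> %.1f A^2, final-window range %.1f, charge %d+\n",
    nConformers(object), object@ccsSeries[1], object@finalCcs,
    object@finalWindowRange, object@netCharge))
})

setMethod("show", "CalibrationFit", function(object) {
  cat(sprintf("CalibrationFit: CCS' = %.6g * t'^%.6g (rms resid %.3g, n = %d)\n",
              object@A, object@B, object@residualRms, object@nCalibrants))
})

setMethod("show", "ChargeAssignment", function(object) {
  cat(sprintf("ChargeAssignment: %d+ over %d sites (%s rule)\n",
              object@netCharge, length(object@sites), object@rule))
})

setMethod("show", "StageReport", function(object) {
  cat("StageReport\n")
  st <- object@stages
  un <- object@uncertainties
  lab <- c(initial = "initial model CCS",
           sampledMin = "Fab-arm sampling CCS (min)",
           collapsedFinal = "collapsed model CCS")
  for (nm in names(st)) {
    if (is.na(st[[nm]])) {
      cat(sprintf("  %-28s (not run)\n", lab[[nm]]))
    } else {
      cat(sprintf("  %-28s %9.1f A^2 (+/- %.1f)\n", lab[[nm]], st[[nm]],
                  if (is.na(un[[nm]])) 0 else un[[nm]]))
    }
  }
  for (nm in names(object@reductions))
    cat(sprintf("  reduction %-18s %8.1f %%\n", nm, object@reductions[[nm]]))
  if (nrow(object@comparison)) {
    cat("  vs experiment:\n")
    print(object@comparison, row.names = FALSE)
  } else {
    cat("  (no experimental CCS supplied)\n")
  }
})
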