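#' @include AllClasses.R AllGenerics.R structure-io.R
NULL

#' Wrap angles into (-180, 180] degrees
#' @param x numeric vector of angles in degrees
#' @return wrapped angles
#' @export
wrapAngle <- function(x) {
  y <- ((x + 180) %% 360) - 180
  y[y == -180] <- 180
  y
}

#' Dihedral angle of four points
#'
#' Standard signed torsion (IUPAC convention), degrees in (-180, 180].
#'
#' @param p1,p2,p3,p4 numeric 3-vectors
#' @return dihedral angle in degrees
#' @export
dihedralAngle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2],
          b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2],
          b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  b2h <- b2 / sqrt(sum(b2^2))
  m1 <- c(n1[2] * b2h[3] - n1[3] * b2h[2],
          n1[3] * b2h[1] - n1[1] * b2h[3],
          n1[1] * b2h[2] - n1[2] * b2h[1])
  wrapAngle(atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi)
}

#' Rotate points about an axis (Rodrigues formula)
#'
#' @param pts n x 3 matrix
#' @param origin point on the axis (3-vector)
#' @param axis axis direction (3-vector, need not be unit)
#' @param angleDeg rotation angle in degrees (right-handed about `axis`)
#' @return rotated n x 3 matrix
#' @export
rotatePoints <- function(pts, origin, axis, angleDeg) {
  u <- axis / sqrt(sum(axis^2))
  th <- angleDeg * pi / 180
  ct <- cos(th); st <- sin(th)
  v <- sweep(pts, 2, origin)
  ux <- cbind(u[2] * v[, 3] - u[3] * v[, 2],
              u[3] * v[, 1] - u[1] * v[, 3],
              u[1] * v[, 2] - u[2] * v[, 1])
  ud <- drop(v %*% u)
  vr <- v * ct + ux * st + outer(ud * (1 - ct), u)
  sweep(vr, 2, origin, `+`)
}

# Precompute, per flexible residue, the torsion bookkeeping needed by
# applyDihedrals: axis atoms, measurement reference atoms and the index set
# of atoms that move with the Fab side of each rotatable bond.
.torsionInfo <- function(structure, topology) {
  a <- atoms(structure)
  keys <- atomResidueKeys(structure)
  nm <- trimws(a$name)
  atomIdx <- function(key, name) {
    i <- which(keys == key & nm == name)
    if (length(i)) i[1] else NA_integer_
  }
  resAtoms <- function(key) which(keys == key)

  arms <- list(
    list(flex = topology@flexibleResidues$arm1, fab = "Fab1"),
    list(flex = topology@flexibleResidues$arm2, fab = "Fab2"))
  torsions <- list()
  for (arm in arms) {
    flex <- arm$flex
    if (!length(flex)) next
    fabAtoms <- which(keys %in% topology@rigidBodies[[arm$fab]])
    for (i in seq_along(flex)) {
      key <- flex[i]
      Ni <- atomIdx(key, "N"); CAi <- atomIdx(key, "CA"); Ci <- atomIdx(key, "C")
      if (any(is.na(c(Ni, CAi, Ci))))
        stop("flexible residue ", key, " lacks N/CA/C backbone atoms")
      before <- if (i > 1) unlist(lapply(flex[seq_len(i - 1)], resAtoms)) else integer()
      # reference atoms for absolute phi/psi: previous C and next N along the
      # chain (the Fab-side anchor residue supplies them for the first/last)
      ai <- a[resAtoms(key)[1], ]
      prevC <- {
        pk <- residueKey(ai$chain, ai$resid - 1L)
        if (i > 1) atomIdx(flex[i - 1], "C") else atomIdx(pk, "C")
      }
      nextN <- {
        nk <- residueKey(ai$chain, ai$resid + 1L)
        if (i < length(flex)) atomIdx(flex[i + 1], "N") else atomIdx(nk, "N")
      }
      resIdx <- resAtoms(key)
      hIdx <- resIdx[nm[resIdx] %in% c("H", "HN", "H1", "H2", "H3")]
      phiMoving <- c(fabAtoms, before, Ni, hIdx)
      psiMoving <- c(fabAtoms, before,
                     setdiff(resIdx, resIdx[nm[resIdx] %in% c("C", "O", "OXT")]))
      torsions[[length(torsions) + 1]] <- list(
        kind = "phi", axisA = Ni, axisB = CAi, ref = prevC, fourth = Ci,
        moving = unique(phiMoving))
      torsions[[length(torsions) + 1]] <- list(
        kind = "psi", axisA = CAi, axisB = Ci, ref = Ni, fourth = nextN,
        moving = unique(psiMoving))
    }
  }
  torsions
}

# measure the current dihedral of one torsion from a coordinate matrix;
# NA when a reference atom is missing (angle then treated as relative)
.measureTorsion <- function(xyz, tor) {
  if (is.na(tor$ref) || is.na(tor$fourth)) return(NA_real_)
  dihedralAngle(xyz[tor$ref, ], xyz[tor$axisA, ], xyz[tor$axisB, ],
                xyz[tor$fourth, ])
}

# flatten the torsion bookkeeping into parallel vectors for the C++ kernel
.torsionArrays <- function(torsions) {
  toIdx <- function(v) ifelse(is.na(v), 0L, as.integer(v))
  list(axisA = toIdx(vapply(torsions, `[[`, numeric(1), "axisA")),
       axisB = toIdx(vapply(torsions, `[[`, numeric(1), "axisB")),
       ref = toIdx(vapply(torsions, function(t) as.numeric(t$ref),
                          numeric(1))),
       fourth = toIdx(vapply(torsions, function(t) as.numeric(t$fourth),
                             numeric(1))),
       moving = lapply(torsions, function(t) as.integer(t$moving)))
}

# Apply target torsion angles to a coordinate matrix. Moving sets contain the
# Fab-side atoms, so rotating a bond reorients the arm while the Fc core
# stays fixed; rigid-body internal geometry is preserved exactly (pure
# rotations).
.applyTorsionsCoords <- function(xyz, torsions, targets, arrays = NULL) {
  if (is.null(arrays)) arrays <- .torsionArrays(torsions)
  .apply_torsions(xyz, arrays$axisA, arrays$axisB, arrays$ref, arrays$fourth,
                  arrays$moving, as.numeric(targets))
}

#' Measure the upper-hinge dihedral vector of a conformation
#'
#' @param structure a [Structure]
#' @param topology an [AntibodyTopology]
#' @return numeric vector of phi/psi angles (degrees), ordered arm1 then
#'   arm2, `(phi, psi)` per flexible residue; NA where a terminal reference
#'   atom is missing.
#' @export
measureDihedrals <- function(structure, topology) {
  info <- .torsionInfo(structure, topology)
  xyz <- coords(structure)
  vapply(info, function(tor) .measureTorsion(xyz, tor), numeric(1))
}

#' Pose the antibody at a given upper-hinge dihedral vector
#'
#' Sets each flexible residue's phi/psi by rigidly rotating all atoms on the
#' Fab side of the rotation bond; Fc-core atoms never move and bond lengths
#' and angles within rigid bodies are preserved exactly. Angles are absolute
#' targets in degrees; where a terminal reference atom is absent the value is
#' applied as a relative rotation.
#'
#' @param structure a [Structure]
#' @param topology an [AntibodyTopology]
#' @param dihedrals numeric vector, `2 x` total flexible residues, ordered as
#'   in [measureDihedrals()]
#' @return a new [Structure] in the requested pose
#' @export
applyDihedrals <- function(structure, topology, dihedrals) {
  info <- .torsionInfo(structure, topology)
  if (length(dihedrals) != length(info))
    stop("expected ", length(info), " dihedrals (2 per flexible residue), got ",
         length(dihedrals))
  xyz <- .applyTorsionsCoords(coords(structure), info, wrapAngle(dihedrals))
  coords(structure) <- xyz
  structure
}

#' RMSD after optimal superposition (Kabsch)
#'
#' @param A,B n x 3 coordinate matrices
#' @return RMSD in Angstrom after optimal rigid superposition of `B` onto `A`
#' @export
superposedRmsd <- function(A, B) {
  stopifnot(nrow(A) == nrow(B))
  ca <- colMeans(A); cb <- colMeans(B)
  A0 <- sweep(A, 2, ca); B0 <- sweep(B, 2, cb)
  s <- svd(crossprod(B0, A0))
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  Br <- B0 %*% t(R)
  sqrt(mean(rowSums((A0 - Br)^2)))
}
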