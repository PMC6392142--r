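#' @include AllClasses.R AllGenerics.R
NULL

#' Build a Structure from an atom table
#'
#' @param atoms data.frame with at least `name`, `element`, `resid`, `chain`,
#'   `x`, `y`, `z`; `serial`, `resname`, `ins` and `het` are filled with
#'   defaults when absent.
#' @param metadata optional list of free-form metadata.
#' @return a [Structure]
#' @export
structureFromAtoms <- function(atoms, metadata = list()) {
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  if (is.null(atoms$serial)) atoms$serial <- seq_len(nrow(atoms))
  if (is.null(atoms$resname)) atoms$resname <- "UNK"
  if (is.null(atoms$ins)) atoms$ins <- ""
  if (is.null(atoms$het)) atoms$het <- FALSE
  atoms$ins[is.na(atoms$ins)] <- ""
  atoms <- atoms[, c("serial", "name", "element", "resname", "resid", "ins",
                     "chain", "x", "y", "z", "het")]
  new("Structure", atoms = atoms, metadata = metadata)
}

#' Residue keys ("chain:resid" with any insertion code appended)
#'
#' @param chain,resid,ins vectors of chain id, residue number, insertion code
#' @return character vector of residue keys
#' @export
residueKey <- function(chain, resid, ins = "") {
  ins[is.na(ins) | ins == " "] <- ""
  paste0(chain, ":", resid, ins)
}

#' Residue keys of every atom in a structure
#' @param structure a [Structure]
#' @return character vector, one key per atom
#' @export
atomResidueKeys <- function(structure) {
  a <- atoms(structure)
  residueKey(a$chain, a$resid, a$ins)
}

#' Read a PDB file
#'
#' Parses ATOM/HETATM records in file order. Alternate locations: only blank
#' or 'A' altloc records are kept. HETATM records are retained and flagged in
#' the `het` column; their presence is noted in the metadata.
#'
#' @param path PDB file path
#' @return a [Structure]
#' @export
readPDB <- function(path) {
  if (!file.exists(path)) stop("cannot read PDB file: ", path)
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = FALSE, verbose = FALSE)),
    error = function(e) {
      stop("not a parseable PDB file (no ATOM records?): ", path,
           " [", conditionMessage(e), "]")
    })
  a <- pdb$atom
  if (is.null(a) || nrow(a) == 0)
    stop("PDB file contains no ATOM/HETATM records: ", path)
  keep <- is.na(a$alt) | a$alt %in% c("", "A")
  a <- a[keep, , drop = FALSE]
  if (nrow(a) == 0) stop("no atoms left after altloc filtering: ", path)
  element <- a$elesy
  bad <- is.na(element) | !nzchar(element)
  if (any(bad)) {
    # derive the element from the atom name: leading letters, digits stripped
    nm <- gsub("[^A-Za-z].*$", "", gsub("^[0-9]+", "", a$elety[bad]))
    element[bad] <- toupper(substr(nm, 1, 1))
  }
  chain <- a$chain
  chain[is.na(chain)] <- " "
  ins <- a$insert
  ins[is.na(ins)] <- ""
  atoms <- data.frame(
    serial = a$eleno, name = a$elety, element = element, resname = a$resid,
    resid = a$resno, ins = ins, chain = chain,
    x = a$x, y = a$y, z = a$z, het = a$type == "HETATM",
    stringsAsFactors = FALSE)
  if (anyDuplicated(atoms$serial))
    atoms$serial <- seq_len(nrow(atoms))
  structureFromAtoms(atoms, metadata = list(
    source = path, hasHet = any(atoms$het)))
}

#' Write a structure to a PDB file
#'
#' Coordinates are written at the fixed PDB precision (3 decimals), so a
#' read/write round trip reproduces coordinates to within 0.001 Angstrom.
#' Atom serials above 99999 are written in hexadecimal (a common widening
#' convention for oversized models). Chain identifiers must be single
#' characters.
#'
#' @param structure a [Structure]
#' @param path output file path
#' @return invisibly, the path
#' @export
writePDB <- function(structure, path) {
  stopifnot(is(structure, "Structure"))
  a <- atoms(structure)
  long <- unique(a$chain[nchar(trimws(a$chain)) > 1])
  if (length(long))
    stop("chain id(s) longer than one character: ", paste(long, collapse = ", "))
  ok <- tryCatch({
    con <- file(path, open = "wt"); close(con); TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop("cannot write to path: ", path)
  if (max(a$serial) <= 99999 && nrow(a) <= 99999) {
    xyz <- as.vector(t(coords(structure)))
    type <- ifelse(a$het, "HETATM", "ATOM")
    n <- nrow(a)
    bio3d::write.pdb(pdb = NULL, file = path, xyz = xyz, type = type,
                     resno = a$resid, resid = a$resname, eleno = a$serial,
                     elety = a$name, chain = a$chain, insert = a$ins,
                     elesy = a$element, o = rep(1, n), b = rep(0, n))
  } else {
    # hexadecimal serial convention for very large models
    lines <- sprintf("%-6s%5s %-4s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                     ifelse(a$het, "HETATM", "ATOM"),
                     ifelse(a$serial <= 99999, format(a$serial),
                            sprintf("%05X", a$serial)),
                     substr(a$name, 1, 4), "", substr(a$resname, 1, 3),
                     a$chain, a$resid %% 10000, substr(paste0(a$ins, " "), 1, 1),
                     a$x, a$y, a$z, 1, 0, a$element)
    writeLines(c(lines, "END"), path)
  }
  invisible(path)
}

#' Detect disulfide bonds from SG-SG distances
#'
#' One bond per cysteine SG pair within the cutoff; each SG participates in at
#' most one bond (greedy nearest-first pairing). The result is independent of
#' atom ordering: candidate pairs are ranked by distance with a lexicographic
#' tie-break on residue keys.
#'
#' @param structure a [Structure]
#' @param cutoff SG-SG distance cutoff in Angstrom (default 2.5: a typical
#'   2.05 Angstrom S-S bond plus slack)
#' @return data.frame with columns `chain_a`, `resid_a`, `chain_b`, `resid_b`,
#'   `sg_distance` (possibly 0 rows)
#' @export
detectDisulfides <- function(structure, cutoff = 2.5) {
  stopifnot(cutoff > 0)
  a <- atoms(structure)
  sel <- which(a$resname %in% c("CYS", "CYX") & trimws(a$name) == "SG")
  empty <- data.frame(chain_a = character(), resid_a = integer(),
                      chain_b = character(), resid_b = integer(),
                      sg_distance = numeric(), stringsAsFactors = FALSE)
  if (length(sel) < 2) return(empty)
  key <- residueKey(a$chain[sel], a$resid[sel], a$ins[sel])
  xyz <- coords(structure)[sel, , drop = FALSE]
  cand <- NULL
  for (i in seq_along(sel)) {
    for (j in seq_along(sel)) {
      if (j <= i || key[i] == key[j]) next
      d <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
      if (d <= cutoff) cand <- rbind(cand, data.frame(i = i, j = j, d = d))
    }
  }
  if (is.null(cand)) return(empty)
  ord <- order(cand$d, pmin(key[cand$i], key[cand$j]),
               pmax(key[cand$i], key[cand$j]))
  cand <- cand[ord, , drop = FALSE]
  used <- logical(length(sel))
  out <- empty
  for (r in seq_len(nrow(cand))) {
    i <- cand$i[r]; j <- cand$j[r]
    if (used[i] || used[j]) next
    used[i] <- used[j] <- TRUE
    # canonical order: smaller key first
    if (key[i] > key[j]) { tmp <- i; i <- j; j <- tmp }
    out <- rbind(out, data.frame(
      chain_a = a$chain[sel[i]], resid_a = a$resid[sel[i]],
      chain_b = a$chain[sel[j]], resid_b = a$resid[sel[j]],
      sg_distance = cand$d[r], stringsAsFactors = FALSE))
  }
  rownames(out) <- NULL
  out
}

#' Partition an antibody into rigid bodies and flexible upper-hinge residues
#'
#' The flexible (torsionally sampled) residues of each arm run from the
#' Fab-side end of the hinge span up to, and excluding, the most N-terminal
#' hinge disulfide cysteine of that heavy chain. Everything C-terminal of
#' that cysteine joins the Fc core; the Fab bodies take the heavy-chain
#' portion N-terminal of the hinge span plus the nearest light chain.
#' HETATM residues (e.g. glycans) are attached to the rigid body of the
#' nearest protein atom.
#'
#' @param structure a [Structure]
#' @param chainAnnotation named character vector mapping chain id to
#'   `"heavy"` or `"light"`; exactly two heavy chains (light chains optional
#'   in coarse models, otherwise exactly two).
#' @param hingeSpan named list mapping each heavy chain id to `c(first, last)`
#'   residue numbers of its hinge (typically taken from sequence annotation).
#' @param disulfides optional data.frame in the [detectDisulfides()] format;
#'   detected automatically when `NULL`.
#' @param cutoff SG-SG cutoff used when detecting disulfides.
#' @return an [AntibodyTopology]
#' @export
partitionAntibody <- function(structure, chainAnnotation, hingeSpan,
                              disulfides = NULL, cutoff = 2.5) {
  a <- atoms(structure)
  heavy <- names(chainAnnotation)[chainAnnotation == "heavy"]
  light <- names(chainAnnotation)[chainAnnotation == "light"]
  if (length(heavy) != 2)
    stop("exactly two heavy chains required, got ", length(heavy))
  if (!(length(light) %in% c(0L, 2L)))
    stop("expected zero or two light chains, got ", length(light))
  if (!all(heavy %in% names(hingeSpan)))
    stop("hingeSpan must name both heavy chains")
  if (is.null(disulfides)) disulfides <- detectDisulfides(structure, cutoff)

  inHinge <- function(ch, rs) {
    ch %in% heavy & rs >= hingeSpan[[ch]][1] & rs <= hingeSpan[[ch]][2]
  }
  hingeBond <- logical(nrow(disulfides))
  for (r in seq_len(nrow(disulfides))) {
    hingeBond[r] <- inHinge(disulfides$chain_a[r], disulfides$resid_a[r]) &&
      inHinge(disulfides$chain_b[r], disulfides$resid_b[r])
  }
  if (!any(hingeBond))
    stop("no hinge disulfide found within the hinge span; supply an explicit ",
         "'disulfides' table (the flexible segment cannot be bounded without one)")
  hb <- disulfides[hingeBond, , drop = FALSE]

  firstCys <- vapply(heavy, function(ch) {
    rs <- c(hb$resid_a[hb$chain_a == ch], hb$resid_b[hb$chain_b == ch])
    if (!length(rs)) stop("heavy chain ", ch, " has no hinge disulfide cysteine")
    min(rs)
  }, numeric(1))

  prot <- !a$het
  resKeyAll <- residueKey(a$chain, a$resid, a$ins)
  chainRes <- function(ch, lo = -Inf, hi = Inf) {
    sel <- prot & a$chain == ch & a$resid >= lo & a$resid < hi
    unique(resKeyAll[sel])
  }

  flexible <- lapply(heavy, function(ch)
    chainRes(ch, hingeSpan[[ch]][1], firstCys[[ch]]))
  names(flexible) <- c("arm1", "arm2")
  fcCore <- unlist(lapply(heavy, function(ch) chainRes(ch, firstCys[[ch]])))
  fabHeavy <- lapply(heavy, function(ch) chainRes(ch, -Inf, hingeSpan[[ch]][1]))

  # pair each light chain with the nearest heavy-chain Fab portion
  fabBodies <- fabHeavy
  if (length(light) == 2) {
    hCent <- lapply(seq_along(heavy), function(i) {
      sel <- resKeyAll %in% fabHeavy[[i]]
      colMeans(coords(structure)[sel, , drop = FALSE])
    })
    lCent <- lapply(light, function(ch) {
      sel <- prot & a$chain == ch
      colMeans(coords(structure)[sel, , drop = FALSE])
    })
    d <- outer(seq_along(light), seq_along(heavy),
               Vectorize(function(i, j) sqrt(sum((lCent[[i]] - hCent[[j]])^2))))
    first <- which(d == min(d), arr.ind = TRUE)[1, ]
    pairing <- integer(2)
    pairing[first[1]] <- first[2]
    pairing[-first[1]] <- setdiff(1:2, first[2])
    for (i in seq_along(light))
      fabBodies[[pairing[i]]] <- c(fabBodies[[pairing[i]]],
                                   chainRes(light[i]))
  }

  bodies <- list(Fab1 = fabBodies[[1]], Fab2 = fabBodies[[2]],
                 Fc_core = unique(fcCore))

  # glycans / heteroatoms: attach to the rigid body of the nearest protein atom
  hetKeys <- setdiff(unique(resKeyAll[a$het]), unlist(c(bodies, flexible)))
  if (length(hetKeys)) {
    xyz <- coords(structure)
    bodyOfAtom <- rep(NA_character_, nrow(a))
    for (nm in names(bodies)) bodyOfAtom[resKeyAll %in% bodies[[nm]]] <- nm
    candidates <- which(!is.na(bodyOfAtom) & prot)
    for (hk in hetKeys) {
      sel <- which(resKeyAll == hk)
      cent <- colMeans(xyz[sel, , drop = FALSE])
      d2 <- rowSums((xyz[candidates, , drop = FALSE] -
                       matrix(cent, length(candidates), 3, byrow = TRUE))^2)
      nm <- bodyOfAtom[candidates[which.min(d2)]]
      bodies[[nm]] <- c(bodies[[nm]], hk)
    }
  }

  unassigned <- setdiff(unique(resKeyAll), unlist(c(bodies, flexible)))
  new("AntibodyTopology", rigidBodies = bodies, flexibleResidues = flexible,
      disulfides = disulfides, unassigned = unassigned)
}

#' Export / import an AntibodyTopology as JSON
#'
#' @param topology an [AntibodyTopology]
#' @param path JSON file path
#' @return `topologyToJSON` invisibly returns the path; `readTopologyJSON`
#'   returns an [AntibodyTopology].
#' @export
topologyToJSON <- function(topology, path) {
  obj <- list(rigid_bodies = topology@rigidBodies,
              flexible_residues = topology@flexibleResidues,
              disulfides = topology@disulfides,
              unassigned = topology@unassigned)
  jsonlite::write_json(obj, path, auto_unbox = FALSE, pretty = TRUE)
  invisible(path)
}

#' @rdname topologyToJSON
#' @export
readTopologyJSON <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  ds <- as.data.frame(obj$disulfides, stringsAsFactors = FALSE)
  if (!nrow(ds))
    ds <- data.frame(chain_a = character(), resid_a = integer(),
                     chain_b = character(), resid_b = integer(),
                     sg_distance = numeric())
  new("AntibodyTopology",
      rigidBodies = lapply(obj$rigid_bodies, as.character),
      flexibleResidues = lapply(obj$flexible_residues, as.character),
      disulfides = ds,
      unassigned = as.character(obj$unassigned))
}
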