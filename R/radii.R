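#' @include AllClasses.R
NULL

#' Construct a collision radii table
#'
#' @param radii named numeric vector of element radii in Angstrom. Defaults to
#'   a standard van der Waals set (H 1.2, C 1.7, N 1.55, O 1.52, S 1.8) plus
#'   coarse-grained bead entries: `BB` (synthetic fixture bead, 3.0) and `CG`
#'   (one-bead-per-residue collapse bead, 3.8).
#' @param probe probe radius in Angstrom added to every element radius when
#'   building projection disks (default 1.0).
#' @return a [CollisionRadii] object
#' @examples
#' r <- defaultRadii()
#' radiusOf(r, c("C", "N"))
#' @export
collisionRadii <- function(radii = c(H = 1.2, C = 1.7, N = 1.55, O = 1.52,
                                     S = 1.8, BB = 3.0, CG = 3.8),
                           probe = 1.0) {
  new("CollisionRadii", radii = radii, probe = probe)
}

#' @rdname collisionRadii
#' @export
defaultRadii <- function(probe = 1.0) collisionRadii(probe = probe)

#' Look up per-atom collision radii (element radius + probe)
#'
#' @param radii a [CollisionRadii]
#' @param elements character vector of element symbols
#' @return numeric vector of disk radii (element radius + probe), Angstrom
#' @export
radiusOf <- function(radii, elements) {
  stopifnot(is(radii, "CollisionRadii"))
  el <- toupper(elements)
  known <- toupper(names(radii@radii))
  miss <- setdiff(unique(el), known)
  if (length(miss))
    stop("no collision radius for element(s): ", paste(miss, collapse = ", "))
  unname(radii@radii[match(el, known)] + radii@probe)
}

#' Read a radii table from a two-column CSV (element, radius)
#'
#' @param path CSV file with columns `element` and `radius`; an optional
#'   single-row `probe` entry sets the probe radius.
#' @param probe probe radius used when the file has no `probe` row.
#' @return a [CollisionRadii]
#' @export
readRadii <- function(path, probe = 1.0) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("element", "radius") %in% names(tab)))
  is_probe <- tolower(tab$element) == "probe"
  if (any(is_probe)) probe <- tab$radius[is_probe][1]
  r <- tab$radius[!is_probe]
  names(r) <- tab$element[!is_probe]
  collisionRadii(radii = r, probe = probe)
}
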