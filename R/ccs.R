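#' @include AllClasses.R AllGenerics.R radii.R
NULL

#' Projection-approximation collision cross section
#'
#' Computes the orientation-averaged projected area (PA) of the union of
#' atom-centred disks (disk radius = element collision radius + probe) over
#' uniformly random rigid rotations, and scales it to the model CCS
#' convention `CCS = PA x 1.14`. Two per-orientation estimators are
#' available: `"monte_carlo"` (uniform points inside the projected bounding
#' box; the default) and `"grid"` (square-cell rasterisation; slower, used as
#' the numerical oracle). A single-atom structure projects to one disk whose
#' area is taken in closed form, so its PA is exact for any orientation
#' count.
#'
#' @param structure a [Structure] (or a plain atoms x 3 coordinate matrix if
#'   `elements` is supplied).
#' @param radii a [CollisionRadii]; every element present in the structure
#'   must be covered.
#' @param nOrientations number of random orientations to average (>= 1).
#'   Default 300.
#' @param sampler `"monte_carlo"` or `"grid"`.
#' @param nPoints Monte-Carlo points per orientation (default 40000).
#' @param cell grid cell edge in Angstrom for the grid sampler (default 0.5;
#'   0.2 is the oracle setting).
#' @param seed RNG seed for orientations and points.
#' @param elements character vector of element symbols, required only when
#'   `structure` is a bare coordinate matrix.
#' @return a [CCSResult]
#' @examples
#' s <- structureFromAtoms(data.frame(name = "CA", element = "C", resid = 1,
#'                                    chain = "A", x = 0, y = 0, z = 0))
#' projectionArea(s, defaultRadii(), nOrientations = 5, seed = 1)
#' @export
projectionArea <- function(structure, radii = defaultRadii(),
                           nOrientations = 300L,
                           sampler = c("monte_carlo", "grid"),
                           nPoints = 40000L, cell = 0.5, seed = 1,
                           elements = NULL) {
  sampler <- match.arg(sampler)
  if (nOrientations < 1) stop("nOrientations must be >= 1")
  if (is(structure, "Structure")) {
    xyz <- coords(structure)
    elements <- atoms(structure)$element
  } else {
    xyz <- as.matrix(structure)
    if (is.null(elements)) stop("elements required for a bare coordinate matrix")
  }
  r <- radiusOf(radii, elements)

  if (nrow(xyz) == 1) {
    # single disk: closed form, identical in every orientation
    pa <- pi * r[1]^2
    return(new("CCSResult", paArea = pa, ccs = 1.14 * pa,
               mcStandardError = 0, nOrientations = as.integer(nOrientations),
               sampler = sampler, seed = as.numeric(seed)))
  }
  areas <- .pa_orientations(xyz, r, as.integer(nOrientations), sampler,
                            as.integer(nPoints), cell, as.numeric(seed))
  pa <- mean(areas)
  se <- if (length(areas) > 1) stats::sd(areas) / sqrt(length(areas)) else 0
  new("CCSResult", paArea = pa, ccs = 1.14 * pa, mcStandardError = se,
      nOrientations = as.integer(nOrientations), sampler = sampler,
      seed = as.numeric(seed))
}

#' Scale a projected area to the model CCS convention
#'
#' @param paArea projected area in Angstrom^2 (non-negative)
#' @return `1.14 * paArea`
#' @examples
#' paToCcs(100) # 114
#' @export
paToCcs <- function(paArea) {
  if (any(paArea < 0)) stop("paArea must be non-negative")
  1.14 * paArea
}

#' CCS along a trajectory of structures
#'
#' Scores every `stride`-th frame by [projectionArea()] and summarises the
#' final window: `finalWindowRange` is max - min CCS over the final 10
#' percent of the strided frames (at least one frame).
#'
#' @param frames list of [Structure] objects, or a list of coordinate
#'   matrices accompanied by `elements`.
#' @param radii a [CollisionRadii]
#' @param stride keep every `stride`-th frame (>= 1)
#' @param nOrientations,nPoints,sampler,cell,seed forwarded to
#'   [projectionArea()]; each frame uses the same seed so identical frames
#'   score identically.
#' @param elements element symbols when `frames` holds bare matrices.
#' @return list with `results` (list of [CCSResult]), `ccs` (numeric vector),
#'   `finalCcs` and `finalWindowRange`.
#' @export
ccsTrajectory <- function(frames, radii = defaultRadii(), stride = 1L,
                          nOrientations = 100L, nPoints = 20000L,
                          sampler = "monte_carlo", cell = 0.5, seed = 1,
                          elements = NULL) {
  if (length(frames) < 1) stop("at least one frame required")
  if (stride < 1) stop("stride must be >= 1")
  idx <- seq(1, length(frames), by = stride)
  res <- lapply(frames[idx], function(f)
    projectionArea(f, radii, nOrientations = nOrientations, sampler = sampler,
                   nPoints = nPoints, cell = cell, seed = seed,
                   elements = elements))
  v <- vapply(res, ccs, numeric(1))
  nw <- max(1L, ceiling(0.1 * length(v)))
  w <- v[(length(v) - nw + 1L):length(v)]
  list(results = res, ccs = v, frameIndex = idx,
       finalCcs = v[length(v)], finalWindowRange = max(w) - min(w))
}
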