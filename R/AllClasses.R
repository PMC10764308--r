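#' @import methods
NULL

#' FundusImage: a color fundus photograph
#'
#' Holds an RGB raster as an H x W x 3 numeric array with channel values in
#' \code{[0, 1]}, indexed \code{[row, col, channel]} (1-based, row 1 at the
#' top). All downstream geometry (ROI side, line-profile length, initial
#' contour radius) is expressed as a fraction of the retina diameter carried
#' by \linkS4class{RetinaGeometry}.
#'
#' @slot pixels numeric array, H x W x 3, values in [0, 1]
#' @slot path character scalar, source identifier ("" for in-memory images)
#' @exportClass FundusImage
setClass("FundusImage",
  representation(pixels = "array", path = "character"),
  prototype(path = "")
)

setValidity("FundusImage", function(object) {
  p <- object@pixels
  if (length(dim(p)) != 3L || dim(p)[3] != 3L)
    return("pixels must be an H x W x 3 array")
  if (dim(p)[1] < 64L || dim(p)[2] < 64L)
    return("image must be at least 64 x 64")
  if (anyNA(p) || !all(is.finite(p)))
    return("pixels must be finite")
  rng <- range(p)
  if (rng[1] < 0 || rng[2] > 1)
    return("channel values must lie in [0, 1]")
  TRUE
})

#' RetinaGeometry: center and diameter of the imaged retina
#'
#' The retina diameter D is the reference length for every geometric
#' parameter of the pipeline: the ROI is a square of side D/3, a
#' non-edematous optic disk is assumed to have diameter D/6, and the
#' intensity line profile has length D/2.
#'
#' @slot center numeric length-2, (row, col) of the retina center in pixels
#' @slot diameter numeric scalar, retina diameter D in pixels
#' @exportClass RetinaGeometry
setClass("RetinaGeometry",
  representation(center = "numeric", diameter = "numeric")
)

setValidity("RetinaGeometry", function(object) {
  if (length(object@center) != 2L) return("center must be (row, col)")
  if (length(object@diameter) != 1L || object@diameter <= 0)
    return("diameter must be a positive scalar")
  TRUE
})

#' VesselMap: segmented vasculature of a fundus image
#'
#' @slot mask integer/numeric matrix of 0/1, the vessel mask
#' @slot skeleton matrix of 0/1, the morphological skeleton (subset of mask)
#' @slot segments list of n x 2 matrices (row, col), skeleton pixel chains
#'   split at branch points
#' @exportClass VesselMap
setClass("VesselMap",
  representation(mask = "matrix", skeleton = "matrix", segments = "list")
)

setValidity("VesselMap", function(object) {
  if (!all(dim(object@mask) == dim(object@skeleton)))
    return("mask and skeleton must share a shape")
  if (any(object@skeleton > 0 & object@mask == 0))
    return("skeleton must be a subset of the mask")
  TRUE
})

#' ODLocation: the localized optic disk position
#'
#' @slot center numeric (row, col), pixel coordinates of the OD
#' @slot method character, one of "parabola", "convergence",
#'   "brightest_fallback"
#' @slot warning logical, TRUE when the non-vascular fallback was used
#' @exportClass ODLocation
setClass("ODLocation",
  representation(center = "numeric", method = "character",
                 warning = "logical"),
  prototype(warning = FALSE)
)

setValidity("ODLocation", function(object) {
  if (length(object@center) != 2L) return("center must be (row, col)")
  if (!object@method %in% c("parabola", "convergence", "brightest_fallback"))
    return("unknown localization method tag")
  TRUE
})

#' ROIPatch: square region of interest around the optic disk
#'
#' A square window of side round(D/3) centered on the localized OD, possibly
#' clipped at the image border (then \code{clipped} is TRUE and the actual
#' extent is \code{dim(pixels)}).
#'
#' @slot pixels numeric array h x w x 3 in [0, 1]
#' @slot offset numeric (row0, col0): position of pixel [1,1] of the patch in
#'   the full image (1-based)
#' @slot widthPx integer, the nominal (unclipped) window side round(D/3)
#' @slot clipped logical
#' @exportClass ROIPatch
setClass("ROIPatch",
  representation(pixels = "array", offset = "numeric", widthPx = "numeric",
                 clipped = "logical"),
  prototype(clipped = FALSE)
)

#' FGVFParams: tunables of the factorized texture level-set segmenter
#'
#' @slot tau data-term weight (default 50)
#' @slot upsilon distance-regularization weight (default 1.5)
#' @slot noiseEps additive-noise scale of the factorization model (default 0.5)
#' @slot heavisideEps width of the smooth Heaviside, pixels (default 1.5)
#' @slot dt explicit Euler time step (default 0.1)
#' @slot minIters iterations run before convergence is first tested, so the
#'   distance regularization can settle the level-set field (default 300)
#' @slot maxIters maximum evolution iterations (default 1000)
#' @slot convThreshold mean contour displacement (px) below which the contour
#'   is converged (default 0.05)
#' @slot checkEvery iterations between representative-feature refresh and
#'   convergence checks (default 10)
#' @exportClass FGVFParams
setClass("FGVFParams",
  representation(tau = "numeric", upsilon = "numeric", noiseEps = "numeric",
                 heavisideEps = "numeric", dt = "numeric",
                 minIters = "numeric", maxIters = "numeric",
                 convThreshold = "numeric", checkEvery = "numeric")
)

setValidity("FGVFParams", function(object) {
  vals <- c(object@tau, object@upsilon, object@noiseEps, object@heavisideEps,
            object@dt, object@maxIters, object@convThreshold,
            object@checkEvery)
  if (any(!is.finite(vals)) || any(vals <= 0))
    return("all FGVF parameters must be positive and finite")
  if (!is.finite(object@minIters) || object@minIters < 0)
    return("minIters must be non-negative")
  TRUE
})

#' Construct FGVF parameters
#'
#' @param tau,upsilon,noiseEps,heavisideEps,dt,minIters,maxIters,convThreshold,checkEvery
#'   see the corresponding slots of \linkS4class{FGVFParams}
#' @return an \linkS4class{FGVFParams} object
#' @examples
#' fgvfParams(maxIters = 200)
#' @export
fgvfParams <- function(tau = 50, upsilon = 1.5, noiseEps = 0.5,
                       heavisideEps = 1.5, dt = 0.1, minIters = 300,
                       maxIters = 1000, convThreshold = 0.05,
                       checkEvery = 10) {
  new("FGVFParams", tau = tau, upsilon = upsilon, noiseEps = noiseEps,
      heavisideEps = heavisideEps, dt = dt, minIters = minIters,
      maxIters = maxIters, convThreshold = convThreshold,
      checkEvery = checkEvery)
}

#' Phantom: a synthetic fundus image with full ground truth
#'
#' @slot image \linkS4class{FundusImage}
#' @slot geometry \linkS4class{RetinaGeometry}
#' @slot odMask 0/1 matrix, ground-truth optic disk
#' @slot vesselMask 0/1 matrix, ground-truth vessels
#' @slot odCenter numeric (row, col)
#' @slot label "edematous" or "non_edematous"
#' @exportClass Phantom
setClass("Phantom",
  representation(image = "FundusImage", geometry = "RetinaGeometry",
                 odMask = "matrix", vesselMask = "matrix",
                 odCenter = "numeric", label = "character")
)

setValidity("Phantom", function(object) {
  if (!object@label %in% c("edematous", "non_edematous"))
    return("label must be edematous or non_edematous")
  TRUE
})

# ---- show methods -----------------------------------------------------------

setMethod("show", "FundusImage", function(object) {
  d <- dim(object@pixels)
  cat(sprintf("FundusImage %d x %d RGB", d[1], d[2]))
  if (nzchar(object@path)) cat(" <", object@path, ">", sep = "")
  cat("\n")
})

setMethod("show", "RetinaGeometry", function(object) {
  cat(sprintf("RetinaGeometry center=(%.1f, %.1f) diameter=%.1f px\n",
              object@center[1], object@center[2], object@diameter))
})

setMethod("show", "ODLocation", function(object) {
  cat(sprintf("ODLocation (%.1f, %.1f) via %s%s\n", object@center[1],
              object@center[2], object@method,
              if (object@warning) " [fallback warning]" else ""))
})

setMethod("show", "VesselMap", function(object) {
  cat(sprintf("VesselMap %d vessel px, %d skeleton px, %d segments\n",
              sum(object@mask), sum(object@skeleton),
              length(object@segments)))
})

setMethod("show", "Phantom", function(object) {
  d <- dim(object@image@pixels)
  cat(sprintf("Phantom %s %d x %d, OD at (%.0f, %.0f)\n", object@label,
              d[1], d[2], object@odCenter[1], object@odCenter[2]))
})

# ---- accessors --------------------------------------------------------------

#' @rdname accessors
#' @param x an object of one of the package's S4 classes
#' @export
setGeneric("imagePixels", function(x) standardGeneric("imagePixels"))
#' @rdname accessors
#' @export
setMethod("imagePixels", "FundusImage", function(x) x@pixels)
#' @rdname accessors
#' @export
setMethod("imagePixels", "ROIPatch", function(x) x@pixels)
#' @rdname accessors
#' @export
setMethod("imagePixels", "Phantom", function(x) x@image@pixels)

#' Accessors for the package's S4 classes
#'
#' Small read-only accessors so user code never touches slots directly.
#'
#' @name accessors
#' @rdname accessors
#' @export
setGeneric("retinaDiameter", function(x) standardGeneric("retinaDiameter"))
#' @rdname accessors
#' @export
setMethod("retinaDiameter", "RetinaGeometry", function(x) x@diameter)
#' @rdname accessors
#' @export
setGeneric("retinaCenter", function(x) standardGeneric("retinaCenter"))
#' @rdname accessors
#' @export
setMethod("retinaCenter", "RetinaGeometry", function(x) x@center)
#' @rdname accessors
#' @export
setGeneric("odCenter", function(x) standardGeneric("odCenter"))
#' @rdname accessors
#' @export
setMethod("odCenter", "ODLocation", function(x) x@center)
#' @rdname accessors
#' @export
setMethod("odCenter", "Phantom", function(x) x@odCenter)
#' @rdname accessors
#' @export
setGeneric("vesselMask", function(x) standardGeneric("vesselMask"))
#' @rdname accessors
#' @export
setMethod("vesselMask", "VesselMap", function(x) x@mask)
#' @rdname accessors
#' @export
setMethod("vesselMask", "Phantom", function(x) x@vesselMask)
#' @rdname accessors
#' @export
setGeneric("odMask", function(x) standardGeneric("odMask"))
#' @rdname accessors
#' @export
setMethod("odMask", "Phantom", function(x) x@odMask)
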