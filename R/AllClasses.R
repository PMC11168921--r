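#' @import methods
NULL

## Central S4 containers. Arrays are stored base-R style, 1-based, with
## dimension order (z, y, x) for stacks and (y, x) for planes/masks; all
## physical distances are in micrometres via the pixelSizeXY calibration.

#' Calibrated multi-channel image stack
#'
#' Holds one 3-D intensity array per channel (dimension order z, y, x),
#' a mapping from channel name to biological role, and the pixel
#' calibration in micrometres. All channels must share dimensions and all
#' intensities must be finite and non-negative.
#'
#' @slot planes named list of 3-D numeric arrays (z, y, x), one per channel.
#' @slot channelRoles named character vector mapping channel name to a role
#'   in \code{c("dapi","mark","reporter","mito","tmrm","sensor405",
#'   "sensor488","other")}.
#' @slot pixelSizeXY numeric(1), micrometres per pixel in x/y.
#' @slot pixelSizeZ numeric(1), micrometres per z plane.
#' @slot discId character(1) free-text identifier.
#'
#' @exportClass ImageStack
setClass("ImageStack",
    representation(
        planes = "list",
        channelRoles = "character",
        pixelSizeXY = "numeric",
        pixelSizeZ = "numeric",
        discId = "character"
    )
)

.VALID_ROLES <- c("dapi", "mark", "reporter", "mito", "tmrm",
                  "sensor405", "sensor488", "other")

setValidity("ImageStack", function(object) {
    msg <- NULL
    p <- object@planes
    if (length(p) == 0L) msg <- c(msg, "stack has no channels")
    if (is.null(names(p)) || any(names(p) == ""))
        msg <- c(msg, "channels must be named")
    dims <- lapply(p, dim)
    if (any(vapply(dims, length, 1L) != 3L))
        msg <- c(msg, "each channel must be a 3-D (z, y, x) array")
    if (length(p) > 1L && !all(vapply(dims, identical, TRUE, dims[[1L]])))
        msg <- c(msg, "all channels must share (z, y, x) dimensions")
    for (ch in names(p)) {
        v <- p[[ch]]
        if (anyNA(v) || any(!is.finite(v)))
            msg <- c(msg, sprintf("channel '%s' has non-finite values", ch))
        else if (any(v < 0))
            msg <- c(msg, sprintf("channel '%s' has negative values", ch))
    }
    if (!all(names(p) %in% names(object@channelRoles)))
        msg <- c(msg, "every channel needs an entry in channelRoles")
    if (!all(object@channelRoles %in% .VALID_ROLES))
        msg <- c(msg, sprintf("roles must be in {%s}",
                              paste(.VALID_ROLES, collapse = ", ")))
    if (length(object@pixelSizeXY) != 1L || !is.finite(object@pixelSizeXY) ||
        object@pixelSizeXY <= 0)
        msg <- c(msg, "pixelSizeXY must be a single positive number")
    if (length(object@pixelSizeZ) != 1L || !is.finite(object@pixelSizeZ) ||
        object@pixelSizeZ <= 0)
        msg <- c(msg, "pixelSizeZ must be a single positive number")
    if (is.null(msg)) TRUE else msg
})

#' Single calibrated 2-D image plane
#'
#' @slot values numeric matrix (y, x), finite and non-negative.
#' @slot pixelSizeXY micrometres per pixel.
#' @slot provenance character(1) describing which stack/channel/projection
#'   produced the plane.
#'
#' @exportClass Plane
setClass("Plane",
    representation(values = "matrix", pixelSizeXY = "numeric",
                   provenance = "character")
)

setValidity("Plane", function(object) {
    v <- object@values
    if (anyNA(v) || any(!is.finite(v))) return("values must be finite")
    if (any(v < 0)) return("values must be non-negative")
    if (object@pixelSizeXY <= 0) return("pixelSizeXY must be positive")
    TRUE
})

#' Binary whole-tissue mask
#'
#' A single filled connected component marking the tissue, congruent with
#' its source plane, plus the segmentation parameters that produced it.
#'
#' @slot mask logical matrix (y, x).
#' @slot pixelSizeXY micrometres per pixel, inherited from the source plane.
#' @slot params list of segmentation parameters (threshold, smoothing, ...).
#'
#' @exportClass TissueMask
setClass("TissueMask",
    representation(mask = "matrix", pixelSizeXY = "numeric", params = "list")
)

setValidity("TissueMask", function(object) {
    m <- object@mask
    if (!is.logical(m)) return("mask must be logical")
    if (!any(m)) return("mask is empty")
    lab <- EBImage::bwlabel(m)
    if (max(lab) != 1L) return("mask must be one connected component")
    filled <- EBImage::fillHull(lab) > 0
    if (!identical(as.vector(filled), as.vector(m)))
        return("mask must have no holes")
    TRUE
})

#' Rim / centre partition of a tissue mask
#'
#' The rim is the band of foreground pixels whose Euclidean distance to
#' the nearest background pixel is at most \code{widthPx}; the centre is
#' the remaining foreground. The two masks are disjoint and cover the
#' tissue exactly.
#'
#' @slot rim logical matrix.
#' @slot centre logical matrix.
#' @slot widthPx integer rim width in pixels.
#' @slot pixelSizeXY micrometres per pixel.
#'
#' @exportClass RegionPartition
setClass("RegionPartition",
    representation(rim = "matrix", centre = "matrix", widthPx = "numeric",
                   pixelSizeXY = "numeric")
)

setValidity("RegionPartition", function(object) {
    if (!identical(dim(object@rim), dim(object@centre)))
        return("rim and centre must be congruent")
    if (any(object@rim & object@centre))
        return("rim and centre must be disjoint")
    if (object@widthPx < 0) return("widthPx must be >= 0")
    TRUE
})

#' Labelled objects (nuclei or mitochondria)
#'
#' @slot labels integer matrix; 0 is background, objects are labelled with
#'   consecutive positive integers.
#' @slot kind "nuclei" or "mitochondria".
#' @slot pixelSizeXY micrometres per pixel.
#' @slot params list of segmentation parameters.
#'
#' @exportClass LabelImage
setClass("LabelImage",
    representation(labels = "matrix", kind = "character",
                   pixelSizeXY = "numeric", params = "list")
)

setValidity("LabelImage", function(object) {
    l <- object@labels
    u <- sort(unique(as.integer(l)))
    u <- u[u > 0L]
    if (length(u) && !identical(u, seq_along(u)))
        return("labels must be consecutive positive integers")
    if (!object@kind %in% c("nuclei", "mitochondria"))
        return("kind must be 'nuclei' or 'mitochondria'")
    TRUE
})

#' Reporter-defined compartment masks
#'
#' Splits the tissue into reporter-positive and reporter-negative parts;
#' the two are disjoint and together cover the tissue mask exactly.
#'
#' @slot positive logical matrix.
#' @slot negative logical matrix.
#'
#' @exportClass CompartmentMask
setClass("CompartmentMask",
    representation(positive = "matrix", negative = "matrix")
)

setValidity("CompartmentMask", function(object) {
    if (!identical(dim(object@positive), dim(object@negative)))
        return("positive and negative must be congruent")
    if (any(object@positive & object@negative))
        return("positive and negative must be disjoint")
    TRUE
})

#' Ratiometric sensor map
#'
#' Pixelwise 488/405 excitation ratio, defined only where the 405 channel
#' exceeded the intensity floor (the validity mask).
#'
#' @slot values numeric matrix of ratios; NA outside validity.
#' @slot validity logical matrix marking pixels where the ratio is defined.
#'
#' @exportClass RatioMap
setClass("RatioMap",
    representation(values = "matrix", validity = "matrix")
)

setValidity("RatioMap", function(object) {
    if (!identical(dim(object@values), dim(object@validity)))
        return("values and validity must be congruent")
    v <- object@values[object@validity]
    if (length(v) && (anyNA(v) || any(!is.finite(v))))
        return("values must be finite inside validity")
    TRUE
})

#' Synthetic phantom specification
#'
#' Parameters of one synthetic disc image with known ground truth. The
#' defaults are the standard study conditions used throughout the test
#' suite; see the methods vignette for their rationale.
#'
#' @slot shape integer(2), image (H, W) in pixels.
#' @slot pixelSizeXY micrometres per pixel (default 0.5).
#' @slot pixelSizeZ micrometres per plane.
#' @slot geometry "disc_xy", "cross_section" or "sensor".
#' @slot rimWidthTrue true rim band width in pixels.
#' @slot enrichmentR true rim/centre mark enrichment factor.
#' @slot nNuclei number of nuclei to place.
#' @slot nucleusRadius nucleus radius in pixels.
#' @slot depthProfile list describing mark intensity vs surface distance
#'   (cross-sections): type "exp", "linear", "step" or "constant" plus
#'   parameters.
#' @slot targetDepths requested nucleus surface distances in micrometres
#'   (cross-sections; empty = defaults spanning all three bins).
#' @slot nMito number of mitochondria.
#' @slot reporterFraction fraction of tissue assigned reporter-positive.
#' @slot sensorField list describing the true 488/405 ratio field.
#' @slot noise list(poissonScale, gaussianSD); both 0 = noise-free.
#' @slot nz number of z planes.
#' @slot seed integer seed; generation is deterministic given the spec.
#'
#' @exportClass PhantomSpec
setClass("PhantomSpec",
    representation(
        shape = "integer", pixelSizeXY = "numeric", pixelSizeZ = "numeric",
        geometry = "character", rimWidthTrue = "numeric",
        enrichmentR = "numeric", nNuclei = "integer",
        nucleusRadius = "numeric", depthProfile = "list",
        targetDepths = "numeric", nMito = "integer",
        reporterFraction = "numeric", sensorField = "list",
        noise = "list", nz = "integer", seed = "integer"
    )
)

setValidity("PhantomSpec", function(object) {
    msg <- NULL
    if (length(object@shape) != 2L || any(object@shape < 16L))
        msg <- c(msg, "shape must be two integers >= 16")
    if (object@enrichmentR <= 0) msg <- c(msg, "enrichmentR must be > 0")
    if (object@rimWidthTrue >= min(object@shape) / 2)
        msg <- c(msg, "rimWidthTrue must be < min(shape)/2")
    if (object@nNuclei < 0L || object@nMito < 0L || object@nz < 1L)
        msg <- c(msg, "counts must be non-negative and nz >= 1")
    if (object@reporterFraction < 0 || object@reporterFraction > 1)
        msg <- c(msg, "reporterFraction must be in [0, 1]")
    if (!object@geometry %in% c("disc_xy", "cross_section", "sensor"))
        msg <- c(msg, "geometry must be disc_xy, cross_section or sensor")
    n <- object@noise
    if (!all(c("poissonScale", "gaussianSD") %in% names(n)) ||
        n$poissonScale < 0 || n$gaussianSD < 0)
        msg <- c(msg, "noise must have poissonScale >= 0 and gaussianSD >= 0")
    if (is.null(msg)) TRUE else msg
})

#' Phantom ground truth
#'
#' Everything the analysis is supposed to recover from the matching
#' \linkS4class{ImageStack}: the true tissue and rim masks, the nucleus and
#' mitochondrion tables, compartment masks, the true enrichment factor and,
#' for sensor phantoms, the true ratio field.
#'
#' @slot tissueMask logical matrix.
#' @slot rimMask logical matrix.
#' @slot nuclei data.frame (label, y, x, radius, distSurface, and per-channel
#'   true means).
#' @slot mito data.frame (label, y, x, radius).
#' @slot trueRatio numeric(1), the generating enrichment factor.
#' @slot positiveMask,negativeMask logical matrices (compartments).
#' @slot sensorField numeric matrix or NULL-like empty matrix.
#' @slot spec the generating \linkS4class{PhantomSpec}.
#'
#' @exportClass PhantomTruth
setClass("PhantomTruth",
    representation(
        tissueMask = "matrix", rimMask = "matrix",
        nuclei = "data.frame", mito = "data.frame",
        trueRatio = "numeric", positiveMask = "matrix",
        negativeMask = "matrix", sensorField = "matrix",
        spec = "PhantomSpec"
    )
)
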