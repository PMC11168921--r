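#' @include AllClasses.R
NULL

#' Accessors for discRim classes
#'
#' Small accessor family: channel arrays and roles of an
#' \linkS4class{ImageStack}, pixel calibration, mask matrices, label
#' matrices and object counts.
#'
#' @param object a discRim object.
#' @param ... unused.
#' @return the slot value (see each method).
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("planes", function(object, ...) standardGeneric("planes"))

#' @rdname accessors
#' @export
setGeneric("channelRoles", function(object) standardGeneric("channelRoles"))

#' @rdname accessors
#' @export
setGeneric("pixelSizeXY", function(object) standardGeneric("pixelSizeXY"))

#' @rdname accessors
#' @export
setGeneric("pixelSizeZ", function(object) standardGeneric("pixelSizeZ"))

#' @rdname accessors
#' @export
setGeneric("discId", function(object) standardGeneric("discId"))

#' @rdname accessors
#' @export
setGeneric("maskValues", function(object) standardGeneric("maskValues"))

#' @rdname accessors
#' @export
setGeneric("rimMask", function(object) standardGeneric("rimMask"))

#' @rdname accessors
#' @export
setGeneric("centreMask", function(object) standardGeneric("centreMask"))

#' @rdname accessors
#' @export
setGeneric("labelMatrix", function(object) standardGeneric("labelMatrix"))

#' @rdname accessors
#' @export
setGeneric("nObjects", function(object) standardGeneric("nObjects"))

#' @rdname accessors
#' @export
setGeneric("planeValues", function(object) standardGeneric("planeValues"))

#' @rdname accessors
#' @export
setMethod("planes", "ImageStack", function(object, ...) object@planes)

#' @rdname accessors
#' @export
setMethod("channelRoles", "ImageStack", function(object) object@channelRoles)

#' @rdname accessors
#' @export
setMethod("pixelSizeXY", "ImageStack", function(object) object@pixelSizeXY)

#' @rdname accessors
#' @export
setMethod("pixelSizeXY", "Plane", function(object) object@pixelSizeXY)

#' @rdname accessors
#' @export
setMethod("pixelSizeXY", "TissueMask", function(object) object@pixelSizeXY)

#' @rdname accessors
#' @export
setMethod("pixelSizeXY", "LabelImage", function(object) object@pixelSizeXY)

#' @rdname accessors
#' @export
setMethod("pixelSizeZ", "ImageStack", function(object) object@pixelSizeZ)

#' @rdname accessors
#' @export
setMethod("discId", "ImageStack", function(object) object@discId)

#' @rdname accessors
#' @export
setMethod("maskValues", "TissueMask", function(object) object@mask)

#' @rdname accessors
#' @export
setMethod("rimMask", "RegionPartition", function(object) object@rim)

#' @rdname accessors
#' @export
setMethod("centreMask", "RegionPartition", function(object) object@centre)

#' @rdname accessors
#' @export
setMethod("labelMatrix", "LabelImage", function(object) object@labels)

#' @rdname accessors
#' @export
setMethod("nObjects", "LabelImage",
          function(object) max(0L, max(object@labels)))

#' @rdname accessors
#' @export
setMethod("planeValues", "Plane", function(object) object@values)

setMethod("show", "ImageStack", function(object) {
    d <- dim(object@planes[[1L]])
    cat(sprintf("ImageStack '%s': %d channel(s), %d x %d px, %d plane(s)\n",
                object@discId, length(object@planes), d[2L], d[3L], d[1L]))
    cat(sprintf("  pixel size: %.4g um (xy), %.4g um (z)\n",
                object@pixelSizeXY, object@pixelSizeZ))
    roles <- object@channelRoles[names(object@planes)]
    cat(sprintf("  channels: %s\n",
                paste(sprintf("%s[%s]", names(roles), roles), collapse = ", ")))
})

setMethod("show", "Plane", function(object) {
    d <- dim(object@values)
    cat(sprintf("Plane %d x %d px (%.4g um/px), from %s\n",
                d[1L], d[2L], object@pixelSizeXY, object@provenance))
})

setMethod("show", "TissueMask", function(object) {
    cat(sprintf("TissueMask: %d / %d px foreground\n",
                sum(object@mask), length(object@mask)))
})

setMethod("show", "RegionPartition", function(object) {
    cat(sprintf("RegionPartition (width %g px): rim %d px, centre %d px\n",
                object@widthPx, sum(object@rim), sum(object@centre)))
})

setMethod("show", "LabelImage", function(object) {
    cat(sprintf("LabelImage (%s): %d object(s)\n", object@kind,
                nObjects(object)))
})

setMethod("show", "CompartmentMask", function(object) {
    cat(sprintf("CompartmentMask: positive %d px, negative %d px\n",
                sum(object@positive), sum(object@negative)))
})

setMethod("show", "RatioMap", function(object) {
    v <- object@values[object@validity]
    if (length(v))
        cat(sprintf("RatioMap: %d valid px, ratio range [%.3g, %.3g]\n",
                    length(v), min(v), max(v)))
    else cat("RatioMap: no valid pixels\n")
})

setMethod("show", "PhantomSpec", function(object) {
    cat(sprintf(
        "PhantomSpec '%s' %dx%d px @ %.3g um/px, R = %g, noise (s = %g, sd = %g), seed %d\n",
        object@geometry, object@shape[1L], object@shape[2L],
        object@pixelSizeXY, object@enrichmentR, object@noise$poissonScale,
        object@noise$gaussianSD, object@seed))
})

setMethod("show", "PhantomTruth", function(object) {
    cat(sprintf(
        "PhantomTruth: tissue %d px, rim %d px, %d nuclei, %d mitochondria, true R = %g\n",
        sum(object@tissueMask), sum(object@rimMask), nrow(object@nuclei),
        nrow(object@mito), object@trueRatio))
})
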