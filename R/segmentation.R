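#' Segment the whole-tissue mask from a reference plane
#'
#' Automates the manual disc outlining step: Gaussian smoothing, a global
#' threshold (Otsu by default, or a fixed value), hole filling, removal of
#' small components and retention of the largest connected component. A
#' manually drawn mask can be substituted via \code{\link{tissueMaskFromMatrix}}.
#'
#' @param reference a DAPI or phalloidin \linkS4class{Plane} (or projection).
#' @param smoothingSigma Gaussian sigma in pixels (0 = none; default 2).
#' @param minArea minimum component area in px^2 (default 64).
#' @param threshold \code{"multiotsu_lo"} (default: two-threshold Otsu,
#'   lower cut — separates slide background from tissue even when bright
#'   nuclei form a third intensity class), \code{"otsu"}, or a fixed
#'   intensity value.
#' @return a \linkS4class{TissueMask}.
#' @export
segmentTissue <- function(reference, smoothingSigma = 2, minArea = 64,
                          threshold = "multiotsu_lo") {
    stopifnot(is(reference, "Plane"))
    v <- planeValues(reference)
    sm <- if (smoothingSigma > 0)
        .asMatrix(EBImage::gblur(v, sigma = smoothingSigma)) else v
    thr <- .resolveThreshold(sm, threshold)
    fg <- sm > thr
    if (!any(fg))
        .stopSegmentation("empty foreground at threshold %.6g", thr)
    lab <- .asMatrix(EBImage::bwlabel(fg))
    sizes <- tabulate(lab[lab > 0])
    keep <- which(sizes >= minArea)
    if (!length(keep)) keep <- which.max(sizes)
    big <- keep[which.max(sizes[keep])]
    mask <- lab == big
    mask <- .asMatrix(EBImage::fillHull(mask)) > 0
    new("TissueMask", mask = mask, pixelSizeXY = pixelSizeXY(reference),
        params = list(smoothingSigma = smoothingSigma, minArea = minArea,
                      threshold = threshold, thresholdValue = thr))
}

.resolveThreshold <- function(values, threshold, within = NULL) {
    if (is.numeric(threshold)) return(threshold)
    if (!threshold %in% c("otsu", "multiotsu_lo"))
        .stopConfig("threshold must be 'otsu', 'multiotsu_lo' or a numeric value")
    v <- if (is.null(within)) as.vector(values) else values[within]
    if (!is.null(within) && length(unique(v)) < 2L)
        v <- as.vector(values)   # constant inside the mask: threshold globally
    rg <- range(v)
    if (rg[1L] == rg[2L])
        .stopSegmentation("cannot threshold a constant image (value %.6g)",
                          rg[1L])
    if (identical(threshold, "otsu"))
        EBImage::otsu(matrix(v, nrow = 1L), range = rg, levels = 256L)
    else .multiOtsuLo(v)
}

## two-threshold Otsu on a 256-bin histogram; returns the LOWER threshold.
## Exhaustive maximization of the three-class between-class variance.
.multiOtsuLo <- function(v, levels = 256L) {
    rg <- range(v)
    br <- seq(rg[1L], rg[2L], length.out = levels + 1L)
    h <- tabulate(pmin(findInterval(v, br, rightmost.closed = TRUE), levels),
                  nbins = levels)
    p <- h / sum(h)
    mids <- (br[-1L] + br[-(levels + 1L)]) / 2
    cw <- cumsum(p)
    cm <- cumsum(p * mids)
    total <- cm[levels]
    best <- -Inf; lo <- 1L
    for (i in seq_len(levels - 2L)) {
        w0 <- cw[i]; m0 <- cm[i]
        if (w0 <= 0) next
        j <- (i + 1L):(levels - 1L)
        w1 <- cw[j] - w0; w2 <- 1 - cw[j]
        m1 <- cm[j] - m0; m2 <- total - cm[j]
        s <- m0^2 / w0 + ifelse(w1 > 0, m1^2 / w1, NA) +
            ifelse(w2 > 0, m2^2 / w2, NA)
        sm <- suppressWarnings(max(s, na.rm = TRUE))
        if (is.finite(sm) && sm > best) { best <- sm; lo <- i }
    }
    br[lo + 1L]
}

#' Wrap an externally produced binary mask as a TissueMask
#'
#' @param mask logical or 0/1 matrix.
#' @param pixelSizeXY micrometres per pixel.
#' @return a \linkS4class{TissueMask}.
#' @export
tissueMaskFromMatrix <- function(mask, pixelSizeXY) {
    mask <- mask > 0
    new("TissueMask", mask = mask, pixelSizeXY = as.numeric(pixelSizeXY),
        params = list(threshold = "manual"))
}

#' Partition a tissue mask into a fixed-width rim band and the centre
#'
#' The rim is the set of foreground pixels whose Euclidean distance to
#' the nearest background pixel is at most \code{widthPx} (the default 10
#' px matches the immunofluorescence analyses; membrane-potential
#' analyses use 13 px). The centre is the remaining foreground, so the
#' two regions are disjoint and cover the tissue exactly.
#'
#' @param tissue a \linkS4class{TissueMask}.
#' @param widthPx rim width in pixels (>= 0).
#' @param widthUm alternatively, a width in micrometres, converted via the
#'   pixel calibration and rounded half-up.
#' @return a \linkS4class{RegionPartition}.
#' @export
partitionRimCentre <- function(tissue, widthPx = 10, widthUm = NULL) {
    stopifnot(is(tissue, "TissueMask"))
    if (!is.null(widthUm))
        widthPx <- floor(widthUm / pixelSizeXY(tissue) + 0.5)
    if (widthPx < 0) .stopConfig("widthPx must be >= 0")
    m <- maskValues(tissue)
    d <- .distToBackground(m)
    rim <- m & d <= widthPx
    centre <- m & !rim
    if (!any(centre))
        warning(sprintf("rim width %g px swallows the whole tissue; centre is empty",
                        widthPx))
    new("RegionPartition", rim = rim, centre = centre,
        widthPx = as.numeric(widthPx), pixelSizeXY = pixelSizeXY(tissue))
}

#' Segment nuclei from a DAPI plane
#'
#' Gaussian smoothing, Otsu (optionally restricted to the tissue mask so
#' the threshold separates nuclei from cytoplasmic background rather than
#' tissue from slide), size filtering, and optionally a watershed split
#' of touching nuclei on the smoothed DAPI intensity.
#'
#' @param dapi a DAPI \linkS4class{Plane} (single optical section).
#' @param smoothingSigma Gaussian sigma in px (default 1).
#' @param minArea minimum nucleus area in px^2 (default 20).
#' @param split split touching nuclei by intensity watershed (default TRUE).
#' @param threshold \code{"otsu"} or fixed value.
#' @param within optional \linkS4class{TissueMask} restricting both the
#'   threshold estimation and the segmentation support.
#' @param tolerance watershed tolerance (intensity units; default 10 —
#'   peaks separated by saddles shallower than this are merged, which
#'   keeps smoothed noise from oversplitting nuclei).
#' @return a \linkS4class{LabelImage} of kind \code{"nuclei"} (possibly
#'   with zero objects, which is logged, not an error).
#' @export
segmentNuclei <- function(dapi, smoothingSigma = 1, minArea = 20,
                          split = TRUE, threshold = "otsu", within = NULL,
                          tolerance = 10) {
    stopifnot(is(dapi, "Plane"))
    v <- planeValues(dapi)
    sm <- if (smoothingSigma > 0)
        .asMatrix(EBImage::gblur(v, sigma = smoothingSigma)) else v
    wmask <- if (is.null(within)) NULL else maskValues(within)
    if (!is.null(wmask)) .checkCongruent(v, wmask, "dapi and tissue mask")
    thr <- tryCatch(.resolveThreshold(sm, threshold, within = wmask),
                    error = function(e) Inf)
    fg <- sm > thr
    if (!is.null(wmask)) fg <- fg & wmask
    if (!any(fg)) {
        .log("segmentNuclei: no nuclei found (threshold %.6g)", thr)
        return(new("LabelImage",
                   labels = matrix(0L, nrow(v), ncol(v)), kind = "nuclei",
                   pixelSizeXY = pixelSizeXY(dapi),
                   params = list(threshold = thr)))
    }
    lab <- if (split) {
        ws <- EBImage::watershed(sm * fg, tolerance = tolerance)
        .asMatrix(ws)
    } else .asMatrix(EBImage::bwlabel(fg))
    lab <- .dropSmallAndRelabel(lab, minArea)
    new("LabelImage", labels = lab, kind = "nuclei",
        pixelSizeXY = pixelSizeXY(dapi),
        params = list(smoothingSigma = smoothingSigma, minArea = minArea,
                      split = split, threshold = thr, tolerance = tolerance))
}

.dropSmallAndRelabel <- function(lab, minArea) {
    storage.mode(lab) <- "integer"
    n <- max(lab)
    if (n == 0L) return(lab)
    sizes <- tabulate(lab[lab > 0L], nbins = n)
    keep <- which(sizes >= minArea)
    remap <- integer(n)
    remap[keep] <- seq_along(keep)
    out <- matrix(0L, nrow(lab), ncol(lab))
    pos <- lab > 0L
    out[pos] <- remap[lab[pos]]
    out
}

#' Wrap an externally produced label matrix as a LabelImage
#'
#' @param labels integer matrix (0 background, consecutive positive labels).
#' @param kind \code{"nuclei"} or \code{"mitochondria"}.
#' @param pixelSizeXY micrometres per pixel.
#' @return a \linkS4class{LabelImage}.
#' @export
labelImageFromMatrix <- function(labels, kind, pixelSizeXY) {
    storage.mode(labels) <- "integer"
    new("LabelImage", labels = labels, kind = kind,
        pixelSizeXY = as.numeric(pixelSizeXY), params = list())
}

#' Split the tissue into reporter-positive and -negative compartments
#'
#' The reporter (GFP or IFP) plane is smoothed and thresholded within the
#' tissue mask; pixels above the threshold form the positive compartment,
#' the rest of the tissue the negative one. Either side may be empty
#' (logged, not an error).
#'
#' @param reporter a reporter \linkS4class{Plane}.
#' @param tissue a \linkS4class{TissueMask} congruent with it.
#' @param threshold \code{"otsu"} (within the tissue) or fixed value.
#' @param smoothingSigma Gaussian sigma in px (default 2).
#' @return a \linkS4class{CompartmentMask}.
#' @export
segmentReporterRegion <- function(reporter, tissue, threshold = "otsu",
                                  smoothingSigma = 2) {
    stopifnot(is(reporter, "Plane"), is(tissue, "TissueMask"))
    v <- planeValues(reporter)
    m <- maskValues(tissue)
    .checkCongruent(v, m, "reporter and tissue mask")
    sm <- if (smoothingSigma > 0)
        .asMatrix(EBImage::gblur(v, sigma = smoothingSigma)) else v
    thr <- tryCatch(.resolveThreshold(sm, threshold, within = m),
                    error = function(e) Inf)
    pos <- m & sm > thr
    neg <- m & !pos
    if (!any(pos)) .log("segmentReporterRegion: positive compartment empty")
    if (!any(neg)) .log("segmentReporterRegion: negative compartment empty")
    new("CompartmentMask", positive = pos, negative = neg)
}

#' Per-pixel distance to the tissue surface
#'
#' Euclidean distance, in micrometres, from each foreground pixel to the
#' nearest background pixel; background pixels carry 0. This is the map
#' nucleus surface distances are read from.
#'
#' @param tissue a \linkS4class{TissueMask}.
#' @return a \linkS4class{Plane} of distances in micrometres.
#' @export
surfaceDistanceMap <- function(tissue) {
    stopifnot(is(tissue, "TissueMask"))
    d <- .distToBackground(maskValues(tissue)) * pixelSizeXY(tissue)
    .newPlane(d, pixelSizeXY(tissue), "surface distance map")
}
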