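#' Reference-normalized rim/centre intensity ratio
#'
#' The core disc statistic: integrated mark intensity is normalized to
#' the integrated reference (DAPI for immunofluorescence, mitoGFP for
#' TMRM) separately in the rim band and in the centre, and the two
#' normalized values are divided:
#' \deqn{ratio = (\sum_{rim} M / \sum_{rim} D) / (\sum_{centre} M / \sum_{centre} D)}
#' The ratio is dimensionless and invariant under global rescaling of
#' either channel.
#'
#' @param mark mark \linkS4class{Plane}.
#' @param reference normalization \linkS4class{Plane}.
#' @param partition a \linkS4class{RegionPartition}.
#' @param restrict optional logical matrix (e.g. one compartment); the
#'   ratio is then computed within \code{restrict} only.
#' @param discId identifier copied into the result.
#' @param markRole,referenceRole role strings recorded in the result.
#' @param compartment label recorded in the result
#'   (\code{"whole"}, \code{"reporter_positive"}, \code{"reporter_negative"}).
#' @param backgroundOffset constant intensity subtracted from the mark
#'   channel before integration (default 0: no background subtraction).
#' @return a one-row data.frame (disc_id, mark, reference, compartment,
#'   rim_intensity, centre_intensity, rim_reference, centre_reference,
#'   ratio, width_px).
#' @export
rimCentreRatio <- function(mark, reference, partition, restrict = NULL,
                           discId = "disc", markRole = "mark",
                           referenceRole = "dapi", compartment = "whole",
                           backgroundOffset = 0) {
    stopifnot(is(mark, "Plane"), is(reference, "Plane"),
              is(partition, "RegionPartition"))
    mv <- planeValues(mark); rv <- planeValues(reference)
    .checkCongruent(mv, rv, "mark and reference")
    .checkCongruent(mv, rimMask(partition), "planes and partition")
    rim <- rimMask(partition); cen <- centreMask(partition)
    if (!is.null(restrict)) {
        .checkCongruent(mv, restrict, "planes and restriction mask")
        rim <- rim & restrict
        cen <- cen & restrict
    }
    if (!any(rim)) .stopMeasurement("empty rim region (after restriction)")
    if (!any(cen)) .stopMeasurement("empty centre region (after restriction)")
    if (backgroundOffset != 0) mv <- pmax(mv - backgroundOffset, 0)
    mRim <- sum(mv[rim]); mCen <- sum(mv[cen])
    dRim <- sum(rv[rim]); dCen <- sum(rv[cen])
    if (dRim <= 0) .stopMeasurement("zero reference signal in rim")
    if (dCen <= 0) .stopMeasurement("zero reference signal in centre")
    data.frame(disc_id = discId, mark = markRole, reference = referenceRole,
               compartment = compartment, rim_intensity = mRim,
               centre_intensity = mCen, rim_reference = dRim,
               centre_reference = dCen,
               ratio = (mRim / dRim) / (mCen / dCen),
               width_px = partition@widthPx,
               stringsAsFactors = FALSE)
}

#' Rim/centre ratios per reporter compartment
#'
#' Computes \code{\link{rimCentreRatio}} restricted to the
#' reporter-positive and reporter-negative compartments of the same disc.
#' A compartment without rim or centre pixels yields an NA ratio for that
#' side (with a warning); the other side is still returned.
#'
#' @inheritParams rimCentreRatio
#' @param compartments a \linkS4class{CompartmentMask}.
#' @return a two-row data.frame (rows \code{reporter_positive},
#'   \code{reporter_negative}); failed sides have NA intensities/ratio.
#' @export
compartmentRatioPair <- function(mark, reference, partition, compartments,
                                 discId = "disc", markRole = "mark",
                                 referenceRole = "dapi") {
    stopifnot(is(compartments, "CompartmentMask"))
    one <- function(restrict, label) {
        tryCatch(
            rimCentreRatio(mark, reference, partition, restrict,
                           discId = discId, markRole = markRole,
                           referenceRole = referenceRole,
                           compartment = label),
            discRim_measurement_error = function(e) {
                warning(sprintf("%s: %s", label, conditionMessage(e)))
                data.frame(disc_id = discId, mark = markRole,
                           reference = referenceRole, compartment = label,
                           rim_intensity = NA_real_,
                           centre_intensity = NA_real_,
                           rim_reference = NA_real_,
                           centre_reference = NA_real_, ratio = NA_real_,
                           width_px = partition@widthPx,
                           stringsAsFactors = FALSE)
            })
    }
    rbind(one(compartments@positive, "reporter_positive"),
          one(compartments@negative, "reporter_negative"))
}

#' Total rim intensity per compartment
#'
#' For analyses where a total rim intensity per compartment is reported
#' instead of a rim/centre ratio: the summed mark intensity over
#' rim-and-compartment pixels, per compartment. Empty intersections give
#' 0 (logged).
#'
#' @inheritParams compartmentRatioPair
#' @return named numeric: \code{c(reporter_positive=, reporter_negative=)}.
#' @export
rimTotalIntensity <- function(mark, partition, compartments) {
    stopifnot(is(mark, "Plane"), is(partition, "RegionPartition"),
              is(compartments, "CompartmentMask"))
    mv <- planeValues(mark)
    .checkCongruent(mv, rimMask(partition), "mark and partition")
    .checkCongruent(mv, compartments@positive, "mark and compartments")
    rim <- rimMask(partition)
    out <- c(reporter_positive = sum(mv[rim & compartments@positive]),
             reporter_negative = sum(mv[rim & compartments@negative]))
    if (any(out == 0)) .log("rimTotalIntensity: empty rim-compartment sum")
    out
}

#' Integrated-intensity ratio of sum projections
#'
#' Sum-projects the mark and reference channels over z and returns the
#' quotient of their integrated intensities over a region (the whole
#' image when no region is given). This is the whole-disc normalization
#' used for cytoplasmic marks and FISH signals.
#'
#' @param stack an \linkS4class{ImageStack}.
#' @param referenceChannel,markChannel channel names or roles.
#' @param region optional logical matrix.
#' @return dimensionless ratio (numeric scalar).
#' @export
projectedIntensityRatio <- function(stack, referenceChannel, markChannel,
                                    region = NULL) {
    mp <- planeValues(sumProjection(stack, markChannel))
    rp <- planeValues(sumProjection(stack, referenceChannel))
    if (is.null(region)) region <- matrix(TRUE, nrow(mp), ncol(mp))
    .checkCongruent(mp, region, "projection and region")
    den <- sum(rp[region])
    if (den <= 0) .stopMeasurement("zero reference integral over region")
    sum(mp[region]) / den
}

#' Per-nucleus mean intensities
#'
#' One record per labelled nucleus with its centroid, area and the mean
#' intensity of each supplied channel over the nucleus pixels.
#'
#' @param nuclei a \linkS4class{LabelImage} of kind \code{"nuclei"}.
#' @param channels named list of \linkS4class{Plane}s (names become
#'   \code{mean_<name>} columns).
#' @param discId identifier copied into the records.
#' @return data.frame (disc_id, label, centroid_y, centroid_x, area,
#'   mean_<channel>...); zero rows when the label image is empty.
#' @export
measureNuclei <- function(nuclei, channels, discId = "disc") {
    stopifnot(is(nuclei, "LabelImage"))
    if (is(channels, "Plane")) channels <- list(channel = channels)
    lab <- labelMatrix(nuclei)
    n <- nObjects(nuclei)
    base <- data.frame(disc_id = character(0), label = integer(0),
                       centroid_y = numeric(0), centroid_x = numeric(0),
                       area = numeric(0), stringsAsFactors = FALSE)
    for (nm in names(channels))
        base[[paste0("mean_", nm)]] <- numeric(0)
    if (n == 0L) return(base)
    pos <- lab > 0L
    ids <- lab[pos]
    co <- .maskCoords(pos)
    area <- tabulate(ids, nbins = n)
    rec <- data.frame(disc_id = discId, label = seq_len(n),
                      centroid_y = .byLabel(co[, "y"], ids, n, mean),
                      centroid_x = .byLabel(co[, "x"], ids, n, mean),
                      area = area, stringsAsFactors = FALSE)
    for (nm in names(channels)) {
        v <- planeValues(channels[[nm]])
        .checkCongruent(v, lab, sprintf("channel '%s' and labels", nm))
        rec[[paste0("mean_", nm)]] <- .byLabel(v[pos], ids, n, sum) / area
    }
    rownames(rec) <- NULL
    rec
}

#' Annotate nucleus records with distance to the tissue surface
#'
#' The surface distance of a nucleus is taken at its most outward-facing
#' part: the minimum, over the nucleus's pixels, of the Euclidean
#' distance-to-background map of the tissue mask, in micrometres. Nuclei
#' with pixels outside the tissue mask get distance 0 with a warning.
#'
#' @param records data.frame from \code{\link{measureNuclei}}.
#' @param nuclei the matching \linkS4class{LabelImage}.
#' @param tissue the \linkS4class{TissueMask}.
#' @return \code{records} with a \code{dist_surface} column (micrometres).
#' @export
annotateSurfaceDistance <- function(records, nuclei, tissue) {
    stopifnot(is(nuclei, "LabelImage"), is(tissue, "TissueMask"))
    lab <- labelMatrix(nuclei)
    .checkCongruent(lab, maskValues(tissue), "labels and tissue mask")
    dmap <- planeValues(surfaceDistanceMap(tissue))
    records$dist_surface <- NA_real_
    if (!nrow(records)) return(records)
    pos <- lab > 0L
    ids <- lab[pos]
    outside <- tapply(!maskValues(tissue)[pos], ids, any)
    mins <- tapply(dmap[pos], ids, min)
    if (any(outside[as.character(records$label)]))
        warning("nucleus pixels outside the tissue mask; their surface distance is 0")
    records$dist_surface <- as.numeric(mins[as.character(records$label)])
    records
}

#' Annotate nucleus records with distance to the nearest mitochondrion
#'
#' Surface-to-surface distance between each nucleus and its closest
#' mitochondrion, measured as the minimum pairwise pixel distance in
#' micrometres (0 when they overlap). When there are no mitochondria the
#' column is NA.
#'
#' @param records data.frame from \code{\link{measureNuclei}}.
#' @param nuclei the matching nuclei \linkS4class{LabelImage}.
#' @param mitochondria a \linkS4class{LabelImage} of kind
#'   \code{"mitochondria"}.
#' @return \code{records} with a \code{dist_mito} column (micrometres).
#' @export
annotateMitoDistance <- function(records, nuclei, mitochondria) {
    stopifnot(is(nuclei, "LabelImage"), is(mitochondria, "LabelImage"))
    lab <- labelMatrix(nuclei)
    mlab <- labelMatrix(mitochondria)
    .checkCongruent(lab, mlab, "nucleus and mitochondrion labels")
    records$dist_mito <- NA_real_
    if (!nrow(records) || max(mlab) == 0L) return(records)
    px <- pixelSizeXY(nuclei)
    mco <- .maskCoords(mlab > 0L)
    for (i in seq_len(nrow(records))) {
        nco <- .maskCoords(lab == records$label[i])
        d2 <- outer(nco[, "y"], mco[, "y"], "-")^2 +
              outer(nco[, "x"], mco[, "x"], "-")^2
        records$dist_mito[i] <- sqrt(min(d2)) * px
    }
    records
}

#' Bin nuclei by surface distance and normalize to the reference bin
#'
#' Sorts nuclei into three distance bins (default \code{<5}, \code{5-10}
#' and \code{>10} micrometres; boundaries are half-open, so a distance of
#' exactly 5 falls in \code{5-10}) and divides each nucleus's mean
#' intensity by the average of the reference bin (default the \code{<5}
#' bin).
#'
#' @param records data.frame with \code{dist_surface} and a
#'   \code{mean_<channel>} column.
#' @param channel channel name whose \code{mean_<channel>} column is
#'   normalized.
#' @param edges two increasing bin edges in micrometres (default 5, 10).
#' @param referenceBin bin label to normalize to (default \code{"<5"}).
#' @return \code{records} with \code{bin} and \code{normalized_intensity}
#'   columns.
#' @export
binAndNormalize <- function(records, channel, edges = c(5, 10),
                            referenceBin = NULL) {
    if (length(edges) != 2L || diff(edges) <= 0)
        .stopInput("edges must be two strictly increasing values")
    col <- paste0("mean_", channel)
    if (!col %in% names(records))
        .stopInput("records have no column '%s'", col)
    if (anyNA(records$dist_surface))
        .stopInput("dist_surface must be present on all records")
    labs <- c(sprintf("<%g", edges[1L]),
              sprintf("%g-%g", edges[1L], edges[2L]),
              sprintf(">%g", edges[2L]))
    if (is.null(referenceBin)) referenceBin <- labs[1L]
    d <- records$dist_surface
    records$bin <- ifelse(d < edges[1L], labs[1L],
                          ifelse(d < edges[2L], labs[2L], labs[3L]))
    ref <- records[[col]][records$bin == referenceBin]
    if (!length(ref))
        .stopInput("reference bin '%s' is empty", referenceBin)
    records$normalized_intensity <- records[[col]] / mean(ref)
    records
}

#' Normalize replicates to their control group
#'
#' To combine biological replicates, every value is divided by the mean
#' of the control group of its own replicate, so control groups have mean
#' 1 in each replicate.
#'
#' @param data data.frame with columns \code{value}, \code{replicate},
#'   \code{group}.
#' @param controlLabel the control group label.
#' @return \code{data} with a \code{normalized} column.
#' @export
replicateNormalize <- function(data, controlLabel) {
    stopifnot(all(c("value", "replicate", "group") %in% names(data)))
    data$normalized <- NA_real_
    for (rep in unique(data$replicate)) {
        sel <- data$replicate == rep
        ctrl <- data$value[sel & data$group == controlLabel]
        if (!length(ctrl))
            .stopInput("replicate '%s' has no '%s' control measurements",
                       rep, controlLabel)
        data$normalized[sel] <- data$value[sel] / mean(ctrl)
    }
    data
}

#' Ratiometric dual-excitation sensor map
#'
#' Pixelwise ratio of the pH-sensitive 488 nm excitation channel to the
#' pH-insensitive 405 nm excitation channel, inside the tissue mask and
#' only where the 405 channel exceeds an intensity floor (default 5\% of
#' its maximum).
#'
#' @param ex488,ex405 \linkS4class{Plane}s of the two excitation channels.
#' @param mask a \linkS4class{TissueMask} (or NULL for the whole image).
#' @param floor denominator floor in intensity units; default
#'   \code{0.05 * max(ex405)}.
#' @return a \linkS4class{RatioMap}.
#' @export
ratiometricMap <- function(ex488, ex405, mask = NULL, floor = NULL) {
    stopifnot(is(ex488, "Plane"), is(ex405, "Plane"))
    a <- planeValues(ex488); b <- planeValues(ex405)
    .checkCongruent(a, b, "ex488 and ex405")
    m <- if (is.null(mask)) matrix(TRUE, nrow(a), ncol(a)) else maskValues(mask)
    .checkCongruent(a, m, "channels and mask")
    if (is.null(floor)) floor <- 0.05 * max(b)
    valid <- m & b > floor
    vals <- matrix(NA_real_, nrow(a), ncol(a))
    vals[valid] <- a[valid] / b[valid]
    if (!any(valid)) .log("ratiometricMap: no valid pixels above floor %.6g",
                          floor)
    new("RatioMap", values = vals, validity = valid)
}

#' Rim/centre summary of a ratio map
#'
#' Mean ratio over valid rim pixels divided by the mean over valid centre
#' pixels; the scalar summary used to compare sensor maps across discs.
#'
#' @param map a \linkS4class{RatioMap}.
#' @param partition a \linkS4class{RegionPartition}.
#' @return numeric scalar.
#' @export
ratioMapRimCentre <- function(map, partition) {
    stopifnot(is(map, "RatioMap"), is(partition, "RegionPartition"))
    v <- map@values
    rim <- rimMask(partition) & map@validity
    cen <- centreMask(partition) & map@validity
    if (!any(rim) || !any(cen))
        .stopMeasurement("no valid rim or centre pixels in ratio map")
    mean(v[rim]) / mean(v[cen])
}

#' Named analysis presets
#'
#' \code{"immuno"} binds reference = DAPI with a 10-px rim;
#' \code{"tmrm"} binds reference = mitoGFP with a 13-px rim.
#'
#' @param name \code{"immuno"} or \code{"tmrm"}.
#' @return list(reference = role, widthPx = integer).
#' @export
quantPreset <- function(name = c("immuno", "tmrm")) {
    switch(match.arg(name),
           immuno = list(reference = "dapi", widthPx = 10L),
           tmrm = list(reference = "mito", widthPx = 13L))
}
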