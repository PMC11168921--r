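## Synthetic disc phantoms with exact ground truth. Three geometries:
## an x-y disc section with a rim-enriched mark, a cross-section with
## nuclei at controlled surface distances, and a dual-excitation sensor
## disc. Intensity levels (arbitrary detector units) are fixed study
## conditions, documented in the methods vignette.

.DISC_DAPI_BASE <- 100
.DISC_DAPI_NUCLEUS <- 250
.DISC_MARK_SCALE <- 0.8
.DISC_REPORTER_LEVEL <- 150
.MITO_LEVEL <- 180
.XS_DAPI_BASE <- 40
.XS_DAPI_NUCLEUS <- 200
.XS_MARK_BASE <- 10
.SENSOR_EX405_PEAK <- 200

#' Construct a phantom specification
#'
#' Geometry-aware constructor for \linkS4class{PhantomSpec} with the
#' package's standard study conditions as defaults. Any field can be
#' overridden by name.
#'
#' @param geometry \code{"disc_xy"}, \code{"cross_section"} or
#'   \code{"sensor"}.
#' @param seed integer seed (phantom generation is deterministic given
#'   the full spec).
#' @param ... overrides for any \linkS4class{PhantomSpec} slot
#'   (\code{shape}, \code{enrichmentR}, \code{noise}, ...).
#' @return a validated \linkS4class{PhantomSpec}.
#' @export
phantomSpec <- function(geometry = c("disc_xy", "cross_section", "sensor"),
                        seed = 1L, ...) {
    geometry <- match.arg(geometry)
    defaults <- switch(geometry,
        disc_xy = list(
            shape = c(160L, 160L), rimWidthTrue = 10, enrichmentR = 3,
            nNuclei = 30L, nucleusRadius = 3, targetDepths = numeric(0),
            nMito = 0L, reporterFraction = 0.5),
        cross_section = list(
            shape = c(96L, 256L), rimWidthTrue = 10, enrichmentR = 1,
            nNuclei = 12L, nucleusRadius = 4,
            targetDepths = c(1, 2, 3, 4, 6, 7, 8, 9, 11, 13, 15, 17),
            nMito = 15L, reporterFraction = 0),
        sensor = list(
            shape = c(160L, 160L), rimWidthTrue = 13, enrichmentR = 1,
            nNuclei = 0L, nucleusRadius = 3, targetDepths = numeric(0),
            nMito = 0L, reporterFraction = 0))
    args <- utils::modifyList(c(defaults, list(
        pixelSizeXY = 0.5, pixelSizeZ = 1,
        depthProfile = list(type = "exp", hi = 200, lo = 20, tau = 5),
        sensorField = list(type = "rim_step", base = 1, factor = 2),
        noise = list(poissonScale = 1, gaussianSD = 5),
        nz = 1L)), list(...))
    new("PhantomSpec",
        shape = as.integer(args$shape), pixelSizeXY = args$pixelSizeXY,
        pixelSizeZ = args$pixelSizeZ, geometry = geometry,
        rimWidthTrue = args$rimWidthTrue, enrichmentR = args$enrichmentR,
        nNuclei = as.integer(args$nNuclei),
        nucleusRadius = args$nucleusRadius,
        depthProfile = args$depthProfile,
        targetDepths = as.numeric(args$targetDepths),
        nMito = as.integer(args$nMito),
        reporterFraction = args$reporterFraction,
        sensorField = args$sensorField, noise = args$noise,
        nz = as.integer(args$nz), seed = as.integer(seed))
}

#' Noise-free phantom spec helper
#'
#' @param geometry,seed,... as \code{\link{phantomSpec}}.
#' @return a \linkS4class{PhantomSpec} with both noise terms zeroed.
#' @export
phantomSpecNoiseFree <- function(geometry = "disc_xy", seed = 1L, ...) {
    phantomSpec(geometry = geometry, seed = seed,
                noise = list(poissonScale = 0, gaussianSD = 0), ...)
}

## elliptical mask; centre (cy, cx), semi-axes (ry, rx)
.ellipseMask <- function(H, W, cy, cx, ry, rx) {
    y <- matrix(seq_len(H), H, W)
    x <- matrix(seq_len(W), H, W, byrow = TRUE)
    ((y - cy) / ry)^2 + ((x - cx) / rx)^2 <= 1
}

.diskMask <- function(H, W, cy, cx, r) {
    y <- matrix(seq_len(H), H, W)
    x <- matrix(seq_len(W), H, W, byrow = TRUE)
    (y - cy)^2 + (x - cx)^2 <= r^2
}

## Poisson shot noise (photon scaling s) + Gaussian read noise, then
## quantization to non-negative integer detector counts. Both terms 0
## => the exact ideal field is returned untouched.
.applyNoise <- function(values, noise) {
    s <- noise$poissonScale; sd <- noise$gaussianSD
    if (s == 0 && sd == 0) return(values)
    v <- as.vector(values)
    if (s > 0) v <- stats::rpois(length(v), v * s) / s
    if (sd > 0) v <- v + stats::rnorm(length(v), 0, sd)
    matrix(pmax(round(v), 0), nrow(values), ncol(values))
}

## split a 2-D ideal field into nz planes summing to the original, apply
## noise per plane independently
.toStackArray <- function(field, spec) {
    nz <- spec@nz
    a <- array(0, dim = c(nz, nrow(field), ncol(field)))
    for (zi in seq_len(nz)) a[zi, , ] <- .applyNoise(field / nz, spec@noise)
    a
}

.hardCorePlace <- function(n, allowed, minDist, maxAttempts = 400L) {
    ## rejection-sample n centres inside `allowed` with pairwise distance
    ## > minDist; deterministic under the caller's seed
    co <- .maskCoords(allowed)
    if (!nrow(co)) .stopInput("no room to place objects")
    ys <- numeric(0); xs <- numeric(0)
    attempts <- 0L
    while (length(ys) < n) {
        attempts <- attempts + 1L
        if (attempts > maxAttempts * n)
            .stopInput("could not place %d non-overlapping objects", n)
        k <- sample.int(nrow(co), 1L)
        y <- co[k, "y"]; x <- co[k, "x"]
        if (!length(ys) || all((ys - y)^2 + (xs - x)^2 > minDist^2)) {
            ys <- c(ys, y); xs <- c(xs, x)
        }
    }
    cbind(y = ys, x = xs)
}

.renderObjects <- function(H, W, centres, r) {
    lab <- matrix(0L, H, W)
    for (i in seq_len(nrow(centres)))
        lab[.diskMask(H, W, centres[i, "y"], centres[i, "x"], r)] <- i
    lab
}

.nucleusTruth <- function(lab, tissue, px, channels) {
    ## per-object centroid, area, exact surface distance and true means
    ## derived from the noise-free channel fields (construction truth)
    n <- max(lab)
    if (n == 0L)
        return(data.frame(label = integer(0), y = numeric(0), x = numeric(0),
                          area = integer(0), distSurface = numeric(0)))
    dmap <- .distToBackground(tissue) * px
    pos <- lab > 0L
    ids <- lab[pos]
    co <- .maskCoords(pos)
    out <- data.frame(label = seq_len(n),
                      y = .byLabel(co[, "y"], ids, n, mean),
                      x = .byLabel(co[, "x"], ids, n, mean),
                      area = as.integer(tabulate(ids, nbins = n)),
                      distSurface = .byLabel(dmap[pos], ids, n, min))
    for (nm in names(channels))
        out[[paste0("mean_", nm)]] <- .byLabel(channels[[nm]][pos], ids, n, mean)
    out
}

.emptyTruthBits <- function(H, W) {
    list(mito = data.frame(label = integer(0), y = numeric(0),
                           x = numeric(0), radius = numeric(0)),
         empty = matrix(FALSE, H, W),
         emptyField = matrix(numeric(0), 0, 0))
}

#' Generate an x-y disc-section phantom
#'
#' Elliptical tissue with a rim band (Euclidean-distance rule, matching
#' the segmentation module) in which the mark is enriched by the factor
#' \code{enrichmentR}. The mark field is proportional to the DAPI field
#' (nuclear marks scale with chromatin content), so the DAPI-normalized
#' rim/centre ratio equals R exactly by construction. A reporter channel
#' fills \code{reporterFraction} of the tissue from one side.
#'
#' @param spec a \linkS4class{PhantomSpec} with geometry
#'   \code{"disc_xy"}.
#' @return list(stack = \linkS4class{ImageStack},
#'   truth = \linkS4class{PhantomTruth}).
#' @export
makeDiscPhantom <- function(spec) {
    stopifnot(is(spec, "PhantomSpec"))
    if (spec@geometry != "disc_xy")
        .stopInput("spec geometry must be 'disc_xy'")
    methods::validObject(spec)
    H <- spec@shape[1L]; W <- spec@shape[2L]
    withr::with_seed(spec@seed, {
        tissue <- .ellipseMask(H, W, (H + 1) / 2, (W + 1) / 2,
                               H / 2 - 8, W / 2 - 8)
        d <- .distToBackground(tissue)
        rim <- tissue & d <= spec@rimWidthTrue
        enrich <- matrix(1, H, W)
        enrich[rim] <- spec@enrichmentR

        dapi <- .DISC_DAPI_BASE * tissue
        nucLab <- matrix(0L, H, W)
        if (spec@nNuclei > 0L) {
            allowed <- tissue & d > spec@nucleusRadius + 1
            centres <- .hardCorePlace(spec@nNuclei, allowed,
                                      2 * spec@nucleusRadius + 2)
            nucLab <- .renderObjects(H, W, centres, spec@nucleusRadius)
            dapi[nucLab > 0L] <- .DISC_DAPI_NUCLEUS
        }
        mark <- .DISC_MARK_SCALE * enrich * dapi

        positive <- matrix(FALSE, H, W)
        if (spec@reporterFraction > 0) {
            xs <- .maskCoords(tissue)[, "x"]
            cut <- stats::quantile(xs, 1 - spec@reporterFraction,
                                   names = FALSE, type = 1)
            xcol <- matrix(seq_len(W), H, W, byrow = TRUE)
            positive <- tissue & xcol >= cut
        }
        reporter <- .DISC_REPORTER_LEVEL * positive

        bits <- .emptyTruthBits(H, W)
        mitoLab <- matrix(0L, H, W)
        mitoTruth <- bits$mito
        channels <- list(dapi = dapi, mark = mark, reporter = reporter)
        if (spec@nMito > 0L) {
            mc <- .hardCorePlace(spec@nMito, tissue & nucLab == 0L, 4)
            mitoLab <- .renderObjects(H, W, mc, 1)
            mitoLab[nucLab > 0L] <- 0L
            channels$mito <- .MITO_LEVEL * (mitoLab > 0L)
            mitoTruth <- data.frame(label = seq_len(spec@nMito),
                                    y = mc[, "y"], x = mc[, "x"], radius = 1)
        }
        nucTruth <- .nucleusTruth(nucLab, tissue, spec@pixelSizeXY,
                                  channels[c("dapi", "mark")])

        pl <- lapply(channels, .toStackArray, spec = spec)
        roles <- c(dapi = "dapi", mark = "mark", reporter = "reporter",
                   mito = "mito")[names(pl)]
        stack <- new("ImageStack", planes = pl, channelRoles = roles,
                     pixelSizeXY = spec@pixelSizeXY,
                     pixelSizeZ = spec@pixelSizeZ,
                     discId = sprintf("phantom_disc_seed%d", spec@seed))
        truth <- new("PhantomTruth", tissueMask = tissue, rimMask = rim,
                     nuclei = nucTruth, mito = mitoTruth,
                     trueRatio = spec@enrichmentR, positiveMask = positive,
                     negativeMask = tissue & !positive,
                     sensorField = bits$emptyField, spec = spec)
        list(stack = stack, truth = truth)
    })
}

.depthProfileFun <- function(profile) {
    hi <- if (is.null(profile$hi)) 200 else profile$hi
    lo <- if (is.null(profile$lo)) 20 else profile$lo
    switch(profile$type,
        exp = function(d) lo + (hi - lo) * exp(-d / profile$tau),
        linear = function(d) pmax(lo, hi - profile$slope * d),
        step = function(d) ifelse(d < profile$edge, hi, lo),
        constant = function(d) rep(hi, length(d)),
        .stopInput("unknown depth profile type '%s'", profile$type))
}

#' Generate a cross-section phantom
#'
#' A band-shaped epithelium with nuclei whose most outward-facing pixel
#' sits at the requested surface distances (quantized to the pixel grid)
#' and whose true mark mean follows the configured depth profile.
#' Mitochondria are scattered as small labelled objects at known
#' positions.
#'
#' @param spec a \linkS4class{PhantomSpec} with geometry
#'   \code{"cross_section"}; \code{targetDepths} (micrometres) are
#'   recycled to \code{nNuclei}.
#' @return list(stack, truth) as in \code{\link{makeDiscPhantom}}.
#' @export
makeCrossSectionPhantom <- function(spec) {
    stopifnot(is(spec, "PhantomSpec"))
    if (spec@geometry != "cross_section")
        .stopInput("spec geometry must be 'cross_section'")
    methods::validObject(spec)
    H <- spec@shape[1L]; W <- spec@shape[2L]
    px <- spec@pixelSizeXY
    r <- spec@nucleusRadius
    depths <- rep_len(spec@targetDepths, spec@nNuclei)
    withr::with_seed(spec@seed, {
        bandTop <- 7L
        bandBottom <- H - 12L
        bandLeft <- 7L
        bandRight <- W - 6L
        tissue <- matrix(FALSE, H, W)
        tissue[bandTop:bandBottom, bandLeft:bandRight] <- TRUE

        kPx <- round(depths / px)          # surface distance in pixels
        if (any(kPx < 1))
            .stopInput("target depths must be >= one pixel")
        maxK <- max(kPx)
        lowest <- bandTop + maxK - 1L + 2 * r
        if (bandBottom - lowest + 1 <= maxK)
            .stopInput("band too thin for the requested depths")
        ## keep every nucleus pixel farther from the side edges than the
        ## deepest requested top distance, so the top surface is nearest
        xLo <- bandLeft + maxK + ceiling(r)
        xHi <- bandRight - maxK - ceiling(r)
        if (spec@nNuclei > 0L) {
            xs <- round(seq(xLo, xHi, length.out = max(spec@nNuclei, 2L)))
            xs <- xs[seq_len(spec@nNuclei)]
            if (spec@nNuclei > 1L && min(diff(sort(xs))) <= 2 * r + 1)
                .stopInput("cannot place %d non-overlapping nuclei in width %d",
                           spec@nNuclei, W)
        } else xs <- integer(0)

        nucLab <- matrix(0L, H, W)
        prof <- .depthProfileFun(spec@depthProfile)
        dapi <- .XS_DAPI_BASE * tissue
        mark <- .XS_MARK_BASE * tissue
        for (i in seq_len(spec@nNuclei)) {
            topRow <- bandTop + kPx[i] - 1L     # EDT there = kPx[i] px
            disk <- .diskMask(H, W, topRow + r, xs[i], r)
            nucLab[disk] <- i
            dapi[disk] <- .XS_DAPI_NUCLEUS
            mark[disk] <- prof(kPx[i] * px)
        }

        channels <- list(dapi = dapi, mark = mark)
        bits <- .emptyTruthBits(H, W)
        mitoLab <- matrix(0L, H, W)
        mitoTruth <- bits$mito
        if (spec@nMito > 0L) {
            mc <- .hardCorePlace(spec@nMito, tissue & nucLab == 0L, 4)
            mitoLab <- .renderObjects(H, W, mc, 1)
            mitoLab[nucLab > 0L] <- 0L
            channels$mito <- .MITO_LEVEL * (mitoLab > 0L)
            mitoTruth <- data.frame(label = seq_len(spec@nMito),
                                    y = mc[, "y"], x = mc[, "x"], radius = 1)
        }
        nucTruth <- .nucleusTruth(nucLab, tissue, px,
                                  channels[c("dapi", "mark")])
        nucTruth$requestedDepth <- depths[nucTruth$label]

        pl <- lapply(channels, .toStackArray, spec = spec)
        roles <- c(dapi = "dapi", mark = "mark", mito = "mito")[names(pl)]
        stack <- new("ImageStack", planes = pl, channelRoles = roles,
                     pixelSizeXY = px, pixelSizeZ = spec@pixelSizeZ,
                     discId = sprintf("phantom_xsection_seed%d", spec@seed))
        d <- .distToBackground(tissue)
        truth <- new("PhantomTruth", tissueMask = tissue,
                     rimMask = tissue & d <= spec@rimWidthTrue,
                     nuclei = nucTruth, mito = mitoTruth,
                     trueRatio = spec@enrichmentR,
                     positiveMask = bits$empty, negativeMask = tissue,
                     sensorField = bits$emptyField, spec = spec)
        list(stack = stack, truth = truth)
    })
}

#' Generate a dual-excitation sensor phantom
#'
#' The 405 nm excitation channel is a smooth positive dome over the
#' tissue; the 488 nm channel is the 405 channel multiplied by the true
#' ratio field (uniform, or stepping up by \code{factor} in the rim
#' band). A uniform DAPI channel supports tissue segmentation.
#'
#' @param spec a \linkS4class{PhantomSpec} with geometry \code{"sensor"}.
#' @return list(stack, truth); \code{truth@sensorField} holds the true
#'   ratio field (NA outside the tissue).
#' @export
makeSensorPhantom <- function(spec) {
    stopifnot(is(spec, "PhantomSpec"))
    if (spec@geometry != "sensor")
        .stopInput("spec geometry must be 'sensor'")
    methods::validObject(spec)
    sf <- spec@sensorField
    if (is.null(sf$base) || sf$base <= 0)
        .stopInput("sensor ratio field must be positive")
    H <- spec@shape[1L]; W <- spec@shape[2L]
    withr::with_seed(spec@seed, {
        cy <- (H + 1) / 2; cx <- (W + 1) / 2
        tissue <- .ellipseMask(H, W, cy, cx, H / 2 - 8, W / 2 - 8)
        d <- .distToBackground(tissue)
        rim <- tissue & d <= spec@rimWidthTrue

        y <- matrix(seq_len(H), H, W)
        x <- matrix(seq_len(W), H, W, byrow = TRUE)
        dome <- exp(-(((y - cy) / (0.7 * H))^2 + ((x - cx) / (0.7 * W))^2))
        ex405 <- .SENSOR_EX405_PEAK * (0.25 + 0.75 * dome) * tissue

        field <- matrix(NA_real_, H, W)
        if (identical(sf$type, "uniform")) {
            field[tissue] <- sf$base
        } else if (identical(sf$type, "rim_step")) {
            if (is.null(sf$factor) || sf$factor <= 0)
                .stopInput("sensor ratio field must be positive")
            field[tissue] <- sf$base
            field[rim] <- sf$base * sf$factor
        } else .stopInput("unknown sensor field type '%s'", sf$type)

        ex488 <- ex405
        ex488[tissue] <- ex405[tissue] * field[tissue]
        channels <- list(dapi = .DISC_DAPI_BASE * tissue,
                         sensor405 = ex405, sensor488 = ex488)
        pl <- lapply(channels, .toStackArray, spec = spec)
        roles <- c(dapi = "dapi", sensor405 = "sensor405",
                   sensor488 = "sensor488")
        stack <- new("ImageStack", planes = pl, channelRoles = roles,
                     pixelSizeXY = spec@pixelSizeXY,
                     pixelSizeZ = spec@pixelSizeZ,
                     discId = sprintf("phantom_sensor_seed%d", spec@seed))
        bits <- .emptyTruthBits(H, W)
        truth <- new("PhantomTruth", tissueMask = tissue, rimMask = rim,
                     nuclei = data.frame(), mito = bits$mito,
                     trueRatio = if (identical(sf$type, "rim_step"))
                         sf$factor else 1,
                     positiveMask = bits$empty, negativeMask = tissue,
                     sensorField = field, spec = spec)
        list(stack = stack, truth = truth)
    })
}

#' Generate a phantom from any spec
#'
#' Dispatches on the spec's geometry.
#'
#' @param spec a \linkS4class{PhantomSpec}.
#' @return list(stack, truth).
#' @export
makePhantom <- function(spec) {
    switch(spec@geometry,
           disc_xy = makeDiscPhantom(spec),
           cross_section = makeCrossSectionPhantom(spec),
           sensor = makeSensorPhantom(spec))
}
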