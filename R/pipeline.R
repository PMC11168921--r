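#' Run the full analysis pipeline from one configuration
#'
#' Orchestrates simulate/load -> segment -> quantify (-> statistics) and
#' writes all tabular outputs plus a JSON run manifest. Configuration is
#' a named list (or a path to a JSON file with the same fields):
#'
#' \describe{
#'   \item{input}{either \code{list(phantom = "xy"|"cross"|"sensor",
#'     n = <discs>, overrides = list(...))} or
#'     \code{list(paths = <tiff paths>, channelRoles = ..., pixelSizeXY =
#'     ..., pixelSizeZ = ...)}.}
#'   \item{analysis}{character vector out of \code{"ratio"},
#'     \code{"compartments"}, \code{"nuclei"}, \code{"sensor"},
#'     \code{"project"}.}
#'   \item{rimWidthPx}{rim width in px (default 10; TMRM preset uses 13).}
#'   \item{reference}{normalization role (default \code{"dapi"}).}
#'   \item{mark}{mark role (default \code{"mark"}).}
#'   \item{binEdges}{distance bin edges in micrometres (default c(5, 10)).}
#'   \item{seed}{base seed for simulated inputs.}
#' }
#'
#' Configuration problems abort before any computation or output
#' (fail-fast); re-running an identical config reproduces all
#' deterministic outputs.
#'
#' @param config named list or JSON path.
#' @param outDir output directory (created if needed).
#' @return the manifest, invisibly (also written to
#'   \code{manifest.json}).
#' @export
runPipeline <- function(config, outDir) {
    if (is.character(config) && length(config) == 1L)
        config <- jsonlite::read_json(config, simplifyVector = TRUE)
    config <- .validateConfig(config)
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)

    stacks <- .pipelineInputs(config)
    ratios <- list(); nuclei <- list(); sensors <- list(); projections <- list()
    for (st in stacks) {
        id <- discId(st)
        .log("pipeline: disc '%s'", id)
        res <- .analyseDisc(st, config)
        if (!is.null(res$ratio)) ratios[[id]] <- res$ratio
        if (!is.null(res$nuclei)) nuclei[[id]] <- res$nuclei
        if (!is.null(res$sensor)) sensors[[id]] <- res$sensor
        if (!is.null(res$project)) projections[[id]] <- res$project
    }
    outputs <- character(0)
    writeTab <- function(lst, name) {
        if (!length(lst)) return(invisible(NULL))
        path <- file.path(outDir, name)
        writeRecords(do.call(rbind, c(lst, list(make.row.names = FALSE))),
                     path)
        outputs <<- c(outputs, name)
    }
    writeTab(ratios, "ratios.csv")
    writeTab(nuclei, "nuclei.csv")
    writeTab(sensors, "sensor.csv")
    writeTab(projections, "projections.csv")

    manifest <- list(
        package = "discRim",
        version = as.character(utils::packageVersion("discRim")),
        config = config,
        n_discs = length(stacks),
        outputs = as.list(outputs))
    jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    invisible(manifest)
}

.validateConfig <- function(config) {
    if (!is.list(config) || is.null(config$input))
        .stopConfig("config must be a list with an 'input' entry")
    defaults <- list(analysis = c("ratio"), rimWidthPx = 10,
                     reference = "dapi", mark = "mark",
                     binEdges = c(5, 10), seed = 1L,
                     tissueChannel = "dapi", floor = NULL)
    config <- utils::modifyList(defaults, config)
    bad <- setdiff(config$analysis,
                   c("ratio", "compartments", "nuclei", "sensor", "project"))
    if (length(bad))
        .stopConfig("unknown analysis step(s): %s", paste(bad, collapse = ", "))
    if (config$rimWidthPx < 0) .stopConfig("rimWidthPx must be >= 0")
    if (length(config$binEdges) != 2L || diff(config$binEdges) <= 0)
        .stopConfig("binEdges must be two increasing values")
    inp <- config$input
    roles <- NULL
    if (!is.null(inp$phantom)) {
        if (!inp$phantom %in% c("xy", "cross", "sensor"))
            .stopConfig("input$phantom must be 'xy', 'cross' or 'sensor'")
        roles <- switch(inp$phantom,
                        xy = c("dapi", "mark", "reporter"),
                        cross = c("dapi", "mark", "mito"),
                        sensor = c("dapi", "sensor405", "sensor488"))
    } else if (!is.null(inp$paths)) {
        if (is.null(inp$channelRoles))
            .stopConfig("file input requires channelRoles")
        roles <- unname(unlist(inp$channelRoles))
    } else .stopConfig("input needs either 'phantom' or 'paths'")
    need <- c(
        if ("ratio" %in% config$analysis) c(config$mark, config$reference),
        if ("compartments" %in% config$analysis) "reporter",
        if ("nuclei" %in% config$analysis) "dapi",
        if ("sensor" %in% config$analysis) c("sensor405", "sensor488"))
    miss <- setdiff(unique(need), roles)
    if (length(miss))
        .stopConfig("analysis needs channel role(s) not in the input: %s",
                    paste(miss, collapse = ", "))
    config
}

.pipelineInputs <- function(config) {
    inp <- config$input
    if (!is.null(inp$phantom)) {
        n <- if (is.null(inp$n)) 1L else as.integer(inp$n)
        geometry <- switch(inp$phantom, xy = "disc_xy",
                           cross = "cross_section", sensor = "sensor")
        ov <- if (is.null(inp$overrides)) list() else inp$overrides
        lapply(seq_len(n), function(i) {
            sp <- do.call(phantomSpec,
                          c(list(geometry = geometry,
                                 seed = as.integer(config$seed) + i - 1L), ov))
            makePhantom(sp)$stack
        })
    } else {
        lapply(seq_along(inp$paths), function(i) {
            readStack(inp$paths[[i]],
                      channelRoles = unlist(inp$channelRoles),
                      pixelSizeXY = inp$pixelSizeXY,
                      pixelSizeZ = inp$pixelSizeZ)
        })
    }
}

.analyseDisc <- function(st, config) {
    out <- list()
    ref <- getPlane(st, config$tissueChannel)
    tissue <- segmentTissue(ref)
    part <- partitionRimCentre(tissue, widthPx = config$rimWidthPx)

    if ("ratio" %in% config$analysis || "compartments" %in% config$analysis) {
        mark <- getPlane(st, config$mark)
        refPlane <- getPlane(st, config$reference)
        rows <- list()
        if ("ratio" %in% config$analysis)
            rows$whole <- rimCentreRatio(mark, refPlane, part,
                                         discId = discId(st),
                                         markRole = config$mark,
                                         referenceRole = config$reference)
        if ("compartments" %in% config$analysis) {
            comp <- segmentReporterRegion(getPlane(st, "reporter"), tissue)
            rows$comp <- compartmentRatioPair(mark, refPlane, part, comp,
                                              discId = discId(st),
                                              markRole = config$mark,
                                              referenceRole = config$reference)
        }
        out$ratio <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
    }
    if ("nuclei" %in% config$analysis) {
        dapi <- getPlane(st, "dapi")
        nuc <- segmentNuclei(dapi, within = tissue)
        chans <- list()
        for (ch in names(planes(st)))
            chans[[ch]] <- getPlane(st, ch)
        rec <- measureNuclei(nuc, chans, discId = discId(st))
        rec <- annotateSurfaceDistance(rec, nuc, tissue)
        if ("mito" %in% channelRoles(st)) {
            mito <- segmentNuclei(getPlane(st, "mito"), smoothingSigma = 0,
                                  minArea = 1, split = FALSE,
                                  within = tissue)
            mito <- labelImageFromMatrix(labelMatrix(mito), "mitochondria",
                                         pixelSizeXY(st))
            rec <- annotateMitoDistance(rec, nuc, mito)
        }
        if (nrow(rec) && "mark" %in% names(planes(st)))
            rec <- tryCatch(
                binAndNormalize(rec, "mark", edges = config$binEdges),
                discRim_input_error = function(e) {
                    warning(conditionMessage(e)); rec
                })
        out$nuclei <- rec
    }
    if ("sensor" %in% config$analysis) {
        map <- ratiometricMap(getPlane(st, "sensor488"),
                              getPlane(st, "sensor405"), tissue,
                              floor = config$floor)
        out$sensor <- data.frame(
            disc_id = discId(st),
            valid_px = sum(map@validity),
            mean_ratio = mean(map@values[map@validity]),
            rim_centre_ratio = ratioMapRimCentre(map, part),
            width_px = config$rimWidthPx, stringsAsFactors = FALSE)
    }
    if ("project" %in% config$analysis) {
        out$project <- data.frame(
            disc_id = discId(st),
            ratio = projectedIntensityRatio(st, config$reference,
                                            config$mark),
            stringsAsFactors = FALSE)
    }
    out
}
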