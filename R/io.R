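#' Read a calibrated multi-channel image stack from TIFF
#'
#' Reads a grayscale (OME-)TIFF whose frames hold the z planes of each
#' channel in channel-major order (all z of channel 1, then channel 2,
#' ...). A JSON sidecar written by \code{\link{writeStack}} (same path
#' plus \code{".json"}) supplies channel roles and calibration when
#' present; Fiji-style resolution tags are honoured otherwise. Explicitly
#' supplied arguments always win, with a logged warning when they
#' override file metadata.
#'
#' @param path TIFF file path.
#' @param channelRoles named character vector, channel name -> role; may be
#'   omitted when a sidecar provides it.
#' @param pixelSizeXY,pixelSizeZ calibration in micrometres; may be omitted
#'   when the file (sidecar or TIFF tags) provides it.
#' @param discId identifier; defaults to the file name.
#' @return an \linkS4class{ImageStack}.
#' @export
readStack <- function(path, channelRoles = NULL, pixelSizeXY = NULL,
                      pixelSizeZ = NULL, discId = NULL) {
    if (!file.exists(path)) .stopIO("cannot read '%s': no such file", path)
    frames <- tryCatch(tiff::readTIFF(path, all = TRUE, info = TRUE),
                       error = function(e) .stopIO("cannot read '%s': %s",
                                                   path, conditionMessage(e)))
    if (!is.list(frames)) frames <- list(frames)
    info <- attributes(frames[[1L]])
    if (!is.null(info$bits.per.sample) && info$bits.per.sample < 32L) {
        ## integer samples: take the raw counts
        frames <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
        if (!is.list(frames)) frames <- list(frames)
    }

    side <- paste0(path, ".json")
    meta <- if (file.exists(side)) jsonlite::read_json(side) else NULL

    if (is.null(channelRoles) && !is.null(meta))
        channelRoles <- unlist(meta$channel_roles)
    if (is.null(channelRoles))
        .stopConfig("channelRoles not given and no sidecar for '%s'", path)

    filePx <- NULL
    if (!is.null(meta)) {
        filePx <- c(meta$pixel_size_xy, meta$pixel_size_z)
    } else if (!is.null(info$x.resolution) && info$x.resolution > 0) {
        ## TIFF resolution is pixels per unit; unit "cm" -> um/px
        unit <- if (is.null(info$resolution.unit)) "inch" else info$resolution.unit
        perUm <- switch(unit,
                        cm = info$x.resolution / 1e4,
                        inch = info$x.resolution / 25400,
                        info$x.resolution)
        filePx <- c(1 / perUm, NA_real_)
    }
    if (is.null(pixelSizeXY)) {
        if (is.null(filePx) || !is.finite(filePx[1L]))
            .stopConfig("pixelSizeXY missing: not in '%s' and not supplied", path)
        pixelSizeXY <- filePx[1L]
    } else if (!is.null(filePx) && is.finite(filePx[1L]) &&
               abs(filePx[1L] - pixelSizeXY) > 1e-9) {
        warning(sprintf(
            "overriding file calibration %.6g um/px with supplied %.6g um/px",
            filePx[1L], pixelSizeXY))
    }
    if (is.null(pixelSizeZ))
        pixelSizeZ <- if (!is.null(filePx) && length(filePx) > 1L &&
                          is.finite(filePx[2L])) filePx[2L] else pixelSizeXY

    nC <- length(channelRoles)
    nF <- length(frames)
    if (nF %% nC != 0L)
        .stopConfig("file '%s' has %d frame(s), not divisible by %d declared channel(s)",
                    path, nF, nC)
    nz <- nF %/% nC
    if (!is.null(meta) && !is.null(meta$n_channels) &&
        meta$n_channels != nC)
        .stopConfig("channel-count mismatch for '%s': file has %d, %d declared",
                    path, meta$n_channels, nC)

    ## our own float files are scaled by 1/65536 (recorded in the
    ## sidecar); third-party float TIFFs carry raw intensities
    scale <- if (!is.null(meta) && !is.null(meta$intensity_scale))
        meta$intensity_scale
    else if (!is.null(info$bits.per.sample) && info$bits.per.sample < 32L)
        1
    else 1
    pl <- vector("list", nC)
    names(pl) <- names(channelRoles)
    for (ci in seq_len(nC)) {
        fs <- frames[((ci - 1L) * nz + 1L):(ci * nz)]
        a <- array(0, dim = c(nz, nrow(fs[[1L]]), ncol(fs[[1L]])))
        for (zi in seq_len(nz)) a[zi, , ] <- fs[[zi]] * scale
        pl[[ci]] <- a
    }
    if (is.null(discId)) discId <- sub("\\.[^.]+$", "", basename(path))
    new("ImageStack", planes = pl, channelRoles = channelRoles,
        pixelSizeXY = as.numeric(pixelSizeXY),
        pixelSizeZ = as.numeric(pixelSizeZ), discId = discId)
}

#' Write an ImageStack to TIFF (plus JSON sidecar)
#'
#' Frames are written channel-major (all z planes of the first channel,
#' then the second, ...). The default 16-bit mode stores integer
#' detector counts exactly (values are rounded and must fit 0..65535);
#' 32-bit mode stores values scaled by 1/65536 at a quantization step of
#' 65536/2^32 = 1.5e-5 intensity units, for non-integer data. The
#' sidecar (\code{<path>.json}) records channel roles, calibration,
#' intensity scale and disc id, so \code{\link{readStack}} restores the
#' stack without arguments.
#'
#' @param stack an \linkS4class{ImageStack}.
#' @param path output TIFF path.
#' @param bits 16 (integer counts, default) or 32 (scaled high-range).
#' @return \code{path}, invisibly.
#' @export
writeStack <- function(stack, path, bits = 16L) {
    stopifnot(is(stack, "ImageStack"), bits %in% c(16L, 32L))
    frames <- list()
    for (ch in names(planes(stack))) {
        a <- planes(stack)[[ch]]
        if (bits == 16L && max(a) > 65535)
            .stopIO("channel '%s' exceeds the 16-bit range; use bits = 32",
                    ch)
        for (zi in seq_len(dim(a)[1L])) {
            m <- a[zi, , ]
            frames[[length(frames) + 1L]] <-
                if (bits == 32L) m / 65536 + 2^-33 else round(m) / 65535
        }
    }
    ok <- tryCatch(tiff::writeTIFF(frames, path,
                                   bits.per.sample = as.integer(bits)),
                   error = function(e) .stopIO("cannot write '%s': %s", path,
                                               conditionMessage(e)))
    meta <- list(channel_roles = as.list(channelRoles(stack)),
                 n_channels = length(planes(stack)),
                 n_z = dim(planes(stack)[[1L]])[1L],
                 pixel_size_xy = pixelSizeXY(stack),
                 pixel_size_z = pixelSizeZ(stack),
                 intensity_scale = if (bits == 32L) 65536 else 1,
                 disc_id = discId(stack))
    jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA)
    invisible(path)
}

#' Extract one z plane or channel plane from a stack
#'
#' @param stack an \linkS4class{ImageStack}.
#' @param channel channel name, or a role (matched against
#'   \code{channelRoles} when no channel has that name).
#' @param z plane index (default 1).
#' @return a \linkS4class{Plane}.
#' @export
getPlane <- function(stack, channel, z = 1L) {
    ch <- .resolveChannel(stack, channel)
    a <- planes(stack)[[ch]]
    if (z < 1L || z > dim(a)[1L])
        .stopConfig("z = %d out of range (stack has %d plane(s))", z,
                    dim(a)[1L])
    .newPlane(a[z, , ], pixelSizeXY(stack),
              sprintf("%s/%s z=%d", discId(stack), ch, z))
}

.resolveChannel <- function(stack, channel) {
    if (channel %in% names(planes(stack))) return(channel)
    hit <- names(channelRoles(stack))[channelRoles(stack) == channel]
    hit <- intersect(hit, names(planes(stack)))
    if (length(hit) == 1L) return(hit)
    .stopConfig("unknown channel '%s' (have: %s)", channel,
                paste(names(planes(stack)), collapse = ", "))
}

#' Sum-intensity projection of one channel
#'
#' Each output pixel is the sum over z of the channel at that (y, x);
#' total intensity is conserved exactly for integer inputs.
#'
#' @param stack an \linkS4class{ImageStack}.
#' @param channel channel name or role.
#' @return a \linkS4class{Plane}.
#' @export
sumProjection <- function(stack, channel) {
    ch <- .resolveChannel(stack, channel)
    a <- planes(stack)[[ch]]
    .newPlane(apply(a, c(2L, 3L), sum), pixelSizeXY(stack),
              sprintf("%s/%s sumproj", discId(stack), ch))
}

#' Write / read result tables as CSV
#'
#' Plain CSV with a header and stable column order; reading back
#' reproduces the records up to textual precision. Used for nucleus
#' records and ratio results alike.
#'
#' @param records a data.frame (nucleus records or ratio results).
#' @param path output CSV path.
#' @return \code{path} invisibly (write) or a data.frame (read).
#' @export
writeRecords <- function(records, path) {
    stopifnot(is.data.frame(records))
    ok <- tryCatch(utils::write.csv(records, path, row.names = FALSE),
                   error = function(e) .stopIO("cannot write '%s': %s", path,
                                               conditionMessage(e)))
    invisible(path)
}

#' @rdname writeRecords
#' @export
readRecords <- function(path) {
    if (!file.exists(path)) .stopIO("cannot read '%s': no such file", path)
    utils::read.csv(path, stringsAsFactors = FALSE)
}
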