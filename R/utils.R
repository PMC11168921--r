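## internal helpers shared across modules

.log <- function(fmt, ...) {
    if (isTRUE(getOption("discRim.verbose", TRUE)))
        message(sprintf(fmt, ...))
    invisible(NULL)
}

.stopConfig <- function(fmt, ...) {
    stop(errorCondition(sprintf(fmt, ...),
                        class = c("discRim_config_error", "error")))
}

.stopIO <- function(fmt, ...) {
    stop(errorCondition(sprintf(fmt, ...),
                        class = c("discRim_io_error", "error")))
}

.stopSegmentation <- function(fmt, ...) {
    stop(errorCondition(sprintf(fmt, ...),
                        class = c("discRim_segmentation_error", "error")))
}

.stopMeasurement <- function(fmt, ...) {
    stop(errorCondition(sprintf(fmt, ...),
                        class = c("discRim_measurement_error", "error")))
}

.stopInput <- function(fmt, ...) {
    stop(errorCondition(sprintf(fmt, ...),
                        class = c("discRim_input_error", "error")))
}

.newPlane <- function(values, pixelSizeXY, provenance = "unknown") {
    storage.mode(values) <- "double"
    new("Plane", values = values, pixelSizeXY = as.numeric(pixelSizeXY),
        provenance = provenance)
}

.asMatrix <- function(x) {
    ## EBImage ops return Image objects; back to a plain base matrix
    m <- as.matrix(x)
    dim(m) <- dim(x)[1:2]
    m
}

.checkCongruent <- function(a, b, what = "inputs") {
    if (!identical(dim(a), dim(b)))
        .stopConfig("%s must be congruent (got %s vs %s)", what,
                    paste(dim(a), collapse = "x"),
                    paste(dim(b), collapse = "x"))
    invisible(TRUE)
}

## Euclidean distance (px) of every foreground pixel to the nearest
## background pixel; background pixels carry 0. The image border is not
## treated as background.
.distToBackground <- function(mask) {
    storage.mode(mask) <- "double"
    d <- .asMatrix(EBImage::distmap(mask, metric = "euclidean"))
    d[!mask] <- 0
    d
}

## per-label summary in label order 1..n (factor levels pinned so labels
## >= 10 don't get string-sorted)
.byLabel <- function(values, ids, n, fun) {
    as.numeric(tapply(values, factor(ids, levels = seq_len(n)), fun))
}

## pixel coordinates (y, x) of the TRUE entries of a mask
.maskCoords <- function(mask) {
    idx <- which(mask)
    cbind(y = ((idx - 1L) %% nrow(mask)) + 1L,
          x = ((idx - 1L) %/% nrow(mask)) + 1L)
}
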