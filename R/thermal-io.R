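#' @include AllClasses.R
NULL

.frameIndex <- function(files) {
    idx <- suppressWarnings(as.numeric(gsub("\\D", "", basename(files))))
    if (anyNA(idx)) order(basename(files)) else order(idx)
}

.seqMeta <- function(seq) {
    list(frameInterval = frameInterval(seq), subjectId = subjectId(seq),
         label = subjectLabel(seq), noiseSigma = seq@noiseSigma,
         shape = dim(frames(seq))[2:3], nFrames = nFrames(seq))
}

.writeMeta <- function(meta, dir) {
    jsonlite::write_json(meta, file.path(dir, "sequence.json"),
                         auto_unbox = TRUE, digits = NA)
}

.readMeta <- function(dir) {
    f <- file.path(dir, "sequence.json")
    if (file.exists(f)) jsonlite::read_json(f, simplifyVector = TRUE)
    else list(frameInterval = 15, subjectId = basename(dir),
              label = "unknown", noiseSigma = 0)
}

#' Write a thermal sequence to disk
#'
#' Supported dialects: \describe{
#'   \item{\code{bin}}{raw little-endian float64 frames plus a JSON header --
#'     exactly lossless.}
#'   \item{\code{txt_matrix}}{one whitespace-delimited text matrix per frame
#'     (\code{frame_001.txt}, ...), full \code{\%.17g} precision -- lossless;
#'     this is the dialect of public infrared screening archives.}
#'   \item{\code{tiff}}{one multi-page 16-bit TIFF; temperatures are affinely
#'     mapped to [0, 1] over the sequence range recorded in the JSON
#'     sidecar. Quantization is ~range/65535 (about 1.5 mK for a 100 degC
#'     span), below the 0.04 degC sensor noise but not bit-exact.}
#'   \item{\code{png_stack}}{numbered 8-bit PNGs, same affine mapping
#'     (coarser quantization, ~range/255; preview quality).}
#' }
#' A \code{sequence.json} sidecar always stores metadata (interval, label,
#' noise, and the affine range for the quantized dialects).
#'
#' @param seq a \linkS4class{ThermalSequence}.
#' @param dir output directory (created if needed).
#' @param dialect one of \code{"bin"}, \code{"txt_matrix"}, \code{"tiff"},
#'   \code{"png_stack"}.
#' @return \code{dir}, invisibly.
#' @export
writeSequence <- function(seq, dir,
                          dialect = c("bin", "txt_matrix", "tiff",
                                      "png_stack")) {
    dialect <- match.arg(dialect)
    stopifnot(is(seq, "ThermalSequence"))
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    fr <- frames(seq)
    meta <- .seqMeta(seq)
    meta$dialect <- dialect
    tau <- dim(fr)[1L]
    if (dialect %in% c("tiff", "png_stack")) {
        lo <- min(fr); hi <- max(fr)
        if (hi <= lo) hi <- lo + 1
        meta$range <- c(lo, hi)
        norm <- (fr - lo) / (hi - lo)
    }
    switch(dialect,
        bin = {
            con <- file(file.path(dir, "frames.bin"), "wb")
            on.exit(close(con))
            ## frame-major, row-major within frame
            for (f in seq_len(tau))
                writeBin(as.vector(t(fr[f, , ])), con, size = 8,
                         endian = "little")
        },
        txt_matrix = {
            for (f in seq_len(tau)) {
                m <- fr[f, , ]
                utils::write.table(
                    matrix(sprintf("%.17g", m), nrow(m), ncol(m)),
                    file.path(dir, sprintf("frame_%03d.txt", f)),
                    row.names = FALSE, col.names = FALSE, quote = FALSE)
            }
        },
        tiff = {
            pages <- lapply(seq_len(tau), function(f) norm[f, , ])
            tiff::writeTIFF(pages, file.path(dir, "frames.tiff"),
                            bits.per.sample = 16L)
        },
        png_stack = {
            for (f in seq_len(tau))
                png::writePNG(norm[f, , ],
                              file.path(dir, sprintf("frame_%03d.png", f)))
        })
    .writeMeta(meta, dir)
    invisible(dir)
}

#' Read a thermal sequence from disk
#'
#' Counterpart of \code{\link{writeSequence}}. Frames are ordered by the
#' numeric index embedded in their file names. All frames must share one
#' shape; a mismatch is an error naming the offending frame and both shapes.
#'
#' @param dir directory containing the frames (and optional
#'   \code{sequence.json} sidecar).
#' @param dialect \code{"auto"} (detect from files present) or one of
#'   \code{"bin"}, \code{"txt_matrix"}, \code{"tiff"}, \code{"png_stack"}.
#' @return A \linkS4class{ThermalSequence}.
#' @export
readSequence <- function(dir, dialect = c("auto", "bin", "txt_matrix",
                                          "tiff", "png_stack")) {
    dialect <- match.arg(dialect)
    if (!dir.exists(dir)) stop("no such directory: ", dir)
    if (dialect == "auto") {
        dialect <-
            if (file.exists(file.path(dir, "frames.bin"))) "bin"
            else if (file.exists(file.path(dir, "frames.tiff"))) "tiff"
            else if (length(Sys.glob(file.path(dir, "*.txt")))) "txt_matrix"
            else if (length(Sys.glob(file.path(dir, "*.png")))) "png_stack"
            else stop("no recognizable thermal frames in ", dir)
    }
    meta <- .readMeta(dir)
    mats <- switch(dialect,
        bin = {
            shape <- as.integer(meta$shape)
            con <- file(file.path(dir, "frames.bin"), "rb")
            on.exit(close(con))
            lapply(seq_len(meta$nFrames), function(f) {
                v <- readBin(con, "double", prod(shape), size = 8,
                             endian = "little")
                matrix(v, shape[1L], shape[2L], byrow = TRUE)
            })
        },
        txt_matrix = {
            files <- Sys.glob(file.path(dir, "*.txt"))
            if (!length(files)) stop("no .txt frames in ", dir)
            files <- files[.frameIndex(files)]
            lapply(files, function(f)
                as.matrix(utils::read.table(f, header = FALSE)))
        },
        tiff = {
            pages <- tiff::readTIFF(file.path(dir, "frames.tiff"),
                                    all = TRUE)
            rg <- as.numeric(meta$range %||% c(0, 1))
            lapply(pages, function(p) rg[1L] + p * (rg[2L] - rg[1L]))
        },
        png_stack = {
            files <- Sys.glob(file.path(dir, "*.png"))
            if (!length(files)) stop("no .png frames in ", dir)
            files <- files[.frameIndex(files)]
            rg <- as.numeric(meta$range %||% c(0, 1))
            lapply(files, function(f) {
                p <- png::readPNG(f)
                if (length(dim(p)) == 3L) p <- p[, , 1L]
                rg[1L] + p * (rg[2L] - rg[1L])
            })
        })
    shapes <- lapply(mats, dim)
    ref <- shapes[[1L]]
    bad <- which(!vapply(shapes, identical, TRUE, ref))
    if (length(bad))
        stop(sprintf(
            "frame %d has shape %s but frame 1 has shape %s",
            bad[1L], paste(shapes[[bad[1L]]], collapse = "x"),
            paste(ref, collapse = "x")))
    mats <- lapply(mats, function(m) { dimnames(m) <- NULL; m })
    ThermalSequence(mats,
                    frameInterval = as.numeric(meta$frameInterval %||% 15),
                    subjectId = as.character(meta$subjectId %||% basename(dir)),
                    label = as.character(meta$label %||% "unknown"),
                    noiseSigma = as.numeric(meta$noiseSigma %||% 0))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Default centred square ROI for a frame shape
#'
#' @param shape integer(2) frame shape (rows, cols).
#' @param fraction side of the square as a fraction of min(shape)
#'   (default 0.75).
#' @return integer(4): row0, col0, height, width (0-based, half-open).
#' @export
centeredRoi <- function(shape, fraction = 0.75) {
    side <- max(2L, as.integer(floor(fraction * min(shape))))
    r0 <- as.integer(floor((shape[1L] - side) / 2))
    c0 <- as.integer(floor((shape[2L] - side) / 2))
    c(r0, c0, side, side)
}

#' Build the zero-mean heat matrix of a thermal sequence
#'
#' Column j of the heat matrix is the row-major vectorization of the ROI of
#' frame j; the per-pixel temporal mean is then removed (and stored), so
#' each row has zero mean and the decomposition maximizes variance across
#' acquisition time. The economy shape p > n is enforced.
#'
#' @param seq a \linkS4class{ThermalSequence}.
#' @param roi integer(4) rectangle (row0, col0, height, width), 0-based and
#'   half-open; default a centred square covering 75\% of the short side.
#' @return A \linkS4class{HeatMatrix}.
#' @examples
#' ts <- ThermalSequence(array(rnorm(5 * 12 * 12, 30), c(5, 12, 12)))
#' hm <- buildHeatMatrix(ts)
#' dim(heatValues(hm))
#' @export
buildHeatMatrix <- function(seq, roi = NULL) {
    stopifnot(is(seq, "ThermalSequence"))
    fr <- frames(seq)
    shape <- dim(fr)[2:3]
    if (is.null(roi)) roi <- centeredRoi(shape)
    roi <- as.integer(roi)
    if (length(roi) != 4L)
        stop("'roi' must be (row0, col0, height, width)")
    if (roi[1L] < 0L || roi[2L] < 0L || roi[3L] < 1L || roi[4L] < 1L ||
        roi[1L] + roi[3L] > shape[1L] || roi[2L] + roi[4L] > shape[2L])
        stop("'roi' [", paste(roi, collapse = ", "),
             "] exceeds the frame bounds ", shape[1L], " x ", shape[2L])
    n <- dim(fr)[1L]
    p <- roi[3L] * roi[4L]
    if (p <= n)
        stop(sprintf(
            "ROI has p = %d pixels for n = %d frames; the heat matrix requires p > n",
            p, n))
    rows <- roi[1L] + seq_len(roi[3L])
    cols <- roi[2L] + seq_len(roi[4L])
    X <- vapply(seq_len(n),
                function(j) as.vector(t(fr[j, rows, cols])),
                numeric(p))
    rm <- rowMeans(X)
    new("HeatMatrix", X = X - rm, rowMean = rm, roi = roi,
        sourceShape = as.integer(shape))
}

#' Undo the centering of a heat matrix
#'
#' @param hm a \linkS4class{HeatMatrix}.
#' @return The p x n matrix of original ROI temperatures (centering undone).
#' @export
uncenteredMatrix <- function(hm) {
    stopifnot(is(hm, "HeatMatrix"))
    hm@X + hm@rowMean
}

#' Reshape a heat-matrix column back to its ROI frame
#'
#' Inverts the row-major vectorization used by \code{\link{buildHeatMatrix}}.
#'
#' @param hm a \linkS4class{HeatMatrix}.
#' @param j frame (column) index.
#' @param centered return the centred values (default FALSE: original
#'   temperatures).
#' @return A height x width matrix.
#' @export
roiFrame <- function(hm, j, centered = FALSE) {
    stopifnot(is(hm, "HeatMatrix"), j >= 1L, j <= ncol(hm@X))
    v <- if (centered) hm@X[, j] else hm@X[, j] + hm@rowMean
    matrix(v, hm@roi[3L], hm@roi[4L], byrow = TRUE)
}

#' Read a per-subject ROI table
#'
#' @param path CSV with columns subjectId, row0, col0, height, width.
#' @return A data.frame keyed by subjectId.
#' @export
readRoiTable <- function(path) {
    tab <- utils::read.csv(path, stringsAsFactors = FALSE)
    need <- c("subjectId", "row0", "col0", "height", "width")
    if (!all(need %in% names(tab)))
        stop("ROI table must have columns: ", paste(need, collapse = ", "))
    tab
}
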