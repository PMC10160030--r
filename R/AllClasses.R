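#' @import methods
NULL

#' Raster geometry of a mass spectrometry imaging acquisition
#'
#' Physical pixel geometry of a DESI-MSI raster. The pixel width along the
#' scan (lateral) direction is determined by the stage kinematics: one full
#' MS scan is one pixel, so width = stage speed x cycle time per scan. The
#' pixel height is the vertical step between raster rows.
#'
#' @slot pixelWidth pixel width in micrometres (scan direction)
#' @slot pixelHeight pixel height in micrometres (step direction)
#' @slot stageSpeed lateral stage speed in micrometres per second
#'   (\code{NA_real_} when unknown, e.g. read from a file without kinematics)
#' @slot cycleTime scan cycle time in seconds (\code{NA_real_} when unknown)
#' @slot mzRange length-2 numeric, low/high end of the acquired m/z range (Th)
#'
#' @seealso [rasterGeometry()], [pixelWidthFromKinematics()]
#' @exportClass RasterGeometry
setClass("RasterGeometry",
    representation(
        pixelWidth  = "numeric",
        pixelHeight = "numeric",
        stageSpeed  = "numeric",
        cycleTime   = "numeric",
        mzRange     = "numeric"
    ),
    prototype(
        pixelWidth = 1, pixelHeight = 1,
        stageSpeed = NA_real_, cycleTime = NA_real_,
        mzRange = c(50, 1000)
    )
)

setValidity("RasterGeometry", function(object) {
    msg <- character()
    if (length(object@pixelWidth) != 1L || !is.finite(object@pixelWidth) ||
        object@pixelWidth <= 0)
        msg <- c(msg, "pixelWidth must be a single positive number")
    if (length(object@pixelHeight) != 1L || !is.finite(object@pixelHeight) ||
        object@pixelHeight <= 0)
        msg <- c(msg, "pixelHeight must be a single positive number")
    if (length(object@mzRange) != 2L || any(!is.finite(object@mzRange)) ||
        object@mzRange[1] >= object@mzRange[2])
        msg <- c(msg, "mzRange must be c(low, high) with low < high")
    sp <- object@stageSpeed; ct <- object@cycleTime
    if (!is.na(sp) && sp <= 0) msg <- c(msg, "stageSpeed must be positive")
    if (!is.na(ct) && ct <= 0) msg <- c(msg, "cycleTime must be positive")
    if (!is.na(sp) && !is.na(ct)) {
        w <- sp * ct
        if (abs(w - object@pixelWidth) > 1e-6 * object@pixelWidth)
            msg <- c(msg, sprintf(
                "pixelWidth (%.6g) inconsistent with stageSpeed * cycleTime (%.6g)",
                object@pixelWidth, w))
    }
    if (length(msg)) msg else TRUE
})

#' Construct a RasterGeometry
#'
#' If `stageSpeed` and `cycleTime` are both supplied and `pixelWidth` is not,
#' the width is computed from the kinematics.
#'
#' @param pixelWidth pixel width in um (scan direction); may be omitted when
#'   both kinematic parameters are given
#' @param pixelHeight pixel height in um (vertical step)
#' @param stageSpeed lateral stage speed in um/s (optional)
#' @param cycleTime scan cycle time in s (optional)
#' @param mzRange acquired m/z range, `c(low, high)` in Th
#' @return a [RasterGeometry-class] object
#' @examples
#' rasterGeometry(pixelHeight = 80, stageSpeed = 53.69,
#'                cycleTime = 72.6 / 53.69)
#' @export
rasterGeometry <- function(pixelWidth = NULL, pixelHeight,
                           stageSpeed = NA_real_, cycleTime = NA_real_,
                           mzRange = c(50, 1000)) {
    if (is.null(pixelWidth)) {
        if (is.na(stageSpeed) || is.na(cycleTime))
            stop("pixelWidth must be given unless both stageSpeed and ",
                 "cycleTime are supplied")
        pixelWidth <- pixelWidthFromKinematics(stageSpeed, cycleTime)
    }
    new("RasterGeometry",
        pixelWidth = as.numeric(pixelWidth),
        pixelHeight = as.numeric(pixelHeight),
        stageSpeed = as.numeric(stageSpeed),
        cycleTime = as.numeric(cycleTime),
        mzRange = as.numeric(mzRange))
}

#' In-memory mass spectrometry imaging dataset
#'
#' A dense rectangular raster of centroided pixel spectra. Pixels are indexed
#' `(row, col)` 0-based and stored row-major: row = vertical stage step,
#' col = scan (lateral) direction. This matches an acquisition where each
#' raster row is one continuous stage sweep. Empty (all-zero, off-tissue)
#' pixels are legal and are stored as zero-length spectra.
#'
#' @slot spectra row-major list of length `nRows * nCols`; each element is a
#'   `list(mz = <ascending numeric>, intensity = <non-negative numeric>)`
#' @slot nRows,nCols raster dimensions
#' @slot geometry a [RasterGeometry-class]
#' @slot metadata named character vector of free-form acquisition notes
#'   (polarity, resolution setting, ...)
#'
#' @seealso [msiDataset()], [readImzML()], [writeImzML()], [simulateRoot()]
#' @exportClass MSIDataset
setClass("MSIDataset",
    representation(
        spectra  = "list",
        nRows    = "integer",
        nCols    = "integer",
        geometry = "RasterGeometry",
        metadata = "character"
    )
)

setValidity("MSIDataset", function(object) {
    msg <- character()
    nr <- object@nRows; nc <- object@nCols
    if (length(nr) != 1L || is.na(nr) || nr < 1L)
        msg <- c(msg, "nRows must be a positive integer")
    if (length(nc) != 1L || is.na(nc) || nc < 1L)
        msg <- c(msg, "nCols must be a positive integer")
    if (!length(msg) && length(object@spectra) != nr * nc)
        msg <- c(msg, sprintf("expected %d spectra (%d x %d), found %d",
                              nr * nc, nr, nc, length(object@spectra)))
    # spot-check spectrum structure (full scan of every pixel is done at
    # construction time by msiDataset())
    if (!length(msg) && length(object@spectra)) {
        s <- object@spectra[[1L]]
        if (!is.list(s) || !all(c("mz", "intensity") %in% names(s)))
            msg <- c(msg, "spectra elements must be list(mz=, intensity=)")
    }
    if (length(msg)) msg else TRUE
})

.check_spectrum <- function(mz, intensity, where) {
    if (length(mz) != length(intensity))
        stop("pixel ", where, ": mz and intensity lengths differ")
    if (length(mz) > 1L && any(diff(mz) <= 0))
        stop("pixel ", where, ": m/z values not strictly ascending")
    if (any(intensity < 0))
        stop("pixel ", where, ": negative intensities")
    invisible(TRUE)
}

#' Construct an MSIDataset from a list of pixel spectra
#'
#' @param spectra row-major list of `list(mz=, intensity=)` pairs of length
#'   `nRows * nCols`. Pixel `(row, col)` (0-based) is element
#'   `row * nCols + col + 1`.
#' @param nRows,nCols raster dimensions
#' @param geometry a [RasterGeometry-class]
#' @param metadata named character vector
#' @return an [MSIDataset-class]
#' @export
msiDataset <- function(spectra, nRows, nCols, geometry,
                       metadata = character()) {
    nRows <- as.integer(nRows); nCols <- as.integer(nCols)
    for (i in seq_along(spectra)) {
        s <- spectra[[i]]
        r <- (i - 1L) %/% nCols; cc <- (i - 1L) %% nCols
        .check_spectrum(s$mz, s$intensity, sprintf("(%d,%d)", r, cc))
    }
    new("MSIDataset", spectra = spectra, nRows = nRows, nCols = nCols,
        geometry = geometry, metadata = metadata)
}

#' Single-ion image
#'
#' Per-pixel summed intensity inside a ppm mass-tolerance window around one
#' target m/z, optionally expressed as a percentage of each pixel's total
#' ion current (TIC).
#'
#' @slot values `nRows x nCols` numeric matrix of window intensities
#' @slot targetMz target m/z (Th)
#' @slot tolerancePpm half-width of the extraction window in ppm
#' @slot normalization `"none"` or `"tic_percent"`
#' @slot sourceId free-form provenance string naming the source dataset
#' @seealso [buildIonImage()]
#' @exportClass IonImage
setClass("IonImage",
    representation(
        values        = "matrix",
        targetMz      = "numeric",
        tolerancePpm  = "numeric",
        normalization = "character",
        sourceId      = "character"
    )
)

setValidity("IonImage", function(object) {
    msg <- character()
    if (any(object@values < 0, na.rm = TRUE))
        msg <- c(msg, "ion image values must be non-negative")
    if (!object@normalization %in% c("none", "tic_percent"))
        msg <- c(msg, "normalization must be 'none' or 'tic_percent'")
    if (identical(object@normalization, "tic_percent") &&
        any(object@values > 100 + 1e-9, na.rm = TRUE))
        msg <- c(msg, "tic_percent values must lie in [0, 100]")
    if (length(object@tolerancePpm) != 1L || object@tolerancePpm < 0)
        msg <- c(msg, "tolerancePpm must be a single non-negative number")
    if (length(msg)) msg else TRUE
})

#' Per-pixel ratio image of two ion images
#'
#' Elementwise numerator/denominator of two ion images on the same raster.
#' Pixels whose denominator falls below a floor are masked rather than
#' inflated; stored values are never clipped (clipping to `scaleMax` is a
#' rendering concern only).
#'
#' @slot values numeric matrix of ratios (NA where masked)
#' @slot numeratorMz,denominatorMz the two target m/z values (Th)
#' @slot mask logical matrix, TRUE where the denominator was below the floor
#' @slot scaleMax display scale maximum (default 11)
#' @seealso [ratioImage()]
#' @exportClass RatioImage
setClass("RatioImage",
    representation(
        values        = "matrix",
        numeratorMz   = "numeric",
        denominatorMz = "numeric",
        mask          = "matrix",
        scaleMax      = "numeric"
    )
)

setValidity("RatioImage", function(object) {
    msg <- character()
    if (!identical(dim(object@values), dim(object@mask)))
        msg <- c(msg, "values and mask dimensions differ")
    if (length(object@scaleMax) != 1L || object@scaleMax <= 0)
        msg <- c(msg, "scaleMax must be a single positive number")
    if (any(is.na(object@values) & !object@mask))
        msg <- c(msg, "NA values only allowed at masked pixels")
    if (length(msg)) msg else TRUE
})

#' Longitudinal intensity profile along the developmental axis
#'
#' Intensity-versus-distance curves sampled along a line through the root,
#' one per tissue section, each scaled to its own maximum, with the
#' pointwise mean and sample standard deviation across sections.
#'
#' @slot distances ascending positions along the line, micrometres
#' @slot sections `nSections x length(distances)` matrix of per-section
#'   scaled values (each row has maximum 1)
#' @slot mean pointwise mean across sections
#' @slot sd pointwise sample standard deviation (denominator n - 1)
#' @slot nSections number of sections aggregated
#' @seealso [aggregateProfiles()], [compareProfiles()]
#' @exportClass AxisProfile
setClass("AxisProfile",
    representation(
        distances = "numeric",
        sections  = "matrix",
        mean      = "numeric",
        sd        = "numeric",
        nSections = "integer"
    )
)

setValidity("AxisProfile", function(object) {
    msg <- character()
    np <- length(object@distances)
    if (length(object@mean) != np || length(object@sd) != np)
        msg <- c(msg, "mean/sd length must match distances")
    if (ncol(object@sections) != np)
        msg <- c(msg, "sections must have one column per distance")
    if (nrow(object@sections) != object@nSections)
        msg <- c(msg, "sections must have one row per section")
    if (np > 1L && any(diff(object@distances) <= 0))
        msg <- c(msg, "distances must be strictly ascending")
    if (any(object@sd < 0, na.rm = TRUE)) msg <- c(msg, "sd must be >= 0")
    if (any(object@sections < -1e-12 | object@sections > 1 + 1e-9))
        msg <- c(msg, "scaled section values must lie in [0, 1]")
    if (length(msg)) msg else TRUE
})

## ---- generics ----

#' @rdname MSIDataset-accessors
#' @export
setGeneric("nRows", function(x) standardGeneric("nRows"))
#' @rdname MSIDataset-accessors
#' @export
setGeneric("nCols", function(x) standardGeneric("nCols"))
#' @rdname MSIDataset-accessors
#' @export
setGeneric("geometry", function(x) standardGeneric("geometry"))
#' @rdname MSIDataset-accessors
#' @export
setGeneric("spectrumAt", function(x, row, col) standardGeneric("spectrumAt"))
#' @rdname MSIDataset-accessors
#' @export
setGeneric("pixelTIC", function(x, ...) standardGeneric("pixelTIC"))
#' @rdname IonImage-accessors
#' @export
setGeneric("intensityValues", function(x) standardGeneric("intensityValues"))

#' Accessors for MSIDataset
#'
#' `nRows`/`nCols` return the raster dimensions, `geometry` the
#' [RasterGeometry-class], and `spectrumAt(x, row, col)` the centroided
#' spectrum of one pixel (0-based indices) as `list(mz=, intensity=)`.
#' `pixelTIC` returns the per-pixel total ion current; for a dataset it is
#' the full `nRows x nCols` TIC matrix.
#'
#' @param x an [MSIDataset-class]
#' @param row,col 0-based pixel indices
#' @param ... unused
#' @name MSIDataset-accessors
NULL

#' @rdname MSIDataset-accessors
#' @export
setMethod("nRows", "MSIDataset", function(x) x@nRows)
#' @rdname MSIDataset-accessors
#' @export
setMethod("nCols", "MSIDataset", function(x) x@nCols)
#' @rdname MSIDataset-accessors
#' @export
setMethod("geometry", "MSIDataset", function(x) x@geometry)

#' @rdname MSIDataset-accessors
#' @export
setMethod("spectrumAt", "MSIDataset", function(x, row, col) {
    row <- as.integer(row); col <- as.integer(col)
    if (row < 0L || row >= x@nRows || col < 0L || col >= x@nCols)
        stop(sprintf("pixel (%d,%d) outside %d x %d raster",
                     row, col, x@nRows, x@nCols))
    x@spectra[[row * x@nCols + col + 1L]]
})

#' Accessors for IonImage / RatioImage
#'
#' `intensityValues` returns the raw numeric grid of an image object.
#'
#' @param x an [IonImage-class] or [RatioImage-class]
#' @name IonImage-accessors
NULL

#' @rdname IonImage-accessors
#' @export
setMethod("intensityValues", "IonImage", function(x) x@values)
#' @rdname IonImage-accessors
#' @export
setMethod("intensityValues", "RatioImage", function(x) x@values)

## ---- show methods ----

setMethod("show", "RasterGeometry", function(object) {
    cat("RasterGeometry:", sprintf("%.4g x %.4g um pixels", object@pixelWidth,
        object@pixelHeight), "\n")
    if (!is.na(object@stageSpeed))
        cat("  stage speed:", object@stageSpeed, "um/s, cycle time:",
            object@cycleTime, "s\n")
    cat("  m/z range:", object@mzRange[1], "-", object@mzRange[2], "Th\n")
})

setMethod("show", "MSIDataset", function(object) {
    npk <- sum(vapply(object@spectra, function(s) length(s$mz), 0L))
    cat("MSIDataset:", object@nRows, "rows x", object@nCols, "cols,",
        npk, "centroids total\n")
    show(object@geometry)
    if (length(object@metadata))
        cat("  metadata:", paste(names(object@metadata), object@metadata,
            sep = "=", collapse = ", "), "\n")
})

setMethod("show", "IonImage", function(object) {
    cat(sprintf("IonImage: m/z %.4f +/- %g ppm, %d x %d, normalization=%s\n",
        object@targetMz, object@tolerancePpm, nrow(object@values),
        ncol(object@values), object@normalization))
    v <- object@values
    cat(sprintf("  range [%.4g, %.4g], mean %.4g\n", min(v), max(v), mean(v)))
})

setMethod("show", "RatioImage", function(object) {
    cat(sprintf(
        "RatioImage: m/z %.4f / %.4f, %d x %d, %d masked, scaleMax=%g\n",
        object@numeratorMz, object@denominatorMz, nrow(object@values),
        ncol(object@values), sum(object@mask), object@scaleMax))
})

setMethod("show", "AxisProfile", function(object) {
    cat(sprintf(
        "AxisProfile: %d positions over %.4g um, %d sections (mean +/- sd)\n",
        length(object@distances), diff(range(object@distances)),
        object@nSections))
})
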