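## Single-ion image extraction. The TIC of a pixel is the sum over the full
## acquired mass range of its spectrum (the convention of %TIC imaging
## software), not a sum over a target list; because TIC normalization is
## susceptible to matrix effects, the unnormalized mode is first-class.

#' @rdname MSIDataset-accessors
#' @export
setMethod("pixelTIC", "list", function(x, ...) sum(x$intensity))

#' @rdname MSIDataset-accessors
#' @export
setMethod("pixelTIC", "MSIDataset", function(x, ...) {
    tic <- vapply(x@spectra, function(s) sum(s$intensity), 0)
    matrix(tic, nrow = x@nRows, ncol = x@nCols, byrow = TRUE)
})

#' Summed intensity inside a ppm window
#'
#' Sums the intensities of all centroids with m/z in
#' `[target * (1 - ppm * 1e-6), target * (1 + ppm * 1e-6)]`, both ends
#' inclusive, located by binary search on the ascending m/z array.
#'
#' @param spectrum a pixel spectrum `list(mz=, intensity=)`
#' @param targetMz target m/z (Th)
#' @param tolerancePpm window half-width in ppm
#' @param mzRange optional acquired range `c(low, high)`; a target outside
#'   it raises a warning and returns 0 so that batch extraction proceeds
#' @return summed intensity (0 for an empty spectrum)
#' @examples
#' sp <- list(mz = c(117.0193, 117.0300), intensity = c(50, 7))
#' extractWindow(sp, 117.0193, 5)  # 50: +/-5 ppm excludes 117.0300
#' @export
extractWindow <- function(spectrum, targetMz, tolerancePpm,
                          mzRange = NULL) {
    if (!is.null(mzRange) &&
        (targetMz < mzRange[1] || targetMz > mzRange[2])) {
        warning(sprintf("target m/z %.4f outside acquired range [%g, %g]",
                        targetMz, mzRange[1], mzRange[2]))
        return(0)
    }
    mz <- spectrum$mz
    if (!length(mz)) return(0)
    lo <- targetMz * (1 - tolerancePpm * 1e-6)
    hi <- targetMz * (1 + tolerancePpm * 1e-6)
    # findInterval on the sorted axis: first index > lo-eps, last index <= hi
    i1 <- findInterval(lo, mz, left.open = TRUE) + 1L
    i2 <- findInterval(hi, mz)
    if (i1 > i2) return(0)
    sum(spectrum$intensity[i1:i2])
}

#' Build a single-ion image
#'
#' Extracts the ppm-window intensity at every pixel. With
#' `normalization = "tic_percent"` each value is expressed as
#' `100 * window / TIC` of its own pixel (0 where the pixel TIC is 0),
#' which cancels per-pixel sensitivity drift; `"none"` keeps raw summed
#' counts so normalized and unnormalized distributions can be compared.
#'
#' @param dataset an [MSIDataset-class]
#' @param targetMz target m/z (Th)
#' @param tolerancePpm window half-width in ppm (default 5)
#' @param normalization `"tic_percent"` (default) or `"none"`
#' @return an [IonImage-class]
#' @seealso [extractWindow()], [ratioImage()]
#' @export
buildIonImage <- function(dataset, targetMz, tolerancePpm = 5,
                          normalization = c("tic_percent", "none")) {
    normalization <- match.arg(normalization)
    stopifnot(is(dataset, "MSIDataset"))
    rng <- dataset@geometry@mzRange
    if (targetMz < rng[1] || targetMz > rng[2])
        warning(sprintf("target m/z %.4f outside acquired range [%g, %g]",
                        targetMz, rng[1], rng[2]))
    vals <- vapply(dataset@spectra, extractWindow, 0,
                   targetMz = targetMz, tolerancePpm = tolerancePpm)
    m <- matrix(vals, nrow = dataset@nRows, ncol = dataset@nCols,
                byrow = TRUE)
    if (normalization == "tic_percent") {
        tic <- pixelTIC(dataset)
        m <- ifelse(tic > 0, 100 * m / tic, 0)
    }
    src <- dataset@metadata["source"]
    new("IonImage", values = m, targetMz = targetMz,
        tolerancePpm = tolerancePpm, normalization = normalization,
        sourceId = if (is.na(src)) "in-memory" else unname(src))
}

#' Per-pixel ratio of two ion images
#'
#' Elementwise numerator/denominator. Pixels whose denominator is below
#' `denominatorFloor` are masked (NA) rather than inflated by an epsilon;
#' stored ratios are never clipped -- `scaleMax` (default 11) only caps the
#' rendered color scale.
#'
#' @param num,den [IonImage-class] objects on the same raster with the same
#'   normalization
#' @param denominatorFloor mask pixels with denominator < floor; the
#'   default 0 masks only zero/negative denominators
#' @param scaleMax display scale maximum
#' @return a [RatioImage-class]
#' @export
ratioImage <- function(num, den, denominatorFloor = 0, scaleMax = 11) {
    stopifnot(is(num, "IonImage"), is(den, "IonImage"))
    if (!identical(dim(num@values), dim(den@values)))
        stop("numerator and denominator image dimensions differ")
    if (!identical(num@normalization, den@normalization))
        stop("numerator and denominator use different normalization modes")
    d <- den@values
    mask <- d < denominatorFloor | d <= 0
    vals <- num@values / d
    vals[mask] <- NA_real_
    new("RatioImage", values = vals, numeratorMz = num@targetMz,
        denominatorMz = den@targetMz, mask = mask, scaleMax = scaleMax)
}

#' Write an intensity grid as delimited text
#'
#' Numeric grids (not rendered images) are the contract surface of the
#' pipeline. The file carries a two-line `#`-prefixed header with the grid
#' dimensions and pixel geometry, then one comma-separated row per raster
#' row at full float precision.
#'
#' @param image an [IonImage-class], [RatioImage-class] or bare matrix
#' @param path output path
#' @param geometry optional [RasterGeometry-class] for the header
#' @return `path`, invisibly
#' @export
writeGrid <- function(image, path, geometry = NULL) {
    m <- if (is.matrix(image)) image else intensityValues(image)
    hdr <- c(sprintf("# rows=%d cols=%d", nrow(m), ncol(m)),
             if (!is.null(geometry))
                 sprintf("# pixel_width_um=%g pixel_height_um=%g",
                         geometry@pixelWidth, geometry@pixelHeight)
             else "# pixel_width_um=NA pixel_height_um=NA")
    body <- apply(m, 1L, function(r)
        paste(formatC(r, format = "g", digits = 17), collapse = ","))
    writeLines(c(hdr, body), path)
    invisible(path)
}
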