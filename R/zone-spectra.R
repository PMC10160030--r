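## Zone-averaged spectra: scans across one raster row of one tissue are
## averaged per developmental zone (root tip, meristem, differentiation
## zone) and the background -- averaged from scans on the adjacent glass
## slide in the same row, eight by default -- is subtracted. Centroid
## positions jitter at the ppm scale from pixel to pixel, so averaging
## requires binning peaks onto a shared axis; 5 ppm bins match the imaging
## tolerance.

# cluster sorted peaks into ppm-width bins: a new bin starts when a peak is
# more than binPpm away (relative) from the running intensity-weighted bin
# center
.bin_peaks <- function(mz, intensity, binPpm) {
    o <- order(mz)
    mz <- mz[o]; intensity <- intensity[o]
    n <- length(mz)
    bin <- integer(n)
    if (n == 0L) return(list(assign = bin, centers = numeric(0)))
    b <- 1L
    bin[1L] <- 1L
    ctr <- mz[1L]; wsum <- intensity[1L]
    centers <- numeric(0)
    for (i in seq_len(n)[-1L]) {
        if ((mz[i] - ctr) / ctr > binPpm * 1e-6) {
            centers[b] <- ctr
            b <- b + 1L
            ctr <- mz[i]; wsum <- intensity[i]
        } else {
            wsum2 <- wsum + intensity[i]
            ctr <- if (wsum2 > 0) (ctr * wsum + mz[i] * intensity[i]) / wsum2
                   else (ctr + mz[i]) / 2
            wsum <- wsum2
        }
        bin[i] <- b
    }
    centers[b] <- ctr
    list(assign = bin[order(o)], centers = centers)
}

#' Average scans from selected pixels of one raster row
#'
#' Accumulates the centroids of the selected pixels onto a shared m/z axis
#' binned at `binPpm` and returns the per-bin mean intensity over the
#' number of scans (pixels lacking a peak in a bin contribute zero).
#'
#' @param dataset an [MSIDataset-class]
#' @param row 0-based raster row
#' @param cols 0-based column indices of the scans to average
#' @param binPpm bin width in ppm (default 5, the imaging tolerance)
#' @return list of class `AverageSpectrum`: `mz` (ascending bin centers),
#'   `intensity` (per-bin means), `n_scans`
#' @seealso [subtractBackground()], [zoneAverageSpectrum()]
#' @export
averageScans <- function(dataset, row, cols, binPpm = 5) {
    stopifnot(is(dataset, "MSIDataset"))
    row <- as.integer(row); cols <- as.integer(cols)
    if (!length(cols)) stop("empty column selection")
    if (row < 0L || row >= dataset@nRows) stop("row out of range")
    if (any(cols < 0L | cols >= dataset@nCols))
        stop("column selection out of range")
    idx <- row * dataset@nCols + cols + 1L
    sel <- dataset@spectra[idx]
    mz <- unlist(lapply(sel, `[[`, "mz"), use.names = FALSE)
    intensity <- unlist(lapply(sel, `[[`, "intensity"), use.names = FALSE)
    if (!length(mz))
        return(structure(list(mz = numeric(0), intensity = numeric(0),
                              n_scans = length(cols)),
                         class = "AverageSpectrum"))
    bins <- .bin_peaks(mz, intensity, binPpm)
    tot <- as.numeric(tapply(intensity, bins$assign, sum))
    structure(list(mz = bins$centers,
                   intensity = tot / length(cols),
                   n_scans = length(cols)),
              class = "AverageSpectrum")
}

#' Subtract a background spectrum from a tissue spectrum
#'
#' Elementwise `tissue - background` on a shared m/z axis; negative results
#' are floored at zero by default (average-intensity semantics; disable for
#' diagnostics). Axes must match bin for bin within `tolPpm`.
#'
#' @param tissue,background `AverageSpectrum` objects on the same axis
#' @param floorNegative floor negative differences at 0 (default TRUE)
#' @param tolPpm axis agreement tolerance in ppm
#' @return an `AverageSpectrum` with the tissue's `n_scans`
#' @export
subtractBackground <- function(tissue, background, floorNegative = TRUE,
                               tolPpm = 0.5) {
    if (length(tissue$mz) != length(background$mz) ||
        (length(tissue$mz) &&
         any(abs(tissue$mz - background$mz) / tissue$mz > tolPpm * 1e-6)))
        stop("tissue and background spectra are on different m/z axes; ",
             "bin them jointly (see zoneAverageSpectrum)")
    d <- tissue$intensity - background$intensity
    if (floorNegative) d <- pmax(d, 0)
    structure(list(mz = tissue$mz, intensity = d, n_scans = tissue$n_scans),
              class = "AverageSpectrum")
}

#' Background-subtracted average spectrum of one developmental zone
#'
#' Bins the on-tissue and off-tissue (glass) scans of one raster row onto a
#' single shared axis, averages each group, and subtracts the background
#' average from the tissue average (negatives floored).
#'
#' @param dataset an [MSIDataset-class]
#' @param row 0-based raster row crossing the zone
#' @param onTissueCols 0-based on-tissue column indices
#' @param backgroundCols 0-based off-tissue column indices (8 scans on the
#'   adjacent glass by convention); must be disjoint from `onTissueCols`
#' @param binPpm shared-axis bin width in ppm
#' @param floorNegative floor negative differences at 0
#' @return an `AverageSpectrum`
#' @export
zoneAverageSpectrum <- function(dataset, row, onTissueCols, backgroundCols,
                                binPpm = 5, floorNegative = TRUE) {
    if (length(intersect(onTissueCols, backgroundCols)))
        stop("background columns overlap on-tissue columns")
    if (!length(backgroundCols))
        stop("at least one background column required")
    nc <- dataset@nCols
    grab <- function(cols) dataset@spectra[row * nc + as.integer(cols) + 1L]
    ts <- grab(onTissueCols); bs <- grab(backgroundCols)
    all_mz <- c(unlist(lapply(ts, `[[`, "mz"), use.names = FALSE),
                unlist(lapply(bs, `[[`, "mz"), use.names = FALSE))
    all_int <- c(unlist(lapply(ts, `[[`, "intensity"), use.names = FALSE),
                 unlist(lapply(bs, `[[`, "intensity"), use.names = FALSE))
    is_tissue <- c(rep(TRUE, sum(lengths(lapply(ts, `[[`, "mz")))),
                   rep(FALSE, sum(lengths(lapply(bs, `[[`, "mz")))))
    if (!length(all_mz))
        return(structure(list(mz = numeric(0), intensity = numeric(0),
                              n_scans = length(onTissueCols)),
                         class = "AverageSpectrum"))
    bins <- .bin_peaks(all_mz, all_int, binPpm)
    nb <- length(bins$centers)
    tsum <- numeric(nb); bsum <- numeric(nb)
    tt <- tapply(all_int[is_tissue], bins$assign[is_tissue], sum)
    bb <- tapply(all_int[!is_tissue], bins$assign[!is_tissue], sum)
    tsum[as.integer(names(tt))] <- tt
    bsum[as.integer(names(bb))] <- bb
    d <- tsum / length(onTissueCols) - bsum / length(backgroundCols)
    if (floorNegative) d <- pmax(d, 0)
    structure(list(mz = bins$centers, intensity = d,
                   n_scans = length(onTissueCols)),
              class = "AverageSpectrum")
}

#' @export
print.AverageSpectrum <- function(x, ...) {
    cat(sprintf("AverageSpectrum: %d bins, mean of %d scans\n",
                length(x$mz), x$n_scans))
    invisible(x)
}
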