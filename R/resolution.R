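## Lateral spatial resolution by the 80-20% edge rule: the distance over
## which a single-ion signal rises from 20% to 80% of its maximum across
## the tissue edge. A straight line is fit (ordinary least squares) to the
## measured points on the edge and solved, via the point-slope formula, for
## the x-coordinates of the exact 20% and 80% levels. Any biological
## gradient in the chosen ion broadens the estimate, so calibration uses a
## gradient-free simulated section.

#' Single-ion row chromatogram
#'
#' Extracts the ppm-window intensity of one target ion along one raster
#' row; the along-scan time axis is converted to distance using the stage
#' speed, i.e. distance = column index x pixel width.
#'
#' @param dataset an [MSIDataset-class]
#' @param row 0-based raster row
#' @param targetMz target m/z (Th)
#' @param tolerancePpm window half-width in ppm (default 5)
#' @return list with `distances_um`, `intensities` (class `RowChromatogram`)
#' @export
rowChromatogram <- function(dataset, row, targetMz, tolerancePpm = 5) {
    stopifnot(is(dataset, "MSIDataset"))
    row <- as.integer(row)
    if (row < 0L || row >= dataset@nRows)
        stop("row ", row, " out of range [0, ", dataset@nRows - 1L, "]")
    nc <- dataset@nCols
    idx <- row * nc + seq_len(nc)
    vals <- vapply(dataset@spectra[idx], extractWindow, 0,
                   targetMz = targetMz, tolerancePpm = tolerancePpm)
    structure(list(
        distances_um = (seq_len(nc) - 1L) * dataset@geometry@pixelWidth,
        intensities = vals,
        pixel_width_um = dataset@geometry@pixelWidth),
        class = "RowChromatogram")
}

#' Fit one edge of a row chromatogram and estimate resolution
#'
#' The chromatogram is baseline-subtracted (baseline = mean of the
#' `nBaseline` leading off-tissue points, the same off-tissue convention
#' used for background spectra) and referenced to its maximum. The edge is
#' localized at the 50% crossing (first upward crossing for the rising
#' edge, last downward crossing for the falling edge); the maximal
#' consecutive run of points with relative intensity strictly between 20%
#' and 80% around that crossing is collected, an ordinary least squares
#' line is fit to those points (if only one interior point exists, its two
#' bracketing points are included), and the fitted line is solved for the x
#' at exactly the 20% and 80% levels. Resolution is `|x80 - x20|`.
#'
#' @param chrom a [rowChromatogram()] result, or a list with
#'   `distances_um` and `intensities`
#' @param edge `"rising"` or `"falling"`
#' @param nBaseline number of leading points averaged as baseline
#'   (default 8); set 0 for a zero baseline
#' @return list of class `EdgeFit`: `edge`, `slope`, `intercept`,
#'   `x20_um`, `x80_um`, `resolution_um`, `fit_points`
#' @export
fitEdge <- function(chrom, edge = c("rising", "falling"), nBaseline = 8) {
    edge <- match.arg(edge)
    x <- chrom$distances_um
    y <- chrom$intensities
    if (length(x) != length(y) || length(x) < 3L)
        stop("chromatogram needs >= 3 points")
    baseline <- if (nBaseline > 0L)
        mean(y[seq_len(min(nBaseline, length(y)))]) else 0
    top <- max(y)
    if (top <= baseline)
        stop("no detectable edge: maximum does not exceed baseline")
    rel <- (y - baseline) / (top - baseline)

    above <- rel >= 0.5
    if (edge == "rising") {
        cross <- which(above)[1L]
        if (is.na(cross) || cross == 1L)
            stop("no rising 50% crossing in chromatogram")
    } else {
        last_above <- max(which(above))
        if (last_above >= length(rel))
            stop("no falling 50% crossing in chromatogram")
        cross <- last_above + 1L   # first point below 50% after the plateau
    }

    interior <- rel > 0.2 & rel < 0.8
    # gather the consecutive interior run around the crossing
    run <- integer(0)
    for (cand in c(cross, cross - 1L)) {
        if (cand >= 1L && cand <= length(rel) && interior[cand]) {
            i0 <- cand
            while (i0 > 1L && interior[i0 - 1L]) i0 <- i0 - 1L
            i1 <- cand
            while (i1 < length(rel) && interior[i1 + 1L]) i1 <- i1 + 1L
            run <- i0:i1
            break
        }
    }
    pw <- if (!is.null(chrom$pixel_width_um)) chrom$pixel_width_um
          else stats::median(diff(x))
    if (length(run) == 0L) {
        # step sharper than the sampling: bracket the crossing
        run <- c(cross - 1L, cross)
        if (diff(rel[run]) == 0)
            stop("edge too sharp to fit; resolution <= pixel width (",
                 format(pw), " um)")
    } else if (length(run) == 1L) {
        run <- intersect((run - 1L):(run + 1L), seq_along(rel))
    }

    fx <- x[run]; fy <- rel[run]
    if (length(unique(fx)) < 2L)
        stop("degenerate edge: fit points share one x position")
    fit <- stats::lm.fit(cbind(1, fx), fy)
    slope <- fit$coefficients[2L]
    intercept <- fit$coefficients[1L]
    if (!is.finite(slope) || slope == 0)
        stop("edge too sharp to fit; resolution <= pixel width (",
             format(pw), " um)")
    # point-slope: x(level) = x_ref + (level - y_ref) / slope
    x20 <- fx[1L] + (0.2 - (intercept + slope * fx[1L])) / slope
    x80 <- fx[1L] + (0.8 - (intercept + slope * fx[1L])) / slope
    structure(list(edge = edge, slope = unname(slope),
                   intercept = unname(intercept),
                   x20_um = unname(x20), x80_um = unname(x80),
                   resolution_um = abs(unname(x80 - x20)),
                   fit_points = data.frame(distance_um = fx, relative = fy)),
              class = "EdgeFit")
}

#' Aggregate edge fits into per-edge resolution statistics
#'
#' Groups individual edge measurements (several raster rows per tissue
#' section are expected) by edge kind, reports mean, sample standard
#' deviation and n per edge, and compares rising vs falling means with a
#' two-tailed, two-sample equal-variance (Student) t-test.
#'
#' @param fits list of [fitEdge()] results (or a data.frame with columns
#'   `edge`, `resolution_um`)
#' @return list of class `EdgeResolutionSet`: `measurements` (data.frame),
#'   `summary` (per-edge mean/sd/n), `t`, `p`
#' @export
aggregateResolution <- function(fits) {
    tab <- if (is.data.frame(fits)) fits
           else do.call(rbind, lapply(fits, function(f)
               data.frame(edge = f$edge, resolution_um = f$resolution_um)))
    if (!all(c("rising", "falling") %in% tab$edge))
        stop("need fits for both rising and falling edges")
    counts <- table(tab$edge)
    if (any(counts < 2L))
        stop("need >= 2 fits per edge kind")
    rs <- tab$resolution_um[tab$edge == "rising"]
    fl <- tab$resolution_um[tab$edge == "falling"]
    smry <- data.frame(
        edge = c("rising", "falling"),
        mean_um = c(mean(rs), mean(fl)),
        sd_um = c(stats::sd(rs), stats::sd(fl)),
        n = c(length(rs), length(fl)))
    tt <- stats::t.test(rs, fl, var.equal = TRUE)
    structure(list(measurements = tab, summary = smry,
                   t = unname(tt$statistic), p = tt$p.value),
              class = "EdgeResolutionSet")
}

#' @export
print.EdgeResolutionSet <- function(x, ...) {
    cat("EdgeResolutionSet\n")
    print(x$summary, row.names = FALSE)
    cat(sprintf("rising vs falling: t = %.3f, p = %.4f (Student, two-tailed)\n",
                x$t, x$p))
    invisible(x)
}
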