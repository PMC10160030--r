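## Longitudinal intensity profiles along the root developmental axis.
## A slice is drawn through the center of the root and the intensity is
## averaged across a band of raster pixels perpendicular to it; a ten-pixel
## band is realized as the line pixel plus five pixels on each side
## (nearest-pixel sampling, no interpolation, mirroring line-width averaging
## in raster image tools).

#' Define a profile line across an image
#'
#' @param start,end line endpoints as `c(row, col)` in pixel coordinates
#'   (0-based, fractional allowed)
#' @param bandWidthPx band width in pixels; a width of `w` samples
#'   `floor(w / 2)` pixels on each side of the line point
#' @param nSamples number of equally spaced sample points along the line;
#'   default one per pixel of line length
#' @return a `ProfileLine` list
#' @export
profileLine <- function(start, end, bandWidthPx = 10, nSamples = NULL) {
    stopifnot(length(start) == 2L, length(end) == 2L, bandWidthPx >= 1)
    if (all(start == end)) stop("degenerate line: start equals end")
    len <- sqrt(sum((end - start)^2))
    if (is.null(nSamples)) nSamples <- max(2L, ceiling(len) + 1L)
    structure(list(start = as.numeric(start), end = as.numeric(end),
                   bandWidthPx = as.integer(bandWidthPx),
                   nSamples = as.integer(nSamples)),
              class = "ProfileLine")
}

#' Band-averaged intensity along a line
#'
#' At each of `nSamples` equally spaced points along the line, averages the
#' nearest-pixel values across the band perpendicular to the line
#' (`floor(bandWidthPx / 2)` pixels each side of the line point). Band
#' pixels falling outside the image are dropped; a warning reports how many
#' sample points had a truncated band.
#'
#' @param image an [IonImage-class] or numeric matrix
#' @param line a [profileLine()]
#' @return list with `distances_px` (along-line position in pixels),
#'   `values` (band means)
#' @export
sampleBand <- function(image, line) {
    m <- if (is.matrix(image)) image else intensityValues(image)
    nr <- nrow(m); nc <- ncol(m)
    p0 <- line$start; p1 <- line$end
    if (any(p0 < -0.5) || any(p1 < -0.5) ||
        p0[1] > nr - 0.5 || p1[1] > nr - 0.5 ||
        p0[2] > nc - 0.5 || p1[2] > nc - 0.5)
        stop("line endpoints outside image bounds")
    len <- sqrt(sum((p1 - p0)^2))
    tfrac <- seq(0, 1, length.out = line$nSamples)
    dirv <- (p1 - p0) / len
    perp <- c(-dirv[2], dirv[1])
    half <- line$bandWidthPx %/% 2L
    offs <- seq(-half, half)
    vals <- numeric(line$nSamples)
    truncated <- 0L
    for (i in seq_along(tfrac)) {
        ctr <- p0 + tfrac[i] * len * dirv
        rr <- round(ctr[1] + offs * perp[1])
        cc <- round(ctr[2] + offs * perp[2])
        ok <- rr >= 0 & rr < nr & cc >= 0 & cc < nc
        if (!all(ok)) truncated <- truncated + 1L
        if (!any(ok)) stop("entire band outside image at sample ", i)
        vals[i] <- mean(m[cbind(rr[ok] + 1L, cc[ok] + 1L)])
    }
    if (truncated > 0L)
        warning(truncated, " of ", line$nSamples,
                " sample points had a truncated band")
    list(distances_px = tfrac * len, values = vals)
}

#' Scale a profile to its maximum
#'
#' Divides by the maximum so the peak value is 1; the scaling that lets
#' profiles of different ions be overlaid on one axis.
#'
#' @param values numeric vector with `max(values) > 0`
#' @return rescaled vector with maximum 1
#' @export
scaleToMax <- function(values) {
    m <- max(values)
    if (!is.finite(m) || m <= 0) stop("cannot scale all-zero profile")
    values / m
}

#' Aggregate per-section profiles into an axis profile
#'
#' Each section's profile is rescaled to its own maximum, linearly resampled
#' onto a common distance grid (as long as the longest section), and the
#' pointwise mean and sample standard deviation (denominator n - 1) across
#' sections are computed.
#'
#' @param perSection list of per-section profiles; each element either a
#'   numeric vector (positions assumed equally spaced over the section
#'   length) or a list with `distances_um` and `values`
#' @param pixelWidthUm physical spacing used when a section is given as a
#'   bare vector
#' @return an [AxisProfile-class]
#' @seealso [compareProfiles()]
#' @export
aggregateProfiles <- function(perSection, pixelWidthUm = 1) {
    if (length(perSection) < 2L)
        stop("at least 2 sections required for a sample s.d.")
    norm <- lapply(perSection, function(s) {
        if (is.numeric(s))
            s <- list(distances_um = (seq_along(s) - 1) * pixelWidthUm,
                      values = s)
        s$values <- scaleToMax(s$values)
        s
    })
    npts <- max(vapply(norm, function(s) length(s$values), 0L))
    maxlen <- max(vapply(norm, function(s) max(s$distances_um), 0))
    grid <- seq(0, maxlen, length.out = npts)
    sec <- t(vapply(norm, function(s) {
        # resample each section onto the common grid over its own span
        gi <- seq(min(s$distances_um), max(s$distances_um),
                  length.out = npts)
        stats::approx(s$distances_um, s$values, xout = gi)$y
    }, numeric(npts)))
    mu <- colMeans(sec)
    sdv <- apply(sec, 2L, stats::sd)
    new("AxisProfile", distances = grid, sections = sec, mean = mu,
        sd = sdv, nSections = nrow(sec))
}

# vectorized two-sample equal-variance (Student) t-test across positions;
# cross-checked against stats::t.test in the unit tests
.student_t_cols <- function(A, B) {
    na <- nrow(A); nb <- nrow(B)
    ma <- colMeans(A); mb <- colMeans(B)
    va <- apply(A, 2L, stats::var); vb <- apply(B, 2L, stats::var)
    df <- na + nb - 2L
    sp2 <- ((na - 1L) * va + (nb - 1L) * vb) / df
    se <- sqrt(sp2 * (1 / na + 1 / nb))
    t <- (ma - mb) / se
    t[se == 0 & ma == mb] <- 0
    t[se == 0 & ma != mb] <- Inf * sign((ma - mb)[se == 0 & ma != mb])
    p <- 2 * stats::pt(abs(t), df, lower.tail = FALSE)
    list(t = t, p = p, df = df)
}

#' Per-position comparison of two axis profiles
#'
#' At every position along the common distance grid, a two-sample,
#' two-tailed, equal-variance (Student) t-test compares the per-section
#' scaled values of the two profiles. Raw p-values are reported and flagged
#' at `alpha` with no multiple-testing correction (each position is marked
#' independently); set `correction = "bonferroni"` to adjust.
#'
#' @param a,b [AxisProfile-class] objects on the same distance grid
#' @param alpha significance level (default 0.05)
#' @param correction `"none"` (default) or `"bonferroni"`
#' @return data.frame with columns `distance_um`, `t`, `p`, `significant`
#' @export
compareProfiles <- function(a, b, alpha = 0.05,
                            correction = c("none", "bonferroni")) {
    correction <- match.arg(correction)
    stopifnot(is(a, "AxisProfile"), is(b, "AxisProfile"))
    if (length(a@distances) != length(b@distances) ||
        max(abs(a@distances - b@distances)) > 1e-9 * max(a@distances, 1))
        stop("profiles are on different distance grids")
    if (a@nSections < 2L || b@nSections < 2L)
        stop("need >= 2 sections per profile")
    res <- .student_t_cols(a@sections, b@sections)
    p <- res$p
    if (correction == "bonferroni") p <- pmin(1, p * length(p))
    data.frame(distance_um = a@distances, t = res$t, p = p,
               significant = p < alpha)
}
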