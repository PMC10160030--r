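# shared fixture builders; everything is generated in code at test time

spec_of <- function(mz, intensity) list(mz = mz, intensity = intensity)

# tiny dataset whose pixel (r, c) carries one peak at `mz` with intensity
# base + r * nCols + c (distinct per pixel)
toyDataset <- function(nRows = 2L, nCols = 2L, mz = 117.0193, base = 10) {
    spectra <- lapply(seq_len(nRows * nCols), function(i)
        spec_of(mz, base + i - 1))
    msiDataset(spectra, nRows, nCols,
               rasterGeometry(pixelWidth = 100, pixelHeight = 100,
                              mzRange = c(50, 1000)))
}

# gradient-free simulation config for edge-resolution calibration: constant
# species only, no noise, no drift, negligible tip taper so row
# chromatograms cross clean Gaussian-CDF edges
calibrationConfig <- function(sigmaUm, seed = 1L, noiseModel = "none",
                              ticDriftSd = 0) {
    rootSimConfig(
        gradients = list(
            gradientSpec(metaboliteRecord("malate", "C4H6O5"),
                         amplitude = 50000, profile = "constant"),
            gradientSpec(metaboliteRecord("PG(16:0/18:2)", "C40H75O10P"),
                         amplitude = 20000, profile = "constant")),
        taperFrac = 1e-6, edgeBlurSigmaUm = sigmaUm,
        mzJitterPpm = 0, noiseModel = noiseModel, ticDriftSd = ticDriftSd,
        seed = seed)
}

# analytic row chromatogram with Gaussian-blurred rising and falling edges
# (pitch um between points), plus optional multiplicative lognormal noise
blurredEdgeChromatogram <- function(pitch = 72.6, n = 60, sigma = 150,
                                    x0 = 12 * pitch, x1 = 45 * pitch,
                                    amplitude = 1e4, noiseCv = 0) {
    x <- (seq_len(n) - 1) * pitch
    y <- amplitude * pnorm((x - x0) / sigma) * pnorm((x1 - x) / sigma)
    if (noiseCv > 0)
        y <- y * exp(rnorm(n, -log(1 + noiseCv^2) / 2,
                           sqrt(log(1 + noiseCv^2))))
    list(distances_um = x, intensities = y, pixel_width_um = pitch)
}

# AxisProfile straight from a sections matrix (rows = sections, values
# already in [0, 1])
axisProfileFromMatrix <- function(sec, distances = NULL) {
    if (is.null(distances)) distances <- seq_len(ncol(sec)) * 10
    new("AxisProfile", distances = as.numeric(distances), sections = sec,
        mean = colMeans(sec), sd = apply(sec, 2, sd),
        nSections = nrow(sec))
}

# brute-force linear-scan oracle for ppm-window extraction
windowOracle <- function(spectrum, targetMz, ppm) {
    lo <- targetMz * (1 - ppm * 1e-6)
    hi <- targetMz * (1 + ppm * 1e-6)
    s <- 0
    for (i in seq_along(spectrum$mz))
        if (spectrum$mz[i] >= lo && spectrum$mz[i] <= hi)
            s <- s + spectrum$intensity[i]
    s
}

# random centroid spectrum for oracle-equivalence sweeps
randomSpectrum <- function(npeaks = 30, mzlo = 50, mzhi = 1000) {
    if (npeaks == 0) return(spec_of(numeric(0), numeric(0)))
    mz <- sort(runif(npeaks, mzlo, mzhi))
    mz <- mz[c(TRUE, diff(mz) > 1e-9)]
    spec_of(mz, rexp(length(mz), 1 / 100))
}
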