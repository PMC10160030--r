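## Synthetic DESI-MSI root sections. The simulator emulates what a raster
## scan of a longitudinal root cryosection on a glass slide produces:
## a tapered-capsule tissue region surrounded by off-tissue glass pixels,
## opposing longitudinal gradients of target metabolites along the
## developmental axis (tip/meristem at low columns, differentiation zone at
## high columns), an off-tissue matrix/solvent peak, per-pixel TIC drift,
## ppm-scale m/z jitter, and counting noise. Every run returns bookkept
## ground truth (noiseless expected intensities, tissue mask, emitted TIC)
## so each pipeline stage can be tested against construction.

#' Specify one metabolite gradient
#'
#' Shape of a metabolite's expected intensity along the developmental axis,
#' parameterized on the axis fraction `f` (0 = root tip, 1 = shank end of
#' the imaged tissue).
#'
#' @param metabolite one-row data.frame from [metaboliteRecord()] (or a
#'   registry row)
#' @param amplitude peak expected intensity in arbitrary counts
#' @param profile `"logistic"`, `"linear"`, `"constant"` or
#'   `"gaussian_bump"`
#' @param centerFrac profile center on the axis, in `[0, 1]`
#' @param widthFrac profile width (logistic scale / Gaussian sd) as an
#'   axis fraction
#' @param direction `"shankward"` (increasing toward differentiation) or
#'   `"tipward"` (mirrored)
#' @return a `GradientSpec` list
#' @export
gradientSpec <- function(metabolite, amplitude,
                         profile = c("logistic", "linear", "constant",
                                     "gaussian_bump"),
                         centerFrac = 0.5, widthFrac = 0.1,
                         direction = c("shankward", "tipward")) {
    profile <- match.arg(profile)
    direction <- match.arg(direction)
    stopifnot(is.data.frame(metabolite), nrow(metabolite) == 1L,
              amplitude >= 0, centerFrac >= 0, centerFrac <= 1,
              widthFrac > 0)
    structure(list(metabolite = metabolite, amplitude = amplitude,
                   profile = profile, centerFrac = centerFrac,
                   widthFrac = widthFrac, direction = direction),
              class = "GradientSpec")
}

.profile_value <- function(spec, f) {
    g <- if (spec$direction == "tipward") 1 - f else f
    ctr <- if (spec$direction == "tipward") 1 - spec$centerFrac
           else spec$centerFrac
    switch(spec$profile,
        constant = rep(1, length(f)),
        linear = g,
        logistic = 1 / (1 + exp(-(g - ctr) / spec$widthFrac)),
        gaussian_bump = exp(-(g - ctr)^2 / (2 * spec$widthFrac^2)))
}

#' Simulation configuration for a synthetic root section
#'
#' @param nRows,nCols raster dimensions (default 40 x 150)
#' @param geometry a [RasterGeometry-class]; default 72.6 x 80 um pixels at
#'   a 53.69 um/s stage speed, m/z range 50-1000
#' @param gradients list of [gradientSpec()]s
#' @param matrixPeaks data.frame with columns `mz`, `amplitude`, `where`
#'   (`"off_tissue"`, `"on_tissue"` or `"everywhere"`)
#' @param tipFrac,endFrac tissue extent along the columns, as fractions of
#'   the raster width
#' @param maxHalfWidthRows tissue half-width at full width, in rows
#' @param taperFrac axis fraction over which the tip tapers to full width
#' @param edgeBlurSigmaUm Gaussian blur (um) applied to the tissue
#'   boundary; 0 gives a hard-edged mask
#' @param mzJitterPpm uniform per-peak m/z jitter bound in ppm (default 2)
#' @param noiseModel `"poisson"`, `"lognormal"` or `"none"`
#' @param noiseCv coefficient of variation of the lognormal noise
#' @param ticDriftSd sd of the per-pixel multiplicative lognormal TIC
#'   drift (0 disables)
#' @param seed master seed; per-pixel streams are split from it so earlier
#'   pixels' draws do not depend on the grid size
#' @return a `RootSimConfig` list
#' @seealso [defaultRootConfig()], [simulateRoot()]
#' @export
rootSimConfig <- function(nRows = 40L, nCols = 150L,
                          geometry = rasterGeometry(
                              pixelHeight = 80, stageSpeed = 53.69,
                              cycleTime = 72.6 / 53.69,
                              mzRange = c(50, 1000)),
                          gradients = list(),
                          matrixPeaks = data.frame(
                              mz = numeric(0), amplitude = numeric(0),
                              where = character(0)),
                          tipFrac = 0.06, endFrac = 0.97,
                          maxHalfWidthRows = 12, taperFrac = 0.18,
                          edgeBlurSigmaUm = 110,
                          mzJitterPpm = 2,
                          noiseModel = c("poisson", "lognormal", "none"),
                          noiseCv = 0.2, ticDriftSd = 0.15, seed = 1L) {
    noiseModel <- match.arg(noiseModel)
    stopifnot(nRows >= 1, nCols >= 2, tipFrac < endFrac,
              edgeBlurSigmaUm >= 0, mzJitterPpm >= 0, ticDriftSd >= 0)
    for (g in gradients) stopifnot(inherits(g, "GradientSpec"))
    rng <- geometry@mzRange
    for (g in gradients) {
        mz <- g$metabolite$theoretical_mz
        if (mz < rng[1] || mz > rng[2])
            stop("gradient metabolite '", g$metabolite$name,
                 "' m/z ", round(mz, 4), " outside acquired range [",
                 rng[1], ", ", rng[2], "]")
    }
    structure(list(nRows = as.integer(nRows), nCols = as.integer(nCols),
                   geometry = geometry, gradients = gradients,
                   matrixPeaks = matrixPeaks, tipFrac = tipFrac,
                   endFrac = endFrac, maxHalfWidthRows = maxHalfWidthRows,
                   taperFrac = taperFrac,
                   edgeBlurSigmaUm = edgeBlurSigmaUm,
                   mzJitterPpm = mzJitterPpm, noiseModel = noiseModel,
                   noiseCv = noiseCv, ticDriftSd = ticDriftSd,
                   seed = as.integer(seed)),
              class = "RootSimConfig")
}

#' Default synthetic root configuration
#'
#' A 40 x 150 raster at 72.6 x 80 um pixels emulating the qualitative
#' structure of a maize root section: succinate as a Gaussian bump centered
#' in the meristem (axis fraction 0.15), aconitate and fumarate as logistic
#' gradients rising toward the differentiation zone, malate as the
#' dominant, roughly uniform TIC contributor (so %TIC normalization is
#' exercised non-trivially), a strong constant lipid
#' (phosphatidylglycerol 16:0/18:2) for edge-resolution work, and one
#' off-tissue matrix peak.
#'
#' @param seed master seed
#' @param ... overrides passed on to [rootSimConfig()]
#' @return a `RootSimConfig`
#' @export
defaultRootConfig <- function(seed = 1L, ...) {
    grads <- list(
        gradientSpec(metaboliteRecord("succinate", "C4H6O4"),
                     amplitude = 10000, profile = "gaussian_bump",
                     centerFrac = 0.15, widthFrac = 0.12),
        gradientSpec(metaboliteRecord("aconitate", "C6H6O6"),
                     amplitude = 8000, profile = "logistic",
                     centerFrac = 0.5, widthFrac = 0.08,
                     direction = "shankward"),
        gradientSpec(metaboliteRecord("malate", "C4H6O5"),
                     amplitude = 50000, profile = "constant"),
        gradientSpec(metaboliteRecord("fumarate", "C4H4O4"),
                     amplitude = 6000, profile = "logistic",
                     centerFrac = 0.55, widthFrac = 0.10,
                     direction = "shankward"),
        gradientSpec(metaboliteRecord("PG(16:0/18:2)", "C40H75O10P",
                                      verified = FALSE),
                     amplitude = 20000, profile = "constant"))
    rootSimConfig(gradients = grads,
                  matrixPeaks = data.frame(
                      mz = 283.2643, amplitude = 20000,
                      where = "off_tissue", stringsAsFactors = FALSE),
                  seed = seed, ...)
}

# blurred tissue factor in [0, 1]: product of Gaussian-CDF edges at the
# tip, the shank end and the two lateral flanks (half-width tapers near
# the tip)
.tissue_factor <- function(config) {
    nr <- config$nRows; nc <- config$nCols
    pw <- config$geometry@pixelWidth; ph <- config$geometry@pixelHeight
    x <- (seq_len(nc) - 1L) * pw
    y <- (seq_len(nr) - 1L) * ph
    x_tip <- config$tipFrac * (nc - 1L) * pw
    x_end <- config$endFrac * (nc - 1L) * pw
    f <- pmin(pmax((x - x_tip) / (x_end - x_tip), 0), 1)
    taper <- pmin(1, f / config$taperFrac)^0.5
    hw_um <- config$maxHalfWidthRows * ph * taper
    yc <- (nr - 1L) / 2 * ph
    s <- config$edgeBlurSigmaUm
    edge <- function(d) if (s > 0) stats::pnorm(d / s) else as.numeric(d >= 0)
    along <- edge(x - x_tip) * edge(x_end - x)
    fac <- outer(y, seq_len(nc), function(yy, cc)
        edge(hw_um[cc] - abs(yy - yc)))
    sweep(fac, 2L, along, `*`)
}

#' Simulate a synthetic root MSI dataset with ground truth
#'
#' Builds the per-pixel expected intensity of every configured species
#' (gradient metabolites masked by the blurred tissue region, matrix peaks
#' by their `where` rule), applies multiplicative TIC drift, draws noisy
#' intensities (Poisson counts by default), jitters each centroid's m/z
#' uniformly within the configured ppm bound, and assembles the pixels into
#' an [MSIDataset-class]. Randomness is split per pixel from the master
#' seed, so a pixel's draws do not depend on the raster dimensions.
#'
#' @param config a [rootSimConfig()] / [defaultRootConfig()]
#' @return list with `dataset` (an [MSIDataset-class]) and `truth`, a list
#'   holding `expected` (named list of noiseless expected-intensity
#'   matrices, one per species), `tissueFactor` (blurred mask in `[0,1]`),
#'   `tissueMask` (`tissueFactor > 0.5`), `axisFrac` (per-column axis
#'   fraction), `ticExpected`/`ticEmitted` matrices, `targets` (name ->
#'   theoretical m/z), and the `config`
#' @export
simulateRoot <- function(config = defaultRootConfig()) {
    stopifnot(inherits(config, "RootSimConfig"))
    nr <- config$nRows; nc <- config$nCols
    fac <- .tissue_factor(config)
    x <- (seq_len(nc) - 1L) * config$geometry@pixelWidth
    x_tip <- config$tipFrac * (nc - 1L) * config$geometry@pixelWidth
    x_end <- config$endFrac * (nc - 1L) * config$geometry@pixelWidth
    axisFrac <- pmin(pmax((x - x_tip) / (x_end - x_tip), 0), 1)

    species <- list()
    for (g in config$gradients) {
        prof <- .profile_value(g, axisFrac)
        exp_mat <- sweep(fac, 2L, g$amplitude * prof, `*`)
        species[[g$metabolite$name]] <- list(
            mz = g$metabolite$theoretical_mz, expected = exp_mat)
    }
    if (nrow(config$matrixPeaks)) {
        for (i in seq_len(nrow(config$matrixPeaks))) {
            mp <- config$matrixPeaks[i, ]
            w <- switch(as.character(mp$where),
                off_tissue = (1 - fac) * mp$amplitude,
                on_tissue = fac * mp$amplitude,
                everywhere = matrix(mp$amplitude, nr, nc),
                stop("matrix peak 'where' must be off_tissue/on_tissue/",
                     "everywhere"))
            species[[sprintf("matrix_%.4f", mp$mz)]] <- list(
                mz = mp$mz, expected = w)
        }
    }
    if (!length(species)) stop("config defines no species to emit")

    sp_mz <- unname(vapply(species, `[[`, 0, "mz"))
    ord <- order(sp_mz)
    species <- species[ord]; sp_mz <- sp_mz[ord]
    ns <- length(species)

    # prefix-stable per-pixel seeds split from the master seed
    set.seed(config$seed)
    pixel_seeds <- sample.int(.Machine$integer.max - 1L, nr * nc,
                              replace = TRUE)

    exp_arr <- array(0, dim = c(nr, nc, ns))
    for (k in seq_len(ns)) exp_arr[, , k] <- species[[k]]$expected

    spectra <- vector("list", nr * nc)
    tic_emitted <- matrix(0, nr, nc)
    jit <- config$mzJitterPpm * 1e-6
    for (r in seq_len(nr)) {
        for (cc in seq_len(nc)) {
            i <- (r - 1L) * nc + cc
            set.seed(pixel_seeds[i])
            drift <- if (config$ticDriftSd > 0)
                exp(stats::rnorm(1L, -config$ticDriftSd^2 / 2,
                                 config$ticDriftSd)) else 1
            lam <- exp_arr[r, cc, ] * drift
            inten <- switch(config$noiseModel,
                poisson = as.numeric(stats::rpois(ns, lam)),
                lognormal = lam * exp(stats::rnorm(ns,
                    -log(1 + config$noiseCv^2) / 2,
                    sqrt(log(1 + config$noiseCv^2)))),
                none = lam)
            mz <- sp_mz * (1 + stats::runif(ns, -jit, jit))
            keep <- inten > 0
            o <- order(mz[keep])
            spectra[[i]] <- list(mz = mz[keep][o],
                                 intensity = inten[keep][o])
            tic_emitted[r, cc] <- sum(inten[keep])
        }
    }

    dataset <- new("MSIDataset", spectra = spectra, nRows = nr, nCols = nc,
                   geometry = config$geometry,
                   metadata = c(source = "simulateRoot",
                                polarity = "negative"))
    truth <- list(
        expected = lapply(species, `[[`, "expected"),
        tissueFactor = fac,
        tissueMask = fac > 0.5,
        axisFrac = axisFrac,
        ticExpected = apply(exp_arr, c(1L, 2L), sum),
        ticEmitted = tic_emitted,
        targets = stats::setNames(sp_mz, names(species)),
        config = config)
    list(dataset = dataset, truth = truth)
}

#' Write simulation ground truth as structured text
#'
#' Serializes the ground-truth record of [simulateRoot()] to JSON (the
#' tissue mask is stored as per-row run-length encoding to stay compact).
#'
#' @param truth the `truth` element returned by [simulateRoot()]
#' @param path output path
#' @return `path`, invisibly
#' @export
writeGroundTruth <- function(truth, path) {
    rle_rows <- apply(truth$tissueMask, 1L, function(r) {
        e <- rle(as.logical(r))
        list(lengths = e$lengths, values = e$values)
    })
    out <- list(
        targets = as.list(truth$targets),
        axis_frac = truth$axisFrac,
        tissue_mask_rle = rle_rows,
        tic_expected = truth$ticExpected,
        expected = truth$expected,
        seed = truth$config$seed)
    jsonlite::write_json(out, path, digits = NA, auto_unbox = TRUE)
    invisible(path)
}
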