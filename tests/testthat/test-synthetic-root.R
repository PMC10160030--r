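test_that("the default configuration satisfies its invariants", {
    cfg <- defaultRootConfig()
    expect_s3_class(cfg, "RootSimConfig")
    expect_equal(cfg$nRows, 40L)
    expect_equal(cfg$nCols, 150L)
    expect_equal(cfg$geometry@pixelWidth, 72.6)
    expect_equal(cfg$geometry@pixelHeight, 80)
    expect_true(all(vapply(cfg$gradients, function(g) g$amplitude, 0) >= 0))
    # a target outside the acquired mass range is a config error
    expect_error(rootSimConfig(gradients = list(
        gradientSpec(metaboliteRecord("tiny", "H2O"), 10))),
        "outside acquired range")
})

test_that("simulation is deterministic per seed down to imzML bytes", {
    cfg <- defaultRootConfig(seed = 42)
    s1 <- simulateRoot(cfg)
    s2 <- simulateRoot(cfg)
    expect_identical(s1$dataset@spectra, s2$dataset@spectra)
    expect_identical(s1$truth$ticEmitted, s2$truth$ticEmitted)

    p1 <- withr::local_tempfile(fileext = ".imzML")
    p2 <- withr::local_tempfile(fileext = ".imzML")
    set.seed(1); writeImzML(s1$dataset, p1)
    set.seed(1); writeImzML(s2$dataset, p2)
    expect_identical(readBin(p1, "raw", file.size(p1)),
                     readBin(p2, "raw", file.size(p2)))
    expect_identical(readBin(sub("imzML$", "ibd", p1), "raw", 1e7),
                     readBin(sub("imzML$", "ibd", p2), "raw", 1e7))

    s3 <- simulateRoot(defaultRootConfig(seed = 43))
    expect_false(identical(s1$dataset@spectra, s3$dataset@spectra))
})

test_that("per-pixel streams are split: earlier pixels ignore grid growth", {
    # hard-edged ribbon spanning all rows, so the expected emission of a
    # pixel depends only on its column; appending raster rows must leave
    # earlier pixels' noisy draws untouched
    ribbon <- function(nr) rootSimConfig(
        nRows = nr, nCols = 30L,
        gradients = list(gradientSpec(metaboliteRecord("malate", "C4H6O5"),
                                      5000, profile = "linear")),
        tipFrac = 0.1, endFrac = 0.9, maxHalfWidthRows = 1000,
        taperFrac = 1e-6, edgeBlurSigmaUm = 0,
        mzJitterPpm = 2, noiseModel = "poisson", ticDriftSd = 0.15,
        seed = 4L)
    small <- simulateRoot(ribbon(6L))
    big <- simulateRoot(ribbon(12L))
    for (cc in c(0L, 10L, 29L))
        expect_identical(spectrumAt(small$dataset, 2, cc),
                         spectrumAt(big$dataset, 2, cc))
})

test_that("noise off and constant profiles give identical on-tissue pixels", {
    cfg <- rootSimConfig(
        nRows = 8L, nCols = 30L,
        gradients = list(gradientSpec(metaboliteRecord("malate", "C4H6O5"),
                                      1000, profile = "constant")),
        tipFrac = 0.2, endFrac = 0.9, maxHalfWidthRows = 2,
        taperFrac = 1e-6, edgeBlurSigmaUm = 0, mzJitterPpm = 0,
        noiseModel = "none", ticDriftSd = 0, seed = 1L)
    sim <- simulateRoot(cfg)
    on <- which(t(sim$truth$tissueMask))  # row-major positions
    specs <- sim$dataset@spectra[on]
    expect_true(all(vapply(specs, function(s)
        identical(s, specs[[1]]), TRUE)))
})

test_that("noiseless imaging reproduces ground truth exactly", {
    cfg <- defaultRootConfig(seed = 2, noiseModel = "none", ticDriftSd = 0,
                             mzJitterPpm = 0)
    sim <- simulateRoot(cfg)
    for (nm in c("succinate", "aconitate")) {
        img <- buildIonImage(sim$dataset, sim$truth$targets[[nm]], 5,
                             normalization = "none")
        expect_equal(intensityValues(img), sim$truth$expected[[nm]],
                     tolerance = 1e-12)
    }
})

test_that("Poisson-noise %TIC images track ground truth at r > 0.98", {
    sim <- simulateRoot(defaultRootConfig(seed = 31))
    mask <- sim$truth$tissueMask
    for (nm in c("succinate", "aconitate", "malate")) {
        img <- buildIonImage(sim$dataset, sim$truth$targets[[nm]], 5)
        truth_pct <- 100 * sim$truth$expected[[nm]] / sim$truth$ticExpected
        r <- cor(intensityValues(img)[mask], truth_pct[mask])
        expect_gt(r, 0.98)
    }
})

test_that("succinate peaks in the tip third, aconitate in the far third", {
    sim <- simulateRoot(defaultRootConfig(seed = 19))
    mask <- sim$truth$tissueMask
    f <- sim$truth$axisFrac
    colmean <- function(mz) vapply(seq_len(150L), function(cc)
        if (any(mask[, cc]))
            mean(intensityValues(buildIonImage(sim$dataset, mz,
                 5))[mask[, cc], cc]) else 0, 0)
    succ <- colmean(sim$truth$targets[["succinate"]])
    acon <- colmean(sim$truth$targets[["aconitate"]])
    expect_lt(f[which.max(succ)], 1 / 3)
    expect_gt(f[which.max(acon)], 2 / 3)
})

test_that("ground-truth succinate/aconitate ratio falls monotonically", {
    cfg <- defaultRootConfig()
    sim <- simulateRoot(cfg)
    f <- sim$truth$axisFrac
    central <- f >= 0.2 & f <= 0.8
    ratio <- (sim$truth$expected[["succinate"]] /
              sim$truth$expected[["aconitate"]])[20, central]
    expect_true(all(diff(ratio) < 0))
})

test_that("a default-sized section simulates within the runtime budget", {
    t0 <- Sys.time()
    invisible(simulateRoot(defaultRootConfig(seed = 99)))
    expect_lt(as.numeric(Sys.time() - t0, units = "secs"), 60)
})

test_that("ground truth serializes to structured text", {
    sim <- simulateRoot(defaultRootConfig(seed = 1, nRows = 5L,
                                          nCols = 20L))
    path <- withr::local_tempfile(fileext = ".json")
    writeGroundTruth(sim$truth, path)
    back <- jsonlite::read_json(path)
    expect_equal(back$seed, 1L)
    expect_equal(back$targets$succinate, 117.01933, tolerance = 1e-5)
    lens <- vapply(back$tissue_mask_rle, function(r) sum(unlist(r$lengths)),
                   0)
    expect_true(all(lens == 20))
})
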