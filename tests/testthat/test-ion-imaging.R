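test_that("pixel TIC sums the full spectrum, zero for empty pixels", {
    expect_equal(pixelTIC(spec_of(c(100, 200, 300), c(1, 2, 3))), 6)
    expect_equal(pixelTIC(spec_of(numeric(0), numeric(0))), 0)
    sim <- simulateRoot(defaultRootConfig(seed = 5))
    expect_equal(pixelTIC(sim$dataset), sim$truth$ticEmitted)
})

test_that("ppm window bounds are computed and applied inclusively", {
    sp <- spec_of(c(117.0193, 117.0300), c(50, 7))
    # +/-5 ppm at 117.0193 is a half-width of ~0.000585 Th: excludes 117.0300
    expect_equal(extractWindow(sp, 117.0193, 5), 50)
    expect_equal(extractWindow(sp, 117.0193, 100), 57)
    # a peak exactly on the window boundary is included (inclusive ends)
    lo_edge <- 117.0193 * (1 - 5e-6)
    expect_equal(extractWindow(spec_of(lo_edge, 3), 117.0193, 5), 3)
    expect_equal(extractWindow(spec_of(numeric(0), numeric(0)),
                               117.0193, 5), 0)
    # target outside the acquired range warns and returns 0
    expect_warning(v <- extractWindow(sp, 2000, 5, mzRange = c(50, 1000)),
                   "outside acquired range")
    expect_equal(v, 0)
})

test_that("binary-search extraction equals a linear-scan oracle", {
    set.seed(101)
    for (i in seq_len(1000)) {
        sp <- randomSpectrum(npeaks = sample(0:60, 1))
        target <- runif(1, 50, 1000)
        ppm <- runif(1, 0.5, 2000)
        expect_identical(extractWindow(sp, target, ppm),
                         windowOracle(sp, target, ppm))
    }
})

test_that("windows are monotone in tolerance and bounded by TIC", {
    set.seed(7)
    for (i in 1:50) {
        sp <- randomSpectrum(40)
        target <- runif(1, 50, 1000)
        a <- extractWindow(sp, target, 5)
        b <- extractWindow(sp, target, 50)
        expect_lte(a, b)
        expect_lte(b, pixelTIC(sp))
    }
})

test_that("disjoint-window %TIC values sum to at most 100 per pixel", {
    sim <- simulateRoot(defaultRootConfig(seed = 9))
    targets <- sim$truth$targets
    imgs <- lapply(targets, function(mz)
        intensityValues(buildIonImage(sim$dataset, mz, 5)))
    total <- Reduce(`+`, imgs)
    expect_true(all(total <= 100 + 1e-9))
})

test_that("uniform data gives a constant image; %TIC of the only peak is 100", {
    ds <- msiDataset(rep(list(spec_of(117.0193, 42)), 6), 2L, 3L,
                     rasterGeometry(pixelWidth = 10, pixelHeight = 10))
    raw <- buildIonImage(ds, 117.0193, 5, normalization = "none")
    expect_true(all(intensityValues(raw) == 42))
    pct <- buildIonImage(ds, 117.0193, 5, normalization = "tic_percent")
    expect_true(all(intensityValues(pct) == 100))
})

test_that("%TIC normalization cancels per-pixel intensity rescaling", {
    sim <- simulateRoot(defaultRootConfig(seed = 13))
    ds <- sim$dataset
    before <- buildIonImage(ds, 133.01424, 5)
    s <- spectrumAt(ds, 20, 80)
    ds@spectra[[20L * 150L + 81L]] <- spec_of(s$mz, s$intensity * 10)
    after <- buildIonImage(ds, 133.01424, 5)
    expect_equal(intensityValues(after)[21, 81],
                 intensityValues(before)[21, 81])
})

test_that("a programmed monotone gradient yields a monotone ion image", {
    sim <- simulateRoot(defaultRootConfig(seed = 21))
    img <- buildIonImage(sim$dataset, 173.00916, 5)  # aconitate, shankward
    mask <- sim$truth$tissueMask
    cols <- which(colSums(mask) > 0)
    cols <- cols[-c(1:3, (length(cols) - 2):length(cols))]  # clip edge blur
    colmean <- vapply(cols, function(cc)
        mean(intensityValues(img)[mask[, cc], cc]), 0)
    rho <- cor(colmean, seq_along(colmean), method = "spearman")
    expect_gt(rho, 0.9)
})

test_that("ratio images divide elementwise and mask a zero denominator", {
    den <- buildIonImage(toyDataset(2L, 2L, mz = 133.0142), 133.0142, 5,
                         normalization = "none")
    num <- den
    num@values <- den@values * 2
    ri <- ratioImage(num, den)
    expect_true(all(intensityValues(ri) == 2))
    expect_true(all(!ri@mask))

    den0 <- den
    den0@values[1, 1] <- 0
    ri0 <- ratioImage(num, den0)
    expect_true(ri0@mask[1, 1])
    expect_true(is.na(intensityValues(ri0)[1, 1]))
    expect_equal(sum(ri0@mask), 1L)

    small <- den
    small@values <- matrix(1, 3, 3)
    expect_error(ratioImage(num, small), "dimensions differ")
})

test_that("opposing gradients give a ratio profile that falls from the tip", {
    sim <- simulateRoot(defaultRootConfig(seed = 17))
    num <- buildIonImage(sim$dataset, 117.01933, 5)   # succinate, tip bump
    den <- buildIonImage(sim$dataset, 173.00916, 5)   # aconitate, shankward
    ri <- ratioImage(num, den)
    mask <- sim$truth$tissueMask
    f <- sim$truth$axisFrac
    central <- which(f >= 0.2 & f <= 0.8)
    prof <- vapply(central, function(cc) {
        v <- intensityValues(ri)[mask[, cc], cc]
        mean(v[is.finite(v)])
    }, 0)
    rho <- cor(prof, seq_along(prof), method = "spearman")
    expect_lt(rho, -0.9)
})

test_that("grids export as delimited text with a geometry header", {
    sim <- simulateRoot(rootSimConfig(
        nRows = 3L, nCols = 4L,
        gradients = list(gradientSpec(metaboliteRecord("malate", "C4H6O5"),
                                      100, profile = "constant")),
        noiseModel = "none", ticDriftSd = 0, seed = 1L))
    img <- buildIonImage(sim$dataset, 133.01424, 5, normalization = "none")
    path <- withr::local_tempfile(fileext = ".csv")
    writeGrid(img, path, geometry = geometry(sim$dataset))
    lines <- readLines(path)
    expect_match(lines[1], "rows=3 cols=4")
    expect_match(lines[2], "pixel_width_um=72.6")
    parsed <- do.call(rbind, lapply(lines[-(1:2)], function(l)
        as.numeric(strsplit(l, ",")[[1]])))
    expect_equal(parsed, unname(intensityValues(img)), tolerance = 1e-12)
})
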