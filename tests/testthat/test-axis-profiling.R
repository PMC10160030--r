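test_that("band sampling: constant images give constant profiles", {
    m <- matrix(3.5, 20, 50)
    line <- profileLine(c(10, 2), c(10, 47), bandWidthPx = 10)
    prof <- sampleBand(m, line)
    expect_true(all(prof$values == 3.5))
    expect_equal(length(prof$values), line$nSamples)
})

test_that("band sampling along a column-aligned line recovers row structure", {
    # image varies only by row; a vertical line's band averages identical
    # columns, so the profile equals the row values
    m <- matrix(rep(1:20, times = 10), 20, 10)
    line <- profileLine(c(0, 5), c(19, 5), bandWidthPx = 4, nSamples = 20)
    prof <- sampleBand(m, line)
    expect_equal(prof$values, as.numeric(1:20))
})

test_that("bands truncated at the image border raise a warning", {
    m <- matrix(1, 10, 30)
    line <- profileLine(c(0.5, 2), c(0.5, 27), bandWidthPx = 10)
    expect_warning(sampleBand(m, line), "truncated band")
    expect_error(sampleBand(m, profileLine(c(5, -10), c(5, 50))),
                 "outside image bounds")
})

test_that("scaling to the maximum behaves and rejects all-zero profiles", {
    expect_equal(scaleToMax(c(1, 2, 4)), c(0.25, 0.5, 1))
    expect_equal(scaleToMax(5), 1)
    v <- c(0.2, 0.9, 0.4)
    expect_equal(scaleToMax(scaleToMax(v)), scaleToMax(v))
    expect_error(scaleToMax(c(0, 0)), "all-zero")
})

test_that("aggregation computes pointwise mean and sample sd (n - 1)", {
    two <- aggregateProfiles(list(c(1, 2, 4), c(1, 2, 4)))
    expect_true(all(two@sd == 0))
    expect_equal(two@mean, c(0.25, 0.5, 1))

    mixed <- aggregateProfiles(list(c(0, 1), c(1, 0)))
    expect_equal(mixed@mean, c(0.5, 0.5))
    expect_equal(mixed@sd, rep(sqrt(0.5), 2), tolerance = 1e-12)

    expect_error(aggregateProfiles(list(c(1, 2))), "at least 2 sections")
})

test_that("sd across noisy sections sits in the sampling envelope", {
    set.seed(33)
    sigma <- 0.05
    base <- seq(0.2, 0.9, length.out = 40)
    secs <- lapply(1:10, function(i) base + rnorm(40, 0, sigma))
    prof <- aggregateProfiles(lapply(secs, abs))
    # per-section max-scaling shrinks sigma by roughly the max; allow the
    # spec'd factor-of-1.5 envelope around the programmed noise level
    expect_gt(mean(prof@sd), 0.5 * sigma / max(base))
    expect_lt(mean(prof@sd), 1.5 * sigma)
})

test_that("profiles are invariant under global image rescaling", {
    sim <- simulateRoot(defaultRootConfig(seed = 23))
    img <- intensityValues(buildIonImage(sim$dataset, 117.01933, 5))
    line <- profileLine(c(19.5, 12), c(19.5, 140), bandWidthPx = 10)
    p1 <- scaleToMax(sampleBand(img, line)$values)
    p2 <- scaleToMax(sampleBand(img * 37.5, line)$values)
    expect_equal(p1, p2, tolerance = 1e-12)
})

test_that("a logistic gradient's midpoint is recovered within 2 pixels", {
    cfg <- defaultRootConfig(seed = 3, noiseModel = "none", ticDriftSd = 0,
                             mzJitterPpm = 0)
    sim <- simulateRoot(cfg)
    img <- buildIonImage(sim$dataset, 173.00916, 5, normalization = "none")
    line <- profileLine(c(19.5, 0), c(19.5, 149), bandWidthPx = 10,
                        nSamples = 150L)
    prof <- sampleBand(img, line)
    v <- prof$values / max(prof$values)
    # aconitate: logistic centered at axis fraction 0.5, rising shankward
    half <- (min(v[30:140]) + max(v)) / 2
    crossing <- which(v >= half)[1]
    pw <- geometry(sim$dataset)@pixelWidth
    x_cross <- prof$distances_px[crossing] * pw
    x_tip <- cfg$tipFrac * 149 * pw
    x_end <- cfg$endFrac * 149 * pw
    x_true <- x_tip + 0.5 * (x_end - x_tip)
    expect_lt(abs(x_cross - x_true), 2 * pw)
})

test_that("identical groups give t = 0 and p = 1 everywhere", {
    sec <- matrix(runif(50, 0.2, 0.9), 5, 10)
    a <- axisProfileFromMatrix(sec)
    b <- axisProfileFromMatrix(sec)
    cmp <- compareProfiles(a, b)
    expect_true(all(cmp$t == 0))
    expect_true(all(cmp$p == 1))
    expect_true(all(!cmp$significant))
})

test_that("per-position t and p agree with stats::t.test", {
    set.seed(55)
    A <- matrix(runif(60, 0.1, 1), 6, 10)
    B <- matrix(runif(80, 0.1, 1), 8, 10)
    cmp <- compareProfiles(axisProfileFromMatrix(A), axisProfileFromMatrix(B))
    for (j in c(1, 4, 10)) {
        tt <- t.test(A[, j], B[, j], var.equal = TRUE)
        expect_equal(cmp$t[j], unname(tt$statistic), tolerance = 1e-12)
        expect_equal(cmp$p[j], tt$p.value, tolerance = 1e-12)
    }
})

test_that("a five-sigma mean gap is flagged at nearly every position", {
    set.seed(77)
    n <- 10L; P <- 40L; sigma <- 0.05
    A <- matrix(pmin(pmax(rnorm(n * P, 0.40, sigma), 0), 1), n, P)
    B <- matrix(pmin(pmax(rnorm(n * P, 0.65, sigma), 0), 1), n, P)
    cmp <- compareProfiles(axisProfileFromMatrix(A), axisProfileFromMatrix(B))
    expect_gte(mean(cmp$significant), 0.95)
})

test_that("zero-variance unequal groups yield p near 0 without errors", {
    A <- matrix(0.3, 4, 5)
    B <- matrix(0.7, 4, 5)
    cmp <- compareProfiles(axisProfileFromMatrix(A), axisProfileFromMatrix(B))
    expect_true(all(is.infinite(cmp$t)))
    expect_true(all(cmp$p == 0))
    expect_true(all(cmp$significant))
})

test_that("profiles on different grids are rejected; Bonferroni shrinks hits", {
    A <- matrix(runif(40, 0.3, 1), 4, 10)
    B <- matrix(runif(40, 0.3, 1), 4, 10)
    a <- axisProfileFromMatrix(A)
    b <- axisProfileFromMatrix(B, distances = seq_len(10) * 99)
    expect_error(compareProfiles(a, b), "different distance grids")
    b2 <- axisProfileFromMatrix(B)
    raw <- compareProfiles(a, b2)
    adj <- compareProfiles(a, b2, correction = "bonferroni")
    expect_true(all(adj$p >= raw$p))
})
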