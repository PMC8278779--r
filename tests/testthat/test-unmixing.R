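test_that("noise-free nonnegative mixtures are recovered exactly", {
    bases <- defaultBasisSet()
    w <- c(SHG = 0.21, NADH = 0.47, KERATIN = 1.3, MELANIN = 0.65)
    fit <- nnlsUnmix(composeSpectrum(w, bases), bases)
    expect_true(all(abs(fit$weights - w) / w < 1e-6))
    expect_lt(fit$residualNorm, 1e-8)
    ## the same holds after smoothing, against smoothed bases
    fitSm <- nnlsUnmix(smoothSpectra(composeSpectrum(w, bases), 40), bases)
    expect_true(all(abs(fitSm$weights - w) / w < 1e-6))
})

test_that("the zero spectrum unmixes to zero weights and residual", {
    fit <- nnlsUnmix(Spectrum(makeDefaultGrid(), numeric(301)))
    expect_true(all(fit$weights == 0))
    expect_equal(fit$residualNorm, 0)
})

test_that("NNLS matches the exhaustive grid-search oracle on toy instances", {
    bases <- defaultBasisSet()
    B <- vapply(bases, intensities, numeric(301))
    for (seed in 1:3) {
        set.seed(seed)
        wTrue <- round(stats::runif(4, 0, 0.2), 2)  # on the oracle grid
        names(wTrue) <- names(bases)
        y <- as.numeric(B %*% wTrue) +
            stats::rnorm(301, sd = 0.005)  # slight perturbation
        y[y < 0] <- 0
        oracle <- gridSearchUnmix(y, B, step = 0.01, upper = 0.25)
        fit <- nnlsUnmix(Spectrum(makeDefaultGrid(), y), bases)
        expect_true(all(abs(fit$weights - oracle) <= 0.01))
    }
})

test_that("the NNLS objective beats random nonnegative weight vectors", {
    bases <- defaultBasisSet()
    B <- vapply(bases, intensities, numeric(301))
    scan <- generateLesion(lesionRecipe("SK", nSpectra = 1, seed = 44))
    y <- intensityMatrix(scan)[, 1]
    fit <- nnlsUnmix(getSpectrum(scan, 1), bases)
    best <- sum((y - as.numeric(B %*% fit$weights))^2)
    set.seed(9)
    for (i in 1:1000) {
        w <- stats::runif(4, 0, 3000)
        expect_lte(best, sum((y - as.numeric(B %*% w))^2))
    }
})

test_that("a spectrum minus itself is exactly zero", {
    for (seed in c(5, 50)) {
        scan <- generateLesion(lesionRecipe("CM", nSpectra = 1,
                                            seed = seed))
        sp <- getSpectrum(scan, 1)
        d <- differenceSpectrum(sp, sp)
        expect_true(all(d@intensities == 0))
        expect_identical(stage(d), "difference")
    }
})

test_that("the SK-minus-hyperkeratotic difference exposes NAD(P)H and melanin", {
    d <- differenceSpectrum(composeTemplate("SK"),
                            composeTemplate("HYPERKERATOTIC"))
    wl <- wavelengths(d)
    peakBlue <- peakWavelength(d, c(380, 500))
    expect_gte(peakBlue, 430); expect_lte(peakBlue, 460)
    melExcess <- mean(intensities(d)[wl >= 530 & wl <= 650])
    shgExcess <- mean(intensities(d)[wl >= 395 & wl <= 405])
    expect_gt(melExcess, shgExcess)
})

test_that("unmixing the SK template ranks keratin above NAD(P)H above SHG", {
    fit <- nnlsUnmix(smoothSpectra(composeTemplate("SK"), 40))
    w <- fit$weights
    expect_gt(w[["KERATIN"]], w[["NADH"]])
    expect_gt(w[["NADH"]], w[["SHG"]])
})

test_that("peak localization reads band maxima with a shortest-wavelength tie rule", {
    bases <- defaultBasisSet()
    expect_equal(peakWavelength(composeSpectrum(c(KERATIN = 1), bases),
                                c(430, 520)), 470)
    expect_equal(peakWavelength(composeSpectrum(c(NADH = 1), bases),
                                c(430, 520)), 450)
    y <- numeric(301); y[c(50, 80)] <- 2  # equal maxima at 429 and 459
    sp <- Spectrum(makeDefaultGrid(), y)
    expect_equal(peakWavelength(sp, c(400, 500)), 429)
    expect_error(peakWavelength(Spectrum(makeDefaultGrid(), numeric(301)),
                                c(430, 520)), "zero")
})
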