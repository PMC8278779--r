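grid301 <- makeDefaultGrid()

test_that("moving-average smoothing has the documented window conventions", {
    const <- Spectrum(grid301, rep(4.2, 301))
    expect_equal(intensities(smoothSpectra(const, 40)), rep(4.2, 301))
    ## span 1 is the identity
    sp <- generateLesion(lesionRecipe("SK", nSpectra = 1, seed = 3))
    one <- getSpectrum(sp, 1)
    expect_equal(intensities(smoothSpectra(one, 1)), intensities(one))
    ## unit impulse, span 40 -> symmetrized 41-point window of value 1/41
    y <- numeric(301); y[150] <- 1
    sm <- intensities(smoothSpectra(Spectrum(grid301, y), 40))
    expect_equal(sm[130:170], rep(1 / 41, 41))
    expect_equal(sm[c(129, 171)], c(0, 0))
    expect_error(smoothSpectra(Spectrum(grid301, y), 302), "span")
})

test_that("smoothing preserves mass away from edges and never creates negatives", {
    ## interior-mass preservation holds for broad-band spectra; a narrow
    ## line within one window of the interior boundary (the nevus SHG line
    ## at 400 nm) necessarily leaks mass across it
    for (phenotype in c("CM", "SK", "BACKGROUND")) {
        scan <- singleTypeScan(phenotype, nSpectra = 5, seed = 3)
        sm <- smoothSpectra(scan, 40)
        expect_true(all(intensityMatrix(sm) >= 0))
        interior <- 41:260  # full 41-point windows only
        raw <- colSums(intensityMatrix(scan)[interior, ])
        smo <- colSums(intensityMatrix(sm)[interior, ])
        expect_true(all(abs(smo - raw) / raw < 0.005))
    }
})

test_that("SNR is zero for empty spectra, huge for noise-free templates", {
    cfg <- preprocessConfig()
    expect_equal(estimateSnr(Spectrum(grid301, numeric(301))), 0)
    snrSK <- estimateSnr(composeTemplate("SK"))
    expect_gt(snrSK, cfg$snrThreshold)
    ## a flat positive spectrum has no smoothing residual at all
    expect_equal(estimateSnr(Spectrum(grid301, rep(1, 301))), Inf)
})

test_that("SNR filtering partitions every scan exhaustively and disjointly", {
    cfg <- preprocessConfig()
    for (seed in c(2, 12)) {
        scan <- generateLesion(lesionRecipe("SK", nSpectra = 200,
                                            seed = seed))
        parts <- filterLowSnr(scan, cfg)
        expect_equal(nSpectra(parts$accepted) + nSpectra(parts$rejected),
                     nSpectra(scan))
        expect_setequal(c(spectrumIds(parts$accepted),
                          spectrumIds(parts$rejected)),
                        spectrumIds(scan))
        ## order preserved within each part
        expect_identical(spectrumIds(parts$accepted),
                         spectrumIds(scan)[cfg$snrThreshold <= parts$snr])
    }
})

test_that("noise-free scans lose nothing; pure low-SNR scans lose everything", {
    tplScan <- LesionScan(grid301,
                          cbind(intensities(composeTemplate("SK")),
                                intensities(composeTemplate("CM"))),
                          lesionId = "templates")
    parts <- filterLowSnr(tplScan)
    expect_equal(nSpectra(parts$rejected), 0L)
    low <- generateLesion(lesionRecipe("SK", nSpectra = 30,
                                       lowSnrFraction = 1, seed = 6))
    parts <- filterLowSnr(low)
    expect_equal(nSpectra(parts$accepted), 0L)
})

test_that("normalization scales the band maximum to one and is idempotent", {
    sp <- smoothSpectra(composeTemplate("SK"), 40)
    nz <- normalizeSpectra(sp)
    expect_equal(max(intensities(nz)), 1)
    expect_equal(intensities(normalizeSpectra(nz)), intensities(nz))
    expect_identical(stage(nz), "normalized")
    expect_error(normalizeSpectra(Spectrum(grid301, numeric(301))),
                 "positive")
})
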