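test_that("the SHG basis line sits at half the excitation wavelength", {
    b <- basisSHG(800, 5)
    expect_equal(peakNm(b), 400)
    wl <- wavelengths(b)
    expect_equal(wl[which.max(intensities(b))], 400)
    expect_equal(peakNm(basisSHG(760, 5)), 380)
    ## 15 sigma away the line has decayed to numerical nothing
    expect_lt(intensities(b)[wl == 475], 1e-6 * max(intensities(b)))
    expect_error(basisSHG(1500, 5), "outside")
})

test_that("Gaussian bases peak where the reference measurements place them", {
    nadh <- basisGaussian("NADH", 450, 75)
    ker <- basisGaussian("KERATIN", 470, 120)
    wl <- wavelengths(nadh)
    expect_equal(wl[which.max(intensities(nadh))], 450)
    expect_equal(wl[which.max(intensities(ker))], 470)
    ## symmetry about the peak
    for (d in c(5, 20, 60))
        expect_equal(intensities(nadh)[wl == 450 - d],
                     intensities(nadh)[wl == 450 + d])
})

test_that("the melanin tail rises monotonically to 1 at the grid end", {
    mel <- basisMelanin()
    wl <- wavelengths(mel)
    v <- intensities(mel)
    expect_equal(v[wl == 680], 1)
    band <- v[wl >= 430 & wl <= 650]
    expect_true(all(diff(band) > 0))
    expect_lt(v[wl == 400], v[wl == 650])
})

test_that("all bases are nonnegative and unit-max", {
    for (b in defaultBasisSet()) {
        expect_true(all(intensities(b) >= 0))
        expect_equal(max(intensities(b)), 1)
    }
})

test_that("composition is exactly linear in the weights", {
    bases <- defaultBasisSet()
    zero <- composeSpectrum(c(SHG = 0, NADH = 0, KERATIN = 0, MELANIN = 0),
                            bases)
    expect_true(all(intensities(zero) == 0))
    ## unit weight on one basis reproduces that basis
    expect_equal(intensities(composeSpectrum(c(KERATIN = 1), bases)),
                 intensities(bases$KERATIN))
    w1 <- c(SHG = 0.2, NADH = 0.4, KERATIN = 0.9, MELANIN = 0.1)
    w2 <- c(SHG = 0.05, NADH = 0.3, KERATIN = 0.2, MELANIN = 0.7)
    expect_equal(intensities(composeSpectrum(w1, bases)) +
                     intensities(composeSpectrum(w2, bases)),
                 intensities(composeSpectrum(w1 + w2, bases)))
    expect_error(composeSpectrum(c(KERATIN = -1), bases), "nonnegative")
})

test_that("phenotype templates satisfy their printed constraints", {
    expect_equal(peakWavelength(composeTemplate("SK"), c(430, 520)), 475)
    expect_equal(peakWavelength(composeTemplate("PURE_NADH"), c(430, 520)),
                 450)
    expect_equal(peakWavelength(composeTemplate("PURE_KERATIN"),
                                c(430, 520)), 470)
    hk <- peakWavelength(composeTemplate("HYPERKERATOTIC"), c(430, 520))
    expect_gte(hk, 460); expect_lte(hk, 490)
    ## nevus: SHG band is the global maximum of the template
    nev <- composeTemplate("NEVUS")
    expect_equal(peakWavelength(nev), 400)
    expect_error(composeTemplate("BASAL_CELL"), "unknown phenotype")
})

test_that("the SK blue band is about ten times the nevus blue band and dominates the nevus red band", {
    wl <- wavelengths(makeDefaultGrid())
    blue <- wl >= 450 & wl <= 490
    red <- wl >= 550 & wl <= 650
    sk <- intensities(composeTemplate("SK"))
    nev <- intensities(composeTemplate("NEVUS"))
    ratio <- mean(sk[blue]) / mean(nev[blue])
    expect_lte(ratio, 10 + 1e-6)
    expect_gte(ratio, 9)
    expect_gte(mean(sk[blue]), 5 * mean(nev[red]))
})

test_that("the documented melanin-weight search reproduces the frozen SK constant", {
    w <- calibrateSkMelaninWeight()
    expect_lt(abs(w - templateWeights("SK")[["MELANIN"]]), 1e-3)
    ## and the calibrated composite indeed peaks at 475 nm
    sp <- composeSpectrum(c(SHG = 0.03, NADH = 0.05, KERATIN = 1,
                            MELANIN = w))
    expect_equal(peakWavelength(sp, c(430, 520)), 475)
})

test_that("templates cross the classification rules consistently", {
    ## CM passes the monotonicity rule; SK and nevus fail it
    thr <- typingThresholds()
    fCM <- templateFeatures("CM")
    fSK <- templateFeatures("SK")
    fNV <- templateFeatures("NEVUS")
    expect_gte(fCM$monotonicity, thr$monotonicityMin)
    expect_lt(fSK$monotonicity, thr$monotonicityMin)
    expect_lt(fNV$monotonicity, thr$monotonicityMin)
})
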