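test_that("template features carry the published spectral signatures", {
    fNV <- templateFeatures("NEVUS")
    expect_gt(fNV$shg_band, fNV$blue_band)
    expect_gt(fNV$shg_band, fNV$red_band)
    fCM <- templateFeatures("CM")
    expect_equal(fCM$monotonicity, 1.0)
    fSK <- templateFeatures("SK")
    expect_equal(fSK$peak_nm, 475)
    ## melanoma suppresses the SHG line relative to nevus
    expect_lt(fCM$shg_band, fNV$shg_band)
})

test_that("feature extraction refuses non-normalized input", {
    expect_error(extractFeatures(composeTemplate("SK")), "normalized")
})

test_that("the rule backend types the three phenotype templates correctly", {
    expect_identical(classifyRule(templateFeatures("SK")), "SK_TYPE")
    expect_identical(classifyRule(templateFeatures("CM")), "CM_TYPE")
    expect_identical(classifyRule(templateFeatures("NEVUS")), "NEVUS_TYPE")
    expect_identical(classifyRule(templateFeatures("BACKGROUND")),
                     "UNINFORMATIVE")
})

test_that("a featureless flat spectrum is uninformative", {
    flat <- data.frame(shg_band = 1, blue_band = 1, red_band = 1,
                       monotonicity = 0, peak_nm = 430)
    expect_identical(classifyRule(flat), "UNINFORMATIVE")
})

test_that("classification is invariant under positive rescaling of a spectrum", {
    base <- composeTemplate("SK")
    f1 <- extractFeatures(normalizeSpectra(smoothSpectra(base, 40)))
    for (c in c(0.01, 3, 1e4)) {
        scaled <- Spectrum(base@grid, c * intensities(base))
        f2 <- extractFeatures(normalizeSpectra(smoothSpectra(scaled, 40)))
        expect_equal(f2[, 1:5], f1[, 1:5])
    }
})

test_that("only the melanoma type is malignancy evidence", {
    expect_identical(
        isMalignantType(c("CM_TYPE", "SK_TYPE", "NEVUS_TYPE",
                          "UNINFORMATIVE")),
        c(TRUE, FALSE, FALSE, FALSE))
    expect_error(isMalignantType("REJECTED_LOW_SNR"), "rejected")
    expect_error(isMalignantType("SOMETHING"), "unknown")
})

test_that("the surrogate classifier separates the classes and needs balanced data", {
    tr <- labeledFeatureSet(100, seed = 300)
    model <- trainSurrogate(tr$features, tr$labels, seed = 1)
    ## noise-free templates are classified perfectly
    for (p in c("SK", "CM", "NEVUS")) {
        expected <- paste0(p, "_TYPE")
        expect_identical(predictSurrogate(model, templateFeatures(p)),
                         expected)
    }
    expect_error(trainSurrogate(tr$features[1:120, ], tr$labels[1:120]),
                 "50")
})

test_that("permuted labels carry no information: accuracy drops to chance", {
    tr <- labeledFeatureSet(100, seed = 310)
    te <- labeledFeatureSet(100, seed = 320)
    set.seed(1)
    model <- trainSurrogate(tr$features, sample(tr$labels), seed = 1)
    ## predictions are independent of labels drawn from the null, so the
    ## match rate against permuted held-out labels is binomial at 1/K
    acc <- mean(predictSurrogate(model, te$features) == sample(te$labels))
    expect_lt(abs(acc - 0.25), 3 * sqrt(0.25 * 0.75 / 400))
})

test_that("rule and surrogate backends agree on default-noise spectra", {
    tr <- labeledFeatureSet(100, seed = 330)
    te <- labeledFeatureSet(100, seed = 340)
    model <- trainSurrogate(tr$features, tr$labels, seed = 1)
    agree <- mean(predictSurrogate(model, te$features) ==
                      classifyRule(te$features))
    expect_gte(agree, 0.9)
})
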