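test_that("decision accuracy percentages recompute from counts", {
    decisions <- c(rep("BENIGN", 27), "MALIGNANT", rep("BENIGN", 5))
    truths <- c(rep("SK", 28), rep("NEVUS", 5))
    conf <- confusionCounts(decisions, truths)
    sk <- conf$table[conf$table$diagnosis == "SK", ]
    expect_equal(sk$correct, 27)
    expect_equal(sk$correct_pct, 96.4)
    nv <- conf$table[conf$table$diagnosis == "NEVUS", ]
    expect_equal(nv$correct_pct, 100)
    ## 32 of 33 correct overall
    expect_equal(round(100 * sum(conf$table$correct) /
                           sum(conf$table$n), 1), 97.0)
    expect_equal(conf$specificity, 32 / 33)
    expect_error(confusionCounts("BENIGN", c("SK", "CM")), "length")
})

test_that("the mean-score interval matches the closed-form t computation", {
    ci <- meanScoreCI(c(10, 20), level = 0.95)
    half <- stats::qt(0.975, df = 1) * stats::sd(c(10, 20)) / sqrt(2)
    expect_equal(unname(ci), c(15, 15 - half, 15 + half))
    ## identical scores give a zero-width interval
    ci0 <- meanScoreCI(rep(14.4, 6))
    expect_equal(unname(ci0), rep(14.4, 3))
    ## interval always contains the mean
    set.seed(31)
    for (i in 1:20) {
        s <- stats::runif(sample(2:40, 1), 0, 100)
        ci <- meanScoreCI(s)
        expect_lte(ci["lower"], ci["mean"])
        expect_gte(ci["upper"], ci["mean"])
    }
    expect_error(meanScoreCI(5), "at least 2")
})

test_that("dominant-type assignment ignores rejected and uninformative spectra and reports ties", {
    expect_identical(dominantSpectralType(
        c("SK_TYPE", "SK_TYPE", "UNINFORMATIVE", "CM_TYPE")), "SK_TYPE")
    expect_identical(dominantSpectralType(c("SK_TYPE", "CM_TYPE")),
                     "NO_DOMINANT")
    expect_identical(dominantSpectralType(rep("UNINFORMATIVE", 5)),
                     "NO_DOMINANT")
})

test_that("the spectral-type table partitions the cohort", {
    doms <- c(rep("SK_TYPE", 4), "CM_TYPE", rep("NEVUS_TYPE", 2),
              "NO_DOMINANT")
    truths <- c(rep("SK", 5), rep("NEVUS", 2), "CM")
    tab <- spectralTypeTable(doms, truths)
    expect_equal(unname(rowSums(tab)), c(5L, 2L, 1L))
    expect_equal(tab["SK", "SK_TYPE"], 4L)
    ## pure-template lesions give a diagonal table
    tab2 <- spectralTypeTable(c("SK_TYPE", "NEVUS_TYPE", "CM_TYPE"),
                              c("SK", "NEVUS", "CM"))
    expect_equal(unname(diag(tab2[c("SK", "NEVUS", "CM"),
                                  c("SK_TYPE", "NEVUS_TYPE", "CM_TYPE")])),
                 c(1L, 1L, 1L))
})

test_that("a small seeded cohort evaluates with coherent bookkeeping", {
    cohort <- generateCohort(cohortRecipe(nSk = 4, nNevus = 2, nCm = 3,
                                          nSpectra = 120, seed = 77))
    ev <- evaluateCohort(cohort)
    expect_equal(nrow(ev$lesions), 9L)
    expect_equal(unname(rowSums(ev$typeTable)), c(4L, 2L, 3L))
    expect_true(all(ev$lesions$n_classified ==
                        ev$lesions$n_total - ev$lesions$n_rejected))
    ## single-lesion groups get a bare mean, larger groups a full CI
    expect_named(ev$meanScores$SK, c("mean", "lower", "upper"))
})
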