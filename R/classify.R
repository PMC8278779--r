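## Per-spectrum feature extraction and spectral-type assignment: a
## rule-based primary backend and a trainable linear-SVM surrogate.

.FEATURE_NAMES <- c("shg_band", "blue_band", "red_band", "monotonicity",
                    "peak_nm")

#' Classification thresholds of the rule-based backend
#'
#' Cut points on the spectral features; all calibrated once so that each of
#' the three noise-free phenotype templates is classified correctly with
#' margin against default-level noise.
#'
#' @param shgHigh minimum normalized SHG-band intensity for a
#'   nevus-dominant SHG line (default 0.75).
#' @param shgLow maximum SHG-band intensity regarded as suppressed
#'   (default 0.45).
#' @param blueDominance minimum blue/red band ratio for the SK type
#'   (default 1.5).
#' @param monotonicityMin minimum Spearman monotonicity for the CM type
#'   (default 0.95).
#' @return A list of class `"TypingThresholds"`.
#' @export
typingThresholds <- function(shgHigh = 0.75, shgLow = 0.45,
                             blueDominance = 1.5, monotonicityMin = 0.95) {
    stopifnot(shgHigh > 0, shgLow > 0, shgLow < shgHigh,
              blueDominance > 0, monotonicityMin > 0)
    structure(list(shgHigh = shgHigh, shgLow = shgLow,
                   blueDominance = blueDominance,
                   monotonicityMin = monotonicityMin),
              class = "TypingThresholds")
}

## Features from a matrix of smoothed+normalized intensities (columns =
## spectra).
.featureMatrix <- function(y, wl) {
    shgIdx  <- .bandIndex(wl, c(395, 405))
    blueIdx <- .bandIndex(wl, c(450, 490))
    redIdx  <- .bandIndex(wl, c(550, 650))
    monoIdx <- .bandIndex(wl, c(430, 650))
    peakIdx <- .bandIndex(wl, c(430, 520))
    mono <- apply(y[monoIdx, , drop = FALSE], 2L, function(v) {
        if (stats::sd(v) == 0) return(0)
        stats::cor(v, wl[monoIdx], method = "spearman")
    })
    data.frame(
        shg_band  = colMeans(y[shgIdx, , drop = FALSE]),
        blue_band = colMeans(y[blueIdx, , drop = FALSE]),
        red_band  = colMeans(y[redIdx, , drop = FALSE]),
        monotonicity = mono,
        peak_nm = wl[peakIdx][apply(y[peakIdx, , drop = FALSE], 2L,
                                    which.max)],
        row.names = NULL)
}

#' Extract spectral-type features
#'
#' The features the classification is based on, computed from smoothed,
#' normalized spectra: mean normalized intensity in the SHG band
#' (395--405 nm), the blue band (450--490 nm) and the red band
#' (550--650 nm); the Spearman rank correlation of intensity versus
#' wavelength over 430--650 nm (`monotonicity`); and the peak wavelength
#' over 430--520 nm.
#'
#' @param x a `stage = "normalized"` [Spectrum-class] or
#'   [LesionScan-class] (all spectra normalized).
#' @param snr optional SNR value(s) carried along as a column.
#' @return A `data.frame`, one row per spectrum.
#' @export
setGeneric("extractFeatures",
    function(x, snr = NULL) standardGeneric("extractFeatures"))

#' @rdname extractFeatures
#' @export
setMethod("extractFeatures", "Spectrum", function(x, snr = NULL) {
    if (stage(x) != "normalized")
        stop("extractFeatures expects a normalized spectrum")
    f <- .featureMatrix(matrix(intensities(x), ncol = 1), wavelengths(x))
    f$spectrum_id <- spectrumId(x)
    if (!is.null(snr)) f$snr <- snr
    f
})

#' @rdname extractFeatures
#' @export
setMethod("extractFeatures", "LesionScan", function(x, snr = NULL) {
    if (!all(stage(x) == "normalized"))
        stop("extractFeatures expects a fully normalized scan")
    f <- .featureMatrix(assay(x, "intensity"), wavelengths(x))
    f$spectrum_id <- spectrumIds(x)
    if (!is.null(snr)) f$snr <- snr
    f
})

#' Rule-based spectral-type assignment
#'
#' Rules are evaluated in order, first match wins:
#' \enumerate{
#'   \item `NEVUS_TYPE` --- dominant SHG line
#'     (`shg_band >= shgHigh` and `shg_band > blue_band`, the line being
#'     the spectral maximum) without blue dominance
#'     (`blue_band/red_band < blueDominance`);
#'   \item `SK_TYPE` --- suppressed SHG (`shg_band <= shgLow`), blue
#'     dominance (`blue_band/red_band >= blueDominance`) and a peak in
#'     450--490 nm;
#'   \item `CM_TYPE` --- monotone rise over 430--650 nm
#'     (`monotonicity >= monotonicityMin`) with suppressed SHG;
#'   \item `UNINFORMATIVE` otherwise.
#' }
#' The nevus rule comes first because an intense second-harmonic line
#' (intact dermal collagen reached by the focus) is the clearest single
#' discriminator.
#'
#' @param features data.frame from [extractFeatures()] (accepted spectra
#'   only).
#' @param thresholds a [typingThresholds()].
#' @return Character vector of spectral types, one per feature row.
#' @export
classifyRule <- function(features, thresholds = typingThresholds()) {
    ratio <- ifelse(features$red_band > 0,
                    features$blue_band / features$red_band, Inf)
    type <- rep("UNINFORMATIVE", nrow(features))
    r3 <- features$monotonicity >= thresholds$monotonicityMin &
          features$shg_band <= thresholds$shgLow
    type[r3] <- "CM_TYPE"
    r2 <- features$shg_band <= thresholds$shgLow &
          ratio >= thresholds$blueDominance &
          features$peak_nm >= 450 & features$peak_nm <= 490
    type[r2] <- "SK_TYPE"
    r1 <- features$shg_band >= thresholds$shgHigh &
          features$shg_band > features$blue_band &
          ratio < thresholds$blueDominance
    type[r1] <- "NEVUS_TYPE"
    type
}

#' Does a spectral type count as malignancy evidence?
#'
#' Only `CM_TYPE` spectra contribute to the lesion score.  Rejected spectra
#' must not reach this predicate.
#'
#' @param type character vector of spectral types.
#' @return Logical vector, `TRUE` iff `CM_TYPE`.
#' @export
isMalignantType <- function(type) {
    if (any(type == "REJECTED_LOW_SNR"))
        stop("rejected spectra carry no malignancy evidence")
    if (!all(type %in% spectralTypes()))
        stop("unknown spectral type")
    type == "CM_TYPE"
}

#' Classify all spectra of an accepted scan
#'
#' Convenience chain: smooth, normalize, extract features and classify with
#' either the rule-based backend or a trained surrogate model.  The input
#' scan must already have passed SNR filtering (see [filterLowSnr()]).
#'
#' @param scan a raw [LesionScan-class] of accepted spectra.
#' @param config a [preprocessConfig()].
#' @param thresholds a [typingThresholds()] (rule backend).
#' @param backend `"rule"` or `"surrogate"`.
#' @param model a [SurrogateModel-class], required for the surrogate
#'   backend.
#' @return A `data.frame` with the features, `assigned_type` and
#'   `malignant` per spectrum.
#' @export
classifyScan <- function(scan, config = preprocessConfig(),
                         thresholds = typingThresholds(),
                         backend = c("rule", "surrogate"), model = NULL) {
    backend <- match.arg(backend)
    sm <- smoothSpectra(scan, config$smoothingSpan)
    nz <- normalizeSpectra(sm, config$normalizationBand)
    feats <- extractFeatures(nz)
    feats$assigned_type <- if (backend == "rule") {
        classifyRule(feats, thresholds)
    } else {
        if (is.null(model)) stop("surrogate backend requires a model")
        predictSurrogate(model, feats)
    }
    feats$malignant <- isMalignantType(feats$assigned_type)
    feats
}

#' Train the surrogate margin classifier
#'
#' Fits a linear support-vector machine on spectral features with generator
#' truth labels --- a stand-in for the device's certified classifier, whose
#' trained weights are unavailable.  Deterministic given data and seed.
#'
#' @param features data.frame from [extractFeatures()].
#' @param labels character vector of true spectral types (one per row); at
#'   least 50 per class.
#' @param cost SVM cost parameter.
#' @param seed RNG seed (libsvm cross-validation is unused, but the seed
#'   pins any tie-breaking).
#' @return A [SurrogateModel-class].
#' @importFrom e1071 svm
#' @export
trainSurrogate <- function(features, labels, cost = 10, seed = 1) {
    labels <- factor(labels)
    counts <- table(labels)
    if (length(counts) < 2L)
        stop("need at least two classes")
    if (any(counts < 50L))
        stop("need at least 50 spectra per class; short: ",
             paste(names(counts)[counts < 50L], collapse = ", "))
    x <- as.matrix(features[, .FEATURE_NAMES])
    fit <- .withSeed(seed,
        e1071::svm(x = x, y = labels, kernel = "linear", cost = cost,
                   scale = TRUE))
    new("SurrogateModel", fit = fit, featureNames = .FEATURE_NAMES,
        classLevels = levels(labels))
}

#' Predict spectral types with a surrogate model
#'
#' @param model a [SurrogateModel-class].
#' @param features data.frame from [extractFeatures()].
#' @return Character vector of predicted spectral types.
#' @export
predictSurrogate <- function(model, features) {
    x <- as.matrix(features[, model@featureNames])
    as.character(stats::predict(model@fit, x))
}
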