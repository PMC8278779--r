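## Lesion-level scoring: the 0-100 score and the strict >28 excision rule.

#' Excision decision from a lesion score
#'
#' The decision is `"MALIGNANT"` iff the score is strictly greater than the
#' cut-off: a score of exactly 28 is benign, 28.01 is malignant.  The
#' default cut-off of 28 is the device's certified threshold.
#'
#' @param score lesion score(s) in \[0, 100\].
#' @param cutoff decision threshold, default 28.
#' @return Character vector, `"MALIGNANT"` or `"BENIGN"`.
#' @examples
#' decideMalignancy(c(14.4, 28, 33))
#' @export
decideMalignancy <- function(score, cutoff = 28) {
    if (any(score < 0 | score > 100)) stop("score must lie in [0, 100]")
    ifelse(score > cutoff, "MALIGNANT", "BENIGN")
}

#' Lesion score from spectrum counts
#'
#' The score scales linearly with the number of spectra classified as
#' melanoma-characteristic: it is defined here as the percentage of
#' classified (SNR-accepted) spectra typed `CM_TYPE`, on a 0--100 scale, so
#' the cut-off of 28 reads as a percentage.  Uninformative spectra stay in
#' the denominator; rejected spectra do not.
#'
#' @param nTotal spectra acquired.
#' @param nRejected low-SNR removals.
#' @param nMalignant spectra typed `CM_TYPE`.
#' @param cutoff decision threshold, default 28.
#' @param lesionId identifier.
#' @return A [LesionScore-class].
#' @examples
#' lesionScore(100, 0, 33)   # score 33 -> MALIGNANT
#' lesionScore(300, 15, 0)   # score 0  -> BENIGN
#' @export
lesionScore <- function(nTotal, nRejected, nMalignant, cutoff = 28,
                        lesionId = "lesion") {
    nTotal <- as.integer(nTotal); nRejected <- as.integer(nRejected)
    nMalignant <- as.integer(nMalignant)
    nClassified <- nTotal - nRejected
    if (nClassified < 1L)
        stop("no classified spectra: the scan is uninterpretable")
    if (nMalignant < 0L || nMalignant > nClassified)
        stop("nMalignant must lie in [0, nClassified]")
    score <- 100 * nMalignant / nClassified
    new("LesionScore", lesionId = as.character(lesionId), nTotal = nTotal,
        nRejected = nRejected, nClassified = nClassified,
        nMalignant = nMalignant, score = score, cutoff = cutoff,
        decision = decideMalignancy(score, cutoff))
}

#' Score a lesion scan end to end
#'
#' Chains SNR filtering, classification and score aggregation for one raw
#' scan.
#'
#' @param scan a raw [LesionScan-class].
#' @param config a [preprocessConfig()].
#' @param thresholds a [typingThresholds()].
#' @param cutoff decision threshold, default 28.
#' @param backend,model classification backend, see [classifyScan()].
#' @return A [LesionScore-class].
#' @export
scoreScan <- function(scan, config = preprocessConfig(),
                      thresholds = typingThresholds(), cutoff = 28,
                      backend = "rule", model = NULL) {
    parts <- filterLowSnr(scan, config)
    nTotal <- nSpectra(scan)
    nRejected <- nSpectra(parts$rejected)
    if (nSpectra(parts$accepted) == 0L)
        stop("no classified spectra: the scan is uninterpretable")
    cls <- classifyScan(parts$accepted, config, thresholds,
                        backend = backend, model = model)
    lesionScore(nTotal, nRejected, sum(cls$malignant), cutoff = cutoff,
                lesionId = lesionId(scan))
}

#' Convert a LesionScore to a one-row data.frame
#'
#' @param x a [LesionScore-class].
#' @return A data.frame with the counts, score and decision.
#' @export
scoreAsDataFrame <- function(x) {
    data.frame(lesion_id = x@lesionId, n_total = x@nTotal,
               n_rejected = x@nRejected, n_classified = x@nClassified,
               n_malignant = x@nMalignant, score = x@score,
               decision = x@decision)
}
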