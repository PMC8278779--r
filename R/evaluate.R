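## Cohort-level evaluation: decision accuracy per diagnosis, mean-score
## confidence intervals, and the dominant-spectral-type cross table.

#' Per-diagnosis decision accuracy
#'
#' Cross-tabulates excision decisions against histopathology diagnoses.
#' A decision is correct when a melanoma is called `"MALIGNANT"` or a benign
#' lesion (`"SK"`, `"NEVUS"`) is called `"BENIGN"`.  Percentages are always
#' recomputed from counts.
#'
#' @param decisions character vector, `"MALIGNANT"`/`"BENIGN"` per lesion.
#' @param truths character vector of diagnoses (`"SK"`, `"NEVUS"`, `"CM"`).
#' @param scores optional numeric lesion scores for per-group means.
#' @return A list with `table` (one row per diagnosis: n, correct n and %,
#'   mean scores), `sensitivity` and `specificity`.
#' @examples
#' confusionCounts(c("BENIGN", "MALIGNANT"), c("SK", "CM"))
#' @export
confusionCounts <- function(decisions, truths, scores = NULL) {
    if (length(decisions) != length(truths))
        stop("decisions and truths must have equal length")
    ok <- ifelse(truths == "CM", decisions == "MALIGNANT",
                 decisions == "BENIGN")
    groups <- intersect(c("SK", "NEVUS", "CM"), unique(truths))
    tab <- do.call(rbind, lapply(groups, function(g) {
        sel <- truths == g
        n <- sum(sel); nOk <- sum(ok[sel])
        data.frame(
            diagnosis = g, n = n, correct = nOk,
            correct_pct = round(100 * nOk / n, 1),
            incorrect = n - nOk,
            incorrect_pct = round(100 * (n - nOk) / n, 1),
            mean_score_correct = if (!is.null(scores) && nOk > 0)
                mean(scores[sel & ok]) else NA_real_,
            mean_score_incorrect = if (!is.null(scores) && (n - nOk) > 0)
                mean(scores[sel & !ok]) else NA_real_)
    }))
    benign <- truths %in% c("SK", "NEVUS")
    list(table = tab,
         sensitivity = if (any(truths == "CM"))
             mean(decisions[truths == "CM"] == "MALIGNANT") else NA_real_,
         specificity = if (any(benign))
             mean(decisions[benign] == "BENIGN") else NA_real_)
}

#' Mean score with a Student-t confidence interval
#'
#' Two-sided t-interval with `n - 1` degrees of freedom, the conventional
#' interval for mean scores of cohorts of a few dozen lesions.  Requires at
#' least two scores (a CI is undefined for a single lesion).
#'
#' @param scores numeric vector, length at least 2.
#' @param level confidence level in (0, 1), default 0.95.
#' @return Named numeric vector `c(mean, lower, upper)`.
#' @examples
#' meanScoreCI(c(10, 20))
#' @export
meanScoreCI <- function(scores, level = 0.95) {
    n <- length(scores)
    if (n < 2L) stop("need at least 2 scores for a confidence interval")
    if (level <= 0 || level >= 1) stop("level must lie in (0, 1)")
    m <- mean(scores)
    half <- stats::qt(1 - (1 - level) / 2, df = n - 1) *
        stats::sd(scores) / sqrt(n)
    c(mean = m, lower = m - half, upper = m + half)
}

#' Dominant spectral type of a lesion
#'
#' The most frequent type among `SK_TYPE`, `CM_TYPE` and `NEVUS_TYPE`
#' (rejected and uninformative spectra carry no lesion-level
#' characteristic).  Ties, or no informative spectra at all, give
#' `"NO_DOMINANT"`.
#'
#' @param types character vector of per-spectrum types of one lesion.
#' @return A single type label or `"NO_DOMINANT"`.
#' @export
dominantSpectralType <- function(types) {
    informative <- c("SK_TYPE", "CM_TYPE", "NEVUS_TYPE")
    counts <- vapply(informative, function(t) sum(types == t), integer(1))
    top <- max(counts)
    if (top == 0L || sum(counts == top) > 1L) return("NO_DOMINANT")
    informative[which.max(counts)]
}

#' Cross table of dominant spectral types by diagnosis
#'
#' Rows are histopathology diagnoses, columns the dominant spectral type of
#' each lesion; row sums equal the lesion counts per diagnosis.
#'
#' @param dominantTypes character vector, one dominant type per lesion
#'   (see [dominantSpectralType()]).
#' @param truths character vector of diagnoses per lesion.
#' @return An integer matrix, diagnoses x dominant types.
#' @export
spectralTypeTable <- function(dominantTypes, truths) {
    if (length(dominantTypes) != length(truths))
        stop("dominantTypes and truths must have equal length")
    cols <- c("SK_TYPE", "CM_TYPE", "NEVUS_TYPE", "NO_DOMINANT")
    rows <- intersect(c("SK", "NEVUS", "CM"), unique(truths))
    out <- matrix(0L, nrow = length(rows), ncol = length(cols),
                  dimnames = list(rows, cols))
    for (i in seq_along(truths))
        out[truths[i], dominantTypes[i]] <-
            out[truths[i], dominantTypes[i]] + 1L
    out
}

#' Evaluate a synthetic cohort end to end
#'
#' Scores every scan, determines dominant types, and assembles the decision
#' table, the spectral-type table and summary metrics.
#'
#' @param scans list of raw [LesionScan-class] (e.g. from
#'   [generateCohort()]).
#' @param config a [preprocessConfig()].
#' @param thresholds a [typingThresholds()].
#' @param cutoff decision threshold, default 28.
#' @param backend,model classification backend, see [classifyScan()].
#' @return A list with `lesions` (per-lesion data.frame), `decisionTable`,
#'   `typeTable`, `sensitivity`, `specificity` and per-group `meanScores`
#'   (mean with 95% CI where n >= 2, otherwise the bare mean).
#' @export
evaluateCohort <- function(scans, config = preprocessConfig(),
                           thresholds = typingThresholds(), cutoff = 28,
                           backend = "rule", model = NULL) {
    rows <- lapply(scans, function(scan) {
        parts <- filterLowSnr(scan, config)
        cls <- classifyScan(parts$accepted, config, thresholds,
                            backend = backend, model = model)
        sc <- lesionScore(nSpectra(scan), nSpectra(parts$rejected),
                          sum(cls$malignant), cutoff = cutoff,
                          lesionId = lesionId(scan))
        cbind(scoreAsDataFrame(sc),
              diagnosis = diagnosis(scan),
              dominant_type = dominantSpectralType(cls$assigned_type))
    })
    lesions <- do.call(rbind, rows)
    conf <- confusionCounts(lesions$decision, lesions$diagnosis,
                            lesions$score)
    meanScores <- lapply(split(lesions$score, lesions$diagnosis),
                         function(s) {
        if (length(s) >= 2) meanScoreCI(s) else c(mean = mean(s))
    })
    list(lesions = lesions, decisionTable = conf$table,
         typeTable = spectralTypeTable(lesions$dominant_type,
                                       lesions$diagnosis),
         sensitivity = conf$sensitivity, specificity = conf$specificity,
         meanScores = meanScores)
}
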