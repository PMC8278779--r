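## SNR-based rejection, moving-average smoothing and maximum normalization.

#' Preprocessing configuration
#'
#' @param smoothingSpan moving-average span in grid points (default 40; an
#'   even span is symmetrized to the next odd centered window, so 40 points
#'   become an effective 41-point window).
#' @param snrThreshold signal-to-noise rejection threshold (default 3).
#' @param snrBand wavelength band (nm) over which SNR is evaluated, default
#'   430--650 nm (excluding the narrow SHG line, whose sharpness would
#'   inflate the smoothing residual).
#' @param normalizationBand band (nm) whose maximum is scaled to 1, default
#'   the full 380--680 nm range.
#' @return A list with the four settings, class `"PreprocessConfig"`.
#' @export
preprocessConfig <- function(smoothingSpan = 40, snrThreshold = 3,
                             snrBand = c(430, 650),
                             normalizationBand = c(380, 680)) {
    stopifnot(smoothingSpan >= 1, snrThreshold > 0,
              length(snrBand) == 2L, snrBand[1] < snrBand[2],
              length(normalizationBand) == 2L,
              normalizationBand[1] < normalizationBand[2])
    structure(list(smoothingSpan = smoothingSpan,
                   snrThreshold = snrThreshold,
                   snrBand = snrBand,
                   normalizationBand = normalizationBand),
              class = "PreprocessConfig")
}

## Centered moving average of a vector.  An even span is symmetrized to the
## odd window 2*floor(span/2)+1; at the edges the window shrinks
## symmetrically to the largest centered window that fits.
.movingAverage <- function(x, span) {
    n <- length(x)
    h <- floor(span / 2)
    if (h == 0L) return(x)
    cs <- c(0, cumsum(x))
    i <- seq_len(n)
    hi <- pmin(h, i - 1L, n - i)
    (cs[i + hi + 1L] - cs[i - hi]) / (2 * hi + 1)
}

.movingAverageMatrix <- function(x, span) {
    if (floor(span / 2) == 0L) return(x)
    apply(x, 2L, .movingAverage, span = span)
}

#' Moving-average smoothing
#'
#' Centered moving average with span 40 grid points by default (the filter
#' applied before all spectral interpretation).  See [preprocessConfig()]
#' for the parity and edge conventions.
#'
#' @param x a `stage = "raw"` [Spectrum-class] or [LesionScan-class].
#' @param span window span in grid points.
#' @return The smoothed object, `stage = "smoothed"`.
#' @export
setGeneric("smoothSpectra",
    function(x, span = 40) standardGeneric("smoothSpectra"))

#' @rdname smoothSpectra
#' @export
setMethod("smoothSpectra", "Spectrum", function(x, span = 40) {
    if (stage(x) != "raw")
        stop("smoothSpectra expects a raw spectrum, got stage '",
             stage(x), "'")
    if (span < 1 || span > x@grid@nPoints)
        stop("span must lie in [1, nPoints]")
    x@intensities <- .movingAverage(x@intensities, span)
    x@stage <- "smoothed"
    x
})

#' @rdname smoothSpectra
#' @export
setMethod("smoothSpectra", "LesionScan", function(x, span = 40) {
    if (!all(stage(x) == "raw"))
        stop("smoothSpectra expects a raw scan")
    if (span < 1 || span > nrow(x))
        stop("span must lie in [1, nPoints]")
    assay(x, "intensity") <- .movingAverageMatrix(assay(x, "intensity"), span)
    colData(x)$stage <- rep("smoothed", ncol(x))
    x
})

## Core SNR computation on a raw intensity vector.
.snrVector <- function(y, wl, config) {
    idx <- .bandIndex(wl, config$snrBand)
    sm <- .movingAverage(y, config$smoothingSpan)
    resid <- y[idx] - sm[idx]
    sdr <- stats::sd(resid)
    m <- mean(sm[idx])
    if (sdr == 0) {
        if (m > 0) return(Inf)
        return(0)
    }
    m / sdr
}

#' Estimate the signal-to-noise ratio of a raw spectrum
#'
#' SNR is the mean of the smoothed signal within the SNR band divided by the
#' standard deviation of the smoothing residual (raw minus smoothed) in that
#' band.  A noise-free spectrum with signal returns `Inf`; an all-zero
#' spectrum returns 0.
#'
#' @param x a `stage = "raw"` [Spectrum-class] or [LesionScan-class].
#' @param config a [preprocessConfig()].
#' @return A single SNR value, or one per spectrum for a scan.
#' @export
setGeneric("estimateSnr",
    function(x, config = preprocessConfig()) standardGeneric("estimateSnr"))

#' @rdname estimateSnr
#' @export
setMethod("estimateSnr", "Spectrum", function(x, config = preprocessConfig()) {
    if (stage(x) != "raw") stop("estimateSnr expects a raw spectrum")
    .snrVector(x@intensities, wavelengths(x), config)
})

#' @rdname estimateSnr
#' @export
setMethod("estimateSnr", "LesionScan",
    function(x, config = preprocessConfig()) {
    if (!all(stage(x) == "raw")) stop("estimateSnr expects a raw scan")
    wl <- wavelengths(x)
    apply(assay(x, "intensity"), 2L, .snrVector, wl = wl, config = config)
})

#' Partition a scan into accepted and rejected spectra by SNR
#'
#' Spectra with `estimateSnr >= snrThreshold` are accepted; the rest are
#' rejected (in the measured data around 5% of spectra fall below the
#' threshold).  Order is preserved and the two parts partition the input.
#'
#' @param scan a raw [LesionScan-class].
#' @param config a [preprocessConfig()].
#' @return A list with elements `accepted` and `rejected` (both
#'   [LesionScan-class], possibly with zero spectra) and the numeric `snr`
#'   vector.
#' @export
filterLowSnr <- function(scan, config = preprocessConfig()) {
    snr <- estimateSnr(scan, config)
    keep <- snr >= config$snrThreshold
    list(accepted = scan[, keep, drop = FALSE],
         rejected = scan[, !keep, drop = FALSE],
         snr = snr)
}

#' Normalize a spectrum to unit band maximum
#'
#' Divides intensities by the maximum within `band` (the convention used for
#' all spectral comparisons: normalization to a maximum, not to area).
#' Idempotent; errors on a nonpositive band maximum.
#'
#' @param x a [Spectrum-class] or [LesionScan-class] (raw or smoothed).
#' @param band wavelength band (nm) over which the maximum is taken.
#' @return The normalized object, `stage = "normalized"`.
#' @export
setGeneric("normalizeSpectra",
    function(x, band = c(380, 680)) standardGeneric("normalizeSpectra"))

#' @rdname normalizeSpectra
#' @export
setMethod("normalizeSpectra", "Spectrum", function(x, band = c(380, 680)) {
    idx <- .bandIndex(wavelengths(x), band)
    m <- max(x@intensities[idx])
    if (m <= 0) stop("band maximum must be positive")
    x@intensities <- x@intensities / m
    x@stage <- "normalized"
    x
})

#' @rdname normalizeSpectra
#' @export
setMethod("normalizeSpectra", "LesionScan", function(x, band = c(380, 680)) {
    idx <- .bandIndex(wavelengths(x), band)
    y <- assay(x, "intensity")
    m <- apply(y[idx, , drop = FALSE], 2L, max)
    if (any(m <= 0)) stop("band maximum must be positive for every spectrum")
    assay(x, "intensity") <- sweep(y, 2L, m, "/")
    colData(x)$stage <- rep("normalized", ncol(x))
    x
})
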