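## Nonnegative decomposition onto fluorophore bases and the
## difference-spectrum procedure.

#' Nonnegative least-squares unmixing onto fluorophore bases
#'
#' Finds nonnegative weights minimizing the Euclidean norm of
#' `spectrum - sum_b w_b * basis_b` (solved with `pracma::lsqnonneg`).
#' Unmixing operates on raw or smoothed, *unnormalized* spectra so the
#' recovered weights keep the detector-counts scale.
#'
#' For a `stage = "smoothed"` spectrum the basis shapes are smoothed with
#' the same span before fitting: smoothing is linear, so a smoothed mixture
#' equals the same mixture of smoothed bases and the weights remain exactly
#' recoverable.
#'
#' @param spectrum a raw or smoothed [Spectrum-class].
#' @param basisSet named list of [FluorophoreBasis-class] on the spectrum's
#'   grid; fewer bases than grid points.
#' @param span smoothing span applied to the bases when the spectrum is
#'   smoothed (must match the span used on the spectrum).
#' @return A list with `weights` (named, nonnegative) and `residualNorm`.
#' @examples
#' w <- c(SHG = 0.2, NADH = 0.5, KERATIN = 1, MELANIN = 0.3)
#' fit <- nnlsUnmix(composeSpectrum(w), defaultBasisSet())
#' fit$weights
#' @importFrom pracma lsqnonneg
#' @export
nnlsUnmix <- function(spectrum, basisSet = defaultBasisSet(), span = 40) {
    if (!stage(spectrum) %in% c("raw", "smoothed"))
        stop("nnlsUnmix expects a raw or smoothed spectrum")
    wl <- wavelengths(spectrum)
    B <- vapply(basisSet, function(b) {
        if (!isTRUE(all.equal(wavelengths(b@grid), wl)))
            stop("basis grid does not match spectrum grid")
        if (stage(spectrum) == "smoothed")
            .movingAverage(b@values, span)
        else b@values
    }, numeric(length(wl)))
    if (ncol(B) >= nrow(B))
        stop("basis count must be smaller than the number of grid points")
    y <- intensities(spectrum)
    if (all(y == 0)) {
        w <- stats::setNames(numeric(ncol(B)), names(basisSet))
        return(list(weights = w, residualNorm = 0))
    }
    fit <- pracma::lsqnonneg(B, y)
    w <- stats::setNames(as.numeric(fit$x), names(basisSet))
    list(weights = w,
         residualNorm = sqrt(sum((y - as.numeric(B %*% fit$x))^2)))
}

#' Difference spectrum between a target and a rescaled reference
#'
#' The interpretation device for assigning fluorophores: both spectra are
#' smoothed (if not already), the reference is rescaled so its maximum
#' equals the target's maximum, and the rescaled reference is subtracted
#' from the target.  Subtracting the hyperkeratotic-skin (keratin-dominated)
#' reference from the SK spectrum exposes the NAD(P)H excess at 430--460 nm
#' and the melanin excess beyond 530 nm.
#'
#' @param target,reference [Spectrum-class] objects on the same grid, raw or
#'   smoothed; the target maximum must be positive.
#' @param span smoothing span applied to raw inputs.
#' @return A `stage = "difference"` [Spectrum-class] (values may be
#'   negative).
#' @export
differenceSpectrum <- function(target, reference, span = 40) {
    if (!isTRUE(all.equal(wavelengths(target), wavelengths(reference))))
        stop("target and reference must share one grid")
    if (stage(target) == "raw") target <- smoothSpectra(target, span)
    if (stage(reference) == "raw") reference <- smoothSpectra(reference, span)
    if (stage(target) != "smoothed" || stage(reference) != "smoothed")
        stop("difference spectrum requires raw or smoothed inputs")
    mT <- max(intensities(target))
    if (mT <= 0) stop("target maximum must be positive")
    mR <- max(intensities(reference))
    if (mR <= 0) stop("reference maximum must be positive")
    d <- intensities(target) - intensities(reference) * (mT / mR)
    new("Spectrum", grid = target@grid, intensities = d,
        spectrumId = paste0(spectrumId(target), "-", spectrumId(reference)),
        stage = "difference",
        meta = list(target = spectrumId(target),
                    reference = spectrumId(reference)))
}

#' Wavelength of the maximum within a band
#'
#' Reads the peak position of a spectrum restricted to a closed wavelength
#' band; ties are broken toward the shorter wavelength.
#'
#' @param spectrum a [Spectrum-class] (any stage).
#' @param band numeric length-2 band (nm) within the grid.
#' @return The peak wavelength (nm).
#' @examples
#' peakWavelength(composeTemplate("PURE_NADH"), c(430, 520))  # 450
#' @export
peakWavelength <- function(spectrum, band = c(380, 680)) {
    wl <- wavelengths(spectrum)
    idx <- .bandIndex(wl, band)
    if (length(idx) == 0L) stop("band contains no grid points")
    y <- intensities(spectrum)[idx]
    if (all(y == 0)) stop("spectrum is identically zero within the band")
    wl[idx[which.max(y)]]
}
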