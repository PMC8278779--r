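## Fluorophore basis shapes and the forward model composing noise-free
## phenotype spectra.  Functional forms (Gaussian lines, sigmoidal melanin
## tail) are the simplest shapes consistent with the measured constraints:
## peak positions, monotone melanin rise over 430-650 nm, band dominances.

#' Second-harmonic-generation basis line
#'
#' The collagen SHG line appears at half the excitation wavelength: with the
#' instrument's 800 nm pulses the line sits at 400 nm.  Modeled as a narrow
#' Gaussian; `linewidthNm` is its standard deviation.
#'
#' @param excitationNm laser excitation wavelength (nm); the line center is
#'   `excitationNm / 2` and must fall inside the grid.
#' @param linewidthNm Gaussian standard deviation (nm), default 5.
#' @param grid a [WavelengthGrid-class].
#' @return A [FluorophoreBasis-class] named `"SHG"`.
#' @examples
#' b <- basisSHG(800)
#' peakNm(b)  # 400
#' @export
basisSHG <- function(excitationNm = 800, linewidthNm = 5,
                     grid = makeDefaultGrid()) {
    stopifnot(linewidthNm > 0)
    center <- excitationNm / 2
    if (center < grid@startNm || center > grid@stopNm)
        stop("SHG line center ", center, " nm lies outside the grid range")
    wl <- wavelengths(grid)
    v <- exp(-(wl - center)^2 / (2 * linewidthNm^2))
    v <- v / max(v)
    new("FluorophoreBasis", name = "SHG", shape = "gaussian_line",
        peakNm = center, widthNm = linewidthNm, values = v, grid = grid)
}

#' Gaussian fluorophore emission band
#'
#' Unit-maximum Gaussian line for a broad-band fluorophore.  The reference
#' measurements place the NAD(P)H emission maximum at 450 nm (solid phantom)
#' and the keratin maximum at 470 nm (human nail); bandwidths are free model
#' parameters since none are measured.
#'
#' @param name `"NADH"`, `"KERATIN"`, `"SHG"` or `"MELANIN"`.
#' @param peakNm emission maximum (nm), must lie on the grid range.
#' @param fwhmNm full width at half maximum (nm).
#' @param grid a [WavelengthGrid-class].
#' @return A [FluorophoreBasis-class].
#' @examples
#' nadh <- basisGaussian("NADH", 450, 60)
#' @export
basisGaussian <- function(name, peakNm, fwhmNm, grid = makeDefaultGrid()) {
    stopifnot(fwhmNm > 0)
    if (peakNm < grid@startNm || peakNm > grid@stopNm)
        stop("peak ", peakNm, " nm lies outside the grid range")
    wl <- wavelengths(grid)
    sigma <- fwhmNm / (2 * sqrt(2 * log(2)))
    v <- exp(-(wl - peakNm)^2 / (2 * sigma^2))
    v <- v / max(v)
    new("FluorophoreBasis", name = name, shape = "gaussian_line",
        peakNm = peakNm, widthNm = fwhmNm, values = v, grid = grid)
}

#' Melanin emission tail
#'
#' Melanin dominates the signal beyond 550 nm and rises monotonically toward
#' longer wavelengths over 430--650 nm.  Modeled as a logistic sigmoid
#' `1 / (1 + exp(-(lambda - onsetNm)/softnessNm))`, rescaled so the value at
#' the long-wavelength end of the grid is exactly 1.
#'
#' @param onsetNm sigmoid midpoint (nm), default 520.
#' @param softnessNm sigmoid width (nm), default 60.
#' @param grid a [WavelengthGrid-class].
#' @return A [FluorophoreBasis-class] named `"MELANIN"` with shape
#'   `"rising_tail"`.
#' @examples
#' mel <- basisMelanin()
#' tail(intensities(mel), 1)  # 1 at 680 nm
#' @export
basisMelanin <- function(onsetNm = 520, softnessNm = 60,
                         grid = makeDefaultGrid()) {
    stopifnot(onsetNm >= grid@startNm, onsetNm <= grid@stopNm,
              softnessNm > 0)
    wl <- wavelengths(grid)
    v <- 1 / (1 + exp(-(wl - onsetNm) / softnessNm))
    v <- v / v[length(v)]
    new("FluorophoreBasis", name = "MELANIN", shape = "rising_tail",
        peakNm = grid@stopNm, widthNm = softnessNm, values = v, grid = grid)
}

#' Default basis set of the forward model
#'
#' SHG line at 400 nm (800 nm excitation, sd 5 nm), NAD(P)H Gaussian at
#' 450 nm (FWHM 75 nm), keratin Gaussian at 470 nm (FWHM 120 nm) and the
#' melanin rising tail (onset 520 nm, softness 60 nm).  Peak positions are
#' measured facts; the bandwidths are model choices fixed once so that
#' every template constraint (SK composite peak at 475 nm, blue-over-red
#' dominance of SK, the NAD(P)H bump of the difference spectrum) holds with
#' margin.
#'
#' @param grid a [WavelengthGrid-class].
#' @return Named list of four [FluorophoreBasis-class] objects.
#' @export
defaultBasisSet <- function(grid = makeDefaultGrid()) {
    list(SHG     = basisSHG(800, 5, grid),
         NADH    = basisGaussian("NADH", 450, 75, grid),
         KERATIN = basisGaussian("KERATIN", 470, 120, grid),
         MELANIN = basisMelanin(520, 60, grid))
}

#' Compose a spectrum as a nonnegative mixture of bases
#'
#' The forward model is exactly linear: intensities are
#' `sum_b weight_b * basis_b`.
#'
#' @param weights named nonnegative numeric vector; names must match basis
#'   names in `basisSet`.
#' @param basisSet named list of [FluorophoreBasis-class] objects on a
#'   common grid, e.g. [defaultBasisSet()].
#' @param spectrumId identifier for the resulting spectrum.
#' @param meta metadata list.
#' @return A `stage = "raw"` [Spectrum-class].
#' @examples
#' sp <- composeSpectrum(c(KERATIN = 1), defaultBasisSet())
#' @export
composeSpectrum <- function(weights, basisSet = defaultBasisSet(),
                            spectrumId = "composite", meta = list()) {
    if (any(weights < 0)) stop("weights must be nonnegative")
    if (is.null(names(weights)) || !all(names(weights) %in% names(basisSet)))
        stop("weights must be named after bases in basisSet")
    grid <- basisSet[[1]]@grid
    y <- numeric(grid@nPoints)
    for (nm in names(weights)) {
        b <- basisSet[[nm]]
        if (!identical(wavelengths(b@grid), wavelengths(grid)))
            stop("all bases must share one grid")
        y <- y + weights[[nm]] * b@values
    }
    Spectrum(grid, y, spectrumId = spectrumId, stage = "raw", meta = meta)
}

## ---------------------------------------------------------------------------
## Phenotype templates
## ---------------------------------------------------------------------------

## Fixed template mixture weights (counts scale, relative within a template).
## The SK melanin weight is the result of the documented one-dimensional
## calibration (calibrateSkMelaninWeight): keratin peaks at 470 nm and the
## rising melanin tail shifts the composite maximum to 475 nm.
.TEMPLATE_WEIGHTS <- list(
    SK              = c(SHG = 0.03, NADH = 0.05, KERATIN = 1.00,
                        MELANIN = 0.6898),
    CM              = c(SHG = 0.05, NADH = 0.03, KERATIN = 0.02,
                        MELANIN = 1.00),
    NEVUS           = c(SHG = 1.00, NADH = 0.04, KERATIN = 0.05,
                        MELANIN = 0.12),
    HYPERKERATOTIC  = c(SHG = 0.02, NADH = 0.00, KERATIN = 1.00,
                        MELANIN = 0.60),
    HEALTHY_FOREARM = c(SHG = 1.00, NADH = 0.05, KERATIN = 0.05,
                        MELANIN = 0.03),
    PURE_KERATIN    = c(KERATIN = 1.00),
    PURE_NADH       = c(NADH = 1.00),
    BACKGROUND      = c(SHG = 0.50, NADH = 0.30, KERATIN = 0.30,
                        MELANIN = 0.35))

## Relative template brightness (dimensionless, multiplies the mixture).
## Calibrated once so that the SK blue-band (450-490 nm) mean is 10x the
## nevus blue-band mean -- the upper end of the observed SK-to-nevus
## intensity contrast -- with melanoma and background at intermediate
## brightness and the reference phenotypes near unity.
.TEMPLATE_SCALES <- c(
    SK = 0.7709, CM = 0.45, NEVUS = 0.80, HYPERKERATOTIC = 0.65,
    HEALTHY_FOREARM = 0.70, PURE_KERATIN = 1.00, PURE_NADH = 1.00,
    BACKGROUND = 0.40)

#' Template mixture weights and brightness for a phenotype
#'
#' The fixed constants of the forward model: per-fluorophore weights and the
#' overall brightness scale of each phenotype template.
#'
#' @param phenotype one of `"SK"`, `"CM"`, `"NEVUS"`, `"HYPERKERATOTIC"`,
#'   `"HEALTHY_FOREARM"`, `"PURE_KERATIN"`, `"PURE_NADH"`, `"BACKGROUND"`.
#' @return `templateWeights`: named numeric vector of basis weights.
#' @export
templateWeights <- function(phenotype) {
    w <- .TEMPLATE_WEIGHTS[[phenotype]]
    if (is.null(w)) stop("unknown phenotype: ", phenotype)
    w
}

#' @rdname templateWeights
#' @return `templateScale`: single positive number.
#' @export
templateScale <- function(phenotype) {
    if (!(phenotype %in% names(.TEMPLATE_SCALES)))
        stop("unknown phenotype: ", phenotype)
    unname(.TEMPLATE_SCALES[phenotype])
}

#' @rdname templateWeights
#' @return `templatePhenotypes`: the recognized phenotype names.
#' @export
templatePhenotypes <- function() names(.TEMPLATE_WEIGHTS)

#' Compose a noise-free phenotype template spectrum
#'
#' Deterministic, noise-free spectra of the phenotypes the analysis
#' distinguishes: the three lesion spectral types (`"SK"`, `"CM"`,
#' `"NEVUS"`), an `"UNINFORMATIVE"`-like `"BACKGROUND"`, and the reference
#' measurements (`"HYPERKERATOTIC"` skin, `"HEALTHY_FOREARM"`,
#' `"PURE_KERATIN"` nail, `"PURE_NADH"` phantom).
#'
#' Template properties on the default grid: the SK composite peaks at 475 nm
#' over 430--520 nm (keratin at 470 nm red-shifted by the calibrated melanin
#' weight) with a blue band (450--490 nm) ten times brighter than the nevus
#' blue band; the CM template rises monotonically over 430--650 nm with less
#' SHG than nevus; the nevus template is dominated by its 400 nm SHG line.
#'
#' @param phenotype see [templateWeights()].
#' @param grid a [WavelengthGrid-class].
#' @param weights,scale override the fixed defaults (rarely needed).
#' @return A `stage = "raw"` [Spectrum-class] with `meta$phenotype` set.
#' @examples
#' sk <- composeTemplate("SK")
#' peakWavelength(sk, c(430, 520))  # 475
#' @export
composeTemplate <- function(phenotype, grid = makeDefaultGrid(),
                            weights = NULL, scale = NULL) {
    if (is.null(weights)) weights <- templateWeights(phenotype)
    if (is.null(scale)) scale <- templateScale(phenotype)
    stopifnot(scale > 0)
    sp <- composeSpectrum(weights, defaultBasisSet(grid),
                          spectrumId = paste0("template_", phenotype),
                          meta = list(phenotype = phenotype))
    sp@intensities <- scale * sp@intensities
    sp
}

#' Calibrate the SK melanin weight
#'
#' The documented one-dimensional search fixing the SK template: keratin
#' alone peaks at 470 nm; the rising melanin tail shifts the composite
#' maximum red-ward.  For both the raw composite and its span-40 smoothed
#' version (feature extraction reads the smoothed spectrum) the argmax over
#' `band` must be exactly `targetNm`.  The search locates, by bisection,
#' the weight interval satisfying each condition, intersects them, and
#' returns the midpoint.  The result is frozen in the package's default SK
#' weights.
#'
#' @param grid a [WavelengthGrid-class].
#' @param weights fixed SK weights for the other three bases.
#' @param targetNm desired composite peak (nm), default 475.
#' @param band peak search band (nm), default `c(430, 520)`.
#' @param span smoothing span of the smoothed-peak condition.
#' @param upper upper bracket of the search.
#' @param tol bisection tolerance on the weight.
#' @return The calibrated melanin weight (single number).
#' @examples
#' w <- calibrateSkMelaninWeight()
#' abs(w - templateWeights("SK")[["MELANIN"]]) < 0.05
#' @export
calibrateSkMelaninWeight <- function(grid = makeDefaultGrid(),
                                     weights = c(SHG = 0.03, NADH = 0.05,
                                                 KERATIN = 1.00),
                                     targetNm = 475, band = c(430, 520),
                                     span = 40, upper = 5, tol = 1e-4) {
    bases <- defaultBasisSet(grid)
    peakAt <- function(w, smooth) {
        sp <- composeSpectrum(c(weights, MELANIN = w), bases)
        if (smooth) sp <- smoothSpectra(sp, span)
        peakWavelength(sp, band)
    }
    for (smooth in c(FALSE, TRUE)) {
        if (peakAt(0, smooth) >= targetNm)
            stop("melanin-free composite already peaks at or beyond target")
        if (peakAt(upper, smooth) <= targetNm)
            stop("upper bracket too small: peak never passes target")
    }
    ## smallest weight with peak >= threshold, by bisection (the peak
    ## position is nondecreasing in the melanin weight)
    lowest <- function(threshold, smooth) {
        lo <- 0; hi <- upper
        while (hi - lo > tol) {
            mid <- (lo + hi) / 2
            if (peakAt(mid, smooth) >= threshold) hi <- mid else lo <- mid
        }
        hi
    }
    wEnter <- max(lowest(targetNm, FALSE), lowest(targetNm, TRUE))
    wLeave <- min(lowest(targetNm + grid@stepNm, FALSE),
                  lowest(targetNm + grid@stepNm, TRUE))
    if (wLeave <= wEnter)
        stop("raw and smoothed peak conditions have no common weight")
    (wEnter + wLeave) / 2
}
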