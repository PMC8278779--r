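## Synthetic lesions and cohorts: labeled stand-ins for the in vivo scans,
## with the statistical structure the analysis assumes (mixtures of spectral
## phenotypes, heteroscedastic count noise, ~5% low-SNR contamination).

## Default per-diagnosis mixtures of source templates.  Chosen once so that
## benign lesions score well below the cut-off and melanoma lesions well
## above it; the per-lesion composition of real scans is not measured, so
## these are calibration constants of the generator, not measured facts.
.DEFAULT_TYPE_MIX <- list(
    SK    = c(SK = 0.70, BACKGROUND = 0.20, NEVUS = 0.08, CM = 0.02),
    NEVUS = c(NEVUS = 0.65, BACKGROUND = 0.25, SK = 0.08, CM = 0.02),
    CM    = c(CM = 0.45, BACKGROUND = 0.40, NEVUS = 0.15))

#' Recipe for one synthetic lesion
#'
#' @param diagnosis `"SK"`, `"NEVUS"` or `"CM"` (the histopathology truth of
#'   the simulated lesion).
#' @param nSpectra spectra per scan; real scans collect several hundred,
#'   default 300.
#' @param typeMix named probability vector over source templates
#'   (`SK`, `CM`, `NEVUS`, `BACKGROUND`); must sum to 1.  Defaults depend on
#'   `diagnosis`.
#' @param lowSnrFraction probability that a spectrum is replaced by a
#'   low-SNR spectrum (default 0.05, the fraction removed in practice).
#' @param noiseLevel relative noise scale of the count-noise model.
#' @param countsScale overall detector-counts scale multiplying the
#'   templates (default 2000).
#' @param seed RNG seed making the lesion reproducible.
#' @return A list of class `"LesionRecipe"`.
#' @export
lesionRecipe <- function(diagnosis = c("SK", "NEVUS", "CM"),
                         nSpectra = 300, typeMix = NULL,
                         lowSnrFraction = 0.05, noiseLevel = 1,
                         countsScale = 2000, seed = 1) {
    diagnosis <- match.arg(diagnosis)
    if (is.null(typeMix)) typeMix <- .DEFAULT_TYPE_MIX[[diagnosis]]
    if (nSpectra < 1) stop("nSpectra must be at least 1")
    if (any(typeMix < 0) || any(typeMix > 1) ||
        abs(sum(typeMix) - 1) > 1e-8)
        stop("typeMix must be probabilities summing to 1")
    if (lowSnrFraction < 0 || lowSnrFraction > 1)
        stop("lowSnrFraction must lie in [0, 1]")
    stopifnot(noiseLevel >= 0, countsScale > 0)
    structure(list(diagnosis = diagnosis, nSpectra = as.integer(nSpectra),
                   typeMix = typeMix, lowSnrFraction = lowSnrFraction,
                   noiseLevel = noiseLevel, countsScale = countsScale,
                   seed = seed),
              class = "LesionRecipe")
}

#' Recipe for a synthetic cohort
#'
#' Defaults mirror the study composition: 28 seborrheic keratoses, 5
#' melanocytic nevi and 24 melanomas.
#'
#' @param nSk,nNevus,nCm lesion counts per diagnosis.
#' @param nSpectra,lowSnrFraction,noiseLevel,countsScale passed to every
#'   [lesionRecipe()].
#' @param seed master seed; per-lesion seeds are derived from it (see
#'   [generateCohort()]).
#' @return A list of class `"CohortRecipe"`.
#' @export
cohortRecipe <- function(nSk = 28, nNevus = 5, nCm = 24, nSpectra = 300,
                         lowSnrFraction = 0.05, noiseLevel = 1,
                         countsScale = 2000, seed = 1) {
    stopifnot(nSk >= 0, nNevus >= 0, nCm >= 0)
    structure(list(nSk = as.integer(nSk), nNevus = as.integer(nNevus),
                   nCm = as.integer(nCm), nSpectra = nSpectra,
                   lowSnrFraction = lowSnrFraction, noiseLevel = noiseLevel,
                   countsScale = countsScale, seed = seed),
              class = "CohortRecipe")
}

## Heteroscedastic count-noise surrogate: Gaussian with variance growing
## with the signal (Poisson-like), clipped at zero.
.noisyColumns <- function(template, n, noiseLevel, scale) {
    mu <- scale * template
    sd <- noiseLevel * sqrt(mu + 1)
    m <- matrix(stats::rnorm(length(mu) * n, mean = mu, sd = sd),
                nrow = length(mu), ncol = n)
    m[m < 0] <- 0
    m
}

#' Generate one noisy spectrum from a template
#'
#' Intensities are `scale * template` plus Gaussian noise with standard
#' deviation `noiseLevel * sqrt(scale * template + 1)` (a Poisson-like
#' count-noise surrogate), clipped at zero.
#'
#' @param template a noise-free [Spectrum-class], e.g. from
#'   [composeTemplate()].
#' @param noiseLevel relative noise scale; 0 gives exactly
#'   `scale * template`.
#' @param scale detector-counts scale, must be positive.
#' @param spectrumId identifier.
#' @param seed optional RNG seed.
#' @return A raw [Spectrum-class]; `meta$truth_type` records the source
#'   template.
#' @export
generateSpectrum <- function(template, noiseLevel = 1, scale = 2000,
                             spectrumId = "S0001", seed = NULL) {
    stopifnot(scale > 0)
    y <- .withSeed(seed,
        .noisyColumns(intensities(template), 1L, noiseLevel, scale))[, 1]
    truth <- template@meta$phenotype
    Spectrum(template@grid, y, spectrumId = spectrumId, stage = "raw",
             meta = list(truth_type = if (is.null(truth)) "UNKNOWN" else truth))
}

## Low-SNR spectra: a few counts of structureless baseline swamped by noise,
## so the SNR estimate falls far below the rejection threshold.
.LOW_SNR_BASE <- 2
.LOW_SNR_SD <- 3

.lowSnrColumns <- function(nPoints, n) {
    m <- matrix(stats::rnorm(nPoints * n, mean = .LOW_SNR_BASE,
                             sd = .LOW_SNR_SD),
                nrow = nPoints, ncol = n)
    m[m < 0] <- 0
    m
}

#' Generate a spectrum below the SNR rejection threshold
#'
#' Near-zero signal plus noise, constructed so [estimateSnr()] falls below
#' the default threshold with probability at least 0.99.
#'
#' @param grid a [WavelengthGrid-class].
#' @param spectrumId identifier.
#' @param seed optional RNG seed.
#' @return A raw [Spectrum-class] with `meta$truth_type = "LOW_SNR"`.
#' @export
generateLowSnrSpectrum <- function(grid = makeDefaultGrid(),
                                   spectrumId = "S0001", seed = NULL) {
    y <- .withSeed(seed, .lowSnrColumns(grid@nPoints, 1L))[, 1]
    Spectrum(grid, y, spectrumId = spectrumId, stage = "raw",
             meta = list(truth_type = "LOW_SNR"))
}

#' Generate a synthetic lesion scan
#'
#' Each spectrum's source template is drawn from the recipe's `typeMix`; an
#' independent Bernoulli draw with probability `lowSnrFraction` replaces it
#' with a low-SNR spectrum.  Deterministic given the recipe seed.  Truth
#' labels are carried in `colData(scan)$truth_type` and are never consulted
#' by classification.
#'
#' @param recipe a [lesionRecipe()].
#' @param grid a [WavelengthGrid-class].
#' @param lesionId identifier; defaults to the diagnosis plus seed.
#' @param templates optional named list of template [Spectrum-class]s
#'   overriding [composeTemplate()] defaults.
#' @return A raw [LesionScan-class].
#' @examples
#' scan <- generateLesion(lesionRecipe("SK", nSpectra = 50, seed = 7))
#' table(truthTypes(scan))
#' @export
generateLesion <- function(recipe, grid = makeDefaultGrid(),
                           lesionId = NULL, templates = NULL) {
    stopifnot(inherits(recipe, "LesionRecipe"))
    if (is.null(lesionId))
        lesionId <- sprintf("%s_seed%s", recipe$diagnosis, recipe$seed)
    if (is.null(templates))
        templates <- lapply(stats::setNames(nm = names(recipe$typeMix)),
                            composeTemplate, grid = grid)
    n <- recipe$nSpectra
    .withSeed(recipe$seed, {
        src <- sample(names(recipe$typeMix), n, replace = TRUE,
                      prob = recipe$typeMix)
        low <- stats::runif(n) < recipe$lowSnrFraction
        truth <- ifelse(low, "LOW_SNR", src)
        y <- matrix(0, nrow = grid@nPoints, ncol = n)
        for (tp in unique(src)) {
            cols <- which(src == tp & !low)
            if (length(cols))
                y[, cols] <- .noisyColumns(intensities(templates[[tp]]),
                                           length(cols), recipe$noiseLevel,
                                           recipe$countsScale)
        }
        if (any(low))
            y[, low] <- .lowSnrColumns(grid@nPoints, sum(low))
        LesionScan(grid, y, lesionId = lesionId,
                   diagnosis = recipe$diagnosis, truthType = truth,
                   meta = list(seed = recipe$seed,
                               counts_scale = recipe$countsScale,
                               noise_level = recipe$noiseLevel))
    })
}

## Per-lesion seed derived from the master seed by a fixed counter scheme:
## seed_i = (master + 7919 * i) mod (2^31 - 1).
.lesionSeed <- function(master, index)
    (as.numeric(master) + 7919 * index) %% 2147483647

#' Generate a synthetic cohort
#'
#' Lesions are produced in deterministic order (all SK, then nevi, then CM),
#' each with a seed derived from the master seed by the fixed counter scheme
#' `seed_i = (master + 7919 * i) mod (2^31 - 1)`.
#'
#' @param recipe a [cohortRecipe()].
#' @param grid a [WavelengthGrid-class].
#' @param typeMixes optional named list of per-diagnosis type mixes
#'   overriding the defaults.
#' @return A list of [LesionScan-class], one per lesion.
#' @export
generateCohort <- function(recipe, grid = makeDefaultGrid(),
                           typeMixes = NULL) {
    stopifnot(inherits(recipe, "CohortRecipe"))
    plan <- rep(c("SK", "NEVUS", "CM"),
                times = c(recipe$nSk, recipe$nNevus, recipe$nCm))
    if (length(plan) == 0L) return(list())
    templates <- lapply(
        stats::setNames(nm = c("SK", "CM", "NEVUS", "BACKGROUND")),
        composeTemplate, grid = grid)
    lapply(seq_along(plan), function(i) {
        dx <- plan[i]
        mix <- if (!is.null(typeMixes)) typeMixes[[dx]] else NULL
        r <- lesionRecipe(dx, nSpectra = recipe$nSpectra, typeMix = mix,
                          lowSnrFraction = recipe$lowSnrFraction,
                          noiseLevel = recipe$noiseLevel,
                          countsScale = recipe$countsScale,
                          seed = .lesionSeed(recipe$seed, i))
        generateLesion(r, grid = grid,
                       lesionId = sprintf("%s_%02d", dx, i),
                       templates = templates[names(r$typeMix)])
    })
}
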