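#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay assay<-
#'   assayNames rowData colData colData<-
NULL

## ---------------------------------------------------------------------------
## WavelengthGrid
## ---------------------------------------------------------------------------

#' Uniform emission-wavelength grid
#'
#' A uniformly spaced wavelength axis (nm) on which all spectra of a scan
#' live.  The default acquisition range of the instrument is 380--680 nm;
#' with the package's 1 nm sampling every wavelength the analysis refers to
#' (400, 450, 470, 475, 490, 530, 550, 650 nm) falls exactly on a grid point.
#'
#' @slot startNm first wavelength (nm)
#' @slot stopNm last wavelength (nm)
#' @slot stepNm grid increment (nm)
#' @slot nPoints number of grid points
#'
#' @seealso [makeDefaultGrid()]
#' @export
setClass("WavelengthGrid",
    representation(startNm = "numeric", stopNm = "numeric",
                   stepNm = "numeric", nPoints = "integer"))

setValidity("WavelengthGrid", function(object) {
    msg <- character()
    if (length(object@startNm) != 1L || length(object@stopNm) != 1L ||
        length(object@stepNm) != 1L || length(object@nPoints) != 1L)
        msg <- c(msg, "all slots must have length 1")
    else {
        if (!(object@startNm < object@stopNm))
            msg <- c(msg, "startNm must be < stopNm")
        if (!(object@stepNm > 0))
            msg <- c(msg, "stepNm must be > 0")
        n <- (object@stopNm - object@startNm) / object@stepNm + 1
        if (abs(n - object@nPoints) > 1e-9)
            msg <- c(msg, "nPoints must equal (stopNm - startNm)/stepNm + 1")
    }
    if (length(msg)) msg else TRUE
})

#' Construct a wavelength grid
#'
#' @param startNm,stopNm,stepNm grid range and increment in nm.
#' @return A [WavelengthGrid-class] object.
#' @examples
#' WavelengthGrid(380, 680, 1)
#' @export
WavelengthGrid <- function(startNm, stopNm, stepNm = 1) {
    n <- (stopNm - startNm) / stepNm + 1
    new("WavelengthGrid", startNm = as.numeric(startNm),
        stopNm = as.numeric(stopNm), stepNm = as.numeric(stepNm),
        nPoints = as.integer(round(n)))
}

#' Default 380--680 nm grid
#'
#' The acquisition window of the spectrometer, sampled at 1 nm
#' (301 points).
#'
#' @return A [WavelengthGrid-class] spanning 380--680 nm in 1 nm steps.
#' @examples
#' g <- makeDefaultGrid()
#' nPoints(g)
#' @export
makeDefaultGrid <- function() WavelengthGrid(380, 680, 1)

## ---------------------------------------------------------------------------
## Generics
## ---------------------------------------------------------------------------

#' @rdname WavelengthGrid-class
#' @param x,object an object with a wavelength axis.
#' @export
setGeneric("wavelengths", function(x) standardGeneric("wavelengths"))

#' @rdname WavelengthGrid-class
#' @export
setGeneric("nPoints", function(x) standardGeneric("nPoints"))

#' @rdname Spectrum-class
#' @export
setGeneric("intensities", function(x) standardGeneric("intensities"))

#' @rdname Spectrum-class
#' @export
setGeneric("stage", function(x) standardGeneric("stage"))

#' @rdname Spectrum-class
#' @export
setGeneric("spectrumId", function(x) standardGeneric("spectrumId"))

#' @rdname LesionScan-class
#' @export
setGeneric("lesionId", function(x) standardGeneric("lesionId"))

#' @rdname LesionScan-class
#' @export
setGeneric("diagnosis", function(x) standardGeneric("diagnosis"))

#' @rdname LesionScan-class
#' @export
setGeneric("nSpectra", function(x) standardGeneric("nSpectra"))

#' @rdname LesionScan-class
#' @export
setGeneric("spectrumIds", function(x) standardGeneric("spectrumIds"))

#' @rdname LesionScan-class
#' @export
setGeneric("intensityMatrix", function(x) standardGeneric("intensityMatrix"))

#' @rdname LesionScan-class
#' @export
setGeneric("truthTypes", function(x) standardGeneric("truthTypes"))

#' @rdname LesionScan-class
#' @param i spectrum index (column).
#' @export
setGeneric("getSpectrum", function(x, i) standardGeneric("getSpectrum"))

#' @rdname FluorophoreBasis-class
#' @export
setGeneric("peakNm", function(x) standardGeneric("peakNm"))

#' @rdname FluorophoreBasis-class
#' @export
setGeneric("basisName", function(x) standardGeneric("basisName"))

#' @rdname LesionScore-class
#' @export
setGeneric("scoreValue", function(x) standardGeneric("scoreValue"))

#' @rdname LesionScore-class
#' @export
setGeneric("decision", function(x) standardGeneric("decision"))

setMethod("wavelengths", "WavelengthGrid", function(x)
    seq(x@startNm, by = x@stepNm, length.out = x@nPoints))

setMethod("nPoints", "WavelengthGrid", function(x) x@nPoints)

setMethod("show", "WavelengthGrid", function(object) {
    cat(sprintf("WavelengthGrid: %g-%g nm, step %g nm (%d points)\n",
                object@startNm, object@stopNm, object@stepNm, object@nPoints))
})

## ---------------------------------------------------------------------------
## Spectrum
## ---------------------------------------------------------------------------

.STAGES <- c("raw", "smoothed", "normalized", "difference")

#' A single emission spectrum
#'
#' Intensity (arbitrary detector counts) versus wavelength on a
#' [WavelengthGrid-class].  The `stage` slot tracks the processing state:
#' `"raw"` and `"smoothed"` spectra are nonnegative; `"normalized"` spectra
#' have unit maximum within the normalization band; `"difference"` spectra
#' (from [differenceSpectrum()]) may be negative.
#'
#' @slot grid a [WavelengthGrid-class]
#' @slot intensities numeric vector, one value per grid point
#' @slot spectrumId identifier
#' @slot stage one of `"raw"`, `"smoothed"`, `"normalized"`, `"difference"`
#' @slot meta list of provenance metadata (lesion id, synthetic truth type, ...)
#'
#' @export
setClass("Spectrum",
    representation(grid = "WavelengthGrid", intensities = "numeric",
                   spectrumId = "character", stage = "character",
                   meta = "list"))

setValidity("Spectrum", function(object) {
    msg <- character()
    if (length(object@intensities) != object@grid@nPoints)
        msg <- c(msg, "intensities length must equal grid nPoints")
    if (length(object@stage) != 1L || !(object@stage %in% .STAGES))
        msg <- c(msg, sprintf("stage must be one of %s",
                              paste(.STAGES, collapse = ", ")))
    else if (object@stage %in% c("raw", "smoothed") &&
             any(object@intensities < 0))
        msg <- c(msg, "raw/smoothed intensities must be nonnegative")
    if (length(object@spectrumId) != 1L)
        msg <- c(msg, "spectrumId must be a single string")
    if (length(msg)) msg else TRUE
})

#' Construct a Spectrum
#'
#' @param grid a [WavelengthGrid-class].
#' @param intensities numeric vector of detector counts, one per grid point.
#' @param spectrumId identifier string.
#' @param stage processing stage; see [Spectrum-class].
#' @param meta list of metadata.
#' @return A [Spectrum-class] object.
#' @export
Spectrum <- function(grid, intensities, spectrumId = "S1", stage = "raw",
                     meta = list()) {
    new("Spectrum", grid = grid, intensities = as.numeric(intensities),
        spectrumId = as.character(spectrumId), stage = stage, meta = meta)
}

setMethod("wavelengths", "Spectrum", function(x) wavelengths(x@grid))
setMethod("intensities", "Spectrum", function(x) x@intensities)
setMethod("stage", "Spectrum", function(x) x@stage)
setMethod("spectrumId", "Spectrum", function(x) x@spectrumId)

setMethod("show", "Spectrum", function(object) {
    cat(sprintf("Spectrum '%s' [%s]: %g-%g nm, max intensity %.4g\n",
                object@spectrumId, object@stage, object@grid@startNm,
                object@grid@stopNm, max(object@intensities)))
})

## ---------------------------------------------------------------------------
## FluorophoreBasis
## ---------------------------------------------------------------------------

#' A unit-normalized fluorophore emission shape
#'
#' One component of the forward model: the collagen second-harmonic (SHG)
#' line, the NAD(P)H or keratin emission band (Gaussian lines), or the
#' melanin tail (a sigmoid rising monotonically toward long wavelengths).
#' Values are nonnegative with maximum exactly 1.
#'
#' @slot name one of `"SHG"`, `"NADH"`, `"KERATIN"`, `"MELANIN"`
#' @slot shape `"gaussian_line"` or `"rising_tail"`
#' @slot peakNm wavelength of maximum (nm)
#' @slot widthNm spread parameter (nm): Gaussian FWHM, or sigmoid softness
#' @slot values unit-max intensity per grid point
#' @slot grid the [WavelengthGrid-class] the values live on
#'
#' @seealso [basisSHG()], [basisGaussian()], [basisMelanin()]
#' @export
setClass("FluorophoreBasis",
    representation(name = "character", shape = "character",
                   peakNm = "numeric", widthNm = "numeric",
                   values = "numeric", grid = "WavelengthGrid"))

.BASIS_NAMES <- c("SHG", "NADH", "KERATIN", "MELANIN")

setValidity("FluorophoreBasis", function(object) {
    msg <- character()
    if (!(object@name %in% .BASIS_NAMES))
        msg <- c(msg, sprintf("name must be one of %s",
                              paste(.BASIS_NAMES, collapse = ", ")))
    if (!(object@shape %in% c("gaussian_line", "rising_tail")))
        msg <- c(msg, "shape must be gaussian_line or rising_tail")
    if (length(object@values) != object@grid@nPoints)
        msg <- c(msg, "values length must equal grid nPoints")
    if (any(object@values < 0))
        msg <- c(msg, "values must be nonnegative")
    if (abs(max(object@values) - 1) > 1e-9)
        msg <- c(msg, "values must be unit-normalized (max = 1)")
    if (length(msg)) msg else TRUE
})

setMethod("wavelengths", "FluorophoreBasis", function(x) wavelengths(x@grid))
setMethod("intensities", "FluorophoreBasis", function(x) x@values)
setMethod("peakNm", "FluorophoreBasis", function(x) x@peakNm)
setMethod("basisName", "FluorophoreBasis", function(x) x@name)

setMethod("show", "FluorophoreBasis", function(object) {
    cat(sprintf("FluorophoreBasis %s (%s), peak %g nm, width %g nm\n",
                object@name, object@shape, object@peakNm, object@widthNm))
})

## ---------------------------------------------------------------------------
## LesionScan
## ---------------------------------------------------------------------------

.DIAGNOSES <- c("SK", "NEVUS", "CM", "UNKNOWN")

#' A lesion scan: all spectra measured in one pigmented skin lesion
#'
#' Extends [SummarizedExperiment][SummarizedExperiment::SummarizedExperiment]:
#' rows are wavelengths (with `rowData` column `wavelength_nm`), columns are
#' individual spectra.  The single assay `"intensity"` holds detector counts.
#' `colData` carries `spectrum_id`, the processing `stage` of every spectrum
#' and, for synthetic data, the generator truth label `truth_type` --- which
#' is bookkeeping only and is never consulted by classification.
#' `metadata()` carries `lesion_id`, `diagnosis` (histopathology label:
#' `"SK"`, `"NEVUS"`, `"CM"` or `"UNKNOWN"`) and free-form metadata.
#'
#' @seealso [readScan()], [writeScan()], [generateLesion()]
#' @export
setClass("LesionScan", contains = "SummarizedExperiment")

setValidity("LesionScan", function(object) {
    msg <- character()
    if (!identical(SummarizedExperiment::assayNames(object), "intensity"))
        msg <- c(msg, "LesionScan must have a single assay named 'intensity'")
    rd <- rowData(object)
    if (!("wavelength_nm" %in% colnames(rd)))
        msg <- c(msg, "rowData must contain 'wavelength_nm'")
    else {
        wl <- rd$wavelength_nm
        if (length(wl) > 1 && any(diff(wl) <= 0))
            msg <- c(msg, "wavelengths must be strictly increasing")
    }
    cd <- colData(object)
    need <- c("spectrum_id", "stage")
    if (!all(need %in% colnames(cd)))
        msg <- c(msg, "colData must contain 'spectrum_id' and 'stage'")
    md <- metadata(object)
    if (is.null(md$lesion_id))
        msg <- c(msg, "metadata must contain 'lesion_id'")
    if (is.null(md$diagnosis) || !(md$diagnosis %in% .DIAGNOSES))
        msg <- c(msg, sprintf("metadata 'diagnosis' must be one of %s",
                              paste(.DIAGNOSES, collapse = ", ")))
    if (length(msg)) msg else TRUE
})

#' Construct a LesionScan
#'
#' @param grid a [WavelengthGrid-class] shared by all spectra.
#' @param intensities numeric matrix, `nPoints(grid)` rows, one column per
#'   spectrum.
#' @param lesionId lesion identifier.
#' @param diagnosis histopathology label: `"SK"`, `"NEVUS"`, `"CM"`,
#'   `"UNKNOWN"`.
#' @param spectrumIds character vector of per-spectrum identifiers.
#' @param stage processing stage, a single value or one per spectrum.
#' @param truthType optional generator truth label per spectrum (synthetic
#'   data only).
#' @param meta list of additional scan metadata.
#' @return A [LesionScan-class] object.
#' @export
LesionScan <- function(grid, intensities, lesionId, diagnosis = "UNKNOWN",
                       spectrumIds = NULL, stage = "raw", truthType = NULL,
                       meta = list()) {
    intensities <- as.matrix(intensities)
    if (is.null(spectrumIds))
        spectrumIds <- sprintf("S%04d", seq_len(ncol(intensities)))
    if (length(stage) == 1L) stage <- rep(stage, ncol(intensities))
    cd <- DataFrame(spectrum_id = spectrumIds, stage = stage,
                    row.names = spectrumIds)
    if (!is.null(truthType)) cd$truth_type <- truthType
    colnames(intensities) <- spectrumIds
    se <- SummarizedExperiment(
        assays = list(intensity = intensities),
        rowData = DataFrame(wavelength_nm = wavelengths(grid)),
        colData = cd)
    metadata(se) <- c(list(lesion_id = lesionId, diagnosis = diagnosis), meta)
    new("LesionScan", se)
}

setMethod("wavelengths", "LesionScan", function(x)
    rowData(x)$wavelength_nm)
setMethod("intensityMatrix", "LesionScan", function(x)
    assay(x, "intensity"))
setMethod("lesionId", "LesionScan", function(x) metadata(x)$lesion_id)
setMethod("diagnosis", "LesionScan", function(x) metadata(x)$diagnosis)
setMethod("nSpectra", "LesionScan", function(x) ncol(x))
setMethod("spectrumIds", "LesionScan", function(x) colData(x)$spectrum_id)
setMethod("stage", "LesionScan", function(x) colData(x)$stage)
setMethod("truthTypes", "LesionScan", function(x) {
    cd <- colData(x)
    if ("truth_type" %in% colnames(cd)) cd$truth_type else NULL
})

#' @describeIn LesionScan-class reconstruct the shared wavelength grid.
#' @export
scanGrid <- function(x) {
    wl <- wavelengths(x)
    step <- if (length(wl) > 1) wl[2] - wl[1] else 1
    WavelengthGrid(wl[1], wl[length(wl)], step)
}

setMethod("getSpectrum", "LesionScan", function(x, i) {
    cd <- colData(x)
    meta <- list(lesion_id = lesionId(x))
    if ("truth_type" %in% colnames(cd))
        meta$truth_type <- cd$truth_type[i]
    Spectrum(scanGrid(x), assay(x, "intensity")[, i],
             spectrumId = cd$spectrum_id[i], stage = cd$stage[i],
             meta = meta)
})

setMethod("show", "LesionScan", function(object) {
    cat(sprintf("LesionScan '%s' (diagnosis %s): %d spectra, %d wavelengths\n",
                lesionId(object), diagnosis(object), ncol(object),
                nrow(object)))
})

## ---------------------------------------------------------------------------
## LesionScore
## ---------------------------------------------------------------------------

#' A lesion-level malignancy score
#'
#' Aggregate of per-spectrum classifications: the score is the percentage of
#' accepted (non-rejected) spectra typed as melanoma-characteristic, on a
#' 0--100 scale, and the excision decision is `"MALIGNANT"` iff the score is
#' strictly greater than the cut-off (default 28).
#'
#' @slot lesionId lesion identifier
#' @slot nTotal spectra acquired
#' @slot nRejected low-SNR removals
#' @slot nClassified accepted spectra (`nTotal - nRejected`)
#' @slot nMalignant spectra typed `CM_TYPE`
#' @slot score `100 * nMalignant / nClassified`
#' @slot cutoff decision threshold (default 28)
#' @slot decision `"MALIGNANT"` or `"BENIGN"`
#'
#' @seealso [lesionScore()], [scoreScan()]
#' @export
setClass("LesionScore",
    representation(lesionId = "character", nTotal = "integer",
                   nRejected = "integer", nClassified = "integer",
                   nMalignant = "integer", score = "numeric",
                   cutoff = "numeric", decision = "character"))

setValidity("LesionScore", function(object) {
    msg <- character()
    if (object@nClassified != object@nTotal - object@nRejected)
        msg <- c(msg, "nClassified must equal nTotal - nRejected")
    if (object@nMalignant < 0 || object@nMalignant > object@nClassified)
        msg <- c(msg, "nMalignant must lie in [0, nClassified]")
    if (object@score < 0 || object@score > 100)
        msg <- c(msg, "score must lie in [0, 100]")
    expected <- if (object@score > object@cutoff) "MALIGNANT" else "BENIGN"
    if (object@decision != expected)
        msg <- c(msg, "decision inconsistent with score and cutoff")
    if (length(msg)) msg else TRUE
})

setMethod("scoreValue", "LesionScore", function(x) x@score)
setMethod("decision", "LesionScore", function(x) x@decision)
setMethod("lesionId", "LesionScore", function(x) x@lesionId)

setMethod("show", "LesionScore", function(object) {
    cat(sprintf(
        "LesionScore '%s': %d/%d classified, %d malignant, score %.1f -> %s\n",
        object@lesionId, object@nClassified, object@nTotal,
        object@nMalignant, object@score, object@decision))
})

## ---------------------------------------------------------------------------
## SurrogateModel
## ---------------------------------------------------------------------------

#' Surrogate margin classifier for spectral types
#'
#' A linear support-vector machine trained on synthetic spectra, standing in
#' for the device's certified (and unavailable) classifier.  It predicts the
#' per-spectrum spectral type from the same features the rule-based
#' classifier uses.  It is a stand-in and makes no claim of reproducing the
#' certified device's decisions.
#'
#' @slot fit the fitted `e1071::svm` object
#' @slot featureNames feature columns used for training
#' @slot classLevels class labels seen during training
#'
#' @seealso [trainSurrogate()]
#' @export
setClass("SurrogateModel",
    representation(fit = "ANY", featureNames = "character",
                   classLevels = "character"))

setMethod("show", "SurrogateModel", function(object) {
    cat(sprintf("SurrogateModel (linear SVM): %d classes [%s], features: %s\n",
                length(object@classLevels),
                paste(object@classLevels, collapse = ", "),
                paste(object@featureNames, collapse = ", ")))
})

## ---------------------------------------------------------------------------
## Shared small helpers
## ---------------------------------------------------------------------------

#' Spectral type labels
#'
#' The per-spectrum labels assigned by classification: `SK_TYPE` (seborrheic
#' keratosis-like), `CM_TYPE` (melanoma-like), `NEVUS_TYPE`, `UNINFORMATIVE`
#' (no diagnostic pattern) and `REJECTED_LOW_SNR` (removed before
#' classification).
#'
#' @return Character vector of the five labels.
#' @examples
#' spectralTypes()
#' @export
spectralTypes <- function()
    c("SK_TYPE", "CM_TYPE", "NEVUS_TYPE", "UNINFORMATIVE", "REJECTED_LOW_SNR")

## index of grid points falling in a closed wavelength band
.bandIndex <- function(wl, band) {
    stopifnot(length(band) == 2L, band[1] <= band[2])
    which(wl >= band[1] & wl <= band[2])
}

## run code with a temporary RNG seed, restoring the caller's RNG state
.withSeed <- function(seed, expr) {
    if (is.null(seed)) return(expr)
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        old <- get(".Random.seed", envir = globalenv())
        on.exit(assign(".Random.seed", old, envir = globalenv()))
    } else {
        on.exit(rm(".Random.seed", envir = globalenv()))
    }
    set.seed(seed)
    expr
}
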