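## On-disk spectra format: UTF-8, tab-separated.  '#' lines hold
## '# key = value' metadata (lesion_id and diagnosis required); one header
## row names the wavelength column and the spectrum ids; data rows are
## wavelength then intensities, wavelengths strictly increasing.

.fmtNum <- function(x) {
    ## shortest decimal representation that round-trips a double exactly
    out <- formatC(x, digits = 17, format = "g")
    short <- formatC(x, digits = 15, format = "g")
    ok <- as.numeric(short) == x
    out[ok] <- short[ok]
    trimws(out)
}

#' Write a lesion scan to the spectra text format
#'
#' @param scan a [LesionScan-class]; all spectra must share the scan's grid
#'   and processing stage.
#' @param path output file path.
#' @return Invisibly, `path`.
#' @seealso [readScan()] for the format definition; the round trip
#'   `readScan(writeScan(scan))` reproduces the scan exactly.
#' @export
writeScan <- function(scan, path) {
    stopifnot(is(scan, "LesionScan"))
    validObject(scan)
    st <- unique(stage(scan))
    if (length(st) != 1L)
        stop("cannot write a scan with mixed processing stages")
    meta <- c(list(lesion_id = lesionId(scan),
                   diagnosis = diagnosis(scan), stage = st),
              metadata(scan)[setdiff(names(metadata(scan)),
                                     c("lesion_id", "diagnosis"))])
    lines <- sprintf("# %s = %s", names(meta),
                     vapply(meta, function(v) paste(v, collapse = ","),
                            character(1)))
    tt <- truthTypes(scan)
    if (!is.null(tt))
        lines <- c(lines, sprintf("# truth_type = %s",
                                  paste(tt, collapse = ",")))
    header <- paste(c("wavelength_nm", spectrumIds(scan)), collapse = "\t")
    y <- intensityMatrix(scan)
    body <- vapply(seq_len(nrow(y)), function(i)
        paste(c(.fmtNum(wavelengths(scan)[i]), .fmtNum(y[i, ])),
              collapse = "\t"),
        character(1))
    writeLines(c(lines, header, body), path)
    invisible(path)
}

.scanFormatError <- function(path, lineNo, what)
    stop(sprintf("malformed spectra file '%s', line %d: %s",
                 path, lineNo, what), call. = FALSE)

#' Read a lesion scan from the spectra text format
#'
#' The format is UTF-8, tab-separated: leading `# key = value` metadata
#' lines (keys `lesion_id` and `diagnosis` required), one header row
#' (`wavelength_nm` followed by spectrum ids), then one row per wavelength
#' with strictly increasing, uniformly spaced wavelengths and nonnegative
#' intensities.  Malformed input raises an error naming the offending line.
#'
#' @param path file in the spectra format.
#' @return A [LesionScan-class].
#' @export
readScan <- function(path) {
    if (!file.exists(path)) stop("no such file: ", path)
    lines <- readLines(path, encoding = "UTF-8")
    isMeta <- grepl("^#", lines)
    firstData <- which(!isMeta)[1]
    if (is.na(firstData) || any(!isMeta[seq_len(firstData - 1)] ))
        .scanFormatError(path, 1L, "missing header row")
    metaLines <- lines[seq_len(firstData - 1)]
    meta <- list()
    for (i in seq_along(metaLines)) {
        m <- regmatches(metaLines[i],
                        regexec("^#\\s*([^=]+?)\\s*=\\s*(.*)$", metaLines[i]))[[1]]
        if (length(m) != 3)
            .scanFormatError(path, i, "metadata line is not '# key = value'")
        meta[[m[2]]] <- m[3]
    }
    if (is.null(meta$lesion_id))
        .scanFormatError(path, 1L, "missing required key 'lesion_id'")
    if (is.null(meta$diagnosis))
        .scanFormatError(path, 1L, "missing required key 'diagnosis'")
    header <- strsplit(lines[firstData], "\t", fixed = TRUE)[[1]]
    if (header[1] != "wavelength_nm")
        .scanFormatError(path, firstData,
                         "header must start with 'wavelength_nm'")
    ids <- header[-1]
    if (length(ids) == 0L)
        .scanFormatError(path, firstData, "no spectrum columns")
    dataLines <- lines[(firstData + 1):length(lines)]
    dataLines <- dataLines[nzchar(dataLines)]
    n <- length(dataLines)
    if (n < 2L) .scanFormatError(path, firstData + 1L, "too few data rows")
    wl <- numeric(n)
    y <- matrix(NA_real_, nrow = n, ncol = length(ids))
    for (i in seq_len(n)) {
        lineNo <- firstData + i
        parts <- strsplit(dataLines[i], "\t", fixed = TRUE)[[1]]
        if (length(parts) != length(ids) + 1L)
            .scanFormatError(path, lineNo, sprintf(
                "expected %d columns, found %d", length(ids) + 1L,
                length(parts)))
        vals <- suppressWarnings(as.numeric(parts))
        if (any(is.na(vals)))
            .scanFormatError(path, lineNo, "non-numeric value")
        wl[i] <- vals[1]
        if (i > 1 && wl[i] <= wl[i - 1])
            .scanFormatError(path, lineNo,
                             "wavelengths must be strictly increasing")
        if (any(vals[-1] < 0) && !identical(meta$stage, "difference"))
            .scanFormatError(path, lineNo, "negative intensity")
        y[i, ] <- vals[-1]
    }
    steps <- diff(wl)
    if (max(steps) - min(steps) > 1e-9)
        .scanFormatError(path, firstData + 1L,
                         "wavelengths must be uniformly spaced")
    grid <- WavelengthGrid(wl[1], wl[n], steps[1])
    truth <- NULL
    if (!is.null(meta$truth_type)) {
        truth <- strsplit(meta$truth_type, ",", fixed = TRUE)[[1]]
        if (length(truth) != length(ids))
            .scanFormatError(path, 1L,
                             "truth_type length does not match spectra")
    }
    extra <- meta[setdiff(names(meta),
                          c("lesion_id", "diagnosis", "stage", "truth_type"))]
    ## numeric-looking metadata values come back as numbers
    extra <- lapply(extra, function(v) {
        nv <- suppressWarnings(as.numeric(v))
        if (!is.na(nv)) nv else v
    })
    LesionScan(grid, y, lesionId = meta$lesion_id,
               diagnosis = meta$diagnosis, spectrumIds = ids,
               stage = if (is.null(meta$stage)) "raw" else meta$stage,
               truthType = truth, meta = extra)
}
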