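test_that("the default grid spans 380-680 nm with every cited wavelength on-grid", {
    g <- makeDefaultGrid()
    wl <- wavelengths(g)
    expect_equal(nPoints(g), 301L)
    expect_equal(wl[1], 380)
    expect_equal(wl[301], 680)
    expect_true(all(c(400, 450, 470, 475, 490, 530, 550, 650) %in% wl))
    ## grid arithmetic is exact
    expect_lt(max(abs(wl - seq(380, 680, by = 1))), 1e-9)
})

test_that("grid validity rejects inconsistent parameters", {
    expect_error(WavelengthGrid(680, 380, 1), "startNm")
    expect_error(new("WavelengthGrid", startNm = 380, stopNm = 680,
                     stepNm = 1, nPoints = 300L), "nPoints")
})

test_that("scans round-trip through the spectra file format exactly", {
    path <- withr::local_tempfile(fileext = ".tsv")
    for (seed in c(3, 17, 91)) {
        scan <- generateLesion(lesionRecipe("CM", nSpectra = 15,
                                            seed = seed))
        writeScan(scan, path)
        back <- readScan(path)
        expect_identical(intensityMatrix(back), intensityMatrix(scan))
        expect_identical(wavelengths(back), wavelengths(scan))
        expect_identical(spectrumIds(back), spectrumIds(scan))
        expect_identical(truthTypes(back), truthTypes(scan))
        expect_identical(lesionId(back), lesionId(scan))
        expect_identical(diagnosis(back), diagnosis(scan))
        expect_identical(stage(back), stage(scan))
    }
})

test_that("a written scan has one wavelength row per grid point and one column per spectrum", {
    path <- withr::local_tempfile(fileext = ".tsv")
    scan <- generateLesion(lesionRecipe("SK", nSpectra = 300, seed = 5))
    writeScan(scan, path)
    lines <- readLines(path)
    body <- lines[!grepl("^#", lines)]
    expect_equal(length(body), 301L + 1L)  # header + data rows
    expect_equal(length(strsplit(body[1], "\t")[[1]]), 301L)  # wl + 300 ids
})

test_that("malformed spectra files raise errors naming the offending line", {
    path <- withr::local_tempfile(fileext = ".tsv")
    scan <- generateLesion(lesionRecipe("SK", nSpectra = 3, seed = 1))
    writeScan(scan, path)
    lines <- readLines(path)
    headerAt <- which(!grepl("^#", lines))[1]

    descending <- lines
    dataIdx <- (headerAt + 1):length(lines)
    descending[dataIdx] <- rev(lines[dataIdx])
    writeLines(descending, path)
    expect_error(readScan(path), "strictly increasing")

    negative <- lines
    parts <- strsplit(lines[headerAt + 4], "\t")[[1]]
    parts[2] <- "-1.5"
    negative[headerAt + 4] <- paste(parts, collapse = "\t")
    writeLines(negative, path)
    expect_error(readScan(path), sprintf("line %d.*negative", headerAt + 4))

    ragged <- lines
    ragged[headerAt + 2] <- paste(parts[1:2], collapse = "\t")
    writeLines(ragged, path)
    expect_error(readScan(path), "columns")

    noKey <- lines[-1]  # drop '# lesion_id = ...'
    writeLines(noKey, path)
    expect_error(readScan(path), "lesion_id")
})

test_that("scans with mixed processing stages cannot be written", {
    scan <- generateLesion(lesionRecipe("SK", nSpectra = 4, seed = 1))
    SummarizedExperiment::colData(scan)$stage[2] <- "smoothed"
    path <- withr::local_tempfile(fileext = ".tsv")
    expect_error(writeScan(scan, path), "mixed")
    expect_false(file.exists(path))
})

test_that("getSpectrum extracts a consistent single-spectrum view", {
    scan <- generateLesion(lesionRecipe("NEVUS", nSpectra = 8, seed = 2))
    sp <- getSpectrum(scan, 3)
    expect_s4_class(sp, "Spectrum")
    expect_identical(intensities(sp), intensityMatrix(scan)[, 3])
    expect_identical(spectrumId(sp), spectrumIds(scan)[3])
    expect_identical(sp@meta$truth_type, truthTypes(scan)[3])
})
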