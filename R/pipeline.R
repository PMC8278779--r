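## Pipeline driver: one configuration file holding every tunable, and the
## simulate -> preprocess -> classify -> score -> report chain.

#' Default pipeline configuration
#'
#' Every tunable of the pipeline in one nested list: grid, basis
#' parameters, template weights and brightness, cohort composition and
#' noise, preprocessing settings, classification thresholds, the score
#' cut-off and the master seed.
#'
#' @return A nested list, serializable with [writeDefaultConfig()].
#' @export
defaultConfig <- function() {
    list(
        grid = list(start_nm = 380, stop_nm = 680, step_nm = 1),
        bases = list(
            shg     = list(excitation_nm = 800, linewidth_nm = 5),
            nadh    = list(peak_nm = 450, fwhm_nm = 60),
            keratin = list(peak_nm = 470, fwhm_nm = 120),
            melanin = list(onset_nm = 520, softness_nm = 60)),
        templates = lapply(
            stats::setNames(nm = templatePhenotypes()),
            function(p) list(weights = as.list(templateWeights(p)),
                             scale = templateScale(p))),
        cohort = list(n_sk = 28, n_nevus = 5, n_cm = 24, n_spectra = 300,
                      low_snr_fraction = 0.05, noise_level = 1,
                      counts_scale = 2000),
        type_mix = lapply(.DEFAULT_TYPE_MIX, as.list),
        preprocess = list(smoothing_span = 40, snr_threshold = 3,
                          snr_band = c(430, 650),
                          normalization_band = c(380, 680)),
        thresholds = list(shg_high = 0.75, shg_low = 0.45,
                          blue_dominance = 1.5, monotonicity_min = 0.95),
        scoring = list(cutoff = 28),
        seed = 20210714)
}

#' Write the default configuration to a YAML file
#'
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
writeDefaultConfig <- function(path) {
    yaml::write_yaml(defaultConfig(), path)
    invisible(path)
}

.REQUIRED_CONFIG_KEYS <- c("grid", "cohort", "preprocess", "thresholds",
                           "scoring", "seed")

.validateConfig <- function(config) {
    missing <- setdiff(.REQUIRED_CONFIG_KEYS, names(config))
    if (length(missing))
        stop("config is missing required keys: ",
             paste(missing, collapse = ", "))
    if (!is.null(config$cohort$n_spectra) && config$cohort$n_spectra < 1)
        stop("config error: cohort n_spectra must be at least 1")
    invisible(config)
}

.log <- function(...) message(format(Sys.time(), "%H:%M:%S "), sprintf(...))

#' Run the full analysis pipeline
#'
#' Executes simulate, preprocess, classify, score and report in order,
#' writing every intermediate table under `outDir`.  Identical
#' configuration and seed give byte-identical outputs.  Progress and
#' per-stage timings are logged to standard error.
#'
#' Outputs: `spectra/<lesion>.tsv` (simulated scans), `manifest.tsv`,
#' `preprocess_log.tsv` (per-lesion rejection counts),
#' `classification.tsv` (per-spectrum features and types), `scores.tsv`
#' (per-lesion scores and decisions), `decision_table.tsv`,
#' `type_table.tsv`, `metrics.yaml` and `summary.txt`.
#'
#' @param config a configuration list (see [defaultConfig()]) or the path
#'   of a YAML file holding one.
#' @param outDir output directory, created if needed.
#' @param seed optional master seed overriding `config$seed`.
#' @return Invisibly, the [evaluateCohort()] result.
#' @export
runPipeline <- function(config = defaultConfig(), outDir, seed = NULL) {
    if (is.character(config)) config <- yaml::read_yaml(config)
    .validateConfig(config)
    if (!is.null(seed)) config$seed <- seed
    dir.create(file.path(outDir, "spectra"), recursive = TRUE,
               showWarnings = FALSE)
    g <- config$grid
    grid <- WavelengthGrid(g$start_nm, g$stop_nm, g$step_nm)
    co <- config$cohort
    recipe <- cohortRecipe(nSk = co$n_sk, nNevus = co$n_nevus,
                           nCm = co$n_cm, nSpectra = co$n_spectra,
                           lowSnrFraction = co$low_snr_fraction,
                           noiseLevel = co$noise_level,
                           countsScale = co$counts_scale,
                           seed = config$seed)
    typeMixes <- if (!is.null(config$type_mix))
        lapply(config$type_mix, unlist) else NULL

    t0 <- proc.time()[["elapsed"]]
    .log("simulate: %d lesions x %d spectra, master seed %s",
         co$n_sk + co$n_nevus + co$n_cm, co$n_spectra, config$seed)
    scans <- generateCohort(recipe, grid = grid, typeMixes = typeMixes)
    manifest <- data.frame(
        lesion_id = vapply(scans, lesionId, character(1)),
        diagnosis = vapply(scans, diagnosis, character(1)),
        n_spectra = vapply(scans, nSpectra, integer(1)),
        seed = vapply(scans, function(s) metadata(s)$seed, numeric(1)))
    .writeTsv(manifest, file.path(outDir, "manifest.tsv"))
    for (scan in scans)
        writeScan(scan, file.path(outDir, "spectra",
                                  paste0(lesionId(scan), ".tsv")))
    t1 <- proc.time()[["elapsed"]]
    .log("simulate done (%.1f s)", t1 - t0)

    pp <- config$preprocess
    ppConfig <- preprocessConfig(
        smoothingSpan = pp$smoothing_span, snrThreshold = pp$snr_threshold,
        snrBand = unlist(pp$snr_band),
        normalizationBand = unlist(pp$normalization_band))
    th <- config$thresholds
    thresholds <- typingThresholds(
        shgHigh = th$shg_high, shgLow = th$shg_low,
        blueDominance = th$blue_dominance,
        monotonicityMin = th$monotonicity_min)

    ppLog <- list(); clsRows <- list()
    for (scan in scans) {
        parts <- filterLowSnr(scan, ppConfig)
        ppLog[[lesionId(scan)]] <- data.frame(
            lesion_id = lesionId(scan), n_total = nSpectra(scan),
            n_rejected = nSpectra(parts$rejected),
            rejected_fraction = round(
                nSpectra(parts$rejected) / nSpectra(scan), 4))
        cls <- classifyScan(parts$accepted, ppConfig, thresholds)
        clsRows[[lesionId(scan)]] <- cbind(lesion_id = lesionId(scan),
                                           cls)
    }
    ppLog <- do.call(rbind, ppLog)
    .writeTsv(ppLog, file.path(outDir, "preprocess_log.tsv"))
    .log("preprocess: %d/%d spectra rejected (%.1f%%)",
         sum(ppLog$n_rejected), sum(ppLog$n_total),
         100 * sum(ppLog$n_rejected) / sum(ppLog$n_total))
    .writeTsv(do.call(rbind, clsRows), file.path(outDir,
                                                 "classification.tsv"))
    t2 <- proc.time()[["elapsed"]]
    .log("classify done (%.1f s)", t2 - t1)

    eval <- evaluateCohort(scans, ppConfig, thresholds,
                           cutoff = config$scoring$cutoff)
    .writeTsv(eval$lesions, file.path(outDir, "scores.tsv"))
    .writeTsv(eval$decisionTable, file.path(outDir, "decision_table.tsv"))
    .writeTsv(cbind(diagnosis = rownames(eval$typeTable),
                    as.data.frame(eval$typeTable)),
              file.path(outDir, "type_table.tsv"))
    yaml::write_yaml(
        list(sensitivity = eval$sensitivity,
             specificity = eval$specificity,
             mean_scores = lapply(eval$meanScores, as.list),
             rejected_fraction =
                 sum(ppLog$n_rejected) / sum(ppLog$n_total)),
        file.path(outDir, "metrics.yaml"))
    summary <- c(
        sprintf("lesions: %d", nrow(eval$lesions)),
        sprintf("sensitivity: %.3f", eval$sensitivity),
        sprintf("specificity: %.3f", eval$specificity),
        sprintf("rejected fraction: %.4f",
                sum(ppLog$n_rejected) / sum(ppLog$n_total)))
    writeLines(summary, file.path(outDir, "summary.txt"))
    t3 <- proc.time()[["elapsed"]]
    .log("score+report done (%.1f s); total %.1f s", t3 - t2, t3 - t0)
    invisible(eval)
}

.writeTsv <- function(df, path)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
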