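## Pipeline configuration, the end-to-end driver, the run manifest and the
## subcommand CLI.

.configDefaults <- function() {
  list(
    seed = 1L,
    simulate = list(design = "compact", nFamilies = 5L, peaksPerFamily = 4L,
                    nSingletons = 20L, withinCor = 0.9, axisLength = 4000L,
                    peakSd = 3, bioSd = 0.5, techSd = 0.5, shiftMax = 10L,
                    dietEffect = 1.2),
    preprocess = list(guard = 1, smoothWindow = 9L, structWidth = 151L,
                      alignWindow = 30L, quantWindow = 4L, scaleMin = 3,
                      lengthMin = 7, noiseQuantile = 0.95, snrMin = 3,
                      scaleMax = 24),
    stabilize = list(pseudoCount = 0.1, offset = 0),
    cluster = list(cutDistance = 0.3),
    classify = list(factor = "diet", sizes = c(3L, 5L, 8L), folds = 10L,
                    nRandom = 200L, acoAnts = 30L, acoIterations = 15L))
}

.mergeConfig <- function(base, override, path = character()) {
  for (k in names(override)) {
    here <- paste(c(path, k), collapse = ".")
    if (!k %in% names(base))
      stop("invalid config key: ", here)
    if (is.list(base[[k]]))
      base[[k]] <- .mergeConfig(base[[k]], as.list(override[[k]]),
                                c(path, k))
    else base[[k]] <- override[[k]]
  }
  base
}

#' Assemble a pipeline configuration
#'
#' Starts from the documented defaults of every stage and applies overrides;
#' unknown keys are rejected with a message naming the offending key. All
#' stage seeds are expanded deterministically from the single root `seed`.
#'
#' @param ... named overrides, e.g. `seed = 7`,
#'   `preprocess = list(structWidth = 101)`.
#' @return A `PipelineConfig` list.
#' @export
pipelineConfig <- function(...) {
  cfg <- .mergeConfig(.configDefaults(), list(...))
  structure(cfg, class = "PipelineConfig")
}

#' Read a YAML pipeline configuration
#'
#' @param path YAML file with (a subset of) the [pipelineConfig()] keys.
#' @return A `PipelineConfig` list.
#' @export
readPipelineConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  do.call(pipelineConfig, read_yaml(path))
}

#' Hash of a configuration for provenance stamping
#'
#' @param config a `PipelineConfig`.
#' @return character(1) md5 digest of the canonical YAML serialization.
#' @export
configHash <- function(config) {
  f <- tempfile(fileext = ".yaml")
  on.exit(unlink(f))
  write_yaml(unclass(config), f)
  unname(md5sum(f))
}

## deterministic per-stage seeds derived from the root seed (kept < 2^31)
.stageSeed <- function(config, stage) {
  offs <- c(simulate = 101L, preprocess = 211L, anova = 307L,
            cluster = 401L, classify = 503L)
  (as.integer(config$seed) * 1009L + offs[[stage]]) %% .Machine$integer.max
}

## the bundled compact simulation study: every genotype x diet x week cell
## populated, with one diet-responsive family planted
.simulateFromConfig <- function(config) {
  sc <- config$simulate
  if (identical(sc$design, "mouse")) {
    design <- mouseStudyDesign()
  } else {
    g <- c("B6", "NZO"); d <- c("SD", "HF", "CHF"); w <- c(3L, 8L)
    cells <- expand.grid(genotype = g, diet = d, week = w,
                         KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    cells$n_spectra <- 4L
    cells$n_samples <- 2L
    design <- buildDesign(g, d, w, cells)
  }
  fam <- peakFamilies(nFamilies = sc$nFamilies,
                      peaksPerFamily = sc$peaksPerFamily,
                      nSingletons = sc$nSingletons,
                      axisLength = sc$axisLength, withinCor = sc$withinCor)
  eff <- plantedEffect(fam$family_id[1], "diet",
                       c(CHF = sc$dietEffect, HF = sc$dietEffect / 2))
  simulateDataset(design, fam, effects = eff, axisLength = sc$axisLength,
                  peakSd = sc$peakSd, bioSd = sc$bioSd, techSd = sc$techSd,
                  shiftMax = sc$shiftMax,
                  seed = .stageSeed(config, "simulate"))
}

## sample-level metadata derived from a replicate-level sheet
.sampleLevelInfo <- function(sheet) {
  first <- !duplicated(sheet$sample_id)
  info <- sheet[first, c("sample_id", "genotype", "diet", "week"),
                drop = FALSE]
  rownames(info) <- info$sample_id
  info
}

#' Run the complete workflow and write all artifacts
#'
#' Stages: (optionally) simulate raw spectra, pre-process them into a
#' replicate-level peak matrix, stabilize the variance, average technical
#' replicates, run the per-peak factorial ANOVA, build and export the
#' annotated dendrogram, and benchmark the three feature-selection methods.
#' A JSON run manifest records inputs, outputs, stage counts, the config
#' hash and all collected warnings.
#'
#' @param outDir output directory.
#' @param sheetPath optional sample-sheet CSV of an existing dataset; when
#'   `NULL`, a dataset is simulated from the config and written first.
#' @param config a [pipelineConfig()].
#' @return The manifest list, invisibly.
#' @export
runPipeline <- function(outDir, sheetPath = NULL,
                        config = pipelineConfig()) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  warnings <- character(0)
  manifest <- list(created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                   config = unclass(config), config_hash = configHash(config),
                   counts = list(), outputs = list())
  collect <- function(expr) withCallingHandlers(expr, warning = function(w) {
    warnings <<- c(warnings, conditionMessage(w))
    invokeRestart("muffleWarning")
  })

  if (is.null(sheetPath)) {
    ds <- collect(.simulateFromConfig(config))
    simDir <- file.path(outDir, "simulated")
    sheetPath <- writeDataset(ds, simDir)
    manifest$outputs$simulated <- simDir
  }
  manifest$inputs <- list(sample_sheet = sheetPath)

  sheet <- readSampleSheet(sheetPath)
  missing <- !file.exists(sheet$spectrum_file)
  if (any(missing))
    stop("spectrum file(s) not found: ",
         paste(sheet$spectrum_file[missing], collapse = ", "))
  spectra <- lapply(seq_len(nrow(sheet)), function(i)
    readSpectrum(sheet$spectrum_file[i], spectrumId = sheet$spectrum_id[i]))
  manifest$counts$spectra_in <- length(spectra)

  pp <- config$preprocess
  repMat <- collect(preprocessSpectra(
    spectra, sheet, guard = pp$guard, smoothWindow = pp$smoothWindow,
    structWidth = pp$structWidth, alignWindow = pp$alignWindow,
    quantWindow = pp$quantWindow, scaleMin = pp$scaleMin,
    lengthMin = pp$lengthMin, noiseQuantile = pp$noiseQuantile,
    snrMin = pp$snrMin, scaleMax = pp$scaleMax))
  manifest$counts$peaks_picked <- nrow(repMat)
  repMat <- stabilizeVariance(repMat, config$stabilize$pseudoCount,
                              config$stabilize$offset)
  samMat <- collect(averageTechnicalReplicates(repMat))
  manifest$counts$samples <- ncol(samMat)
  writePeakMatrix(repMat, file.path(outDir, "peak_matrix_replicate.csv"))
  writePeakMatrix(samMat, file.path(outDir, "peak_matrix_sample.csv"))
  writeAnovaTable(metadata(repMat)$shifts, file.path(outDir, "shifts.tsv"))
  manifest$outputs$peak_matrix_replicate <-
    file.path(outDir, "peak_matrix_replicate.csv")
  manifest$outputs$peak_matrix_sample <-
    file.path(outDir, "peak_matrix_sample.csv")

  anovaTab <- collect(anovaAllPeaks(samMat))
  writeAnovaTable(anovaTab, file.path(outDir, "anova.tsv"))
  manifest$outputs$anova <- file.path(outDir, "anova.tsv")
  nFlagged <- sum(nzchar(anovaTab$flags))
  if (nFlagged) warnings <- c(warnings,
    sprintf("%d peak(s) carry ANOVA flags (rank-deficient or degenerate)",
            nFlagged))

  tree <- collect(clusterPeaks(samMat))
  exportDendrogram(tree, file.path(outDir, "dendrogram.nwk"),
                   file.path(outDir, "dendrogram.json"))
  manifest$outputs$dendrogram <- file.path(outDir, "dendrogram.nwk")

  cc <- config$classify
  labels <- colData(samMat)[[cc$factor]]
  aco <- acoConfig(nAnts = cc$acoAnts, nIterations = cc$acoIterations,
                   seed = .stageSeed(config, "classify"))
  bench <- collect(classificationBenchmark(
    samMat, anovaTab, tree, labels, factor = cc$factor, sizes = cc$sizes,
    aco = aco, cutDistance = config$cluster$cutDistance, folds = cc$folds,
    nRandom = cc$nRandom, seed = .stageSeed(config, "classify")))
  writeReport(bench, file.path(outDir, "classification_report.json"))
  manifest$outputs$classification_report <-
    file.path(outDir, "classification_report.json")

  manifest$warnings <- warnings
  write_json(manifest, file.path(outDir, "manifest.json"),
             auto_unbox = TRUE, digits = NA, null = "null")
  invisible(manifest)
}

.parseArgs <- function(args) {
  opts <- list()
  i <- 1L
  while (i <= length(args)) {
    if (!startsWith(args[i], "--"))
      stop("expected --key value pairs, got: ", args[i])
    key <- substring(args[i], 3)
    if (i == length(args)) stop("missing value for --", key)
    opts[[key]] <- args[i + 1L]
    i <- i + 2L
  }
  opts
}

.optConfig <- function(opts) {
  cfg <- if (!is.null(opts$config)) readPipelineConfig(opts$config)
         else pipelineConfig()
  if (!is.null(opts$seed)) cfg$seed <- as.integer(opts$seed)
  cfg
}

.requireOpts <- function(opts, keys) {
  miss <- setdiff(keys, names(opts))
  if (length(miss))
    stop("missing required option(s): ",
         paste(paste0("--", miss), collapse = ", "))
}

.cliLoadSampleMatrix <- function(opts) {
  .requireOpts(opts, c("matrix", "sheet"))
  sheet <- readSampleSheet(opts$sheet)
  readPeakMatrix(opts$matrix, sampleInfo = .sampleLevelInfo(sheet),
                 level = "sample")
}

#' Command-line entry point
#'
#' Subcommands: `simulate`, `preprocess`, `anova`, `cluster`, `select`,
#' `classify`, `run-all`. Options are `--key value` pairs; `--config`
#' points to a YAML file of [pipelineConfig()] overrides and `--seed`
#' overrides the root seed. Invoked by the installed
#' `scripts/profile-anova` wrapper.
#'
#' @param args character vector of command-line arguments.
#' @return Exit status, invisibly: 0 on success, 1 on error (with the
#'   message on stderr).
#' @export
cliMain <- function(args = commandArgs(trailingOnly = TRUE)) {
  status <- tryCatch({
    if (!length(args))
      stop("usage: profile-anova <simulate|preprocess|anova|cluster|",
           "select|classify|run-all> [--key value ...]")
    cmd <- args[1]
    opts <- .parseArgs(args[-1])
    cfg <- .optConfig(opts)
    switch(cmd,
      "simulate" = {
        .requireOpts(opts, "out")
        ds <- .simulateFromConfig(cfg)
        writeDataset(ds, opts$out)
        message("wrote ", length(ds$spectra), " spectra to ", opts$out)
      },
      "preprocess" = {
        .requireOpts(opts, c("sheet", "out"))
        sheet <- readSampleSheet(opts$sheet)
        missing <- !file.exists(sheet$spectrum_file)
        if (any(missing))
          stop("spectrum file(s) not found: ",
               paste(sheet$spectrum_file[missing], collapse = ", "))
        spectra <- lapply(seq_len(nrow(sheet)), function(i)
          readSpectrum(sheet$spectrum_file[i],
                       spectrumId = sheet$spectrum_id[i]))
        pp <- cfg$preprocess
        repMat <- preprocessSpectra(
          spectra, sheet, guard = pp$guard,
          smoothWindow = pp$smoothWindow, structWidth = pp$structWidth,
          alignWindow = pp$alignWindow, quantWindow = pp$quantWindow,
          scaleMin = pp$scaleMin, lengthMin = pp$lengthMin,
          noiseQuantile = pp$noiseQuantile, snrMin = pp$snrMin,
          scaleMax = pp$scaleMax)
        repMat <- stabilizeVariance(repMat, cfg$stabilize$pseudoCount,
                                    cfg$stabilize$offset)
        dir.create(opts$out, recursive = TRUE, showWarnings = FALSE)
        writePeakMatrix(repMat,
                        file.path(opts$out, "peak_matrix_replicate.csv"))
        writePeakMatrix(averageTechnicalReplicates(repMat),
                        file.path(opts$out, "peak_matrix_sample.csv"))
        writeAnovaTable(metadata(repMat)$shifts,
                        file.path(opts$out, "shifts.tsv"))
      },
      "anova" = {
        .requireOpts(opts, "out")
        samMat <- .cliLoadSampleMatrix(opts)
        writeAnovaTable(anovaAllPeaks(samMat), opts$out)
      },
      "cluster" = {
        .requireOpts(opts, "out")
        samMat <- .cliLoadSampleMatrix(opts)
        tree <- clusterPeaks(samMat)
        exportDendrogram(tree, paste0(opts$out, ".nwk"),
                         paste0(opts$out, ".json"))
      },
      "select" = {
        .requireOpts(opts, c("anova", "n", "out"))
        anovaTab <- utils::read.delim(opts$anova)
        method <- if (is.null(opts$method)) "anova" else opts$method
        n <- as.integer(opts$n)
        fs <- switch(method,
          "anova" = selectTopAnova(anovaTab, cfg$classify$factor, n),
          "cluster_anova" = {
            samMat <- .cliLoadSampleMatrix(opts)
            selectClusterRepresentatives(
              clusterPeaks(samMat, annotate = FALSE), anovaTab, samMat,
              cfg$classify$factor, n, cfg$cluster$cutDistance)
          },
          "aco" = {
            samMat <- .cliLoadSampleMatrix(opts)
            acoSelect(samMat, colData(samMat)[[cfg$classify$factor]], n,
                      acoConfig(nAnts = cfg$classify$acoAnts,
                                nIterations = cfg$classify$acoIterations,
                                seed = .stageSeed(cfg, "classify")))
          },
          stop("unknown selection method: ", method))
        write_json(unclass(fs), opts$out, auto_unbox = TRUE, digits = NA)
      },
      "classify" = {
        .requireOpts(opts, c("anova", "out"))
        samMat <- .cliLoadSampleMatrix(opts)
        anovaTab <- utils::read.delim(opts$anova)
        cc <- cfg$classify
        bench <- classificationBenchmark(
          samMat, anovaTab, clusterPeaks(samMat),
          colData(samMat)[[cc$factor]], factor = cc$factor,
          sizes = cc$sizes,
          aco = acoConfig(nAnts = cc$acoAnts,
                          nIterations = cc$acoIterations,
                          seed = .stageSeed(cfg, "classify")),
          cutDistance = cfg$cluster$cutDistance, folds = cc$folds,
          nRandom = cc$nRandom, seed = .stageSeed(cfg, "classify"))
        writeReport(bench, opts$out)
      },
      "run-all" = {
        .requireOpts(opts, "out")
        runPipeline(opts$out, sheetPath = opts$sheet, config = cfg)
      },
      stop("unknown subcommand: ", cmd))
    0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(status)
}
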