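## Synthetic multi-factorial MALDI profiling data with full ground truth.
##
## The generator emulates the structure of a genotype x diet x week plasma
## profiling study: correlated peak families coming from common parent
## proteins, multiplicative (log-normal) intensity noise split into a
## biological and a technical component, a slowly varying chemical-noise
## baseline, and a per-spectrum integer index drift of the sampling axis.

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so that seeded generator calls do not
#' disturb the caller's random-number stream.
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Define correlated peak families along the sampling axis
#'
#' Peaks are laid out evenly spaced (round-robin family assignment, so that
#' members of one family are spread over the axis like peptides of one parent
#' protein), with log-scale base intensities spanning `baseLogRange` and a
#' shared within-family correlation of the per-sample log abundances.
#'
#' @param nFamilies number of multi-peak families.
#' @param peaksPerFamily peaks per family.
#' @param nSingletons additional independent single-peak "families".
#' @param axisLength number of axis points the peaks must fit into.
#' @param baseLogRange range of base log-intensities (natural log scale).
#' @param withinCor within-family correlation of log abundances, in \[0, 1\].
#' @param margin axis points kept free at both ends.
#' @return data.frame with columns `peak_id`, `family_id`, `apex`,
#'   `base_log`, `within_cor`; apex indices strictly increasing.
#' @examples
#' fam <- peakFamilies(nFamilies = 2, peaksPerFamily = 3, nSingletons = 4)
#' table(fam$family_id)
#' @export
peakFamilies <- function(nFamilies = 5, peaksPerFamily = 4, nSingletons = 20,
                         axisLength = 4000, baseLogRange = c(4, 7),
                         withinCor = 0.9, margin = 150) {
  stopifnot(withinCor >= 0, withinCor <= 1)
  nFam <- nFamilies * peaksPerFamily
  n <- nFam + nSingletons
  apex <- round(seq(margin, axisLength - margin, length.out = n))
  if (any(diff(apex) <= 0))
    stop("axisLength too short to place ", n, " distinct peaks")
  fam <- c(rep_len(sprintf("F%02d", seq_len(nFamilies)), nFam),
           sprintf("S%02d", seq_len(nSingletons)))
  data.frame(peak_id = sprintf("P%05d", apex),
             family_id = fam,
             apex = as.integer(apex),
             base_log = seq(baseLogRange[1], baseLogRange[2], length.out = n),
             within_cor = c(rep(withinCor, nFam), rep(0, nSingletons)))
}

#' Declare a planted factor effect on a peak family
#'
#' Encodes a log-intensity shift applied to all peaks of a family for the
#' given factor levels, e.g. an elevation restricted to one
#' genotype-by-diet combination.
#'
#' @param family family id present in the family table.
#' @param factor one of `"genotype"`, `"diet"`, `"week"`, `"genotype:diet"`.
#' @param shifts named numeric vector of log-intensity shifts; names are
#'   factor levels (for the interaction, `"<genotype>:<diet>"`).
#' @return One-row-per-level data.frame (`family_id`, `factor`, `level`,
#'   `shift`) suitable for `rbind()`ing into the `effects` argument of
#'   [simulateDataset()].
#' @examples
#' plantedEffect("F01", "genotype:diet", c("SJL:CHF" = 1.5))
#' @export
plantedEffect <- function(family, factor, shifts) {
  factor <- match.arg(factor, c("genotype", "diet", "week", "genotype:diet"))
  stopifnot(is.numeric(shifts), all(is.finite(shifts)),
            !is.null(names(shifts)))
  data.frame(family_id = family, factor = factor,
             level = names(shifts), shift = as.numeric(shifts))
}

## shift of the expected log intensity of peaks of family `fam` in one cell
.effectShift <- function(effects, fam, genotype, diet, week) {
  if (is.null(effects) || !nrow(effects)) return(0)
  e <- effects[effects$family_id == fam, , drop = FALSE]
  if (!nrow(e)) return(0)
  lev <- ifelse(e$factor == "genotype", genotype,
         ifelse(e$factor == "diet", diet,
         ifelse(e$factor == "week", as.character(week),
                paste(genotype, diet, sep = ":"))))
  sum(e$shift[e$level == lev])
}

## expand a StudyDesign into a per-spectrum sample sheet; spectra are spread
## as evenly as possible over the cell's samples, grouped into preparations
## of up to 4 technical replicate acquisitions
.expandDesign <- function(design) {
  cells <- designCells(design)
  rows <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    ns <- cells$n_spectra[i]; nsam <- cells$n_samples[i]
    if (nsam == 0L) next
    per <- rep(ns %/% nsam, nsam)
    extra <- ns %% nsam
    if (extra > 0) per[seq_len(extra)] <- per[seq_len(extra)] + 1L
    sid <- sprintf("%s_%s_w%d_s%02d", cells$genotype[i], cells$diet[i],
                   cells$week[i], seq_len(nsam))
    rows[[i]] <- data.frame(
      sample_id = rep(sid, times = per),
      genotype = cells$genotype[i], diet = cells$diet[i],
      week = cells$week[i],
      replicate_in_sample = unlist(lapply(per, seq_len), use.names = FALSE))
  }
  sheet <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(sheet) || !nrow(sheet))
    return(data.frame(spectrum_id = character(), sample_id = character(),
                      genotype = character(), diet = character(),
                      week = integer(), preparation = integer(),
                      replicate = integer()))
  sheet$preparation <- (sheet$replicate_in_sample - 1L) %/% 4L + 1L
  sheet$replicate <- (sheet$replicate_in_sample - 1L) %% 4L + 1L
  sheet$spectrum_id <- sprintf("%s_p%d_r%d", sheet$sample_id,
                               sheet$preparation, sheet$replicate)
  rownames(sheet) <- NULL
  sheet[, c("spectrum_id", "sample_id", "genotype", "diet", "week",
            "preparation", "replicate")]
}

## per-sample true log abundances for every peak: shared family latent plus
## independent per-peak deviation, mixed by the within-family correlation
.sampleLogAbundance <- function(families, effects, genotype, diet, week,
                                bioSd) {
  fams <- unique(families$family_id)
  latent <- setNames(rnorm(length(fams)), fams)
  eps <- rnorm(nrow(families))
  eff <- vapply(families$family_id, .effectShift, numeric(1),
                effects = effects, genotype = genotype, diet = diet,
                week = week)
  rho <- families$within_cor
  families$base_log + eff +
    bioSd * (sqrt(rho) * latent[families$family_id] + sqrt(1 - rho) * eps)
}

#' Simulate a complete multi-factorial raw-spectrum dataset
#'
#' Each raw spectrum is a slowly varying baseline plus one Gaussian shape per
#' peak (in index space, sd `peakSd`), translated by a per-spectrum planted
#' integer index drift. Peak heights follow a multiplicative error model:
#' technical replicates of one sample share the biological log-abundance draw
#' (correlated within peak families) but receive independent log-normal
#' technical noise. Identical seeds give bit-identical output.
#'
#' @param design a [StudyDesign-class].
#' @param families peak family table from [peakFamilies()].
#' @param effects planted effects, `rbind()` of [plantedEffect()] rows, or
#'   `NULL`.
#' @param axisLength number of sampled axis points per spectrum.
#' @param mzRange m/z interval mapped linearly onto the axis.
#' @param peakSd Gaussian peak width (sd) in index units.
#' @param bioSd sd of the biological log-abundance noise.
#' @param techSd sd of the technical (per-spectrum) log-intensity noise.
#' @param baseline list with `expAmp`, `expTau`, `sinAmp`, `sinPeriod`:
#'   amplitude/decay of an exponential component and amplitude/period of a
#'   non-negative low-frequency sinusoid (random phase per spectrum).
#' @param additiveNoiseSd sd of additive white detector noise (intensities
#'   are clamped at 0 to stay physical).
#' @param shiftMax maximum absolute planted index drift; drifts are drawn
#'   uniformly from `-shiftMax:shiftMax`.
#' @param seed integer seed (mandatory; the caller's RNG state is restored).
#' @return list with `spectra` (list of raw [MassSpectrum-class]),
#'   `sampleSheet` (one row per spectrum) and `truth` (a `SyntheticTruth`
#'   list: planted shifts, true apex indices, family table, effects, noise
#'   parameters, seed).
#' @examples
#' fam <- peakFamilies(nFamilies = 1, peaksPerFamily = 2, nSingletons = 2,
#'                     axisLength = 1000)
#' des <- buildDesign("B6", "SD", 3L, data.frame(genotype = "B6", diet = "SD",
#'   week = 3, n_spectra = 4, n_samples = 2))
#' ds <- simulateDataset(des, fam, axisLength = 1000, seed = 1)
#' length(ds$spectra)
#' @export
simulateDataset <- function(design, families, effects = NULL,
                            axisLength = 4000, mzRange = c(700, 10000),
                            peakSd = 3, bioSd = 0.5, techSd = 0.5,
                            baseline = list(expAmp = 50,
                                            expTau = axisLength / 3,
                                            sinAmp = 10,
                                            sinPeriod = axisLength / 2),
                            additiveNoiseSd = 0, shiftMax = 10, seed) {
  if (missing(seed)) stop("a seed is mandatory for simulateDataset()")
  if (max(families$apex) + 6 * peakSd + shiftMax > axisLength)
    stop("axisLength too short for the declared apex positions plus margin")
  sheet <- .expandDesign(design)
  mzAxis <- seq(mzRange[1], mzRange[2], length.out = axisLength)
  t <- seq_len(axisLength)
  halfSupport <- ceiling(6 * peakSd)

  out <- withSeed(seed, {
    spectra <- vector("list", nrow(sheet))
    shifts <- integer(nrow(sheet))
    i <- 0L
    for (sid in unique(sheet$sample_id)) {
      rows <- which(sheet$sample_id == sid)
      first <- rows[1]
      logAb <- .sampleLogAbundance(families, effects, sheet$genotype[first],
                                   sheet$diet[first], sheet$week[first],
                                   bioSd)
      for (r in rows) {
        i <- i + 1L
        heights <- exp(logAb + techSd * rnorm(length(logAb)))
        shift <- if (shiftMax > 0)
          sample.int(2L * shiftMax + 1L, 1L) - shiftMax - 1L else 0L
        phase <- runif(1, 0, 2 * pi)
        y <- baseline$expAmp * exp(-(t - 1) / baseline$expTau) +
          baseline$sinAmp *
            (1 + sin(2 * pi * (t - 1) / baseline$sinPeriod + phase)) / 2
        for (j in seq_len(nrow(families))) {
          ctr <- families$apex[j] + shift
          win <- max(1L, ctr - halfSupport):min(axisLength, ctr + halfSupport)
          y[win] <- y[win] +
            heights[j] * exp(-((win - ctr)^2) / (2 * peakSd^2))
        }
        if (additiveNoiseSd > 0)
          y <- pmax(0, y + rnorm(axisLength, sd = additiveNoiseSd))
        shifts[r] <- shift
        spectra[[r]] <- MassSpectrum(mzAxis, y,
                                     spectrumId = sheet$spectrum_id[r],
                                     stage = "raw")
      }
    }
    list(spectra = spectra, shifts = shifts)
  })

  truth <- structure(list(
    seed = as.integer(seed),
    axis_length = as.integer(axisLength),
    mz_range = as.numeric(mzRange),
    peak_sd = peakSd,
    noise = list(bio_sd = bioSd, tech_sd = techSd,
                 additive_sd = additiveNoiseSd,
                 baseline = baseline),
    shift_max = as.integer(shiftMax),
    spectrum_shifts = data.frame(spectrum_id = sheet$spectrum_id,
                                 shift = as.integer(out$shifts)),
    peaks = families,
    effects = if (is.null(effects))
      data.frame(family_id = character(), factor = character(),
                 level = character(), shift = numeric()) else effects),
    class = "SyntheticTruth")
  list(spectra = out$spectra, sampleSheet = sheet, truth = truth)
}

#' Simulate a raw-scale replicate intensity matrix directly
#'
#' Skips the continuous-spectrum layer (no baseline, no drift) and draws peak
#' intensities straight from the multiplicative abundance model, which is the
#' appropriate scale for statistical simulations of the downstream stages.
#'
#' @inheritParams simulateDataset
#' @return list with `matrix` (raw-scale replicate-level
#'   [PeakMatrix-class]), `sampleSheet`, and the `families` table.
#' @export
simulateIntensityMatrix <- function(design, families, effects = NULL,
                                    mzRange = c(700, 10000),
                                    axisLength = 4000,
                                    bioSd = 0.5, techSd = 0.5, seed) {
  if (missing(seed)) stop("a seed is mandatory")
  sheet <- .expandDesign(design)
  vals <- withSeed(seed, {
    m <- matrix(NA_real_, nrow(families), nrow(sheet))
    for (sid in unique(sheet$sample_id)) {
      rows <- which(sheet$sample_id == sid)
      first <- rows[1]
      logAb <- .sampleLogAbundance(families, effects, sheet$genotype[first],
                                   sheet$diet[first], sheet$week[first],
                                   bioSd)
      for (r in rows)
        m[, r] <- exp(logAb + techSd * rnorm(length(logAb)))
    }
    m
  })
  dimnames(vals) <- list(families$peak_id, sheet$spectrum_id)
  mzAxis <- seq(mzRange[1], mzRange[2], length.out = axisLength)
  pm <- PeakMatrix(vals, peakIndex = families$apex,
                   peakMz = mzAxis[families$apex],
                   sampleInfo = sheet, level = "replicate",
                   transformLog = character())
  list(matrix = pm, sampleSheet = sheet, families = families)
}

#' Write and read the ground-truth object as JSON
#'
#' The `SyntheticTruth` list round-trips unchanged so that every planted
#' quantity (drifts, apex indices, family membership, effects, noise
#' parameters, seed) stays recoverable next to the written dataset.
#'
#' @param truth a `SyntheticTruth` (from [simulateDataset()]).
#' @param path output/input JSON file.
#' @return `readTruth()` returns the `SyntheticTruth`; `writeTruth()` returns
#'   `path` invisibly.
#' @export
writeTruth <- function(truth, path) {
  stopifnot(inherits(truth, "SyntheticTruth"))
  write_json(unclass(truth), path, auto_unbox = TRUE, digits = NA,
             dataframe = "columns")
  invisible(path)
}

#' @rdname writeTruth
#' @export
readTruth <- function(path) {
  x <- fromJSON(path, simplifyVector = TRUE)
  x$seed <- as.integer(x$seed)
  x$axis_length <- as.integer(x$axis_length)
  x$shift_max <- as.integer(x$shift_max)
  x$mz_range <- as.numeric(x$mz_range)
  x$spectrum_shifts <- as.data.frame(x$spectrum_shifts)
  x$spectrum_shifts$shift <- as.integer(x$spectrum_shifts$shift)
  x$peaks <- as.data.frame(x$peaks)
  x$peaks$apex <- as.integer(x$peaks$apex)
  x$effects <- as.data.frame(x$effects)
  if (!nrow(x$effects))
    x$effects <- data.frame(family_id = character(), factor = character(),
                            level = character(), shift = numeric())
  structure(x, class = "SyntheticTruth")
}

#' Write a simulated dataset to disk
#'
#' Writes one two-column CSV (`mz,intensity`) per spectrum, the sample sheet
#' CSV (with a `spectrum_file` column), and the ground truth JSON.
#'
#' @param dataset result of [simulateDataset()].
#' @param dir output directory (created if needed).
#' @return Invisibly, the sample-sheet path.
#' @export
writeDataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sheet <- dataset$sampleSheet
  sheet$spectrum_file <- file.path(dir, paste0(sheet$spectrum_id, ".csv"))
  for (i in seq_along(dataset$spectra))
    writeSpectrum(dataset$spectra[[i]], sheet$spectrum_file[i])
  sheetPath <- file.path(dir, "sample_sheet.csv")
  write.csv(sheet, sheetPath, row.names = FALSE)
  writeTruth(dataset$truth, file.path(dir, "truth.json"))
  invisible(sheetPath)
}
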