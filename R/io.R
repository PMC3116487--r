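## Readers and writers for the study's file formats: per-spectrum CSV and
## mzML (profile mode), the sample-sheet CSV, the peak-matrix CSV (peaks as
## rows, m/z first) and the ANOVA TSV.

.SHEET_COLUMNS <- c("spectrum_file", "sample_id", "genotype", "diet", "week",
                    "preparation", "replicate")

#' Read and validate a sample sheet
#'
#' The sheet maps every spectrum file to its biological sample and factor
#' levels. Duplicate (sample, preparation, replicate) keys are rejected.
#'
#' @param path CSV with columns `spectrum_file`, `sample_id`, `genotype`,
#'   `diet`, `week`, `preparation`, `replicate`.
#' @return data.frame, one row per spectrum; a `spectrum_id` column is
#'   derived from the file name when absent.
#' @export
readSampleSheet <- function(path) {
  if (!file.exists(path)) stop("sample sheet not found: ", path)
  sheet <- read.csv(path, stringsAsFactors = FALSE)
  if (!nrow(sheet)) stop("empty sample sheet: ", path)
  miss <- setdiff(.SHEET_COLUMNS, names(sheet))
  if (length(miss))
    stop("sample sheet is missing column(s): ", paste(miss, collapse = ", "))
  key <- paste(sheet$sample_id, sheet$preparation, sheet$replicate)
  if (anyDuplicated(key))
    stop("duplicated (sample_id, preparation, replicate) key(s): ",
         paste(unique(key[duplicated(key)]), collapse = "; "))
  if (is.null(sheet$spectrum_id))
    sheet$spectrum_id <- sub("\\.[^.]*$", "", basename(sheet$spectrum_file))
  sheet$week <- as.integer(sheet$week)
  sheet
}

#' Read one profile spectrum
#'
#' @param path two-column CSV (`mz,intensity`) or an mzML file (first
#'   spectrum; requires the `mzR` package).
#' @param format `"auto"` (by extension), `"csv"` or `"mzml"`.
#' @param spectrumId identifier for the returned object (default: file name
#'   without extension).
#' @return A raw [MassSpectrum-class].
#' @export
readSpectrum <- function(path, format = c("auto", "csv", "mzml"),
                         spectrumId = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("spectrum file not found: ", path)
  if (format == "auto")
    format <- if (grepl("\\.mzml$", path, ignore.case = TRUE)) "mzml"
              else "csv"
  if (is.null(spectrumId)) spectrumId <- sub("\\.[^.]*$", "", basename(path))
  if (format == "csv") {
    d <- read.csv(path)
    if (!all(c("mz", "intensity") %in% names(d)))
      stop("spectrum CSV must have columns 'mz' and 'intensity': ", path)
    mzv <- d$mz; iv <- d$intensity
  } else {
    if (!requireNamespace("mzR", quietly = TRUE))
      stop("reading mzML requires the mzR package")
    h <- mzR::openMSfile(path)
    on.exit(mzR::close(h))
    p <- mzR::peaks(h, 1L)
    mzv <- p[, 1]; iv <- p[, 2]
  }
  if (length(mzv) != length(iv) || anyNA(mzv) || anyNA(iv))
    stop("malformed spectrum (length mismatch or missing values): ", path)
  if (any(diff(mzv) <= 0))
    stop("spectrum axis is not strictly increasing: ", path)
  MassSpectrum(mzv, iv, spectrumId = spectrumId, stage = "raw")
}

#' Write one spectrum
#'
#' @param spectrum a [MassSpectrum-class].
#' @param path output file; `.mzML` selects mzML (requires `mzR`), anything
#'   else a two-column CSV.
#' @return `path`, invisibly.
#' @export
writeSpectrum <- function(spectrum, path) {
  stopifnot(is(spectrum, "MassSpectrum"))
  if (grepl("\\.mzml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("mzR", quietly = TRUE))
      stop("writing mzML requires the mzR package")
    mzv <- mz(spectrum); iv <- intensity(spectrum)
    hdr <- data.frame(
      seqNum = 1L, acquisitionNum = 1L, msLevel = 1L, polarity = 0L,
      peaksCount = length(mzv), totIonCurrent = sum(iv), retentionTime = 0,
      basePeakMZ = mzv[which.max(iv)], basePeakIntensity = max(iv),
      collisionEnergy = 0, ionisationEnergy = 0,
      lowMZ = min(mzv), highMZ = max(mzv),
      precursorScanNum = 0L, precursorMZ = 0, precursorCharge = 0L,
      precursorIntensity = 0, mergedScan = 0L, mergedResultScanNum = 0L,
      mergedResultStartScanNum = 0L, mergedResultEndScanNum = 0L,
      injectionTime = 0, filterString = NA_character_,
      spectrumId = paste0("scan=1"), centroided = FALSE,
      ionMobilityDriftTime = NA_real_,
      isolationWindowTargetMZ = NA_real_,
      isolationWindowLowerOffset = NA_real_,
      isolationWindowUpperOffset = NA_real_,
      scanWindowLowerLimit = NA_real_, scanWindowUpperLimit = NA_real_)
    mzR::writeMSData(list(cbind(mzv, iv)), file = path, header = hdr)
  } else {
    write.csv(data.frame(mz = mz(spectrum), intensity = intensity(spectrum)),
              path, row.names = FALSE)
  }
  invisible(path)
}

#' Write a peak matrix as CSV
#'
#' Rows are peaks (first columns `peak`, `index` and `mz`), remaining
#' columns the profile intensities, matching the discrete-peak-position
#' layout of the workflow.
#'
#' @param x a [PeakMatrix-class].
#' @param path output CSV.
#' @return `path`, invisibly.
#' @export
writePeakMatrix <- function(x, path) {
  stopifnot(is(x, "PeakMatrix"))
  out <- cbind(data.frame(peak = rownames(x), index = peakIndex(x),
                          mz = peakMz(x)),
               as.data.frame(assay(x, "intensity")))
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Read a peak matrix written by [writePeakMatrix()]
#'
#' @param path CSV path.
#' @param sampleInfo optional per-profile metadata (rownames or `spectrum_id`
#'   / `sample_id` matching the intensity columns).
#' @param level profile level of the stored matrix.
#' @param transformLog transforms already applied to the stored values.
#' @return A [PeakMatrix-class].
#' @export
readPeakMatrix <- function(path, sampleInfo = NULL, level = "replicate",
                           transformLog = character()) {
  d <- read.csv(path, check.names = FALSE)
  if (!all(c("peak", "index", "mz") %in% names(d)))
    stop("peak-matrix CSV must start with 'peak', 'index' and 'mz' columns")
  vals <- as.matrix(d[, setdiff(names(d), c("peak", "index", "mz")),
                    drop = FALSE])
  rownames(vals) <- d$peak
  if (!is.null(sampleInfo)) {
    ids <- if (!is.null(sampleInfo$spectrum_id) && level == "replicate")
      sampleInfo$spectrum_id else sampleInfo$sample_id
    m <- match(colnames(vals), ids)
    if (anyNA(m)) stop("sampleInfo does not cover profile(s): ",
                       paste(colnames(vals)[is.na(m)], collapse = ", "))
    sampleInfo <- sampleInfo[m, , drop = FALSE]
    rownames(sampleInfo) <- colnames(vals)
  }
  PeakMatrix(vals, peakIndex = d$index, peakMz = d$mz,
             sampleInfo = sampleInfo, level = level,
             transformLog = transformLog)
}

#' Write an ANOVA table as TSV
#'
#' @param anovaTable result of [anovaAllPeaks()].
#' @param path output TSV.
#' @return `path`, invisibly.
#' @export
writeAnovaTable <- function(anovaTable, path) {
  utils::write.table(anovaTable, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
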