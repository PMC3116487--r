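## Central S4 containers: MassSpectrum, StudyDesign, PeakMatrix (extends
## SummarizedExperiment) and ClusterTree (hclust + per-node annotation).

.SPECTRUM_STAGES <- c("raw", "logged", "smoothed", "baselined", "aligned")

#' One acquisition's continuous intensity trace
#'
#' A `MassSpectrum` holds a single profile-mode acquisition: an ascending m/z
#' axis, one intensity per axis point, and a processing-stage tag that only
#' moves forward through `raw`, `logged`, `smoothed`, `baselined`, `aligned`.
#'
#' @slot spectrumId character(1) acquisition identifier.
#' @slot mz ascending numeric m/z axis.
#' @slot intensity numeric intensities, same length as `mz`.
#' @slot stage character(1), one of the five processing stages.
#'
#' @aliases mz intensity stage spectrumId
#' @export
setClass("MassSpectrum",
  representation(spectrumId = "character", mz = "numeric",
                 intensity = "numeric", stage = "character"))

setValidity("MassSpectrum", function(object) {
  msg <- NULL
  if (length(object@mz) != length(object@intensity))
    msg <- c(msg, "mz and intensity must have equal length")
  if (length(object@mz) > 1L && any(diff(object@mz) <= 0))
    msg <- c(msg, "mz axis must be strictly increasing")
  if (length(object@stage) != 1L || !object@stage %in% .SPECTRUM_STAGES)
    msg <- c(msg, sprintf("stage must be one of %s",
                          paste(.SPECTRUM_STAGES, collapse = ", ")))
  if (is.null(msg)) TRUE else msg
})

#' @param mz ascending numeric m/z axis.
#' @param intensity numeric intensities.
#' @param spectrumId character(1) identifier.
#' @param stage processing stage tag.
#' @return A `MassSpectrum` object.
#' @examples
#' s <- MassSpectrum(mz = 1:10, intensity = rep(1, 10), spectrumId = "s1")
#' stage(s)
#' @rdname MassSpectrum-class
#' @export
MassSpectrum <- function(mz, intensity, spectrumId = "spectrum",
                         stage = "raw") {
  new("MassSpectrum", spectrumId = as.character(spectrumId),
      mz = as.numeric(mz), intensity = as.numeric(intensity),
      stage = stage)
}

#' @rdname MassSpectrum-class
#' @param object,x a `MassSpectrum`.
#' @param ... ignored.
#' @export
setMethod("mz", "MassSpectrum", function(object, ...) object@mz)

#' @rdname MassSpectrum-class
#' @export
setMethod("intensity", "MassSpectrum", function(object, ...) object@intensity)

#' @rdname MassSpectrum-class
#' @export
setMethod("stage", "MassSpectrum", function(object, ...) object@stage)

#' @rdname MassSpectrum-class
#' @export
setMethod("spectrumId", "MassSpectrum", function(object, ...) object@spectrumId)

#' @rdname MassSpectrum-class
#' @export
setMethod("length", "MassSpectrum", function(x) length(x@mz))

setMethod("show", "MassSpectrum", function(object) {
  cat("MassSpectrum '", object@spectrumId, "' [", object@stage, "]\n",
      sep = "")
  cat("  ", length(object@mz), " points, m/z ",
      format(min(object@mz)), "-", format(max(object@mz)), "\n", sep = "")
})

## internal: advance the stage tag, enforcing forward-only transitions
.advanceStage <- function(spectrum, to) {
  from <- match(spectrum@stage, .SPECTRUM_STAGES)
  dest <- match(to, .SPECTRUM_STAGES)
  if (dest < from)
    stop(sprintf("cannot move spectrum '%s' backwards from stage '%s' to '%s'",
                 spectrum@spectrumId, spectrum@stage, to))
  spectrum@stage <- to
  spectrum
}

# ---------------------------------------------------------------------------

#' Multi-factorial study design with per-cell acquisition counts
#'
#' A `StudyDesign` records the factor levels (genotype, diet, week) of a
#' profiling study together with the number of acquired spectra and distinct
#' biological samples for every genotype-by-diet-by-week cell. Cells may be
#' empty (0/0), as happens when sample collection fails for a stratum.
#'
#' @slot genotypeLevels,dietLevels character factor levels.
#' @slot weekLevels integer sampling weeks.
#' @slot cells data.frame with columns `genotype`, `diet`, `week`,
#'   `n_spectra`, `n_samples`; one row per declared cell.
#'
#' @aliases totalSpectra totalSamples designCells
#' @export
setClass("StudyDesign",
  representation(genotypeLevels = "character", dietLevels = "character",
                 weekLevels = "integer", cells = "data.frame"))

setValidity("StudyDesign", function(object) {
  msg <- NULL
  cl <- object@cells
  need <- c("genotype", "diet", "week", "n_spectra", "n_samples")
  if (!all(need %in% names(cl)))
    return(sprintf("cells must have columns %s", paste(need, collapse = ", ")))
  if (!all(cl$genotype %in% object@genotypeLevels))
    msg <- c(msg, "cells reference undeclared genotype levels")
  if (!all(cl$diet %in% object@dietLevels))
    msg <- c(msg, "cells reference undeclared diet levels")
  if (!all(cl$week %in% object@weekLevels))
    msg <- c(msg, "cells reference undeclared week levels")
  if (any(cl$n_spectra < 0) || any(cl$n_samples < 0))
    msg <- c(msg, "counts must be non-negative")
  if (any(cl$n_samples > cl$n_spectra))
    msg <- c(msg, "n_samples cannot exceed n_spectra in any cell")
  if (any(cl$n_samples == 0 & cl$n_spectra > 0))
    msg <- c(msg, "a cell with 0 samples cannot have spectra")
  if (anyDuplicated(cl[, c("genotype", "diet", "week")]))
    msg <- c(msg, "duplicate design cells")
  if (is.null(msg)) TRUE else msg
})

#' Build a study design from per-cell counts
#'
#' @param genotypes,diets character vectors of factor levels.
#' @param weeks integer vector of sampling weeks.
#' @param counts data.frame with columns `genotype`, `diet`, `week`,
#'   `n_spectra`, `n_samples`. Cells not listed default to 0/0.
#' @return A [StudyDesign-class] object with one row per declared cell.
#' @examples
#' d <- buildDesign(c("A", "B"), c("SD", "HF"), weeks = c(3L, 6L),
#'                  counts = data.frame(genotype = "A", diet = "SD",
#'                                      week = 3, n_spectra = 8, n_samples = 2))
#' totalSpectra(d)
#' @export
buildDesign <- function(genotypes, diets, weeks, counts) {
  weeks <- as.integer(weeks)
  full <- expand.grid(genotype = genotypes, diet = diets, week = weeks,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  full$n_spectra <- 0L
  full$n_samples <- 0L
  if (nrow(counts)) {
    bad <- !(counts$genotype %in% genotypes & counts$diet %in% diets &
             counts$week %in% weeks)
    if (any(bad))
      stop("counts reference unknown factor levels: ",
           paste(unique(paste(counts$genotype[bad], counts$diet[bad],
                              counts$week[bad])), collapse = "; "))
    if (any(counts$n_spectra < 0 | counts$n_samples < 0) ||
        any(counts$n_spectra != round(counts$n_spectra)) ||
        any(counts$n_samples != round(counts$n_samples)))
      stop("counts must be non-negative integers")
    if (any(counts$n_samples > counts$n_spectra))
      stop("n_samples cannot exceed n_spectra")
    key <- paste(full$genotype, full$diet, full$week, sep = "\r")
    ckey <- paste(counts$genotype, counts$diet, counts$week, sep = "\r")
    idx <- match(ckey, key)
    full$n_spectra[idx] <- as.integer(counts$n_spectra)
    full$n_samples[idx] <- as.integer(counts$n_samples)
  }
  new("StudyDesign", genotypeLevels = as.character(genotypes),
      dietLevels = as.character(diets), weekLevels = weeks, cells = full)
}

#' @rdname buildDesign
#' @param object a `StudyDesign`.
#' @param ... ignored.
#' @export
setMethod("totalSpectra", "StudyDesign",
          function(object, ...) sum(object@cells$n_spectra))

#' @rdname buildDesign
#' @export
setMethod("totalSamples", "StudyDesign",
          function(object, ...) sum(object@cells$n_samples))

#' @rdname buildDesign
#' @export
setMethod("designCells", "StudyDesign", function(object, ...) object@cells)

setMethod("show", "StudyDesign", function(object) {
  cat("StudyDesign:", length(object@genotypeLevels), "genotypes x",
      length(object@dietLevels), "diets x",
      length(object@weekLevels), "weeks\n")
  cat("  ", totalSpectra(object), "spectra from", totalSamples(object),
      "samples in", sum(object@cells$n_spectra > 0), "non-empty cells\n")
})

#' The diet-induced T2DM mouse profiling design
#'
#' The per-cell spectrum/sample counts of the plasma-profiling study the
#' package emulates: three genotypes (B6, NZO, SJL) crossed with three diets
#' (standard SD, high-fat HF, carbohydrate-free high-fat CHF) sampled at
#' weeks 3, 4, 6 and 8, with up to two preparations of four technical
#' replicate spectra per sample. Two SJL/HF cells are empty because of
#' plasma-collection failures in young lean mice. Totals: 1122 spectra from
#' 155 biological samples.
#'
#' @return A [StudyDesign-class].
#' @examples
#' totalSpectra(mouseStudyDesign())  # 1122
#' @export
mouseStudyDesign <- function() {
  g <- c("B6", "NZO", "SJL")
  d <- c("SD", "HF", "CHF")
  w <- c(3L, 4L, 6L, 8L)
  # per genotype: spectra/samples for (week x diet), diets in SD, HF, CHF order
  tab <- list(
    B6  = list(c(36, 5), c(31, 4), c(12, 2),  c(36, 5), c(40, 5), c(37, 5),
               c(38, 5), c(38, 5), c(32, 5),  c(39, 5), c(34, 5), c(28, 5)),
    NZO = list(c(35, 5), c(35, 5), c(32, 4),  c(40, 5), c(36, 5), c(40, 5),
               c(37, 5), c(38, 5), c(40, 5),  c(28, 5), c(34, 5), c(34, 5)),
    SJL = list(c(4, 1),  c(0, 0),  c(16, 3),  c(12, 2), c(0, 0),  c(40, 5),
               c(32, 4), c(40, 5), c(32, 5),  c(36, 5), c(40, 5), c(40, 5)))
  rows <- do.call(rbind, lapply(g, function(gt) {
    cnt <- do.call(rbind, tab[[gt]])
    data.frame(genotype = gt,
               diet = rep(d, times = length(w)),
               week = rep(w, each = length(d)),
               n_spectra = cnt[, 1], n_samples = cnt[, 2])
  }))
  buildDesign(g, d, w, rows)
}

# ---------------------------------------------------------------------------

#' Peaks-by-profiles intensity matrix
#'
#' `PeakMatrix` extends [SummarizedExperiment::SummarizedExperiment] with one
#' assay `"intensity"` (rows = discrete peak positions, columns = profiles).
#' Row metadata carries the axis index and m/z of each peak; column metadata
#' is the sample sheet. `metadata()` records the profile level
#' (`"replicate"` = one column per spectrum, `"sample"` = technical
#' replicates averaged) and the ordered log of applied transforms.
#'
#' @aliases peakMz peakIndex profileLevel transformLog peakIntensity
#' @export
setClass("PeakMatrix", contains = "SummarizedExperiment")

setValidity("PeakMatrix", function(object) {
  msg <- NULL
  if (!"intensity" %in% assayNames(object))
    msg <- c(msg, "assay 'intensity' is required")
  if (!all(c("index", "mz") %in% names(rowData(object))))
    msg <- c(msg, "rowData must contain 'index' and 'mz'")
  lev <- metadata(object)$level
  if (is.null(lev) || !lev %in% c("replicate", "sample"))
    msg <- c(msg, "metadata()$level must be 'replicate' or 'sample'")
  if (is.null(msg)) TRUE else msg
})

#' @param intensity numeric matrix, peaks x profiles.
#' @param peakIndex integer axis index of each peak.
#' @param peakMz numeric m/z of each peak.
#' @param sampleInfo data.frame of per-profile metadata (one row per column).
#' @param level `"replicate"` or `"sample"`.
#' @param transformLog character vector of transforms applied so far.
#' @return A `PeakMatrix`.
#' @rdname PeakMatrix-class
#' @export
PeakMatrix <- function(intensity, peakIndex, peakMz, sampleInfo = NULL,
                       level = "replicate", transformLog = character()) {
  intensity <- as.matrix(intensity)
  if (is.null(sampleInfo))
    sampleInfo <- data.frame(row.names = colnames(intensity))
  rd <- DataFrame(index = as.integer(peakIndex), mz = as.numeric(peakMz))
  if (is.null(rownames(intensity)))
    rownames(intensity) <- sprintf("peak_%04.0f", round(peakMz))
  rownames(rd) <- rownames(intensity)
  se <- SummarizedExperiment(assays = SimpleList(intensity = intensity),
                             rowData = rd, colData = DataFrame(sampleInfo))
  metadata(se)$level <- level
  metadata(se)$transformLog <- transformLog
  new("PeakMatrix", se)
}

#' @rdname PeakMatrix-class
#' @param object a `PeakMatrix`.
#' @param ... ignored.
#' @export
setMethod("peakMz", "PeakMatrix",
          function(object, ...) rowData(object)$mz)

#' @rdname PeakMatrix-class
#' @export
setMethod("peakIndex", "PeakMatrix",
          function(object, ...) rowData(object)$index)

#' @rdname PeakMatrix-class
#' @export
setMethod("profileLevel", "PeakMatrix",
          function(object, ...) metadata(object)$level)

#' @rdname PeakMatrix-class
#' @export
setMethod("transformLog", "PeakMatrix",
          function(object, ...) metadata(object)$transformLog)

#' @rdname PeakMatrix-class
#' @param x a `PeakMatrix`.
#' @export
peakIntensity <- function(x) assay(x, "intensity")

setMethod("show", "PeakMatrix", function(object) {
  cat("PeakMatrix:", nrow(object), "peaks x", ncol(object), "profiles (",
      metadata(object)$level, "level )\n")
  tl <- metadata(object)$transformLog
  if (length(tl)) cat("  transforms:", paste(tl, collapse = " -> "), "\n")
  callNextMethod()
})

# ---------------------------------------------------------------------------

setOldClass("hclust")

#' Annotated average-linkage dendrogram of peak intensity profiles
#'
#' A `ClusterTree` wraps the [stats::hclust] merge tree built on the
#' 1 - Pearson-correlation distance between peak intensity profiles, plus a
#' per-node annotation table: member peaks, merge height, mean pairwise
#' Pearson correlation of the members, and the four factor-wise ANOVA
#' p-values computed on the node's mean z-transformed profile. Nodes are
#' labelled `L<i>` for leaves and `N<k>` for the k-th merge.
#'
#' @slot hclust the underlying `hclust` object.
#' @slot nodes data.frame: `node`, `height`, `n_members`, `mean_cor`,
#'   `p_diet`, `p_genotype`, `p_week`, `p_interaction`.
#' @slot members named list mapping node labels to member peak ids.
#'
#' @aliases nodeTable nodeMembers
#' @export
setClass("ClusterTree",
  representation(hclust = "hclust", nodes = "data.frame", members = "list"))

setValidity("ClusterTree", function(object) {
  msg <- NULL
  n <- length(object@hclust$labels)
  if (nrow(object@nodes) != 2L * n - 1L)
    msg <- c(msg, "nodes must have one row per leaf and per merge")
  pcols <- grep("^p_", names(object@nodes), value = TRUE)
  for (pc in pcols) {
    pv <- object@nodes[[pc]]
    if (any(!is.na(pv) & (pv <= 0 | pv > 1)))
      msg <- c(msg, sprintf("%s outside (0, 1]", pc))
  }
  if (is.null(msg)) TRUE else msg
})

#' @rdname ClusterTree-class
#' @param object a `ClusterTree`.
#' @param ... ignored.
#' @export
setMethod("nodeTable", "ClusterTree", function(object, ...) object@nodes)

#' @rdname ClusterTree-class
#' @export
setMethod("nodeMembers", "ClusterTree", function(object, ...) object@members)

setMethod("show", "ClusterTree", function(object) {
  n <- length(object@hclust$labels)
  cat("ClusterTree:", n, "peaks,", n - 1L, "merges\n")
  cat("  merge heights:", format(min(object@hclust$height), digits = 3), "-",
      format(max(object@hclust$height), digits = 3), "\n")
})
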