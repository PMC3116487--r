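## Spectral pre-processing: log transform, median smoothing, morphological
## tophat baseline removal, index-shift alignment against reference peaks,
## peak quantification, variance stabilization and technical-replicate
## averaging.

#' Log-transform a raw spectrum
#'
#' First step of the pre-processing chain: `y -> log(y + guard)`. The guard
#' constant keeps zero intensities representable (`log(0 + 1) = 0`).
#'
#' @param spectrum a raw [MassSpectrum-class].
#' @param guard non-negative guard constant added before the log (default 1).
#' @return The spectrum at stage `"logged"`.
#' @export
logTransform <- function(spectrum, guard = 1) {
  stopifnot(is(spectrum, "MassSpectrum"))
  if (spectrum@stage != "raw")
    stop("logTransform() expects a raw spectrum, got stage '",
         spectrum@stage, "'")
  if (any(spectrum@intensity < 0))
    stop("negative raw intensities in spectrum '", spectrum@spectrumId, "'")
  spectrum@intensity <- log(spectrum@intensity + guard)
  .advanceStage(spectrum, "logged")
}

#' Median-filter smoothing
#'
#' Each point is replaced by the median of its centred window; at the edges
#' the window shrinks symmetrically so that it stays inside the spectrum.
#'
#' @param spectrum a logged [MassSpectrum-class].
#' @param window odd window size >= 3 (default 9).
#' @return The spectrum at stage `"smoothed"`.
#' @export
medianSmooth <- function(spectrum, window = 9) {
  stopifnot(is(spectrum, "MassSpectrum"))
  if (spectrum@stage != "logged")
    stop("medianSmooth() expects a logged spectrum")
  n <- length(spectrum@intensity)
  if (window %% 2 == 0 || window < 3)
    stop("window must be odd and >= 3")
  if (window > n)
    stop("window larger than the spectrum")
  x <- spectrum@intensity
  out <- runmed(x, window, endrule = "keep")
  h <- (window - 1L) %/% 2L
  for (i in c(seq_len(h), (n - h + 1L):n)) {
    h2 <- min(h, i - 1L, n - i)
    out[i] <- median(x[(i - h2):(i + h2)])
  }
  spectrum@intensity <- as.numeric(out)
  .advanceStage(spectrum, "smoothed")
}

## centred running extreme with a flat window of odd width w; edge windows
## shrink (achieved by +/-Inf padding). van Herk-Gil-Werman block scheme:
## O(n) regardless of window width.
.runningExtreme <- function(x, w, maximum = FALSE) {
  n <- length(x)
  h <- (w - 1L) %/% 2L
  pad <- if (maximum) -Inf else Inf
  cum <- if (maximum) cummax else cummin
  agg <- if (maximum) pmax else pmin
  xp <- c(rep(pad, h), x, rep(pad, h))
  m <- length(xp)
  nb <- ceiling(m / w)
  xpp <- c(xp, rep(pad, nb * w - m))
  mat <- matrix(xpp, nrow = w)
  pref <- apply(mat, 2L, cum)
  suff <- apply(mat[w:1, , drop = FALSE], 2L, cum)[w:1, , drop = FALSE]
  idx <- seq_len(n)
  agg(as.vector(suff)[idx], as.vector(pref)[idx + w - 1L])
}

#' Tophat baseline correction
#'
#' Subtracts the morphological opening (erosion followed by dilation with a
#' flat structuring element of `structWidth` points) from the smoothed
#' spectrum. The opening tracks the slowly varying baseline underneath peaks
#' narrower than the structuring element, so the output preserves narrow
#' peaks, removes the baseline, and is non-negative everywhere.
#'
#' @param spectrum a smoothed [MassSpectrum-class].
#' @param structWidth odd structuring-element width in index units
#'   (default 151: much wider than peak widths, narrower than baseline
#'   undulations).
#' @return The spectrum at stage `"baselined"`.
#' @export
tophatBaseline <- function(spectrum, structWidth = 151) {
  stopifnot(is(spectrum, "MassSpectrum"))
  if (spectrum@stage != "smoothed")
    stop("tophatBaseline() expects a smoothed spectrum")
  if (structWidth %% 2 == 0) stop("structWidth must be odd")
  if (structWidth < 3) stop("structWidth below the peak-resolving minimum (3)")
  op <- morphologicalOpening(spectrum@intensity, structWidth)
  spectrum@intensity <- spectrum@intensity - op
  .advanceStage(spectrum, "baselined")
}

#' Morphological opening with a flat structuring element
#'
#' @param x numeric vector.
#' @param width odd structuring-element width.
#' @return Numeric vector of the same length; `opening(x) <= x` pointwise,
#'   and opening is idempotent.
#' @export
morphologicalOpening <- function(x, width) {
  if (width %% 2 == 0) stop("width must be odd")
  eroded <- .runningExtreme(x, width, maximum = FALSE)
  .runningExtreme(eroded, width, maximum = TRUE)
}

#' Index-shift estimation against reference peaks
#'
#' For every reference apex, the nearest observed apex within `window` index
#' positions (if any) contributes the signed distance observed minus
#' reference; the spectrum's shift is the mean of these distances rounded
#' half away from zero. With no match at all the shift is 0 and the result is
#' flagged.
#'
#' @param peakset picked peaks of one spectrum (data.frame with column
#'   `index`, as returned by [cwtPickPeaks()]).
#' @param reference reference peaks (data.frame with column `index`).
#' @param window match window in index positions (default 30).
#' @return list with `spectrumId`, `shift` (integer), `nMatched`, `flag`
#'   (`"no_match"` or `""`).
#' @export
alignShift <- function(peakset, reference, window = 30) {
  obs <- peakset$index
  ref <- reference$index
  d <- numeric(0)
  for (r in ref) {
    if (!length(obs)) break
    j <- which.min(abs(obs - r))
    if (abs(obs[j] - r) <= window) d <- c(d, obs[j] - r)
  }
  if (!length(d)) {
    warning("no peak matched any reference peak; shift set to 0")
    return(list(spectrumId = attr(peakset, "spectrumId"), shift = 0L,
                nMatched = 0L, flag = "no_match"))
  }
  m <- mean(d)
  shift <- as.integer(sign(m) * floor(abs(m) + 0.5))  # half away from zero
  list(spectrumId = attr(peakset, "spectrumId"), shift = shift,
       nMatched = length(d), flag = "")
}

#' Translate a spectrum onto the reference index coordinates
#'
#' Intensities are translated by `-shift` index positions so that features
#' observed at `reference + shift` land on the reference coordinates; the
#' vacated edge is filled with the boundary value.
#'
#' @param spectrum a [MassSpectrum-class].
#' @param shift signed integer index shift (as estimated by [alignShift()]).
#' @return The spectrum at stage `"aligned"`.
#' @export
applyShift <- function(spectrum, shift) {
  stopifnot(is(spectrum, "MassSpectrum"))
  n <- length(spectrum@intensity)
  shift <- as.integer(shift)
  if (abs(shift) >= n) stop("|shift| must be smaller than the spectrum length")
  idx <- seq_len(n) + shift
  idx[idx < 1L] <- 1L
  idx[idx > n] <- n
  spectrum@intensity <- spectrum@intensity[idx]
  .advanceStage(spectrum, "aligned")
}

#' Quantify peak intensities at reference positions
#'
#' For every reference apex the intensity is the maximum within `q` index
#' positions on either side (robust to residual misalignment of a few
#' points); windows reaching outside the axis are clipped.
#'
#' @param spectrum an aligned [MassSpectrum-class].
#' @param reference reference peaks (data.frame with column `index`).
#' @param q half-width of the quantification window (default 4; `q = 0`
#'   reads the value at the exact index).
#' @return Numeric vector, one intensity per reference peak.
#' @export
quantifyPeaks <- function(spectrum, reference, q = 4) {
  stopifnot(is(spectrum, "MassSpectrum"))
  if (spectrum@stage != "aligned")
    stop("quantifyPeaks() expects an aligned spectrum")
  n <- length(spectrum@intensity)
  vapply(reference$index, function(i) {
    win <- max(1L, i - q):min(n, i + q)
    max(spectrum@intensity[win])
  }, numeric(1))
}

#' Second log transform stabilizing the peak-intensity variance
#'
#' Applies `v -> log(v + pseudoCount) + offset` elementwise to a
#' replicate-level peak matrix. Peak intensities carry a multiplicative error
#' component even after the continuous-spectrum transforms, visible as a
#' linear dependence of the replicate standard error on the mean intensity;
#' this second log with a pseudo-count removes it (see
#' [varianceDiagnostic()]).
#'
#' @param x a replicate-level [PeakMatrix-class].
#' @param pseudoCount guard added before the log (default 0.1).
#' @param offset constant added afterwards for convenience (default 0).
#' @return The transformed `PeakMatrix`; `transformLog` records both steps.
#' @export
stabilizeVariance <- function(x, pseudoCount = 0.1, offset = 0) {
  stopifnot(is(x, "PeakMatrix"))
  if (profileLevel(x) != "replicate")
    stop("stabilizeVariance() expects a replicate-level matrix")
  v <- assay(x, "intensity")
  if (any(v + pseudoCount <= 0))
    stop("intensities with v + pseudoCount <= 0 cannot be log-transformed")
  assay(x, "intensity") <- log(v + pseudoCount) + offset
  metadata(x)$transformLog <- c(metadata(x)$transformLog,
                                sprintf("log(x + %g)", pseudoCount),
                                sprintf("offset %g", offset))
  x
}

#' Replicate-group error diagnostic for homoscedasticity
#'
#' For every (peak, replicate group) with at least two replicates the mean
#' intensity and the standard error are computed; a least-squares line and a
#' lowess curve are fitted to the (mean, se) cloud. A positive slope
#' indicates a multiplicative error component; a slope near 0 indicates the
#' homoscedasticity required by ANOVA.
#'
#' @param x a replicate-level [PeakMatrix-class] or a plain peaks-by-profiles
#'   matrix.
#' @param groups replicate grouping of the profiles (defaults to the
#'   `sample_id` column of `colData(x)` for a `PeakMatrix`).
#' @param lowessFraction lowess smoother span (default 2/3).
#' @param maxLowessPoints lowess is evaluated on at most this many
#'   evenly-spaced points of the cloud.
#' @return A `VarianceDiagnostic` list: `points` (mean, se per peak x group),
#'   `slope`, `intercept`, `lowess`.
#' @export
varianceDiagnostic <- function(x, groups = NULL, lowessFraction = 2 / 3,
                               maxLowessPoints = 2000) {
  if (is(x, "PeakMatrix")) {
    if (is.null(groups)) groups <- colData(x)$sample_id
    x <- assay(x, "intensity")
  }
  stopifnot(is.matrix(x), length(groups) == ncol(x))
  groups <- as.factor(groups)
  keep <- levels(groups)[table(groups) >= 2L]
  if (!length(keep))
    stop("no replicate group with >= 2 replicates")
  pieces <- lapply(keep, function(g) {
    sub <- x[, groups == g, drop = FALSE]
    data.frame(group = g,
               peak = seq_len(nrow(x)),
               mean = rowMeans(sub),
               se = apply(sub, 1L, sd) / sqrt(ncol(sub)))
  })
  pts <- do.call(rbind, pieces)
  fit <- lm(se ~ mean, data = pts)
  ord <- order(pts$mean)
  sub <- ord[unique(round(seq(1, length(ord),
                              length.out = min(maxLowessPoints,
                                               length(ord)))))]
  lw <- lowess(pts$mean[sub], pts$se[sub], f = lowessFraction)
  structure(list(points = pts,
                 slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 lowess = data.frame(mean = lw$x, se = lw$y)),
            class = "VarianceDiagnostic")
}

#' @export
print.VarianceDiagnostic <- function(x, ...) {
  cat("VarianceDiagnostic:", nrow(x$points), "(peak, group) points\n")
  cat(sprintf("  se ~ mean: slope %.4g, intercept %.4g\n",
              x$slope, x$intercept))
  invisible(x)
}

#' Average technical replicates into sample-level profiles
#'
#' Technical replicates are not independent and would violate the ANOVA
#' assumptions, so each sample's replicate columns are averaged
#' (arithmetically, on the variance-stabilized scale) into one profile.
#'
#' @param x a replicate-level [PeakMatrix-class] whose `colData` maps every
#'   profile to a `sample_id` (plus `genotype`, `diet`, `week`).
#' @return A sample-level `PeakMatrix` with one column per sample.
#' @export
averageTechnicalReplicates <- function(x) {
  stopifnot(is(x, "PeakMatrix"))
  if (profileLevel(x) != "replicate")
    stop("averageTechnicalReplicates() expects a replicate-level matrix")
  cd <- colData(x)
  if (is.null(cd$sample_id) || anyNA(cd$sample_id))
    stop("every profile must be mapped to a sample_id")
  sid <- as.character(cd$sample_id)
  samples <- unique(sid)
  v <- assay(x, "intensity")
  avg <- vapply(samples, function(s)
    rowMeans(v[, sid == s, drop = FALSE]), numeric(nrow(v)))
  avg <- matrix(avg, nrow = nrow(v), dimnames = list(rownames(v), samples))
  first <- match(samples, sid)
  info <- data.frame(sample_id = samples,
                     genotype = cd$genotype[first],
                     diet = cd$diet[first],
                     week = cd$week[first],
                     n_replicates = as.integer(table(sid)[samples]),
                     row.names = samples)
  PeakMatrix(avg, peakIndex = peakIndex(x), peakMz = peakMz(x),
             sampleInfo = info, level = "sample",
             transformLog = c(transformLog(x), "replicate_average"))
}

#' Run the full pre-processing chain on a set of raw spectra
#'
#' For every raw spectrum: log transform, median smoothing, tophat baseline
#' correction. Reference peaks are then picked from the pointwise mean of the
#' baselined spectra; every spectrum is CWT-picked, its index shift against
#' the reference estimated and applied (one pass), and peak intensities are
#' quantified at the reference positions, yielding a replicate-level
#' [PeakMatrix-class].
#'
#' @param spectra list of raw [MassSpectrum-class] objects on a shared axis.
#' @param sampleSheet optional data.frame with one row per spectrum
#'   (matched by `spectrum_id`) that becomes the matrix `colData`.
#' @param guard,smoothWindow,structWidth,quantWindow,alignWindow chain
#'   parameters, see the individual steps.
#' @param ... further arguments passed to [cwtPickPeaks()].
#' @return A replicate-level `PeakMatrix`; `metadata()` carries the
#'   `reference` peak table and the per-spectrum `shifts` table.
#' @export
preprocessSpectra <- function(spectra, sampleSheet = NULL, guard = 1,
                              smoothWindow = 9, structWidth = 151,
                              alignWindow = 30, quantWindow = 4, ...) {
  stopifnot(length(spectra) >= 1L)
  baselined <- lapply(spectra, function(s)
    tophatBaseline(medianSmooth(logTransform(s, guard = guard),
                                window = smoothWindow),
                   structWidth = structWidth))
  reference <- computeReferencePeaks(baselined, ...)
  shifts <- vector("list", length(baselined))
  aligned <- vector("list", length(baselined))
  for (i in seq_along(baselined)) {
    pk <- cwtPickPeaks(baselined[[i]], ...)
    sh <- alignShift(pk, reference, window = alignWindow)
    shifts[[i]] <- data.frame(spectrum_id = spectrumId(baselined[[i]]),
                              shift = sh$shift, n_matched = sh$nMatched,
                              flag = sh$flag)
    aligned[[i]] <- applyShift(baselined[[i]], sh$shift)
  }
  shifts <- do.call(rbind, shifts)
  vals <- vapply(aligned, quantifyPeaks, numeric(nrow(reference)),
                 reference = reference, q = quantWindow)
  vals <- matrix(vals, nrow = nrow(reference))
  colnames(vals) <- vapply(aligned, spectrumId, character(1))
  info <- NULL
  if (!is.null(sampleSheet)) {
    m <- match(colnames(vals), sampleSheet$spectrum_id)
    if (anyNA(m)) stop("sampleSheet is missing spectra: ",
                       paste(colnames(vals)[is.na(m)], collapse = ", "))
    info <- sampleSheet[m, , drop = FALSE]
    rownames(info) <- info$spectrum_id
  }
  mzAxis <- mz(spectra[[1]])
  pm <- PeakMatrix(vals, peakIndex = reference$index,
                   peakMz = mzAxis[reference$index], sampleInfo = info,
                   level = "replicate",
                   transformLog = c(sprintf("log(x + %g)", guard),
                                    sprintf("median_smooth(%d)", smoothWindow),
                                    sprintf("tophat(%d)", structWidth),
                                    "aligned"))
  metadata(pm)$reference <- reference
  metadata(pm)$shifts <- shifts
  pm
}
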