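## Continuous-wavelet-transform peak picking with Mexican-hat mother wavelet
## and ridge-line tracking across scales. The implicit smoothing of the CWT
## makes picking robust to noise: a genuine peak produces a coefficient
## ridge persisting over many scales, noise spikes do not.

## Mexican hat (negative normalized second derivative of a Gaussian)
.mexicanHat <- function(t) {
  (2 / (sqrt(3) * pi^0.25)) * (1 - t^2) * exp(-t^2 / 2)
}

## CWT coefficient matrix (axis points x scales), computed by FFT
## convolution; the signal is edge-padded so every coefficient uses a full
## wavelet support.
.cwtMatrix <- function(x, scales) {
  n <- length(x)
  W <- matrix(0, n, length(scales))
  for (k in seq_along(scales)) {
    s <- scales[k]
    supp <- seq(-ceiling(8 * s), ceiling(8 * s))
    psi <- .mexicanHat(supp / s)
    psi <- psi - mean(psi)
    half <- (length(psi) - 1L) %/% 2L
    xp <- c(rep(x[1], half), x, rep(x[n], half))
    W[, k] <- convolve(xp, psi, type = "filter") / sqrt(s)
  }
  W
}

## positions of strict local maxima of v that dominate a +/- halfWin window
## and are positive
.localMaxima <- function(v, halfWin) {
  n <- length(v)
  if (n < 3L) return(integer(0))
  cand <- which(diff(sign(diff(v))) < 0) + 1L
  cand <- cand[v[cand] > 0]
  keep <- vapply(cand, function(i) {
    lo <- max(1L, i - halfWin); hi <- min(n, i + halfWin)
    v[i] >= max(v[lo:hi])
  }, logical(1))
  cand[keep]
}

#' CWT ridge-line peak picking
#'
#' Computes the continuous wavelet transform of a baselined spectrum with a
#' Mexican-hat mother wavelet over the integer scale ladder
#' `scaleMin:scaleMax`, tracks ridge lines of coefficient local maxima from
#' the coarsest scale down to the finest, and reports an apex for every
#' ridge that (i) spans at least `lengthMin` scales and (ii) exceeds the
#' noise threshold. The noise level is the `noiseQuantile` quantile of the
#' absolute finest-scale coefficients in a window around the apex, and SNR
#' is the ridge's maximum coefficient over that level. Apexes are reported
#' at the finest-scale ridge position.
#'
#' @param spectrum a baselined [MassSpectrum-class] (or the mean spectrum).
#' @param scaleMin finest scale of the ladder (default 3).
#' @param lengthMin minimum ridge length in scales (default 7).
#' @param noiseQuantile quantile defining the noise level (default 0.95).
#' @param snrMin minimum signal-to-noise ratio (default 3).
#' @param scaleMax coarsest scale of the ladder (default 24).
#' @param noiseWindow half-width of the local noise-estimation window
#'   (default 500 index positions).
#' @param gapMax ridge tracking tolerates this many consecutive scales
#'   without a matching maximum (default 3).
#' @return data.frame with columns `index` (apex, strictly increasing),
#'   `snr`, `scale` (ridge-maximum scale), `length` (ridge length); the
#'   spectrum id is attached as attribute `spectrumId`.
#' @examples
#' flat <- MassSpectrum(1:200, rep(0, 200), stage = "baselined")
#' nrow(cwtPickPeaks(flat))  # 0
#' @export
cwtPickPeaks <- function(spectrum, scaleMin = 3, lengthMin = 7,
                         noiseQuantile = 0.95, snrMin = 3, scaleMax = 24,
                         noiseWindow = 500, gapMax = 3) {
  stopifnot(is(spectrum, "MassSpectrum"))
  x <- intensity(spectrum)
  n <- length(x)
  if (n < 64L) stop("spectrum shorter than the minimum CWT support")
  scales <- seq.int(scaleMin, scaleMax)
  scales <- scales[2 * ceiling(8 * scales) + 1 <= n]
  if (!length(scales)) stop("spectrum shorter than the minimum CWT support")
  W <- .cwtMatrix(x, scales)
  J <- length(scales)

  empty <- data.frame(index = integer(0), snr = numeric(0),
                      scale = numeric(0), length = integer(0))
  attr(empty, "spectrumId") <- spectrumId(spectrum)

  ## track ridges coarse -> fine
  ridges <- list()   # each: pos (current), scaleIdx (vector), posHist, gap
  active <- integer(0)
  for (k in J:1) {
    s <- scales[k]
    maxima <- .localMaxima(W[, k], halfWin = max(2L, ceiling(s)))
    claimed <- rep(FALSE, length(maxima))
    winLink <- max(4, ceiling(s))
    surviving <- integer(0)
    for (ri in active) {
      r <- ridges[[ri]]
      j <- NA_integer_
      if (length(maxima)) {
        free <- which(!claimed)
        if (length(free)) {
          jj <- free[which.min(abs(maxima[free] - r$pos))]
          if (abs(maxima[jj] - r$pos) <= winLink) j <- jj
        }
      }
      if (!is.na(j)) {
        claimed[j] <- TRUE
        r$pos <- maxima[j]
        r$scaleIdx <- c(r$scaleIdx, k)
        r$posHist <- c(r$posHist, maxima[j])
        r$gap <- 0L
        ridges[[ri]] <- r
        surviving <- c(surviving, ri)
      } else {
        r$gap <- r$gap + 1L
        ridges[[ri]] <- r
        if (r$gap <= gapMax) surviving <- c(surviving, ri)
      }
    }
    for (j in which(!claimed)) {
      ridges[[length(ridges) + 1L]] <- list(pos = maxima[j], scaleIdx = k,
                                            posHist = maxima[j], gap = 0L)
      surviving <- c(surviving, length(ridges))
    }
    active <- surviving
  }
  if (!length(ridges)) return(empty)

  peaks <- do.call(rbind, lapply(ridges, function(r) {
    len <- length(r$scaleIdx)
    coefs <- W[cbind(r$posHist, r$scaleIdx)]
    best <- which.max(coefs)
    fin <- which.min(r$scaleIdx)  # finest linked scale
    data.frame(index = r$posHist[fin], coef = coefs[best],
               scale = scales[r$scaleIdx[best]], length = len)
  }))
  peaks <- peaks[peaks$length >= lengthMin, , drop = FALSE]
  if (!nrow(peaks)) return(empty)

  ## SNR against local finest-scale noise
  fine <- abs(W[, 1])
  peaks$snr <- vapply(seq_len(nrow(peaks)), function(i) {
    ctr <- peaks$index[i]
    win <- max(1L, ctr - noiseWindow):min(n, ctr + noiseWindow)
    noise <- quantile(fine[win], noiseQuantile, names = FALSE)
    if (noise < .Machine$double.eps) Inf else peaks$coef[i] / noise
  }, numeric(1))
  peaks <- peaks[peaks$snr >= snrMin, , drop = FALSE]
  if (!nrow(peaks)) return(empty)

  ## de-duplicate apexes closer than 3 indices, keeping the stronger ridge
  peaks <- peaks[order(-peaks$snr, peaks$index), , drop = FALSE]
  kept <- integer(0)
  for (i in seq_len(nrow(peaks))) {
    if (!length(kept) || all(abs(peaks$index[kept] - peaks$index[i]) >= 3))
      kept <- c(kept, i)
  }
  peaks <- peaks[kept, , drop = FALSE]
  peaks <- peaks[order(peaks$index), c("index", "snr", "scale", "length")]
  rownames(peaks) <- NULL
  attr(peaks, "spectrumId") <- spectrumId(spectrum)
  peaks
}

#' Reference peaks from the mean spectrum
#'
#' Computes the pointwise mean of all baselined spectra and applies
#' [cwtPickPeaks()] to it. The resulting apex list is the common coordinate
#' system that individual spectra are aligned to and quantified at.
#'
#' @param spectra list of baselined [MassSpectrum-class] objects of equal
#'   length.
#' @param ... passed to [cwtPickPeaks()].
#' @return data.frame of reference peaks (columns as in [cwtPickPeaks()]).
#' @export
computeReferencePeaks <- function(spectra, ...) {
  stopifnot(length(spectra) >= 1L)
  lens <- vapply(spectra, length, integer(1))
  if (length(unique(lens)) != 1L)
    stop("all spectra must have the same length")
  stages <- vapply(spectra, stage, character(1))
  if (!all(stages == "baselined"))
    stop("reference peaks are computed on baselined spectra")
  avg <- rowMeans(vapply(spectra, intensity, numeric(lens[1])))
  meanSpec <- MassSpectrum(mz(spectra[[1]]), avg, spectrumId = "mean",
                           stage = "baselined")
  cwtPickPeaks(meanSpec, ...)
}
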