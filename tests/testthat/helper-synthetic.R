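# shared fixture builders: everything is generated in code at test time

# a single-cell design: nSpectra acquisitions spread over nSamples samples
cellDesign <- function(nSpectra, nSamples, genotype = "B6", diet = "SD",
                       week = 3L) {
  buildDesign(genotype, diet, week,
              data.frame(genotype = genotype, diet = diet, week = week,
                         n_spectra = nSpectra, n_samples = nSamples))
}

# fully crossed design, nSamples samples x nReps replicates per cell
crossedDesign <- function(genotypes = c("B6", "NZO", "SJL"),
                          diets = c("SD", "HF", "CHF"),
                          weeks = c(3L, 8L), nSamples = 3L, nReps = 2L) {
  cells <- expand.grid(genotype = genotypes, diet = diets, week = weeks,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  cells$n_spectra <- nSamples * nReps
  cells$n_samples <- nSamples
  buildDesign(genotypes, diets, weeks, cells)
}

# sample-level metadata of the full mouse study (155 samples)
mouseSampleInfo <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      sim <- simulateIntensityMatrix(
        mouseStudyDesign(),
        peakFamilies(nFamilies = 0, peaksPerFamily = 0, nSingletons = 2),
        seed = 1)
      sheet <- sim$sampleSheet
      cache <<- sheet[!duplicated(sheet$sample_id),
                      c("sample_id", "genotype", "diet", "week")]
    }
    cache
  }
})

# Gaussian bumps on a flat line, for constructed-spectrum tests
gaussianSpectrum <- function(n, apexes, heights, sd = 3, noiseSd = 0,
                             seed = NULL, stage = "baselined") {
  y <- rep(0, n)
  for (i in seq_along(apexes))
    y <- y + heights[i] * exp(-((seq_len(n) - apexes[i])^2) / (2 * sd^2))
  if (noiseSd > 0) {
    if (!is.null(seed)) set.seed(seed)
    y <- y + rnorm(n, sd = noiseSd)
  }
  MassSpectrum(seq_len(n), y, spectrumId = "constructed", stage = stage)
}

# log -> median smooth -> tophat, the continuous-spectrum part of the chain
baselineChain <- function(s, ...) {
  tophatBaseline(medianSmooth(logTransform(s), window = 9), ...)
}
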