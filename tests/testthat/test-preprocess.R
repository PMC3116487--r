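test_that("logTransform handles zeros, analytic values and preserves order", {
  z <- MassSpectrum(1:10, rep(0, 10))
  expect_equal(intensity(logTransform(z)), rep(0, 10))
  e <- MassSpectrum(1:3, rep(exp(1) - 1, 3))
  expect_equal(intensity(logTransform(e)), rep(1, 3))
  set.seed(1)
  r <- MassSpectrum(1:50, runif(50, 0, 100))
  expect_identical(order(intensity(logTransform(r))), order(intensity(r)))
  expect_error(logTransform(MassSpectrum(1:3, c(1, -1, 1))), "negative")
  expect_error(logTransform(logTransform(z)), "raw")
})

test_that("medianSmooth matches a brute-force shrinking-window median", {
  naive <- function(x, k) {
    h <- (k - 1) %/% 2
    n <- length(x)
    vapply(seq_len(n), function(i) {
      h2 <- min(h, i - 1, n - i)
      median(x[(i - h2):(i + h2)])
    }, numeric(1))
  }
  const <- logTransform(MassSpectrum(1:30, rep(3, 30)))
  expect_equal(intensity(medianSmooth(const)), rep(log(4), 30))
  # a 1-point spike on a ramp disappears, the ramp survives
  ramp <- seq(0, 5, length.out = 60)
  spiked <- ramp; spiked[30] <- 50
  s <- medianSmooth(MassSpectrum(1:60, spiked, stage = "logged"), window = 9)
  expect_equal(intensity(s), naive(spiked, 9))
  expect_lt(max(abs(intensity(s)[25:35] - ramp[25:35])), 0.4)
  # random input agrees with the oracle everywhere, including edges
  set.seed(7)
  x <- rnorm(101)
  sm <- medianSmooth(MassSpectrum(1:101, x, stage = "logged"), window = 11)
  expect_equal(intensity(sm), naive(x, 11))
  # monotone input stays monotone
  mono <- cumsum(abs(rnorm(80)))
  out <- intensity(medianSmooth(MassSpectrum(1:80, mono, stage = "logged")))
  expect_true(all(diff(out) >= 0))
  expect_error(medianSmooth(MassSpectrum(1:30, rep(1, 30), stage = "logged"),
                            window = 8), "odd")
  expect_error(medianSmooth(MassSpectrum(1:5, rep(1, 5), stage = "logged"),
                            window = 7), "larger")
})

test_that("tophat equals the brute-force erosion/dilation oracle", {
  naiveOpen <- function(x, w) {
    h <- (w - 1) %/% 2
    n <- length(x)
    er <- vapply(seq_len(n), function(i)
      min(x[max(1, i - h):min(n, i + h)]), numeric(1))
    vapply(seq_len(n), function(i)
      max(er[max(1, i - h):min(n, i + h)]), numeric(1))
  }
  set.seed(3)
  x <- pmax(0, 10 * sin(seq(0, 3, length.out = 300)) + rnorm(300))
  expect_equal(morphologicalOpening(x, 31), naiveOpen(x, 31))
  # narrow peaks on a linear baseline: baseline removed, apexes preserved
  base <- seq(2, 4, length.out = 400)
  y <- base
  apexes <- c(100, 200, 300)
  for (a in apexes) y <- y + 10 * exp(-((seq_len(400) - a)^2) / 18)
  s <- MassSpectrum(1:400, y, stage = "smoothed")
  th <- tophatBaseline(s, structWidth = 151)
  expect_true(all(intensity(th) >= 0))
  expect_true(all(intensity(th) <= intensity(s) + 1e-12))
  expect_equal(intensity(th)[apexes], rep(10, 3), tolerance = 0.01)
  # baseline gone away from the peaks (the right border keeps a ramp
  # remnant of half a structuring element, intrinsic to the opening)
  expect_lt(max(intensity(th)[c(1:60, 140:160, 240:260)]), 0.2)
  # opening is idempotent; a constant spectrum has zero tophat
  op <- morphologicalOpening(y, 151)
  expect_equal(morphologicalOpening(op, 151), op)
  const <- MassSpectrum(1:100, rep(4, 100), stage = "smoothed")
  expect_equal(intensity(tophatBaseline(const, 31)), rep(0, 100))
  expect_error(tophatBaseline(s, structWidth = 150), "odd")
  expect_error(tophatBaseline(s, structWidth = 1), "minimum")
})

test_that("applyShift is an edge-filled translation composing additively", {
  y <- sin(seq(0, 10, length.out = 200))
  s <- MassSpectrum(1:200, y, stage = "baselined")
  expect_equal(intensity(applyShift(s, 0)), y)
  a <- applyShift(s, 5)
  expect_identical(stage(a), "aligned")
  expect_equal(intensity(a)[1:190], y[6:195])
  ab <- applyShift(applyShift(s, 3), 4)
  once <- applyShift(s, 7)
  interior <- 20:180
  expect_equal(intensity(ab)[interior], intensity(once)[interior])
  expect_error(applyShift(s, 200), "smaller than the spectrum length")
})

test_that("quantifyPeaks reads apex heights within the window", {
  y <- rep(0, 100); y[50] <- 7
  s <- MassSpectrum(1:100, y, stage = "aligned")
  ref <- data.frame(index = 50)
  expect_equal(quantifyPeaks(s, ref), 7)
  expect_equal(quantifyPeaks(s, data.frame(index = 47), q = 4), 7)
  expect_equal(quantifyPeaks(s, data.frame(index = 47), q = 0), 0)
  # clipped window at the axis end
  expect_equal(quantifyPeaks(s, data.frame(index = 99), q = 4), 0)
  expect_error(quantifyPeaks(MassSpectrum(1:100, y), ref), "aligned")
})

test_that("stabilizeVariance applies log(v + 0.1) + offset and logs it", {
  m <- matrix(c(0.9, 0.9, 1.9, 1.9), 2, 2,
              dimnames = list(c("a", "b"), c("s1", "s2")))
  pm <- PeakMatrix(m, peakIndex = c(1L, 2L), peakMz = c(100, 200),
                   sampleInfo = data.frame(sample_id = c("s1", "s2"),
                                           row.names = c("s1", "s2")))
  st <- stabilizeVariance(pm)
  expect_equal(unname(assay(st, "intensity")[1, 1]), 0)
  st5 <- stabilizeVariance(pm, offset = 5)
  expect_equal(assay(st5, "intensity"), assay(st, "intensity") + 5)
  expect_identical(tail(transformLog(st5), 2),
                   c("log(x + 0.1)", "offset 5"))
  avg <- averageTechnicalReplicates(
    PeakMatrix(m, peakIndex = c(1L, 2L), peakMz = c(100, 200),
               sampleInfo = data.frame(sample_id = c("s1", "s2"),
                                       genotype = "B6", diet = "SD",
                                       week = 3L,
                                       row.names = c("s1", "s2"))))
  expect_error(stabilizeVariance(avg), "replicate-level")
  neg <- PeakMatrix(-m, peakIndex = c(1L, 2L), peakMz = c(100, 200))
  expect_error(stabilizeVariance(neg), "cannot be log-transformed")
})

test_that("varianceDiagnostic separates multiplicative from additive noise", {
  # identical replicates: all standard errors zero, slope zero
  m <- matrix(rep(1:5, 4), 5, 4)
  vd <- varianceDiagnostic(m, groups = c("a", "a", "b", "b"))
  expect_equal(vd$points$se, rep(0, 10))
  expect_equal(vd$slope, 0)
  # groups below two replicates are excluded
  vd2 <- varianceDiagnostic(m, groups = c("a", "a", "b", "c"))
  expect_setequal(unique(vd2$points$group), "a")
  expect_error(varianceDiagnostic(m, groups = c("a", "b", "c", "d")),
               ">= 2 replicates")
  # additive homoscedastic noise: flat; multiplicative: rising
  set.seed(11)
  mu <- matrix(rep(exp(seq(2, 7, length.out = 40)), 200), 40, 200)
  grp <- rep(seq_len(50), each = 4)
  addm <- mu + rnorm(length(mu), sd = 0.5)
  mult <- mu * exp(rnorm(length(mu), sd = 0.5))
  expect_lt(abs(varianceDiagnostic(log(addm), groups = grp)$slope), 0.05)
  expect_gt(varianceDiagnostic(mult, groups = grp)$slope, 0.2)
})

test_that("averageTechnicalReplicates averages within samples only", {
  m <- matrix(c(1, 2, 3, 5, 2, 4), 1, 6)
  colnames(m) <- sprintf("r%d", 1:6)
  info <- data.frame(sample_id = c("s1", "s1", "s2", "s2", "s3", "s3"),
                     genotype = "B6", diet = "SD", week = 3L,
                     row.names = colnames(m))
  pm <- PeakMatrix(m, 1L, 100, sampleInfo = info)
  avg <- averageTechnicalReplicates(pm)
  expect_identical(profileLevel(avg), "sample")
  expect_equal(unname(assay(avg, "intensity")[1, ]), c(1.5, 4, 3))
  expect_identical(colData(avg)$n_replicates, c(2L, 2L, 2L))
  # single replicate per sample is the identity
  info1 <- data.frame(sample_id = sprintf("s%d", 1:6), genotype = "B6",
                      diet = "SD", week = 3L, row.names = colnames(m))
  one <- averageTechnicalReplicates(PeakMatrix(m, 1L, 100,
                                               sampleInfo = info1))
  expect_equal(unname(assay(one, "intensity")), unname(m))
  # unmapped profiles are an error
  infoNA <- info; infoNA$sample_id[3] <- NA
  expect_error(averageTechnicalReplicates(
    PeakMatrix(m, 1L, 100, sampleInfo = infoNA)), "sample_id")
})

test_that("the full chain is deterministic", {
  fam <- peakFamilies(nFamilies = 1, peaksPerFamily = 2, nSingletons = 2,
                      axisLength = 1200)
  ds <- simulateDataset(cellDesign(6, 3), fam, axisLength = 1200,
                        shiftMax = 4, additiveNoiseSd = 0.3, seed = 13)
  pm1 <- preprocessSpectra(ds$spectra, ds$sampleSheet)
  pm2 <- preprocessSpectra(ds$spectra, ds$sampleSheet)
  expect_identical(assay(pm1, "intensity"), assay(pm2, "intensity"))
  expect_identical(metadata(pm1)$shifts, metadata(pm2)$shifts)
  expect_identical(transformLog(pm1),
                   c("log(x + 1)", "median_smooth(9)", "tophat(151)",
                     "aligned"))
})
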