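# a small benchmark world shared by the selection tests: 90 samples in three
# balanced diet classes, 52 peaks of which two separate the classes
selWorld <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      set.seed(100)
      n <- 90
      labels <- factor(rep(c("CHF", "HF", "SD"), each = 30))
      X <- matrix(rnorm(52 * n), 52, n,
                  dimnames = list(sprintf("pk%02d", 1:52),
                                  sprintf("s%02d", 1:n)))
      X["pk01", ] <- X["pk01", ] + c(CHF = 3, HF = 0, SD = 0)[labels]
      X["pk02", ] <- X["pk02", ] + c(CHF = 0, HF = 3, SD = 0)[labels]
      cache <<- list(X = X, labels = labels)
    }
    cache
  }
})

test_that("selectTopAnova orders by p-value with m/z tie-break", {
  tab <- data.frame(peak = c("a", "b", "c", "d"),
                    mz = c(400, 300, 200, 100),
                    p_diet = c(0.01, 0.5, 0.01, 0.2))
  full <- selectTopAnova(tab, "diet", 4)
  expect_identical(full$peaks, c("c", "a", "d", "b"))  # ties: lower m/z first
  expect_identical(selectTopAnova(tab, "diet", 1)$peaks, "c")
  expect_error(selectTopAnova(tab, "diet", 0), "positive")
  expect_error(selectTopAnova(tab, "diet", 9), "exceeds")
})

test_that("planted target peaks are selected by the ANOVA filter", {
  si <- mouseSampleInfo()
  set.seed(10)
  Y <- matrix(rnorm(20 * nrow(si)), 20, nrow(si),
              dimnames = list(sprintf("pk%02d", 1:20), si$sample_id))
  planted <- c("pk04", "pk09", "pk17")
  for (pk in planted) Y[pk, si$diet == "CHF"] <- Y[pk, si$diet == "CHF"] + 2
  tab <- anovaAllPeaks(Y, sampleInfo = si)
  expect_setequal(selectTopAnova(tab, "diet", 3)$peaks, planted)
})

test_that("a degenerate cut makes cluster selection identical to the filter", {
  si <- mouseSampleInfo()
  fam <- peakFamilies(nFamilies = 0, peaksPerFamily = 0, nSingletons = 12,
                      axisLength = 4000)
  sim <- simulateIntensityMatrix(mouseStudyDesign(), fam, seed = 11)
  sam <- averageTechnicalReplicates(stabilizeVariance(sim$matrix))
  tab <- anovaAllPeaks(sam)
  tree <- clusterPeaks(sam, annotate = FALSE)
  top <- selectTopAnova(tab, "diet", 5)
  reps <- selectClusterRepresentatives(tree, tab, sam, "diet", 5,
                                       cutDistance = 1e-9)
  expect_setequal(reps$peaks, top$peaks)
})

test_that("cluster representatives come from distinct top clusters", {
  si <- mouseSampleInfo()
  fam <- peakFamilies(nFamilies = 2, peaksPerFamily = 4, nSingletons = 8,
                      axisLength = 4000, withinCor = 0.95)
  eff <- plantedEffect("F01", "diet", c(CHF = 1.5))
  sim <- simulateIntensityMatrix(mouseStudyDesign(), fam, effects = eff,
                                 bioSd = 0.7, techSd = 0.4, seed = 12)
  sam <- averageTechnicalReplicates(stabilizeVariance(sim$matrix))
  tab <- anovaAllPeaks(sam)
  tree <- clusterPeaks(sam)
  one <- selectClusterRepresentatives(tree, tab, sam, "diet", 1)
  # the single representative is the diet family's own minimum-p member
  famPeaks <- fam$peak_id[fam$family_id == "F01"]
  expect_true(one$peaks %in% famPeaks)
  rows <- match(famPeaks, tab$peak)
  expect_identical(one$peaks, famPeaks[which.min(tab$p_diet[rows])])
  # n representatives lie in pairwise different flat clusters
  many <- selectClusterRepresentatives(tree, tab, sam, "diet", 4)
  flat <- cutClusters(tree, 0.3)
  expect_false(anyDuplicated(flat[many$peaks]) > 0)
  expect_warning(selectClusterRepresentatives(tree, tab, sam, "diet", 200,
                                              cutDistance = 2),
                 "clusters")
})

test_that("the decision tree splits cleanly separable 1D data", {
  x <- matrix(c(rnorm(20, 0, 0.1), rnorm(20, 5, 0.1)), 1,
              dimnames = list("f1", NULL))
  lab <- rep(c("lo", "hi"), each = 20)
  fit <- trainDecisionTree(x, lab)
  expect_identical(nrow(fit$frame[fit$frame$var != "<leaf>", ]), 1L)
  pred <- predict(fit, as.data.frame(t(x)), type = "class")
  expect_identical(as.character(pred), lab)
  expect_error(trainDecisionTree(x, rep("one", 40)), "two classes")
})

test_that("pure-noise features leave training error above zero under the caps", {
  set.seed(13)
  x <- matrix(rnorm(3 * 120), 3, dimnames = list(sprintf("f%d", 1:3), NULL))
  lab <- sample(rep(c("a", "b", "c"), each = 40))
  fit <- trainDecisionTree(x, lab)
  pred <- predict(fit, as.data.frame(t(x)), type = "class")
  expect_gt(mean(pred != lab), 0)
})

test_that("duplicate feature columns do not change predictions", {
  w <- selWorld()
  fit1 <- trainDecisionTree(w$X, w$labels, "pk01")
  xdup <- rbind(w$X, pk99 = w$X["pk01", ])
  fit2 <- trainDecisionTree(xdup, w$labels, c("pk01", "pk99"))
  newdata <- as.data.frame(t(xdup))
  expect_identical(predict(fit1, newdata, type = "class"),
                   predict(fit2, newdata, type = "class"))
})

test_that("cross-validation pools out-of-fold predictions", {
  w <- selWorld()
  cv <- crossValidate(w$X, w$labels, c("pk01", "pk02"), folds = 10, seed = 3)
  expect_identical(sum(cv$confusion), 90L)
  expect_lt(cv$cvError, 0.25)
  expect_equal(cv$cvError,
               1 - sum(diag(cv$confusion)) / sum(cv$confusion))
  # perfectly separable single feature: zero error, diagonal confusion
  x <- matrix(rep(c(0, 10), each = 20), 1, dimnames = list("f", NULL))
  lab <- rep(c("a", "b"), each = 20)
  cv2 <- crossValidate(x, lab, "f", folds = 10, seed = 1)
  expect_equal(cv2$cvError, 0)
  expect_equal(unname(cv2$confusion), diag(c(20L, 20L)),
               ignore_attr = TRUE)
  expect_error(crossValidate(w$X, w$labels, "pk01", folds = 1), "at least 2")
  expect_warning(crossValidate(w$X[, 1:40], w$labels[1:40], "pk01",
                               folds = 20, seed = 1), "reducing folds")
})

test_that("label permutation drives the CV error to chance", {
  w <- selWorld()
  set.seed(14)
  errs <- vapply(1:12, function(s) {
    perm <- sample(w$labels)
    crossValidate(w$X, perm, c("pk10", "pk11", "pk12"), folds = 10,
                  seed = s)$cvError
  }, numeric(1))
  expect_gt(mean(errs), 0.55)
  expect_lt(mean(errs), 0.78)
})

test_that("ACO is seed-reproducible and recovers the planted pair", {
  w <- selWorld()
  cfg <- acoConfig(nAnts = 25, nIterations = 12, seed = 7)
  fs1 <- acoSelect(w$X, w$labels, 2, cfg)
  fs2 <- acoSelect(w$X, w$labels, 2, cfg)
  expect_identical(fs1$peaks, fs2$peaks)
  expect_identical(fs1$metadata$trace, fs2$metadata$trace)
  expect_setequal(fs1$peaks, c("pk01", "pk02"))
  # subset size = all peaks is the trivial full set
  full <- acoSelect(w$X[1:5, ], w$labels, 5,
                    acoConfig(nAnts = 3, nIterations = 2, seed = 1))
  expect_setequal(full$peaks, rownames(w$X)[1:5])
  expect_error(acoSelect(w$X, w$labels, 99, cfg), "exceeds")
  expect_error(acoConfig(nAnts = 5), "seed")
})

test_that("permutation p-values respect the add-one bounds", {
  w <- selWorld()
  pp <- permutationPvalue(w$X, w$labels, c("pk01", "pk02"), nRandom = 60,
                          folds = 5, seed = 3)
  expect_gte(pp$p.value, 1 / 61)
  expect_lte(pp$p.value, 1)
  expect_equal(pp$p.value,
               (sum(pp$randomErrors <= pp$cvError) + 1) / 61)
  # the planted pair beats almost every random draw
  expect_lte(pp$p.value, 0.05)
  expect_error(permutationPvalue(w$X, w$labels, "pk01", nRandom = 0),
               "at least 1")
  expect_error(permutationPvalue(w$X, w$labels, rownames(w$X)[c(1:52, 1)],
                                 nRandom = 5), "larger")
})

test_that("cluster representatives match the filter's accuracy and are less
           correlated on redundancy-heavy data", {
  design <- mouseStudyDesign()
  fam <- peakFamilies(nFamilies = 3, peaksPerFamily = 4, nSingletons = 16,
                      axisLength = 4000, withinCor = 0.95)
  eff <- rbind(plantedEffect("F01", "diet", c(CHF = 1.2)),
               plantedEffect("F02", "diet", c(HF = 1.1)),
               plantedEffect("F03", "diet", c(CHF = -1.0, HF = -0.5)))
  nSeeds <- 25
  res <- vapply(seq_len(nSeeds), function(s) {
    sim <- simulateIntensityMatrix(design, fam, effects = eff, bioSd = 0.7,
                                   techSd = 0.4, seed = 7000 + s)
    sam <- averageTechnicalReplicates(stabilizeVariance(sim$matrix))
    tab <- anovaAllPeaks(sam)
    tree <- clusterPeaks(sam, annotate = FALSE)
    top <- selectTopAnova(tab, "diet", 3)
    reps <- selectClusterRepresentatives(tree, tab, sam, "diet", 3)
    labels <- colData(sam)$diet
    eTop <- crossValidate(sam, labels, top, folds = 10, seed = s)$cvError
    eRep <- crossValidate(sam, labels, reps, folds = 10, seed = s)$cvError
    meanCor <- function(peaks) {
      C <- cor(t(assay(sam, "intensity")[peaks, ]))
      mean(C[upper.tri(C)])
    }
    c(noWorse = eRep <= eTop + 0.05, corTop = meanCor(top$peaks),
      corRep = meanCor(reps$peaks))
  }, numeric(3))
  expect_gte(mean(res["noWorse", ]), 0.8)
  # representatives are decorrelated relative to the filter's picks
  expect_lt(mean(res["corRep", ]), mean(res["corTop", ]))
})

test_that("permutation p-values are super-uniform when the feature set is
           itself random", {
  set.seed(600)
  n <- 60
  labels <- factor(rep(c("a", "b"), each = 30))
  X <- matrix(rnorm(30 * n), 30, n,
              dimnames = list(sprintf("f%02d", 1:30), NULL))
  nRandom <- 39
  ps <- vapply(seq_len(200), function(r) {
    feats <- sample(rownames(X), 3)
    suppressWarnings(
      permutationPvalue(X, labels, feats, nRandom = nRandom, folds = 3,
                        seed = 601)$p.value)
  }, numeric(1))
  grid <- seq_len(nRandom + 1) / (nRandom + 1)
  ecdfAt <- vapply(grid, function(t) mean(ps <= t), numeric(1))
  expect_true(all(ecdfAt <= grid + 0.05))
})
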