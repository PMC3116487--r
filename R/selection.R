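## Feature selection (ANOVA filter, cluster-representative ANOVA, ant-colony
## wrapper) feeding a CART decision tree with stratified k-fold
## cross-validation and permutation p-values against random feature sets.

.FACTOR_PCOL <- c(diet = "p_diet", genotype = "p_genotype", week = "p_week",
                  interaction = "p_interaction")

.featureSet <- function(method, peaks, meta = list()) {
  structure(list(method = method, peaks = peaks, size = length(peaks),
                 metadata = meta), class = "FeatureSet")
}

#' @export
print.FeatureSet <- function(x, ...) {
  cat("FeatureSet [", x$method, "]: ", x$size, " peaks\n  ",
      paste(x$peaks, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Select the peaks with the most significant ANOVA p-values
#'
#' @param anovaTable result of [anovaAllPeaks()].
#' @param factor one of `"diet"`, `"genotype"`, `"week"`, `"interaction"`.
#' @param n number of peaks to select; ties on the p-value are broken by
#'   lower m/z.
#' @return A `FeatureSet` (method `"anova"`).
#' @export
selectTopAnova <- function(anovaTable, factor = "diet", n) {
  factor <- match.arg(factor, names(.FACTOR_PCOL))
  if (n <= 0) stop("n must be positive")
  if (n > nrow(anovaTable)) stop("n exceeds the number of peaks")
  p <- anovaTable[[.FACTOR_PCOL[factor]]]
  ord <- order(p, anovaTable$mz)
  sel <- anovaTable[ord[seq_len(n)], , drop = FALSE]
  .featureSet("anova", sel$peak,
              meta = list(factor = factor, p = sel[[.FACTOR_PCOL[factor]]]))
}

#' Cluster-representative feature selection
#'
#' The dendrogram is cut at `cutDistance` into flat clusters; clusters are
#' ranked by their cluster-level ANOVA p-value for the factor (computed on
#' the mean z-transformed member profile), and from each of the top `n`
#' clusters the member peak with the most significant individual p-value is
#' chosen as the representative. Representatives therefore come from
#' distinct, weakly correlated clusters.
#'
#' @param tree annotated [ClusterTree-class] of the peaks of `x`.
#' @param anovaTable result of [anovaAllPeaks()] on the same matrix.
#' @param x the sample-level [PeakMatrix-class].
#' @param factor target factor (see [selectTopAnova()]).
#' @param n number of representatives (one per cluster); with fewer clusters
#'   than `n`, all are returned with a warning.
#' @param cutDistance cut height on the 1 - correlation scale (default 0.3).
#' @return A `FeatureSet` (method `"cluster_anova"`).
#' @export
selectClusterRepresentatives <- function(tree, anovaTable, x,
                                         factor = "diet", n,
                                         cutDistance = 0.3) {
  factor <- match.arg(factor, names(.FACTOR_PCOL))
  if (n < 1) stop("n must be at least 1")
  pcol <- .FACTOR_PCOL[factor]
  flat <- cutClusters(tree, h = cutDistance)
  profiles <- assay(x, "intensity")
  sampleInfo <- as.data.frame(colData(x))
  rowOf <- match(names(flat), anovaTable$peak)
  if (anyNA(rowOf)) stop("tree leaves missing from the ANOVA table")

  clusters <- split(names(flat), flat)
  clusterP <- vapply(clusters, function(m) {
    if (length(m) == 1L)
      return(anovaTable[[pcol]][match(m, anovaTable$peak)])
    zx <- .zMatrix(profiles[m, , drop = FALSE])
    if (!nrow(zx)) return(1)
    factorialAnova(colMeans(zx), sampleInfo)[[pcol]]
  }, numeric(1))
  clusterMinMz <- vapply(clusters, function(m)
    min(anovaTable$mz[match(m, anovaTable$peak)]), numeric(1))

  ord <- order(clusterP, clusterMinMz)
  if (length(clusters) < n) {
    warning("only ", length(clusters), " clusters at cut distance ",
            cutDistance, "; returning one representative from each")
    n <- length(clusters)
  }
  reps <- vapply(ord[seq_len(n)], function(ci) {
    m <- clusters[[ci]]
    rows <- match(m, anovaTable$peak)
    m[order(anovaTable[[pcol]][rows], anovaTable$mz[rows])[1]]
  }, character(1))
  .featureSet("cluster_anova", reps,
              meta = list(factor = factor, cut_distance = cutDistance,
                          cluster_p = unname(clusterP[ord[seq_len(n)]])))
}

## data.frame of selected feature columns (samples x features), with
## syntactic names, from a peaks-by-samples matrix or PeakMatrix
.featureFrame <- function(x, features) {
  if (is(x, "PeakMatrix")) x <- assay(x, "intensity")
  miss <- setdiff(features, rownames(x))
  if (length(miss)) stop("unknown features: ", paste(miss, collapse = ", "))
  df <- as.data.frame(t(x[features, , drop = FALSE]))
  names(df) <- make.names(names(df))
  df
}

#' Train a CART decision tree on selected features
#'
#' Binary recursive partitioning with Gini impurity and axis-aligned
#' threshold splits, restricted to the selected features. Depth is capped and
#' leaves have a minimum size to limit overfitting.
#'
#' @param x peaks-by-samples matrix or [PeakMatrix-class].
#' @param labels class label per sample.
#' @param features peak ids to use (default: all rows of `x`).
#' @param maxDepth maximum tree depth (default 5).
#' @param minLeaf minimum observations per leaf (default 5).
#' @return An [rpart::rpart] model.
#' @export
trainDecisionTree <- function(x, labels, features = NULL, maxDepth = 5,
                              minLeaf = 5) {
  if (is.null(features))
    features <- rownames(if (is(x, "PeakMatrix")) assay(x, "intensity") else x)
  labels <- droplevels(as.factor(labels))
  if (nlevels(labels) < 2L) stop("at least two classes are required")
  df <- .featureFrame(x, features)
  df$.class <- labels
  rpart(.class ~ ., data = df, method = "class",
        parms = list(split = "gini"),
        control = rpart.control(maxdepth = maxDepth, minbucket = minLeaf,
                                minsplit = max(2 * minLeaf, 2), cp = 0.001,
                                xval = 0))
}

## stratified fold assignment: within each class, shuffled indices are dealt
## round-robin over the folds
.stratifiedFolds <- function(labels, folds, seed) {
  labels <- as.factor(labels)
  minClass <- min(table(labels))
  if (minClass < folds) {
    warning("smallest class has ", minClass, " members; reducing folds from ",
            folds, " to ", minClass)
    folds <- max(2L, as.integer(minClass))
  }
  assign <- integer(length(labels))
  withSeed(seed, {
    for (lv in levels(labels)) {
      idx <- sample(which(labels == lv))
      assign[idx] <- rep_len(seq_len(folds), length(idx))
    }
  })
  list(assign = assign, folds = folds)
}

#' Stratified k-fold cross-validation of the decision-tree classifier
#'
#' Folds are stratified by class and drawn from the seed; out-of-fold
#' predictions are pooled into one confusion matrix and
#' `cvError = misclassified / total`.
#'
#' @param x peaks-by-samples matrix or [PeakMatrix-class].
#' @param labels class label per sample.
#' @param features peak ids (or a `FeatureSet`).
#' @param folds number of folds (default 10); reduced with a warning when a
#'   class is smaller than `folds`.
#' @param seed integer seed for the fold assignment.
#' @param maxDepth,minLeaf passed to [trainDecisionTree()].
#' @return A `ClassificationReport` list: `confusion` (true x predicted),
#'   `cvError`, `folds`, `seed`, `nSamples`, `features`, `method`.
#' @export
crossValidate <- function(x, labels, features, folds = 10, seed = 1,
                          maxDepth = 5, minLeaf = 5) {
  method <- "manual"
  if (inherits(features, "FeatureSet")) {
    method <- features$method
    features <- features$peaks
  }
  if (folds < 2) stop("folds must be at least 2")
  labels <- droplevels(as.factor(labels))
  df <- .featureFrame(x, features)
  fa <- .stratifiedFolds(labels, folds, seed)
  pred <- factor(rep(NA_character_, length(labels)), levels = levels(labels))
  for (k in seq_len(fa$folds)) {
    test <- fa$assign == k
    dtrain <- df[!test, , drop = FALSE]
    dtrain$.class <- labels[!test]
    fit <- rpart(.class ~ ., data = dtrain, method = "class",
                 parms = list(split = "gini"),
                 control = rpart.control(maxdepth = maxDepth,
                                         minbucket = minLeaf,
                                         minsplit = max(2 * minLeaf, 2),
                                         cp = 0.001, xval = 0))
    pred[test] <- predict(fit, df[test, , drop = FALSE], type = "class")
  }
  confusion <- table(true = labels, predicted = pred)
  structure(list(confusion = unclass(confusion),
                 cvError = 1 - sum(diag(confusion)) / length(labels),
                 folds = fa$folds, seed = seed, nSamples = length(labels),
                 features = features, method = method),
            class = "ClassificationReport")
}

#' @export
print.ClassificationReport <- function(x, ...) {
  cat("ClassificationReport [", x$method, "]: ", x$nSamples, " samples, ",
      x$folds, "-fold CV\n", sep = "")
  print(x$confusion)
  cat(sprintf("  cv error: %.3f", x$cvError))
  if (!is.null(x$p.value)) cat(sprintf("   permutation p: %.3g", x$p.value))
  cat("\n")
  invisible(x)
}

#' Permutation p-value of a classification result
#'
#' Scores `nRandom` uniformly drawn feature sets of the same size with the
#' same folds and seed, and reports
#' `p = (#\{random error <= observed error\} + 1) / (nRandom + 1)`; the
#' smallest attainable value is `1 / (nRandom + 1)`.
#'
#' @inheritParams crossValidate
#' @param featureSet a `FeatureSet` or character vector of peak ids.
#' @param nRandom number of random feature sets (default 1000).
#' @return The observed `ClassificationReport` with `p.value`,
#'   `nRandom` and the vector of random errors added.
#' @export
permutationPvalue <- function(x, labels, featureSet, nRandom = 1000,
                              folds = 10, seed = 1, maxDepth = 5,
                              minLeaf = 5) {
  if (nRandom < 1) stop("nRandom must be at least 1")
  peaks <- if (inherits(featureSet, "FeatureSet")) featureSet$peaks
           else featureSet
  allPeaks <- rownames(if (is(x, "PeakMatrix")) assay(x, "intensity") else x)
  if (length(peaks) > length(allPeaks))
    stop("feature set larger than the number of peaks")
  obs <- crossValidate(x, labels, featureSet, folds = folds, seed = seed,
                       maxDepth = maxDepth, minLeaf = minLeaf)
  randErr <- withSeed(seed + 1L, {
    draws <- replicate(nRandom, sample(allPeaks, length(peaks)),
                       simplify = FALSE)
    vapply(draws, function(f)
      crossValidate(x, labels, f, folds = folds, seed = seed,
                    maxDepth = maxDepth, minLeaf = minLeaf)$cvError,
      numeric(1))
  })
  obs$p.value <- (sum(randErr <= obs$cvError) + 1) / (nRandom + 1)
  obs$nRandom <- nRandom
  obs$randomErrors <- randErr
  obs
}

#' Ant-colony-optimization configuration
#'
#' @param nAnts ants per iteration (default 200).
#' @param nIterations iterations (default 100).
#' @param evaporation pheromone evaporation rate (default 0.1).
#' @param alpha pheromone exponent (default 1).
#' @param beta heuristic exponent (default 1).
#' @param tauMin,tauMax pheromone floor and ceiling.
#' @param cvFolds folds of the internal fitness cross-validation (default 3).
#' @param seed mandatory integer seed.
#' @return A list of class `AcoConfig`.
#' @export
acoConfig <- function(nAnts = 200, nIterations = 100, evaporation = 0.1,
                      alpha = 1, beta = 1, tauMin = 0.01, tauMax = 5,
                      cvFolds = 3, seed) {
  if (missing(seed)) stop("an ACO seed is mandatory")
  stopifnot(nAnts >= 1, nIterations >= 1, evaporation > 0, evaporation < 1,
            tauMin > 0, tauMax > tauMin, cvFolds >= 2)
  structure(list(nAnts = nAnts, nIterations = nIterations,
                 evaporation = evaporation, alpha = alpha, beta = beta,
                 tauMin = tauMin, tauMax = tauMax, cvFolds = cvFolds,
                 seed = as.integer(seed)), class = "AcoConfig")
}

#' Ant-colony-optimization wrapper feature selection
#'
#' Each iteration, every ant samples `nFeatures` peaks without replacement
#' with probability proportional to `pheromone^alpha * heuristic^beta`, where
#' the heuristic is `-log10` of the peak's one-way ANOVA p-value for the
#' class labels. Subset fitness is the stratified internal CV error of the
#' decision tree on the subset; after evaporation, the iteration-best subset
#' is reinforced by `evaporation * (1 - bestError)` with the pheromone
#' clamped to `[tauMin, tauMax]`. The globally best subset is returned.
#' Fixed seed gives bit-identical results.
#'
#' @param x peaks-by-samples matrix or [PeakMatrix-class].
#' @param labels class label per sample.
#' @param nFeatures subset size.
#' @param config an [acoConfig()].
#' @return A `FeatureSet` (method `"aco"`) whose metadata carries the
#'   per-iteration best-fitness trace and the seed.
#' @export
acoSelect <- function(x, labels, nFeatures, config) {
  stopifnot(inherits(config, "AcoConfig"))
  m <- if (is(x, "PeakMatrix")) assay(x, "intensity") else x
  peaks <- rownames(m)
  if (nFeatures > length(peaks))
    stop("nFeatures exceeds the number of peaks")
  labels <- droplevels(as.factor(labels))
  eta <- vapply(seq_len(nrow(m)), function(i)
    -log10(oneWayAnova(m[i, ], labels)$p.value), numeric(1))
  eta <- pmax(eta, 0.01)
  eta[!is.finite(eta)] <- max(eta[is.finite(eta)], 1)

  tau <- rep(1, length(peaks))
  cache <- new.env(parent = emptyenv())
  fitness <- function(subset) {
    key <- paste(sort(subset), collapse = "|")
    if (!is.null(cache[[key]])) return(cache[[key]])
    err <- crossValidate(m, labels, peaks[subset], folds = config$cvFolds,
                         seed = config$seed)$cvError
    cache[[key]] <- err
    err
  }
  bestGlobal <- NULL
  bestGlobalErr <- Inf
  trace <- numeric(config$nIterations)
  withSeed(config$seed, {
    for (it in seq_len(config$nIterations)) {
      w <- (tau^config$alpha) * (eta^config$beta)
      subsets <- replicate(config$nAnts,
                           sample.int(length(peaks), nFeatures, prob = w),
                           simplify = FALSE)
      errs <- vapply(subsets, fitness, numeric(1))
      bestIdx <- which.min(errs)
      if (errs[bestIdx] < bestGlobalErr) {
        bestGlobalErr <- errs[bestIdx]
        bestGlobal <- subsets[[bestIdx]]
      }
      tau <- (1 - config$evaporation) * tau
      tau[subsets[[bestIdx]]] <- tau[subsets[[bestIdx]]] +
        config$evaporation * (1 - errs[bestIdx])
      tau <- pmin(pmax(tau, config$tauMin), config$tauMax)
      trace[it] <- errs[bestIdx]
    }
  })
  .featureSet("aco", sort(peaks[bestGlobal]),
              meta = list(fitness = bestGlobalErr, trace = trace,
                          seed = config$seed))
}

#' Benchmark the three feature-selection strategies
#'
#' Runs the ANOVA filter, the ant-colony wrapper and the
#' cluster-representative selection for each feature-set size, scores every
#' set with stratified k-fold cross-validation, and attaches a permutation
#' p-value against random feature sets of the same size.
#'
#' @param x sample-level [PeakMatrix-class].
#' @param anovaTable result of [anovaAllPeaks()] on `x`.
#' @param tree annotated [ClusterTree-class] of `x`.
#' @param labels class label per sample (e.g. `colData(x)$diet`).
#' @param factor target factor for the filter selections (default
#'   `"diet"`).
#' @param sizes feature-set sizes (default `c(3, 5, 8)`).
#' @param aco an [acoConfig()].
#' @param cutDistance cluster cut height (default 0.3).
#' @param folds CV folds (default 10).
#' @param nRandom random sets for the permutation p-value (default 1000).
#' @param seed CV/permutation seed.
#' @return list with `summary` (data.frame: method, size, cv_error, p_value)
#'   and `reports` (nested `ClassificationReport`s).
#' @export
classificationBenchmark <- function(x, anovaTable, tree, labels,
                                    factor = "diet", sizes = c(3, 5, 8),
                                    aco, cutDistance = 0.3, folds = 10,
                                    nRandom = 1000, seed = 1) {
  reports <- list()
  rows <- list()
  for (sz in sizes) {
    sets <- list(
      anova = selectTopAnova(anovaTable, factor, sz),
      aco = acoSelect(x, labels, sz, aco),
      cluster_anova = selectClusterRepresentatives(tree, anovaTable, x,
                                                   factor, sz, cutDistance))
    for (mth in names(sets)) {
      rep <- permutationPvalue(x, labels, sets[[mth]], nRandom = nRandom,
                               folds = folds, seed = seed)
      rep$method <- mth
      reports[[sprintf("%s_n%d", mth, sz)]] <- rep
      rows[[sprintf("%s_n%d", mth, sz)]] <-
        data.frame(method = mth, size = sz, cv_error = rep$cvError,
                   p_value = rep$p.value)
    }
  }
  list(summary = do.call(rbind, c(rows, list(make.row.names = FALSE))),
       reports = reports)
}

#' Write a classification benchmark report as JSON
#'
#' @param benchmark result of [classificationBenchmark()].
#' @param path output JSON file.
#' @return `path`, invisibly.
#' @export
writeReport <- function(benchmark, path) {
  out <- lapply(benchmark$reports, function(r)
    list(method = r$method, features = r$features, folds = r$folds,
         confusion = as.data.frame.matrix(as.data.frame.matrix(
           as.table(r$confusion))),
         cv_error = r$cvError, p_value = r$p.value))
  write_json(list(summary = benchmark$summary, reports = out), path,
             auto_unbox = TRUE, digits = NA)
  invisible(path)
}
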