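## Nested linear-model ANOVA: per-peak F-tests for each experimental factor
## and the genotype x diet interaction, via model comparison on residual
## sums of squares:
##
##   f = ((RSS1 - RSS2) / (p2 - p1)) / (RSS2 / (n - p2)) ~ F(p2 - p1, n - p2)
##
## where p1, p2 are the effective parameter counts (design-matrix ranks after
## dropping inestimable columns caused by empty factor cells).

.RSS_TOL <- 1e-9

## factor data.frame used for design matrices; week categorical by default
.modelData <- function(sampleInfo, weekAsFactor = TRUE) {
  data.frame(genotype = factor(sampleInfo$genotype),
             diet = factor(sampleInfo$diet),
             week = if (weekAsFactor) factor(sampleInfo$week)
                    else as.numeric(sampleInfo$week))
}

## QR of the design matrix for a term set, with rank detection
.termFit <- function(terms, data) {
  for (v in unique(unlist(strsplit(terms, ":", fixed = TRUE)))) {
    if (is.factor(data[[v]]) && nlevels(droplevels(data[[v]])) < 2L)
      stop("factor '", v, "' needs at least 2 observed levels")
  }
  f <- if (!length(terms)) ~ 1 else
    stats::reformulate(terms)
  X <- model.matrix(f, data = data)
  q <- qr(X)
  list(qr = q, rank = q$rank, ncol = ncol(X), n = nrow(X),
       Q = qr.Q(q)[, seq_len(q$rank), drop = FALSE])
}

#' Least-squares fit of a linear model on experimental factors
#'
#' Fits a treatment-coded design for the requested terms by QR least squares.
#' Columns made inestimable by empty factor cells are dropped through
#' pivoting; the effective parameter count is the design-matrix rank.
#'
#' @param response numeric response vector (one peak's sample-level
#'   intensities).
#' @param terms character vector of model terms, e.g.
#'   `c("genotype", "diet", "week")` or `"genotype:diet"`; `character(0)`
#'   fits the intercept-only model.
#' @param sampleInfo data.frame with `genotype`, `diet`, `week` per
#'   observation.
#' @param weekAsFactor treat week as categorical (default) or numeric.
#' @return list with `rss`, `p` (effective rank), `n`, `dropped` (number of
#'   inestimable columns).
#' @examples
#' si <- data.frame(genotype = rep(c("A", "B"), 5), diet = "SD", week = 3)
#' fitLinearModel(rnorm(10), "genotype", si)$p  # 2
#' @export
fitLinearModel <- function(response, terms, sampleInfo, weekAsFactor = TRUE) {
  data <- .modelData(sampleInfo, weekAsFactor)
  stopifnot(length(response) == nrow(data))
  fit <- .termFit(terms, data)
  if (fit$rank == 0L) stop("zero-rank design")
  if (fit$n <= fit$rank)
    stop("sample size must exceed the number of estimable parameters")
  res <- qr.resid(fit$qr, response)
  list(rss = sum(res^2), p = fit$rank, n = fit$n,
       dropped = fit$ncol - fit$rank)
}

#' Nested-model F-test
#'
#' Compares two nested least-squares fits:
#' `f = ((rss1 - rss2) / (p2 - p1)) / (rss2 / (n - p2))`, with the p-value
#' from the upper tail of `F(p2 - p1, n - p2)`.
#'
#' @param fit1 the smaller (nested) model, a list with `rss`, `p`, `n`.
#' @param fit2 the larger model.
#' @return list with `f`, `p.value`, `df1`, `df2`, `flag` (`""`,
#'   `"degenerate"` for an all-constant response, `"saturated"` when the
#'   larger model is exact while the smaller is not, giving the p = 0 limit).
#' @examples
#' fTestNested(list(rss = 10, p = 1, n = 13), list(rss = 5, p = 3, n = 13))
#' @export
fTestNested <- function(fit1, fit2) {
  if (fit1$n != fit2$n) stop("fits are on different sample sizes")
  n <- fit1$n
  scale <- max(fit1$rss, fit2$rss, 1)
  if (fit1$p >= fit2$p) stop("model 1 must be nested in model 2 (p1 < p2)")
  if (fit1$rss < fit2$rss - .RSS_TOL * scale)
    stop("non-nested inputs: rss1 < rss2")
  df1 <- fit2$p - fit1$p
  df2 <- n - fit2$p
  if (df2 <= 0) stop("no residual degrees of freedom")
  if (fit2$rss <= .RSS_TOL * scale) {
    if (fit1$rss <= .RSS_TOL * scale)
      return(list(f = 0, p.value = 1, df1 = df1, df2 = df2,
                  flag = "degenerate"))
    return(list(f = Inf, p.value = 0, df1 = df1, df2 = df2,
                flag = "saturated"))
  }
  f <- ((fit1$rss - fit2$rss) / df1) / (fit2$rss / df2)
  f <- max(f, 0)
  list(f = f, p.value = pf(f, df1, df2, lower.tail = FALSE),
       df1 = df1, df2 = df2, flag = "")
}

#' One-way ANOVA as a nested-model comparison
#'
#' Tests the null hypothesis that all group means are equal by comparing the
#' intercept-only model against the group-means model; the statistic follows
#' `F(k - 1, N - k)`. For two groups this is equivalent to the
#' pooled-variance two-sided t-test.
#'
#' @param values numeric response values.
#' @param groups group labels (coerced to factor; unused levels dropped).
#' @return list with `f`, `p.value`, `df1`, `df2`, `flag`.
#' @examples
#' oneWayAnova(c(1, 2, 3, 6, 7, 8), rep(c("a", "b"), each = 3))
#' @export
oneWayAnova <- function(values, groups) {
  groups <- droplevels(as.factor(groups))
  k <- nlevels(groups)
  if (k < 2L) stop("at least two non-empty groups are required")
  if (any(table(groups) == 0L)) stop("a group with 0 elements")
  N <- length(values)
  if (N <= k) stop("more observations than groups are required")
  si <- data.frame(genotype = groups, diet = "x", week = 1)
  fit1 <- fitLinearModel(values, character(0), si)
  fit2 <- fitLinearModel(values, "genotype", si)
  fTestNested(fit1, fit2)
}

#' Factorial ANOVA for one peak
#'
#' Tests each main factor by comparing the full main-effects model without
#' that factor against the full main-effects model, and the genotype x diet
#' interaction by comparing the main-effects model against main effects plus
#' interaction (a Type-II-like strategy whose results do not depend on term
#' order). Empty design cells are handled by rank reduction and flagged.
#'
#' @param response numeric sample-level response.
#' @param sampleInfo data.frame with `genotype`, `diet`, `week`.
#' @param weekAsFactor treat week as categorical (default) or numeric.
#' @return Named list with `f_<factor>` and `p_<factor>` for `diet`,
#'   `genotype`, `week` and `interaction`, plus `flags` (semicolon-joined).
#' @export
factorialAnova <- function(response, sampleInfo, weekAsFactor = TRUE) {
  data <- .modelData(sampleInfo, weekAsFactor)
  stopifnot(length(response) == nrow(data))
  mains <- c("genotype", "diet", "week")
  fits <- list(
    main = .termFit(mains, data),
    full = .termFit(c(mains, "genotype:diet"), data))
  for (f in mains) fits[[paste0("no_", f)]] <- .termFit(setdiff(mains, f), data)
  rssOf <- function(ft) {
    res <- qr.resid(ft$qr, response)
    list(rss = sum(res^2), p = ft$rank, n = ft$n, dropped = ft$ncol - ft$rank)
  }
  fitted <- lapply(fits, rssOf)
  flags <- character(0)
  if (fitted$full$dropped > 0L)
    flags <- c(flags, sprintf("dropped_%d_interaction_columns",
                              fitted$full$dropped))
  out <- list()
  for (f in mains) {
    t <- fTestNested(fitted[[paste0("no_", f)]], fitted$main)
    out[[paste0("f_", f)]] <- t$f
    out[[paste0("p_", f)]] <- t$p.value
    if (nzchar(t$flag)) flags <- c(flags, paste0(f, ":", t$flag))
  }
  t <- fTestNested(fitted$main, fitted$full)
  out$f_interaction <- t$f
  out$p_interaction <- t$p.value
  if (nzchar(t$flag)) flags <- c(flags, paste0("interaction:", t$flag))
  out$flags <- paste(unique(flags), collapse = ";")
  out
}

#' Factorial ANOVA for every peak of a sample-level matrix
#'
#' Applies [factorialAnova()] independently to every peak. The five design
#' matrices are shared across peaks, so residual sums of squares are computed
#' for all peaks at once from one set of QR decompositions.
#'
#' @param x a sample-level [PeakMatrix-class], or a plain peaks-by-samples
#'   matrix together with `sampleInfo`.
#' @param sampleInfo data.frame with `genotype`, `diet`, `week` per sample
#'   (defaults to `colData(x)`).
#' @param weekAsFactor treat week as categorical (default) or numeric.
#' @return data.frame (one row per peak, ordered by m/z): `peak`, `mz`,
#'   `f_`/`p_` columns for diet, genotype, week, interaction, and `flags`.
#'   Per-peak degeneracies are flagged, never aborted on.
#' @export
anovaAllPeaks <- function(x, sampleInfo = NULL, weekAsFactor = TRUE) {
  if (is(x, "PeakMatrix")) {
    if (profileLevel(x) != "sample")
      stop("anovaAllPeaks() expects a sample-level matrix; run ",
           "averageTechnicalReplicates() first")
    if (is.null(sampleInfo)) sampleInfo <- as.data.frame(colData(x))
    mzs <- peakMz(x)
    Y <- t(assay(x, "intensity"))
    peaks <- rownames(x)
  } else {
    stopifnot(is.matrix(x), !is.null(sampleInfo))
    mzs <- seq_len(nrow(x))
    Y <- t(x)
    peaks <- if (is.null(rownames(x))) sprintf("peak_%d", seq_len(nrow(x)))
             else rownames(x)
  }
  data <- .modelData(sampleInfo, weekAsFactor)
  mains <- c("genotype", "diet", "week")
  fits <- list(main = .termFit(mains, data),
               full = .termFit(c(mains, "genotype:diet"), data))
  for (f in mains) fits[[paste0("no_", f)]] <- .termFit(setdiff(mains, f), data)

  tot <- colSums(Y^2)
  rss <- lapply(fits, function(ft)
    pmax(0, tot - colSums(crossprod(ft$Q, Y)^2)))
  n <- nrow(Y)

  pair <- function(rss1, p1, rss2, p2) {
    df1 <- p2 - p1
    df2 <- n - p2
    scale <- pmax(rss1, rss2, 1)
    f <- pmax(0, ((rss1 - rss2) / df1) / (rss2 / df2))
    p <- pf(f, df1, df2, lower.tail = FALSE)
    sat <- rss2 <= .RSS_TOL * scale
    deg <- sat & (rss1 <= .RSS_TOL * scale)
    f[sat] <- Inf; p[sat] <- 0
    f[deg] <- 0; p[deg] <- 1
    list(f = f, p = p, sat = sat & !deg, deg = deg)
  }
  out <- data.frame(peak = peaks, mz = mzs)
  flags <- rep("", ncol(Y))
  if (fits$full$ncol > fits$full$rank)
    flags <- sprintf("dropped_%d_interaction_columns",
                     fits$full$ncol - fits$full$rank)
  addFlag <- function(flags, which, txt)
    ifelse(which, ifelse(nzchar(flags), paste(flags, txt, sep = ";"), txt),
           flags)
  for (f in mains) {
    t <- pair(rss[[paste0("no_", f)]], fits[[paste0("no_", f)]]$rank,
              rss$main, fits$main$rank)
    out[[paste0("f_", f)]] <- t$f
    out[[paste0("p_", f)]] <- t$p
    flags <- addFlag(flags, t$deg, paste0(f, ":degenerate"))
    flags <- addFlag(flags, t$sat, paste0(f, ":saturated"))
  }
  t <- pair(rss$main, fits$main$rank, rss$full, fits$full$rank)
  out$f_interaction <- t$f
  out$p_interaction <- t$p
  flags <- addFlag(flags, t$deg, "interaction:degenerate")
  flags <- addFlag(flags, t$sat, "interaction:saturated")
  out$flags <- flags
  out[order(out$mz), , drop = FALSE]
}

#' Bonferroni-corrected significance threshold
#'
#' @param alpha family-wise error rate, in (0, 1).
#' @param m number of tests, >= 1.
#' @return list with `threshold` (`alpha / m`) and `reported` (the threshold
#'   rounded to one significant digit, the form used when quoting it).
#' @examples
#' bonferroniThreshold(0.05, 261)$reported  # 2e-04
#' @export
bonferroniThreshold <- function(alpha, m) {
  stopifnot(alpha > 0, alpha < 1)
  if (m < 1) stop("m must be at least 1")
  th <- alpha / m
  list(threshold = th, reported = signif(th, 1))
}
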