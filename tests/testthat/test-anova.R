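test_that("fitLinearModel matches closed forms and a pseudo-inverse oracle", {
  set.seed(1)
  si <- data.frame(genotype = rep(c("A", "B", "C"), each = 4),
                   diet = rep(c("SD", "HF"), 6), week = rep(c(3, 6), each = 6))
  y <- rnorm(12)
  f0 <- fitLinearModel(y, character(0), si)
  expect_equal(f0$rss, sum((y - mean(y))^2))
  expect_identical(f0$p, 1L)
  # saturated model on noiseless group data
  yg <- c(A = 1, B = 5, C = 9)[si$genotype]
  expect_equal(fitLinearModel(unname(yg), "genotype", si)$rss, 0)
  # arbitrary model vs explicit pseudo-inverse least squares
  fit <- fitLinearModel(y, c("genotype", "diet"), si)
  X <- model.matrix(~ genotype + diet, data = si)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  expect_equal(fit$rss, sum((y - X %*% beta)^2), tolerance = 1e-10)
  expect_identical(fit$p, 4L)
  expect_error(fitLinearModel(y[c(1, 5)], "genotype", si[c(1, 5), ]),
               "sample size must exceed")
  expect_error(fitLinearModel(y[1:3], "genotype", si[1:3, ]),
               "at least 2 observed levels")
})

test_that("the nested F-test follows the RSS-ratio formula", {
  r <- fTestNested(list(rss = 10, p = 1, n = 13),
                   list(rss = 5, p = 3, n = 13))
  expect_equal(r$f, 5)
  expect_equal(r$p.value, pf(5, 2, 10, lower.tail = FALSE))
  same <- fTestNested(list(rss = 5, p = 1, n = 10),
                      list(rss = 5, p = 2, n = 10))
  expect_equal(same$f, 0)
  expect_equal(same$p.value, 1)
  # saturated larger model: p-value 0 limit, flagged
  sat <- fTestNested(list(rss = 3, p = 1, n = 10),
                     list(rss = 0, p = 2, n = 10))
  expect_equal(sat$p.value, 0)
  expect_identical(sat$flag, "saturated")
  deg <- fTestNested(list(rss = 0, p = 1, n = 10),
                     list(rss = 0, p = 2, n = 10))
  expect_equal(deg$p.value, 1)
  expect_identical(deg$flag, "degenerate")
  expect_error(fTestNested(list(rss = 1, p = 3, n = 10),
                           list(rss = 2, p = 2, n = 10)), "nested")
  expect_error(fTestNested(list(rss = 1, p = 1, n = 10),
                           list(rss = 2, p = 2, n = 10)), "non-nested")
})

test_that("one-way ANOVA at k = 2 equals the pooled t-test", {
  set.seed(2)
  for (i in 1:5) {
    v <- rnorm(14, mean = rep(c(0, 0.8), each = 7))
    g <- rep(c("a", "b"), each = 7)
    a <- oneWayAnova(v, g)
    tt <- t.test(v ~ g, var.equal = TRUE)
    expect_equal(a$p.value, tt$p.value, tolerance = 1e-10)
    expect_equal(a$f, unname(tt$statistic)^2, tolerance = 1e-10)
  }
})

test_that("one-way ANOVA matches the hand sums-of-squares decomposition", {
  vals <- c(1, 2, 3, 2, 3, 4, 6, 7, 8)
  grp <- rep(c("g1", "g2", "g3"), each = 3)
  # brute force: SS_between / (k-1) over SS_within / (N-k)
  gm <- tapply(vals, grp, mean)
  ssb <- sum(3 * (gm - mean(vals))^2)
  ssw <- sum((vals - gm[grp])^2)
  fOracle <- (ssb / 2) / (ssw / 6)
  a <- oneWayAnova(vals, grp)
  expect_equal(a$f, fOracle, tolerance = 1e-12)
  expect_equal(a$p.value, pf(fOracle, 2, 6, lower.tail = FALSE))
  # degenerate all-identical response
  d <- oneWayAnova(rep(2, 9), grp)
  expect_equal(d$p.value, 1)
  expect_identical(d$flag, "degenerate")
  expect_error(oneWayAnova(1:5, rep("a", 5)), "two non-empty groups")
})

test_that("factorial F values match lm-based model comparison on balanced data", {
  set.seed(3)
  si <- expand.grid(genotype = c("A", "B", "C"), diet = c("SD", "HF", "CHF"),
                    week = c(3, 6), rep = 1:3,
                    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)[, 1:3]
  y <- rnorm(nrow(si)) + (si$genotype == "B") * 0.5
  a <- factorialAnova(y, si)
  md <- transform(si, week = factor(week))
  full <- lm(y ~ genotype + diet + week + genotype:diet, data = md)
  main <- lm(y ~ genotype + diet + week, data = md)
  expect_equal(a$f_interaction, anova(main, full)$F[2], tolerance = 1e-8)
  for (f in c("genotype", "diet", "week")) {
    red <- lm(stats::reformulate(setdiff(c("genotype", "diet", "week"), f),
                                 response = "y"), data = md)
    expect_equal(a[[paste0("f_", f)]], anova(red, main)$F[2],
                 tolerance = 1e-8)
    expect_equal(a[[paste0("p_", f)]], anova(red, main)$`Pr(>F)`[2],
                 tolerance = 1e-8)
  }
})

test_that("exactly additive noiseless data gives interaction p = 1", {
  si <- expand.grid(genotype = c("A", "B"), diet = c("SD", "HF"),
                    week = c(3, 6), rep = 1:2,
                    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)[, 1:3]
  y <- (si$genotype == "B") * 2 + (si$diet == "HF") * 3 + (si$week == 6) * 1
  a <- factorialAnova(y, si)
  expect_equal(a$p_interaction, 1)
  expect_match(a$flags, "degenerate")
})

test_that("structurally empty genotype-diet cells are rank-dropped and flagged", {
  # SJL never receives HF: one interaction column is inestimable
  si <- expand.grid(genotype = c("B6", "NZO", "SJL"),
                    diet = c("SD", "HF", "CHF"), week = c(3, 6), rep = 1:3,
                    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)[, 1:3]
  si <- si[!(si$genotype == "SJL" & si$diet == "HF"), ]
  set.seed(4)
  y <- rnorm(nrow(si))
  a <- factorialAnova(y, si)
  expect_match(a$flags, "dropped_1_interaction_columns")
  expect_true(all(vapply(c("p_diet", "p_genotype", "p_week",
                           "p_interaction"),
                         function(k) a[[k]] > 0 && a[[k]] <= 1, logical(1))))
})

test_that("the F-test is invariant under affine response rescaling", {
  set.seed(5)
  si <- mouseSampleInfo()
  y <- rnorm(nrow(si))
  a1 <- factorialAnova(y, si)
  a2 <- factorialAnova(3.7 * y - 11, si)
  for (k in c("f_diet", "f_genotype", "f_week", "f_interaction",
              "p_diet", "p_genotype", "p_week", "p_interaction"))
    expect_equal(a2[[k]], a1[[k]], tolerance = 1e-9)
})

test_that("a planted interaction is detected with high power at study scale", {
  si <- mouseSampleInfo()
  hit <- si$genotype == "SJL" & si$diet == "CHF"
  set.seed(6)
  p <- replicate(50, {
    y <- rnorm(nrow(si))
    y[hit] <- y[hit] + 4   # four within-group standard deviations
    factorialAnova(y, si)$p_interaction
  })
  expect_gte(mean(p < 2e-4), 0.9)
})

test_that("increasing effect size never increases the median factor p-value", {
  si <- mouseSampleInfo()
  hit <- si$diet == "CHF"
  medp <- vapply(c(0, 0.4, 0.8, 1.2), function(eff) {
    set.seed(7)
    median(replicate(40, {
      y <- rnorm(nrow(si))
      y[hit] <- y[hit] + eff
      factorialAnova(y, si)$p_diet
    }))
  }, numeric(1))
  expect_true(all(diff(medp) <= 0))
})

test_that("anovaAllPeaks equals per-peak factorialAnova and flags, never aborts", {
  si <- mouseSampleInfo()
  set.seed(8)
  Y <- matrix(rnorm(5 * nrow(si)), 5, nrow(si),
              dimnames = list(sprintf("pk%d", 1:5), si$sample_id))
  Y[3, ] <- 2  # constant peak: degenerate, flagged, table still complete
  tab <- anovaAllPeaks(Y, sampleInfo = si)
  expect_identical(nrow(tab), 5L)
  one <- factorialAnova(Y[1, ], si)
  row1 <- tab[tab$peak == "pk1", ]
  expect_equal(row1$p_interaction, one$p_interaction, tolerance = 1e-9)
  expect_equal(row1$f_diet, one$f_diet, tolerance = 1e-9)
  expect_match(tab$flags[tab$peak == "pk3"], "degenerate")
  expect_equal(tab$p_diet[tab$peak == "pk3"], 1)
})

test_that("planted-effect peaks rank first for their target factor", {
  si <- mouseSampleInfo()
  set.seed(9)
  Y <- matrix(rnorm(30 * nrow(si)), 30, nrow(si),
              dimnames = list(sprintf("pk%02d", 1:30), si$sample_id))
  planted <- c("pk03", "pk11", "pk27")
  for (pk in planted)
    Y[pk, si$diet == "CHF"] <- Y[pk, si$diet == "CHF"] + 2
  tab <- anovaAllPeaks(Y, sampleInfo = si)
  top3 <- tab$peak[order(tab$p_diet)][1:3]
  expect_setequal(top3, planted)
})

test_that("bonferroniThreshold divides and reports to one significant digit", {
  expect_equal(bonferroniThreshold(0.05, 1)$threshold, 0.05)
  b <- bonferroniThreshold(0.05, 261)
  expect_equal(b$threshold, 0.05 / 261)
  expect_equal(b$reported, 2e-4)
  expect_equal(bonferroniThreshold(0.05, 500)$threshold, 1e-4)
  expect_error(bonferroniThreshold(0.05, 0), "at least 1")
})
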