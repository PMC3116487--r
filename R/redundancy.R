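## Redundancy exploitation: peptides of a common parent protein produce
## correlated peak intensity profiles. Average-linkage clustering on the
## 1 - Pearson-correlation distance groups them; every dendrogram node gets
## the mean pairwise correlation of its members and four factor-wise ANOVA
## p-values computed on the node's mean z-transformed profile.

#' z-transform an intensity profile
#'
#' `(x - mean(x)) / sd(x)` with the sample standard deviation (n - 1).
#' Profiles live on different absolute scales for technical and biological
#' reasons, so they must be z-transformed before pointwise averaging.
#'
#' @param x numeric profile with positive standard deviation.
#' @return Numeric vector with mean 0 and sd 1.
#' @examples
#' zTransform(c(1, 2, 3))  # -1 0 1
#' @export
zTransform <- function(x) {
  s <- sd(x)
  if (!is.finite(s) || s == 0) stop("constant profile cannot be z-transformed")
  (x - mean(x)) / s
}

## rows z-transformed; constant rows dropped with a warning
.zMatrix <- function(x) {
  sds <- apply(x, 1L, sd)
  bad <- !is.finite(sds) | sds == 0
  if (any(bad))
    warning("dropping ", sum(bad), " constant profile(s): ",
            paste(rownames(x)[bad], collapse = ", "))
  x <- x[!bad, , drop = FALSE]
  (x - rowMeans(x)) / apply(x, 1L, sd)
}

#' Correlation distance between intensity profiles
#'
#' `d_ij = 1 - rho(x_i, x_j)` with rho the Pearson correlation; the distance
#' lies in \[0, 2\] (2 for perfectly anti-correlated profiles). Constant
#' profiles, whose correlation is undefined, are excluded with a warning.
#'
#' @param profiles numeric matrix, one profile per row (peaks x samples).
#' @return A [stats::dist] object; excluded profile names are attached as
#'   attribute `"dropped"`.
#' @export
correlationDistance <- function(profiles) {
  stopifnot(is.matrix(profiles), nrow(profiles) >= 2L)
  if (is.null(rownames(profiles)))
    rownames(profiles) <- sprintf("peak_%d", seq_len(nrow(profiles)))
  sds <- apply(profiles, 1L, sd)
  bad <- !is.finite(sds) | sds == 0
  if (any(bad))
    warning("excluding ", sum(bad),
            " constant profile(s) with undefined correlation: ",
            paste(rownames(profiles)[bad], collapse = ", "))
  profiles <- profiles[!bad, , drop = FALSE]
  if (nrow(profiles) < 2L) stop("fewer than 2 usable profiles")
  d <- as.dist(1 - cor(t(profiles)))
  attr(d, "dropped") <- rownames(profiles)[bad]
  d
}

## member leaf labels of every node of an hclust tree; leaves "L<i>" carry
## their own label, merges are "N<k>"
.treeMembers <- function(hc) {
  n <- length(hc$labels)
  members <- vector("list", 2L * n - 1L)
  names(members) <- c(paste0("L", seq_len(n)), paste0("N", seq_len(n - 1L)))
  for (i in seq_len(n)) members[[i]] <- hc$labels[i]
  for (k in seq_len(n - 1L)) {
    get1 <- function(j) if (j < 0) members[[-j]] else members[[n + j]]
    members[[n + k]] <- c(get1(hc$merge[k, 1]), get1(hc$merge[k, 2]))
  }
  members
}

#' Average-linkage (UPGMA) hierarchical clustering
#'
#' Builds the agglomerative merge tree with unweighted average inter-cluster
#' distance and wraps it, together with a per-node skeleton table, into a
#' [ClusterTree-class]. Mean correlations and node p-values are filled in by
#' [meanNodeCorrelation()] and [nodePvalues()] (or use [clusterPeaks()] for
#' the full chain).
#'
#' @param d a [stats::dist] object, e.g. from [correlationDistance()].
#' @return A `ClusterTree` with heights and member sets; `mean_cor` and the
#'   p-value columns are `NA` until annotated.
#' @export
averageLinkage <- function(d) {
  stopifnot(inherits(d, "dist"))
  if (attr(d, "Size") < 2L) stop("fewer than 2 items to cluster")
  hc <- hclust(d, method = "average")
  n <- length(hc$labels)
  members <- .treeMembers(hc)
  nodes <- data.frame(
    node = names(members),
    height = c(rep(0, n), hc$height),
    n_members = vapply(members, length, integer(1)),
    mean_cor = NA_real_, p_diet = NA_real_, p_genotype = NA_real_,
    p_week = NA_real_, p_interaction = NA_real_,
    row.names = NULL)
  new("ClusterTree", hclust = hc, nodes = nodes, members = members)
}

#' Mean pairwise member correlation of every node
#'
#' For a node with at least two member peaks this is the mean of all pairwise
#' Pearson correlations among the member profiles; a leaf is 1 by convention.
#'
#' @param tree a [ClusterTree-class].
#' @param profiles peaks-by-samples matrix with rownames matching the tree
#'   leaves.
#' @return The tree with the `mean_cor` node column filled; the vector is
#'   also retrievable via `nodeTable(tree)$mean_cor`.
#' @export
meanNodeCorrelation <- function(tree, profiles) {
  stopifnot(is(tree, "ClusterTree"))
  C <- cor(t(profiles))
  tree@nodes$mean_cor <- vapply(tree@members, function(m) {
    k <- length(m)
    if (k < 2L) return(1)
    sub <- C[m, m]
    (sum(sub) - k) / (k * (k - 1L))
  }, numeric(1))
  tree
}

#' Factor-wise ANOVA p-values for every dendrogram node
#'
#' For each node the member profiles are z-transformed, averaged pointwise,
#' and the mean profile tested with [factorialAnova()]; a leaf uses its own
#' profile, so its p-values are exactly the peak's own [anovaAllPeaks()] row
#' (the F-test is invariant under affine rescaling of the response). Nodes
#' whose members are all constant get p = 1 and a flag.
#'
#' @param tree a [ClusterTree-class].
#' @param x sample-level [PeakMatrix-class] (or a peaks-by-samples matrix
#'   with `sampleInfo`).
#' @param sampleInfo per-sample factors, defaults to `colData(x)`.
#' @return The tree with `p_diet`, `p_genotype`, `p_week`, `p_interaction`
#'   filled for every node.
#' @export
nodePvalues <- function(tree, x, sampleInfo = NULL) {
  stopifnot(is(tree, "ClusterTree"))
  if (is(x, "PeakMatrix")) {
    if (is.null(sampleInfo)) sampleInfo <- as.data.frame(colData(x))
    x <- assay(x, "intensity")
  }
  stopifnot(is.matrix(x), !is.null(sampleInfo))
  leaves <- tree@hclust$labels
  if (!all(leaves %in% rownames(x)))
    stop("tree leaves missing from the profile matrix")
  x <- x[leaves, , drop = FALSE]
  sds <- apply(x, 1L, sd)
  zx <- x
  ok <- is.finite(sds) & sds > 0
  zx[ok, ] <- (x[ok, , drop = FALSE] - rowMeans(x[ok, , drop = FALSE])) /
    sds[ok]
  ## leaves take their rows from the per-peak table (identical code path,
  ## hence exactly equal); merges are tested on the mean z-profile
  perPeak <- anovaAllPeaks(x, sampleInfo = sampleInfo)
  pcols <- c("p_diet", "p_genotype", "p_week", "p_interaction")
  for (i in seq_along(tree@members)) {
    m <- tree@members[[i]]
    use <- m[ok[m]]
    if (!length(use)) {
      tree@nodes[i, pcols] <- 1
      next
    }
    if (length(m) == 1L) {
      tree@nodes[i, pcols] <- perPeak[match(m, perPeak$peak), pcols]
      next
    }
    a <- factorialAnova(colMeans(zx[use, , drop = FALSE]), sampleInfo)
    tree@nodes[i, pcols] <- a[pcols]
  }
  validObject(tree)
  tree
}

#' Cluster the peaks of a sample-level matrix and annotate every node
#'
#' Convenience chain: [correlationDistance()] on the stabilized
#' sample-averaged profiles, [averageLinkage()], [meanNodeCorrelation()] and
#' [nodePvalues()].
#'
#' @param x a sample-level [PeakMatrix-class].
#' @param annotate also compute mean correlations and node p-values
#'   (default `TRUE`).
#' @return An annotated [ClusterTree-class].
#' @export
clusterPeaks <- function(x, annotate = TRUE) {
  stopifnot(is(x, "PeakMatrix"))
  if (profileLevel(x) != "sample")
    stop("clusterPeaks() expects a sample-level matrix")
  profiles <- assay(x, "intensity")
  d <- correlationDistance(profiles)
  keep <- setdiff(rownames(profiles), attr(d, "dropped"))
  tree <- averageLinkage(d)
  if (annotate) {
    tree <- meanNodeCorrelation(tree, profiles[keep, , drop = FALSE])
    tree <- nodePvalues(tree, profiles[keep, , drop = FALSE],
                        sampleInfo = as.data.frame(colData(x)))
  }
  tree
}

#' Cut the dendrogram into flat clusters
#'
#' @param tree a [ClusterTree-class].
#' @param h distance at which to cut (on the 1 - correlation scale).
#' @return Named integer vector of cluster memberships (one per leaf).
#' @export
cutClusters <- function(tree, h) {
  stopifnot(is(tree, "ClusterTree"))
  cutree(tree@hclust, h = h)
}

## newick string of the merge tree with internal labels N<k>; branch lengths
## are half-height differences (ultrametric convention: the leaf-to-leaf
## path length equals the merge height, as in cophenetic())
.newickString <- function(hc) {
  n <- length(hc$labels)
  build <- function(j, parentH) {
    if (j < 0) {
      lab <- gsub("[ ,:;()\\[\\]]", "_", hc$labels[-j])
      sprintf("%s:%g", lab, parentH)
    } else {
      h <- hc$height[j] / 2
      sprintf("(%s,%s)N%d:%g", build(hc$merge[j, 1], h),
              build(hc$merge[j, 2], h), j, parentH - h)
    }
  }
  root <- n - 1L
  h <- hc$height[root] / 2
  sprintf("(%s,%s)N%d;", build(hc$merge[root, 1], h),
          build(hc$merge[root, 2], h), root)
}

#' Export an annotated dendrogram as newick plus a JSON side-table
#'
#' The merge tree is written as a newick string whose internal node labels
#' (`N<k>`) key into a JSON side-table holding, per node, the member peaks,
#' the mean pairwise correlation and `-log10 p` for each of the four factors.
#' Per-factor colour scales (the maximum finite `-log10 p`) are computed
#' independently for each factor, so each factor's annotation spans its own
#' dynamic range.
#'
#' @param tree an annotated [ClusterTree-class].
#' @param newickPath output newick file.
#' @param jsonPath output JSON file.
#' @return Invisibly, a list with the newick string and the annotation list.
#' @export
exportDendrogram <- function(tree, newickPath, jsonPath) {
  stopifnot(is(tree, "ClusterTree"))
  nw <- .newickString(tree@hclust)
  writeLines(nw, newickPath)
  nt <- tree@nodes
  mlog <- function(p) ifelse(is.na(p), NA_real_, -log10(p))
  ann <- lapply(seq_len(nrow(nt)), function(i) {
    list(node = nt$node[i], height = nt$height[i],
         members = tree@members[[i]],
         mean_cor = nt$mean_cor[i],
         minus_log10_p = list(diet = mlog(nt$p_diet[i]),
                              genotype = mlog(nt$p_genotype[i]),
                              week = mlog(nt$p_week[i]),
                              interaction = mlog(nt$p_interaction[i])))
  })
  names(ann) <- nt$node
  scales <- lapply(c(diet = "p_diet", genotype = "p_genotype",
                     week = "p_week", interaction = "p_interaction"),
                   function(cn) {
    v <- mlog(nt[[cn]])
    v <- v[is.finite(v)]
    list(min = 0, max = if (length(v)) max(v) else 0)
  })
  write_json(list(nodes = ann, color_scales = scales), jsonPath,
             auto_unbox = TRUE, digits = NA, null = "null", na = "null")
  invisible(list(newick = nw, annotation = ann))
}
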