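#' Stage-specific dendrogram cut thresholds
#'
#' The similarity cutoffs (on the 1 - Pearson correlation scale) used to cut
#' each stage's dendrogram into its main clusters. Values above 1 are
#' meaningful: they cut between anti-correlated groups.
#'
#' @return Named numeric vector, one cutoff per stage.
#' @export
#' @examples
#' round(mean(stage_cutoffs()), 1)  # 0.9
stage_cutoffs <- function() {
  stats::setNames(c(0.7, 1.3, 1.1, 0.6, 0.9, 0.9, 0.9), stage_names())
}

#' Pearson correlation distance matrix between profiles
#'
#' Entry (i, j) is `1 - r(values_i, values_j)` with `r` the Pearson
#' correlation; the diagonal is exactly zero. Distances range over
#' `[0, 2]`; values above 1 indicate anti-correlated profiles and are kept
#' as-is (no clamping).
#'
#' @param profiles a `profile_set`, list of [standardized_profile()], or a
#'   samples x 100 numeric matrix.
#' @return Square symmetric numeric matrix with zero diagonal and sample
#'   labels on both dimnames. Constant (zero-variance) profiles are an
#'   error naming the offending sample.
#' @export
pearson_distance_matrix <- function(profiles) {
  m <- profile_matrix(profiles)
  if (nrow(m) < 2) stop("need at least 2 profiles")
  sds <- apply(m, 1, stats::sd)
  if (any(sds == 0)) {
    stop("constant profile(s) with zero variance: ",
         paste(rownames(m)[sds == 0], collapse = ", "))
  }
  d <- 1 - stats::cor(t(m))
  diag(d) <- 0
  d
}

#' UPGMA (unweighted average linkage) clustering of a distance matrix
#'
#' Agglomerative clustering where the distance between two clusters is the
#' arithmetic mean of all inter-member leaf distances. Clusters are indexed
#' by their smallest member leaf; when several pairs tie at the minimal
#' distance, the pair with the smallest `(index_a, index_b)` merges first.
#' Heights are on the same scale as the input distances (here, 1 - r).
#'
#' @param dist square symmetric distance matrix with zero diagonal (e.g.
#'   from [pearson_distance_matrix()]).
#' @return Object of class `upgma_dendrogram` with `merge` (hclust
#'   convention: negative entries are leaves, positive are prior merge
#'   steps), `height`, `labels` and `order` (display leaf order: at each
#'   merge the branch with the smaller minimum leaf index goes left).
#' @export
upgma_linkage <- function(dist) {
  d <- as.matrix(dist)
  n <- nrow(d)
  if (n < 2) stop("need at least 2 items")
  if (!isSymmetric(unname(d), tol = 1e-8)) stop("distance matrix must be symmetric")
  if (any(diag(d) != 0)) stop("distance matrix must have a zero diagonal")
  labels <- rownames(d)
  if (is.null(labels)) labels <- sprintf("s%03d", seq_len(n))

  # active cluster bookkeeping, ordered by minimum member leaf index
  active <- seq_len(n)          # positions into d
  min_leaf <- seq_len(n)        # cluster index = smallest member leaf
  size <- rep(1L, n)
  node <- -seq_len(n)           # hclust id: negative leaf or +merge step
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)

  for (step in seq_len(n - 1L)) {
    k <- length(active)
    ord <- order(min_leaf[active])
    acts <- active[ord]
    best <- NULL
    for (ii in seq_len(k - 1L)) {
      for (jj in (ii + 1L):k) {
        dij <- d[acts[ii], acts[jj]]
        if (is.null(best) || dij < best$d) {
          best <- list(d = dij, i = acts[ii], j = acts[jj])
        }
      }
    }
    i <- best$i; j <- best$j
    merge[step, ] <- c(node[i], node[j])
    height[step] <- best$d
    # unweighted average update: mean over all leaf pairs
    others <- setdiff(active, c(i, j))
    if (length(others) > 0) {
      d[i, others] <- (size[i] * d[i, others] + size[j] * d[j, others]) /
        (size[i] + size[j])
      d[others, i] <- d[i, others]
    }
    size[i] <- size[i] + size[j]
    min_leaf[i] <- min(min_leaf[i], min_leaf[j])
    node[i] <- step
    active <- setdiff(active, j)
  }

  dend <- structure(list(merge = merge, height = height, labels = labels,
                         order = integer(n)),
                    class = "upgma_dendrogram")
  dend$order <- .dendrogram_leaf_order(dend)
  dend
}

# leaves under each node of a merge matrix; returns list indexed by step
.merge_leaves <- function(merge) {
  leaves <- vector("list", nrow(merge))
  for (s in seq_len(nrow(merge))) {
    lv <- function(x) if (x < 0) -x else leaves[[x]]
    leaves[[s]] <- c(lv(merge[s, 1]), lv(merge[s, 2]))
  }
  leaves
}

# display order: branch with the smaller minimum leaf index goes left
.dendrogram_leaf_order <- function(dend) {
  leaves <- .merge_leaves(dend$merge)
  walk <- function(x) {
    if (x < 0) return(-x)
    a <- dend$merge[x, 1]; b <- dend$merge[x, 2]
    min_a <- if (a < 0) -a else min(leaves[[a]])
    min_b <- if (b < 0) -b else min(leaves[[b]])
    if (min_a <= min_b) c(walk(a), walk(b)) else c(walk(b), walk(a))
  }
  walk(nrow(dend$merge))
}

#' @export
print.upgma_dendrogram <- function(x, ...) {
  cat("upgma_dendrogram:", length(x$labels), "leaves, root height",
      sprintf("%.4f", max(x$height)), "\n")
  invisible(x)
}

#' Convert a UPGMA dendrogram to an hclust object
#'
#' @param x an `upgma_dendrogram`.
#' @param ... ignored.
#' @return A `stats::hclust` object (method `"average"`), usable with
#'   `plot()`, `stats::cutree()` and `ape::as.phylo()`.
#' @export
as.hclust.upgma_dendrogram <- function(x, ...) {
  structure(list(merge = x$merge, height = x$height, order = x$order,
                 labels = x$labels, method = "average",
                 dist.method = "1 - Pearson r", call = match.call()),
            class = "hclust")
}

#' Cut a dendrogram at a similarity threshold
#'
#' Clusters are the connected components after removing every merge whose
#' height exceeds the threshold. Cluster ids are contiguous from 1, ordered
#' by each cluster's smallest member leaf, so the assignment is invariant to
#' input ordering up to relabeling.
#'
#' @param dend an [upgma_linkage()] dendrogram.
#' @param threshold positive cut height on the 1 - r scale.
#' @return Object of class `cluster_assignment`: list with `cluster` (named
#'   integer vector leaf -> id), `threshold` and `k` (number of clusters).
#' @export
cut_dendrogram <- function(dend, threshold) {
  stopifnot(inherits(dend, "upgma_dendrogram"), threshold > 0)
  n <- length(dend$labels)
  leaves <- .merge_leaves(dend$merge)
  parent <- seq_len(n)
  find2 <- function(p, x) { while (p[x] != x) x <- p[x]; x }
  for (s in seq_len(nrow(dend$merge))) {
    if (dend$height[s] <= threshold) {
      lv <- leaves[[s]]
      r <- find2(parent, lv[1])
      for (l in lv[-1]) parent[find2(parent, l)] <- r
    }
  }
  roots <- vapply(seq_len(n), function(x) find2(parent, x), integer(1))
  first_leaf <- tapply(seq_len(n), roots, min)
  id_of_root <- stats::setNames(rank(first_leaf), names(first_leaf))
  cluster <- as.integer(id_of_root[as.character(roots)])
  names(cluster) <- dend$labels
  structure(list(cluster = cluster, threshold = threshold,
                 k = max(cluster)),
            class = "cluster_assignment")
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat("cluster_assignment:", x$k, "cluster(s)",
      if (!is.null(x$threshold) && is.finite(x$threshold))
        paste0("at threshold ", x$threshold) else "(main-cluster rule)",
      "; sizes:", paste(table(x$cluster), collapse = "/"), "\n")
  invisible(x)
}

#' Split a dendrogram into its 2 or 3 main clusters
#'
#' The root split gives two branches. If the second-highest merge (the
#' higher of the two root children) lies inside the branch with strictly
#' more leaves, that branch is split as well, yielding three main clusters;
#' otherwise two. With equal-sized branches there is no largest branch to
#' reduce and two clusters are returned.
#'
#' @param dend an [upgma_linkage()] dendrogram with at least 3 leaves.
#' @return A `cluster_assignment` with `k` of 2 or 3 (its `threshold` is
#'   `NA`: the split is structural, not a height cut).
#' @export
main_cluster_split <- function(dend) {
  stopifnot(inherits(dend, "upgma_dendrogram"))
  n <- length(dend$labels)
  if (n < 3) stop("need at least 3 leaves")
  leaves <- .merge_leaves(dend$merge)
  root <- nrow(dend$merge)
  kids <- dend$merge[root, ]
  kid_leaves <- lapply(kids, function(x) if (x < 0) -x else leaves[[x]])
  kid_height <- vapply(kids, function(x) if (x < 0) -Inf else dend$height[x],
                       numeric(1))
  sizes <- lengths(kid_leaves)
  groups <- kid_leaves
  if (any(sizes != sizes[1])) {
    larger <- which.max(sizes)
    # does the second-highest merge lie inside the larger branch?
    # (height ties resolve toward the larger branch)
    if (kid_height[larger] >= kid_height[-larger][1] &&
        is.finite(kid_height[larger])) {
      sub <- dend$merge[kids[larger], ]
      sub_leaves <- lapply(sub, function(x) if (x < 0) -x else leaves[[x]])
      groups <- c(groups[-larger], sub_leaves)
    }
  }
  cluster <- integer(n)
  ord <- order(vapply(groups, min, numeric(1)))
  for (g in seq_along(ord)) cluster[groups[[ord[g]]]] <- g
  names(cluster) <- dend$labels
  structure(list(cluster = cluster, threshold = NA_real_,
                 k = length(groups)),
            class = "cluster_assignment")
}

#' Correlation matrix permuted to dendrogram leaf order
#'
#' @param dist distance matrix from [pearson_distance_matrix()].
#' @param dend the matching [upgma_linkage()] dendrogram.
#' @return List with `correlation` (the matrix `1 - dist` with rows and
#'   columns permuted to the dendrogram's display leaf order) and
#'   `leaf_order` (character vector of labels).
#' @export
order_correlation_matrix <- function(dist, dend) {
  stopifnot(inherits(dend, "upgma_dendrogram"))
  d <- as.matrix(dist)
  if (!setequal(rownames(d), dend$labels)) {
    stop("distance matrix labels do not match dendrogram labels")
  }
  ord <- dend$labels[dend$order]
  r <- 1 - d[ord, ord]
  diag(r) <- 1
  list(correlation = r, leaf_order = ord)
}

#' Cluster a set of standardized profiles for one stage
#'
#' Convenience wrapper: builds the 1 - Pearson distance matrix, runs UPGMA,
#' cuts at the stage's cutoff ([stage_cutoffs()]) and also applies the
#' structural 2-vs-3 main-cluster rule. Both partitions are reported, since
#' the cutoff cut and the main-cluster rule need not agree.
#'
#' @param profiles a `profile_set`, profile list or matrix (see
#'   [profile_matrix()]).
#' @param stage stage name used to select the default cutoff.
#' @param cutoff cut height; defaults to the stage's entry in
#'   [stage_cutoffs()].
#' @return List with `distance`, `dendrogram`, `cut` (cutoff-based
#'   `cluster_assignment`), `main` (2-vs-3 rule assignment) and
#'   `correlation` (dendrogram-ordered correlation matrix).
#' @export
cluster_stage_profiles <- function(profiles, stage,
                                   cutoff = stage_cutoffs()[[canonical_stage(stage)]]) {
  d <- pearson_distance_matrix(profiles)
  dend <- upgma_linkage(d)
  list(distance = d,
       dendrogram = dend,
       cut = cut_dendrogram(dend, cutoff),
       main = main_cluster_split(dend),
       correlation = order_correlation_matrix(d, dend))
}

#' Export a dendrogram to a Newick file
#'
#' Branch lengths are on the 1 - r scale; the tree is ultrametric, as UPGMA
#' guarantees.
#'
#' @param dend an [upgma_linkage()] dendrogram.
#' @param path output file path.
#' @export
write_newick <- function(dend, path) {
  phy <- ape::as.phylo(as.hclust.upgma_dendrogram(dend))
  ape::write.tree(phy, file = path)
  invisible(path)
}
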