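# Co-expression clustering and homeologue-pair divergence.
#
# Profiles are clustered with Ward linkage on correlation distance
# d = 1 - r, the combination used for the salmon tissue atlas. Divergence of
# a homeologue pair is membership in different co-expression clusters, and
# enrichment of divergence between two specific clusters is tested by
# randomization of the pairing.

#' Correlation distance between gene expression profiles
#'
#' Computes d(i,j) = 1 - Pearson r(i,j) between all gene pairs of a
#' log2-scale expression matrix. Genes with zero variance across tissues have
#' no defined correlation; they are excluded with a warning and recorded in
#' the `excluded` attribute.
#'
#' @param m An [expression_matrix] on the log2 scale with at least 3 tissues.
#' @return A [stats::dist] object with gene labels; attribute `excluded`
#'   holds the ids of zero-variance genes.
#' @export
correlation_distance <- function(m) {
  stopifnot(inherits(m, "expression_matrix"))
  if (m$scale != "log2")
    stop_wgdfate("correlation_distance() expects log2(FPKM+1) values")
  if (ncol(m$values) < 3)
    stop_wgdfate("at least 3 tissues are required")
  v <- apply(m$values, 1L, function(x) max(x) > min(x))
  excluded <- genes(m)[!v]
  if (length(excluded))
    warning(length(excluded), " zero-variance gene(s) excluded from clustering")
  r <- cor(t(m$values[v, , drop = FALSE]))
  d <- as.dist(1 - r)
  attr(d, "excluded") <- excluded
  d
}

cluster_assignment <- function(labels, k, tree = NULL, method = "ward") {
  stopifnot(is.integer(labels) || is.numeric(labels))
  labels <- setNames(as.integer(labels), names(labels))
  if (!all(sort(unique(labels)) == seq_len(k)))
    stop_wgdfate("cluster labels must be 1..k with no empty cluster")
  structure(list(labels = labels, k = as.integer(k), tree = tree,
                 method = method),
            class = "cluster_assignment")
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat(sprintf("<cluster_assignment> %d genes in %d clusters (%s)\n",
              length(x$labels), x$k, x$method))
  invisible(x)
}

#' Cut a Ward-linkage tree into k co-expression clusters
#'
#' Agglomerative clustering with `hclust(method = "ward.D")` (the algorithm
#' R's `hclust` historically ran under the name `"ward"`) on a correlation
#' distance matrix, cut into exactly `k` clusters.
#'
#' @param d A distance object from [correlation_distance()].
#' @param k Number of clusters, `1 <= k <=` number of genes.
#' @return A `cluster_assignment` with named integer labels `1..k`.
#' @export
ward_clusters <- function(d, k) {
  n <- attr(d, "Size")
  if (k < 1 || k > n) stop_wgdfate("k must be between 1 and ", n)
  hc <- hclust(d, method = "ward.D")
  lab <- cutree(hc, k = k)
  cluster_assignment(setNames(as.integer(lab), attr(d, "Labels")), k, hc)
}

#' Cut a Ward-linkage tree at a cohesion threshold
#'
#' Chooses the smallest number of clusters such that every within-cluster
#' pair of genes has Pearson correlation strictly above `r_min`. Merges are
#' replayed in `hclust` order and stopped at the first merge that would
#' create a cluster containing a pair at or below the threshold; the cut is
#' therefore data-driven rather than fixed at a preset k. Genes with zero
#' variance are excluded as in [correlation_distance()].
#'
#' @param m An [expression_matrix] on the log2 scale.
#' @param r_min Cohesion threshold on the within-cluster Pearson correlation.
#' @return A `cluster_assignment`; element `r_min` records the threshold.
#' @export
cohesion_clusters <- function(m, r_min = 0.55) {
  stopifnot(inherits(m, "expression_matrix"))
  if (m$scale != "log2")
    stop_wgdfate("cohesion_clusters() expects log2(FPKM+1) values")
  v <- apply(m$values, 1L, function(x) max(x) > min(x))
  excluded <- genes(m)[!v]
  if (length(excluded))
    warning(length(excluded), " zero-variance gene(s) excluded from clustering")
  vals <- m$values[v, , drop = FALSE]
  r <- cor(t(vals))
  n <- nrow(vals)
  hc <- hclust(as.dist(1 - r), method = "ward.D")
  # replay merges; members[[i]] = row indices in cluster created at merge i
  members <- vector("list", n - 1L)
  good_merges <- 0L
  for (i in seq_len(n - 1L)) {
    pick <- function(j) if (j < 0) -j else members[[j]]
    a <- pick(hc$merge[i, 1]); b <- pick(hc$merge[i, 2])
    if (min(r[a, b]) <= r_min) break
    members[[i]] <- c(a, b)
    good_merges <- i
  }
  k <- n - good_merges
  lab <- cutree(hc, k = k)
  out <- cluster_assignment(setNames(as.integer(lab), rownames(vals)), k, hc,
                            method = "ward/cohesion")
  out$r_min <- r_min
  out
}

check_pairs <- function(pairs) {
  if (!is.data.frame(pairs) || ncol(pairs) < 2)
    stop_wgdfate("'pairs' must be a data frame with two gene-id columns")
  a <- as.character(pairs[[1]]); b <- as.character(pairs[[2]])
  if (any(a == b)) stop_wgdfate("a pair cannot contain the same gene twice")
  if (anyDuplicated(c(a, b)))
    stop_wgdfate("a gene appears in more than one pair")
  data.frame(a = a, b = b, stringsAsFactors = FALSE)
}

#' Flag homeologue pairs with diverged co-expression
#'
#' A pair is diverged when its two members fall in different co-expression
#' clusters. Pairs with an unclustered member are skipped with a warning and
#' reported in the `n_skipped` attribute.
#'
#' @param clusters A `cluster_assignment`.
#' @param pairs Data frame whose first two columns are gene ids.
#' @return A data frame (geneA, geneB, cluster_a, cluster_b, diverged) with
#'   attributes `fraction_diverged` and `n_skipped`.
#' @export
pair_divergence <- function(clusters, pairs) {
  pairs <- check_pairs(pairs)
  la <- clusters$labels[pairs$a]
  lb <- clusters$labels[pairs$b]
  ok <- !is.na(la) & !is.na(lb)
  if (any(!ok))
    warning(sum(!ok), " pair(s) skipped: unclustered gene")
  out <- data.frame(geneA = pairs$a[ok], geneB = pairs$b[ok],
                    cluster_a = unname(la[ok]), cluster_b = unname(lb[ok]),
                    stringsAsFactors = FALSE)
  out$diverged <- out$cluster_a != out$cluster_b
  attr(out, "fraction_diverged") <-
    if (nrow(out)) mean(out$diverged) else NA_real_
  attr(out, "n_skipped") <- sum(!ok)
  out
}

#' Randomization test for cluster-pair enrichment of homeologue divergence
#'
#' For every unordered pair of co-expression clusters (i, j), counts the
#' homeologue pairs whose members fall in clusters i and j, and compares the
#' observed count against a null in which the second member of every pair is
#' randomly permuted across pairs (cluster assignments kept fixed; both the
#' marginal cluster occupancies and the number of pairs are preserved).
#' Empirical p-values use an add-one pseudo-count,
#' p = (1 + #\{permutations with count >= observed\}) / (1 + n_rand), so p is
#' never exactly zero.
#'
#' @param clusters A `cluster_assignment`.
#' @param pairs Data frame whose first two columns are gene ids.
#' @param n_rand Number of randomizations (the atlas analysis used 10,000).
#' @param seed Optional integer seed for reproducibility.
#' @return Data frame with columns `cluster_i`, `cluster_j` (i <= j),
#'   `observed` and `p`.
#' @export
cluster_pair_enrichment <- function(clusters, pairs, n_rand = 10000,
                                    seed = NULL) {
  if (n_rand < 1) stop_wgdfate("n_rand must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  div <- pair_divergence(clusters, pairs)
  k <- clusters$k
  cell <- function(a, b) (pmin(a, b) - 1L) * k + pmax(a, b)
  ncell <- k * k
  obs <- tabulate(cell(div$cluster_a, div$cluster_b), ncell)
  ge <- integer(ncell)
  cb <- div$cluster_b
  for (i in seq_len(n_rand)) {
    cnt <- tabulate(cell(div$cluster_a, sample(cb)), ncell)
    ge <- ge + (cnt >= obs)
  }
  p <- (1 + ge) / (1 + n_rand)
  ij <- which(upper.tri(matrix(0, k, k), diag = TRUE), arr.ind = TRUE)
  idx <- (ij[, 1] - 1L) * k + ij[, 2]
  data.frame(cluster_i = ij[, 1], cluster_j = ij[, 2],
             observed = obs[idx], p = p[idx])
}
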