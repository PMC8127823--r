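test_that("correlation distance matches hand-computed Pearson values", {
  m <- mk_expr(rbind(a = c(1, 2, 3), b = c(1, 2, 3), c = c(3, 2, 1),
                     d = c(1, 2, 4)),
               genes = c("a", "b", "c", "d"), scale = "log2")
  d <- as.matrix(correlation_distance(m))
  expect_equal(d["a", "b"], 0)
  expect_equal(d["a", "c"], 2)
  expect_equal(d["a", "d"], 1 - 1.5 / sqrt(7 / 3))  # hand Pearson: r = 0.98198
  expect_equal(diag(d), setNames(rep(0, 4), c("a", "b", "c", "d")))
})

test_that("degenerate clustering inputs are handled", {
  expect_error(correlation_distance(mk_expr(matrix(1:4, 2), scale = "log2")),
               "3 tissues")
  m <- mk_expr(rbind(c(1, 2, 3), c(5, 5, 5)), scale = "log2")
  expect_warning(d <- correlation_distance(m), "zero-variance")
  expect_equal(attr(d, "excluded"), "g02")
  expect_error(correlation_distance(mk_expr(matrix(1:9, 3))), "log2")
})

test_that("Ward clustering recovers a planted two-group structure", {
  set.seed(21)
  base1 <- sin(seq(0, 3, length.out = 8)); base2 <- cos(seq(0, 3, length.out = 8))
  vals <- rbind(base1 + rnorm(8, 0, 0.01), base1 + rnorm(8, 0, 0.01),
                base1 + rnorm(8, 0, 0.01), base2 + rnorm(8, 0, 0.01),
                base2 + rnorm(8, 0, 0.01), base2 + rnorm(8, 0, 0.01))
  m <- mk_expr(vals - min(vals), scale = "log2")
  d <- correlation_distance(m)
  cl <- ward_clusters(d, 2)
  # brute-force oracle: best 2-partition by total within-cluster distance
  dm <- as.matrix(d)
  best <- NULL; best_cost <- Inf
  for (code in 1:(2^5 - 1)) {
    grp <- c(1L, as.integer(intToBits(code)[1:5]) + 1L)
    cost <- sum(dm[grp == 1, grp == 1]) / 2 + sum(dm[grp == 2, grp == 2]) / 2
    if (cost < best_cost) { best_cost <- cost; best <- grp }
  }
  expect_equal(unname(cl$labels), best)
  # trivial cuts
  expect_equal(ward_clusters(d, 6)$k, 6L)
  expect_error(ward_clusters(d, 7), "between 1 and 6")
})

test_that("cohesion cut separates all pairs below the correlation floor", {
  set.seed(8)
  n <- 60
  vals <- matrix(pmax(0, rnorm(n * 10, 4, 2)), n)
  m <- mk_expr(vals, scale = "log2")
  cl <- cohesion_clusters(m, r_min = 0.55)
  r <- cor(t(vals))
  for (k in unique(cl$labels)) {
    idx <- which(cl$labels == k)
    if (length(idx) > 1) {
      sub <- r[idx, idx]
      expect_gt(min(sub[upper.tri(sub)]), 0.55)
    }
  }
})

test_that("pair divergence counts cluster disagreement", {
  cl <- mk_clusters(setNames(c(1L, 1L, 2L, 2L, 1L, 2L, 2L, 1L),
                             sprintf("g%d", 1:8)))
  pairs <- data.frame(a = c("g1", "g3", "g5", "g7"),
                      b = c("g2", "g4", "g6", "g8"))
  div <- pair_divergence(cl, pairs)
  expect_equal(div$diverged, c(FALSE, FALSE, TRUE, TRUE))
  expect_equal(attr(div, "fraction_diverged"), 0.5)
  # invariant under relabeling
  cl2 <- mk_clusters(setNames(c(2L, 2L, 1L, 1L, 2L, 1L, 1L, 2L),
                              sprintf("g%d", 1:8)))
  expect_equal(attr(pair_divergence(cl2, pairs), "fraction_diverged"), 0.5)
  # unclustered members are skipped with a warning
  pairs2 <- rbind(pairs, data.frame(a = "g9", b = "g10"))
  expect_warning(div2 <- pair_divergence(cl, pairs2), "skipped")
  expect_equal(attr(div2, "n_skipped"), 1L)
  expect_error(pair_divergence(cl, data.frame(a = "g1", b = "g1")),
               "same gene")
})

test_that("enrichment p-values are exact in degenerate and tiny cases", {
  # single cluster: every permutation reproduces the observation
  cl1 <- mk_clusters(setNames(rep(1L, 6), sprintf("g%d", 1:6)), k = 1)
  pairs <- data.frame(a = c("g1", "g2", "g3"), b = c("g4", "g5", "g6"))
  enr <- cluster_pair_enrichment(cl1, pairs, n_rand = 50, seed = 1)
  expect_equal(enr$p, 1)
  # two clusters, three pairs: compare against exhaustive enumeration of
  # the 3! partner permutations
  cl <- mk_clusters(setNames(c(1L, 1L, 2L, 2L, 1L, 2L), sprintf("g%d", 1:6)))
  ca <- cl$labels[pairs$a]; cb <- cl$labels[pairs$b]
  perms <- rbind(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1),
                 c(3, 1, 2), c(3, 2, 1))
  cell <- function(a, b) (pmin(a, b) - 1L) * 2L + pmax(a, b)
  obs <- tabulate(cell(ca, cb), 4)
  exact_ge <- rowMeans(apply(perms, 1, function(pp)
    tabulate(cell(ca, cb[pp]), 4) >= obs))
  enr2 <- cluster_pair_enrichment(cl, pairs, n_rand = 4000, seed = 7)
  got <- numeric(4)
  got[cell(enr2$cluster_i, enr2$cluster_j)] <- enr2$p
  for (cc in cell(enr2$cluster_i, enr2$cluster_j)) {
    expect_equal(got[cc], exact_ge[cc], tolerance = 0.05)
  }
  expect_true(all(enr2$p > 0 & enr2$p <= 1))
  # determinism under a fixed seed
  enr3 <- cluster_pair_enrichment(cl, pairs, n_rand = 4000, seed = 7)
  expect_identical(enr2, enr3)
})
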