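test_that("correlation p-values reproduce the classifier thresholds", {
  expect_equal(round(pearson_pvalue(0.6, 13), 2), 0.03)
  expect_equal(pearson_pvalue(0.6, 13), 0.0301708, tolerance = 1e-6)
  expect_gt(pearson_pvalue(0.55, 13), 0.05)
  expect_equal(pearson_pvalue(0, 13), 1)
  expect_equal(pearson_pvalue(c(-1, 1), 13), c(0, 0))
  expect_error(pearson_pvalue(1.2, 13), "<= 1")
  expect_error(pearson_pvalue(0.5, 2), ">= 3")
})

test_that("correlation p-values decrease in |r| and in n", {
  rs <- seq(0.05, 0.95, by = 0.05)
  p <- pearson_pvalue(rs, 13)
  expect_true(all(diff(p) < 0))
  ns <- c(5, 8, 13, 21, 34, 55)
  pn <- vapply(ns, function(n) pearson_pvalue(0.6, n), numeric(1))
  expect_true(all(diff(pn) < 0))
})

test_that("conservation calls follow the threshold bands", {
  pike <- log2(1:13 + 1)
  expect_identical(conservation_call(pike, pike)$status, "conserved")
  expect_identical(conservation_call(rep(2, 13), pike)$status, "undefined")
  # profile built to land in the intermediate band (0.55, 0.6)
  scrambled <- c(13, 1, 12, 2, 11, 3, 10, 4, 9, 5, 8, 6, 7)
  x <- 0.44 * (1:13) + 0.56 * scrambled
  cc <- conservation_call(x, 1:13)
  expect_gt(cc$r, 0.55); expect_lt(cc$r, 0.6)
  expect_identical(cc$status, "intermediate")
  expect_error(conservation_call(1:5, 1:6), "length mismatch")
})

test_that("summed-profile conservation works on the FPKM scale", {
  pike <- c(0, 0, 4, 9, 19, 39, 0, 5, 11, 2, 0, 7, 3)
  a <- pike * c(1, 1, 1, 1, 0, 0, 1, 0, 0, 1, 1, 0, 1)
  b <- pike - a
  t <- ortholog_triplet(a, b, pike)
  sm <- summed_profile_conservation(t)
  expect_true(sm$conserved)
  expect_equal(sm$r_sum, 1)
  t0 <- ortholog_triplet(rep(0, 13), rep(0, 13), pike)
  expect_false(summed_profile_conservation(t0)$conserved)
  expect_error(ortholog_triplet(1:3, 1:3, 1:4), "equal tissue length")
})

test_that("the on-off partition rule follows its set algebra", {
  on <- function(idx, n = 8) { x <- numeric(n); x[idx] <- 5; x }
  # perfect partition of the ancestral on-set
  expect_true(on_off_call(ortholog_triplet(on(1:3, 6), on(4:6, 6), on(1:6, 6))))
  # one copy covers the ancestor alone
  expect_false(on_off_call(ortholog_triplet(on(1:6, 6), numeric(6), on(1:6, 6))))
  # overlapping partition still covers without either side alone
  expect_true(on_off_call(ortholog_triplet(on(1:2, 8), on(2:3, 8), on(1:3, 8))))
  # union fails to cover
  expect_false(on_off_call(ortholog_triplet(on(1:2, 8), on(2, 8), on(1:3, 8))))
  # silent ancestor
  expect_false(on_off_call(ortholog_triplet(on(1:2, 8), on(3:4, 8),
                                            numeric(8))))
})

test_that("triplet classification applies the fate rules in order", {
  pike <- c(0, 0, 8, 15, 30, 63, 0, 5, 11, 2, 0, 7, 3)
  redrawn <- c(40, 2, 0, 0, 1, 0, 25, 0, 0, 0, 18, 0, 0) # low r with pike
  cl <- mk_clusters(setNames(c(1L, 2L, 1L, 1L, 2L, 1L, 2L),
                             c("a1", "b1", "a2", "b2", "a3", "b3", "x")))
  # both conserved wins even in different clusters (precedence over neo)
  t1 <- ortholog_triplet(pike, pike, pike, ids = c("a1", "b1", "p"))
  expect_identical(classify_triplet(t1, cl)$category, "both_conserved")
  # one conserved + different clusters: neofunctionalized
  t2 <- ortholog_triplet(pike, redrawn, pike, ids = c("a3", "b3", "p"))
  call2 <- classify_triplet(t2, cl)
  expect_identical(call2$category, "neofunctionalized")
  expect_lt(call2$r_b, 0.55)
  # complementary partition, different clusters: subfunctionalized
  pike2 <- c(74.2, 19.6, 28.7, 10.3, 69, 7.5, 8, 10.1, 18.8, 3.9, 1.6, 12,
             11.4)
  mask <- c(1, 0, 1, 1, 0, 0, 0, 0, 1, 0, 1, 1, 1)
  t3 <- ortholog_triplet(pike2 * mask, pike2 * (1 - mask), pike2,
                         ids = c("a3", "b3", "p"))
  call3 <- classify_triplet(t3, cl)
  expect_identical(call3$status_a, "diverged")
  expect_identical(call3$status_b, "diverged")
  expect_identical(call3$category, "subfunctionalized")
  expect_equal(call3$r_sum, 1)
  # same profiles in the same cluster are not subfunctionalized
  t4 <- ortholog_triplet(pike2 * mask, pike2 * (1 - mask), pike2,
                         ids = c("a2", "b2", "p"))
  expect_identical(classify_triplet(t4, cl)$category, "intermediate")
  expect_error(classify_triplet(
    ortholog_triplet(pike, pike, pike, ids = c("nope", "b1", "p")), cl),
    "missing cluster label")
})

test_that("tissue specificity behaves like tau", {
  expect_equal(tissue_specificity(rep(7, 9)), 0)
  expect_equal(tissue_specificity(c(0, 0, 5, 0)), 1)
  expect_equal(tissue_specificity(c(4, 2, 2)), 0.5)
  # invariant under positive scaling, bounded in [0, 1]
  set.seed(4)
  for (i in 1:20) {
    x <- runif(10, 0, 50)
    tau <- tissue_specificity(x)
    expect_equal(tissue_specificity(3.7 * x), tau)
    expect_gte(tau, 0); expect_lte(tau, 1)
  }
  expect_warning(expect_true(is.na(tissue_specificity(c(0, 0)))),
                 "all-zero")
})

test_that("specificity differences between clusters use the rank-sum test", {
  cl <- mk_clusters(setNames(c(1L, 1L, 1L, 2L, 2L, 2L), sprintf("g%d", 1:6)))
  scores <- setNames(c(0.1, 0.2, 0.3, 0.7, 0.8, 0.9), sprintf("g%d", 1:6))
  res <- specificity_cluster_test(cl, scores)
  expect_equal(res$p, 0.1)  # exact two-sided rank-sum at n = m = 3
  same <- setNames(c(0.4, 0.4), c("g1", "g4"))
  cl2 <- mk_clusters(setNames(c(1L, 2L), c("g1", "g4")))
  expect_equal(specificity_cluster_test(cl2, same)$p, 1)
  # empty clusters are skipped with a warning
  cl3 <- mk_clusters(setNames(c(1L, 1L, 3L, 3L, 2L), sprintf("g%d", c(1:4, 9))),
                     k = 3)
  expect_warning(res3 <- specificity_cluster_test(cl3, scores[1:4]),
                 "skipped")
  expect_equal(nrow(res3), 1)
})
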