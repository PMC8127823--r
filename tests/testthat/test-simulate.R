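test_that("simulation configs are validated", {
  expect_error(sim_config(p_ret_ss4r = 1.2), "probabilities")
  expect_error(sim_config(fate_proportions = c(conserved = 0.5,
                                               neofunctionalized = 0.4)),
               "sum to 1")
  expect_error(sim_config(fate_proportions = c(conserved = 0.5, bogus = 0.5)),
               "named")
  expect_error(sim_config(n_common_tissues = 2), ">= 3")
})

test_that("a fixed seed reproduces the expression bundle byte-identically", {
  cfg <- sim_config(n_triplets = 25, seed = 42)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_expression_sim(simulate_expression(cfg), d1)
  write_expression_sim(simulate_expression(cfg), d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  }
})

test_that("zero-noise fates are constructed exactly as planted", {
  cfg <- sim_config(n_triplets = 80, noise_sd = 0, seed = 5)
  sim <- simulate_expression(cfg)
  common <- sim$tissue_map$salmon
  sv <- sim$salmon$values[, common]
  pv <- sim$pike$values
  for (i in which(sim$truth$fate == "conserved")) {
    tr <- sim$truth[i, ]
    expect_equal(unname(sv[tr$gene_a, ]), unname(pv[tr$gene_pike, ]),
                 tolerance = 1e-9)
    expect_equal(unname(sv[tr$gene_b, ]), unname(pv[tr$gene_pike, ]),
                 tolerance = 1e-9)
  }
  for (i in which(sim$truth$fate == "subfunctionalized")) {
    tr <- sim$truth[i, ]
    expect_equal(unname(sv[tr$gene_a, ] + sv[tr$gene_b, ]),
                 unname(pv[tr$gene_pike, ]), tolerance = 1e-9)
  }
  for (i in which(sim$truth$fate == "pseudogenized")) {
    tr <- sim$truth[i, ]
    expect_true(all(sv[tr$gene_a, ] == 0) || all(sv[tr$gene_b, ] == 0))
  }
})

test_that("forced retention and no-duplication regimes shape the families", {
  full <- simulate_gene_families(sim_config(n_families = 40, p_ret_ss4r = 1,
                                            trout_loss = 0, seed = 2))
  expect_true(all(full$truth_lineages$ss4r_retained))
  none <- simulate_gene_families(sim_config(n_families = 40, p_ret_ts3r = 0,
                                            p_ret_ss4r = 0, ssd_rate = 0,
                                            trout_loss = 0, seed = 2))
  expect_false(any(none$truth_families$ts3r_retained))
  for (nw in none$newick) {
    g <- parse_gene_tree(text = nw)
    expect_equal(sort(g$leaves$species),
                 c("danio", "esox", "oncorhynchus", "salmo"))
    g <- label_duplication_nodes(g)
    expect_false(any(g$events == "duplication"))
  }
})

test_that("planted Ss4R retention matches its binomial law", {
  cfg <- sim_config(n_families = 2000, seed = 3)
  fams <- simulate_gene_families(cfg)
  tl <- fams$truth_lineages
  n <- nrow(tl)
  # 99% binomial interval around the planted retention probability
  lo <- qbinom(0.005, n, cfg$p_ret_ss4r) / n
  hi <- qbinom(0.995, n, cfg$p_ret_ss4r) / n
  expect_gte(mean(tl$ss4r_retained), lo)
  expect_lte(mean(tl$ss4r_retained), hi)
})

test_that("TE family simulation plants the requested divergence", {
  fam <- simulate_te_family(n_copies = 25, length = 600, divergence = 0.13,
                            seed = 9)
  ident <- pairwise_identity(fam)
  vals <- ident[upper.tri(ident)]
  expect_equal(mean(vals), 87, tolerance = 0.02)
  fam2 <- simulate_te_family(n_copies = 25, length = 600, divergence = 0.02,
                             seed = 9)
  ident2 <- pairwise_identity(fam2)
  expect_equal(mean(ident2[upper.tri(ident2)]), 98, tolerance = 0.02)
})

test_that("simulated HSP tables reproduce their planted regimes in windows", {
  hs <- simulate_hsp_table(chrom_length = 1e7, seed = 4)
  track <- windowed_identity(hs$hsps)
  # windows fully inside a region must carry that region's category
  for (w in seq_len(nrow(track))) {
    reg <- hs$truth[hs$truth$start <= track$start[w] &
                      hs$truth$end >= track$end[w], ]
    if (nrow(reg) == 1 && !is.na(track$identity[w]))
      expect_equal(track$category[w], reg$regime)
  }
})
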