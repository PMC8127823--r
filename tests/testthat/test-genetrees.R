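stree <- species_tree()

test_that("gene trees parse with the species|gene|chromosome convention", {
  g <- parse_gene_tree(text = "((salmo|g1|ssa01,salmo|g2|ssa05),esox|g3|elu01);")
  expect_equal(nrow(g$leaves), 3)
  expect_equal(sort(unique(g$leaves$species)), c("esox", "salmo"))
  expect_equal(g$leaves$chromosome[g$leaves$gene == "g2"], "ssa05")
  expect_error(parse_gene_tree(text = "((a,b);"), "could not parse")
  expect_error(parse_gene_tree(text = "(salmo|g1|ssa01,esox|g3);"),
               "species\\|gene\\|chromosome")
  expect_error(parse_gene_tree(text = "(martian|g1|c1,esox|g2|elu01);",
                               species = stree$phylo$tip.label),
               "unknown species in leaf martian")
  # write-then-parse round trip preserves the topology
  nw <- ape::write.tree(g$phylo)
  g2 <- parse_gene_tree(text = nw)
  expect_true(ape::all.equal.phylo(g$phylo, g2$phylo))
})

test_that("species overlap separates duplication from speciation nodes", {
  dup_root <- parse_gene_tree(text = paste0(
    "((salmo|a|ssa01,oncorhynchus|b|omy01),",
    "(salmo|c|ssa02,oncorhynchus|d|omy02));"))
  ev <- label_duplication_nodes(dup_root)$events
  expect_identical(ev[1], "duplication")   # root: {salmo,onco} on both sides
  expect_identical(ev[-1], c("speciation", "speciation"))
  spec_root <- parse_gene_tree(text =
    "((salmo|a|ssa01,oncorhynchus|b|omy01),esox|c|elu01);")
  expect_identical(label_duplication_nodes(spec_root)$events[1], "speciation")
  cherry <- parse_gene_tree(text = "(salmo|a|ssa01,salmo|b|ssa01);")
  expect_identical(label_duplication_nodes(cherry)$events, "duplication")
})

test_that("era assignment maps duplications onto the species tree", {
  # duplication with salmon and trout in both subtrees: Ss4R
  g1 <- assign_era(parse_gene_tree(text = paste0(
    "((salmo|a|ssa01,oncorhynchus|b|omy01),",
    "(salmo|c|ssa02,oncorhynchus|d|omy02));")), stree)
  expect_identical(g1$eras[1], "Ss4R")
  # salmon-only duplication on different chromosomes: Ss4R by chromosome rule
  g2 <- assign_era(parse_gene_tree(
    text = "(salmo|a|ssa03,salmo|b|ssa06);"), stree)
  expect_identical(g2$eras, "Ss4R")
  # same chromosome: small-scale duplication
  g3 <- assign_era(parse_gene_tree(
    text = "(salmo|a|ssa03,salmo|b|ssa03);"), stree)
  expect_identical(g3$eras, "postSs4R_SSD")
  # duplication containing the outgroups on both sides: Ts3R at the root
  g4 <- assign_era(parse_gene_tree(text = paste0(
    "((danio|a|dre01,(esox|b|elu01,salmo|c|ssa01)),",
    "(danio|d|dre01,(esox|e|elu01,salmo|f|ssa02)));")), stree)
  expect_identical(g4$eras[1], "Ts3R")
  # duplication below the root but above the salmonid crown: pre-Ss4R SSD
  g5 <- assign_era(parse_gene_tree(text = paste0(
    "((esox|b|elu01,salmo|c|ssa01),(esox|e|elu02,salmo|f|ssa02));")), stree)
  expect_identical(g5$eras[1], "preSs4R_SSD")
  # salmon leaves on several chromosomes in one subtree: ambiguous
  g6 <- assign_era(parse_gene_tree(text =
    "((salmo|a|ssa01,salmo|b|ssa02),salmo|c|ssa03);"), stree)
  expect_identical(g6$eras[1], "ambiguous")
})

test_that("only the oldest Ss4R candidate per lineage keeps the era", {
  g <- assign_era(parse_gene_tree(text = paste0(
    "(((salmo|a|ssa01,oncorhynchus|b|omy01),",
    "(salmo|c|ssa02,oncorhynchus|d|omy02)),salmo|e|ssa03);")), stree)
  # root (salmon-only sibling, different chromosome rep on one side) and the
  # inner two-salmonid node are both Ss4R candidates on the same path
  expect_equal(sum(g$eras == "Ss4R"), 1)
  expect_identical(g$eras[1], "Ss4R")           # closest to the root wins
  expect_true("postSs4R_SSD" %in% g$eras)
  # property: no root-to-leaf path in simulated families carries two Ss4R
  fams <- simulate_gene_families(sim_config(n_families = 150, seed = 13))
  for (nw in fams$newick) {
    g <- assign_era(parse_gene_tree(text = nw), stree)
    phy <- g$phylo
    ntip <- length(phy$tip.label)
    for (tip in seq_len(ntip)) {
      path <- integer(0); node <- tip
      repeat {
        parent <- phy$edge[phy$edge[, 2] == node, 1]
        if (length(parent) == 0) break
        path <- c(path, parent); node <- parent
      }
      expect_lte(sum(g$eras[path - ntip] == "Ss4R"), 1)
    }
  }
})

test_that("species-overlap labeling matches the pairwise-LCA brute force", {
  set.seed(31)
  tops <- all_rooted_topologies(five_leaf_labels())
  for (nw in sample(tops, 12)) {
    g <- label_duplication_nodes(parse_gene_tree(text = nw))
    expect_identical(g$events, label_duplications_pairwise(g))
  }
})
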