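# End-to-end pipeline: expression filtering, clustering, triplet fate
# classification, retention analysis and block/landscape summaries, joined
# into a single report.

#' Classify homeologue fates for a set of ortholog triplets
#'
#' Runs the full expression stage: filters expressed genes in both species
#' (max tissue FPKM strictly above the threshold), clusters the expressed
#' salmon genes on the log2 scale over all salmon tissues, restricts both
#' matrices to the common tissues, and applies [classify_triplet()] to every
#' triplet whose three members are expressed. Triplets with an unexpressed
#' outgroup orthologue are reported as `pike_unexpressed`; triplets where a
#' salmon copy fails the expressed filter are reported as `silenced_copy`
#' (the expression signature of pseudogenization); triplets with an
#' undefined correlation are reported as `undefined`.
#'
#' @param salmon,pike [expression_matrix] objects on the raw-FPKM scale.
#' @param triplets Data frame with columns `gene_a`, `gene_b`, `gene_pike`.
#' @param map [tissue_map()] of the common tissues.
#' @param cfg A [classifier_config()].
#' @param clustering `"cohesion"` (default) cuts the Ward tree at the
#'   smallest k whose clusters are internally correlated above
#'   `cfg$r_diverged`; `"ward"` cuts at a fixed `k`.
#' @param k Number of clusters for `clustering = "ward"`.
#' @param expressed_threshold FPKM threshold of the expressed filter.
#' @return Data frame of per-triplet calls (category, per-copy status,
#'   correlations, cluster labels); the `clusters` attribute holds the
#'   `cluster_assignment` used.
#' @export
classify_homeolog_fates <- function(salmon, pike, triplets, map,
                                    cfg = classifier_config(),
                                    clustering = c("cohesion", "ward"),
                                    k = 11, expressed_threshold = 1.0) {
  clustering <- match.arg(clustering)
  s_expr <- filter_expressed(salmon, expressed_threshold)
  p_expr <- filter_expressed(pike, expressed_threshold)
  s_log <- log2_transform(s_expr)
  clusters <- if (clustering == "cohesion") {
    suppressWarnings(cohesion_clusters(s_log, r_min = cfg$r_diverged))
  } else {
    suppressWarnings(ward_clusters(correlation_distance(s_log), k))
  }
  aligned <- align_common_tissues(s_expr, p_expr, map)
  sv <- aligned$salmon$values
  pv <- aligned$pike$values
  calls <- vector("list", nrow(triplets))
  for (i in seq_len(nrow(triplets))) {
    ga <- triplets$gene_a[i]; gb <- triplets$gene_b[i]
    gp <- triplets$gene_pike[i]
    row <- data.frame(gene_a = ga, gene_b = gb, gene_pike = gp,
                      category = NA_character_, status_a = NA_character_,
                      status_b = NA_character_, r_a = NA_real_,
                      r_b = NA_real_, r_sum = NA_real_,
                      cluster_a = NA_integer_, cluster_b = NA_integer_,
                      same_cluster = NA, stringsAsFactors = FALSE)
    if (!(gp %in% rownames(pv))) {
      row$category <- "pike_unexpressed"
    } else if (!(ga %in% rownames(sv)) || !(gb %in% rownames(sv))) {
      row$category <- "silenced_copy"
    } else {
      t <- ortholog_triplet(sv[ga, ], sv[gb, ], pv[gp, ],
                            ids = c(ga, gb, gp))
      row <- tryCatch(classify_triplet(t, clusters, cfg),
                      error = function(e) { row$category <- "undefined"; row })
    }
    calls[[i]] <- row
  }
  out <- do.call(rbind, calls)
  attr(out, "clusters") <- clusters
  out
}

#' Accuracy of fate recovery against planted truth
#'
#' Maps each planted fate to the call that a correct classification should
#' produce (`conserved` to `both_conserved`, `on_off` to
#' `on_off_subfunctionalized`, `pseudogenized` to `silenced_copy`, the rest
#' to themselves) and returns the fraction of triplets whose call matches.
#'
#' @param calls Output of [classify_homeolog_fates()].
#' @param truth Truth table from [simulate_expression()].
#' @return List with `accuracy`, `n`, and the confusion table.
#' @export
fate_accuracy <- function(calls, truth) {
  expected_map <- c(conserved = "both_conserved",
                    neofunctionalized = "neofunctionalized",
                    subfunctionalized = "subfunctionalized",
                    on_off = "on_off_subfunctionalized",
                    pseudogenized = "silenced_copy")
  m <- merge(truth[, c("gene_a", "fate")],
             calls[, c("gene_a", "category")], by = "gene_a")
  expected <- expected_map[m$fate]
  list(accuracy = mean(m$category == expected), n = nrow(m),
       confusion = table(planted = m$fate, called = m$category))
}

#' Run configuration for the full pipeline
#'
#' @param sim A [sim_config()] controlling all synthetic inputs (including
#'   the seed recorded in every output header).
#' @param classifier A [classifier_config()].
#' @param stages Character subset of `c("expression", "retention",
#'   "blocks", "landscape")`.
#' @param n_rand Randomizations for the cluster-pair enrichment test.
#' @param out_dir Optional directory; when given, stage outputs are written
#'   as TSV with provenance headers.
#' @return A list of class `run_config`.
#' @export
run_config <- function(sim = sim_config(), classifier = classifier_config(),
                       stages = c("expression", "retention", "blocks",
                                  "landscape"),
                       n_rand = 1000, out_dir = NULL) {
  stages <- match.arg(stages, several.ok = TRUE)
  structure(list(sim = sim, classifier = classifier, stages = stages,
                 n_rand = n_rand, out_dir = out_dir),
            class = "run_config")
}

#' Run the full synthetic-data pipeline
#'
#' Executes the enabled stages in dependency order on freshly simulated
#' data: expression simulation, fate classification, pair divergence and
#' cluster-pair enrichment; gene-family simulation, duplication labeling,
#' era assignment and the conditional retention table with its
#' two-proportion test; windowed block-similarity track; and the TE
#' divergence landscape. Returns a per-stage summary report.
#'
#' @param cfg A [run_config()].
#' @return A list of class `wgdfate_report`.
#' @export
run_pipeline <- function(cfg = run_config()) {
  stopifnot(inherits(cfg, "run_config"))
  report <- list(seed = cfg$sim$seed, config_hash = hash_config(cfg),
                 stages = cfg$stages)
  out <- cfg$out_dir
  if (!is.null(out) && !dir.exists(out)) dir.create(out, recursive = TRUE)

  if ("expression" %in% cfg$stages) {
    sim <- simulate_expression(cfg$sim)
    calls <- classify_homeolog_fates(sim$salmon, sim$pike, sim$triplets,
                                     sim$tissue_map, cfg$classifier,
                                     expressed_threshold =
                                       cfg$sim$expressed_threshold)
    clusters <- attr(calls, "clusters")
    classified <- calls[calls$category %in% FATE_LEVELS, ]
    pairs <- classified[, c("gene_a", "gene_b")]
    div <- suppressWarnings(pair_divergence(clusters, pairs))
    enr <- suppressWarnings(
      cluster_pair_enrichment(clusters, pairs, n_rand = cfg$n_rand,
                              seed = cfg$sim$seed))
    acc <- fate_accuracy(calls, sim$truth)
    report$expression <- list(
      n_triplets = nrow(calls),
      category_counts = table(calls$category),
      fraction_diverged = attr(div, "fraction_diverged"),
      n_clusters = clusters$k,
      enrichment = enr[enr$p < 0.05, ],
      accuracy_vs_truth = acc$accuracy)
    if (!is.null(out)) {
      write_expression_sim(sim, file.path(out, "expression"))
      write_tsv(calls, file.path(out, "fate_calls.tsv"),
                provenance_header(cfg$sim))
    }
  }

  if ("retention" %in% cfg$stages) {
    fams <- simulate_gene_families(cfg$sim)
    stree <- species_tree()
    trees <- lapply(fams$newick, function(nw)
      assign_era(parse_gene_tree(text = nw), stree))
    tab <- retention_conditional_table(trees)
    zt <- two_proportion_z(tab$retained[2], tab$total[2],
                           tab$retained[3], tab$total[3])
    report$retention <- list(table = tab, two_proportion = zt,
                             excluded_lineages =
                               attr(tab, "excluded_lineages"))
    if (!is.null(out)) {
      write_family_sim(fams, file.path(out, "families"))
      write_tsv(tab, file.path(out, "retention_table.tsv"),
                provenance_header(cfg$sim))
    }
  }

  if ("blocks" %in% cfg$stages) {
    set.seed(cfg$sim$seed)
    hs <- simulate_hsp_table()
    track <- windowed_identity(hs$hsps)
    report$blocks <- list(n_windows = nrow(track),
                          category_counts = table(track$category))
    if (!is.null(out))
      write_tsv(track, file.path(out, "similarity_track.tsv"),
                provenance_header(cfg$sim))
  }

  if ("landscape" %in% cfg$stages) {
    set.seed(cfg$sim$seed)
    vals <- unlist(lapply(c(0.02, 0.07, 0.13), function(d) {
      fam <- simulate_te_family(n_copies = 30, length = 400, divergence = d)
      m <- pairwise_identity(fam)
      m[upper.tri(m)]
    }))
    hist <- identity_histogram(vals, width = 1)
    report$landscape <- list(histogram = hist[hist$count > 0, ],
                             modes = hist$lo[order(-hist$count)][1:3])
    if (!is.null(out))
      write_tsv(hist, file.path(out, "te_landscape.tsv"),
                provenance_header(cfg$sim))
  }
  class(report) <- "wgdfate_report"
  report
}

#' @export
print.wgdfate_report <- function(x, ...) {
  cat("wgdfate pipeline report (seed", x$seed, ", config", x$config_hash,
      ")\n")
  if (!is.null(x$expression)) {
    cat("\n== Expression fates ==\n")
    cat("triplets:", x$expression$n_triplets,
        " clusters:", x$expression$n_clusters, "\n")
    print(x$expression$category_counts)
    cat(sprintf("fraction of pairs in different clusters: %.3f\n",
                x$expression$fraction_diverged))
    cat(sprintf("accuracy vs planted truth: %.3f\n",
                x$expression$accuracy_vs_truth))
  }
  if (!is.null(x$retention)) {
    cat("\n== Duplicate retention ==\n")
    print(x$retention$table, row.names = FALSE)
    cat(sprintf("Ss4R|Ts3R-retained vs Ss4R|Ts3R-lost: z = %.3f, p = %.3g%s\n",
                x$retention$two_proportion$z, x$retention$two_proportion$p,
                if (x$retention$two_proportion$significant)
                  " (significant)" else " (not significant)"))
  }
  if (!is.null(x$blocks)) {
    cat("\n== Block similarity ==\n")
    print(x$blocks$category_counts)
  }
  if (!is.null(x$landscape)) {
    cat("\n== TE landscape ==\n")
    cat("modal similarity bins (%):",
        paste(x$landscape$modes, collapse = ", "), "\n")
  }
  invisible(x)
}
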