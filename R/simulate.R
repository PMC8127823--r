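# Synthetic-data generator with recorded ground truth.
#
# Emulates the study design of the salmonid WGD analyses: a 15-tissue
# duplicated-species expression atlas paired with a 13-tissue diploid
# outgroup atlas sharing 13 common tissues; ortholog triplets with planted
# regulatory fates; gene families with planted Ts3R/Ss4R/SSD duplications
# under Bernoulli retention; HSP tables with planted similarity regimes;
# and star-burst TE family alignments with planted divergence peaks.
# Everything is driven by a single integer seed so that outputs are
# byte-identical across runs.

PLANTED_FATES <- c("conserved", "neofunctionalized", "subfunctionalized",
                   "on_off", "pseudogenized")

# construction margins (clean, pre-noise profiles); see the methods vignette
SIM_R_NEO_MAX <- 0.30   # redrawn profile vs outgroup
SIM_R_DIV_MAX <- 0.50   # partitioned copy vs outgroup (margin below 0.55)
SIM_R_PAIR_MAX <- 0.40  # diverged copies vs each other, full profile
SIM_R_SUM_MAX <- 0.50   # on-off summed profile vs outgroup
SIM_MAX_TRIES <- 10000L

#' Simulation configuration
#'
#' Parameters of the synthetic study. Retention defaults follow the
#' observed retention of the two WGDs (20% Ts3R, 55% Ss4R); the tissue
#' design follows the 15-tissue salmon / 13-tissue pike atlases with 13
#' shared tissues; fate proportions echo the observed fate mix.
#'
#' @param n_families Number of gene families to simulate.
#' @param p_ret_ts3r Probability that the Ts3R duplicate pair is retained.
#' @param p_ret_ss4r Probability that a post-Ts3R lineage retains its Ss4R
#'   pair (independent across lineages).
#' @param ssd_rate Expected number of retained small-scale duplications per
#'   post-Ss4R salmon lineage (Poisson).
#' @param p_ssd_same_chrom Probability that an SSD copy lands on the same
#'   chromosome as its template (tandem duplication).
#' @param trout_loss Probability that a trout orthologue is lost from a
#'   lineage, creating Ss4R/SSD-ambiguous salmon-only nodes.
#' @param n_triplets Number of ortholog triplets for the expression
#'   simulation.
#' @param fate_proportions Named probabilities over the planted fates
#'   `conserved`, `neofunctionalized`, `subfunctionalized`, `on_off`,
#'   `pseudogenized`; must sum to 1.
#' @param noise_sd Standard deviation of the Gaussian measurement noise
#'   added to each salmon copy on the log2 scale.
#' @param n_common_tissues Number of tissues shared with the outgroup
#'   (>= 3 so that correlation p-values are defined).
#' @param n_extra_salmon_tissues Salmon-only tissues (clustered but not
#'   correlated against the outgroup).
#' @param expressed_threshold FPKM above which a gene counts as expressed
#'   ("on").
#' @param seed Integer seed; fixed seed reproduces all outputs
#'   byte-identically.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_families = 2000, p_ret_ts3r = 0.20,
                       p_ret_ss4r = 0.55, ssd_rate = 0.05,
                       p_ssd_same_chrom = 0.8, trout_loss = 0.15,
                       n_triplets = 1000,
                       fate_proportions = c(conserved = 0.42,
                                            neofunctionalized = 0.28,
                                            subfunctionalized = 0.05,
                                            on_off = 0.05,
                                            pseudogenized = 0.20),
                       noise_sd = 0.5, n_common_tissues = 13,
                       n_extra_salmon_tissues = 2,
                       expressed_threshold = 1.0, seed = 1L) {
  probs <- c(p_ret_ts3r, p_ret_ss4r, p_ssd_same_chrom, trout_loss)
  if (any(probs < 0 | probs > 1))
    stop_wgdfate("probabilities must lie in [0, 1]")
  if (ssd_rate < 0 || noise_sd < 0)
    stop_wgdfate("rates and noise_sd must be non-negative")
  if (is.null(names(fate_proportions)) ||
      !all(names(fate_proportions) %in% PLANTED_FATES))
    stop_wgdfate("fate_proportions must be named with: ",
                 paste(PLANTED_FATES, collapse = ", "))
  if (any(fate_proportions < 0) || abs(sum(fate_proportions) - 1) > 1e-9)
    stop_wgdfate("fate_proportions must be non-negative and sum to 1")
  if (n_common_tissues < 3)
    stop_wgdfate("n_common_tissues must be >= 3")
  structure(list(n_families = as.integer(n_families),
                 p_ret_ts3r = p_ret_ts3r, p_ret_ss4r = p_ret_ss4r,
                 ssd_rate = ssd_rate, p_ssd_same_chrom = p_ssd_same_chrom,
                 trout_loss = trout_loss, n_triplets = as.integer(n_triplets),
                 fate_proportions = fate_proportions, noise_sd = noise_sd,
                 n_common_tissues = as.integer(n_common_tissues),
                 n_extra_salmon_tissues = as.integer(n_extra_salmon_tissues),
                 expressed_threshold = expressed_threshold,
                 seed = as.integer(seed)),
            class = "sim_config")
}

COMMON_TISSUES <- c("liver", "gill", "brain", "heart", "muscle", "kidney",
                    "head_kidney", "spleen", "gut", "skin", "eye", "gonad",
                    "pyloric_caeca")
EXTRA_TISSUES <- c("olfactory_rosette", "fin")

sim_tissue_names <- function(cfg) {
  common <- if (cfg$n_common_tissues <= length(COMMON_TISSUES))
    COMMON_TISSUES[seq_len(cfg$n_common_tissues)]
  else c(COMMON_TISSUES,
         sprintf("tissue%02d",
                 seq_len(cfg$n_common_tissues - length(COMMON_TISSUES))))
  ne <- cfg$n_extra_salmon_tissues
  extra <- if (ne <= length(EXTRA_TISSUES)) EXTRA_TISSUES[seq_len(ne)]
           else c(EXTRA_TISSUES,
                  sprintf("extra%02d", seq_len(ne - length(EXTRA_TISSUES))))
  list(common = common, extra = extra)
}

# expression draws on the log2(FPKM+1) scale: Gaussian(4, 2) censored at 0
draw_log2 <- function(n) pmax(0, rnorm(n, mean = 4, sd = 2))
# draw conditioned to exceed `lo` (inverse-CDF, "on" tissue values)
draw_log2_on <- function(n, lo) {
  4 + 2 * stats::qnorm(runif(n, stats::pnorm((lo - 4) / 2), 1))
}
l2f <- function(v) pmax(0, 2^v - 1)  # log2(FPKM+1) -> FPKM

#' Simulate ortholog-triplet expression with planted fates
#'
#' Draws an outgroup (pike) expression profile per triplet and constructs
#' the two salmon homeologues according to a planted fate:
#' \itemize{
#'   \item `conserved`: both copies equal the outgroup profile (plus noise);
#'   \item `neofunctionalized`: one copy conserved, the other redrawn by
#'     rejection sampling until its correlation with the outgroup falls
#'     below 0.3;
#'   \item `subfunctionalized`: the outgroup's on-tissues are partitioned
#'     between the copies on the FPKM scale so that the copies' sum equals
#'     the outgroup profile exactly (each copy rejected until clearly
#'     diverged);
#'   \item `on_off`: the on-tissues are partitioned but magnitudes are
#'     redrawn so that the summed profile is no longer conserved;
#'   \item `pseudogenized`: one copy conserved, the other silenced (0 FPKM
#'     in all tissues, no noise — below the detection limit).
#' }
#' Gaussian noise with `noise_sd` is then added to each non-silenced copy on
#' the log2 scale. Salmon-only extra tissues receive independent draws
#' (shared between the copies of a conserved pair); they enter salmon
#' clustering but not the triplet correlations.
#'
#' @param config A [sim_config()].
#' @return List of class `expression_sim`: `salmon` and `pike`
#'   [expression_matrix] objects (raw FPKM), `triplets` (gene-id columns
#'   `gene_a`, `gene_b`, `gene_pike`), `truth` (planted fate per triplet),
#'   `tissue_map`, and the `config`.
#' @export
simulate_expression <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  nt <- config$n_triplets
  nc <- config$n_common_tissues
  ne <- config$n_extra_salmon_tissues
  thr <- config$expressed_threshold
  lo_on <- log2p1(thr)
  names_t <- sim_tissue_names(config)
  fates <- sample(names(config$fate_proportions), nt, replace = TRUE,
                  prob = config$fate_proportions)

  draw_pike <- function() {
    repeat {
      v <- draw_log2(nc)
      f <- l2f(v)
      if (max(f) > thr && sum(f > thr) >= 2) return(v)
    }
  }
  # Rejection sampler with an inner budget per outgroup profile; some
  # profiles (e.g. a single dominant tissue) admit no margin-satisfying
  # partition, in which case the caller redraws the outgroup profile.
  reject <- function(try_fun, inner = 200L) {
    for (i in seq_len(inner)) {
      out <- try_fun()
      if (!is.null(out)) return(out)
    }
    NULL
  }

  construct <- function(fate, pv, pf, on_p, ex_anc) {
    if (fate == "conserved") {
      return(list(a = c(pv, ex_anc), b = c(pv, ex_anc), silenced = FALSE))
    }
    if (fate == "pseudogenized") {
      return(list(a = c(pv, ex_anc), b = NULL, silenced = TRUE))
    }
    if (fate == "neofunctionalized") {
      a <- c(pv, ex_anc)
      b <- reject(function() {
        bv <- draw_log2(nc); bx <- draw_log2(ne)
        if (max(l2f(bv)) <= thr) return(NULL)
        if (cor(bv, pv) >= SIM_R_NEO_MAX) return(NULL)
        full <- c(bv, bx)
        if (cor(a, full) >= SIM_R_PAIR_MAX) return(NULL)
        full
      })
      if (is.null(b)) return(NULL)
      return(list(a = a, b = b, silenced = FALSE))
    }
    if (fate == "subfunctionalized") {
      ab <- reject(function() {
        maskA <- as.logical(rbinom(sum(on_p), 1, 0.5))
        if (!any(maskA) || all(maskA)) return(NULL)
        fa <- numeric(nc)
        fa[on_p][maskA] <- pf[on_p][maskA]
        fb <- pf - fa
        av <- log2p1(fa); bv <- log2p1(fb)
        if (cor(av, pv) >= SIM_R_DIV_MAX) return(NULL)
        if (cor(bv, pv) >= SIM_R_DIV_MAX) return(NULL)
        a <- c(av, draw_log2(ne)); b <- c(bv, draw_log2(ne))
        if (cor(a, b) >= SIM_R_PAIR_MAX) return(NULL)
        list(a = a, b = b, silenced = FALSE)
      })
      return(ab)
    }
    # on_off
    reject(function() {
      maskA <- as.logical(rbinom(sum(on_p), 1, 0.5))
      if (!any(maskA) || all(maskA)) return(NULL)
      av <- bv <- numeric(nc)
      av[on_p][maskA] <- draw_log2_on(sum(maskA), lo_on)
      bv[on_p][!maskA] <- draw_log2_on(sum(!maskA), lo_on)
      if (cor(av, pv) >= SIM_R_DIV_MAX) return(NULL)
      if (cor(bv, pv) >= SIM_R_DIV_MAX) return(NULL)
      if (cor(log2p1(l2f(av) + l2f(bv)), pv) >= SIM_R_SUM_MAX) return(NULL)
      a <- c(av, draw_log2(ne)); b <- c(bv, draw_log2(ne))
      if (cor(a, b) >= SIM_R_PAIR_MAX) return(NULL)
      list(a = a, b = b, silenced = FALSE)
    })
  }

  salmon <- matrix(0, nrow = 2 * nt, ncol = nc + ne)
  pike <- matrix(0, nrow = nt, ncol = nc)
  for (i in seq_len(nt)) {
    fate <- fates[i]
    built <- NULL
    for (outer in seq_len(SIM_MAX_TRIES)) {
      pv <- draw_pike()               # outgroup log2 profile, common tissues
      pf <- l2f(pv)
      built <- construct(fate, pv, pf, pf > thr, draw_log2(ne))
      if (!is.null(built)) break
    }
    if (is.null(built))
      stop_wgdfate("could not construct fate '", fate,
                   "' within the rejection budget")
    # which physical copy diverged/silenced is random
    swap <- fate %in% c("neofunctionalized", "pseudogenized") &&
      runif(1) < 0.5
    noisy <- function(v) {
      if (config$noise_sd > 0) v <- v + rnorm(length(v), 0, config$noise_sd)
      l2f(v)
    }
    fa <- noisy(built$a)
    fb <- if (built$silenced) numeric(nc + ne) else noisy(built$b)
    if (swap) { tmp <- fa; fa <- fb; fb <- tmp }
    salmon[2 * i - 1, ] <- fa
    salmon[2 * i, ] <- fb
    pike[i, ] <- pf
  }
  ids_a <- sprintf("ss%04d_a", seq_len(nt))
  ids_b <- sprintf("ss%04d_b", seq_len(nt))
  ids_p <- sprintf("pk%04d", seq_len(nt))
  rownames(salmon) <- as.vector(rbind(ids_a, ids_b))
  colnames(salmon) <- c(names_t$common, names_t$extra)
  rownames(pike) <- ids_p
  colnames(pike) <- names_t$common
  structure(list(
    salmon = expression_matrix(salmon, species = "salmo", scale = "fpkm"),
    pike = expression_matrix(pike, species = "esox", scale = "fpkm"),
    triplets = data.frame(gene_a = ids_a, gene_b = ids_b, gene_pike = ids_p,
                          stringsAsFactors = FALSE),
    truth = data.frame(triplet = seq_len(nt), gene_a = ids_a, gene_b = ids_b,
                       gene_pike = ids_p, fate = fates,
                       stringsAsFactors = FALSE),
    tissue_map = tissue_map(names_t$common, names_t$common),
    config = config), class = "expression_sim")
}

SALMON_CHROMS <- sprintf("ssa%02d", 1:29)

#' Simulate gene families with planted duplication history
#'
#' Each family follows the species tree (zebrafish, pike, trout, salmon)
#' through the event hierarchy of the two WGDs: the family retains a Ts3R
#' duplicate pair with probability `p_ret_ts3r` (giving two parallel
#' post-Ts3R lineages), each surviving lineage independently retains its
#' Ss4R pair with probability `p_ret_ss4r` (the two salmon copies are
#' placed on different chromosomes), and each post-Ss4R salmon lineage
#' accumulates a Poisson(`ssd_rate`) number of small-scale duplicates, each
#' on the same chromosome as its template with probability
#' `p_ssd_same_chrom`. Trout orthologues are dropped with probability
#' `trout_loss`, which turns fully resolved Ss4R nodes into salmon-only
#' nodes and exercises the chromosome disambiguation rule.
#'
#' @param config A [sim_config()].
#' @return List of class `family_sim`: `newick` (one rooted tree per
#'   family), `chrom_map` (gene, chromosome), `truth_families`,
#'   `truth_lineages` (per post-Ts3R lineage: planted Ss4R retention and
#'   SSD counts), and the `config`.
#' @export
simulate_gene_families <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  nf <- config$n_families
  newick <- character(nf)
  fam_rows <- vector("list", nf)
  lin_rows <- list()
  genes <- list()

  for (f in seq_len(nf)) {
    fam <- sprintf("fam%04d", f)
    counter <- new.env()
    counter$i <- 0L
    leaf <- function(species, chrom) {
      counter$i <- counter$i + 1L
      gene <- sprintf("%s_g%d", fam, counter$i)
      genes[[length(genes) + 1L]] <<- data.frame(gene = gene,
                                                 chromosome = chrom,
                                                 species = species,
                                                 stringsAsFactors = FALSE)
      sprintf("%s|%s|%s", species, gene, chrom)
    }
    salmon_clade <- function(chrom) {
      # caterpillar of 1 + Poisson(ssd_rate) salmon copies
      n_ssd <- rpois(1, config$ssd_rate)
      clade <- leaf("salmo", chrom)
      for (s in seq_len(n_ssd)) {
        ch <- if (runif(1) < config$p_ssd_same_chrom) chrom
              else sample(setdiff(SALMON_CHROMS, chrom), 1)
        clade <- sprintf("(%s,%s)", clade, leaf("salmo", ch))
      }
      list(clade = clade, n_ssd = n_ssd)
    }
    lineage <- function(lin_id, ts3r_retained) {
      ss4r <- runif(1) < config$p_ret_ss4r
      if (ss4r) {
        chr <- sample(SALMON_CHROMS, 2)
        sub <- lapply(chr, salmon_clade)
        pairs <- vapply(1:2, function(j) {
          if (runif(1) < config$trout_loss) sub[[j]]$clade
          else sprintf("(%s,%s)", sub[[j]]$clade,
                       leaf("oncorhynchus", sample(sprintf("omy%02d", 1:29), 1)))
        }, character(1))
        salmonid <- sprintf("(%s,%s)", pairs[1], pairs[2])
        n_ssd <- sum(vapply(sub, `[[`, 0, "n_ssd"))
      } else {
        sub <- salmon_clade(sample(SALMON_CHROMS, 1))
        salmonid <- if (runif(1) < config$trout_loss) sub$clade
                    else sprintf("(%s,%s)", sub$clade,
                                 leaf("oncorhynchus",
                                      sample(sprintf("omy%02d", 1:29), 1)))
        n_ssd <- sub$n_ssd
      }
      lin_rows[[length(lin_rows) + 1L]] <<-
        data.frame(family = fam, lineage = lin_id,
                   ts3r_retained = ts3r_retained, ss4r_retained = ss4r,
                   n_ssd = n_ssd, stringsAsFactors = FALSE)
      sprintf("(%s,(%s,%s))", leaf("danio", "dre01"), leaf("esox", "elu01"),
              salmonid)
    }
    ts3r <- runif(1) < config$p_ret_ts3r
    newick[f] <- if (ts3r) {
      sprintf("(%s,%s);", lineage(1L, TRUE), lineage(2L, TRUE))
    } else {
      sprintf("%s;", lineage(1L, FALSE))
    }
    fam_rows[[f]] <- data.frame(family = fam, ts3r_retained = ts3r,
                                stringsAsFactors = FALSE)
  }
  gene_df <- do.call(rbind, genes)
  structure(list(newick = newick,
                 chrom_map = gene_df[, c("gene", "chromosome")],
                 truth_families = do.call(rbind, fam_rows),
                 truth_lineages = do.call(rbind, lin_rows),
                 config = config), class = "family_sim")
}

#' Simulate a star-burst TE family alignment
#'
#' Generates an ancestral element and `n_copies` descendants, each mutated
#' independently so that the expected pairwise dissimilarity between copies
#' equals `divergence` (a star phylogeny, the topology characteristic of a
#' transposition burst). Pairwise percent similarity of family members is
#' the usual proxy for element age.
#'
#' @param n_copies Number of copies in the family.
#' @param length Element length in bp.
#' @param divergence Target expected pairwise dissimilarity (0-1); e.g.
#'   0.02, 0.07 and 0.13 plant similarity peaks at 98%, 93% and 87%.
#' @param seed Optional integer seed.
#' @return Named character vector of aligned sequences.
#' @export
simulate_te_family <- function(n_copies = 30, length = 400,
                               divergence = 0.13, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (divergence < 0 || divergence >= 0.75)
    stop_wgdfate("divergence must lie in [0, 0.75)")
  bases <- c("A", "C", "G", "T")
  anc <- sample(bases, length, replace = TRUE)
  # per-copy mutation rate p with pairwise mismatch 2p - (4/3)p^2 = divergence
  p <- (2 - sqrt(4 - (16 / 3) * divergence)) / (8 / 3)
  seqs <- vapply(seq_len(n_copies), function(i) {
    s <- anc
    hit <- runif(length) < p
    if (any(hit)) {
      s[hit] <- vapply(s[hit], function(b) sample(setdiff(bases, b), 1), "")
    }
    paste(s, collapse = "")
  }, character(1))
  names(seqs) <- sprintf("copy%03d", seq_len(n_copies))
  seqs
}

#' Simulate an HSP table with planted similarity regimes
#'
#' Tiles a chromosome with contiguous regions, assigns each region one of
#' the similarity regimes of the duplicated-block analysis (high ~97.5%,
#' elevated ~92.5%, low ~87%), and emits HSPs covering most of each region
#' with identities jittered around the regime mean.
#'
#' @param chrom Chromosome name (A side).
#' @param chrom_length Chromosome length in bp.
#' @param region_means Regime mean identities.
#' @param region_probs Regime probabilities.
#' @param seed Optional integer seed.
#' @return List with the [hsp_table()] `hsps` and `truth` (per-region
#'   regime).
#' @export
simulate_hsp_table <- function(chrom = "ssa01", chrom_length = 2e7,
                               region_means = c(high = 97.5,
                                                elevated = 92.5, low = 87),
                               region_probs = c(0.25, 0.35, 0.40),
                               seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  pos <- 0
  rows <- list(); regions <- list()
  while (pos < chrom_length) {
    rlen <- min(round(runif(1, 2e6, 6e6)), chrom_length - pos)
    regime <- sample(names(region_means), 1, prob = region_probs)
    regions[[length(regions) + 1L]] <-
      data.frame(start = pos, end = pos + rlen, regime = regime,
                 stringsAsFactors = FALSE)
    at <- pos
    while (at < pos + rlen) {
      hlen <- min(round(runif(1, 5e4, 4e5)), pos + rlen - at)
      ident <- min(100, max(0, rnorm(1, region_means[[regime]], 0.8)))
      rows[[length(rows) + 1L]] <-
        data.frame(chrom_a = chrom, start_a = at, end_a = at + hlen,
                   chrom_b = "ssa_partner", start_b = at, end_b = at + hlen,
                   identity = ident, stringsAsFactors = FALSE)
      at <- at + hlen + round(runif(1, 0, 5e4))   # small uncovered gaps
    }
    pos <- pos + rlen
  }
  hsps <- do.call(rbind, rows)
  list(hsps = hsp_table(hsps$chrom_a, hsps$start_a, hsps$end_a,
                        hsps$chrom_b, hsps$start_b, hsps$end_b,
                        hsps$identity),
       truth = do.call(rbind, regions))
}

#' Write a simulated expression bundle to TSV files
#'
#' Writes salmon.tsv, pike.tsv, triplets.tsv, truth.tsv and tissue_map.tsv
#' into a directory, each with a provenance header (package version, seed,
#' configuration hash). Fixed seed gives byte-identical files.
#'
#' @param sim An `expression_sim` from [simulate_expression()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_expression_sim <- function(sim, dir) {
  stopifnot(inherits(sim, "expression_sim"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  hdr <- provenance_header(sim$config)
  write_expression_table(sim$salmon, file.path(dir, "salmon.tsv"), hdr)
  write_expression_table(sim$pike, file.path(dir, "pike.tsv"), hdr)
  write_tsv(sim$triplets, file.path(dir, "triplets.tsv"), hdr)
  write_tsv(sim$truth, file.path(dir, "truth.tsv"), hdr)
  write_tsv(sim$tissue_map, file.path(dir, "tissue_map.tsv"), hdr)
  invisible(dir)
}

#' Write a simulated gene-family bundle
#'
#' Writes trees.nwk (one Newick per line), chrom_map.tsv and the truth
#' tables into a directory, with provenance headers on the TSV files.
#'
#' @param sim A `family_sim` from [simulate_gene_families()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_family_sim <- function(sim, dir) {
  stopifnot(inherits(sim, "family_sim"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  hdr <- provenance_header(sim$config)
  writeLines(sim$newick, file.path(dir, "trees.nwk"))
  write_tsv(sim$chrom_map, file.path(dir, "chrom_map.tsv"), hdr)
  write_tsv(sim$truth_families, file.path(dir, "truth_families.tsv"), hdr)
  write_tsv(sim$truth_lineages, file.path(dir, "truth_lineages.tsv"), hdr)
  invisible(dir)
}

provenance_header <- function(config) {
  c(sprintf("wgdfate %s",
            as.character(utils::packageVersion("wgdfate"))),
    sprintf("seed=%d config=%s", config$seed, hash_config(config)))
}

write_tsv <- function(df, path, header = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
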