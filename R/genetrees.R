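# Gene-tree machinery: parsing, duplication/speciation labeling and
# assignment of duplication nodes to eras (Ts3R, Ss4R, small-scale
# duplications before or after the Ss4R).
#
# Trees are handled as ape "phylo" objects. Leaves follow the convention
# "species|gene|chromosome". Duplication nodes are identified by the
# species-overlap criterion (a node is a duplication when the species sets
# of its two child subtrees intersect), a deterministic stand-in for
# reconciliation-based labeling that is cross-checked here against an
# exhaustive LCA-mapping implementation.

#' Species tree with WGD markers
#'
#' A rooted species tree whose root carries the teleost WGD (Ts3R) and whose
#' salmonid crown (the most recent common ancestor of the focal duplicated
#' species and its salmonid sister) marks the salmonid WGD (Ss4R): a gene
#' duplication mapping onto that crown predates the focal-sister split but
#' postdates the split from the diploid outgroup, which is the Ss4R
#' signature.
#'
#' @param text Newick of the species tree (default: zebrafish, pike, trout,
#'   salmon).
#' @param focal The duplicated focal species whose chromosomes drive the
#'   ambiguity rule (default `"salmo"`).
#' @param sister The salmonid sister lineage (default `"oncorhynchus"`).
#' @return An object of class `species_tree`.
#' @export
species_tree <- function(text = "(danio,(esox,(oncorhynchus,salmo)));",
                         focal = "salmo", sister = "oncorhynchus") {
  phy <- ape::read.tree(text = text)
  if (is.null(phy)) stop_wgdfate("invalid species-tree Newick")
  if (!all(c(focal, sister) %in% phy$tip.label))
    stop_wgdfate("focal/sister species absent from the species tree")
  ntip <- length(phy$tip.label)
  root <- ntip + 1L
  crown <- ape::getMRCA(phy, c(focal, sister))
  # internal nodes strictly between the root and the salmonid crown
  between <- integer(0)
  node <- crown
  repeat {
    parent <- phy$edge[phy$edge[, 2] == node, 1]
    if (length(parent) == 0 || parent == root) break
    between <- c(between, parent)
    node <- parent
  }
  structure(list(phylo = phy, focal = focal, sister = sister,
                 root = root, crown = crown, between = between),
            class = "species_tree")
}

#' Parse a gene tree with annotated leaves
#'
#' Reads a rooted gene tree whose leaf labels follow the convention
#' `species|gene|chromosome`. A multifurcating root is resolved
#' deterministically (first two children grouped, via
#' `ape::multi2di(random = FALSE)`) and flagged in the `resolved` field.
#'
#' @param text Newick string (used when `file` is `NULL`).
#' @param file Optional path to a file containing one Newick tree.
#' @param species Optional character vector of known species; a leaf whose
#'   species is not listed is an error naming the leaf.
#' @return An object of class `gene_tree` with fields `phylo` and `leaves`
#'   (data frame: label, species, gene, chromosome).
#' @export
parse_gene_tree <- function(text = NULL, file = NULL, species = NULL) {
  phy <- if (!is.null(file)) ape::read.tree(file = file)
         else tryCatch(ape::read.tree(text = text), error = function(e) NULL)
  if (is.null(phy) || inherits(phy, "multiPhylo") && length(phy) != 1)
    stop_wgdfate("could not parse Newick gene tree")
  if (inherits(phy, "multiPhylo")) phy <- phy[[1]]
  as_gene_tree(phy, species = species)
}

as_gene_tree <- function(phy, species = NULL) {
  resolved <- FALSE
  if (!ape::is.binary(phy)) {
    phy <- ape::multi2di(phy, random = FALSE)
    resolved <- TRUE
  }
  parts <- strsplit(phy$tip.label, "|", fixed = TRUE)
  if (any(lengths(parts) != 3))
    stop_wgdfate("leaf label(s) not of the form species|gene|chromosome: ",
                 paste(phy$tip.label[lengths(parts) != 3], collapse = ", "))
  leaves <- data.frame(label = phy$tip.label,
                       species = vapply(parts, `[`, "", 1),
                       gene = vapply(parts, `[`, "", 2),
                       chromosome = vapply(parts, `[`, "", 3),
                       stringsAsFactors = FALSE)
  if (!is.null(species)) {
    bad <- !(leaves$species %in% species)
    if (any(bad))
      stop_wgdfate("unknown species in leaf ",
                   paste(leaves$label[bad], collapse = ", "))
  }
  structure(list(phylo = phy, leaves = leaves, resolved = resolved,
                 events = NULL, eras = NULL),
            class = "gene_tree")
}

#' @export
print.gene_tree <- function(x, ...) {
  cat(sprintf("<gene_tree> %d leaves, %d internal nodes%s%s\n",
              nrow(x$leaves), x$phylo$Nnode,
              if (!is.null(x$events)) ", events labeled" else "",
              if (!is.null(x$eras)) ", eras assigned" else ""))
  invisible(x)
}

# children of every internal node (list indexed by node id)
node_children <- function(phy) {
  split(phy$edge[, 2], factor(phy$edge[, 1],
                              levels = seq_len(length(phy$tip.label) + phy$Nnode)))
}

# per-node species sets (and focal-leaf chromosome sets), postorder
node_sets <- function(g, what = c("species", "chromosome"), focal = NULL) {
  what <- match.arg(what)
  phy <- g$phylo
  ntip <- length(phy$tip.label)
  sets <- vector("list", ntip + phy$Nnode)
  for (i in seq_len(ntip)) {
    if (what == "species") sets[[i]] <- g$leaves$species[i]
    else sets[[i]] <- if (g$leaves$species[i] == focal)
      g$leaves$chromosome[i] else character(0)
  }
  po <- ape::reorder.phylo(phy, "postorder")$edge
  for (r in seq_len(nrow(po))) {
    p <- po[r, 1]; ch <- po[r, 2]
    sets[[p]] <- union(sets[[p]] %||% character(0), sets[[ch]])
  }
  sets
}

#' Label duplication and speciation nodes by species overlap
#'
#' An internal node is a duplication when the species sets of its two child
#' subtrees share at least one species, and a speciation otherwise.
#'
#' @param g A `gene_tree`.
#' @return The tree with an `events` character vector (indexed by internal
#'   node, values `"duplication"`/`"speciation"`).
#' @export
label_duplication_nodes <- function(g) {
  stopifnot(inherits(g, "gene_tree"))
  phy <- g$phylo
  ntip <- length(phy$tip.label)
  sets <- node_sets(g, "species")
  kids <- node_children(phy)
  events <- character(phy$Nnode)
  for (v in seq_len(phy$Nnode)) {
    ch <- kids[[ntip + v]]
    overlap <- length(intersect(sets[[ch[1]]], sets[[ch[2]]])) > 0
    events[v] <- if (overlap) "duplication" else "speciation"
  }
  g$events <- events
  g
}

#' Label duplication nodes by LCA-mapping reconciliation
#'
#' Independent reconciliation-based criterion used to cross-validate
#' [label_duplication_nodes()]: every gene-tree node is mapped to the most
#' recent common ancestor (in the species tree) of the species under it, and
#' a node is a duplication exactly when it maps to the same species-tree
#' node as one of its children.
#'
#' @param g A `gene_tree`.
#' @param stree A [species_tree()].
#' @return Character vector of events indexed by internal node.
#' @export
label_duplications_lca <- function(g, stree) {
  stopifnot(inherits(g, "gene_tree"), inherits(stree, "species_tree"))
  phy <- g$phylo
  ntip <- length(phy$tip.label)
  sets <- node_sets(g, "species")
  bad <- setdiff(unique(unlist(sets)), stree$phylo$tip.label)
  if (length(bad))
    stop_wgdfate("species not in species tree: ", paste(bad, collapse = ", "))
  smap <- function(spp) {
    tips <- match(spp, stree$phylo$tip.label)
    if (length(tips) == 1) tips else ape::getMRCA(stree$phylo, tips)
  }
  m <- vapply(sets, smap, integer(1))
  kids <- node_children(phy)
  vapply(seq_len(phy$Nnode), function(v) {
    ch <- kids[[ntip + v]]
    if (m[ntip + v] %in% m[ch]) "duplication" else "speciation"
  }, character(1))
}

#' Label duplication nodes by exhaustive same-species leaf-pair LCAs
#'
#' Brute-force implementation of the species-overlap criterion used to
#' cross-validate [label_duplication_nodes()]: a node is a duplication
#' exactly when it is the gene-tree most recent common ancestor of at least
#' one pair of leaves from the same species (equivalently, when some
#' species occurs on both sides of the node). Enumerates every same-species
#' leaf pair and maps it to its LCA, without any recursive set
#' computation.
#'
#' Note that this is a different quantity from reconciliation against a
#' species tree ([label_duplications_lca()]): every species-overlap
#' duplication is also a reconciliation duplication, but a gene-tree
#' topology that conflicts with the species tree can force additional
#' reconciliation duplications with no species overlap.
#'
#' @param g A `gene_tree`.
#' @return Character vector of events indexed by internal node.
#' @export
label_duplications_pairwise <- function(g) {
  stopifnot(inherits(g, "gene_tree"))
  phy <- g$phylo
  ntip <- length(phy$tip.label)
  dup_nodes <- integer(0)
  for (sp in unique(g$leaves$species)) {
    tips <- which(g$leaves$species == sp)
    if (length(tips) < 2) next
    pairs <- utils::combn(tips, 2)
    for (q in seq_len(ncol(pairs))) {
      dup_nodes <- c(dup_nodes, ape::getMRCA(phy, pairs[, q]))
    }
  }
  events <- rep("speciation", phy$Nnode)
  events[unique(dup_nodes) - ntip] <- "duplication"
  events
}

#' Assign duplication eras in a gene tree
#'
#' Maps every duplication node onto the species tree through the most recent
#' common ancestor of its descendant species and assigns an era:
#' \itemize{
#'   \item teleost root: `Ts3R`;
#'   \item between the root and the salmonid crown: `preSs4R_SSD`;
#'   \item salmonid crown (both salmonid lineages present): `Ss4R`;
#'   \item focal-species-only duplications are ambiguous between Ss4R (with
#'     both outgroup and sister orthologues lost) and a post-Ss4R
#'     small-scale duplication, and are resolved by chromosome: each child
#'     subtree is represented by the chromosome of its focal leaves; same
#'     chromosome on both sides means `postSs4R_SSD`, different chromosomes
#'     mean `Ss4R`, and a subtree whose focal leaves span several
#'     chromosomes leaves the node `ambiguous` (excluded from retention
#'     counts);
#'   \item other duplications (confined to a non-focal species): era
#'     `none`.
#' }
#' Because only a single Ss4R duplication can occur along any lineage, when
#' several Ss4R-classified nodes lie on one root-to-leaf path only the
#' oldest (closest to the root) keeps `Ss4R`; the rest become
#' `postSs4R_SSD`.
#'
#' @param g A `gene_tree` (events are computed if missing).
#' @param stree A [species_tree()].
#' @return The tree with an `eras` vector indexed by internal node, plus
#'   `focal`/`salmonids` metadata used by [retention_conditional_table()].
#' @export
assign_era <- function(g, stree) {
  stopifnot(inherits(g, "gene_tree"), inherits(stree, "species_tree"))
  if (is.null(g$events)) g <- label_duplication_nodes(g)
  phy <- g$phylo
  ntip <- length(phy$tip.label)
  sets <- node_sets(g, "species")
  chroms <- node_sets(g, "chromosome", focal = stree$focal)
  kids <- node_children(phy)
  smap_cache <- function(spp) {
    tips <- match(spp, stree$phylo$tip.label)
    if (anyNA(tips))
      stop_wgdfate("species not in species tree: ",
                   paste(spp[is.na(tips)], collapse = ", "))
    if (length(tips) == 1) tips else ape::getMRCA(stree$phylo, tips)
  }
  focal_tip <- match(stree$focal, stree$phylo$tip.label)
  eras <- rep("none", phy$Nnode)
  for (v in seq_len(phy$Nnode)) {
    if (g$events[v] != "duplication") next
    node <- ntip + v
    m <- smap_cache(sets[[node]])
    if (m == stree$root) {
      eras[v] <- "Ts3R"
    } else if (m == stree$crown) {
      eras[v] <- "Ss4R"
    } else if (m %in% stree$between) {
      eras[v] <- "preSs4R_SSD"
    } else if (m == focal_tip) {
      ch <- kids[[node]]
      ca <- chroms[[ch[1]]]; cb <- chroms[[ch[2]]]
      if (length(ca) > 1 || length(cb) > 1) {
        eras[v] <- "ambiguous"
      } else {
        eras[v] <- if (identical(ca, cb)) "postSs4R_SSD" else "Ss4R"
      }
    } # else: duplication confined to a non-focal lineage -> era "none"
  }
  # single-Ss4R-per-lineage rule: preorder walk demoting younger candidates
  demote <- function(node, seen_ss4r) {
    if (node <= ntip) return(invisible(NULL))
    v <- node - ntip
    if (eras[v] == "Ss4R") {
      if (seen_ss4r) eras[v] <<- "postSs4R_SSD"
      seen_ss4r <- TRUE
    }
    for (ch in kids[[node]]) demote(ch, seen_ss4r)
  }
  demote(ntip + 1L, FALSE)
  g$eras <- eras
  g$focal <- stree$focal
  g$salmonids <- c(stree$focal, stree$sister)
  g
}

#' Enumerate all rooted binary tree topologies over a leaf set
#'
#' Builds every rooted, binary, leaf-labelled topology by stepwise leaf
#' insertion (1, 3, 15, 105, ... trees for 2, 3, 4, 5 leaves).
#'
#' @param labels Character vector of leaf labels.
#' @return Character vector of Newick strings (with trailing `;`).
#' @export
all_rooted_topologies <- function(labels) {
  if (length(labels) < 2) stop_wgdfate("need at least 2 labels")
  insert_all <- function(tree, leaf) {
    # tree is a nested list (length-2) or a leaf label
    out <- list(list(tree, leaf))  # join above the current (sub)root
    if (is.list(tree)) {
      for (side in 1:2) {
        for (sub in insert_all(tree[[side]], leaf)) {
          t2 <- tree
          t2[[side]] <- sub
          out <- c(out, list(t2))
        }
      }
    }
    out
  }
  trees <- list(labels[[1]])
  for (leaf in labels[-1]) {
    trees <- unlist(lapply(trees, insert_all, leaf = leaf), recursive = FALSE)
  }
  to_newick <- function(t) {
    if (!is.list(t)) return(t)
    paste0("(", to_newick(t[[1]]), ",", to_newick(t[[2]]), ")")
  }
  vapply(trees, function(t) paste0(to_newick(t), ";"), character(1))
}
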