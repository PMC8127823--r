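# Shared builders for small in-code fixtures.

mk_expr <- function(values, species = "salmo", scale = "fpkm",
                    genes = NULL, tissues = NULL) {
  values <- as.matrix(values)
  rownames(values) <- genes %||% sprintf("g%02d", seq_len(nrow(values)))
  colnames(values) <- tissues %||% sprintf("t%02d", seq_len(ncol(values)))
  expression_matrix(values, species = species, scale = scale)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

mk_clusters <- function(labels, k = max(labels)) {
  wgdfate:::cluster_assignment(labels, k)
}

# five-leaf label set over the four study species (two salmon copies)
five_leaf_labels <- function(chrom2 = "ssa02") {
  c("salmo|g1|ssa01", paste0("salmo|g2|", chrom2), "oncorhynchus|g3|omy01",
    "esox|g4|elu01", "danio|g5|dre01")
}
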