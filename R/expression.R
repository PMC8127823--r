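# Expression matrices: construction, I/O, filtering and transformation.
#
# All downstream fate analyses operate on log2(FPKM+1) values; the raw-FPKM
# scale is kept explicit so that sums of homeologue expression (which are only
# meaningful on the FPKM scale) can be formed before log transformation.

#' Construct an expression matrix
#'
#' A genes-by-tissues matrix of non-negative expression values (FPKM), with a
#' species tag and an explicit scale flag distinguishing raw FPKM from
#' log2(FPKM+1) values.
#'
#' @param values Numeric matrix, genes in rows (unique rownames) and tissues
#'   in columns (unique colnames). All values must be finite and
#'   non-negative.
#' @param species Species tag, e.g. `"salmo"` or `"esox"`.
#' @param scale Either `"fpkm"` (raw) or `"log2"` (log2(FPKM+1)).
#' @return An object of class `expression_matrix`.
#' @export
expression_matrix <- function(values, species = "unknown",
                              scale = c("fpkm", "log2")) {
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values))
    stop_wgdfate("'values' must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop_wgdfate("'values' must have gene rownames and tissue colnames")
  if (anyDuplicated(rownames(values)))
    stop_wgdfate("duplicated gene ids: ",
                 paste(unique(rownames(values)[duplicated(rownames(values))]),
                       collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stop_wgdfate("duplicated tissue names")
  if (any(!is.finite(values)))
    stop_wgdfate("non-finite expression values")
  if (any(values < 0))
    stop_wgdfate("negative expression values are not allowed")
  structure(list(values = values, species = species, scale = scale),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("<expression_matrix> %s: %d genes x %d tissues [%s scale]\n",
              x$species, nrow(x$values), ncol(x$values), x$scale))
  invisible(x)
}

#' @export
dim.expression_matrix <- function(x) dim(x$values)

genes <- function(m) rownames(m$values)
tissues <- function(m) colnames(m$values)

#' Read an expression table from TSV
#'
#' Expects a header row of tissue names and one gene per row, with the gene
#' identifier in the first column. Values are parsed as raw FPKM.
#'
#' @param path Path to a tab-separated file.
#' @param species Species tag recorded on the returned matrix.
#' @return An [expression_matrix] on the raw-FPKM scale.
#' @export
read_expression_table <- function(path, species = "unknown") {
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   colClasses = "character", comment.char = "#")
  if (ncol(df) < 2) stop_wgdfate("expected a gene-id column plus tissues")
  ids <- df[[1]]
  if (anyDuplicated(ids))
    stop_wgdfate("duplicated gene id in ", path, ": ",
                 paste(unique(ids[duplicated(ids)]), collapse = ", "))
  vals <- suppressWarnings(
    vapply(df[-1], function(col) as.numeric(col), numeric(nrow(df))))
  if (nrow(df) == 1L) vals <- matrix(vals, nrow = 1,
                                     dimnames = list(NULL, names(df)[-1]))
  if (any(is.na(vals)))
    stop_wgdfate("malformed numeric cell(s) in ", path)
  if (any(vals < 0))
    stop_wgdfate("negative FPKM value(s) in ", path)
  rownames(vals) <- ids
  expression_matrix(vals, species = species, scale = "fpkm")
}

#' Write an expression table to TSV
#'
#' @param m An [expression_matrix].
#' @param path Output path.
#' @param header Optional character vector of comment lines (written with a
#'   leading `#`), used for provenance.
#' @return `path`, invisibly.
#' @export
write_expression_table <- function(m, path, header = NULL) {
  stopifnot(inherits(m, "expression_matrix"))
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  writeLines(paste(c("gene", tissues(m)), collapse = "\t"), con)
  apply_fmt <- function(v) formatC(v, format = "g", digits = 15)
  body <- vapply(seq_len(nrow(m$values)), function(i) {
    paste(c(genes(m)[i], apply_fmt(m$values[i, ])), collapse = "\t")
  }, character(1))
  writeLines(body, con)
  invisible(path)
}

#' Keep genes expressed above an FPKM threshold
#'
#' A gene is classified as expressed when the FPKM value of at least one
#' tissue is strictly above the threshold (default 1.0).
#'
#' @param m An [expression_matrix] on the raw-FPKM scale.
#' @param threshold FPKM threshold; strict inequality.
#' @return The matrix restricted to expressed genes.
#' @export
filter_expressed <- function(m, threshold = 1.0) {
  stopifnot(inherits(m, "expression_matrix"))
  if (m$scale != "fpkm")
    stop_wgdfate("filter_expressed() requires raw-FPKM scale, got log2")
  keep <- apply(m$values, 1L, max) > threshold
  m$values <- m$values[keep, , drop = FALSE]
  m
}

#' Transform an expression matrix to log2(FPKM+1)
#'
#' @param m An [expression_matrix] on the raw-FPKM scale.
#' @return The matrix with each value x replaced by log2(x+1) and the scale
#'   flag set to `"log2"`. Applying the transform twice is an error.
#' @export
log2_transform <- function(m) {
  stopifnot(inherits(m, "expression_matrix"))
  if (m$scale == "log2")
    stop_wgdfate("matrix is already on the log2(FPKM+1) scale")
  m$values <- log2p1(m$values)
  m$scale <- "log2"
  m
}

#' Construct a tissue map between two species
#'
#' Ordered pairs of (duplicated-species tissue, outgroup tissue) names for the
#' tissues shared by both expression designs.
#'
#' @param salmon Character vector of tissue names in the duplicated species.
#' @param pike Character vector of matching tissue names in the outgroup.
#' @return A data frame with columns `salmon` and `pike`.
#' @export
tissue_map <- function(salmon, pike) {
  if (length(salmon) != length(pike))
    stop_wgdfate("tissue map sides differ in length")
  if (anyDuplicated(salmon) || anyDuplicated(pike))
    stop_wgdfate("tissue map must be injective in both directions")
  data.frame(salmon = as.character(salmon), pike = as.character(pike),
             stringsAsFactors = FALSE)
}

#' Restrict two expression matrices to their common tissues
#'
#' Both matrices are column-restricted and column-ordered according to the
#' tissue map, so that column i of one output is directly comparable to
#' column i of the other. Tissues private to either species are dropped from
#' this paired view only.
#'
#' @param salmon,pike [expression_matrix] objects.
#' @param map A [tissue_map] data frame.
#' @return A list with elements `salmon` and `pike`.
#' @export
align_common_tissues <- function(salmon, pike, map) {
  stopifnot(inherits(salmon, "expression_matrix"),
            inherits(pike, "expression_matrix"))
  miss_s <- setdiff(map$salmon, tissues(salmon))
  miss_p <- setdiff(map$pike, tissues(pike))
  if (length(miss_s) || length(miss_p))
    stop_wgdfate("unmapped tissue name(s): ",
                 paste(c(miss_s, miss_p), collapse = ", "))
  salmon$values <- salmon$values[, map$salmon, drop = FALSE]
  pike$values <- pike$values[, map$pike, drop = FALSE]
  list(salmon = salmon, pike = pike)
}
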