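# Homeologue-block similarity tracks and transposable-element divergence
# landscapes.
#
# Sequence similarity between duplicated regions is summarized in fixed
# windows (1 Mb in the salmon genome analysis) by length-weighted averaging
# of local alignment (HSP) identities, then categorized: >95% "high"
# (recent rediploidization / possible residual tetrasomy), 90-95%
# "elevated" (delayed rediploidization), and lower values (~87%) "low".
# TE-family landscapes are histograms of pairwise percent identity between
# family members, a proxy for element age.

#' Construct/validate an HSP table
#'
#' High-scoring segment pairs from a whole-genome self-alignment, with
#' 0-based half-open coordinates on both sides and a percent identity.
#'
#' @param chrom_a,start_a,end_a,chrom_b,start_b,end_b,identity Columns of
#'   the table (recycled as in `data.frame`).
#' @return A validated data frame of class `hsp_table`.
#' @export
hsp_table <- function(chrom_a, start_a, end_a, chrom_b, start_b, end_b,
                      identity) {
  df <- data.frame(chrom_a = as.character(chrom_a),
                   start_a = as.numeric(start_a), end_a = as.numeric(end_a),
                   chrom_b = as.character(chrom_b),
                   start_b = as.numeric(start_b), end_b = as.numeric(end_b),
                   identity = as.numeric(identity),
                   stringsAsFactors = FALSE)
  if (any(df$start_a >= df$end_a) || any(df$start_b >= df$end_b))
    stop_wgdfate("HSP intervals must satisfy start < end")
  if (any(df$identity < 0 | df$identity > 100))
    stop_wgdfate("HSP identity must lie in [0, 100]")
  class(df) <- c("hsp_table", "data.frame")
  df
}

#' Read an HSP table from TSV
#'
#' @param path TSV with columns chrom_a, start_a, end_a, chrom_b, start_b,
#'   end_b, identity (header required; `#` comment lines allowed).
#' @return An [hsp_table()].
#' @export
read_hsp_table <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                   stringsAsFactors = FALSE)
  need <- c("chrom_a", "start_a", "end_a", "chrom_b", "start_b", "end_b",
            "identity")
  if (!all(need %in% names(df)))
    stop_wgdfate("HSP table must have columns: ", paste(need, collapse = ", "))
  do.call(hsp_table, df[need])
}

#' Windowed homeologue-identity track
#'
#' Tiles one chromosome (A-side coordinates) into fixed windows
#' `[k*w, (k+1)*w)` and computes, per window, the length-weighted mean of
#' the identities of all HSPs overlapping it (weights are overlap lengths).
#' Windows without any HSP overlap get `NA` identity and category `"none"`.
#'
#' @param hsps An [hsp_table()] restricted to a single A-side chromosome.
#' @param window Window size in bp (default 1 Mb).
#' @param chrom_length Optional chromosome length; defaults to the largest
#'   HSP end, rounded up to a whole window.
#' @return Data frame of class `similarity_track`: `chrom`, `start`, `end`,
#'   `identity`, `category`.
#' @export
windowed_identity <- function(hsps, window = 1e6, chrom_length = NULL) {
  stopifnot(inherits(hsps, "hsp_table"))
  if (length(unique(hsps$chrom_a)) > 1)
    stop_wgdfate("windowed_identity() expects HSPs on a single chromosome")
  len <- chrom_length %||% max(hsps$end_a)
  n_win <- ceiling(len / window)
  wsum <- numeric(n_win); isum <- numeric(n_win)
  for (i in seq_len(nrow(hsps))) {
    first <- floor(hsps$start_a[i] / window)
    last <- floor((hsps$end_a[i] - 1) / window)
    for (k in first:last) {
      ov <- min(hsps$end_a[i], (k + 1) * window) - max(hsps$start_a[i],
                                                       k * window)
      wsum[k + 1] <- wsum[k + 1] + ov
      isum[k + 1] <- isum[k + 1] + ov * hsps$identity[i]
    }
  }
  identity <- ifelse(wsum > 0, isum / wsum, NA_real_)
  category <- rep("none", n_win)
  category[!is.na(identity)] <- similarity_category(identity[!is.na(identity)])
  out <- data.frame(chrom = hsps$chrom_a[1],
                    start = (seq_len(n_win) - 1) * window,
                    end = seq_len(n_win) * window,
                    identity = identity, category = category,
                    stringsAsFactors = FALSE)
  class(out) <- c("similarity_track", "data.frame")
  out
}

#' Similarity category of a windowed identity value
#'
#' Categories follow the duplicated-block coloring: above 95% "high",
#' 90-95% (both ends included) "elevated", below 90% "low".
#'
#' @param identity Percent identity value(s) in `[0, 100]`.
#' @return Character vector of categories.
#' @export
similarity_category <- function(identity) {
  if (any(is.na(identity)) || any(identity < 0 | identity > 100))
    stop_wgdfate("identity must lie in [0, 100]")
  ifelse(identity > 95, "high", ifelse(identity >= 90, "elevated", "low"))
}

#' Pairwise percent identity of aligned sequences
#'
#' For every pair of equal-length aligned sequences, identity is the number
#' of matching columns divided by the number of comparable columns
#' (columns where neither sequence has a gap or N), times 100. Gap and N
#' columns are excluded per pair, not list-wise. A pair with zero
#' comparable columns gets `NA` (flagged with a warning).
#'
#' @param seqs Character vector of aligned sequences over `A,C,G,T,-,N`
#'   (case-insensitive), or a matrix of single characters (sequences in
#'   rows), or an `ape` DNAbin alignment.
#' @return Symmetric percent-identity matrix with 100 on the diagonal.
#' @export
pairwise_identity <- function(seqs) {
  if (inherits(seqs, "DNAbin")) {
    ch <- as.character(seqs)
    seqs <- if (is.matrix(ch)) apply(ch, 1L, paste, collapse = "")
            else vapply(ch, paste, "", collapse = "")
    seqs <- toupper(seqs)
  }
  if (is.character(seqs) && !is.matrix(seqs)) {
    if (length(unique(nchar(seqs))) != 1)
      stop_wgdfate("aligned sequences must have equal length")
    mat <- do.call(rbind, strsplit(toupper(seqs), ""))
  } else if (is.matrix(seqs)) {
    mat <- toupper(seqs)
  } else stop_wgdfate("unsupported sequence input")
  n <- nrow(mat)
  if (n < 2) stop_wgdfate("need at least 2 sequences")
  comparable <- mat != "-" & mat != "N"
  out <- matrix(100, n, n, dimnames = list(rownames(mat), rownames(mat)))
  flagged <- FALSE
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      cols <- comparable[i, ] & comparable[j, ]
      if (!any(cols)) {
        out[i, j] <- out[j, i] <- NA_real_
        flagged <- TRUE
      } else {
        out[i, j] <- out[j, i] <-
          100 * sum(mat[i, cols] == mat[j, cols]) / sum(cols)
      }
    }
  }
  if (flagged) warning("pair(s) with zero comparable columns set to NA")
  out
}

#' Histogram of pairwise identities
#'
#' Fixed-width bins `[lo, lo+w)` over `[0, 100]`, with the last bin closed
#' at 100 so that counts are conserved.
#'
#' @param values Percent identities in `[0, 100]`.
#' @param width Bin width in percent.
#' @return Data frame with `lo`, `hi`, `count`.
#' @export
identity_histogram <- function(values, width = 1) {
  values <- values[!is.na(values)]
  if (length(values) && any(values < 0 | values > 100))
    stop_wgdfate("values must lie in [0, 100]")
  lo <- seq(0, 100 - width, by = width)
  idx <- pmin(floor(values / width), length(lo) - 1) + 1
  data.frame(lo = lo, hi = lo + width,
             count = tabulate(idx, nbins = length(lo)))
}
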