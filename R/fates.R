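# Classification of ortholog-triplet regulatory fates.
#
# A triplet consists of two WGD homeologues plus the single orthologue of a
# diploid outgroup (Northern pike), whose expression profile serves as a
# proxy for the ancestral regulatory state. Each homeologue is called
# conserved or diverged by its Pearson correlation with the outgroup across
# the common tissues (r > 0.6 conserved, with P = 0.03 at n = 13; r < 0.55
# diverged, P > 0.05), and the pair's fate follows from the combination of
# these calls, co-expression cluster membership, the conservation of the
# summed profile, and a binary on-off partition test.

FATE_LEVELS <- c("both_conserved", "neofunctionalized", "subfunctionalized",
                 "on_off_subfunctionalized", "diverged_unclassified",
                 "intermediate")

#' Classifier configuration
#'
#' Thresholds for conservation calls and on-off binarization.
#'
#' @param r_conserved Correlation above which a profile is conserved
#'   (default 0.6, P = 0.03 at 13 tissues).
#' @param r_diverged Correlation below which a profile is diverged
#'   (default 0.55, P > 0.05 at 13 tissues). The band
#'   `[r_diverged, r_conserved]` is an explicit intermediate class.
#' @param n_common_tissues Number of tissues shared with the outgroup.
#' @param on_off_threshold FPKM above which a gene counts as "on" in a
#'   tissue (strict inequality; default 1.0, the expressed threshold).
#' @return A list of class `classifier_config`.
#' @export
classifier_config <- function(r_conserved = 0.6, r_diverged = 0.55,
                              n_common_tissues = 13, on_off_threshold = 1.0) {
  if (!(r_diverged >= 0 && r_diverged <= r_conserved && r_conserved <= 1))
    stop_wgdfate("need 0 <= r_diverged <= r_conserved <= 1")
  if (n_common_tissues < 3)
    stop_wgdfate("n_common_tissues must be >= 3")
  structure(list(r_conserved = r_conserved, r_diverged = r_diverged,
                 n_common_tissues = as.integer(n_common_tissues),
                 on_off_threshold = on_off_threshold),
            class = "classifier_config")
}

#' Two-sided p-value for a Pearson correlation
#'
#' Student-t test of r against zero: t = r * sqrt(n-2) / sqrt(1-r^2) with
#' n-2 degrees of freedom. At the thresholds of the fate classifier this
#' gives p(0.6, 13) = 0.030 and p(0.55, 13) = 0.052.
#'
#' @param r Correlation(s) in `[-1, 1]`.
#' @param n Number of paired observations (>= 3).
#' @return Two-sided p-value(s); `r = +/-1` gives 0.
#' @export
pearson_pvalue <- function(r, n) {
  if (any(abs(r) > 1)) stop_wgdfate("|r| must be <= 1")
  if (any(n < 3)) stop_wgdfate("n must be >= 3")
  p <- ifelse(abs(r) == 1, 0,
              2 * pt(-abs(r) * sqrt(n - 2) / sqrt(1 - r^2), df = n - 2))
  unname(p)
}

#' Conservation call for one profile against the outgroup
#'
#' @param x,pike Equal-length expression profiles on the log2 scale over the
#'   common tissues.
#' @param cfg A [classifier_config()].
#' @return List with `status` (`"conserved"`, `"diverged"`, `"intermediate"`
#'   or `"undefined"` for a zero-variance profile) and the correlation `r`.
#' @export
conservation_call <- function(x, pike, cfg = classifier_config()) {
  if (length(x) != length(pike))
    stop_wgdfate("profile length mismatch")
  if (max(x) == min(x) || max(pike) == min(pike))
    return(list(status = "undefined", r = NA_real_))
  r <- cor(x, pike)
  status <- if (r > cfg$r_conserved) "conserved"
            else if (r < cfg$r_diverged) "diverged"
            else "intermediate"
  list(status = status, r = r)
}

#' Construct an ortholog triplet
#'
#' Raw-FPKM profiles over the common tissues for the two homeologues and the
#' outgroup orthologue. Correlations are computed internally on the
#' log2(FPKM+1) scale; the sum of the homeologues is formed on the FPKM
#' scale, where it has an expression meaning, before log transformation.
#'
#' @param a,b,pike Non-negative FPKM profiles of equal length.
#' @param ids Optional character vector `c(a, b, pike)` of gene ids.
#' @return An object of class `ortholog_triplet`.
#' @export
ortholog_triplet <- function(a, b, pike, ids = c("a", "b", "pike")) {
  if (length(a) != length(b) || length(b) != length(pike))
    stop_wgdfate("triplet profiles must have equal tissue length")
  if (any(c(a, b, pike) < 0)) stop_wgdfate("FPKM profiles must be non-negative")
  structure(list(a = as.numeric(a), b = as.numeric(b),
                 pike = as.numeric(pike), ids = ids),
            class = "ortholog_triplet")
}

#' Conservation of the summed homeologue profile
#'
#' Tests whether the sum of the two homeologues' FPKM profiles correlates
#' with the outgroup proxy for the ancestral state above the conserved
#' threshold: r( log2(A+B+1), log2(pike+1) ) > r_conserved. A zero-variance
#' sum or outgroup profile yields `FALSE` with `r_sum = NA`.
#'
#' @param t An [ortholog_triplet()].
#' @param cfg A [classifier_config()].
#' @return List with logical `conserved` and the correlation `r_sum`.
#' @export
summed_profile_conservation <- function(t, cfg = classifier_config()) {
  s <- log2p1(t$a + t$b)
  p <- log2p1(t$pike)
  if (max(s) == min(s) || max(p) == min(p))
    return(list(conserved = FALSE, r_sum = NA_real_))
  r <- cor(s, p)
  list(conserved = r > cfg$r_conserved, r_sum = r)
}

#' On-off subfunctionalization test
#'
#' Binarizes each profile per tissue (on when FPKM is strictly above the
#' threshold) and asks whether the two homeologues partition the ancestral
#' expression domain: the outgroup on-set must be non-empty and covered by
#' the union of the homeologue on-sets, neither homeologue alone may cover
#' it, and both homeologues must be on somewhere.
#'
#' @param t An [ortholog_triplet()].
#' @param cfg A [classifier_config()].
#' @return `TRUE` when the on-off partition criterion is met.
#' @export
on_off_call <- function(t, cfg = classifier_config()) {
  thr <- cfg$on_off_threshold
  on_a <- t$a > thr; on_b <- t$b > thr; on_p <- t$pike > thr
  any(on_p) &&
    all(on_p <= (on_a | on_b)) &&   # union covers ancestral on-set
    !all(on_p <= on_a) &&           # neither copy covers it alone
    !all(on_p <= on_b) &&
    any(on_a) && any(on_b)
}

#' Classify the fate of an ortholog triplet
#'
#' Applies the fate rules in order of precedence:
#' \enumerate{
#'   \item both homeologues conserved: `both_conserved`;
#'   \item at least one conserved and the homeologues in different
#'     co-expression clusters: `neofunctionalized`;
#'   \item both diverged, different clusters, and the summed profile
#'     conserved: `subfunctionalized`;
#'   \item both diverged and different clusters otherwise:
#'     `on_off_subfunctionalized` when [on_off_call()] is true, else
#'     `diverged_unclassified`;
#'   \item everything else: `intermediate`.
#' }
#' Evaluating `both_conserved` before neofunctionalization keeps fully
#' conserved pairs out of the neofunctionalized class even when they happen
#' to fall in different clusters.
#'
#' @param t An [ortholog_triplet()] (raw FPKM).
#' @param clusters A `cluster_assignment` containing both homeologues.
#' @param cfg A [classifier_config()].
#' @return One-row data frame: `category`, per-copy `status_a`/`status_b`,
#'   correlations `r_a`, `r_b`, `r_sum`, and `same_cluster`.
#' @export
classify_triplet <- function(t, clusters, cfg = classifier_config()) {
  stopifnot(inherits(t, "ortholog_triplet"))
  la <- clusters$labels[t$ids[1]]
  lb <- clusters$labels[t$ids[2]]
  if (is.na(la) || is.na(lb))
    stop_wgdfate("missing cluster label for ",
                 paste(t$ids[1:2][c(is.na(la), is.na(lb))], collapse = ", "))
  pl <- log2p1(t$pike)
  ca <- conservation_call(log2p1(t$a), pl, cfg)
  cb <- conservation_call(log2p1(t$b), pl, cfg)
  sm <- summed_profile_conservation(t, cfg)
  same <- la == lb
  category <-
    if (ca$status == "conserved" && cb$status == "conserved") {
      "both_conserved"
    } else if ((ca$status == "conserved" || cb$status == "conserved") && !same) {
      "neofunctionalized"
    } else if (ca$status == "diverged" && cb$status == "diverged" && !same) {
      if (sm$conserved) "subfunctionalized"
      else if (on_off_call(t, cfg)) "on_off_subfunctionalized"
      else "diverged_unclassified"
    } else {
      "intermediate"
    }
  data.frame(gene_a = t$ids[1], gene_b = t$ids[2], gene_pike = t$ids[3],
             category = category, status_a = ca$status, status_b = cb$status,
             r_a = ca$r, r_b = cb$r, r_sum = sm$r_sum,
             cluster_a = unname(la), cluster_b = unname(lb),
             same_cluster = same, stringsAsFactors = FALSE)
}

#' Expression specificity (tau)
#'
#' tau = sum_i (1 - x_i / x_max) / (N - 1), the average shortfall of each
#' tissue relative to the maximally expressing tissue. 0 for a uniform
#' profile, 1 for expression confined to a single tissue, and invariant
#' under positive scaling.
#'
#' @param x Non-negative expression profile with at least 2 tissues.
#' @return Specificity in `[0, 1]`, or `NA` (with a warning) for an all-zero
#'   profile.
#' @export
tissue_specificity <- function(x) {
  if (length(x) < 2) stop_wgdfate("at least 2 samples are required")
  if (any(x < 0)) stop_wgdfate("profile must be non-negative")
  m <- max(x)
  if (m == 0) {
    warning("all-zero profile: specificity undefined")
    return(NA_real_)
  }
  sum(1 - x / m) / (length(x) - 1)
}

#' Wilcoxon rank-sum tests of specificity between clusters
#'
#' Two-sided Wilcoxon rank-sum p-value for every pair of co-expression
#' clusters, comparing the distributions of per-gene specificity scores.
#' Clusters with no scored gene are skipped with a warning.
#'
#' @param clusters A `cluster_assignment`.
#' @param scores Named numeric vector of per-gene specificity scores
#'   (names are gene ids).
#' @return Data frame with `cluster_i`, `cluster_j` and the p-value.
#' @export
specificity_cluster_test <- function(clusters, scores) {
  lab <- clusters$labels[names(scores)]
  ok <- !is.na(lab) & !is.na(scores)
  lab <- lab[ok]; scores <- scores[ok]
  present <- sort(unique(lab))
  skipped <- setdiff(seq_len(clusters$k), present)
  if (length(skipped))
    warning("cluster(s) without scored genes skipped: ",
            paste(skipped, collapse = ", "))
  if (length(present) < 2)
    stop_wgdfate("need at least 2 clusters with scored genes")
  cmb <- utils::combn(present, 2)
  p <- apply(cmb, 2L, function(ij) {
    pv <- suppressWarnings(
      wilcox.test(scores[lab == ij[1]], scores[lab == ij[2]],
                  alternative = "two.sided")$p.value)
    if (is.nan(pv)) pv <- 1  # fully tied comparison carries no evidence
    pv
  })
  data.frame(cluster_i = cmb[1, ], cluster_j = cmb[2, ], p = p)
}
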