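# Conditional duplicate retention and its significance statistics.
#
# Each gene family contributes lineages with an "opportunity" for retention
# at each duplication era: a family may retain the teleost-WGD (Ts3R) pair,
# each surviving post-Ts3R lineage may retain the salmonid-WGD (Ss4R) pair,
# and each post-Ss4R salmon lineage may retain small-scale duplicates (SSD).
# Conditional fractions ask whether retention at one era predicts retention
# at the next.

# all internal-node indices (1..Nnode) in the subtree rooted at `node`
subtree_internal <- function(node, kids, ntip) {
  if (node <= ntip) return(integer(0))
  out <- node - ntip
  for (ch in kids[[node]]) out <- c(out, subtree_internal(ch, kids, ntip))
  out
}

#' Conditional duplicate-retention table
#'
#' Tabulates, over a collection of era-annotated gene trees, the fraction of
#' lineages that retained a duplicate pair at each era, conditional on
#' whether the ancestral-era duplicate was itself retained. A lineage counts
#' as an opportunity when its parent duplicate survived into the relevant
#' era (here: when the subtree contains salmonid genes for Ss4R, and focal
#' genes for SSD). Lineages whose Ss4R status rests on a
#' chromosome-ambiguous node are excluded and reported in the
#' `excluded_lineages` attribute.
#'
#' @param trees List of `gene_tree` objects processed by [assign_era()].
#' @return Data frame with columns `event`, `condition`, `retained`,
#'   `total`, `fraction` (NA when no opportunity was observed).
#' @export
retention_conditional_table <- function(trees) {
  if (!length(trees)) stop_wgdfate("empty tree collection")
  counts <- c(ts3r_ret = 0, ts3r_tot = 0,
              ss4r_ret_given_ts3r = 0, ss4r_tot_given_ts3r = 0,
              ss4r_ret_given_nots3r = 0, ss4r_tot_given_nots3r = 0,
              ssd_ret_given_ss4r = 0, ssd_tot_given_ss4r = 0,
              ssd_ret_given_noss4r = 0, ssd_tot_given_noss4r = 0)
  excluded <- 0L
  for (g in trees) {
    if (is.null(g$eras))
      stop_wgdfate("trees must be era-annotated with assign_era()")
    phy <- g$phylo
    ntip <- length(phy$tip.label)
    kids <- node_children(phy)
    sets <- node_sets(g, "species")
    salmonids <- g$salmonids
    focal <- g$focal
    counts["ts3r_tot"] <- counts["ts3r_tot"] + 1
    if (any(g$eras == "Ts3R")) counts["ts3r_ret"] <- counts["ts3r_ret"] + 1

    lineages <- list()
    descend <- function(node, under_ts3r) {
      has_salmonid <- any(sets[[node]] %in% salmonids)
      if (!has_salmonid) return(invisible(NULL))
      if (all(sets[[node]] %in% salmonids)) {
        lineages[[length(lineages) + 1L]] <<- list(node = node,
                                                   ts3r = under_ts3r)
        return(invisible(NULL))
      }
      v <- node - ntip
      if (g$eras[v] == "Ts3R") under_ts3r <- TRUE
      for (ch in kids[[node]]) descend(ch, under_ts3r)
    }
    descend(ntip + 1L, FALSE)

    for (lin in lineages) {
      inl <- subtree_internal(lin$node, kids, ntip)
      eras <- g$eras[inl]
      ss4r_nodes <- inl[eras == "Ss4R"]
      has_focal <- focal %in% sets[[lin$node]]
      if (length(ss4r_nodes) == 0 && any(eras == "ambiguous")) {
        excluded <- excluded + 1L
        next
      }
      cond <- if (lin$ts3r) "ss4r_%s_given_ts3r" else "ss4r_%s_given_nots3r"
      counts[sprintf(cond, "tot")] <- counts[sprintf(cond, "tot")] + 1
      ss4r_ret <- length(ss4r_nodes) > 0
      if (ss4r_ret)
        counts[sprintf(cond, "ret")] <- counts[sprintf(cond, "ret")] + 1
      # post-Ss4R salmon lineages for the SSD tabulation
      salmon_lineages <- list()
      if (ss4r_ret) {
        for (sn in ss4r_nodes) {
          for (ch in kids[[ntip + sn]]) {
            if (focal %in% sets[[ch]])
              salmon_lineages <- c(salmon_lineages, ch)
          }
        }
      } else if (has_focal) {
        salmon_lineages <- list(lin$node)
      }
      scond <- if (ss4r_ret) "ssd_%s_given_ss4r" else "ssd_%s_given_noss4r"
      for (sl in salmon_lineages) {
        counts[sprintf(scond, "tot")] <- counts[sprintf(scond, "tot")] + 1
        if (any(g$eras[subtree_internal(sl, kids, ntip)] == "postSs4R_SSD"))
          counts[sprintf(scond, "ret")] <- counts[sprintf(scond, "ret")] + 1
      }
    }
  }
  frac <- function(r, t) if (t > 0) r / t else NA_real_
  out <- data.frame(
    event = c("Ts3R", "Ss4R", "Ss4R", "postSs4R_SSD", "postSs4R_SSD"),
    condition = c("all", "Ts3R_retained", "Ts3R_lost",
                  "Ss4R_retained", "Ss4R_lost"),
    retained = c(counts["ts3r_ret"], counts["ss4r_ret_given_ts3r"],
                 counts["ss4r_ret_given_nots3r"], counts["ssd_ret_given_ss4r"],
                 counts["ssd_ret_given_noss4r"]),
    total = c(counts["ts3r_tot"], counts["ss4r_tot_given_ts3r"],
              counts["ss4r_tot_given_nots3r"], counts["ssd_tot_given_ss4r"],
              counts["ssd_tot_given_noss4r"]),
    stringsAsFactors = FALSE)
  out$fraction <- mapply(frac, out$retained, out$total)
  attr(out, "excluded_lineages") <- excluded
  out
}

#' Two-proportion pooled z-test
#'
#' Pooled test of H0: p1 = p2 with
#' z = (x1/n1 - x2/n2) / sqrt(p(1-p)(1/n1 + 1/n2)), p = (x1+x2)/(n1+n2),
#' and a two-sided p-value from the standard normal tail. The significance
#' flag uses the Bonferroni-corrected level alpha = 0.001/7 applied in the
#' retention comparisons.
#'
#' @param x1,n1,x2,n2 Successes and trials of the two groups.
#' @param alpha Significance level (default 0.001/7).
#' @return List with `z`, `p`, `significant`, `alpha` and a `degenerate`
#'   flag (pooled proportion 0 or 1).
#' @export
two_proportion_z <- function(x1, n1, x2, n2, alpha = 0.001 / 7) {
  if (n1 <= 0 || n2 <= 0) stop_wgdfate("group sizes must be positive")
  if (x1 < 0 || x1 > n1 || x2 < 0 || x2 > n2)
    stop_wgdfate("need 0 <= x <= n in both groups")
  diff <- x1 / n1 - x2 / n2
  pooled <- (x1 + x2) / (n1 + n2)
  degenerate <- pooled %in% c(0, 1)
  z <- if (degenerate) {
    if (diff == 0) 0 else sign(diff) * Inf
  } else {
    diff / sqrt(pooled * (1 - pooled) * (1 / n1 + 1 / n2))
  }
  p <- 2 * pnorm(-abs(z))
  list(z = z, p = p, significant = p < alpha, alpha = alpha,
       degenerate = degenerate)
}

#' Odds ratio and relative risk for a 2x2 table
#'
#' OR = (a d)/(b c) with a Haldane-Anscombe 0.5 correction applied to all
#' cells when any cell is zero (flagged); RR = (a/(a+b)) / (c/(c+d)); the
#' two-sided p-value and confidence interval come from the normal
#' approximation on the log odds ratio (Wald).
#'
#' @param tab 2x2 matrix of non-negative counts
#'   (`rbind(c(a, b), c(c, d))`).
#' @param conf_level Confidence level for the Wald interval.
#' @return List with `odds_ratio`, `relative_risk`, `p`, `conf_int`,
#'   and `corrected`.
#' @export
odds_ratio_rr <- function(tab, conf_level = 0.95) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2, 2))) stop_wgdfate("'tab' must be a 2x2 table")
  if (any(tab < 0) || any(tab != round(tab)))
    stop_wgdfate("cells must be non-negative integers")
  if (any(rowSums(tab) == 0)) stop_wgdfate("empty row in 2x2 table")
  a <- tab[1, 1]; b <- tab[1, 2]; c <- tab[2, 1]; d <- tab[2, 2]
  corrected <- any(tab == 0)
  cc <- if (corrected) 0.5 else 0
  or <- ((a + cc) * (d + cc)) / ((b + cc) * (c + cc))
  rr <- (a / (a + b)) / (c / (c + d))
  se <- sqrt(1 / (a + cc) + 1 / (b + cc) + 1 / (c + cc) + 1 / (d + cc))
  z <- log(or) / se
  p <- 2 * pnorm(-abs(z))
  q <- -stats::qnorm((1 - conf_level) / 2)
  ci <- exp(log(or) + c(-1, 1) * q * se)
  list(odds_ratio = or, relative_risk = rr, p = p, conf_int = ci,
       corrected = corrected)
}

#' Co-retention of interaction partners
#'
#' Cross-tabulates duplicate-retention status across annotated interaction
#' partner pairs (e.g. putative physical binding partners): for each pair
#' (g1, g2), whether g2 was retained is tabulated against whether g1 was
#' retained, and association is tested with both [odds_ratio_rr()] and
#' [two_proportion_z()] (P(g2 retained | g1 retained) vs
#' P(g2 retained | g1 lost)). Pairs referencing genes without a defined
#' retention status are skipped and counted.
#'
#' @param retained Named logical vector: retention status per gene.
#' @param pairs Data frame whose first two columns are gene ids.
#' @return List with the 2x2 `table`, `odds_ratio_rr`, `two_proportion`
#'   and `n_skipped`.
#' @export
co_retention_test <- function(retained, pairs) {
  if (is.null(pairs) || nrow(pairs) == 0)
    stop_wgdfate("empty partner-pair list")
  g1 <- as.character(pairs[[1]]); g2 <- as.character(pairs[[2]])
  r1 <- retained[g1]; r2 <- retained[g2]
  ok <- !is.na(r1) & !is.na(r2)
  n_skipped <- sum(!ok)
  r1 <- r1[ok]; r2 <- r2[ok]
  if (!length(r1)) stop_wgdfate("no pair with defined retention status")
  tab <- rbind(c(sum(r1 & r2), sum(r1 & !r2)),
               c(sum(!r1 & r2), sum(!r1 & !r2)))
  dimnames(tab) <- list(g1_retained = c("yes", "no"),
                        g2_retained = c("yes", "no"))
  list(table = tab,
       odds_ratio_rr = odds_ratio_rr(tab),
       two_proportion = two_proportion_z(tab[1, 1], sum(tab[1, ]),
                                         tab[2, 1], sum(tab[2, ])),
       n_skipped = n_skipped)
}
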