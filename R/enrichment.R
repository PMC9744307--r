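#' Distance from each TSS to the nearest loop anchor
#'
#' Both anchors of every loop are pooled; the distance is 0 when the TSS
#' falls inside an anchor interval, otherwise the gap to the nearer interval
#' edge. A TSS on a chromosome with no loop gets `NA`.
#'
#' @param tss Data frame with `chrom` and `tss` (0-based position).
#' @param loops `Pairs` of anchor `GRanges` ([read_intervals()] with
#'   `format = "BEDPE"`), or a `GRanges` of anchor intervals.
#' @return Numeric vector of bp distances, parallel to `tss` rows.
#' @export
nearest_anchor_distance <- function(tss, loops) {
  anchors <- if (is(loops, "Pairs"))
    c(S4Vectors::first(loops), S4Vectors::second(loops))
  else loops
  tss <- as.data.frame(tss)
  pts <- GenomicRanges::GRanges(tss$chrom,
                                IRanges::IRanges(tss$tss + 1L, tss$tss + 1L))
  # chromosomes with no anchor legitimately yield no hit (reported NA);
  # silence the seqlevel mismatch chatter that case triggers
  hit <- suppressWarnings(
    GenomicRanges::distanceToNearest(pts, anchors, ignore.strand = TRUE))
  out <- rep(NA_real_, nrow(tss))
  # GenomicRanges reports the count of bases strictly between the ranges;
  # the edge distance of an outside point is that count plus one, 0 inside.
  gap <- S4Vectors::mcols(hit)$distance
  inside <- suppressWarnings(
    GenomicRanges::countOverlaps(pts, anchors, ignore.strand = TRUE)) > 0
  out[S4Vectors::queryHits(hit)] <- ifelse(inside[S4Vectors::queryHits(hit)],
                                           0, gap + 1)
  out
}

.enrichment_result <- function(tab, odds_ratio, p, tail) {
  structure(list(table = tab, odds_ratio = odds_ratio, p = p, tail = tail),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("Fisher exact (%s): OR = %.3g, p = %.4g\n",
              x$tail, x$odds_ratio, x$p))
  print(x$table)
  invisible(x)
}

#' Loop-anchor proximity enrichment between two gene groups
#'
#' Dichotomises each group's anchor distances at `<= threshold` bp and runs
#' Fisher's exact test on the resulting 2x2 table (near/far x group A/B).
#' Both the one-tailed (enrichment of group A among near genes, upper tail)
#' and two-sided p-values are reported.
#'
#' @param group_a_distances,group_b_distances Numeric bp distances (e.g.
#'   DEG vs nonDEG TSSs from [nearest_anchor_distance()]); `NA` distances
#'   (no anchor on the chromosome) count as far.
#' @param threshold Proximity threshold in bp. Default 5000.
#' @return An `enrichment_result` with `p` (one-tailed greater),
#'   `p_two_sided`, the 2x2 `table`, the conditional-MLE `odds_ratio`, and
#'   the per-group near fractions in `near_fraction`.
#' @export
proximity_enrichment <- function(group_a_distances, group_b_distances,
                                 threshold = 5000) {
  if (!length(group_a_distances) || !length(group_b_distances))
    stop("both groups must be non-empty", call. = FALSE)
  near_a <- !is.na(group_a_distances) & group_a_distances <= threshold
  near_b <- !is.na(group_b_distances) & group_b_distances <= threshold
  tab <- matrix(c(sum(near_a), sum(!near_a), sum(near_b), sum(!near_b)),
                nrow = 2,
                dimnames = list(c("near", "far"), c("group_a", "group_b")))
  ft_g <- stats::fisher.test(tab, alternative = "greater")
  ft_2 <- stats::fisher.test(tab, alternative = "two.sided")
  res <- .enrichment_result(tab, unname(ft_g$estimate), ft_g$p.value, "one_greater")
  res$p_two_sided <- ft_2$p.value
  res$near_fraction <- c(group_a = mean(near_a), group_b = mean(near_b))
  res
}

#' Rank correlation between anchor distance and fold change
#'
#' Spearman correlation of each gene's distance to the nearest loop anchor
#' against its fold change, by default the magnitude `|log2fc|` (genes
#' closer to anchors tending to larger changes give negative rho). Ties are
#' mid-ranked; the two-sided p-value uses the t approximation so tied and
#' untied inputs are treated alike.
#'
#' @param distances Numeric bp distances.
#' @param log2fcs Shrunken log2 fold changes, parallel to `distances`.
#' @param signed Correlate the signed fold change instead of its magnitude.
#'   Default `FALSE`.
#' @return List with `rho` and `p`.
#' @export
distance_fc_correlation <- function(distances, log2fcs, signed = FALSE) {
  keep <- !is.na(distances) & !is.na(log2fcs)
  distances <- distances[keep]
  fc <- if (signed) log2fcs[keep] else abs(log2fcs[keep])
  if (length(distances) < 4L) stop("need >= 4 complete pairs", call. = FALSE)
  if (length(unique(distances)) == 1L || length(unique(fc)) == 1L)
    stop("constant input: correlation undefined", call. = FALSE)
  ct <- stats::cor.test(distances, fc, method = "spearman", exact = FALSE)
  list(rho = unname(ct$estimate), p = ct$p.value)
}

#' Gene-set overlap against a fixed gene universe
#'
#' One-tailed Fisher's exact test (upper hypergeometric tail) for the
#' overlap of two gene sets drawn from a universe of `universe` genes. The
#' 2x2 table is (`n_overlap`, `n_a - n_overlap`; `n_b - n_overlap`,
#' `universe - n_a - n_b + n_overlap`).
#'
#' @param n_a,n_b Sizes of the two gene sets.
#' @param n_overlap Number of shared genes.
#' @param universe Universe size. Default 20000.
#' @return An `enrichment_result` (one-tailed enrichment p).
#' @examples
#' fisher_overlap(1876, 4195, 578, 20000)$p  # ~4e-26
#' @export
fisher_overlap <- function(n_a, n_b, n_overlap, universe = 20000L) {
  stopifnot(n_overlap >= 0, n_a >= 0, n_b >= 0)
  if (n_overlap > min(n_a, n_b))
    stop("n_overlap exceeds a set size", call. = FALSE)
  if (n_a + n_b - n_overlap > universe)
    stop("sets exceed the universe", call. = FALSE)
  tab <- matrix(c(n_overlap, n_a - n_overlap,
                  n_b - n_overlap, universe - n_a - n_b + n_overlap),
                nrow = 2,
                dimnames = list(c("in_b", "not_b"), c("in_a", "not_a")))
  ft <- stats::fisher.test(tab, alternative = "greater")
  .enrichment_result(tab, unname(ft$estimate), ft$p.value, "one_greater")
}

#' Direction concordance of shared DEGs
#'
#' Intersects the DEG sets of two tables and counts shared genes changed in
#' the same direction.
#'
#' @param degs_a,degs_b DEG tables ([as_deg_table()]).
#' @return List with `n_shared`, `n_same_direction`, `fraction` (`NA` when
#'   no gene is shared).
#' @export
shared_direction <- function(degs_a, degs_b) {
  a <- degs_a[degs_a$is_deg, c("gene_id", "direction")]
  b <- degs_b[degs_b$is_deg, c("gene_id", "direction")]
  shared <- intersect(a$gene_id, b$gene_id)
  if (!length(shared))
    return(list(n_shared = 0L, n_same_direction = 0L, fraction = NA_real_))
  same <- sum(a$direction[match(shared, a$gene_id)] ==
              b$direction[match(shared, b$gene_id)])
  list(n_shared = length(shared), n_same_direction = same,
       fraction = same / length(shared))
}
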