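#' Assign gene TSSs to non-overlapping TADs
#'
#' Each gene is assigned to the TAD whose half-open interval `[start, end)`
#' contains its (dominant) TSS. TADs must form a partition within each
#' chromosome: any overlap is an error. Genes falling outside every TAD are
#' excluded from the assignment and counted; TADs containing no gene are
#' dropped.
#'
#' @param genes Data frame with columns `gene_id`, `chrom`, `tss` (0-based)
#'   and optionally `active` (logical; defaults to all `TRUE`).
#' @param tads `GRanges` of TAD intervals (see [read_intervals()]).
#' @param degs Optional DEG table ([as_deg_table()]) keyed by `gene_id`;
#'   genes not in the table get `is_deg = FALSE`, `direction = "none"`.
#' @return A `tad_assignment`: data frame with `gene_id`, `tad` (integer TAD
#'   index), `active`, `is_deg`, `direction`; attributes `n_excluded` (genes
#'   outside all TADs) and `n_tads` (TADs retained).
#' @export
assign_to_tads <- function(genes, tads, degs = NULL) {
  genes <- as.data.frame(genes)
  stopifnot(all(c("gene_id", "chrom", "tss") %in% names(genes)))
  if (length(tads) > 1L) {
    ov <- GenomicRanges::findOverlaps(tads, tads, ignore.strand = TRUE)
    if (any(S4Vectors::queryHits(ov) != S4Vectors::subjectHits(ov)))
      stop("overlapping TADs: per-TAD statistics assume a partition", call. = FALSE)
  }
  # TSS as a 1-based point; TAD gr is [start0+1, end0], so containment in
  # the half-open [start0, end0) means tss0 + 1 in [start0+1, end0].
  pts <- GenomicRanges::GRanges(genes$chrom,
                                IRanges::IRanges(genes$tss + 1L, genes$tss + 1L))
  hit <- GenomicRanges::findOverlaps(pts, tads, ignore.strand = TRUE)
  tad_of <- rep(NA_integer_, nrow(genes))
  tad_of[S4Vectors::queryHits(hit)] <- S4Vectors::subjectHits(hit)
  inside <- !is.na(tad_of)
  a <- data.frame(gene_id = genes$gene_id[inside],
                  tad = tad_of[inside],
                  active = if ("active" %in% names(genes)) genes$active[inside]
                           else rep(TRUE, sum(inside)))
  if (is.null(degs)) {
    a$is_deg <- FALSE
    a$direction <- "none"
  } else {
    i <- match(a$gene_id, degs$gene_id)
    a$is_deg <- !is.na(i) & degs$is_deg[i]
    a$direction <- ifelse(a$is_deg, degs$direction[i], "none")
  }
  structure(a,
            n_excluded = sum(!inside),
            n_tads = length(unique(a$tad)),
            class = c("tad_assignment", "data.frame"))
}

# Mean over TADs (with >= 1 universe gene) of the per-TAD percentage of
# universe genes carrying the label. Both vectors are parallel to the
# universe rows.
.mean_tad_pct <- function(tad, label) {
  n <- tapply(label, tad, length)
  k <- tapply(label, tad, sum)
  mean(100 * k / n)
}

#' Per-TAD DEG clustering statistic
#'
#' The unweighted mean, over TADs containing at least one gene of the
#' relevant universe, of the percentage of that TAD's universe genes carrying
#' the label of interest: DEGs among active genes (`mode = "deg_status"`) or
#' active genes among all genes (`mode = "transcription_status"`).
#'
#' Note that when every TAD holds the same number of universe genes this mean
#' of per-TAD fractions equals the global label fraction identically, so the
#' statistic responds to clustering only through covariance between label
#' placement and per-TAD gene density (see the package vignette).
#'
#' @param assignment A [assign_to_tads()] result.
#' @param mode Which labelling to summarise.
#' @return Percentage (scalar).
#' @export
clustering_statistic <- function(assignment,
                                 mode = c("deg_status", "transcription_status")) {
  mode <- match.arg(mode)
  u <- .clustering_universe(assignment, mode)
  if (nrow(u) == 0L) stop("no qualifying TAD", call. = FALSE)
  .mean_tad_pct(u$tad, u$label)
}

.clustering_universe <- function(assignment, mode) {
  if (mode == "deg_status") {
    u <- assignment[assignment$active, c("tad", "is_deg")]
    names(u) <- c("tad", "label")
  } else {
    u <- data.frame(tad = assignment$tad, label = assignment$active)
  }
  u
}

#' Label-shuffle permutation test for DEG clustering in TADs
#'
#' Shuffles the binary labels (DEG/nonDEG over active genes, or
#' active/inactive over all genes) uniformly across the gene universe,
#' keeping the number in each category constant, and recomputes
#' [clustering_statistic()] for each permutation. The p-value is the
#' percentile rank of the observed statistic: the fraction of null values at
#' or above it (ties count toward the null tail), which can be exactly 0.
#'
#' @inheritParams clustering_statistic
#' @param n_perm Number of permutations. Default 1000.
#' @param seed Integer seed for reproducibility, or `NULL`.
#' @return A `permutation_result`: list with `observed`, `null` (length
#'   `n_perm`), `p`, `n_perm`, `seed`.
#' @export
clustering_permutation_test <- function(assignment,
                                        mode = c("deg_status", "transcription_status"),
                                        n_perm = 1000L, seed = NULL) {
  mode <- match.arg(mode)
  stopifnot(n_perm >= 1)
  u <- .clustering_universe(assignment, mode)
  if (nrow(u) == 0L) stop("no qualifying TAD", call. = FALSE)
  if (all(u$label) || !any(u$label))
    stop("degenerate label set: all genes share one label", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  observed <- .mean_tad_pct(u$tad, u$label)
  null <- vapply(seq_len(n_perm), function(i)
    .mean_tad_pct(u$tad, sample(u$label)), numeric(1))
  .permutation_result(observed, null, n_perm, seed)
}

.permutation_result <- function(observed, null, n_perm, seed) {
  structure(list(observed = observed,
                 null = null,
                 p = mean(null >= observed),
                 n_perm = as.integer(n_perm),
                 seed = seed),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf("permutation test: observed = %.4g, null mean = %.4g, p = %.4g (n_perm = %d)\n",
              x$observed, mean(x$null), x$p, x$n_perm))
  invisible(x)
}

#' Directional coordination score of one TAD
#'
#' The majority fraction of the TAD's DEG directions, as a percentage:
#' `100 * max(#up, #down) / n`. 50% means an even up/down split (random
#' misexpression), 100% means all DEGs in the TAD change in the same
#' direction.
#'
#' @param directions Character vector of `"up"` / `"down"` (length >= 2).
#' @return Percentage in \[50, 100\].
#' @examples
#' coordination_score(rep("down", 6))  # 100
#' coordination_score(c("up", "down")) # 50
#' @export
coordination_score <- function(directions) {
  if (length(directions) < 2L)
    stop("coordination needs >= 2 DEG directions", call. = FALSE)
  stopifnot(all(directions %in% c("up", "down")))
  n_up <- sum(directions == "up")
  100 * max(n_up, length(directions) - n_up) / length(directions)
}

.coordination_bins <- c("50-60", "60-70", "70-80", "80-90", "90-100")

# scores in [50,100] -> five upper-inclusive 10-point bins; 50 joins the
# first bin so the bins partition the closed interval.
.bin_scores <- function(scores) {
  idx <- pmax(1L, ceiling((scores - 50) / 10))
  tab <- tabulate(idx, nbins = 5L)
  stats::setNames(tab, .coordination_bins)
}

#' Average DEG coordination across TADs
#'
#' Computes [coordination_score()] for every TAD holding at least
#' `min_degs` DEGs (default 2; the score is undefined below that), their
#' unweighted mean, and counts per 10-point score bin.
#'
#' @inheritParams clustering_statistic
#' @param min_degs Minimum DEGs for a TAD to enter the analysis. Default 2.
#' @return A `coordination_profile`: list with `scores` (named by TAD
#'   index), `average` (%), `bin_counts` (five 10-point bins, upper
#'   inclusive), `n_tads`.
#' @export
average_coordination <- function(assignment, min_degs = 2L) {
  d <- assignment[assignment$is_deg, c("tad", "direction")]
  .coordination_profile(d$tad, d$direction, min_degs)
}

.coordination_profile <- function(tad, direction, min_degs = 2L) {
  n <- table(tad)
  keep <- names(n)[n >= min_degs]
  if (!length(keep))
    stop("no TAD with >= ", min_degs, " DEGs", call. = FALSE)
  sel <- tad %in% keep
  scores <- vapply(split(direction[sel], as.character(tad[sel])),
                   coordination_score, numeric(1))
  structure(list(scores = scores,
                 average = mean(scores),
                 bin_counts = .bin_scores(scores),
                 n_tads = length(scores)),
            class = "coordination_profile")
}

#' @export
print.coordination_profile <- function(x, ...) {
  cat(sprintf("coordination over %d TADs: average %.1f%%\n", x$n_tads, x$average))
  print(x$bin_counts)
  invisible(x)
}

#' Permutation test for directional coordination
#'
#' Shuffles the up/down directions among the DEG slots (TAD membership and
#' DEG status fixed) and recomputes the average coordination for each
#' permutation. p is the fraction of null averages at or above the observed
#' average. If all DEGs share one direction globally the permutation cannot
#' vary and p = 1 is returned with a warning.
#'
#' @inheritParams clustering_permutation_test
#' @inheritParams average_coordination
#' @return A `permutation_result` (see [clustering_permutation_test()]) with
#'   the observed `coordination_profile` attached as `$profile`.
#' @export
coordination_permutation_test <- function(assignment, n_perm = 1000L,
                                          seed = NULL, min_degs = 2L) {
  stopifnot(n_perm >= 1)
  d <- assignment[assignment$is_deg, c("tad", "direction")]
  obs_profile <- .coordination_profile(d$tad, d$direction, min_degs)
  if (length(unique(d$direction)) < 2L)
    warning("all DEGs share one direction; permutation cannot vary, p = 1",
            call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  null <- vapply(seq_len(n_perm), function(i)
    .coordination_profile(d$tad, sample(d$direction), min_degs)$average,
    numeric(1))
  res <- .permutation_result(obs_profile$average, null, n_perm, seed)
  res$profile <- obs_profile
  res
}

#' Observed-versus-null comparison of binned coordination scores
#'
#' For each 10-point coordination bin, reports the observed TAD count, the
#' mean count under the null profiles, and percentile-rank p-values in each
#' direction (enrichment: null >= observed; depletion: null <= observed).
#'
#' @param observed A `coordination_profile`.
#' @param null_profiles List of `coordination_profile`s with identical
#'   binning (e.g. built from permuted directions).
#' @return Data frame with one row per bin: `bin`, `observed`, `null_mean`,
#'   `p_enrich`, `p_deplete`.
#' @export
coordination_bin_comparison <- function(observed, null_profiles) {
  stopifnot(inherits(observed, "coordination_profile"), length(null_profiles) >= 1L)
  bins <- names(observed$bin_counts)
  null_mat <- vapply(null_profiles, function(p) {
    if (!identical(names(p$bin_counts), bins))
      stop("bin mismatch between observed and null profiles", call. = FALSE)
    p$bin_counts
  }, numeric(length(bins)))
  null_mat <- matrix(null_mat, nrow = length(bins))
  data.frame(bin = bins,
             observed = as.integer(observed$bin_counts),
             null_mean = rowMeans(null_mat),
             p_enrich = rowMeans(null_mat >= observed$bin_counts),
             p_deplete = rowMeans(null_mat <= observed$bin_counts),
             row.names = NULL)
}

#' Null coordination profiles by direction shuffling
#'
#' Convenience generator for [coordination_bin_comparison()]: permutes DEG
#' directions `n_perm` times and returns the resulting profiles.
#'
#' @inheritParams coordination_permutation_test
#' @return List of `coordination_profile`s.
#' @export
null_coordination_profiles <- function(assignment, n_perm = 1000L,
                                       seed = NULL, min_degs = 2L) {
  d <- assignment[assignment$is_deg, c("tad", "direction")]
  if (!is.null(seed)) set.seed(seed)
  lapply(seq_len(n_perm), function(i)
    .coordination_profile(d$tad, sample(d$direction), min_degs))
}
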