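#' Sphere-sphere intersection volume
#'
#' Closed-form lens volume of two intersecting spheres: for centre distance
#' `d` with `|r1 - r2| < d < r1 + r2`,
#' `V = pi (r1 + r2 - d)^2 (d^2 + 2 d (r1 + r2) - 3 (r1 - r2)^2) / (12 d)`;
#' the smaller sphere's volume when one contains the other; 0 when disjoint.
#'
#' @param r1,r2 Radii (nm), vectorised.
#' @param d Centre-to-centre distances (nm).
#' @return Intersection volumes (nm^3).
#' @export
sphere_overlap_volume <- function(r1, r2, d) {
  stopifnot(all(r1 >= 0), all(r2 >= 0), all(d >= 0))
  n <- max(length(r1), length(r2), length(d))
  r1 <- rep_len(r1, n); r2 <- rep_len(r2, n); d <- rep_len(d, n)
  v <- numeric(n)
  contained <- d <= abs(r1 - r2)
  v[contained] <- 4 / 3 * pi * pmin(r1, r2)[contained]^3
  lens <- !contained & d < r1 + r2
  if (any(lens)) {
    dd <- d[lens]; a <- r1[lens]; b <- r2[lens]
    v[lens] <- pi * (a + b - dd)^2 *
      (dd^2 + 2 * dd * (a + b) - 3 * (a - b)^2) / (12 * dd)
  }
  v
}

.sphere_vol <- function(r) 4 / 3 * pi * r^3

#' Fraction of spatial overlap between two labelled domains
#'
#' The intersection volume normalised, by default, by the smaller domain's
#' volume (so identical domains score 1); the union or either single domain
#' can be used as denominator instead.
#'
#' @param m One allele measurement: list/one-row data frame with either
#'   sphere geometry (`ax..az`, `ar`, `bx..bz`, `br`) or precomputed
#'   `overlap_volume` plus `volume_a`, `volume_b`.
#' @param denominator `"smaller"` (default), `"union"`, `"a"` or `"b"`.
#' @return Overlap fraction in \[0, 1\].
#' @export
overlap_fraction <- function(m, denominator = c("smaller", "union", "a", "b")) {
  denominator <- match.arg(denominator)
  if (all(c("ar", "br") %in% names(m))) {
    d <- sqrt((m$ax - m$bx)^2 + (m$ay - m$by)^2 + (m$az - m$bz)^2)
    va <- .sphere_vol(m$ar); vb <- .sphere_vol(m$br)
    ov <- sphere_overlap_volume(m$ar, m$br, d)
  } else {
    va <- m$volume_a; vb <- m$volume_b; ov <- m$overlap_volume
  }
  if (any(va <= 0) || any(vb <= 0))
    stop("zero domain volume: overlap fraction undefined", call. = FALSE)
  den <- switch(denominator,
                smaller = pmin(va, vb),
                union = va + vb - ov,
                a = va, b = vb)
  ov / den
}

#' Contact call at a surface-separation cutoff
#'
#' Two domains are in contact when their surface-to-surface gap is at most
#' `cutoff_nm` (boundary inclusive); overlapping domains (negative gap)
#' always count as contact.
#'
#' @param boundary_gap_nm Surface-to-surface separations (nm; negative when
#'   overlapping).
#' @param cutoff_nm Contact cutoff (nm). Default 250.
#' @return Logical vector.
#' @export
call_contact <- function(boundary_gap_nm, cutoff_nm = 250) {
  boundary_gap_nm <= cutoff_nm
}

#' Contact frequency of a set of alleles
#'
#' @param measurements Data frame with `boundary_gap_nm` (e.g. from
#'   [read_fish_measurements()] or [simulate_fish_alleles()]).
#' @param cutoff_nm Contact cutoff (nm). Default 250.
#' @return Percent of alleles in contact.
#' @export
contact_frequency <- function(measurements, cutoff_nm = 250) {
  if (!nrow(measurements)) stop("no alleles", call. = FALSE)
  100 * mean(call_contact(measurements$boundary_gap_nm, cutoff_nm))
}

#' Change in contact frequency between two conditions
#'
#' @param condition,control Allele measurement tables for the perturbed and
#'   control conditions.
#' @inheritParams contact_frequency
#' @return Percentage-point change (condition minus control).
#' @export
contact_delta <- function(condition, control, cutoff_nm = 250) {
  contact_frequency(condition, cutoff_nm) - contact_frequency(control, cutoff_nm)
}

#' Compare two overlap-fraction distributions
#'
#' Two-sided Mann-Whitney (Wilcoxon rank-sum) test with mid-rank tie
#' handling, plus cumulative frequency curves of both samples on a shared
#' grid. A degenerate pooled sample (all values equal) yields p = 1 with a
#' warning.
#'
#' @param a,b Numeric samples (>= 2 each), e.g. per-allele overlap
#'   fractions.
#' @param grid_n Number of grid points for the cumulative curves.
#' @return List with `p`, `statistic` (rank-sum U), and `curves` (data
#'   frame: `x`, `cum_a`, `cum_b`).
#' @export
compare_overlap_distributions <- function(a, b, grid_n = 101L) {
  stopifnot(length(a) >= 2L, length(b) >= 2L)
  grid <- seq(min(a, b), max(a, b), length.out = grid_n)
  curves <- data.frame(x = grid,
                       cum_a = stats::ecdf(a)(grid),
                       cum_b = stats::ecdf(b)(grid))
  if (length(unique(c(a, b))) == 1L) {
    warning("degenerate samples: all pooled values equal, p = 1", call. = FALSE)
    return(list(p = 1, statistic = length(a) * length(b) / 2, curves = curves))
  }
  wt <- suppressWarnings(stats::wilcox.test(a, b, alternative = "two.sided"))
  list(p = wt$p.value, statistic = unname(wt$statistic), curves = curves)
}

# Fraction of a gene sphere's volume lying inside the union of two domain
# spheres, by deterministic midpoint-lattice integration over the gene
# sphere (resolution: lattice spacing r/n_half).
.inside_union_fraction <- function(gene, upstream, downstream, n_half = 16L) {
  r <- gene$r
  if (r <= 0) stop("gene sphere volume must be positive", call. = FALSE)
  step <- r / n_half
  g <- seq(-r + step / 2, r - step / 2, by = step)
  pts <- expand.grid(x = g, y = g, z = g)
  pts <- pts[pts$x^2 + pts$y^2 + pts$z^2 <= r^2, ]
  inside <- function(dom)
    (pts$x + gene$x - dom$x)^2 + (pts$y + gene$y - dom$y)^2 +
    (pts$z + gene$z - dom$z)^2 <= dom$r^2
  mean(inside(upstream) | inside(downstream))
}

#' Classify a gene-domain configuration as interacting or exclusion
#'
#' A gene signal is \emph{interacting} when the majority (> 0.5, strictly)
#' of its volume lies inside the union of the upstream and downstream
#' domains, \emph{exclusion} otherwise. Geometry is given as spheres
#' (`list(x, y, z, r)`, nm); alternatively a precomputed `inside_fraction`
#' can be supplied directly.
#'
#' @param gene_signal,upstream,downstream Sphere geometries
#'   (`list(x, y, z, r)`).
#' @param inside_fraction Optional precomputed fraction of the gene volume
#'   inside the union; when given, geometry arguments are ignored.
#' @return `"interacting"` or `"exclusion"`.
#' @export
classify_configuration <- function(gene_signal = NULL, upstream = NULL,
                                   downstream = NULL, inside_fraction = NULL) {
  if (is.null(inside_fraction))
    inside_fraction <- .inside_union_fraction(gene_signal, upstream, downstream)
  if (inside_fraction > 0.5) "interacting" else "exclusion"
}
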