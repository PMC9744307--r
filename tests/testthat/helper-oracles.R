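# Independent brute-force oracles used to validate the sampling-based and
# closed-form routes in the package. These deliberately re-derive each
# statistic from first principles (enumeration, quadrature) and share no code
# with the implementation.

# Exhaustive clustering permutation p: enumerate every placement of the k
# labels over the n universe genes and rank the observed mean per-TAD
# percentage against all of them.
oracle_clustering_p <- function(tad, labels) {
  stat <- function(lab) 100 * mean(tapply(lab, tad, mean))
  obs <- stat(labels)
  k <- sum(labels)
  combs <- utils::combn(length(labels), k)
  null <- apply(combs, 2, function(ix) {
    l <- rep(FALSE, length(labels)); l[ix] <- TRUE; stat(l)
  })
  mean(null >= obs)
}

# Exhaustive coordination permutation p over all re-assignments of the
# up/down multiset to the DEG slots (slots with TAD membership fixed).
oracle_coordination_p <- function(tad, dirs, min_degs = 2) {
  avg_coord <- function(dd) {
    by_tad <- split(dd, tad)
    by_tad <- by_tad[vapply(by_tad, length, 1L) >= min_degs]
    mean(vapply(by_tad, function(v) {
      u <- sum(v == "up"); 100 * max(u, length(v) - u) / length(v)
    }, numeric(1)))
  }
  obs <- avg_coord(dirs)
  k <- sum(dirs == "up")
  combs <- utils::combn(length(dirs), k)
  null <- apply(combs, 2, function(ix) {
    d <- rep("down", length(dirs)); d[ix] <- "up"; avg_coord(d)
  })
  mean(null >= obs)
}

# Upper hypergeometric tail by direct binomial-coefficient summation.
oracle_overlap_p <- function(n_a, n_b, n_overlap, universe) {
  ks <- n_overlap:min(n_a, n_b)
  sum(choose(n_a, ks) * choose(universe - n_a, n_b - ks)) / choose(universe, n_b)
}

# Exact two-sided Mann-Whitney p by enumerating every split of the pooled
# (tie-free) sample into the two groups.
oracle_mw_p <- function(a, b) {
  pooled <- c(a, b)
  stopifnot(!anyDuplicated(pooled))
  n <- length(a); m <- length(b)
  r <- rank(pooled)
  u_of <- function(ix) sum(r[ix]) - n * (n + 1) / 2
  u_obs <- u_of(seq_len(n))
  dev_obs <- abs(u_obs - n * m / 2)
  combs <- utils::combn(n + m, n)
  devs <- apply(combs, 2, function(ix) abs(u_of(ix) - n * m / 2))
  mean(devs >= dev_obs)
}

# Sphere-sphere lens volume by 1-D quadrature of the cross-section area.
oracle_lens_volume <- function(r1, r2, d) {
  f <- function(x) {
    rr <- pmin(r1^2 - x^2, r2^2 - (x - d)^2)
    pi * pmax(0, rr)
  }
  stats::integrate(f, max(-r1, d - r2), min(r1, d + r2),
                   rel.tol = 1e-10)$value
}

# Small fixture: a hand-built TAD assignment data frame in the layout
# assign_to_tads() produces.
make_assignment <- function(tad, is_deg, direction = NULL, active = TRUE) {
  n <- length(tad)
  structure(
    data.frame(gene_id = sprintf("g%03d", seq_len(n)),
               tad = tad,
               active = rep_len(active, n),
               is_deg = is_deg,
               direction = if (is.null(direction)) rep("none", n) else direction),
    class = c("tad_assignment", "data.frame"))
}

tmp_write <- function(lines, ext = ".txt") {
  p <- tempfile(fileext = ext)
  writeLines(lines, p)
  p
}
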