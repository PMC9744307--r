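test_that("nearest anchor distance is edge distance with inside = 0", {
  loops <- read_intervals(tmp_write("chr1\t2000\t3000\tchr1\t9000\t9500"), "BEDPE")
  tss <- data.frame(chrom = "chr1", tss = c(2500L, 1000L, 8700L))
  d <- nearest_anchor_distance(tss, loops)
  expect_equal(d[1], 0)      # inside the first anchor
  expect_equal(d[2], 1000)   # gap to [2000,3000)
  expect_equal(d[3], 300)    # nearer of the two anchors wins

  off <- data.frame(chrom = "chrX", tss = 5L)
  expect_true(is.na(nearest_anchor_distance(off, loops)))
})

test_that("proximity enrichment builds the expected 2x2 and Fisher p-values", {
  same <- c(0, 0, 1e6, 1e6)
  res <- proximity_enrichment(same, same, threshold = 5000)
  expect_equal(res$odds_ratio, 1)
  expect_equal(res$p_two_sided, 1)

  # derived example: a = {0,0,0,1e6}, b = {1e6 x4} -> table (3,1,0,4)
  a <- c(0, 0, 0, 1e6); b <- rep(1e6, 4)
  res <- proximity_enrichment(a, b, threshold = 5000)
  expect_equal(unname(res$table), matrix(c(3, 1, 0, 4), 2))
  # one-sided p by exhaustive hypergeometric sum: P(X >= 3) with margins
  # (near = 3, group_a = 4, N = 8) = C(4,3) C(4,0) / C(8,3)
  expect_equal(res$p, choose(4, 3) / choose(8, 3), tolerance = 1e-12)

  # swapping groups inverts the odds ratio, preserves the two-sided p
  r1 <- proximity_enrichment(c(0, 0, 1e6), c(0, 1e6, 1e6), 5000)
  r2 <- proximity_enrichment(c(0, 1e6, 1e6), c(0, 0, 1e6), 5000)
  expect_equal(r1$odds_ratio, 1 / r2$odds_ratio, tolerance = 1e-6)
  expect_equal(r1$p_two_sided, r2$p_two_sided)

  # NA distances (no anchor on the chromosome) count as far
  expect_equal(unname(proximity_enrichment(c(0, NA), c(NA, NA), 5000)$table),
               matrix(c(1, 1, 0, 2), 2))
  expect_error(proximity_enrichment(numeric(), c(1)), "non-empty")
})

test_that("proximity summary fractions reproduce direct counts at both thresholds", {
  set.seed(61)
  d_deg <- c(runif(300, 0, 4000), runif(500, 6000, 150000), runif(200, 2.5e5, 2e6))
  d_non <- runif(1000, 0, 2e6)
  res5 <- proximity_enrichment(d_deg, d_non, threshold = 5000)
  expect_equal(unname(res5$near_fraction["group_a"]), mean(d_deg <= 5000))
  res200 <- proximity_enrichment(d_deg, d_non, threshold = 2e5)
  expect_equal(unname(res200$near_fraction["group_a"]), mean(d_deg <= 2e5))
  expect_equal(unname(res200$near_fraction["group_a"]), 0.8)
})

test_that("distance-fold-change correlation uses mid-ranks and magnitude", {
  d <- c(10, 20, 30, 40, 50)
  fc <- c(5, 4, 3, 2, 1)
  expect_equal(distance_fc_correlation(d, fc)$rho, -1)

  # hand-ranked 6-pair instance with ties
  d6 <- c(1, 2, 2, 3, 4, 5)
  f6 <- c(0.5, -0.4, 0.4, 0.3, 0.3, 0.1)
  got <- distance_fc_correlation(d6, f6)
  expect_equal(got$rho, cor(rank(d6), rank(abs(f6))), tolerance = 1e-12)

  # signed mode correlates the raw fold change
  expect_equal(distance_fc_correlation(d6, f6, signed = TRUE)$rho,
               cor(rank(d6), rank(f6)), tolerance = 1e-12)

  # independent inputs: small |rho|
  set.seed(62)
  expect_lt(abs(distance_fc_correlation(runif(1000), rnorm(1000))$rho), 0.1)

  expect_error(distance_fc_correlation(rep(1, 5), rnorm(5)), "constant")
  expect_error(distance_fc_correlation(1:3, rnorm(3)), ">= 4")
})

test_that("gene-set overlap test equals the upper hypergeometric tail", {
  expect_equal(fisher_overlap(2, 2, 2, 4)$p, 1 / 6, tolerance = 1e-12)

  set.seed(63)
  for (i in 1:10) {
    u <- sample(10:50, 1)
    na <- sample(2:(u - 2), 1)
    nb <- sample(2:(u - 2), 1)
    k <- sample(max(0, na + nb - u):min(na, nb), 1)
    got <- fisher_overlap(na, nb, k, u)$p
    expect_equal(got, oracle_overlap_p(na, nb, k, u), tolerance = 1e-9)
  }

  expect_error(fisher_overlap(5, 5, 6, 100), "n_overlap")
  expect_error(fisher_overlap(60, 60, 0, 100), "universe")
})

test_that("shared-direction concordance counts intersecting DEGs", {
  a <- as_deg_table(data.frame(gene_id = sprintf("g%02d", 1:12),
                               log2fc = c(rep(1, 9), rep(-1, 3)),
                               padj = c(rep(0.001, 10), 0.5, 0.5)))
  b <- as_deg_table(data.frame(gene_id = sprintf("g%02d", 3:14),
                               log2fc = c(rep(1, 5), rep(-1, 7)),
                               padj = rep(0.001, 12)))
  got <- shared_direction(a, b)
  expect_equal(got$n_shared, 8L)   # g03..g10 are DEGs in both
  # g03..g07 up/up (5); g08,g09 a up vs b down; g10 down/down (1)
  expect_equal(got$n_same_direction, 6L)
  expect_equal(got$fraction, 6 / 8)

  disjoint <- shared_direction(a, as_deg_table(
    data.frame(gene_id = "zz", log2fc = 1, padj = 0.001)))
  expect_equal(disjoint$n_shared, 0L)
  expect_true(is.na(disjoint$fraction))

  ident <- shared_direction(a, a)
  expect_equal(ident$fraction, 1)
})
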