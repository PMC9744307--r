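test_that("TAD assignment uses half-open containment and counts exclusions", {
  tads <- read_intervals(tmp_write(c("chr1\t100\t200", "chr1\t300\t400")), "BED")
  genes <- data.frame(gene_id = sprintf("g%d", 1:4),
                      chrom = "chr1",
                      tss = c(150L, 200L, 350L, 500L))
  a <- assign_to_tads(genes, tads)
  expect_equal(a$gene_id, c("g1", "g3"))   # 200 is outside [100,200)
  expect_equal(a$tad, c(1L, 2L))
  expect_equal(attr(a, "n_excluded"), 2L)

  ovl <- read_intervals(tmp_write(c("chr1\t100\t200", "chr1\t150\t400")), "BED")
  expect_error(assign_to_tads(genes, ovl), "overlap")
})

test_that("clustering statistic is the unweighted mean of per-TAD DEG percentages", {
  a <- make_assignment(tad = c(1, 1, 2, 2),
                       is_deg = c(TRUE, FALSE, FALSE, FALSE))
  expect_equal(clustering_statistic(a), 25)  # mean of 50% and 0%

  all_deg <- make_assignment(tad = c(1, 1, 2), is_deg = rep(TRUE, 3))
  expect_equal(clustering_statistic(all_deg), 100)

  a3 <- make_assignment(tad = rep(1:3, c(2, 4, 10)),
                        is_deg = c(TRUE, FALSE,
                                   TRUE, rep(FALSE, 3),
                                   TRUE, rep(FALSE, 9)))
  expect_equal(clustering_statistic(a3), mean(c(50, 25, 10)))

  # invariance under TAD relabeling and gene order
  relab <- a3
  relab$tad <- c(7L, 2L, 9L)[relab$tad]
  expect_equal(clustering_statistic(relab[sample(nrow(relab)), ]),
               clustering_statistic(a3))
})

test_that("clustering permutation test matches exhaustive enumeration on small instances", {
  # fixed tiny instance: 6 genes, 2 TADs, 2 DEGs -> C(6,2) = 15 labelings
  tad <- c(1, 1, 1, 2, 2, 2)
  lab <- c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE)
  a <- make_assignment(tad, lab)
  p_exact <- oracle_clustering_p(tad, lab)
  res <- clustering_permutation_test(a, n_perm = 4000, seed = 31)
  expect_lt(abs(res$p - p_exact), 0.04)

  # randomized instances with <= 8 genes
  set.seed(32)
  for (i in 1:6) {
    n <- sample(5:8, 1)
    tad <- sort(sample(1:3, n, replace = TRUE))
    k <- sample(seq_len(n - 1), 1)
    lab <- seq_len(n) %in% sample(n, k)
    a <- make_assignment(tad, lab)
    res <- clustering_permutation_test(a, n_perm = 4000, seed = 33 + i)
    expect_lt(abs(res$p - oracle_clustering_p(tad, lab)), 0.05)
  }

  expect_error(clustering_permutation_test(
    make_assignment(c(1, 2), c(TRUE, TRUE))), "degenerate")
})

test_that("permutation machinery flags strong clustering into gene-poor TADs", {
  g <- simulate_genome(genome_sim_spec(50, c(rep(4, 5), rep(20, 45)),
                                       gene_count_model = "exact", seed = 34))
  d <- simulate_deg_table(g$genes, g$tads,
                          deg_sim_spec(deg_rate = 20 / nrow(g$genes),
                                       clustering_weight = Inf,
                                       clustered_frac = 0.1, seed = 35))
  a <- assign_to_tads(g$genes, g$tads, degs = d)
  res <- clustering_permutation_test(a, n_perm = 1000, seed = 36)
  expect_equal(res$p, 0)
})

test_that("null mean of the clustering statistic equals the global DEG fraction", {
  # with equal TAD sizes the hypergeometric expectation per TAD is the
  # global rate, and the statistic is in fact permutation-invariant
  g <- simulate_genome(genome_sim_spec(20, 10, gene_count_model = "exact", seed = 37))
  d <- simulate_deg_table(g$genes, g$tads, deg_sim_spec(deg_rate = 0.15, seed = 38))
  a <- assign_to_tads(g$genes, g$tads, degs = d)
  res <- clustering_permutation_test(a, n_perm = 50, seed = 39)
  global_pct <- 100 * sum(a$is_deg) / nrow(a)
  expect_equal(mean(res$null), global_pct, tolerance = 1e-10)
  expect_equal(res$observed, global_pct, tolerance = 1e-10)
})

test_that("coordination score is the majority fraction", {
  expect_equal(coordination_score(rep("down", 6)), 100)
  expect_equal(coordination_score(c("up", "down")), 50)
  expect_equal(coordination_score(c("up", "up", "up", "down")), 75)
  expect_error(coordination_score("up"), ">= 2")
})

test_that("average coordination bins and averages per-TAD scores", {
  a <- make_assignment(tad = c(1, 1, 1, 2, 2),
                       is_deg = rep(TRUE, 5),
                       direction = c("up", "up", "up", "up", "down"))
  prof <- average_coordination(a)
  expect_equal(prof$average, 75)
  expect_equal(unname(prof$bin_counts), c(1L, 0L, 0L, 0L, 1L))
  expect_equal(sum(prof$bin_counts), prof$n_tads)

  solo <- make_assignment(tad = c(1, 2), is_deg = c(TRUE, TRUE),
                          direction = c("up", "up"))
  expect_error(average_coordination(solo), ">= 2")
})

test_that("average coordination recovers the closed-form majority-fraction mean", {
  # 500 TADs x 6 DEGs at coordination 0.9; oracle is the analytic mean of
  # the majority fraction of Binomial(6, 0.9)
  set.seed(41)
  n_tads <- 500; m <- 6
  ups <- rbinom(n_tads, m, 0.9)
  dirs <- unlist(lapply(ups, function(u) c(rep("up", u), rep("down", m - u))))
  a <- make_assignment(tad = rep(seq_len(n_tads), each = m),
                       is_deg = TRUE, direction = dirs)
  analytic <- 100 * sum(dbinom(0:m, m, 0.9) * pmax(0:m, m - (0:m))) / m
  expect_lt(abs(average_coordination(a)$average - analytic), 2)
})

test_that("coordination permutation test matches exhaustive enumeration", {
  # two TADs of two DEGs; 2 up / 2 down -> 6 distinct direction assignments
  tad <- c(1, 1, 2, 2)
  dirs <- c("up", "up", "down", "down")
  a <- make_assignment(tad, rep(TRUE, 4), dirs)
  res <- coordination_permutation_test(a, n_perm = 3000, seed = 42)
  expect_lt(abs(res$p - oracle_coordination_p(tad, dirs)), 0.05)

  # the (up,down)+(up,down) arrangement is the least coordinated: p = 1
  a2 <- make_assignment(tad, rep(TRUE, 4), c("up", "down", "up", "down"))
  res2 <- coordination_permutation_test(a2, n_perm = 500, seed = 43)
  expect_equal(res2$p, 1)

  # all DEGs one direction: permutation cannot vary
  a3 <- make_assignment(tad, rep(TRUE, 4), rep("up", 4))
  expect_warning(res3 <- coordination_permutation_test(a3, n_perm = 50, seed = 44),
                 "cannot vary")
  expect_equal(res3$p, 1)

  # strong coordination in a sizable genome: p = 0
  g <- simulate_genome(genome_sim_spec(40, 8, seed = 45))
  d <- simulate_deg_table(g$genes, g$tads,
                          deg_sim_spec(deg_rate = 0.4, coordination = 0.95, seed = 46))
  a4 <- assign_to_tads(g$genes, g$tads, degs = d)
  expect_equal(coordination_permutation_test(a4, n_perm = 1000, seed = 47)$p, 0)
})

test_that("permutation results are reproducible bit-for-bit given a seed", {
  g <- simulate_genome(genome_sim_spec(15, 6, seed = 48))
  d <- simulate_deg_table(g$genes, g$tads, deg_sim_spec(deg_rate = 0.3, seed = 49))
  a <- assign_to_tads(g$genes, g$tads, degs = d)
  r1 <- clustering_permutation_test(a, n_perm = 100, seed = 50)
  r2 <- clustering_permutation_test(a, n_perm = 100, seed = 50)
  expect_identical(r1, r2)
  c1 <- coordination_permutation_test(a, n_perm = 100, seed = 51)
  c2 <- coordination_permutation_test(a, n_perm = 100, seed = 51)
  expect_identical(c1, c2)
})

test_that("bin comparison reports per-bin enrichment and depletion ranks", {
  mkprof <- function(scores) {
    a <- make_assignment(tad = rep(seq_along(scores), each = 2),
                         is_deg = TRUE,
                         direction = unlist(lapply(scores, function(s)
                           if (s == 100) c("up", "up") else c("up", "down"))))
    average_coordination(a)
  }
  obs <- mkprof(rep(100, 6))             # all TADs in the 90-100 bin
  nulls <- replicate(40, mkprof(rep(50, 6)), simplify = FALSE)
  cmp <- coordination_bin_comparison(obs, nulls)
  expect_equal(cmp$p_enrich[cmp$bin == "90-100"], 0)
  expect_equal(cmp$p_deplete[cmp$bin == "50-60"], 0)
  # single-bin degenerate null: ranks only 0 or 1
  expect_true(all(cmp$p_enrich %in% c(0, 1)))

  bad <- obs
  names(bad$bin_counts)[1] <- "0-10"
  expect_error(coordination_bin_comparison(bad, nulls), "bin mismatch")
})

test_that("observed drawn from the null generator is not flagged in any bin", {
  g <- simulate_genome(genome_sim_spec(30, 8, seed = 52))
  d <- simulate_deg_table(g$genes, g$tads,
                          deg_sim_spec(deg_rate = 0.4, coordination = 0.5, seed = 53))
  a <- assign_to_tads(g$genes, g$tads, degs = d)
  obs <- average_coordination(a)
  nulls <- null_coordination_profiles(a, n_perm = 300, seed = 54)
  cmp <- coordination_bin_comparison(obs, nulls)
  expect_true(all(pmin(cmp$p_enrich, cmp$p_deplete) > 0.01))
})
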