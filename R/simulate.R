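#' Specification for a synthetic TAD genome
#'
#' Defines a single-chromosome genome partitioned into non-overlapping TADs
#' separated by gaps, with genes whose TSSs fall strictly inside a TAD.
#'
#' @param n_tads Number of TADs.
#' @param genes_per_tad Mean genes per TAD (scalar), or a vector of exact
#'   per-TAD gene counts (recycled to `n_tads`); see `gene_count_model`.
#' @param tad_length_bp TAD length in bp. Default 1e6 (the scale of the
#'   TADs highlighted in cohesin-perturbation work).
#' @param inter_tad_gap_bp Gap between consecutive TADs. Default 1e5.
#' @param gene_count_model `"poisson"`: per-TAD counts are
#'   `1 + Poisson(genes_per_tad - 1)` (always >= 1); `"exact"`: counts are
#'   taken from `genes_per_tad` verbatim.
#' @param seed Integer seed.
#' @return A `genome_sim_spec` list.
#' @export
genome_sim_spec <- function(n_tads, genes_per_tad, tad_length_bp = 1e6,
                            inter_tad_gap_bp = 1e5,
                            gene_count_model = c("poisson", "exact"),
                            seed = 1L) {
  gene_count_model <- match.arg(gene_count_model)
  stopifnot(n_tads >= 1, all(genes_per_tad >= 1), tad_length_bp > 0,
            inter_tad_gap_bp > 0)
  structure(list(n_tads = as.integer(n_tads), genes_per_tad = genes_per_tad,
                 tad_length_bp = tad_length_bp,
                 inter_tad_gap_bp = inter_tad_gap_bp,
                 gene_count_model = gene_count_model,
                 seed = as.integer(seed)),
            class = "genome_sim_spec")
}

#' Simulate a TAD genome with transcript annotation
#'
#' Generates `n_tads` non-overlapping TADs on one chromosome and, per TAD,
#' the specified number of genes. Every gene carries 1-3 transcripts sharing
#' its gene id; extra transcripts either reuse the gene TSS exactly (to
#' exercise dominant-TSS tie-breaking) or shift it within the TAD. All
#' output is reproducible from the spec's seed.
#'
#' @param spec A [genome_sim_spec()].
#' @return List with `tads` (`GRanges`), `genes` (one row per gene:
#'   `gene_id`, `chrom`, `tss`, `strand`, `tad`) and `transcripts`
#'   (annotation table as in [read_annotation()]).
#' @export
simulate_genome <- function(spec) {
  stopifnot(inherits(spec, "genome_sim_spec"))
  set.seed(spec$seed)
  n <- spec$n_tads
  len <- spec$tad_length_bp; gap <- spec$inter_tad_gap_bp
  starts <- (seq_len(n) - 1) * (len + gap)
  tads <- GenomicRanges::GRanges("chr1", IRanges::IRanges(starts + 1, starts + len))
  counts <- if (spec$gene_count_model == "poisson")
    1L + stats::rpois(n, max(0, mean(spec$genes_per_tad) - 1))
  else as.integer(rep_len(spec$genes_per_tad, n))
  n_genes <- sum(counts)
  tad_of <- rep(seq_len(n), counts)
  tss <- unlist(lapply(seq_len(n), function(i) {
    if (counts[i] == 0L) return(integer())
    sort(sample(seq(starts[i] + 1, starts[i] + len - 2), counts[i]))
  }))
  genes <- data.frame(gene_id = sprintf("ENSG%06d", seq_len(n_genes)),
                      chrom = "chr1",
                      tss = as.integer(tss),
                      strand = sample(c("+", "-"), n_genes, replace = TRUE),
                      tad = tad_of)
  tx <- lapply(seq_len(n_genes), function(g) {
    k <- sample(1:3, 1L)
    tss_g <- genes$tss[g]
    lo <- starts[tad_of[g]] + 1; hi <- starts[tad_of[g]] + len - 2
    extra <- if (k > 1L)
      ifelse(stats::runif(k - 1L) < 0.5, tss_g,
             pmin(hi, pmax(lo, tss_g + sample(c(-1, 1), k - 1L, TRUE) *
                                   sample(200:2000, k - 1L, TRUE))))
    else integer()
    data.frame(gene_id = genes$gene_id[g],
               transcript_id = sprintf("ENST%06d%02d", g, seq_len(k)),
               chrom = "chr1",
               tss = as.integer(c(tss_g, extra)),
               strand = genes$strand[g],
               transcript_length = sample(500:5000, k, replace = TRUE))
  })
  list(tads = tads, genes = genes, transcripts = do.call(rbind, tx))
}

#' Specification for a synthetic differential-expression table
#'
#' @param deg_rate Fraction of genes that are DEGs, in (0, 1).
#' @param clustering_weight Sampling-weight multiplier (>= 1) concentrating
#'   DEG labels into the designated TAD subset; 1 = uniform placement
#'   (null); `Inf` confines all DEGs to the designated TADs.
#' @param coordination Probability that a DEG adopts its TAD's latent
#'   majority direction, in \[0.5, 1\]; 0.5 = random directions (null).
#' @param lfc_scale Dispersion (SD) of DEG log2 fold-change magnitudes.
#' @param clustered_frac Fraction of TADs designated for clustering; the
#'   gene-poorest TADs are designated (clustering of DEGs into gene-poor
#'   TADs is the regime the per-TAD-fraction statistic detects). Default
#'   0.1.
#' @param alpha Significance threshold used to draw adjusted p-values: DEGs
#'   get `padj` log-uniform on (0, alpha], others uniform on (alpha, 1\].
#' @param seed Integer seed.
#' @return A `deg_sim_spec` list.
#' @export
deg_sim_spec <- function(deg_rate = 0.1, clustering_weight = 1,
                         coordination = 0.9, lfc_scale = 0.5,
                         clustered_frac = 0.1, alpha = 0.01, seed = 1L) {
  stopifnot(deg_rate > 0, deg_rate < 1, clustering_weight >= 1)
  if (coordination < 0.5 || coordination > 1)
    stop("coordination must lie in [0.5, 1]", call. = FALSE)
  structure(list(deg_rate = deg_rate, clustering_weight = clustering_weight,
                 coordination = coordination, lfc_scale = lfc_scale,
                 clustered_frac = clustered_frac, alpha = alpha,
                 seed = as.integer(seed)),
            class = "deg_sim_spec")
}

#' Simulate a DEG table with tunable TAD clustering and coordination
#'
#' Draws exactly `round(deg_rate * n_genes)` DEG labels over the genes,
#' weighted toward the designated (gene-poorest) `clustered_frac` of TADs by
#' `clustering_weight`. Each TAD carries a latent direction; each DEG
#' adopts it with probability `coordination`, otherwise the opposite.
#' Adjusted p-values respect the threshold by construction.
#'
#' @param genes Gene table from [simulate_genome()] (needs `gene_id`,
#'   `tad`).
#' @param tads `GRanges` of TADs (used only for the designated-subset size).
#' @param spec A [deg_sim_spec()].
#' @return DEG table ([as_deg_table()] layout) in gene order.
#' @export
simulate_deg_table <- function(genes, tads, spec) {
  stopifnot(inherits(spec, "deg_sim_spec"))
  set.seed(spec$seed)
  n_genes <- nrow(genes)
  n_deg <- round(spec$deg_rate * n_genes)
  n_tads <- length(tads)
  n_desig <- max(1L, ceiling(spec$clustered_frac * n_tads))
  tad_sizes <- table(factor(genes$tad, levels = seq_len(n_tads)))
  designated <- order(as.integer(tad_sizes), seq_len(n_tads))[seq_len(n_desig)]
  in_desig <- genes$tad %in% designated
  if (is.infinite(spec$clustering_weight)) {
    if (sum(in_desig) < n_deg)
      stop("designated TADs hold fewer genes than DEG labels to place",
           call. = FALSE)
    deg_idx <- sample(which(in_desig), n_deg)
  } else {
    w <- ifelse(in_desig, spec$clustering_weight, 1)
    deg_idx <- sample(n_genes, n_deg, prob = w)
  }
  is_deg <- seq_len(n_genes) %in% deg_idx
  latent <- sample(c(1, -1), n_tads, replace = TRUE)
  adopt <- stats::runif(n_genes) < spec$coordination
  dir_sign <- ifelse(adopt, latent[genes$tad], -latent[genes$tad])
  lfc <- ifelse(is_deg,
                dir_sign * (abs(stats::rnorm(n_genes, 0, spec$lfc_scale)) + 0.05),
                stats::rnorm(n_genes, 0, spec$lfc_scale / 4))
  padj <- ifelse(is_deg,
                 10^stats::runif(n_genes, -8, log10(spec$alpha)),
                 stats::runif(n_genes, spec$alpha + 1e-9, 1))
  as_deg_table(data.frame(gene_id = genes$gene_id, log2fc = lfc, padj = padj),
               alpha = spec$alpha)
}

#' Simulate a double-knockdown table with known rescue fractions
#'
#' Starting from a single-knockdown table, a designated `frac_full` of its
#' DEGs lose significance (`padj > alpha`), a designated `frac_partial`
#' remain significant with the same sign but strictly diminished
#' `|log2fc|`, and the remainder are left unchanged (hence classified not
#' rescued). Non-DEG rows pass through untouched.
#'
#' @param single DEG table ([as_deg_table()]).
#' @param frac_full,frac_partial Fractions of single-knockdown DEGs to
#'   rescue fully / partially; their sum must be <= 1.
#' @param alpha Significance threshold. Default 0.01.
#' @param seed Integer seed.
#' @return Double-knockdown DEG table, same gene order as `single`.
#' @export
simulate_double_kd <- function(single, frac_full, frac_partial,
                               alpha = 0.01, seed = 1L) {
  stopifnot(frac_full >= 0, frac_partial >= 0, frac_full + frac_partial <= 1)
  set.seed(seed)
  out <- single[, c("gene_id", "log2fc", "padj")]
  deg_idx <- which(single$is_deg)
  n <- length(deg_idx)
  n_full <- round(frac_full * n)
  n_part <- round(frac_partial * n)
  pick <- sample(deg_idx)
  full <- pick[seq_len(n_full)]
  part <- pick[n_full + seq_len(n_part)]
  out$padj[full] <- stats::runif(n_full, alpha + 1e-9, 1)
  out$log2fc[full] <- out$log2fc[full] * stats::runif(n_full, 0, 0.2)
  out$padj[part] <- 10^stats::runif(n_part, -8, log10(alpha))
  out$log2fc[part] <- out$log2fc[part] * stats::runif(n_part, 0.2, 0.8)
  as_deg_table(out, alpha = alpha)
}

#' Simulate PRO-seq 3'-end signal over promoter windows
#'
#' A designated `active_fraction` of genes receive a negative-binomial
#' promoter-window total with the stated mean at their first annotated
#' transcript; all other transcripts receive small totals capped at 9 (below
#' the default activity threshold). Totals are spread multinomially over the
#' single-base positions of the strand-aware window.
#'
#' @param transcripts Annotation table ([simulate_genome()]'s
#'   `$transcripts`).
#' @param active_fraction Fraction of genes transcribed, in \[0, 1\].
#' @param mean_count Expected window total for an active TSS.
#' @param window Window width, nt. Default 150.
#' @param nb_size Negative-binomial size (dispersion) parameter. Default 5.
#' @param seed Integer seed.
#' @return A [signal_track()].
#' @export
simulate_proseq_track <- function(transcripts, active_fraction, mean_count,
                                  window = 150L, nb_size = 5, seed = 1L) {
  stopifnot(mean_count > 0, active_fraction >= 0, active_fraction <= 1)
  set.seed(seed)
  genes <- unique(transcripts$gene_id)
  n_active <- round(active_fraction * length(genes))
  active_genes <- sample(genes, n_active)
  first_tx <- transcripts$transcript_id[!duplicated(transcripts$gene_id)]
  totals <- ifelse(transcripts$gene_id %in% active_genes &
                     transcripts$transcript_id %in% first_tx,
                   stats::rnbinom(nrow(transcripts), mu = mean_count, size = nb_size),
                   pmin(stats::rpois(nrow(transcripts), 2), 9L))
  rows <- lapply(which(totals > 0), function(i) {
    tot <- totals[i]
    offs <- sample(0:window, tot, replace = TRUE)
    pos <- if (transcripts$strand[i] == "+") transcripts$tss[i] + offs
           else transcripts$tss[i] - offs
    data.frame(chrom = transcripts$chrom[i], pos = pos,
               strand = transcripts$strand[i])
  })
  if (!length(rows)) return(signal_track())
  dt <- data.table::as.data.table(do.call(rbind, rows))
  dt <- dt[, list(count = .N), by = c("strand", "chrom", "pos")]
  signal_track(dt[dt$strand == "+", c("chrom", "pos", "count")],
               dt[dt$strand == "-", c("chrom", "pos", "count")])
}

#' Simulate per-allele FISH domain geometries
#'
#' Each allele carries two domain spheres of radius `radius_nm`. With
#' probability `contact_prob` their surface gap is drawn at or below the
#' contact cutoff (allowing spatial overlap); otherwise beyond it, with mean
#' excess separation `sep_mean_nm`. Overlap volumes come from the
#' closed-form sphere intersection.
#'
#' @param n_alleles Number of alleles.
#' @param contact_prob Probability of contact, in \[0, 1\].
#' @param sep_mean_nm Mean surface gap beyond the cutoff for non-contact
#'   alleles (nm). Default 400.
#' @param radius_nm Domain sphere radius (nm). Default 400.
#' @param cutoff_nm Contact cutoff (nm). Default 250.
#' @param condition Condition label stored per allele. Default `"sim"`.
#' @param seed Integer seed.
#' @return Allele measurement table (sphere geometry plus
#'   `boundary_gap_nm`, `overlap_volume`).
#' @export
simulate_fish_alleles <- function(n_alleles, contact_prob, sep_mean_nm = 400,
                                  radius_nm = 400, cutoff_nm = 250,
                                  condition = "sim", seed = 1L) {
  stopifnot(contact_prob >= 0, contact_prob <= 1, n_alleles >= 1)
  set.seed(seed)
  in_contact <- stats::runif(n_alleles) < contact_prob
  lower <- if (radius_nm > 0) -1.5 * radius_nm else 0
  gap <- ifelse(in_contact,
                stats::runif(n_alleles, lower, cutoff_nm),
                cutoff_nm + 1e-6 + stats::rexp(n_alleles, 1 / sep_mean_nm))
  d <- pmax(0, gap + 2 * radius_nm)
  df <- data.frame(allele_id = sprintf("a%05d", seq_len(n_alleles)),
                   condition = condition,
                   ax = 0, ay = 0, az = 0, ar = radius_nm,
                   bx = d, by = 0, bz = 0, br = radius_nm)
  df$boundary_gap_nm <- d - 2 * radius_nm
  df$overlap_volume <- sphere_overlap_volume(radius_nm, radius_nm, d)
  df
}
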