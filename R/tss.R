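#' Promoter-window 3'-end count for one transcript
#'
#' Sums strand-matched 3' end counts over the promoter window. On the plus
#' strand the window covers positions `tss` to `tss + window` inclusive (151
#' positions at the default 150 nt); on the minus strand it mirrors to
#' `tss - window` to `tss`. A chromosome absent from the track yields 0 with
#' a warning.
#'
#' @param track A [signal_track()].
#' @param transcript One-row data frame (or list) with `chrom`, `tss`,
#'   `strand`.
#' @param window Window width in nt downstream of the TSS. Default 150.
#' @return Integer count.
#' @export
tss_window_count <- function(track, transcript, window = 150L) {
  stopifnot(inherits(track, "signal_track"), window > 0)
  strand <- transcript$strand
  stopifnot(strand %in% c("+", "-"))
  side <- if (strand == "+") track$plus else track$minus
  tss <- transcript$tss
  lo <- if (strand == "+") tss else tss - window
  hi <- if (strand == "+") tss + window else tss
  if (nrow(side) == 0L || !any(side$chrom == transcript$chrom)) {
    if (nrow(track$plus) + nrow(track$minus) > 0L)
      warning("chromosome '", transcript$chrom, "' absent from signal track; count 0",
              call. = FALSE)
    return(0L)
  }
  sel <- side[side$chrom == transcript$chrom & side$pos >= lo & side$pos <= hi, ]
  as.integer(sum(sel$count))
}

# Vectorised window counts for an annotation table; one pass per strand.
.window_counts <- function(track, annotation, window) {
  counts <- integer(nrow(annotation))
  for (str in c("+", "-")) {
    idx <- which(annotation$strand == str)
    if (!length(idx)) next
    side <- if (str == "+") track$plus else track$minus
    if (nrow(side) == 0L) next
    lo <- if (str == "+") annotation$tss[idx] else annotation$tss[idx] - window
    hi <- lo + window
    for (ch in unique(annotation$chrom[idx])) {
      jdx <- idx[annotation$chrom[idx] == ch]
      sub <- side[side$chrom == ch, ]
      if (nrow(sub) == 0L) next
      cum <- c(0, cumsum(sub$count))
      a <- findInterval(lo[match(jdx, idx)] - 1L, sub$pos)
      b <- findInterval(hi[match(jdx, idx)], sub$pos)
      counts[jdx] <- as.integer(cum[b + 1L] - cum[a + 1L])
    }
  }
  counts
}

#' Activity call from promoter-window counts
#'
#' A TSS is active when its window count reaches `min_count` (default 10,
#' i.e. counts of 9 or fewer are inactive).
#'
#' @param counts Integer vector of window counts.
#' @param min_count Activity threshold (>= 1).
#' @return Logical vector.
#' @export
call_active <- function(counts, min_count = 10L) {
  stopifnot(min_count >= 1)
  counts >= min_count
}

# numeric portion of an identifier such as "ENSG000010" -> 10
.id_numeric <- function(id) {
  num <- suppressWarnings(as.numeric(gsub("[^0-9]", "", id)))
  ifelse(is.na(num), Inf, num)
}

#' Select the dominant TSS among one gene's active transcripts
#'
#' Deterministic total order: (1) highest promoter-window count; (2) among
#' ties, the TSS furthest upstream in a strand-aware sense (smallest
#' coordinate on `+`, largest on `-`); (3) among equal start positions, the
#' longest annotated transcript; (4) the lowest numeric portion of the gene
#' identifier. A final comparison on the numeric portion of the transcript
#' identifier makes the order total for transcripts of a single gene, where
#' rule (4) cannot discriminate. The result is independent of input order.
#'
#' @param transcripts Data frame of active transcripts (columns `gene_id`,
#'   `transcript_id`, `chrom`, `tss`, `strand`, `transcript_length`) with a
#'   `window_count` column.
#' @return The selected row, as a one-row data frame.
#' @export
select_dominant <- function(transcripts) {
  if (nrow(transcripts) == 0L) stop("no active TSS", call. = FALSE)
  upstream <- ifelse(transcripts$strand == "+", transcripts$tss, -transcripts$tss)
  ord <- order(-transcripts$window_count,
               upstream,
               -transcripts$transcript_length,
               .id_numeric(transcripts$gene_id),
               .id_numeric(transcripts$transcript_id))
  transcripts[ord[1L], , drop = FALSE]
}

#' Call one dominant TSS per gene from 3'-end signal
#'
#' Counts 3' ends in each transcript's promoter window, drops inactive TSSs
#' (window count below `min_count`), and collapses the remaining TSSs of each
#' gene to a single dominant call via [select_dominant()]. Genes with no
#' active transcript are absent from the calls and listed separately.
#' Dominant TSSs of different genes sharing the same start position are kept
#' (one call per gene) but flagged in `shared_start`.
#'
#' @param track A [signal_track()] (pool samples first with
#'   [sum_signal_tracks()]).
#' @param annotation Transcript table (see [read_annotation()]).
#' @param window Promoter window width, nt. Default 150.
#' @param min_count Activity threshold. Default 10.
#' @return List with `calls` (one row per gene with >= 1 active TSS: gene,
#'   dominant transcript, TSS, strand, `window_count`, `active`,
#'   `shared_start`) and `inactive_genes` (character vector).
#' @export
call_dominant_tss <- function(track, annotation, window = 150L, min_count = 10L) {
  stopifnot(inherits(track, "signal_track"))
  annotation <- as.data.frame(annotation)
  annotation$window_count <- .window_counts(track, annotation, window)
  annotation$active <- call_active(annotation$window_count, min_count)
  act <- annotation[annotation$active, , drop = FALSE]
  genes <- unique(annotation$gene_id)
  if (nrow(act) == 0L) {
    return(list(calls = act[, c("gene_id", "transcript_id", "chrom", "tss",
                                "strand", "window_count", "active")],
                inactive_genes = genes))
  }
  calls <- do.call(rbind, lapply(split(act, act$gene_id), select_dominant))
  calls <- calls[order(match(calls$gene_id, genes)), , drop = FALSE]
  rownames(calls) <- NULL
  key <- paste(calls$chrom, calls$tss)
  calls$shared_start <- key %in% key[duplicated(key)]
  list(calls = calls[, c("gene_id", "transcript_id", "chrom", "tss", "strand",
                         "transcript_length", "window_count", "active",
                         "shared_start")],
       inactive_genes = setdiff(genes, calls$gene_id))
}
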