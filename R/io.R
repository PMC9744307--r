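#' @import methods
#' @importFrom GenomicRanges GRanges seqnames start end strand findOverlaps
#'   distanceToNearest mcols
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors Pairs first second queryHits subjectHits mcols
#' @importFrom data.table fread fwrite data.table setkey :=
#' @importFrom stats fisher.test cor.test wilcox.test rbinom rpois rnbinom
#'   runif rnorm rexp setNames ecdf
#' @importFrom utils head
NULL

# Split a tab-separated file into fields, enforcing a minimum column count.
# Errors name the offending 1-based line number.
.read_tab_lines <- function(path, min_cols, what) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) return(list())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(fields, length, 1L) < min_cols)
  if (length(bad))
    stop(sprintf("%s parse error at line %d: expected >= %d tab-separated columns",
                 what, bad[1L], min_cols), call. = FALSE)
  fields
}

.as_num <- function(x, what, line) {
  v <- suppressWarnings(as.numeric(x))
  if (anyNA(v))
    stop(sprintf("%s parse error at line %d: non-numeric coordinate", what, line),
         call. = FALSE)
  v
}

.validate_interval <- function(chrom, start, end, what, line) {
  if (!nzchar(chrom))
    stop(sprintf("%s validation error at line %d: empty chromosome name", what, line),
         call. = FALSE)
  if (start < 0)
    stop(sprintf("%s validation error at line %d: start < 0", what, line),
         call. = FALSE)
  if (end <= start)
    stop(sprintf("%s validation error at line %d: end <= start", what, line),
         call. = FALSE)
  invisible(TRUE)
}

#' Read genomic intervals (BED) or loops (BEDPE)
#'
#' Coordinates are kept in the BED convention, 0-based half-open, throughout
#' the package; the returned `GRanges` stores them unshifted in
#' `start0`/`end0` metadata-free form via `start = start0`, `end = end0 - 1`
#' is *not* applied -- instead ranges are stored 1-based internally
#' (`IRanges(start0 + 1, end0)`) so that width equals `end0 - start0` and all
#' GenomicRanges arithmetic is exact. Use [gr_start0()] / [gr_end0()] to
#' recover BED coordinates.
#'
#' @param path File path.
#' @param format `"BED"` (>= 3 columns -> `GRanges`) or `"BEDPE"`
#'   (>= 6 columns -> `Pairs` of anchor `GRanges`).
#' @return A `GRanges` (BED) or `S4Vectors::Pairs` of two anchor `GRanges`
#'   (BEDPE), in input order.
#' @examples
#' p <- tempfile(fileext = ".bed")
#' writeLines("chr2\t0\t100", p)
#' read_intervals(p)
#' @export
read_intervals <- function(path, format = c("BED", "BEDPE")) {
  format <- match.arg(format)
  min_cols <- if (format == "BED") 3L else 6L
  fields <- .read_tab_lines(path, min_cols, format)
  if (length(fields) == 0L) {
    empty <- GenomicRanges::GRanges()
    return(if (format == "BED") empty else S4Vectors::Pairs(empty, empty))
  }
  n <- length(fields)
  if (format == "BED") {
    chrom <- vapply(fields, `[[`, "", 1L)
    s <- numeric(n); e <- numeric(n)
    for (i in seq_len(n)) {
      s[i] <- .as_num(fields[[i]][2L], "BED", i)
      e[i] <- .as_num(fields[[i]][3L], "BED", i)
      .validate_interval(chrom[i], s[i], e[i], "BED", i)
    }
    name <- vapply(fields, function(f) if (length(f) >= 4L) f[[4L]] else NA_character_, "")
    gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(s + 1, e))
    if (!all(is.na(name))) S4Vectors::mcols(gr)$name <- name
    gr
  } else {
    ca <- vapply(fields, `[[`, "", 1L); cb <- vapply(fields, `[[`, "", 4L)
    sa <- numeric(n); ea <- numeric(n); sb <- numeric(n); eb <- numeric(n)
    for (i in seq_len(n)) {
      sa[i] <- .as_num(fields[[i]][2L], "BEDPE", i)
      ea[i] <- .as_num(fields[[i]][3L], "BEDPE", i)
      sb[i] <- .as_num(fields[[i]][5L], "BEDPE", i)
      eb[i] <- .as_num(fields[[i]][6L], "BEDPE", i)
      .validate_interval(ca[i], sa[i], ea[i], "BEDPE", i)
      .validate_interval(cb[i], sb[i], eb[i], "BEDPE", i)
      if (ca[i] != cb[i])
        stop(sprintf("BEDPE validation error at line %d: inter-chromosomal loop", i),
             call. = FALSE)
    }
    S4Vectors::Pairs(
      GenomicRanges::GRanges(ca, IRanges::IRanges(sa + 1, ea)),
      GenomicRanges::GRanges(cb, IRanges::IRanges(sb + 1, eb)))
  }
}

#' BED (0-based half-open) coordinates of a GRanges
#'
#' @param gr A `GRanges` produced by this package.
#' @return Integer vector of 0-based starts / exclusive ends.
#' @export
gr_start0 <- function(gr) GenomicRanges::start(gr) - 1L

#' @rdname gr_start0
#' @export
gr_end0 <- function(gr) GenomicRanges::end(gr)

#' Write intervals back to BED / BEDPE
#'
#' @param x `GRanges` (BED) or `Pairs` (BEDPE).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_intervals <- function(x, path) {
  if (is(x, "Pairs")) {
    a <- S4Vectors::first(x); b <- S4Vectors::second(x)
    lines <- paste(as.character(GenomicRanges::seqnames(a)), gr_start0(a), gr_end0(a),
                   as.character(GenomicRanges::seqnames(b)), gr_start0(b), gr_end0(b),
                   sep = "\t")
  } else {
    lines <- paste(as.character(GenomicRanges::seqnames(x)), gr_start0(x), gr_end0(x),
                   sep = "\t")
    nm <- S4Vectors::mcols(x)$name
    if (!is.null(nm)) lines <- paste(lines, nm, sep = "\t")
  }
  writeLines(lines, path)
  invisible(path)
}

#' Derive DEG status and direction from a differential-expression table
#'
#' Applies the significance filter: a gene is a DEG when its adjusted p is
#' present and `padj <= alpha` (inclusive). Genes with missing `padj` are
#' retained -- the rescue classifier needs them -- but never count as DEGs.
#' Direction is `"up"` / `"down"` by the sign of the shrunken log2 fold
#' change for DEGs, `"none"` otherwise.
#'
#' @param df Data frame with columns `gene_id`, `log2fc`, `padj`.
#' @param alpha DEG significance threshold. Default 0.01.
#' @return The input with added logical `is_deg` and character `direction`.
#' @examples
#' as_deg_table(data.frame(gene_id = "g1", log2fc = -0.5, padj = 0.005))
#' @export
as_deg_table <- function(df, alpha = 0.01) {
  stopifnot(all(c("gene_id", "log2fc", "padj") %in% names(df)))
  if (anyDuplicated(df$gene_id))
    stop("duplicate gene_id in DEG table: ",
         df$gene_id[duplicated(df$gene_id)][1L], call. = FALSE)
  if (!is.numeric(df$log2fc)) stop("non-numeric log2fc", call. = FALSE)
  if (!is.numeric(df$padj)) stop("non-numeric padj", call. = FALSE)
  if (any(df$padj < 0 | df$padj > 1, na.rm = TRUE))
    stop("padj outside [0, 1]", call. = FALSE)
  df <- as.data.frame(df)
  df$is_deg <- !is.na(df$padj) & df$padj <= alpha
  df$direction <- ifelse(df$is_deg & df$log2fc > 0, "up",
                  ifelse(df$is_deg & df$log2fc < 0, "down", "none"))
  df
}

#' Read a differential-expression TSV
#'
#' Expects a header with at least `gene_id`, `log2fc`, `padj`; `padj` may be
#' `NA`. Duplicate gene ids and non-numeric fold changes are errors.
#'
#' @inheritParams as_deg_table
#' @param path TSV path.
#' @return Data frame of DEG records (see [as_deg_table()]).
#' @export
read_deg_table <- function(path, alpha = 0.01) {
  df <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE,
                          na.strings = c("NA", ""))
  as_deg_table(df, alpha = alpha)
}

#' @rdname read_deg_table
#' @param df DEG table to write (extra derived columns are dropped).
#' @export
write_deg_table <- function(df, path) {
  data.table::fwrite(df[, intersect(c("gene_id", "log2fc", "padj"), names(df))],
                     path, sep = "\t", na = "NA", quote = FALSE)
  invisible(path)
}

#' Read strand-specific 3'-end signal from a bedGraph pair
#'
#' Each bedGraph run `chrom start end value` is expanded to per-base counts
#' over `[start, end)`. Values must be non-negative integers; overlapping
#' runs on one strand are an error (bedGraph runs partition the covered
#' positions).
#'
#' @param path_plus bedGraph of plus-strand 3' end counts.
#' @param path_minus bedGraph of minus-strand 3' end counts.
#' @return A `signal_track`: list with `plus` / `minus` `data.table`s of
#'   (`chrom`, `pos`, `count`), positions 0-based.
#' @export
read_signal <- function(path_plus, path_minus) {
  signal_track(.read_bedgraph(path_plus), .read_bedgraph(path_minus))
}

.read_bedgraph <- function(path) {
  fields <- .read_tab_lines(path, 4L, "bedGraph")
  if (length(fields) == 0L)
    return(data.table::data.table(chrom = character(), pos = integer(),
                                  count = integer()))
  n <- length(fields)
  chrom <- vapply(fields, `[[`, "", 1L)
  s <- numeric(n); e <- numeric(n); v <- numeric(n)
  for (i in seq_len(n)) {
    s[i] <- .as_num(fields[[i]][2L], "bedGraph", i)
    e[i] <- .as_num(fields[[i]][3L], "bedGraph", i)
    v[i] <- .as_num(fields[[i]][4L], "bedGraph", i)
    .validate_interval(chrom[i], s[i], e[i], "bedGraph", i)
    if (v[i] < 0)
      stop(sprintf("bedGraph validation error at line %d: negative value", i),
           call. = FALSE)
    if (v[i] != round(v[i]))
      stop(sprintf("bedGraph validation error at line %d: non-integer count", i),
           call. = FALSE)
  }
  w <- e - s
  dt <- data.table::data.table(
    chrom = rep(chrom, w),
    pos = as.integer(unlist(lapply(seq_len(n), function(i) seq(s[i], e[i] - 1)))),
    count = as.integer(rep(v, w)))
  if (anyDuplicated(dt[, c("chrom", "pos")]))
    stop("bedGraph validation error: overlapping runs on one strand", call. = FALSE)
  dt <- dt[dt$count > 0L, ]
  data.table::setkey(dt, chrom, pos)
  dt
}

#' Construct a signal track from per-base count tables
#'
#' @param plus,minus `data.table`/data.frame with columns `chrom`, `pos`
#'   (0-based), `count` (non-negative integer).
#' @return A `signal_track` object.
#' @export
signal_track <- function(plus = NULL, minus = NULL) {
  mk <- function(x) {
    if (is.null(x))
      x <- data.frame(chrom = character(), pos = integer(), count = integer())
    dt <- data.table::as.data.table(x[, c("chrom", "pos", "count")])
    if (any(dt$count < 0L)) stop("negative signal counts", call. = FALSE)
    dt <- dt[dt$count > 0L, ]
    data.table::setkey(dt, chrom, pos)
    dt
  }
  structure(list(plus = mk(plus), minus = mk(minus)), class = "signal_track")
}

#' @export
print.signal_track <- function(x, ...) {
  cat(sprintf("signal_track: %d plus / %d minus covered bases, %d total 3' ends\n",
              nrow(x$plus), nrow(x$minus),
              sum(x$plus$count) + sum(x$minus$count)))
  invisible(x)
}

#' Sum several signal tracks base-wise
#'
#' Composite counts pooled across samples feed the dominant-TSS caller.
#'
#' @param ... `signal_track` objects.
#' @return A `signal_track` with per-base counts summed.
#' @export
sum_signal_tracks <- function(...) {
  tracks <- list(...)
  stopifnot(length(tracks) >= 1L, all(vapply(tracks, inherits, TRUE, "signal_track")))
  comb <- function(side) {
    dt <- data.table::rbindlist(lapply(tracks, `[[`, side))
    if (nrow(dt) == 0L) return(dt)
    dt <- dt[, list(count = sum(count)), by = c("chrom", "pos")]
    dt
  }
  signal_track(comb("plus"), comb("minus"))
}

#' Write a signal track as a bedGraph pair
#'
#' Adjacent equal-count bases are merged back into runs.
#'
#' @param track A `signal_track`.
#' @param path_plus,path_minus Output paths.
#' @return Invisibly, `c(path_plus, path_minus)`.
#' @export
write_signal <- function(track, path_plus, path_minus) {
  wr <- function(dt, path) {
    if (nrow(dt) == 0L) { writeLines(character(), path); return() }
    dt <- dt[order(dt$chrom, dt$pos), ]
    newrun <- c(TRUE, dt$chrom[-1L] != dt$chrom[-nrow(dt)] |
                      dt$pos[-1L] != dt$pos[-nrow(dt)] + 1L |
                      dt$count[-1L] != dt$count[-nrow(dt)])
    id <- cumsum(newrun)
    runs <- data.frame(chrom = tapply(dt$chrom, id, `[`, 1L),
                       s = tapply(dt$pos, id, min),
                       e = tapply(dt$pos, id, max) + 1L,
                       v = tapply(dt$count, id, `[`, 1L))
    writeLines(paste(runs$chrom, runs$s, runs$e, runs$v, sep = "\t"), path)
  }
  wr(track$plus, path_plus)
  wr(track$minus, path_minus)
  invisible(c(path_plus, path_minus))
}

#' Read / write transcript annotation tables
#'
#' TSV with header `gene_id`, `transcript_id`, `chrom`, `tss` (0-based base
#' position), `strand` (`+`/`-`), `transcript_length` (nt).
#'
#' @param path TSV path.
#' @return Data frame of transcript records.
#' @export
read_annotation <- function(path) {
  df <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE)
  need <- c("gene_id", "transcript_id", "chrom", "tss", "strand", "transcript_length")
  stopifnot(all(need %in% names(df)))
  if (!all(df$strand %in% c("+", "-")))
    stop("annotation strand must be '+' or '-'", call. = FALSE)
  if (any(df$transcript_length <= 0))
    stop("transcript_length must be positive", call. = FALSE)
  df
}

#' @rdname read_annotation
#' @param df Annotation data frame to write.
#' @export
write_annotation <- function(df, path) {
  data.table::fwrite(df, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Read per-allele FISH measurements
#'
#' TSV with header `allele_id`, `condition`, then either sphere geometry
#' (`ax`, `ay`, `az`, `ar`, `bx`, `by`, `bz`, `br`; nm) or precomputed
#' summaries (`overlap_volume` nm^3, `boundary_gap_nm`). When geometry is
#' present, gap and overlap volume are (re)computed from it.
#'
#' @param path TSV path.
#' @return Data frame of allele measurements with `boundary_gap_nm` and
#'   `overlap_volume` filled in.
#' @export
read_fish_measurements <- function(path) {
  df <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE)
  stopifnot(all(c("allele_id", "condition") %in% names(df)))
  geom <- c("ax", "ay", "az", "ar", "bx", "by", "bz", "br")
  if (all(geom %in% names(df))) {
    if (any(df$ar < 0 | df$br < 0)) stop("negative radius", call. = FALSE)
    d <- sqrt((df$ax - df$bx)^2 + (df$ay - df$by)^2 + (df$az - df$bz)^2)
    df$boundary_gap_nm <- d - df$ar - df$br
    df$overlap_volume <- sphere_overlap_volume(df$ar, df$br, d)
  } else if (!all(c("overlap_volume", "boundary_gap_nm") %in% names(df))) {
    stop("FISH table needs sphere geometry columns or precomputed ",
         "overlap_volume + boundary_gap_nm", call. = FALSE)
  }
  df
}

#' @rdname read_fish_measurements
#' @param df FISH measurement table to write.
#' @export
write_fish_measurements <- function(df, path) {
  data.table::fwrite(df, path, sep = "\t", quote = FALSE)
  invisible(path)
}
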