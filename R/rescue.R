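#' Classify single-knockdown DEGs as fully, partially, or not rescued
#'
#' Compares each DEG of the single-knockdown table against the co-depletion
#' (double-knockdown) table:
#' \itemize{
#'   \item \strong{fully} rescued: no longer significant in the double
#'     knockdown (`padj > alpha`, or `padj` missing, or the gene is absent
#'     from the double table -- absence passed no significance call and is
#'     flagged with a warning);
#'   \item \strong{partially} rescued: still significant in the same
#'     direction but with strictly diminished magnitude
#'     (`|log2fc_double| < |log2fc_single|`; equality is not diminished);
#'   \item \strong{not rescued}: everything else. Significant sign flips are
#'     not a category of their own: they are classed not rescued and flagged
#'     in `sign_flip`.
#' }
#'
#' @param single DEG table of the single knockdown ([as_deg_table()]); only
#'   its `is_deg` rows are classified.
#' @param double DEG table of the double knockdown, keyed by `gene_id`.
#' @param alpha Significance threshold in (0, 1). Default 0.01.
#' @return List with `calls` (data frame: `gene_id`, `category`,
#'   `sign_flip`, `lfc_single`, `lfc_double`, `padj_double`) and `summary`
#'   (counts and percentages per category).
#' @examples
#' s <- as_deg_table(data.frame(gene_id = "g", log2fc = -1, padj = 0.002))
#' d <- as_deg_table(data.frame(gene_id = "g", log2fc = -0.1, padj = 0.13))
#' classify_rescue(s, d)$summary
#' @export
classify_rescue <- function(single, double, alpha = 0.01) {
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1)
    stop("alpha must be in (0, 1)", call. = FALSE)
  degs <- single[single$is_deg, , drop = FALSE]
  i <- match(degs$gene_id, double$gene_id)
  if (anyNA(i))
    warning(sum(is.na(i)), " single-knockdown DEG(s) absent from the double ",
            "table; classified fully rescued", call. = FALSE)
  lfc_d <- double$log2fc[i]
  padj_d <- double$padj[i]
  still_sig <- !is.na(i) & !is.na(padj_d) & padj_d <= alpha
  same_sign <- sign(lfc_d) == sign(degs$log2fc) & sign(degs$log2fc) != 0
  diminished <- abs(lfc_d) < abs(degs$log2fc)
  category <- ifelse(!still_sig, "fully",
              ifelse(same_sign & diminished, "partially", "not_rescued"))
  sign_flip <- category == "not_rescued" & still_sig &
    !is.na(same_sign) & !same_sign
  calls <- data.frame(gene_id = degs$gene_id,
                      category = category,
                      sign_flip = sign_flip,
                      lfc_single = degs$log2fc,
                      lfc_double = lfc_d,
                      padj_double = padj_d)
  counts <- vapply(c("fully", "partially", "not_rescued"),
                   function(k) sum(category == k), integer(1))
  list(calls = calls,
       summary = data.frame(category = names(counts),
                            n = as.integer(counts),
                            percent = 100 * counts / max(1L, nrow(degs)),
                            row.names = NULL))
}
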