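#' Analysis configuration
#'
#' Bundles every fixed constant of the pipeline in one validated list. The
#' defaults are the values used throughout the package: adjusted-p cutoff for
#' calling a gene differentially expressed, permutation count for the TAD
#' statistics, the promoter window summed by the TSS caller, the activity
#' threshold on that window, the two loop-anchor proximity thresholds, the
#' gene universe backing set-overlap tests, and the FISH contact cutoff.
#'
#' @param alpha Adjusted-p threshold for DEG status; a gene is a DEG when
#'   `padj <= alpha` (boundary inclusive). Default 0.01.
#' @param n_perm Number of label permutations for the null distributions.
#'   Default 1000.
#' @param tss_window Width in nt of the promoter window downstream of the TSS
#'   summed by the TSS caller (window spans TSS to TSS + `tss_window`,
#'   inclusive of both ends; mirrored on the minus strand). Default 150.
#' @param active_min_count Minimum promoter-window 3' end count for a TSS to
#'   be called active; counts of `active_min_count - 1` or fewer are
#'   inactive. Default 10.
#' @param anchor_near_kb Primary TSS-to-loop-anchor proximity threshold, kb.
#'   Default 5.
#' @param anchor_far_kb Secondary proximity threshold, kb. Default 200.
#' @param universe_size Total number of genes backing gene-set overlap tests.
#'   Default 20000.
#' @param contact_cutoff_nm Surface-to-surface separation (nm) at or below
#'   which two FISH domains are in contact. Default 250.
#' @param seed Integer seed recorded for downstream use, or `NULL`.
#' @return A list of class `"tadcoord_config"`.
#' @examples
#' cfg <- analysis_config()
#' cfg$alpha
#' @export
analysis_config <- function(alpha = 0.01,
                            n_perm = 1000L,
                            tss_window = 150L,
                            active_min_count = 10L,
                            anchor_near_kb = 5,
                            anchor_far_kb = 200,
                            universe_size = 20000L,
                            contact_cutoff_nm = 250,
                            seed = NULL) {
  stopifnot(is.numeric(alpha), length(alpha) == 1L, alpha > 0, alpha < 1)
  for (nm in c("n_perm", "tss_window", "active_min_count", "anchor_near_kb",
               "anchor_far_kb", "universe_size", "contact_cutoff_nm")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop("'", nm, "' must be a single positive number", call. = FALSE)
  }
  structure(
    list(alpha = alpha,
         n_perm = as.integer(n_perm),
         tss_window = as.integer(tss_window),
         active_min_count = as.integer(active_min_count),
         anchor_near_kb = anchor_near_kb,
         anchor_far_kb = anchor_far_kb,
         universe_size = as.integer(universe_size),
         contact_cutoff_nm = contact_cutoff_nm,
         seed = if (is.null(seed)) NULL else as.integer(seed)),
    class = "tadcoord_config")
}

#' @export
print.tadcoord_config <- function(x, ...) {
  cat("tadcoord analysis configuration\n")
  for (nm in setdiff(names(x), "seed"))
    cat(sprintf("  %-18s %s\n", nm, format(x[[nm]])))
  if (!is.null(x$seed)) cat(sprintf("  %-18s %d\n", "seed", x$seed))
  invisible(x)
}
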