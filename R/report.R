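# Run-level accounting: unique-peptide reductions between methods and
# deterministic plain-text report rendering.

#' Percent reduction in unique peptides
#'
#' `100 * (1 - n_new / n_old)`, rounded half-up to an integer percent (the
#' convention that reproduces published method-comparison tables).
#'
#' @param n_new,n_old Unique-peptide counts under the new and old method;
#'   `n_old` must be > 0.
#' @return Integer percent.
#' @examples
#' percent_reduction(83, 346) # 76
#' percent_reduction(43, 194) # 78
#' @export
percent_reduction <- function(n_new, n_old) {
  if (any(n_old <= 0)) abort("`n_old` must be > 0.")
  as.integer(floor(100 * (1 - n_new / n_old) + 0.5))
}

#' Compare unique-peptide counts across runs
#'
#' @param runs Tibble (or data frame) with columns `label`, `n_new`,
#'   `n_old`; at least one row.
#' @return An `sva_comparison` tibble with a `pct_reduction` column;
#'   `glance()` reports the maximum reduction.
#' @examples
#' compare_runs(tibble::tibble(
#'   label = c("mAb3", "mAb4", "mAb5", "FP1"),
#'   n_new = c(86, 24, 22, 49), n_old = c(346, 194, 298, 458)))
#' @export
compare_runs <- function(runs) {
  stopifnot(is.data.frame(runs))
  if (nrow(runs) == 0L) abort("`runs` must have at least one row.")
  out <- as_tibble(runs)
  out$pct_reduction <- percent_reduction(out$n_new, out$n_old)
  structure(out, class = c("sva_comparison", class(out)))
}

#' @export
glance.sva_comparison <- function(x, ...) {
  tibble(n_runs = nrow(x), max_pct_reduction = max(x$pct_reduction))
}

#' @export
tidy.sva_comparison <- function(x, ...) as_tibble(unclass(x))

#' Render a run report
#'
#' Deterministic markdown report: per-variant quantitation (relative quant
#' to 1 decimal, PSM count, best score) and, when a comparison is supplied,
#' the unique-peptide reduction table.
#'
#' @param quants Variant quantitation tibble (from [quantify_variants()]).
#' @param summary Optional one-row run summary (from `glance()` on an
#'   `sva_triage`).
#' @param comparison Optional [compare_runs()] result.
#' @param label Run label used in headings.
#' @return Character scalar (markdown).
#' @export
render_report <- function(quants, summary = NULL, comparison = NULL,
                          label = "run") {
  lines <- c(sprintf("# Sequence variant report: %s", label), "")
  if (!is.null(summary)) {
    lines <- c(lines,
      sprintf("- PSMs: %d (%d with variant calls)", summary$n_psms,
              summary$n_variant_psms),
      sprintf("- Unique variant peptides: %d", summary$unique_variant_peptides),
      sprintf("- Retained variant sites: %d", summary$retained_variant_sites),
      "")
  }
  lines <- c(lines, "## Variant quantitation", "",
             "| Sequence Variant | Rel. Quant (%) | Number of PSMs | Best Score |",
             "|---|---|---|---|")
  if (nrow(quants) > 0L) {
    q <- arrange(quants, .data$variant)
    lines <- c(lines, sprintf("| %s | %.1f | %d | %g |",
                              q$variant, q$rel_quant_pct, q$n_psms, q$best_score))
  }
  if (!is.null(comparison)) {
    lines <- c(lines, "", "## Method comparison", "",
               "| Run | Unique Peptides (new) | Unique Peptides (old) | % Reduction |",
               "|---|---|---|---|",
               sprintf("| %s | %d | %d | %d%% |", comparison$label,
                       comparison$n_new, comparison$n_old,
                       comparison$pct_reduction),
               "",
               sprintf("Maximum reduction: %d%%",
                       max(comparison$pct_reduction)))
  }
  paste(c(lines, ""), collapse = "\n")
}
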