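# Relative quantitation of variant peptides against their wildtype
# counterparts from XIC areas. The convention is fraction-of-pool:
# 100 * A_variant / (A_variant + A_wildtype), so a 0.5% spike reads ~0.5%.
# Areas are summed across charge states and enzymes before ratioing.

#' Pair a variant PSM with its wildtype counterpart peptides
#'
#' Prefers wildtype PSMs (no variant call) with the identical protein span
#' and enzyme; when a substitution created or destroyed a cleavage site and
#' no exact-span wildtype exists, falls back to the shortest wildtype span
#' covering the variant position.
#'
#' @param variant_psm One-row PSM tibble with a variant call.
#' @param psms Full PSM tibble to search for wildtype counterparts.
#' @return Tibble of wildtype PSM rows (possibly several charge states).
#'   Zero rows when no covering wildtype peptide exists (the caller reports
#'   the variant as unpaired).
#' @export
pair_wildtype <- function(variant_psm, psms) {
  if (is.na(variant_psm$variant)) abort("PSM has no variant call.")
  wt <- psms[is.na(psms$variant) & psms$protein_id == variant_psm$protein_id, ]
  exact <- wt[wt$enzyme == variant_psm$enzyme &
                wt$start == variant_psm$start & wt$end == variant_psm$end, ]
  if (nrow(exact) > 0L) return(exact)
  pos <- variant_psm$variant_position
  covering <- wt[wt$start <= pos & wt$end >= pos, ]
  if (nrow(covering) == 0L) return(covering)
  len <- covering$end - covering$start + 1L
  best <- covering[len == min(len), ]
  # all charge states of the single shortest covering span
  best_span <- best[1, c("start", "end", "enzyme")]
  covering[covering$start == best_span$start & covering$end == best_span$end &
             covering$enzyme == best_span$enzyme, ]
}

#' Relative quantitation from two XIC areas
#'
#' @param area_variant,area_wildtype Non-negative XIC areas (arbitrary
#'   units), not both zero.
#' @return Percentage `100 * area_variant / (area_variant + area_wildtype)`,
#'   full precision (outputs round to 1 decimal at rendering time). A zero
#'   wildtype area yields 100% with a warning.
#' @examples
#' relative_quant(1, 199) # 0.5
#' @export
relative_quant <- function(area_variant, area_wildtype) {
  stopifnot(area_variant >= 0, area_wildtype >= 0)
  if (area_variant == 0 && area_wildtype == 0) {
    abort("Both XIC areas are zero; relative quantitation undefined.")
  }
  if (area_wildtype == 0) {
    warn("Wildtype XIC area is zero; reporting 100%.")
  }
  100 * area_variant / (area_variant + area_wildtype)
}

#' Summarise one variant's PSMs into a quantitation row
#'
#' Areas are summed across charge states and enzymes on both sides before
#' ratioing (ratio of sums, not mean of ratios).
#'
#' @param variant_psms PSM rows for one variant (>= 1 row).
#' @param wildtype_psms Paired wildtype PSM rows (possibly zero rows).
#' @return One-row tibble: `variant`, `rel_quant_pct`, `n_psms`,
#'   `best_score`, `area_variant`, `area_wildtype`, `unpaired`.
#' @export
summarize_variant <- function(variant_psms, wildtype_psms) {
  stopifnot(nrow(variant_psms) >= 1L)
  a_v <- sum(variant_psms$xic_area)
  a_w <- sum(wildtype_psms$xic_area)
  unpaired <- nrow(wildtype_psms) == 0L
  rq <- if (unpaired && a_v == 0) NA_real_ else relative_quant(a_v, a_w)
  tibble(
    variant = variant_psms$variant[1],
    rel_quant_pct = rq,
    n_psms = nrow(variant_psms),
    best_score = max(variant_psms$score),
    area_variant = a_v,
    area_wildtype = a_w,
    unpaired = unpaired
  )
}

#' Quantify every variant in a PSM table
#'
#' For each distinct variant call, pools the variant's PSM areas and the
#' areas of the paired wildtype peptides (deduplicated across the variant's
#' spans) and computes the relative quantitation.
#'
#' @param psms PSM tibble with variant columns.
#' @param proteins Protein tibble (currently used for validation only).
#' @param cfg Optional [triage_config()]; unused in the ratio itself, kept
#'   for interface symmetry with [triage_run()].
#' @param retained_only If `TRUE` and `psms` carries a `status` column, only
#'   retained variant PSMs contribute (`n_psms` then counts retained PSMs,
#'   as in final reports).
#' @return Tibble with one row per variant (see [summarize_variant()]).
#' @export
quantify_variants <- function(psms, proteins = NULL, cfg = NULL,
                              retained_only = FALSE) {
  psms <- ensure_variant_columns(psms)
  pool <- psms
  if (retained_only && "status" %in% names(psms)) {
    pool <- psms[is.na(psms$variant) | psms$status == "retained", ]
  }
  variants <- unique(pool$variant[!is.na(pool$variant)])
  if (length(variants) == 0L) {
    return(tibble(variant = character(), rel_quant_pct = numeric(),
                  n_psms = integer(), best_score = numeric(),
                  area_variant = numeric(), area_wildtype = numeric(),
                  unpaired = logical()))
  }
  rows <- lapply(variants, function(v) {
    vp <- pool[!is.na(pool$variant) & pool$variant == v, ]
    wt_rows <- lapply(seq_len(nrow(vp)), function(i) pair_wildtype(vp[i, ], psms))
    wt <- bind_rows(wt_rows)
    wt <- wt[!duplicated(wt$psm_id), ]
    summarize_variant(vp, wt)
  })
  arrange(bind_rows(rows), .data$variant)
}
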