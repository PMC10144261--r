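# Rule-based false-positive annotation of variant PSMs. The four rules
# encode recurrent false-positive classes seen in sequence variant analysis:
#   R1_semi_nonKR        semi-tryptic peptide, variant not involving K/R
#   R2_terminal_residue  delta equals a residue mass present near a terminus
#   R3_below_quant_limit relative quantitation below the reporting limit
#   R4_orthogonal_redundant orthogonal-digest hit already covered by trypsin
# plus two gates: G_score (engine score below cutoff) and G_mass_error
# (precursor mass error beyond the MS1 tolerance). PSMs are annotated, never
# deleted; a PSM is a false positive iff at least one rule or gate fires.

TRIAGE_RULES <- c("R1_semi_nonKR", "R2_terminal_residue",
                  "R3_below_quant_limit", "R4_orthogonal_redundant",
                  "G_score", "G_mass_error")

RULE_TEXT <- c(
  R1_semi_nonKR = "semi-tryptic peptide with variant not involving Lys/Arg",
  R2_terminal_residue = "mass shift matches a residue present near a peptide terminus",
  R3_below_quant_limit = "relative quantitation below the quantification limit",
  R4_orthogonal_redundant = "orthogonal digest site already covered by a confident tryptic PSM",
  G_score = "engine score below cutoff",
  G_mass_error = "precursor mass error beyond MS1 tolerance"
)

#' Semi-tryptic non-K/R rule (condition 1)
#'
#' Flags variant PSMs from the trypsin digest that sit on semi-tryptic
#' peptides where neither lysine nor arginine is involved in the called
#' substitution. A substitution "involves" K/R when the wildtype or observed
#' residue is K or R, or when the variant position is the residue at the
#' nonspecific terminus (where a gained/lost cleavage site legitimately
#' produces a semi-tryptic peptide).
#'
#' @param psm One-row PSM tibble with variant columns (see
#'   [read_psm_table()]).
#' @param protein Protein record covering the PSM.
#' @param enzyme Enzyme used to judge specificity; default [enzyme_trypsin()].
#' @return `TRUE` if the rule fires.
#' @export
rule_semi_nonKR <- function(psm, protein, enzyme = enzyme_trypsin()) {
  if (is.null(protein)) abort("Protein record required for the semi-tryptic rule.")
  if (!identical(psm$enzyme, "trypsin") || is.na(psm$variant)) return(FALSE)
  spec <- classify_specificity(psm$start, psm$end, protein$sequence, enzyme)
  if (spec != "semi") return(FALSE)
  if (psm$variant_wt %in% c("K", "R") || psm$variant_obs %in% c("K", "R")) {
    return(FALSE)
  }
  # which terminus is nonspecific?
  cuts <- cleavage_sites(protein$sequence, enzyme)
  n <- nchar(protein$sequence)
  n_ok <- psm$start == 1L || (psm$start - 1L) %in% cuts
  junction <- if (n_ok) psm$end else psm$start
  psm$variant_position != junction
}

#' Terminal-residue rule (condition 2)
#'
#' Flags variants whose mass shift equals the mass of an amino acid that is
#' itself present within `near_terminus_window` residues of either peptide
#' terminus -- the signature of an in-source or transpeptidation artifact
#' misread as a substitution. With `match_loss` enabled in the config,
#' residue losses (delta = -residue mass) are matched as well.
#'
#' @param psm One-row PSM tibble with a variant call.
#' @param cfg A [triage_config()].
#' @param masses Residue mass table.
#' @return `TRUE` if the rule fires.
#' @export
rule_terminal_residue <- function(psm, cfg, masses = residue_masses(include_mnl = FALSE)) {
  if (is.na(psm$variant)) return(FALSE)
  delta <- substitution_delta(psm$variant_wt, psm$variant_obs,
                              masses = residue_masses())
  hits <- names(masses)[abs(masses - delta) <= cfg$residue_match_tol_da]
  if (isTRUE(cfg$match_loss)) {
    hits <- union(hits, names(masses)[abs(masses + delta) <= cfg$residue_match_tol_da])
  }
  if (length(hits) == 0L) return(FALSE)
  chars <- strsplit(psm$peptide, "", fixed = TRUE)[[1]]
  w <- min(cfg$near_terminus_window, length(chars))
  near <- unique(c(head(chars, w), chars[seq.int(length(chars) - w + 1L, length(chars))]))
  any(hits %in% near)
}

#' Quantification-limit rule (condition 3)
#'
#' @param rel_quant_pct Relative quantitation of the variant, percent.
#' @param cfg A [triage_config()].
#' @return `TRUE` when strictly below `quant_limit_pct` (a variant exactly at
#'   the limit is kept: the assay must detect variants at levels >= the
#'   limit).
#' @export
rule_below_quant_limit <- function(rel_quant_pct, cfg) {
  stopifnot(rel_quant_pct >= 0)
  rel_quant_pct < cfg$quant_limit_pct
}

#' Orthogonal-redundancy rule (condition 4)
#'
#' A variant PSM from a non-trypsin digest is redundant when the same
#' variant site (protein, position, observed residue) carries at least one
#' trypsin PSM scoring at or above the cutoff. Trypsin PSMs never trigger
#' this rule.
#'
#' @param psms PSM tibble with variant columns.
#' @param cfg A [triage_config()].
#' @return Logical vector aligned with `psms` rows.
#' @export
rule_orthogonal_redundant <- function(psms, cfg) {
  if (nrow(psms) == 0L) return(logical(0))
  site <- paste(psms$protein_id, psms$variant_position, psms$variant_obs, sep = "|")
  covered <- unique(site[!is.na(psms$variant) &
                           psms$enzyme == "trypsin" &
                           psms$score >= cfg$score_cutoff])
  !is.na(psms$variant) & psms$enzyme != "trypsin" & site %in% covered
}

#' Score and mass-error gates
#'
#' @param psms PSM tibble.
#' @param cfg A [triage_config()].
#' @return Tibble of logicals `G_score` (score strictly below the cutoff --
#'   "detected" means score >= cutoff) and `G_mass_error` (|precursor ppm|
#'   strictly beyond the MS1 tolerance).
#' @export
apply_gates <- function(psms, cfg) {
  tibble(
    G_score = psms$score < cfg$score_cutoff,
    G_mass_error = abs(psms$precursor_ppm) > cfg$ms1_tol_ppm
  )
}

#' Annotate a run of variant PSMs
#'
#' Applies the four false-positive rules and both gates to every PSM with a
#' variant call. PSMs are annotated, never removed: `status` is
#' `"false_positive"` iff at least one rule fired, `"retained"` otherwise,
#' and the comment names every triggered rule. Wildtype PSMs (no variant
#' call) pass through as retained with no rules evaluated. The annotation is
#' idempotent: re-annotating an annotated table changes nothing.
#'
#' @param psms PSM tibble (as from [read_psm_table()] or
#'   [synth_project()]).
#' @param proteins Protein tibble (as from [read_fasta()]); every
#'   `protein_id` in `psms` must be present.
#' @param quants Optional per-variant quantitation tibble with columns
#'   `variant` and `rel_quant_pct`; computed with [quantify_variants()] when
#'   `NULL`.
#' @param cfg A [triage_config()].
#' @return An `sva_triage` object: list with `annotations` (tibble `psm_id`,
#'   `status`, `triggered_rules`, `comment`), `psms` (input joined with the
#'   annotations), `summary` (unique variant peptides and variant sites
#'   before/after triage), `cfg`.
#' @export
triage_run <- function(psms, proteins, quants = NULL, cfg = triage_config()) {
  stopifnot(is.data.frame(psms))
  psms <- ensure_variant_columns(psms)
  dangling <- setdiff(unique(psms$protein_id), proteins$id)
  if (length(dangling)) {
    abort(sprintf("PSMs reference unknown protein id(s): %s",
                  paste(dangling, collapse = ", ")))
  }
  if (nrow(psms) == 0L) {
    return(new_sva_triage(
      annotations = tibble(psm_id = character(), status = character(),
                           triggered_rules = character(), comment = character()),
      psms = psms, cfg = cfg,
      summary = triage_summary(psms, character(0))))
  }
  if (is.null(quants)) {
    quants <- quantify_variants(psms, proteins, cfg = NULL)
  }

  prot_index <- split(proteins, proteins$id)
  has_var <- !is.na(psms$variant)

  r1 <- r2 <- logical(nrow(psms))
  for (i in which(has_var)) {
    row <- psms[i, ]
    prot <- prot_index[[row$protein_id]]
    r1[i] <- rule_semi_nonKR(row, prot)
    r2[i] <- rule_terminal_residue(row, cfg)
  }
  quant_of <- setNames(quants$rel_quant_pct, quants$variant)
  r3 <- has_var & vapply(seq_len(nrow(psms)), function(i) {
    if (!has_var[i]) return(FALSE)
    q <- unname(quant_of[psms$variant[i]])
    !is.na(q) && rule_below_quant_limit(q, cfg)
  }, logical(1))
  r4 <- rule_orthogonal_redundant(psms, cfg)
  gates <- apply_gates(psms, cfg)
  g_score <- has_var & gates$G_score
  g_mass <- has_var & gates$G_mass_error

  trig <- cbind(R1_semi_nonKR = r1, R2_terminal_residue = r2,
                R3_below_quant_limit = r3, R4_orthogonal_redundant = r4,
                G_score = g_score, G_mass_error = g_mass)
  rules_str <- apply(trig, 1L, function(x) paste(TRIAGE_RULES[x], collapse = ";"))
  status <- if_else(rules_str == "", "retained", "false_positive")
  comment <- vapply(seq_len(nrow(trig)), function(i) {
    fired <- TRIAGE_RULES[trig[i, ]]
    if (length(fired) == 0L) return("")
    paste(sprintf("[%s] %s", fired, RULE_TEXT[fired]), collapse = "; ")
  }, character(1))

  annotations <- tibble(psm_id = psms$psm_id, status = status,
                        triggered_rules = rules_str, comment = comment)
  retained_variants <- unique(psms$variant[has_var & status == "retained"])
  out_psms <- psms
  out_psms$status <- status
  out_psms$triggered_rules <- rules_str
  out_psms$comment <- comment
  new_sva_triage(annotations = annotations, psms = out_psms, cfg = cfg,
                 summary = triage_summary(psms, retained_variants))
}

triage_summary <- function(psms, retained_variants) {
  has_var <- !is.na(psms$variant)
  vp <- unique(paste(psms$peptide[has_var], psms$variant[has_var]))
  tibble(
    n_psms = nrow(psms),
    n_variant_psms = sum(has_var),
    unique_variant_peptides = length(vp),
    retained_variant_sites = length(retained_variants)
  )
}

new_sva_triage <- function(annotations, psms, cfg, summary) {
  structure(list(annotations = annotations, psms = psms, cfg = cfg,
                 summary = summary),
            class = "sva_triage")
}

#' @export
print.sva_triage <- function(x, ...) {
  cat("<sva_triage>\n")
  cat(sprintf("  PSMs: %d (%d with variant calls)\n",
              x$summary$n_psms, x$summary$n_variant_psms))
  cat(sprintf("  Unique variant peptides: %d\n", x$summary$unique_variant_peptides))
  cat(sprintf("  Retained variant sites: %d (score cutoff %g)\n",
              x$summary$retained_variant_sites, x$cfg$score_cutoff))
  invisible(x)
}

#' @export
tidy.sva_triage <- function(x, ...) x$annotations

#' @export
glance.sva_triage <- function(x, ...) x$summary

#' Variant sites retained by a triage run
#'
#' @param x An `sva_triage` object.
#' @return Character vector of retained variant names.
#' @export
retained_sites <- function(x) {
  stopifnot(inherits(x, "sva_triage"))
  p <- x$psms
  sort(unique(p$variant[!is.na(p$variant) & p$status == "retained"]))
}

#' Score-cutoff sweep
#'
#' Re-runs triage across a grid of score cutoffs, reporting how many unique
#' variant peptides and variant sites survive at each. Retained counts are
#' non-increasing in the cutoff. When a truth table from [synth_project()]
#' is supplied, the number of retained *true* sites is reported as well --
#' the quantity a spike-in calibration study reads off to pick the cutoff.
#'
#' @param psms PSM tibble.
#' @param proteins Protein tibble.
#' @param cutoffs Non-empty numeric vector of score cutoffs.
#' @param cfg Base [triage_config()]; each sweep point overrides
#'   `score_cutoff` only.
#' @param quants Optional per-variant quantitation (computed once if `NULL`).
#' @param truth Optional truth tibble with columns `variant` and `class`
#'   (`"true_sv"` marks genuine variants).
#' @return An `sva_sweep` tibble: `cutoff`, `retained_unique_peptides`,
#'   `retained_sites`, and `retained_true_sites` when truth is given.
#' @export
threshold_sweep <- function(psms, proteins, cutoffs, cfg = triage_config(),
                            quants = NULL, truth = NULL) {
  if (length(cutoffs) == 0L) abort("`cutoffs` must be non-empty.")
  psms <- ensure_variant_columns(psms)
  if (is.null(quants)) quants <- quantify_variants(psms, proteins, cfg = NULL)
  true_sites <- if (!is.null(truth)) {
    unique(truth$variant[truth$class == "true_sv"])
  }
  rows <- lapply(sort(cutoffs), function(ct) {
    cfg_i <- cfg
    cfg_i$score_cutoff <- ct
    run <- triage_run(psms, proteins, quants = quants, cfg = cfg_i)
    p <- run$psms
    keep <- !is.na(p$variant) & p$status == "retained"
    out <- tibble(
      cutoff = ct,
      retained_unique_peptides = length(unique(paste(p$peptide[keep], p$variant[keep]))),
      retained_sites = length(unique(p$variant[keep]))
    )
    if (!is.null(true_sites)) {
      out$retained_true_sites <- length(intersect(unique(p$variant[keep]), true_sites))
    }
    out
  })
  structure(bind_rows(rows), class = c("sva_sweep", "tbl_df", "tbl", "data.frame"))
}

ensure_variant_columns <- function(psms) {
  if (!"variant" %in% names(psms)) psms$variant <- NA_character_
  if (!"variant_position" %in% names(psms)) {
    psms <- expand_variant(psms)
  }
  psms
}
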