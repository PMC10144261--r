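# Tabular I/O: FASTA protein records, the PSM CSV schema every other module
# consumes, and the key-value triage configuration.

PSM_COLUMNS <- c(
  "psm_id", "peptide", "protein_id", "start", "end", "enzyme", "charge",
  "mz_observed", "mz_theoretical", "precursor_ppm", "score", "engine",
  "rt", "xic_area", "mods", "variant"
)

#' Read protein records from FASTA
#'
#' @param path FASTA file (wrapped or unwrapped).
#' @param chain_labels Optional named character vector mapping protein ids to
#'   chain labels (e.g. `c(mab1_lc = "LC")`); defaults to the first header
#'   token.
#' @return Tibble with `id`, `chain_label`, `sequence`, `length`.
#' @export
read_fasta <- function(path, chain_labels = NULL) {
  set <- Biostrings::readAAStringSet(path)
  ids <- vapply(strsplit(names(set), "\\s+"), `[[`, character(1), 1L)
  labels <- if (is.null(chain_labels)) ids else {
    ifelse(ids %in% names(chain_labels), chain_labels[ids], ids)
  }
  seqs <- unname(as.character(set))
  tibble(
    id = ids,
    chain_label = unname(labels),
    sequence = seqs,
    length = nchar(seqs)
  )
}

#' Write protein records to FASTA
#'
#' @param proteins Tibble with `id` and `sequence` columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(proteins, path) {
  set <- Biostrings::AAStringSet(setNames(proteins$sequence, proteins$id))
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read a PSM table
#'
#' Reads the package's peptide-spectrum-match CSV schema and validates each
#' record: all schema columns present, numeric fields parseable, and the
#' stated `precursor_ppm` consistent with `mz_observed`/`mz_theoretical` to
#' within 0.001 ppm.
#'
#' @param path CSV file with header.
#' @return Tibble of PSMs with variant-call columns (`variant`,
#'   `variant_position`, `variant_wt`, `variant_obs`, `variant_chain`)
#'   expanded from the canonical `variant` name.
#' @export
read_psm_table <- function(path) {
  hdr <- names(readr::read_csv(path, n_max = 0,
                               col_types = readr::cols(.default = readr::col_character()),
                               progress = FALSE))
  missing <- setdiff(PSM_COLUMNS, hdr)
  if (length(missing)) {
    abort(sprintf("PSM table is missing column(s): %s",
                  paste(missing, collapse = ", ")))
  }
  df <- readr::read_csv(path, col_types = readr::cols(
    psm_id = readr::col_character(), peptide = readr::col_character(),
    protein_id = readr::col_character(), start = readr::col_integer(),
    end = readr::col_integer(), enzyme = readr::col_character(),
    charge = readr::col_integer(), mz_observed = readr::col_double(),
    mz_theoretical = readr::col_double(), precursor_ppm = readr::col_double(),
    score = readr::col_double(), engine = readr::col_character(),
    rt = readr::col_double(), xic_area = readr::col_double(),
    mods = readr::col_character(), variant = readr::col_character()
  ), progress = FALSE)
  probs <- readr::problems(df)
  if (nrow(probs)) {
    abort(sprintf("Unparsable value in PSM table at row %d, column '%s'.",
                  probs$row[1], names(df)[probs$col[1]]))
  }
  df$psm_id[is.na(df$psm_id)] <- paste0("row", which(is.na(df$psm_id)))
  validate_psms(df)
  expand_variant(df)
}

#' Write a PSM table
#'
#' Inverse of [read_psm_table()]: writes the schema columns only, so
#' `read_psm_table(write_psm_table(x))` is field-for-field identity.
#'
#' @param psms PSM tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_psm_table <- function(psms, path) {
  readr::write_csv(psms[, PSM_COLUMNS], path, progress = FALSE)
  invisible(path)
}

validate_psms <- function(df) {
  ppm <- 1e6 * (df$mz_observed - df$mz_theoretical) / df$mz_theoretical
  bad <- which(abs(ppm - df$precursor_ppm) > 1e-3)
  if (length(bad)) {
    abort(sprintf(
      "precursor_ppm inconsistent with m/z values at row %d (stated %.4f, recomputed %.4f).",
      bad[1], df$precursor_ppm[bad[1]], ppm[bad[1]]))
  }
  if (any(df$xic_area < 0, na.rm = TRUE)) abort("xic_area must be >= 0.")
  if (any(df$charge < 1, na.rm = TRUE)) abort("charge must be >= 1.")
  invisible(df)
}

#' Build and parse canonical variant names
#'
#' A variant call is named `{wildtype}{position}{observed}_{chain}`, e.g.
#' `"D1E_LC"` or `"I48Mnl_LC"`: a single-letter wildtype, the 1-based
#' position in the chain, the observed residue (possibly multi-letter), and
#' the chain label.
#'
#' @param wildtype Single wildtype residue letter.
#' @param position 1-based residue position in the protein chain.
#' @param observed Observed residue symbol.
#' @param chain Chain label (e.g. `"LC"`, `"HC"`).
#' @return `variant_name()`: the canonical name string.
#' @examples
#' variant_name("D", 1, "E", "LC")
#' parse_variant_name("I48Mnl_LC")
#' @export
variant_name <- function(wildtype, position, observed, chain) {
  paste0(wildtype, position, observed, "_", chain)
}

#' @rdname variant_name
#' @param name Canonical variant name(s).
#' @return `parse_variant_name()`: tibble with `variant`, `variant_wt`,
#'   `variant_position`, `variant_obs`, `variant_chain` (NA rows for NA
#'   input).
#' @export
parse_variant_name <- function(name) {
  m <- regmatches(name, regexec("^([A-Z])([0-9]+)([A-Za-z]+)_(.+)$", name))
  bad <- !is.na(name) & lengths(m) != 5L
  if (any(bad)) {
    abort(sprintf("Malformed variant name '%s'.", name[bad][1]))
  }
  tibble(
    variant = name,
    variant_wt = vapply(m, function(x) if (length(x) == 5L) x[2] else NA_character_, character(1)),
    variant_position = vapply(m, function(x) if (length(x) == 5L) as.integer(x[3]) else NA_integer_, integer(1)),
    variant_obs = vapply(m, function(x) if (length(x) == 5L) x[4] else NA_character_, character(1)),
    variant_chain = vapply(m, function(x) if (length(x) == 5L) x[5] else NA_character_, character(1))
  )
}

expand_variant <- function(df) {
  parsed <- parse_variant_name(df$variant)
  bind_cols_safe(df, parsed[, -1])
}

bind_cols_safe <- function(df, extra) {
  for (nm in names(extra)) df[[nm]] <- extra[[nm]]
  df
}

#' Triage configuration
#'
#' Bundles the score cutoff, mass-error gates and rule parameters used by
#' [triage_run()]. Two profiles carry the documented defaults:
#'
#' * `"high_res"` — Orbitrap workflow with internal calibration: score
#'   cutoff 225, MS1 tolerance 2.0 ppm, MS2 tolerance 5.0 ppm, XIC window
#'   10 ppm, quantification limit 0.2%.
#' * `"legacy"` — ion-trap / Mascot-era workflow: score cutoff 15, MS1
#'   tolerance 8 ppm, MS2 tolerance 0.8 Da (Da-mode flag set).
#'
#' @param profile `"high_res"` or `"legacy"`.
#' @param score_cutoff,ms1_tol_ppm,ms2_tol,xic_window_ppm,quant_limit_pct
#'   Overrides of the profile defaults. Tolerances must be positive.
#' @param near_terminus_window Residue window for the terminal-residue rule
#'   (default 2).
#' @param residue_match_tol_da Absolute Da tolerance when matching a variant
#'   delta to a residue mass (default 0.005).
#' @param match_loss Also match residue *losses* (delta = -residue mass) in
#'   the terminal-residue rule; default `FALSE` (additions only).
#' @param ms2_tol_unit `"ppm"` or `"Da"`.
#' @return A `triage_config` list.
#' @examples
#' triage_config("high_res")
#' triage_config("legacy")
#' @export
triage_config <- function(profile = c("high_res", "legacy"),
                          score_cutoff = NULL, ms1_tol_ppm = NULL,
                          ms2_tol = NULL, xic_window_ppm = NULL,
                          quant_limit_pct = NULL,
                          near_terminus_window = 2L,
                          residue_match_tol_da = 0.005,
                          match_loss = FALSE,
                          ms2_tol_unit = NULL) {
  if (is.character(profile) && length(profile) == 1L &&
      !profile %in% c("high_res", "legacy")) {
    abort(sprintf("Unknown profile '%s'; use \"high_res\" or \"legacy\".", profile))
  }
  profile <- match.arg(profile)
  defaults <- if (profile == "high_res") {
    list(score_cutoff = 225, ms1_tol_ppm = 2.0, ms2_tol = 5.0,
         ms2_tol_unit = "ppm", xic_window_ppm = 10, quant_limit_pct = 0.2)
  } else {
    list(score_cutoff = 15, ms1_tol_ppm = 8.0, ms2_tol = 0.8,
         ms2_tol_unit = "Da", xic_window_ppm = 10, quant_limit_pct = 0.2)
  }
  cfg <- list(
    profile = profile,
    score_cutoff = as.numeric(score_cutoff %||% defaults$score_cutoff),
    ms1_tol_ppm = as.numeric(ms1_tol_ppm %||% defaults$ms1_tol_ppm),
    ms2_tol = as.numeric(ms2_tol %||% defaults$ms2_tol),
    ms2_tol_unit = ms2_tol_unit %||% defaults$ms2_tol_unit,
    xic_window_ppm = as.numeric(xic_window_ppm %||% defaults$xic_window_ppm),
    quant_limit_pct = as.numeric(quant_limit_pct %||% defaults$quant_limit_pct),
    near_terminus_window = as.integer(near_terminus_window),
    residue_match_tol_da = residue_match_tol_da,
    match_loss = isTRUE(match_loss)
  )
  tols <- c(cfg$ms1_tol_ppm, cfg$ms2_tol, cfg$xic_window_ppm,
            cfg$residue_match_tol_da)
  if (any(tols <= 0)) abort("All tolerances must be > 0.")
  if (cfg$quant_limit_pct < 0) abort("quant_limit_pct must be >= 0.")
  structure(cfg, class = "triage_config")
}

#' Read a triage configuration file
#'
#' YAML key-value file; unspecified keys take the profile defaults (see
#' [triage_config()]). The file may also carry `enzymes:` (a list of
#' [enzyme_spec()] fields) and `modifications:` (a list of
#' [modification_def()] fields), returned as attributes `"enzymes"` and
#' `"modifications"`.
#'
#' @param path YAML config path.
#' @return A `triage_config`, with optional registries attached.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  profile <- raw$profile %||% "high_res"
  cfg <- triage_config(
    profile = profile,
    score_cutoff = raw$score_cutoff, ms1_tol_ppm = raw$ms1_tol_ppm,
    ms2_tol = raw$ms2_tol, xic_window_ppm = raw$xic_window_ppm,
    quant_limit_pct = raw$quant_limit_pct,
    near_terminus_window = raw$near_terminus_window %||% 2L,
    residue_match_tol_da = raw$residue_match_tol_da %||% 0.005,
    match_loss = raw$match_loss %||% FALSE,
    ms2_tol_unit = raw$ms2_tol_unit
  )
  if (!is.null(raw$enzymes)) {
    attr(cfg, "enzymes") <- lapply(raw$enzymes, function(e) do.call(enzyme_spec, e))
  }
  if (!is.null(raw$modifications)) {
    attr(cfg, "modifications") <- bind_rows(
      lapply(raw$modifications, function(m) do.call(modification_def, m)))
  }
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a
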