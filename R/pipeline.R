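# End-to-end pipeline: read inputs, triage, quantify, report. All outputs
# are plain text; a provenance header records config, seed and version so a
# re-run with identical inputs is byte-identical apart from the timestamp.

#' Run the sequence-variant triage pipeline
#'
#' digest-aware triage of a PSM table against its protein FASTA, relative
#' quantitation of retained variants, and a markdown report. On any module
#' error, partial outputs are removed and the error is re-raised.
#'
#' @param psms_path PSM CSV (see [read_psm_table()]).
#' @param fasta_path Protein FASTA.
#' @param config_path Optional YAML triage config; defaults to the
#'   `high_res` profile.
#' @param out_dir Output directory (created if needed).
#' @param profile Profile override when no config file is given.
#' @param seed Seed recorded in provenance (the pipeline itself is
#'   deterministic).
#' @return Invisibly, a list with `triage`, `quants`, `paths`.
#' @export
run_pipeline <- function(psms_path, fasta_path, config_path = NULL,
                         out_dir = "sva_out", profile = "high_res",
                         seed = 1L) {
  for (p in c(psms_path, fasta_path, config_path)) {
    if (!is.null(p) && !file.exists(p)) {
      abort(sprintf("Input file does not exist: %s", p))
    }
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(
    annotated = file.path(out_dir, "psms_annotated.csv"),
    quant = file.path(out_dir, "variant_quant.csv"),
    report = file.path(out_dir, "report.md")
  )
  cleanup <- function() unlink(unlist(paths))
  tryCatch({
    cfg <- if (is.null(config_path)) triage_config(profile) else
      read_config(config_path)
    proteins <- read_fasta(fasta_path)
    psms <- read_psm_table(psms_path)
    run <- triage_run(psms, proteins, cfg = cfg)
    quants <- quantify_variants(run$psms, proteins, retained_only = TRUE)
    prov <- provenance_header(cfg, seed)

    ann <- run$psms
    readr::write_csv(ann[, c(PSM_COLUMNS, "status", "triggered_rules", "comment")],
                     paths$annotated, progress = FALSE)
    readr::write_csv(quants, paths$quant, progress = FALSE)
    writeLines(c(prov, render_report(quants, summary = glance(run),
                                     label = basename(psms_path))),
               paths$report)
    invisible(list(triage = run, quants = quants, paths = paths))
  }, error = function(e) {
    cleanup()
    abort(conditionMessage(e))
  })
}

provenance_header <- function(cfg, seed) {
  cfg_str <- paste(names(unclass(cfg)), unlist(lapply(unclass(cfg), paste,
                                                      collapse = ",")),
                   sep = "=", collapse = ";")
  chars <- utf8ToInt(cfg_str)
  hash <- sprintf("%09d", sum(chars * seq_along(chars)) %% 1e9)
  c(sprintf("<!-- svatriage %s | profile=%s | seed=%d | config_hash=%s | %s -->",
            as.character(utils::packageVersion("svatriage")), cfg$profile,
            as.integer(seed), hash, format(Sys.time(), "%Y-%m-%dT%H:%M:%S")))
}
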