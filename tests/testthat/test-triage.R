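# protein: cuts after K2 and K9; full tryptic span 3-9 is "SAVADLK"
P1 <- tibble::tibble(id = "p1", chain_label = "LC",
                     sequence = "MKSAVADLKCDER", length = 13L)

test_that("semi-tryptic rule fires only for non-K/R variants off the junction", {
  # semi peptide 3-7 (specific N-terminus after K2, nonspecific C-terminus)
  semi_mid <- make_psm("SAVAD", start = 3, end = 7,
                       variant = "V5A_LC")      # mid-peptide, no K/R involved
  expect_true(rule_semi_nonKR(semi_mid, P1))

  semi_kr <- make_psm("SAVAD", start = 3, end = 7, variant = "V5K_LC")
  expect_false(rule_semi_nonKR(semi_kr, P1))    # observed Lys involved

  semi_junc <- make_psm("SAVAD", start = 3, end = 7, variant = "D7E_LC")
  expect_false(rule_semi_nonKR(semi_junc, P1))  # variant at nonspecific junction

  full_pep <- make_psm("SAVADLK", start = 3, end = 9, variant = "V5A_LC")
  expect_false(rule_semi_nonKR(full_pep, P1))   # rule scoped to semi peptides

  aspn <- make_psm("SAVAD", start = 3, end = 7, enzyme = "aspn",
                   variant = "V5A_LC")
  expect_false(rule_semi_nonKR(aspn, P1))       # rule scoped to trypsin
  expect_error(rule_semi_nonKR(semi_mid, NULL), "Protein")
})

test_that("terminal-residue rule matches delta to residues near termini", {
  cfg <- triage_config("high_res")
  # G->Q is +71.0371 Da = Ala; Ala sits at position 2 of SAPLK
  expect_true(rule_terminal_residue(
    make_psm("SAPLK", start = 1, end = 5, variant = "G3Q_LC"), cfg))
  # +58.0055 (A->E) matches no canonical residue mass within 5 mDa
  expect_false(rule_terminal_residue(
    make_psm("SAPLK", start = 1, end = 5, variant = "A2E_LC"), cfg))
  # matching residue absent from the peptide entirely
  expect_false(rule_terminal_residue(
    make_psm("SGPLK", start = 1, end = 5, variant = "G3Q_LC"), cfg))
  # residue present but buried mid-peptide, outside the 2-residue window
  expect_false(rule_terminal_residue(
    make_psm("SGGAGGK", start = 1, end = 7, variant = "G3Q_LC"), cfg))
  # loss matching is off by default, on behind the flag
  loss <- make_psm("SAPLK", start = 1, end = 5, variant = "Q3G_LC")
  expect_false(rule_terminal_residue(loss, cfg))
  cfg_loss <- triage_config("high_res", match_loss = TRUE)
  expect_true(rule_terminal_residue(loss, cfg_loss))
})

test_that("quant-limit rule is strictly-below: the limit itself is kept", {
  cfg <- triage_config("high_res") # limit 0.2%
  expect_true(rule_below_quant_limit(0.1, cfg))
  expect_false(rule_below_quant_limit(0.2, cfg))
  expect_false(rule_below_quant_limit(0.5, cfg))
})

test_that("orthogonal redundancy requires a confident tryptic PSM at the site", {
  cfg <- triage_config("high_res")
  tryp <- make_psm("SAVADLK", start = 3, end = 9, score = 300,
                   variant = "V5A_LC", psm_id = "t")
  therm <- make_psm("AVADL", start = 4, end = 8, enzyme = "thermolysin",
                    score = 260, variant = "V5A_LC", psm_id = "h")
  both <- dplyr::bind_rows(tryp, therm)
  expect_identical(rule_orthogonal_redundant(both, cfg), c(FALSE, TRUE))

  # site seen only on Asp-N: nothing to be redundant with
  aspn <- make_psm("AVADL", start = 4, end = 8, enzyme = "aspn",
                   score = 260, variant = "V5A_LC")
  expect_identical(rule_orthogonal_redundant(aspn, cfg), FALSE)

  # low-scoring tryptic evidence does not count as coverage
  weak <- dplyr::bind_rows(
    make_psm("SAVADLK", start = 3, end = 9, score = 100, variant = "V5A_LC"),
    make_psm("AVADL", start = 4, end = 8, enzyme = "aspn", score = 260,
             variant = "V5A_LC"))
  expect_identical(rule_orthogonal_redundant(weak, cfg), c(FALSE, FALSE))
})

test_that("score and mass-error gates use strict boundaries", {
  cfg <- triage_config("high_res")
  g <- apply_gates(make_psm("AK", start = 1, end = 2, score = 224.9, ppm = 0), cfg)
  expect_true(g$G_score)
  g <- apply_gates(make_psm("AK", start = 1, end = 2, score = 225, ppm = -1.9), cfg)
  expect_false(g$G_score); expect_false(g$G_mass_error)
  g <- apply_gates(make_psm("AK", start = 1, end = 2, score = 300, ppm = 2.1), cfg)
  expect_true(g$G_mass_error)
})

test_that("triage annotates, never deletes, and comments name every rule", {
  proj <- sva7_fixture()
  run <- triage_run(proj$psms, proj$proteins)
  expect_identical(nrow(run$annotations), nrow(proj$psms))
  ann <- run$annotations
  expect_identical(ann$status == "false_positive",
                   nzchar(ann$triggered_rules))
  # parsing the comment recovers exactly the triggered rule set
  for (i in which(nzchar(ann$triggered_rules))) {
    from_comment <- regmatches(ann$comment[i],
                               gregexpr("\\[([A-Za-z0-9_]+)\\]", ann$comment[i]))[[1]]
    from_comment <- gsub("[][]", "", from_comment)
    expect_setequal(from_comment,
                    strsplit(ann$triggered_rules[i], ";")[[1]])
  }
  expect_error(triage_run(proj$psms, proj$proteins[0, ]), "unknown protein")
})

test_that("triage is idempotent and handles empty input", {
  proj <- sva7_fixture()
  run1 <- triage_run(proj$psms, proj$proteins)
  run2 <- triage_run(run1$psms, proj$proteins)
  expect_identical(run1$annotations, run2$annotations)
  expect_identical(run1$summary, run2$summary)

  empty <- triage_run(proj$psms[0, ], proj$proteins)
  expect_identical(nrow(empty$annotations), 0L)
  expect_identical(empty$summary$retained_variant_sites, 0L)
})

test_that("no planted true variant at or above limit and cutoff is flagged", {
  proj <- sva7_fixture()
  run <- triage_run(proj$psms, proj$proteins)
  truth <- proj$truth
  true_sv <- truth$variant[truth$class == "true_sv"]
  p <- run$psms
  for (v in true_sv) {
    tryp_rows <- p[!is.na(p$variant) & p$variant == v & p$enzyme == "trypsin", ]
    expect_true(all(tryp_rows$status == "retained"), info = v)
  }
})

test_that("retained counts are monotone in cutoff, quant limit and MS1 tolerance", {
  proj <- sva7_fixture()
  sw <- threshold_sweep(proj$psms, proj$proteins,
                        c(0, 100, 200, 225, 250, 300, 1e9),
                        truth = proj$truth)
  expect_true(all(diff(sw$retained_unique_peptides) <= 0))
  expect_true(all(diff(sw$retained_sites) <= 0))
  expect_identical(sw$retained_sites[sw$cutoff == 1e9], 0L)

  n_sites <- function(cfg) {
    length(retained_sites(triage_run(proj$psms, proj$proteins, cfg = cfg)))
  }
  by_limit <- vapply(c(0.05, 0.2, 0.35), function(q) {
    n_sites(triage_config("high_res", quant_limit_pct = q))
  }, integer(1))
  expect_true(all(diff(by_limit) <= 0))
  by_tol <- vapply(c(0.5, 2, 8), function(tol) {
    n_sites(triage_config("high_res", ms1_tol_ppm = tol))
  }, integer(1))
  expect_true(all(diff(by_tol) >= 0))
})
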