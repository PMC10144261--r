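test_that("synthetic projects are byte-identical for the same seed", {
  d1 <- file.path(tempdir(), "synth_a"); d2 <- file.path(tempdir(), "synth_b")
  synth_project(synth_config(), seed = 7, out_dir = d1)
  synth_project(synth_config(), seed = 7, out_dir = d2)
  for (f in c("proteins.fasta", "psms.csv", "truth.csv")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
  }
  # and a different seed gives different data
  d3 <- file.path(tempdir(), "synth_c")
  synth_project(synth_config(), seed = 8, out_dir = d3)
  expect_false(identical(readLines(file.path(d1, "psms.csv")),
                         readLines(file.path(d3, "psms.csv"))))
})

test_that("the default fixture plants the documented truth mix", {
  proj <- sva7_fixture()
  counts <- table(proj$truth$class)
  expect_identical(as.integer(counts[["true_sv"]]), 7L)
  expect_identical(as.integer(counts[["semi_nonKR"]]), 20L)
  expect_identical(as.integer(counts[["terminal_residue"]]), 10L)
  expect_identical(as.integer(counts[["below_limit"]]), 10L)
  expect_identical(as.integer(counts[["orthogonal"]]), 10L)
  # exactly three true variants have best scores in [225, 250)
  p <- proj$psms
  best <- vapply(proj$truth$variant[proj$truth$class == "true_sv"], function(v) {
    max(p$score[!is.na(p$variant) & p$variant == v & p$enzyme == "trypsin"])
  }, numeric(1))
  expect_identical(sum(best >= 225 & best < 250), 3L)
  expect_identical(sum(best >= 250), 4L)
  expect_true(all(best >= 225))
})

test_that("planted classes a, b, d are caught by their matching rule with zero misses", {
  # a structural property of the generator + rules, checked across seeds
  for (seed in c(101, 202, 303)) {
    proj <- sva7_fixture(seed)
    run <- triage_run(proj$psms, proj$proteins)
    p <- run$psms
    v <- p[!is.na(p$variant), ]
    truth <- proj$truth
    class_of <- function(row) {
      if (row$enzyme != "trypsin") return("orthogonal")
      truth$class[match(row$variant, truth$variant)]
    }
    for (i in seq_len(nrow(v))) {
      cls <- class_of(v[i, ])
      fired <- strsplit(v$triggered_rules[i], ";")[[1]]
      if (cls == "semi_nonKR") expect_true("R1_semi_nonKR" %in% fired)
      if (cls == "terminal_residue") expect_true("R2_terminal_residue" %in% fired)
      if (cls == "orthogonal") expect_true("R4_orthogonal_redundant" %in% fired)
      if (cls == "below_limit") expect_true("R3_below_quant_limit" %in% fired)
    }
  }
})

test_that("with no planted false positives every true variant is retained", {
  cfg <- synth_config(fp_counts = c(semi_nonKR = 0L, terminal_residue = 0L,
                                    below_limit = 0L, orthogonal = 0L))
  proj <- synth_project(cfg, seed = 55)
  run <- triage_run(proj$psms, proj$proteins)
  expect_setequal(retained_sites(run),
                  proj$truth$variant[proj$truth$class == "true_sv"])
})

test_that("variant names in the truth table are consistent with the chains", {
  proj <- sva7_fixture()
  parsed <- parse_variant_name(proj$truth$variant)
  for (i in seq_len(nrow(proj$truth))) {
    prot <- proj$proteins[proj$proteins$id == proj$truth$protein_id[i], ]
    expect_identical(parsed$variant_chain[i], prot$chain_label)
    expect_identical(
      substring(prot$sequence, parsed$variant_position[i],
                parsed$variant_position[i]),
      parsed$variant_wt[i])
  }
})

test_that("high-ppm decoys pass the legacy gate but fail the 2 ppm gate", {
  proj <- synth_project(synth_config(n_ppm_decoys = 5L), seed = 66)
  decoys <- proj$truth$variant[proj$truth$class == "ppm_decoy"]
  expect_identical(length(decoys), 5L)
  hr <- triage_run(proj$psms, proj$proteins, cfg = triage_config("high_res"))
  lg <- triage_run(proj$psms, proj$proteins,
                   cfg = triage_config("legacy", score_cutoff = 225,
                                       quant_limit_pct = 0.2))
  expect_identical(length(intersect(retained_sites(hr), decoys)), 0L)
  expect_setequal(intersect(retained_sites(lg), decoys), decoys)
  expect_lt(length(retained_sites(hr)), length(retained_sites(lg)))
})
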