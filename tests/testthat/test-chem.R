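test_that("residue masses follow the standard monoisotopic table", {
  expect_equal(residue_mass("G"), 57.021464, tolerance = 1e-6)
  expect_equal(residue_mass("A"), 71.037114, tolerance = 1e-6)
  expect_identical(residue_mass("I"), residue_mass("L"))
  expect_true(all(residue_masses() > 0))
  expect_error(residue_mass("B"), "Unknown residue symbol 'B'")
})

test_that("peptide mass is residues plus water plus modifications", {
  expect_equal(peptide_mass("G"), 57.021464 + 18.010565, tolerance = 1e-6)
  expect_equal(peptide_mass("AG"), 71.037114 + 57.021464 + 18.010565,
               tolerance = 1e-6)
  expect_error(peptide_mass(""), "non-empty")
  mods <- tibble::tibble(position = 2L, name = "carboxymethyl")
  expect_equal(
    peptide_mass("ACK", mods, registry = default_modifications(0L)),
    peptide_mass("ACK") + 58.005479, tolerance = 1e-6)
  # mod applied where its target residue is absent
  expect_error(peptide_mass("AGK", tibble::tibble(position = 2L, name = "carboxymethyl")),
               "targets")
})

test_that("Ala->Glu and Gly->Asp share the +58.0055 Da isobaric shift", {
  expect_equal(round(substitution_delta("A", "E"), 4), 58.0055)
  expect_equal(round(substitution_delta("G", "D"), 4), 58.0055)
  expect_identical(substitution_delta("A", "A"), 0)
  expect_equal(substitution_delta("I", "Mnl"), 14.01565, tolerance = 1e-5)
})

test_that("substitution deltas are antisymmetric over the whole table", {
  syms <- names(residue_masses())
  for (a in syms) for (b in syms) {
    expect_identical(substitution_delta(a, b), -substitution_delta(b, a))
  }
})

test_that("isobaric partners of +58.0055 are A->E, G->D, and light carboxymethyl", {
  light <- modification_def("carboxymethyl", 58.005479, "C", n_13C = 0L)
  hits <- isobaric_partners(58.0055, 0.005, registry = light)
  expect_setequal(hits$label, c("A->E", "G->D", "carboxymethyl"))
  # the heavy 2x13C reagent moves the adduct off the isobar
  heavy <- modification_def("carboxymethyl", 58.005479, "C", n_13C = 2L)
  hits2 <- isobaric_partners(58.0055, 0.005, registry = heavy)
  expect_setequal(hits2$label, c("A->E", "G->D"))
  # the only exactly isobaric canonical pair
  expect_setequal(isobaric_partners(0, 5e-4)$label, c("I->L", "L->I"))
  expect_error(isobaric_partners(10, 0), "tolerance")
})

test_that("isobaric_partners agrees with an exhaustive scan on random queries", {
  masses <- residue_masses()
  reg <- rbind(default_modifications(2L),
               modification_def("deamidation", 0.984016, c("N", "Q")))
  brute <- function(q, tol) {
    labs <- character(0)
    for (a in names(masses)) for (b in names(masses)) {
      if (a == b) next
      if (abs((masses[[b]] - masses[[a]]) - q) <= tol) {
        labs <- c(labs, paste0(a, "->", b))
      }
    }
    for (k in seq_len(nrow(reg))) {
      if (abs(reg$delta[k] - q) <= tol) labs <- c(labs, reg$name[k])
    }
    sort(labs)
  }
  withr::with_seed(11, {
    for (i in 1:200) {
      q <- runif(1, -60, 190)
      tol <- runif(1, 1e-4, 0.2)
      got <- isobaric_partners(q, tol, registry = reg)
      expect_identical(sort(got$label), brute(q, tol))
      # deterministic ordering: ascending |query - candidate|
      expect_true(!is.unsorted(got$abs_diff))
    }
  })
})

test_that("heavy and light modification deltas differ by n_13C x 1.0033548", {
  for (n in 0:3) {
    m <- modification_def("x", 12.5, "C", n_13C = n)
    expect_equal(m$delta, 12.5 + n * 1.0033548, tolerance = 1e-9)
  }
})
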