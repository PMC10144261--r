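# Shared fixtures, built once per test run.

.fixture_cache <- new.env(parent = emptyenv())

# default "sva7" spike-calibration project (seed fixed for the suite)
sva7_fixture <- function(seed = 101) {
  key <- paste0("sva7_", seed)
  if (is.null(.fixture_cache[[key]])) {
    .fixture_cache[[key]] <- synth_project(synth_config(), seed = seed)
  }
  .fixture_cache[[key]]
}

# minimal hand-built PSM row for rule unit tests
make_psm <- function(peptide, protein_id = "p1", start, end, enzyme = "trypsin",
                     score = 300, ppm = 0.5, xic_area = 1000,
                     variant = NA_character_, psm_id = "x1", charge = 2L) {
  row <- tibble::tibble(
    psm_id = psm_id, peptide = peptide, protein_id = protein_id,
    start = as.integer(start), end = as.integer(end), enzyme = enzyme,
    charge = charge, mz_observed = 500 * (1 + ppm / 1e6),
    mz_theoretical = 500, precursor_ppm = ppm, score = score,
    engine = "byonic-like", rt = 10, xic_area = xic_area,
    mods = NA_character_, variant = variant
  )
  svatriage:::expand_variant(row)
}

# Independent brute-force digestion oracle: judges every substring directly
# from the enzyme definition, without using cleavage_sites()/digest().
oracle_digest <- function(sequence, enzyme, mode = c("full", "semi")) {
  mode <- match.arg(mode)
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  n <- length(chars)
  is_cut <- function(i) { # bond between residues i and i+1
    if (i < 1 || i >= n) return(FALSE)
    if (enzyme$cut_side == "C") {
      chars[i] %in% enzyme$residues &&
        !(isTRUE(enzyme$suppress_before_proline) && chars[i + 1] == "P")
    } else {
      chars[i + 1] %in% enzyme$residues
    }
  }
  lo <- enzyme$length_bounds[1]; hi <- enzyme$length_bounds[2]
  out <- list()
  for (s in 1:n) for (e in s:n) {
    len <- e - s + 1
    if (len < lo || len > hi) next
    n_spec <- s == 1 || is_cut(s - 1)
    c_spec <- e == n || is_cut(e)
    kind <- if (n_spec && c_spec) "full" else if (n_spec || c_spec) "semi" else "nonspecific"
    if (kind == "nonspecific") next
    if (mode == "full" && kind != "full") next
    missed <- sum(vapply(seq_len(max(0, e - s)), function(k) is_cut(s + k - 1), logical(1)))
    if (missed > enzyme$max_missed_cleavages) next
    out[[length(out) + 1L]] <- c(s, e)
  }
  if (!length(out)) return(tibble::tibble(start = integer(), end = integer()))
  m <- unique(do.call(rbind, out))
  tibble::tibble(start = m[, 1], end = m[, 2])[order(m[, 1], m[, 2]), ]
}

random_protein <- function(len, kr_frac = 0.15) {
  canon <- c("G","A","S","P","V","T","C","L","I","N","D","Q","K","E","M","H","F","R","Y","W")
  paste(sample(canon, len, replace = TRUE), collapse = "")
}
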