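# In-silico proteolysis. Cut positions are inter-residue: cut index i means
# the bond between residues i and i+1 (1-based residues); protein ends are
# never listed as cuts. Coordinates of peptides are 1-based inclusive.

#' Define a protease
#'
#' @param name Enzyme name (used verbatim in PSM tables; `"trypsin"` drives
#'   the semi-tryptic triage rule).
#' @param cut_side `"C"` (cut after a member residue) or `"N"` (cut before).
#' @param residues Residue letters the enzyme recognises.
#' @param suppress_before_proline Drop cuts immediately followed by proline
#'   (the usual search-engine convention for trypsin).
#' @param max_missed_cleavages Non-negative integer or `Inf` for unlimited.
#' @param length_bounds Integer vector `c(min, max)` peptide length in
#'   residues; with unlimited missed cleavages the max bound also caps the
#'   span enumeration.
#' @return An `enzyme_spec` list.
#' @examples
#' enzyme_trypsin()
#' enzyme_spec("aspn", "N", "D", max_missed_cleavages = 2)
#' @export
enzyme_spec <- function(name, cut_side = c("C", "N"), residues,
                        suppress_before_proline = FALSE,
                        max_missed_cleavages = 2,
                        length_bounds = c(1L, 50L)) {
  cut_side <- match.arg(cut_side)
  stopifnot(length(residues) >= 1L, all(nchar(residues) == 1L))
  if (length_bounds[1] < 1L || length_bounds[1] > length_bounds[2]) {
    abort("`length_bounds` must satisfy 1 <= min <= max.")
  }
  if (max_missed_cleavages < 0) abort("`max_missed_cleavages` must be >= 0.")
  structure(
    list(name = name, cut_side = cut_side, residues = residues,
         suppress_before_proline = suppress_before_proline,
         max_missed_cleavages = max_missed_cleavages,
         length_bounds = as.numeric(length_bounds)),
    class = "enzyme_spec"
  )
}

#' @rdname enzyme_spec
#' @param ... Overrides passed to [enzyme_spec()] field defaults.
#' @export
enzyme_trypsin <- function(...) {
  args <- list(name = "trypsin", cut_side = "C", residues = c("K", "R"),
               suppress_before_proline = TRUE, max_missed_cleavages = 1,
               length_bounds = c(1L, 50L))
  args[names(list(...))] <- list(...)
  do.call(enzyme_spec, args)
}

#' @rdname enzyme_spec
#' @export
enzyme_aspn <- function(...) {
  # sequencing-grade convention: D only, E excluded
  args <- list(name = "aspn", cut_side = "N", residues = "D",
               max_missed_cleavages = 2, length_bounds = c(1L, 50L))
  args[names(list(...))] <- list(...)
  do.call(enzyme_spec, args)
}

#' @rdname enzyme_spec
#' @export
enzyme_thermolysin <- function(...) {
  # unlimited missed cleavages; spans capped at 40 residues to bound the
  # enumeration while keeping every practically observable peptide
  args <- list(name = "thermolysin", cut_side = "N",
               residues = c("A", "F", "I", "L", "M", "V"),
               max_missed_cleavages = Inf, length_bounds = c(1L, 40L))
  args[names(list(...))] <- list(...)
  do.call(enzyme_spec, args)
}

#' Enzymatic cleavage sites of a protein
#'
#' @param sequence Protein sequence string (1-based residues).
#' @param enzyme An [enzyme_spec()].
#' @return Sorted integer vector of inter-residue cut positions: cut `i`
#'   falls between residues `i` and `i + 1`. Protein ends are not included.
#' @examples
#' cleavage_sites("AKRPG", enzyme_trypsin()) # 2 (R3-P4 suppressed)
#' cleavage_sites("MDAD", enzyme_aspn())     # 1, 3
#' @export
cleavage_sites <- function(sequence, enzyme) {
  stopifnot(inherits(enzyme, "enzyme_spec"), nzchar(sequence))
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  n <- length(chars)
  if (enzyme$cut_side == "C") {
    cuts <- which(chars %in% enzyme$residues)
    if (isTRUE(enzyme$suppress_before_proline)) {
      cuts <- cuts[!(cuts < n & chars[pmin(cuts + 1L, n)] == "P")]
    }
  } else {
    cuts <- which(chars %in% enzyme$residues) - 1L
  }
  sort(unique(cuts[cuts >= 1L & cuts <= n - 1L]))
}

#' Digest a protein in silico
#'
#' Enumerates fully specific peptides as spans between cleavage sites with at
#' most `max_missed_cleavages` internal sites, filtered to the enzyme's
#' length bounds. In `"semi"` mode every sub-peptide of a fully specific
#' peptide that retains exactly one specific terminus is added (protein
#' termini count as specific). Results are deduplicated by coordinates and
#' ordered by `(start, end)`.
#'
#' @param protein One-row tibble or list with `id`, `sequence` and optionally
#'   `chain_label`, or a plain sequence string.
#' @param enzyme An [enzyme_spec()].
#' @param specificity `"full"` or `"semi"`.
#' @return Tibble of peptides: `protein_id`, `start`, `end`, `sequence`,
#'   `enzyme`, `n_missed`, `specificity`.
#' @examples
#' digest("AKCKD", enzyme_trypsin())
#' @export
digest <- function(protein, enzyme, specificity = c("full", "semi")) {
  specificity <- match.arg(specificity)
  protein <- as_protein(protein)
  seqstr <- protein$sequence
  n <- nchar(seqstr)
  cuts <- cleavage_sites(seqstr, enzyme)
  bounds <- c(0L, cuts, n)
  lo <- enzyme$length_bounds[1]; hi <- enzyme$length_bounds[2]

  spans <- list()
  nb <- length(bounds)
  for (i in seq_len(nb - 1L)) {
    for (j in (i + 1L):nb) {
      start <- bounds[i] + 1L
      end <- bounds[j]
      len <- end - start + 1L
      if (len > hi) break
      missed <- j - i - 1L
      if (missed > enzyme$max_missed_cleavages) break
      if (len >= lo) spans[[length(spans) + 1L]] <- c(start, end, missed)
    }
  }
  full <- if (length(spans)) do.call(rbind, spans) else
    matrix(integer(0), ncol = 3)
  res <- tibble(
    start = as.integer(full[, 1]), end = as.integer(full[, 2]),
    n_missed = as.integer(full[, 3]), specificity = "full"
  )

  if (specificity == "semi") {
    # one-specific-terminus spans, anchored at each specific boundary
    semi <- list()
    n_starts <- c(1L, cuts + 1L)            # specific N-termini
    c_ends <- c(cuts, n)                    # specific C-termini
    for (s in n_starts) {
      for (e in seq.int(s, min(s + hi - 1L, n))) {
        missed <- sum(cuts >= s & cuts < e)
        if (missed > enzyme$max_missed_cleavages) break
        if (e - s + 1L >= lo && !(e %in% c_ends)) {
          semi[[length(semi) + 1L]] <- c(s, e, missed)
        }
      }
    }
    for (e in c_ends) {
      for (s in seq.int(e, max(1L, e - hi + 1L))) {
        missed <- sum(cuts >= s & cuts < e)
        if (missed > enzyme$max_missed_cleavages) break
        if (e - s + 1L >= lo && !(s %in% n_starts)) {
          semi[[length(semi) + 1L]] <- c(s, e, missed)
        }
      }
    }
    if (length(semi)) {
      sm <- unique(do.call(rbind, semi))
      res <- bind_rows(res, tibble(
        start = as.integer(sm[, 1]), end = as.integer(sm[, 2]),
        n_missed = as.integer(sm[, 3]), specificity = "semi"
      ))
    }
  }

  res <- res[!duplicated(res[c("start", "end")]), ]
  res <- res[order(res$start, res$end), ]
  tibble(
    protein_id = protein$id,
    start = res$start, end = res$end,
    sequence = substring(seqstr, res$start, res$end),
    enzyme = enzyme$name,
    n_missed = res$n_missed,
    specificity = res$specificity
  )
}

#' Classify the enzymatic specificity of a peptide span
#'
#' A terminus is specific when it coincides with a cleavage site of the
#' enzyme or with a protein terminus.
#'
#' @param start,end 1-based inclusive residue coordinates.
#' @param sequence Protein sequence string.
#' @param enzyme An [enzyme_spec()].
#' @return `"full"`, `"semi"`, or `"nonspecific"`.
#' @examples
#' classify_specificity(3, 4, "AKCKD", enzyme_trypsin()) # full
#' classify_specificity(4, 5, "AKCKD", enzyme_trypsin()) # semi
#' @export
classify_specificity <- function(start, end, sequence, enzyme) {
  n <- nchar(sequence)
  if (start < 1L || end > n || start > end) {
    abort(sprintf("Peptide span %d-%d outside protein of length %d.",
                  start, end, n))
  }
  cuts <- cleavage_sites(sequence, enzyme)
  n_ok <- start == 1L || (start - 1L) %in% cuts
  c_ok <- end == n || end %in% cuts
  if (n_ok && c_ok) "full" else if (n_ok || c_ok) "semi" else "nonspecific"
}

#' Locate a peptide within a protein
#'
#' @param sequence Protein sequence string.
#' @param peptide Non-empty query sequence.
#' @return Tibble of 1-based inclusive `(start, end)` occurrences, including
#'   overlapping matches; zero rows when absent.
#' @examples
#' map_peptide("AAA", "AA")
#' @export
map_peptide <- function(sequence, peptide) {
  if (!nzchar(peptide)) abort("`peptide` must be non-empty.")
  starts <- integer(0)
  from <- 1L
  repeat {
    hit <- regexpr(peptide, substring(sequence, from), fixed = TRUE)
    if (hit == -1L) break
    starts <- c(starts, from + as.integer(hit) - 1L)
    from <- from + as.integer(hit)
  }
  tibble(start = starts, end = starts + nchar(peptide) - 1L)
}

# Coerce sequence strings / lists / one-row tibbles to a protein record.
as_protein <- function(protein) {
  if (is.character(protein) && length(protein) == 1L) {
    protein <- list(id = "protein1", sequence = protein)
  }
  if (is.data.frame(protein)) {
    stopifnot(nrow(protein) == 1L)
    protein <- as.list(protein)
  }
  if (is.null(protein$chain_label)) protein$chain_label <- protein$id
  if (is.null(protein$sequence) || !nzchar(protein$sequence)) {
    abort("Protein sequence must be non-empty.")
  }
  protein
}
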