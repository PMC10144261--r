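# Monoisotopic mass bookkeeping for residues, modifications and amino acid
# substitutions. All masses are residue (dehydrated) masses in Da; peptide
# masses add one water. Values are fixed constants so results do not depend
# on any external mass table.

# 13C - 12C monoisotopic mass difference, Da
C13_SHIFT <- 1.0033548

# Water monoisotopic mass, Da; the single constant used by every peptide-mass
# computation in the package.
WATER_MASS <- 18.010565

.CANONICAL_MASSES <- c(
  G = 57.021464, A = 71.037114, S = 87.032028, P = 97.052764,
  V = 99.068414, T = 101.047679, C = 103.009185, L = 113.084064,
  I = 113.084064, N = 114.042927, D = 115.026943, Q = 128.058578,
  K = 128.094963, E = 129.042593, M = 131.040485, H = 137.058912,
  F = 147.068414, R = 156.101111, Y = 163.063329, W = 186.079313
)

#' Monoisotopic residue mass table
#'
#' Returns the table of monoisotopic residue masses (in Da) used by all mass
#' arithmetic in the package: the 20 canonical amino acids, optionally
#' extended with configured non-canonical targets. `Mnl` (methylnorleucine,
#' an isoleucine misincorporation product) is included by default at
#' Ile + CH2 (+14.015650 Da).
#'
#' Residue masses are dehydrated: a peptide's neutral mass is the sum of its
#' residue masses plus one water ([WATER_MASS]). Isoleucine and leucine are
#' exactly isobaric by construction.
#'
#' @param extra Named numeric vector of additional residue symbols and their
#'   monoisotopic masses in Da. Symbols may be multi-letter (e.g. `"Mnl"`).
#' @param include_mnl Include methylnorleucine (`Mnl`)? Default `TRUE`.
#' @return Named numeric vector of residue masses in Da.
#' @examples
#' residue_masses()[["G"]]
#' residue_masses(extra = c(Hyp = 113.047679))
#' @export
residue_masses <- function(extra = NULL, include_mnl = TRUE) {
  tab <- .CANONICAL_MASSES
  if (include_mnl) {
    tab <- c(tab, Mnl = unname(.CANONICAL_MASSES[["I"]] + 14.015650))
  }
  if (!is.null(extra)) {
    if (is.null(names(extra)) || any(!nzchar(names(extra)))) {
      abort("`extra` residue masses must be a named numeric vector.")
    }
    tab[names(extra)] <- extra
  }
  if (any(tab <= 0)) {
    abort("All residue masses must be strictly positive.")
  }
  tab
}

#' Look up a monoisotopic residue mass
#'
#' @param symbol One residue symbol present in `masses`.
#' @param masses Residue mass table, as from [residue_masses()].
#' @return Residue monoisotopic mass in Da.
#' @examples
#' residue_mass("G") # 57.021464
#' @export
residue_mass <- function(symbol, masses = residue_masses()) {
  stopifnot(is.character(symbol), length(symbol) == 1L)
  if (!symbol %in% names(masses)) {
    abort(sprintf("Unknown residue symbol '%s'; configured symbols: %s",
                  symbol, paste(names(masses), collapse = ", ")))
  }
  unname(masses[[symbol]])
}

#' Define a (possibly isotope-labelled) modification
#'
#' A modification is a named mass delta applied to a set of target residues
#' and/or peptide termini. A heavy (13C-labelled) variant of a light
#' modification shifts the delta by exactly `n_13C` times the 13C-12C mass
#' difference (1.0033548 Da). The motivating case is cysteine
#' carboxymethylation (+58.005479 Da), whose light form is isobaric with the
#' Ala->Glu / Gly->Asp substitution shift; alkylating with heavy iodoacetic
#' acid moves the adduct off that isobar.
#'
#' @param name Modification name.
#' @param delta Mass delta of the light form, Da.
#' @param targets Character vector of residue symbols and/or `"N-term"`,
#'   `"C-term"`.
#' @param n_13C Number of 13C atoms in the heavy label; 0 for unlabelled.
#' @return One-row tibble with columns `name`, `delta`, `targets`
#'   (list-column), `n_13C`. The stored `delta` includes the heavy shift.
#' @examples
#' modification_def("carboxymethyl", 58.005479, "C")
#' modification_def("carboxymethyl_heavy", 58.005479, "C", n_13C = 2)
#' @export
modification_def <- function(name, delta, targets, n_13C = 0L) {
  stopifnot(is.character(name), length(name) == 1L,
            is.numeric(delta), length(delta) == 1L,
            is.character(targets), length(targets) >= 1L,
            n_13C >= 0)
  tibble(
    name = name,
    delta = delta + n_13C * C13_SHIFT,
    light_delta = delta,
    targets = list(targets),
    n_13C = as.integer(n_13C)
  )
}

#' Default modification registry
#'
#' Carbamidomethyl-free default registry for the heavy-iodoacetic-acid
#' workflow: cysteine carboxymethylation with a 2 x 13C label, which places
#' the adduct at +60.012189 Da, cleanly separated from the +58.0055 Da
#' substitution isobar.
#'
#' @param heavy_n_13C Label count for the carboxymethyl reagent (0 gives the
#'   light, isobar-conflicting form).
#' @return Modification registry tibble (rows as from [modification_def()]).
#' @export
default_modifications <- function(heavy_n_13C = 2L) {
  modification_def("carboxymethyl", 58.005479, "C", n_13C = heavy_n_13C)
}

#' Neutral monoisotopic peptide mass
#'
#' Sum of residue masses plus one water plus any modification deltas.
#'
#' @param sequence Non-empty residue string over the configured table.
#'   Multi-letter symbols are not parsed from strings; sequences containing
#'   them must be passed as a character vector of symbols.
#' @param mods Optional tibble of modification applications with columns
#'   `position` (1-based residue index, or `NA` for terminal mods) and
#'   `name` (a name in `registry`).
#' @param registry Modification registry, as from [default_modifications()].
#' @param masses Residue mass table.
#' @return Neutral monoisotopic mass in Da.
#' @examples
#' peptide_mass("G")  # 75.032029
#' peptide_mass("AG") # 146.069143
#' @export
peptide_mass <- function(sequence, mods = NULL, registry = default_modifications(),
                         masses = residue_masses()) {
  symbols <- split_residues(sequence)
  if (length(symbols) == 0L) abort("Peptide sequence must be non-empty.")
  total <- sum(vapply(symbols, residue_mass, numeric(1), masses = masses)) +
    WATER_MASS
  if (!is.null(mods) && nrow(mods) > 0L) {
    for (i in seq_len(nrow(mods))) {
      row <- registry[registry$name == mods$name[[i]], ]
      if (nrow(row) == 0L) {
        abort(sprintf("Modification '%s' is not in the registry.", mods$name[[i]]))
      }
      pos <- mods$position[[i]]
      targets <- row$targets[[1]]
      residue_targets <- setdiff(targets, c("N-term", "C-term"))
      if (!is.na(pos)) {
        if (pos < 1L || pos > length(symbols)) {
          abort(sprintf("Modification position %d outside peptide (length %d).",
                        pos, length(symbols)))
        }
        if (length(residue_targets) > 0L && !symbols[[pos]] %in% residue_targets) {
          abort(sprintf(
            "Modification '%s' targets {%s} but residue at position %d is '%s'.",
            row$name, paste(residue_targets, collapse = ","), pos, symbols[[pos]]))
        }
      } else if (!any(c("N-term", "C-term") %in% targets)) {
        abort(sprintf("Modification '%s' needs a residue position.", row$name))
      }
      total <- total + row$delta
    }
  }
  total
}

#' Signed mass shift of an amino acid substitution
#'
#' `mass(observed) - mass(wildtype)`, the precursor-level delta a search
#' engine reports for a single-residue substitution. Ala->Glu and Gly->Asp
#' share the +58.0055 Da shift (to 4 decimals) that is also produced by
#' light carboxymethylation.
#'
#' @param wildtype,observed Residue symbols in the configured table.
#' @param masses Residue mass table.
#' @return Signed delta in Da.
#' @examples
#' substitution_delta("A", "E") # +58.005479
#' substitution_delta("G", "D") # +58.005479
#' substitution_delta("I", "Mnl") # +14.01565
#' @export
substitution_delta <- function(wildtype, observed, masses = residue_masses()) {
  residue_mass(observed, masses) - residue_mass(wildtype, masses)
}

#' Enumerate isobaric explanations of a mass shift
#'
#' Scans every ordered substitution pair in the residue table and every
#' registered modification for deltas within `tolerance` of the query. Used
#' to flag shifts (such as +58.0055 Da) that cannot be attributed to a
#' substitution without orthogonal evidence.
#'
#' @param delta Query mass shift, Da.
#' @param tolerance Absolute match tolerance, Da; must be > 0.
#' @param registry Modification registry searched alongside substitutions
#'   (`NULL` to search substitutions only).
#' @param masses Residue mass table.
#' @return Tibble with columns `type` (`"substitution"`/`"modification"`),
#'   `label` (e.g. `"A->E"` or the modification name), `from`, `to`,
#'   `delta`, `abs_diff`, ordered by ascending `abs_diff` then `label`.
#' @examples
#' isobaric_partners(58.0055, 0.005)
#' isobaric_partners(0, 0.0005) # the I/L pair
#' @export
isobaric_partners <- function(delta, tolerance, registry = NULL,
                              masses = residue_masses()) {
  stopifnot(is.numeric(tolerance), length(tolerance) == 1L)
  if (tolerance <= 0) abort("`tolerance` must be > 0.")
  syms <- names(masses)
  pairs <- expand.grid(from = syms, to = syms, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$from != pairs$to, ]
  subs <- tibble(
    type = "substitution",
    label = paste0(pairs$from, "->", pairs$to),
    from = pairs$from,
    to = pairs$to,
    delta = unname(masses[pairs$to] - masses[pairs$from])
  )
  out <- subs
  if (!is.null(registry) && nrow(registry) > 0L) {
    mods <- tibble(
      type = "modification",
      label = registry$name,
      from = NA_character_,
      to = NA_character_,
      delta = registry$delta
    )
    out <- bind_rows(out, mods)
  }
  out$abs_diff <- abs(out$delta - delta)
  out <- out[out$abs_diff <= tolerance, , drop = FALSE]
  out <- out[order(out$abs_diff, out$label), , drop = FALSE]
  as_tibble(out)
}

# Split a peptide into residue symbols. Plain uppercase strings split per
# character; character vectors (needed for multi-letter symbols like "Mnl")
# pass through.
split_residues <- function(sequence) {
  if (length(sequence) == 1L) {
    strsplit(sequence, "", fixed = TRUE)[[1]]
  } else {
    as.character(sequence)
  }
}
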