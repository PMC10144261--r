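# Seeded synthetic peptide-map projects: two antibody-like chains, their
# tryptic/Asp-N/thermolysin wildtype PSMs, planted true sequence variants at
# spike-study levels, and planted false positives of the four triage
# classes. XIC areas are integers constructed so that a variant planted at
# level p has a relative quantitation of exactly p (1:499 area ratio for
# 0.2%), keeping at-limit variants on the detection boundary rather than a
# floating-point ulp below it.

#' Synthetic project configuration
#'
#' Defaults define the "sva7" spike-calibration fixture: seven true sequence
#' variants at 0.2% whose best scores all clear 225 and of which exactly
#' three fall in [225, 250) -- so triage retains all seven sites at a cutoff
#' of 225 but only four at 250 -- plus fifty planted false positives (20
#' semi-tryptic non-K/R, 10 terminal-residue, 10 below-limit at 0.1%, 10
#' orthogonal duplicates).
#'
#' @param chain_lengths Named integer vector of chain lengths (defaults: LC
#'   215, HC 450 residues, antibody scale).
#' @param n_true_sv True sequence variants to plant.
#' @param n_borderline How many true variants get best scores in
#'   `[score_floor, high_floor)`.
#' @param true_level_pct Spike level of true variants, percent.
#' @param fp_counts Named counts of planted false positives per class:
#'   `semi_nonKR`, `terminal_residue`, `below_limit`, `orthogonal`.
#' @param below_limit_level_pct Level of class-`below_limit` plants
#'   (default 0.1, under a 0.2 limit).
#' @param fp_level_pct Level of class-a/b plants (default 0.3, above limit).
#' @param score_floor,high_floor Score band edges: borderline PSMs score in
#'   `[score_floor + 1, high_floor - 1]`, confident PSMs in
#'   `[high_floor + 5, 380]`.
#' @param n_ppm_decoys Extra variant PSMs with precursor errors of 3-7 ppm
#'   (pass a legacy 8 ppm gate, fail a high-resolution 2 ppm gate);
#'   default 0.
#' @param kr_frac Combined K+R frequency in the random chains (default 0.10,
#'   a typical tryptic-site density).
#' @return A `synth_config` list.
#' @export
synth_config <- function(chain_lengths = c(LC = 215L, HC = 450L),
                         n_true_sv = 7L, n_borderline = 3L,
                         true_level_pct = 0.2,
                         fp_counts = c(semi_nonKR = 20L, terminal_residue = 10L,
                                       below_limit = 10L, orthogonal = 10L),
                         below_limit_level_pct = 0.1, fp_level_pct = 0.3,
                         score_floor = 225, high_floor = 250,
                         n_ppm_decoys = 0L, kr_frac = 0.10) {
  stopifnot(n_borderline <= n_true_sv, all(chain_lengths >= 30L))
  structure(
    list(chain_lengths = chain_lengths, n_true_sv = as.integer(n_true_sv),
         n_borderline = as.integer(n_borderline),
         true_level_pct = true_level_pct, fp_counts = fp_counts,
         below_limit_level_pct = below_limit_level_pct,
         fp_level_pct = fp_level_pct, score_floor = score_floor,
         high_floor = high_floor, n_ppm_decoys = as.integer(n_ppm_decoys),
         kr_frac = kr_frac),
    class = "synth_config"
  )
}

#' Generate a synthetic peptide-map project
#'
#' Emits antibody-like protein chains, wildtype PSMs from three digests,
#' planted true sequence variants, and planted false positives of the four
#' triage classes, with a truth table recording the class and level of every
#' plant. Fully reproducible from the seed.
#'
#' @param config A [synth_config()].
#' @param seed Integer seed.
#' @param out_dir Optional directory; when given, writes `proteins.fasta`,
#'   `psms.csv` and `truth.csv` there.
#' @return List with `proteins`, `psms`, `truth`, `config`.
#' @export
synth_project <- function(config = synth_config(), seed = 1L, out_dir = NULL) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)

  enz <- list(trypsin = enzyme_trypsin(length_bounds = c(5L, 30L)),
              aspn = enzyme_aspn(length_bounds = c(5L, 30L)),
              thermolysin = enzyme_thermolysin(max_missed_cleavages = 2,
                                               length_bounds = c(5L, 30L)))

  # some random chains cannot host every requested plant (e.g. too few
  # peptides with the residue patterns the terminal-residue class needs);
  # draw fresh chains from the same RNG stream until placement succeeds,
  # keeping the whole project a deterministic function of the seed
  plants <- NULL
  for (attempt in 1:20) {
    proteins <- bind_rows(lapply(names(config$chain_lengths), function(lbl) {
      tibble(id = paste0("mab_", tolower(lbl)), chain_label = lbl,
             sequence = random_chain(config$chain_lengths[[lbl]], config$kr_frac))
    }))
    proteins$length <- nchar(proteins$sequence)
    peptides <- bind_rows(lapply(seq_len(nrow(proteins)), function(i) {
      bind_rows(lapply(enz, function(e) digest(proteins[i, ], e)))
    }))
    wt <- wildtype_psms(peptides)
    plants <- tryCatch(plant_variants(proteins, peptides, wt, config),
                       error = function(e) {
                         if (grepl("Infeasible synthetic config", conditionMessage(e))) NULL
                         else abort(conditionMessage(e))
                       })
    if (!is.null(plants)) break
  }
  if (is.null(plants)) {
    abort("Infeasible synthetic config: requested plants could not be placed in 20 chain draws.")
  }
  psms <- bind_rows(plants$wt, plants$variant_psms)
  psms$psm_id <- sprintf("psm%04d", seq_len(nrow(psms)))
  psms <- finalize_mz(psms)
  psms <- expand_variant(psms)

  out <- list(proteins = proteins, psms = psms, truth = plants$truth,
              config = config)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_fasta(proteins, file.path(out_dir, "proteins.fasta"))
    write_psm_table(psms, file.path(out_dir, "psms.csv"))
    readr::write_csv(plants$truth, file.path(out_dir, "truth.csv"),
                     progress = FALSE)
  }
  out
}

random_chain <- function(n, kr_frac) {
  canon <- names(residue_masses(include_mnl = FALSE))
  w <- setNames(rep((1 - kr_frac) / 18, 20), canon)
  w[c("K", "R")] <- kr_frac / 2
  paste(sample(canon, n, replace = TRUE, prob = w), collapse = "")
}

wildtype_psms <- function(peptides) {
  n <- nrow(peptides)
  tibble(
    psm_id = NA_character_,
    peptide = peptides$sequence,
    protein_id = peptides$protein_id,
    start = peptides$start, end = peptides$end,
    enzyme = peptides$enzyme,
    charge = 2L,
    mz_observed = NA_real_, mz_theoretical = NA_real_,
    precursor_ppm = round(runif(n, -1.5, 1.5), 3),
    score = sample(255:380, n, replace = TRUE),
    engine = "byonic-like",
    rt = round(runif(n, 5, 85), 2),
    xic_area = sample(20000:500000, n, replace = TRUE),
    mods = NA_character_,
    variant = NA_character_
  )
}

# Substitutions safe from the terminal-residue rule: delta matches no
# residue mass within 6 mDa (clear of the 5 mDa rule tolerance) either way.
safe_substitutions <- function() {
  masses <- residue_masses(include_mnl = FALSE)
  syms <- names(masses)
  grid <- expand.grid(wt = syms, obs = syms, stringsAsFactors = FALSE)
  grid <- grid[grid$wt != grid$obs & !grid$obs %in% c("K", "R"), ]
  delta <- masses[grid$obs] - masses[grid$wt]
  near <- vapply(delta, function(d) min(abs(masses - d)), numeric(1))
  keep <- near > 0.006 & abs(delta) > 0.02
  tibble(wt = grid$wt[keep], obs = grid$obs[keep], delta = unname(delta[keep]))
}

plant_variants <- function(proteins, peptides, wt, config) {
  chain_of <- setNames(proteins$chain_label, proteins$id)
  safe <- safe_substitutions()
  tryp <- peptides[peptides$enzyme == "trypsin" & peptides$specificity == "full" &
                     nchar(peptides$sequence) >= 7, ]
  tryp <- tryp[sample.int(nrow(tryp)), ]  # shuffle once; assignments draw in order

  used_sites <- character(0)
  used_peptides <- character(0)
  truth <- list(); vp <- list()
  fp <- config$fp_counts

  pick_site <- function(pep_row, residue_pool = NULL, avoid_junction = NA) {
    seqstr <- proteins$sequence[proteins$id == pep_row$protein_id]
    positions <- seq.int(pep_row$start + 1L, pep_row$end - 1L)
    if (!is.na(avoid_junction)) positions <- setdiff(positions, avoid_junction)
    for (pos in shuffle(positions)) {
      wt_res <- substring(seqstr, pos, pos)
      if (wt_res %in% c("K", "R")) next
      if (!is.null(residue_pool) && !wt_res %in% residue_pool) next
      cand <- safe[safe$wt == wt_res, ]
      if (nrow(cand) == 0L) next
      obs <- cand$obs[sample.int(nrow(cand), 1L)]
      site <- paste(pep_row$protein_id, pos, obs, sep = "|")
      if (site %in% used_sites) next
      return(list(pos = pos, wt = wt_res, obs = obs, site = site))
    }
    NULL
  }

  # exclusive draws reserve the peptide span (needed where the wildtype
  # area is rewritten to pin an exact quant ratio); non-exclusive draws may
  # revisit spans, relying on used_sites to keep variant sites distinct
  next_peptide <- function(pred = function(p) TRUE, consume = TRUE) {
    for (k in shuffle(seq_len(nrow(tryp)))) {
      key <- paste(tryp$protein_id[k], tryp$start[k], tryp$end[k])
      if (consume && key %in% used_peptides) next
      if (!pred(tryp[k, ])) next
      if (consume) used_peptides <<- c(used_peptides, key)
      return(tryp[k, ])
    }
    abort("Infeasible synthetic config: not enough eligible peptides for the requested plants.")
  }

  add_variant_psms <- function(pep, site, enzyme, level_pct, scores, wt_env,
                               exact = TRUE) {
    # exact-ratio areas: level p maps to integer ratio a : b with a/(a+b) = p/100
    chain <- chain_of[[pep$protein_id]]
    vname <- variant_name(site$wt, site$pos, site$obs, chain)
    n_psm <- length(scores)
    ratio <- level_ratio(level_pct)
    m <- 2L * sample(60:420, 1L)
    wt_idx <- which(wt_env$psms$protein_id == pep$protein_id &
                      wt_env$psms$enzyme == enzyme &
                      wt_env$psms$start == pep$start & wt_env$psms$end == pep$end)
    span_key <- paste(pep$protein_id, enzyme, pep$start, pep$end)
    if (exact && !is.null(ratio) && length(wt_idx) > 0L) {
      area_v <- ratio[1] * m
      wt_env$psms$xic_area[wt_idx[1]] <- ratio[2] * m
      if (length(wt_idx) > 1L) wt_env$psms$xic_area[wt_idx[-1]] <- 0
      wt_env$pinned <- c(wt_env$pinned, span_key)
    } else {
      # fallback/inexact levels: round against the covering wildtype area
      w_area <- if (length(wt_idx)) sum(wt_env$psms$xic_area[wt_idx]) else {
        cov <- wt_env$psms[wt_env$psms$protein_id == pep$protein_id &
                             is.na(wt_env$psms$variant) &
                             wt_env$psms$start <= site$pos &
                             wt_env$psms$end >= site$pos, ]
        len <- cov$end - cov$start + 1L
        sum(cov$xic_area[len == min(len)][1])
      }
      area_v <- max(1, round(w_area * level_pct / (100 - level_pct)))
    }
    var_seq <- pep$sequence
    off <- site$pos - pep$start + 1L
    substring(var_seq, off, off) <- site$obs
    split_areas <- exact_split(area_v, n_psm)
    vp[[length(vp) + 1L]] <<- tibble(
      psm_id = NA_character_, peptide = var_seq,
      protein_id = pep$protein_id, start = pep$start, end = pep$end,
      enzyme = enzyme, charge = seq(2L, 1L + n_psm),
      mz_observed = NA_real_, mz_theoretical = NA_real_,
      precursor_ppm = round(runif(n_psm, -1.5, 1.5), 3),
      score = scores, engine = "byonic-like",
      rt = round(runif(n_psm, 5, 85), 2),
      xic_area = split_areas, mods = NA_character_, variant = vname
    )
    vname
  }

  wt_env <- new.env()
  wt_env$psms <- wt
  wt_env$pinned <- character(0)

  # --- true sequence variants -------------------------------------------
  borderline <- seq_len(config$n_true_sv) <= config$n_borderline
  true_names <- character(config$n_true_sv)
  for (i in seq_len(config$n_true_sv)) {
    repeat {
      pep <- next_peptide()
      site <- pick_site(pep)
      if (!is.null(site)) break
    }
    used_sites <- c(used_sites, site$site)
    scores <- if (borderline[i]) {
      sample(seq(config$score_floor + 1, config$high_floor - 1), 2L)
    } else {
      c(sample(seq(config$high_floor + 5, 380), 1L),
        sample(seq(config$score_floor + 1, 380), 1L))
    }
    vname <- add_variant_psms(pep, site, "trypsin", config$true_level_pct,
                              scores, wt_env)
    true_names[i] <- vname
    truth[[length(truth) + 1L]] <- tibble(
      variant = vname, class = "true_sv", level_pct = config$true_level_pct,
      protein_id = pep$protein_id, position = site$pos,
      borderline = borderline[i])
  }

  # --- class c: below the quantification limit ---------------------------
  for (i in seq_len(fp[["below_limit"]])) {
    repeat {
      pep <- next_peptide()
      site <- pick_site(pep)
      if (!is.null(site)) break
    }
    used_sites <- c(used_sites, site$site)
    vname <- add_variant_psms(pep, site, "trypsin", config$below_limit_level_pct,
                              sample(255:380, 1L), wt_env)
    truth[[length(truth) + 1L]] <- tibble(
      variant = vname, class = "below_limit",
      level_pct = config$below_limit_level_pct, protein_id = pep$protein_id,
      position = site$pos, borderline = FALSE)
  }

  # --- class d: orthogonal duplicates of tryptic-covered sites -----------
  truth_df <- bind_rows(truth)
  true_rows <- truth_df[truth_df$class == "true_sv", ]
  ortho <- peptides[peptides$enzyme != "trypsin", ]
  n_d <- fp[["orthogonal"]]
  for (i in seq_len(n_d)) {
    pep <- NULL
    for (j in seq_len(nrow(true_rows))) {
      tr <- true_rows[1 + (i + j - 2) %% nrow(true_rows), ]
      cov <- ortho[ortho$protein_id == tr$protein_id &
                     ortho$start < tr$position & ortho$end > tr$position, ]
      # one pinned wildtype span per duplicate keeps the pooled ratio exact
      cov <- cov[!paste(cov$protein_id, cov$enzyme, cov$start, cov$end) %in%
                   wt_env$pinned, ]
      if (nrow(cov) > 0L) { pep <- cov[sample.int(nrow(cov), 1L), ]; break }
    }
    if (is.null(pep)) {
      abort("Infeasible synthetic config: no orthogonal coverage left for duplicates.")
    }
    parsed <- parse_variant_name(tr$variant)
    site <- list(pos = tr$position, wt = parsed$variant_wt,
                 obs = parsed$variant_obs, site = NA)
    vname <- add_variant_psms(pep, site, pep$enzyme, config$true_level_pct,
                              sample(seq(config$score_floor + 1,
                                         config$high_floor - 1), 1L), wt_env)
    truth[[length(truth) + 1L]] <- tibble(
      variant = vname, class = "orthogonal", level_pct = config$true_level_pct,
      protein_id = pep$protein_id, position = tr$position, borderline = FALSE)
  }

  # --- class a: semi-tryptic, variant not involving K/R ------------------
  for (i in seq_len(fp[["semi_nonKR"]])) {
    tries <- 0L
    repeat {
      tries <- tries + 1L
      if (tries > 500L) abort("Infeasible synthetic config: cannot place semi-tryptic plants.")
      pep <- next_peptide(function(p) nchar(p$sequence) >= 9, consume = FALSE)
      # trim two residues off the C-terminus to make it semi-tryptic
      semi <- pep
      semi$end <- pep$end - 2L
      semi$sequence <- substring(pep$sequence, 1L, nchar(pep$sequence) - 2L)
      prot_seq <- proteins$sequence[proteins$id == pep$protein_id]
      if (classify_specificity(semi$start, semi$end, prot_seq,
                               enzyme_trypsin()) != "semi") next
      site <- pick_site(semi, avoid_junction = semi$end)
      if (!is.null(site)) break
    }
    used_sites <- c(used_sites, site$site)
    vname <- add_variant_psms(semi, site, "trypsin", config$fp_level_pct,
                              sample(255:380, 1L), wt_env, exact = FALSE)
    truth[[length(truth) + 1L]] <- tibble(
      variant = vname, class = "semi_nonKR", level_pct = config$fp_level_pct,
      protein_id = pep$protein_id, position = site$pos, borderline = FALSE)
  }

  # --- class b: mass shift equals a near-terminal residue ----------------
  # patterns: G->Q (delta ~ Ala), A->Q and G->N (delta ~ Gly)
  b_patterns <- list(c(wt = "G", obs = "Q", res = "A"),
                     c(wt = "A", obs = "Q", res = "G"),
                     c(wt = "G", obs = "N", res = "G"))
  match_pattern <- function(p, pat) {
    chars <- strsplit(p$sequence, "")[[1]]
    len <- length(chars)
    if (len < 8L) return(NULL)
    near <- c(chars[1:2], chars[(len - 1):len])
    if (!pat[["res"]] %in% near) return(NULL)
    inner <- which(chars == pat[["wt"]])
    inner[inner > 2L & inner < len - 1L]
  }
  for (i in seq_len(fp[["terminal_residue"]])) {
    found <- FALSE
    tries <- 0L
    repeat {
      tries <- tries + 1L
      if (tries > 500L) abort("Infeasible synthetic config: cannot place terminal-residue plants.")
      pep <- next_peptide(function(p) {
        any(vapply(b_patterns, function(pat) length(match_pattern(p, pat)) > 0,
                   logical(1)))
      }, consume = FALSE)
      for (pat in shuffle(b_patterns)) {
        inner <- match_pattern(pep, pat)
        for (off in shuffle(inner)) {
          pos <- pep$start + off - 1L
          site <- list(pos = pos, wt = pat[["wt"]], obs = pat[["obs"]],
                       site = paste(pep$protein_id, pos, pat[["obs"]], sep = "|"))
          if (!site$site %in% used_sites) { found <- TRUE; break }
        }
        if (found) break
      }
      if (found) break
    }
    used_sites <- c(used_sites, site$site)
    vname <- add_variant_psms(pep, site, "trypsin", config$fp_level_pct,
                              sample(255:380, 1L), wt_env, exact = FALSE)
    truth[[length(truth) + 1L]] <- tibble(
      variant = vname, class = "terminal_residue",
      level_pct = config$fp_level_pct, protein_id = pep$protein_id,
      position = site$pos, borderline = FALSE)
  }

  # --- optional high-ppm decoys ------------------------------------------
  for (i in seq_len(config$n_ppm_decoys)) {
    repeat {
      pep <- next_peptide()
      site <- pick_site(pep)
      if (!is.null(site)) break
    }
    used_sites <- c(used_sites, site$site)
    vname <- add_variant_psms(pep, site, "trypsin", config$fp_level_pct,
                              sample(255:380, 1L), wt_env)
    vp[[length(vp)]]$precursor_ppm <- round(runif(1, 3, 7), 3) *
      sample(c(-1, 1), 1)
    truth[[length(truth) + 1L]] <- tibble(
      variant = vname, class = "ppm_decoy", level_pct = config$fp_level_pct,
      protein_id = pep$protein_id, position = site$pos, borderline = FALSE)
  }

  list(wt = wt_env$psms, variant_psms = bind_rows(vp), truth = bind_rows(truth))
}

shuffle <- function(x) if (length(x) <= 1L) x else sample(x)

# integer area ratio a:b with a/(a+b) == level/100 exactly, or NULL
level_ratio <- function(level_pct) {
  frac <- level_pct / 100
  for (total in c(500L, 1000L, 2000L, 10000L)) {
    a <- frac * total
    if (abs(a - round(a)) < 1e-9 && round(a) >= 1) {
      return(c(as.integer(round(a)), total - as.integer(round(a))))
    }
  }
  NULL
}

exact_split <- function(total, n) {
  base <- total %/% n
  out <- rep(base, n)
  out[1] <- out[1] + total - base * n
  out
}

finalize_mz <- function(psms) {
  proton <- 1.007276
  mass <- vapply(psms$peptide, function(s) peptide_mass(s), numeric(1))
  theo <- (mass + psms$charge * proton) / psms$charge
  obs <- theo * (1 + psms$precursor_ppm / 1e6)
  psms$mz_theoretical <- round(theo, 6)
  psms$mz_observed <- round(obs, 6)
  # 4 decimals keeps read-back validation (1e-3 ppm) and CSV round-trips stable
  psms$precursor_ppm <- round(1e6 * (psms$mz_observed - psms$mz_theoretical) /
                                psms$mz_theoretical, 4)
  psms
}
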