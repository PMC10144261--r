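---
title: "Sequence variant triage: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sequence variant triage: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(svatriage)
```

## The problem

Sequence variant analysis (SVA) detects unintended single amino-acid
substitutions in recombinant protein therapeutics from multi-enzyme peptide
maps (trypsin, Asp-N, thermolysin) searched by engines such as Byonic or
Mascot. At the 0.1–0.5% levels where variants matter, search engines emit
large numbers of spurious substitution calls; the analytical bottleneck is
not detection but review. `svatriage` formalizes the recurring
false-positive classes as annotation rules, so that candidates are machine-
flagged with an auditable reason and the analyst reviews only what
survives.

## Mass arithmetic

Residue masses are fixed monoisotopic constants (6 decimals), so results
cannot drift with an external table. Peptide mass is the residue sum plus
one water (18.010565 Da). The motivating isobar: Ala→Glu and Gly→Asp both
shift mass by +58.0055 Da, exactly where cysteine carboxymethylation by
iodoacetic acid sits. The workflow this package supports alkylates with a
heavy ¹³C reagent instead; `modification_def()` models the label as
`delta + n_13C × 1.0033548` Da. The reagent's label count is not fixed by
the chemistry alone, so it is configurable; the default is `n_13C = 2`
(+60.0122 Da), which moves the adduct ~6.7 mDa per ppm at typical peptide
masses away from the substitution isobar — far beyond a 2 ppm search
tolerance. `isobaric_partners()` makes such conflicts explicit by
brute-force scan over all ordered substitution pairs and registered
modifications.

Methylnorleucine (Mnl), an isoleucine-misincorporation product, is modeled
as a residue at Ile + CH₂ (+14.01565 Da). Exact chemistry being
configurable, any non-canonical target can be added to the table.

## Digestion semantics

Cut sites are inter-residue indices; C-terminal enzymes (trypsin: K/R) cut
after a member residue, N-terminal enzymes (Asp-N: D; thermolysin:
A/F/I/L/M/V) before one. Decisions where conventions differ:

* Trypsin suppresses cleavage before proline by default (the common
  search-engine convention), configurable.
* Asp-N cleaves N-terminal to D only — the sequencing-grade convention;
  E is excluded but configurable.
* Protein termini count as specific termini; this is required for the
  semi-tryptic logic to treat N-/C-terminal peptides correctly.
* "Unlimited" missed cleavages (thermolysin) are realized by enumerating
  all inter-cut spans up to the length cap (default 40 residues); beyond
  that length peptides are not practically observable, and the cap bounds
  the combinatorics.
* Semi-specific enumeration is defined by the predicate "exactly one
  specific terminus", applied to every substring within the length and
  missed-cleavage bounds — not by trimming enumerated full peptides, which
  would couple the semi set to the full-peptide length cap. The test suite
  holds both modes equal to a brute-force substring oracle.

Coordinates are 1-based inclusive throughout, matching variant names like
`D1E_LC` (wildtype, chain position, observed, chain label).

## Triage rules

Annotation never deletes: every PSM receives `retained` or
`false_positive` plus a comment naming each triggered rule, and re-running
triage on its own output changes nothing.

* **R1 (semi-tryptic, non-K/R).** A substitution can only legitimately
  produce a semi-tryptic peptide if it creates or destroys a tryptic site.
  "Involves K/R" is therefore formalized as: wildtype ∈ {K,R}, observed ∈
  {K,R}, or the variant sits at the residue flanking the nonspecific
  junction. Anything else on a semi-tryptic peptide is an artifact.
* **R2 (terminal residue).** A delta equal to a residue mass, with that
  residue near a terminus, is the signature of in-source fragmentation or
  transpeptidation read as a substitution. "Near" defaults to 2 residues
  of either terminus — wide enough for the observed artifact class, narrow
  enough not to flag every peptide containing the residue. The mass match
  uses an absolute 0.005 Da tolerance: comfortably above 2 ppm precursor
  error at peptide masses, and below the 0.0364 Da minimum spacing between
  distinct residue masses (K/Q, the closest pair). Residue *loss*
  (delta = −mass) is matched only behind the `match_loss` flag, off by
  default: the artifact class is additions.
* **R3 (quantification limit).** Strictly below the limit triggers; a
  variant exactly at the limit is kept, because the assay's contract is to
  detect variants at levels ≥ the limit (default 0.2%).
* **R4 (orthogonal redundancy).** The orthogonal digests exist to confirm
  tryptic findings; a non-trypsin PSM at a site already carried by at
  least one trypsin PSM scoring ≥ cutoff adds review burden without
  information. One confident tryptic identification is the minimal
  defensible notion of "covered"; trypsin PSMs never trigger the rule.
* **Gates.** `score < cutoff` and `|ppm| > tol` are strict: "detected"
  means score ≥ cutoff, so a PSM exactly at the cutoff is retained.

`threshold_sweep()` re-runs triage over a cutoff grid; retained counts are
non-increasing in the cutoff by construction, and with a truth table the
sweep reads off the spike-calibration result directly.

## Quantitation

`rel_quant = 100·A_v/(A_v + A_w)` — the fraction-of-pool convention, under
which a 0.5% spike reads 0.5%. At these levels it is numerically almost
identical to the variant/wildtype ratio, but one convention must be fixed.
Areas are summed across charge states and enzymes on both sides before
ratioing (ratio of sums); pairing prefers the wildtype peptide with the
identical span and enzyme and falls back to the shortest covering span when
a substitution created or destroyed a cleavage site. A variant whose
position no wildtype peptide covers is reported unpaired rather than
silently dropped.

## The acquisition simulator

The simulator is phenomenological: it reproduces the observable bias with
auditable parameters rather than instrument physics.

Per MS1 scan: Gaussian elution fluxes, nominal fill time
`min(max_inject, AGC/flux)`, predicted space-charge shift
`κ × fill fraction` (κ default 5 ppm at full fill). In DDA mode a shift
beyond the gating threshold (IIT) divides the actual fill time by `G`
(default 10) — and, the consequential part, inflates the reported
intensity of any species carrying ≥ 30% of the scan's ions by the gain γ.
γ is an explicit parameter (default 2.0) because the observation is an
approximately twofold inflation of the abundant peptide, not a derivable
constant. Detected ions are Poisson at mean `flux × fill time`; reported
intensity is ions over fill time, which makes the γ = 1 (or
threshold = 100 ppm) limit provably unbiased and convergence testable.

Defaults: max fill 120 ms, AGC 4×10⁵, IIT threshold 0.75 ppm (gated) or
100 ppm (off), top-5 DDA. Scan durations (0.25 s MS1, 0.15 s MS2) are free
parameters chosen at Orbitrap scale; the spike experiments use a combined
apex flux of 4×10⁶ ions/s so the trap fill saturates across the peak core
and gating engages over ≈ ±2σ of the peak. Under those conditions the
closed-form expectation for a 0.5% spike under γ ∈ [1.6, 2.0] is
0.25–0.32%, the under-quantitation band the tests assert. XICs integrate
reported intensity trapezoidally over MS1 scan times — not apex intensity —
which is also why the design check insists on ≥ 8 MS1 scans within ±2σ of
a peak (`scans_per_peak()` computes the count in closed form from the duty
cycle).

## The synthetic generator

`synth_project()` emulates a spike-in calibration study: two antibody-like
chains (LC 215, HC 450 residues; K+R at 10%, a typical tryptic-site
density), wildtype PSMs from all three digests, seven true variants at
0.2%, and fifty planted false positives (20 semi-tryptic non-K/R, 10
terminal-residue, 10 below-limit at 0.1%, 10 orthogonal duplicates of the
true sites). Engine scores for true variants are drawn so that all best
scores clear 225 and exactly three fall in [225, 250): triage then retains
all seven sites at a cutoff of 225 but only four at 250 — the calibration
argument for 225, reproduced in one function call.

Numerical choice worth noting: XIC areas are integers with the variant :
wildtype ratio constructed exactly (1 : 499 for 0.2%, 1 : 999 for 0.1%).
Planted at-limit variants then sit *exactly* on the quantification limit in
double arithmetic; with areas drawn continuously, roughly 3% of draws land
one ulp below the limit and would be spuriously flagged by the
strictly-below rule. Terminal-residue plants use the three substitution
patterns whose delta matches a residue mass within the rule tolerance
(G→Q ≈ Ala, A→Q and G→N ≈ Gly). Not every random chain can host all ten
such plants, so the generator redraws chains from the same RNG stream
until placement succeeds — the project remains a deterministic,
byte-reproducible function of the seed.

What the generator does **not** emulate: chimeric spectra, retention-time
structure, isotope envelopes, charge-state-dependent response, correlated
noise between enzymes, or real search-engine score distributions. Passing
tests therefore demonstrate that the rules implement their definitions and
that the accounting is exact — not that the rule set is complete for real
data, where false-positive classes outside these four exist.

## Problem sizes

The test fixture is one ~550-PSM project with 64 variant PSMs; the
digestion oracle runs 200 random proteins of ≤ 30 residues across three
enzymes and both specificity modes; spike-recovery checks use 15–25 seeded
simulator runs per setting. These sizes exercise every code path while
keeping the full suite under a minute on one CPU.

## Known limitations

* Engine scores are opaque: no rescoring, FDR estimation, or
  spectrum-level evidence is computed; the score cutoff means whatever the
  engine's score means.
* Sequence coverage is accepted as an input field, never computed from
  spectra.
* The simulator's gating model is mode-dependent configuration (DDA only),
  matching where the bias is observed; it does not explain why MS1-only
  acquisition is spared on real hardware.
* The quantification-limit rule needs a per-variant quantitation; when
  none is supplied it is computed from the same PSM table, so a gross
  XIC-extraction error upstream propagates into R3 decisions.
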