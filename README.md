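# svatriage

Post-processing toolkit for **sequence variant analysis (SVA)** of
recombinant protein therapeutics by peptide-map LC-MS/MS.

Sequence variants (SVs) are unintended single amino-acid substitutions in a
recombinant protein, arising from DNA mutations or translational
misincorporation, typically present at 0.1–0.5% of the wildtype level. A
multi-enzyme peptide map searched for substitutions produces hundreds of
candidate peptide-spectrum matches (PSMs), most of them false positives,
which an analyst must review by hand. `svatriage` automates the downstream
triage of those candidates for scientists running SVA in biopharma
characterization labs: it annotates (never deletes) each variant PSM with
the false-positive classes it falls into, calibrates the engine-score
cutoff against spike-in data, quantifies retained variants from
extracted-ion-chromatogram (XIC) areas, and reports run-to-run reductions
in review burden. A seeded synthetic generator and a phenomenological
acquisition simulator make every step testable without instrument data.

## The rules and models at the core

A variant PSM is annotated `false_positive` iff at least one rule or gate
fires:

| Rule | Fires when |
|---|---|
| `R1_semi_nonKR` | trypsin PSM on a **semi-tryptic** peptide whose variant does not involve Lys/Arg (wildtype or observed residue ∈ {K, R}, or variant at the nonspecific junction) |
| `R2_terminal_residue` | the substitution delta equals a residue mass (±0.005 Da) and that residue occurs within 2 residues of a peptide terminus |
| `R3_below_quant_limit` | relative quantitation strictly below the limit (default 0.2%) |
| `R4_orthogonal_redundant` | non-trypsin PSM at a variant site already carried by a trypsin PSM scoring ≥ cutoff |
| `G_score` | engine score < cutoff (default 225, high-res profile) |
| `G_mass_error` | \|precursor error\| > MS1 tolerance (default 2 ppm) |

Relative quantitation uses the fraction-of-pool convention

```
rel_quant(%) = 100 · A_variant / (A_variant + A_wildtype)
```

with areas summed over charge states and enzymes before ratioing.

The acquisition simulator models MS1/DDA duty cycles over Gaussian elution
profiles with Poisson ion statistics: reported intensity is detected ions
over actual injection time. When the predicted space-charge mass shift
`κ · fill fraction` exceeds the instrument's gating threshold (IIT) in DDA
mode, the fill time is slashed and the dominant species' intensity is
inflated by a gain γ ≈ 2, reproducing the relative under-quantitation of
low-level peptides (a 0.5% spike reads ≈ 0.25–0.32%); raising the
threshold to 100 ppm disables the feature and restores unbiased
quantitation.

## Worked example

```r
library(svatriage)

proj <- synth_project(synth_config(), seed = 1)   # spike-calibration fixture
run  <- triage_run(proj$psms, proj$proteins, cfg = triage_config("high_res"))
run
#> <sva_triage>
#>   PSMs: 585 (64 with variant calls)
#>   Unique variant peptides: 57
#>   Retained variant sites: 7 (score cutoff 225)

threshold_sweep(proj$psms, proj$proteins, c(200, 225, 250, 300),
                truth = proj$truth)
#>   cutoff retained_unique_peptides retained_sites retained_true_sites
#> 1    200                        7              7                   7
#> 2    225                        7              7                   7
#> 3    250                        4              4                   4
#> 4    300                        3              3                   3
```

All 57 candidate variant peptides collapse to the 7 genuine variant sites:
the 50 planted false positives are each flagged by their matching rule. The
sweep shows why a cutoff of 225 is right for this assay: at 250, three true
variants whose best scores fall in [225, 250) are lost. Quantitation of the
retained sites recovers the planted 0.2% level:

```r
quantify_variants(run$psms, proj$proteins, retained_only = TRUE)
#>   variant  rel_quant_pct n_psms best_score ...
#> 1 A317F_HC           0.2      2        363
#> 2 C358I_HC           0.2      2        338
#> ...
```

Method-comparison accounting and the acquisition bias:

```r
glance(compare_runs(tibble::tibble(
  label = c("mAb3", "mAb4", "mAb5", "FP1"),
  n_new = c(86, 24, 22, 49), n_old = c(346, 194, 298, 458))))
#>   n_runs max_pct_reduction
#> 1      4                93

spike_recovery(0.5, acquisition_config("MS1_only", iit_threshold_ppm = 100,
                                       seed = 1))$rel_quant_pct
#> [1] 0.502   # unbiased: 0.5% spike reads 0.5%
spike_recovery(0.5, acquisition_config("DDA", iit_threshold_ppm = 0.75,
                                       dominant_gain = 2, seed = 1))$rel_quant_pct
#> [1] 0.255   # gated: the same spike under-quantifies ~2x
```

A thin command-line wrapper ships in `inst/cli/sva.R`
(`Rscript sva.R run --psms psms.csv --fasta proteins.fasta --out out/`).

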