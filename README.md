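# pmscreen

Statistics for a two-tier differential plasma-membrane (PM) proteomics
screen, of the kind used to map yeast alpha-arrestin adaptors (Art1-10,
Bul1/2) to the transporters they pull out of the membrane, plus the
companion fluorescence quantification of endocytosis. It is aimed at
proteomics/cell-biology analysts who have per-peptide abundance ratios from
isobaric labelling (iTRAQ/TMT) across biological replicates and want
reproducible fold-change calls, and at anyone needing internal-over-PM
fluorescence ratio statistics from ellipse regions of interest.

## The method

For each protein, comparison (e.g. CHX-treated vs mock wild type) and
biological replicate *i* with *n<sub>i</sub>* quantified peptides:

- replicate ratio: geometric mean of peptide ratios,
  *r<sub>i</sub>* = exp(mean log ρ<sub>ij</sub>);
- replicate p-value: two-sided one-sample t-test of log2 peptide ratios
  against 0 (requires at least `min_peptides`, default 2);
- pooled ratio: geometric ("logarithmic") mean of the *r<sub>i</sub>*;
- pooled significance: signed z per replicate,
  *z<sub>i</sub>* = sign(log *r<sub>i</sub>*) Φ⁻¹(1 − *p<sub>i</sub>*/2),
  combined with peptide counts as weights by the Stouffer–Liptak statistic

  *Z* = Σ *w<sub>i</sub> z<sub>i</sub>* / √(Σ *w<sub>i</sub>*²),  *p* = 2(1 − Φ(|*Z*|)),

- Bonferroni correction within each comparison, then a
  DECREASED / INCREASED / UNCHANGED call at α = 0.05.

Tier 1 screens the wild-type CHX comparison; tier 2 classifies every
affected protein in each arrestin-knockout comparison as STABILIZED,
DEPLETED or UNAFFECTED, and the target map keeps the proteins that CHX
depletes in the wild type but that a given knockout stabilizes — the
candidate cargo of that arrestin.

The package also ships: a seeded synthetic peptide-ratio generator with
explicit ground truth (log-normal peptide noise plus per-replicate offsets)
for power and type-I calibration; verbatim machine-readable copies of the
published 33-protein screen tables; and an imaging module that measures
per-cell internal-over-PM intensity ratios from concentric ellipses,
summarizes conditions by median with bootstrap 95% CI, normalizes time
courses to their time-0 baseline, and compares conditions by exact/approx
Wilcoxon rank-sum tests with Holm adjustment. See the methods vignette
(`vignettes/pm-proteome-screen.Rmd`) for model assumptions, conventions and
limitations.

## Worked example

Plant the published Thi7 biology into an otherwise null screen at the
published design (6 wild-type replicates, 3 per knockout) and re-detect it:

```r
library(pmscreen)

design <- default_design()
truth <- ground_truth(1, design) |>
  plant_fold_change("THI7", "WT_CHX", 0.14) |>     # CHX clears Thi7 from the PM
  plant_fold_change("THI7", "art2_CHX", 4.1) |>    # ... unless ART2 is deleted
  plant_fold_change("THI7", "art9_CHX", 11.3)      # ... or ART9

path <- tempfile(fileext = ".tsv")
write_dataset(simulate_peptide_ratios(design, truth, seed = 1), path)
screen <- run_screen(path)

dplyr::filter(screen$pooled, protein_id == "THI7",
              test %in% c("WT_CHX", "art2_CHX", "art9_CHX"))
#> # A tibble: 3 × 10
#>   protein_id test     reference pooled_ratio combined_z  pooled_p n_replicates
#>   <chr>      <chr>    <chr>            <dbl>      <dbl>     <dbl>        <int>
#> 1 THI7       WT_CHX   WT_ctrl          0.137      -28.7 9.94e-182            6
#> 2 THI7       art2_CHX WT_CHX           3.84        17.9 2.82e- 71            3
#> 3 THI7       art9_CHX WT_CHX           9.46        20.3 1.69e- 91            3

screen$target_map
#> $art1
#> [1] "THI7"
#> $art2
#> [1] "THI7"
#> $art9
#> [1] "THI7"
```

The pooled ratios recover the planted 0.14 / 4.1 / 11.3 within sampling
error and both planted arrestins are mapped; the `art1` entry is a
false positive from between-replicate variation at 3 replicates (the
vignette explains why the published pooling construction admits these).

The published tables themselves are available directly:

```r
summarize_counts(load_table1())
#> $n_decreased
#> [1] 24
#> $n_increased
#> [1] 9
#> $n_total
#> [1] 33
lookup_ratio(load_table2(), "THI7", "art9")
#> [1] 11.3
```

## Acceptance script

`scripts/acceptance.R` re-runs the package end to end: it simulates a full
screen using the published fold-change tables as ground truth at the
published sample sizes, runs the two-tier classifier on it, replays the
packaged tables through the fixture path, and runs the imaging pipeline
(synthetic fields → per-cell ratios → medians with bootstrap CIs → Wilcoxon
with Holm), then writes its JSON result file:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
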