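# ToxProfiler

Bioassay response profiling for animal acute toxicity.

Public screening repositories hold millions of categorical high-throughput
screening (HTS) outcomes — active / inactive / inconclusive calls for
compound–assay pairs. ToxProfiler is for computational toxicologists who
want to mine such data for *in vitro–in vivo* correlations: it builds a
sparse compound × bioassay response matrix, finds the assays whose
outcomes track a binary animal acute-toxicity endpoint (rat oral LD50
classes), selects a top assay panel, and ranks compounds by a consensus
score over that panel — prioritizing untested compounds for animal
testing without using any chemical structure information.

## The method in brief

A response matrix `M` holds `M[j, i] = 1` (compound *j* active in assay
*i*), `-1` (inactive) or `0` (untested/inconclusive). Compounds are
labeled toxic when −log₁₀ LD50 (mol/kg) > 3.00, nontoxic when < 2.00;
the marginal band in between is removed. Assays with fewer than 6 actives
are dropped.

Each assay is scored against the endpoint on its conclusive calls
(TP/FP/TN/FN):

- **CCR** — balanced accuracy, `(TPR + TNR) / 2`;
- **L score** — `L = TPR · TP / (FP + 1)`: rewards a high true-positive
  rate backed by many confirmed actives, sharply penalizes false
  positives, ignores the true-negative side (an inactive response does
  not prove a compound safe);
- **chi-square** — Pearson 2×2 association, reported for comparison only.

Selection is two-staged: assays with CCR strictly above 0.6 become
candidates; the top `floor(0.5 × n_candidates)` by L form the panel.

Compounds are then scored over the panel by
`S = Σᵢ R`, with `R = Aᵢ·Aⱼ/Aₜ` for an active cell, `−Iᵢ·Iⱼ/Iₜ` for an
inactive cell, and exactly 0 for a missing one, where `Aₜ/Iₜ`, `Aᵢ/Iᵢ`,
`Aⱼ/Iⱼ` are the total, per-assay and per-compound active/inactive counts
of the panel submatrix. Compounds are eligible for classification with
≥ 3 active panel responses or conclusive data in more than half the panel;
`S > 0` flags a potential toxicant. See the vignette
(`vignettes/bioassay-profiling.Rmd`) for the full model, design
rationale and limitations.

A seeded planted-signal simulator generates sparse matrices with a known
set of toxicity-correlated assays, so the entire workflow is validated
offline against ground truth.

## Worked example

```r
library(ToxProfiler)

sim <- simulateScreen(syntheticSpec(seed = 1))   # 1000 x 100, 10 planted assays
sim$matrix
#> ResponseMatrix: 1000 compounds x 100 assays
#>   entries: 3855 active, 43623 inactive, 52.5% untested/inconclusive

flt <- filterLowInfoAssays(sim$matrix, min_actives = 6)
rel <- assayRelevance(flt$matrix, sim$truth$labels)
sel <- rankAndSelect(rel, ccr_cutoff = 0.6, top_fraction = 0.5)
sel
#> AssaySelection: 10/100 assays pass CCR > 0.6; panel of 5 (top 50% by L)
#>   smallest L in panel: 23.682
```

Ten assays clear the CCR cutoff — exactly the ten planted ones — and the
top half by L becomes the panel:

```r
head(relevanceTable(sel)[relevanceTable(sel)$panel_flag,
     c("assay_id", "tp", "fp", "ccr", "l_score", "rank")])
#>    assay_id  tp fp       ccr  l_score rank
#> 1     A0001 169  5 0.9115012 23.68242    5
#> 14    A0014 199  4 0.9583088 37.01028    3
#> 39    A0039 176  3 0.9552183 40.54450    1
#> 59    A0059 156  4 0.9263158 27.04000    4
#> 87    A0087 170  3 0.9327486 37.24227    2
```

`A0039` ranks first: 176 true positives against only 3 false positives.
Compound prioritization over that panel:

```r
scores <- prioritizeCompounds(flt$matrix, panelAssays(sel), sim$truth$labels)
head(scores, 5)
#>   compound_id s_score n_active n_inactive n_reported eligible predicted_toxic label
#> 1      C00012       5        5          0          5     TRUE            TRUE toxic
#> 2      C00244       5        5          0          5     TRUE            TRUE toxic
#> 3      C00383       5        5          0          5     TRUE            TRUE toxic
#> 4      C00463       5        5          0          5     TRUE            TRUE toxic
#> 5      C00464       5        5          0          5     TRUE            TRUE toxic

mean(scores$label[scores$predicted_toxic] == "toxic")
#> [1] 1
```

The top-ranked compounds are active across the whole panel and reach the
maximum S (the panel size, 5); here every compound flagged by the
`S > 0` rule is a true toxicant.

## Command line

A thin Rscript over the same functions ships in `inst/scripts/toxprofile`
with subcommands `run` (YAML-configured end-to-end pipeline with a
provenance manifest), `build-matrix`, `rank-assays`, `score-compounds`
and `simulate`.

```sh
TP=$(Rscript -e 'cat(system.file("scripts/toxprofile", package="ToxProfiler"))')
Rscript $TP run --config run.yaml
```

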