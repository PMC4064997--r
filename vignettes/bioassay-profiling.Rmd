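---
title: "Profiling compounds for acute toxicity from public bioassay data"
author: "ToxProfiler"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profiling compounds for acute toxicity from public bioassay data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ToxProfiler)
```

# The problem

Animal acute-toxicity testing (rat oral LD50) is slow and expensive, while
public repositories such as PubChem hold enormous numbers of categorical
high-throughput screening (HTS) outcomes — active / inactive /
inconclusive calls for millions of compound-assay pairs. If some of those
bioassays probe receptors or cellular systems that sit on toxicity
pathways, a compound's *response profile* across a well-chosen assay panel
should carry information about its in-vivo toxicity, without any use of
chemical structure.

ToxProfiler implements that idea as a reusable workflow:

1. encode screening outcomes as a sparse compound-by-assay matrix,
2. score every assay's relevance to a binary toxic/nontoxic endpoint,
3. select a top assay panel, and
4. rank compounds by a consensus **S score** over the panel.

Because the original public-data snapshot cannot be redistributed or
re-downloaded, the package ships a planted-signal simulator that generates
screening matrices with the same statistical shape, so every stage of the
workflow is testable offline against a known ground truth.

# Data model

The central container is the `ResponseMatrix`, an S4 wrapper around a
sparse `dgCMatrix` with compounds as rows and assays as columns. A cell
$M_{ji}$ is $1$ when compound $j$ is active in assay $i$, $-1$ when it is
inactive, and $0$ when it is untested or inconclusive; $0$ is the sparse
default, matching the reality that most HTS matrices are overwhelmingly
missing or inactive. Duplicate records for one cell (several screening
substances mapping to the same compound) are resolved *any-active-wins*,
which is conservative toward detecting activity and mirrors how public
repositories roll substances up to compounds.

The endpoint lives in `ToxicityLabels`: each compound carries an optional
$-\log_{10} LD_{50}$ (mol/kg) potency and a class derived from it with
strict cutoffs — toxic above $3.00$, nontoxic below $2.00$, and a closed
*marginal* band $[2.00, 3.00]$ (the boundaries belong to the band because
both class rules are strict inequalities). Marginal compounds are removed
with `dropMarginal()` before any relevance computation so the endpoint is
binary.

Assays with fewer than `min_actives = 6` active responses are dropped by
`filterLowInfoAssays()` before scoring; an assay that almost never fires
contributes noise rather than signal. The cutoff is deliberately a tunable
parameter, since any such threshold is a pragmatic choice rather than a
principled one.

# Scoring assay relevance

For each assay column $A_i$, compounds with a conclusive response and a
binary label are cross-tabulated against the endpoint: TP (active, toxic),
FP (active, nontoxic), TN (inactive, nontoxic), FN (inactive, toxic).
Compounds with a $0$ entry or a marginal/absent label are excluded — the
four definitions only cover conclusive responses.

Three statistics are computed per assay:

**CCR (correct classification rate).** Balanced accuracy of the assay as
a predictor of the endpoint,
$$\mathrm{CCR} = \tfrac12\left(\frac{TP}{TP+FN} + \frac{TN}{TN+FP}\right),$$
which is insensitive to the heavy active/inactive imbalance of HTS data.
If an assay saw no conclusive toxic compounds or no conclusive nontoxic
compounds, one of the rates is undefined; the assay is flagged
*unscorable* (`NA`) and excluded from ranking rather than imputed to 0 or
1.

**The L relevance score.** CCR alone favors assays whose few conclusive
calls happen to agree with the endpoint. The package's L score encodes an
asymmetric, systemic-toxicity view of screening data: an *active* response
in a toxicity-relevant assay is strong evidence for in-vivo toxicity,
while an *inactive* response proves little, because a toxicant may act
through a different receptor. L therefore rewards a high true-positive
rate backed by many confirmed true positives and sharply penalizes false
positives, while ignoring the true-negative side:
$$L(A_i) = \mathrm{TPR} \times \frac{TP}{FP + 1}, \qquad
  \mathrm{TPR} = \frac{TP}{TP+FN}.$$
The $+1$ guards the denominator at $FP = 0$ without changing the ordering;
with all other counts fixed, L strictly decreases as FP grows (a property
the test suite sweeps across the count space). TN never enters: a specific
but insensitive assay can reach a high CCR but never a high L.

**Chi-square association.** Pearson's statistic on the 2x2 table, without
continuity correction by default (a `correct` flag exposes the Yates
version). It is reported for comparison only: chi-square rewards sheer
overlap between the assay's tested set and the labeled set, which is not
the same thing as usefulness for prioritization, so it plays no part in
the selection.

**Panel selection** (`rankAndSelect()`) is two-staged: assays with CCR
*strictly* greater than `ccr_cutoff = 0.6` (a conventional model-selection
cutoff) become candidates; candidates are ranked by L descending (ties
broken by assay id, so the ranking is reproducible regardless of input
order) and the top `floor(top_fraction * n_candidates)` form the panel —
with 95 candidates and the default `top_fraction = 0.5` that is a
47-assay panel. An optional `min_l` floor supports selecting by an L
threshold instead of a fraction.

# Scoring compounds

Over a selected panel, the consensus score of compound $j$ is the sum of
normalized per-cell contributions,
$$S_j = \sum_{i \in \text{panel}} R_{ji}, \qquad
R_{ji} = \begin{cases}
  \dfrac{A_i\,A_j}{A_t} & M_{ji} = 1,\\[1ex]
  -\dfrac{I_i\,I_j}{I_t} & M_{ji} = -1,\\[1ex]
  0 & M_{ji} = 0,
\end{cases}$$
where $A_t$ ($I_t$) is the total number of active (inactive) entries in
the panel submatrix, $A_i$ ($I_i$) the count in assay $i$, and $A_j$
($I_j$) the count for compound $j$. An active response therefore counts
for more when the assay and the compound are both broadly active relative
to the total — an observed-over-expected co-occurrence weight — and a
missing or inconclusive cell contributes exactly zero rather than being
treated as evidence of safety. On a panel of $p$ assays with roughly
uniform per-assay activity, the contribution of one active cell for a
broadly active compound is close to 1, so the maximum attainable $S$
approaches the panel size; broadly inactive compounds accumulate negative
scores symmetrically.

Two design points deserve note:

* **Normalization scope.** All counts default to the panel submatrix
  (`scope = "panel"`), keeping $S$ self-contained and comparable across
  runs that share a panel; `scope = "full"` instead takes $A_t$, $I_t$
  and the per-compound counts over the whole matrix, for users who want
  contributions weighted by a compound's global activity.
* **Eligibility.** $S$ is meaningless for a compound with almost no panel
  data, and sparse coverage must not be mistaken for safety. A compound is
  scored only if it has at least `min_actives = 3` active panel responses
  *or* a reported (conclusive) response in more than half of the panel —
  operationalized as the smallest integer strictly greater than the
  half-up rounding of `coverage_fraction * panel_size`, i.e. 25 of a
  47-assay panel. Unlabeled compounds (the new-compound screening use
  case) are admitted through the actives clause only.

Compounds with $S$ strictly above 0 are flagged as potential toxicants;
`prioritizeCompounds()` returns the eligible compounds ranked by $S$
(ties broken by compound id) together with their \{1, -1, 0\} panel
profiles for heatmap-style export.

# The synthetic screening generator

`syntheticSpec()` / `simulateScreen()` generate matrices with planted
structure: a fraction of compounds is toxic (each also receives a potency
drawn on the matching side of the class cutoffs, so the LD50 path is
exercised); a known subset of assays is *relevant* — active with
probability `relevant_sensitivity` for conclusive toxic compounds and
`relevant_fp_rate` for nontoxic ones — while background assays fire at
`irrelevant_active_rate` regardless of the label; each cell is
independently untested with probability `1 - tested_fraction`, and tested
cells are inconclusive with probability `inconclusive_fraction` (both
encoded 0, as in real categorical HTS exports; the generator tracks the
inconclusive count separately for diagnostics).

The defaults — 1,000 compounds, 100 assays, 10 relevant assays,
sensitivity 0.9, false-positive rate 0.02, background rate 0.05, half of
the cells tested, 5% inconclusive, 40% toxic — are the package's standard
validation condition: a sparse, active-poor matrix with a strong but
minority planted signal, sized so the full workflow runs in seconds. The
5% inconclusive share is a typical order of magnitude for curve-fit
failures in quantitative HTS.

What the generator deliberately does **not** emulate: assay-assay
correlation (real panels contain families of near-replicate assays,
e.g. 60 tumor cell lines screened with one protocol), compound clustering
by chemical series, dose-response semantics, and batch artifacts. Passing
the recovery tests therefore shows that the selection and scoring
mathematics work as specified under cell-level independence — not that
the workflow is robust to the correlation structure of any particular
real screening collection.

# Validation experiments

`recoveryExperiment()` runs the whole chain — simulate, filter, score
relevance, select, compute $S$ — over seeded replicates (replicate $r$
uses `seed + r - 1`) and reports per replicate the **panel precision**
(share of panel slots occupied by planted assays; under no signal its
chance level is `n_relevant_assays / n_assays`), the panel recall, and
the mean $S$ of toxic and nontoxic compounds with their standardized
separation (Cohen's d).

Two subtleties shaped the experiment design:

* **Selection bias in the null control.** When the panel is selected and
  $S$ is scored on the *same* draw, chance candidates are, by
  construction, assays whose actives lined up with the toxic labels, so
  the apparent class separation is inflated even with no planted signal
  (standardized separations above 1 are typical at small sample sizes).
  `holdout = TRUE` scores $S$ on an independent draw from the same spec,
  where the no-signal expectation is exactly zero; the null-control test
  uses this mode.
* **Null problem size.** With 1,000 compounds the sampling noise of CCR
  is so small that under the null no assay ever crosses the 0.6 cutoff
  and every panel is empty, leaving chance-level precision undefined.
  The null control therefore uses 40 compounds and a 0.3 base activity
  rate — enough conclusive calls per assay to clear the 6-actives filter,
  and enough CCR noise that panels of a few assays form, whose
  composition can be compared to chance.

```{r recovery}
rec <- recoveryExperiment(syntheticSpec(seed = 1), n_reps = 5)
rec$summary
```

Under the default strong-signal condition every panel slot is taken by a
planted assay and toxic compounds outscore nontoxic ones in every
replicate.

# Numerical and degenerate-input conventions

* Strict boundaries throughout: CCR must exceed the cutoff, $S$ must
  exceed the classification threshold, and the LD50 class rules are
  strict, with ties falling to candidate-rejection, non-toxic, and
  marginal respectively.
* Unscorable assays (a zero toxic-side or nontoxic-side denominator)
  propagate `NA` and are excluded from candidacy; chi-square returns `NA`
  on any zero margin.
* All rankings break ties on identifiers, so outputs are invariant to
  input ordering; the pipeline writes byte-identical artifacts for
  identical inputs and configuration, and the manifest records
  parameters, seed and input checksums (no timestamps).
* The simulator draws through a private RNG stream and restores the
  caller's `.Random.seed`.
* Empty candidate sets and empty eligible sets produce warnings and empty
  results, never errors, so screening pipelines fail soft on weak data.

# Limitations

The package operates on categorical outcome calls only; continuous
potencies (GI50/IC50) are out of scope, as are structure-based similarity,
live repository retrieval, and any correction for multiple testing on the
per-assay chi-square values (reported as descriptive statistics, not
inference). The L and R formulations are the package's own concrete
realizations of the qualitative design goals stated above — up-weight
true positives, penalize false alarms, normalize contributions by
activity totals — and alternative formulas satisfying the same contracts
would reorder borderline assays and compounds.
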