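---
title: "Marker discovery and microenvironment scoring: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Marker discovery and microenvironment scoring: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mcpkit)
```

## The model

Bulk transcriptomic measurements of a heterogeneous tissue average the
signals of the cell populations it contains. If a feature $f$ is expressed
at level $f_i$ in population $i$ and the sample $S$ contains populations
in mRNA proportions $\pi_i$, linearity of the measurement gives

$$ f_S = \sum_{i=1}^n f_i \,\pi_i. $$

A *transcriptomic marker* (TM) of population $k$ is a feature expressed in
$k$ and only in $k$, at a homogeneous level. For such a feature the sum
collapses to $f_S = f_k\,\pi_k$: the bulk signal is proportional to the
population's mRNA proportion. Two consequences drive everything in this
package:

1. any monotone summary of a population's markers tracks that population's
   abundance across samples, and
2. two markers of the same population are proportional across samples, so
   their Pearson correlation approaches 1 in noiseless data
   (`tm_correlation()` checks this signature).

The per-sample abundance score of population $k$ is the log2 geometric
mean of its markers — the arithmetic mean of their log2 expression
(`mcp_estimate()`). Scores are in arbitrary log2 units: they order samples
within one platform but carry no meaning across populations or platforms.
Cross-cohort work therefore goes through per-dataset Z-standardization
(`z_by_dataset()`) before pooling.

## Marker screening

Markers are found empirically in a compendium of purified-cell profiles.
Labels are organized in a *category pyramid*: a rooted DAG whose directed
edges state inclusion (CD8 T cells are T cells, which are microenvironment
cells). Relative to a category $C$, a sample is *positive* (its label is
included in $C$), *negative* (strictly non-overlapping) or *mixed* (partly
overlapping — PBMC contain CD8 T cells together with monocytes, so they
are mixed for the CD8 T-cell category and are discarded when that node is
screened).

Only inclusion is derivable from the graph: positivity is filled in by
transitive closure, while mixture relations must be declared explicitly in
a relation table. Any pair that is neither included nor declared defaults
to negative, which matches the definition of the negative set as "all
non-positive, non-mixed samples" and keeps the stored relation table
exhaustive without forcing users to enumerate thousands of negative pairs.
A declared relation contradicting inclusion is an error. Tumor cell-line
nodes are flagged non-screenable: they only serve as negative controls.

For each screenable category, three per-feature statistics are computed on
log2 data, with $X$ the positive centroid, $\bar X$ the grand negative
centroid (unweighted over negative *samples*, not over class centroids),
and $\bar X_j$ the centroid of negative class $j = 1..k$:

- $FC = X - \bar X$,
- $sFC = (X - \bar X_{\min}) / (\bar X_{\max} - \bar X_{\min})$,
- the ROC AUC of the feature for recognizing positive samples, computed as
  the normalized Mann–Whitney $U$ with midrank ties (half credit).

A feature is selected iff $FC > 2$, $AUC > 0.97$ and $sFC > 1.5$, all
strict: a feature landing exactly on a threshold fails. The FC cutoff of 2
log2 units is a deliberately stringent differential-expression bar; the
AUC cutoff can be calibrated with `screening_power_sim()`, which draws
2000 negative values from $N(0, s)$ and 100 positives from $N(2, s)$ and
reports the type-II error of a candidate cutoff. The spread $s$ has no
default: it should be the median per-feature standard deviation of the
compendium actually being screened. The sFC cutoff is chosen by inspecting
the sFC distribution of features already passing the other two criteria
(`sfc_cutoff_report()`); the package reports that distribution rather than
auto-picking a cutoff, because the "upper flat tail" is a judgment call.

Degenerate case: with a single negative class, $\bar X_{\max} =
\bar X_{\min}$ and the sFC denominator is zero. We define the value as
$+\infty$ when $X$ exceeds the centroid, $-\infty$ below it, and 0 at
equality — zero within-negative spread means any positive excess is
infinitely specific. Real screens always have several negative classes.

Categories with fewer than 30 positive samples are skipped (reliable
marker selection from high-dimensional data needs that many), reported
with a reason rather than failing. Marker sets screened in independent
series can be trimmed to their intersection (`reduce_markers()`), and the
overlap of two screens is scored with the upper-tail hypergeometric
probability (`overlap_significance()`) — the natural null for "two subsets
of a common feature universe share at least this many members".

## The synthetic compendium

`synth_compendium()` generates the study conditions all tests run under:
five marker-bearing populations (named after the immune sources of the
dilution design, so the same fixture feeds the mixture protocol), 10
planted markers each, 500 unspecific background genes, 40 samples per
label, plus a tumor cell-line label as a negative control. Marker features
follow $N(\text{baseline} + \text{effect}, \sigma)$ in their population
and $N(\text{baseline}, \sigma)$ elsewhere, with baseline 4, effect 6 and
$\sigma = 0.5$ — values typical of strong lineage markers on fRMA-style
log2 microarray data, where purified-cell marker expression sits 5–8 log2
units above array background and per-feature spreads are a fraction of a
log2 unit. Forty samples per label keeps every category above the
30-positive floor while staying small enough that a full screen runs in
well under a second.

What the generator does *not* emulate: platform/batch effects, correlated
co-expression structure among background genes, probe saturation, and
count noise of RNA-seq. Passing the planted-marker recovery tests
therefore shows the screen's statistics and thresholds are implemented
correctly and have the designed operating characteristics under Gaussian
noise — not that any particular real compendium yields any particular
marker list.

## Mixture simulation and quantitative validation

`simulate_mixtures()` implements $S^* = d'\,W + \varepsilon$ and
$S' = \log_2 S^*$, with $\varepsilon$ drawn i.i.d. per matrix cell from
$N(0, \sigma)$ (the "per feature" wording of the generative recipe is
ambiguous between per-feature and per-cell draws; per-cell is the less
structured choice). Since additive noise can drive low-signal cells
non-positive, the linear view clamps at 0 and the log2 view at a
configurable floor of $2^{-10}$, far below any meaningful signal.

Two designs are built in. `table4_design()` introduces the five immune
populations at a common weight $w \in \{0.002, 0.004, 0.01, 0.02, 0.04,
0.1, 0.18\}$ with the tumor line taking $1 - 5w$ (0.99 down to 0.1).
`latin_square_design()` reproduces the in vitro layout: four twofold
serial dilutions per population arranged in two transposed $5 \times 5$
latin squares over a fixed background aliquot, plus two pure-background
mixtures — 12 mixtures in which the population proportions are mutually
decorrelated, making per-population specificity identifiable. The relative
weight of the background aliquot is not fully determined by the published
layout; we default it to the weight of an undiluted aliquot and normalize
each column to proportions.

`run_fig4_protocol()` repeats, under one seed: draw one profile per source
phenotype from the compendium (uniformly, with replacement across runs —
the protocol description does not constrain replacement semantics, and
independence across runs is the simpler model), convolve with the
dilution design, add noise, log2, score. Fifty runs over seven mixtures
yield 350 per-(population, weight) estimates; at zero noise the scores are
strictly increasing in $w$, and at the default noise the monotonicity
holds in the mean.

`synth_source_profiles()` provides the idealized counterpart used for
linearity checks: markers strictly exclusive to their population (zero
elsewhere), so a marker's mixture signal is exactly $w \cdot f_k$ and the
population score equals $\log_2 w + \text{const}$, giving correlation 1
with log2 proportions at zero noise.

**Limit of detection.** `estimate_lod()` regresses known *natural-log*
proportions on calibration-mixture scores, predicts at the scores of
control samples lacking the population, and reports
$\exp(\text{mean prediction})$ — the exp/log pairing follows the
"exponential of the mean of the estimated log-proportions" definition.
LOD is scale-equivariant in the proportions, which the tests exercise.

**Composite scores.** A cytotoxic-lymphocyte score aggregates signal from
NK cells and from T cells (via their CD8 subset). Writing the underlying
mRNA amount as linear in both, and the score as $\log_2$ of that amount,
gives $2^{score} = a_{NK}\,NK + a_T\,T + b$, an ordinary bivariate linear
model fitted by `cytotoxic_model()`. The latin-square layout's
decorrelation is what makes $a_{NK}$ and $a_T$ separable; a collinear
design is refused, and a constant regressor is dropped with a warning
rather than silently producing an unidentifiable fit.

## Cohort-level utilities

- `z_by_dataset()`: per-dataset, per-population standardization (sample
  SD, ddof 1); a zero-variance row is an error naming the row and dataset.
- `pan_summary()`: per platform and population column, scores are
  centered, divided by the platform's column SD and rescaled by the
  cross-platform average of that column's SDs, then averaged across
  platforms omitting missing cancers. When a column exists on one platform
  only, the average SD degenerates to that platform's own and the output
  is simply the centered column; this is flagged with a warning.
- `median_binarize()`: strictly above the row median is "high", at or
  below is "low" — the tie rule makes all-constant rows all "low" and the
  split invariant under monotone transforms.
- `micro_classes()`: concatenates two binarized rows into
  high–high / high–low / low–high / low–low.
- `fixed_effect_meta()`: inverse-variance pooling with normal two-sided
  p-values. Fixed effect is the deliberate choice — after per-dataset
  standardization the per-study effects are modeled as a common effect —
  and no random-effects alternative is provided. Cox model fitting itself
  is delegated: the core consumes (β, se) pairs, and
  `cox_study_estimates()` is a thin optional wrapper over the `survival`
  package for producing them.

## Identifier mapping and deduplication

`map_features()` renames features across namespaces (probe set, HUGO
symbol, Entrez); many-to-one collisions are collapsed by the per-sample
arithmetic mean *on the stored scale*, the simplest order-independent
rule, applied before scoring so the scorer always sees one row per target
identifier. The mapping policy for uncovered features (drop or error) is
explicit. `dedupe_samples()` resolves content-identical samples (as
flagged by upstream file checksums, treated here as opaque strings) by
keeping the sample from the oldest series, with a deterministic
lexicographic tie-break; a tie that cannot be broken for lack of a date is
an error rather than a silent choice.

## Numerical and testing choices

- Strict inequalities at all three screening thresholds; boundary features
  are rejected.
- AUC ties get half credit via midranks, making the statistic exactly the
  normalized Mann–Whitney $U$; tests verify it against a brute-force
  all-pairs oracle on a thousand random small instances.
- Seeds are explicit arguments for every stochastic operation
  (`synth_compendium()`, `simulate_mixtures()`, `run_fig4_protocol()`,
  `screening_power_sim()`); protocols refuse to run unseeded.
- Test problem sizes — 550 genes × 240 samples for the compendium, 20
  seeds for recovery checks, 50 runs for the dilution protocol — were
  chosen so the full suite exercises every code path in well under a
  minute while keeping the statistical assertions comfortably away from
  their thresholds.

## Limitations

- The shipped marker configuration (`default_markers()`) is illustrative —
  a handful of canonical markers per population for demonstrating the
  interface. Production marker sets should be screened from a real
  purified-cell compendium and dropped in as a TSV.
- The bundled pyramid is schematic: it covers the ten scored populations
  and the PBMC/tumor-line idioms, not a full curated annotation of
  hundreds of labels.
- Scores remain arbitrary units; nothing in the package converts them to
  cell fractions. The mixture tooling shows how a calibration experiment
  could do so for a fixed platform.
- The simulators use additive Gaussian noise on the linear scale; they do
  not model platform-specific mean–variance relationships.
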