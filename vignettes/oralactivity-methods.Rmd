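---
title: "Quantifying microbial transcriptional activity from paired metagenomes and metatranscriptomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying microbial transcriptional activity from paired metagenomes and metatranscriptomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oralactivity)
```

## The problem and the statistic

Shotgun metagenomics of a microbial community measures which functions its
members *could* perform (gene content, DNA); metatranscriptomics measures
which functions are *being* performed (transcripts, RNA). When both layers
are profiled from the same sample and summarized on the same feature space —
MetaCyc pathways, Enzyme Commission numbers or KEGG orthologs, stratified by
contributing species — their ratio becomes an activity measure:

$$ a_{fj} \;=\; \log_{10}\!\frac{\text{RNA}_{fj}}{\text{DNA}_{fj}}, $$

for feature $f$ in sample $j$, both layers expressed as within-sample
relative abundances. $a > 0$ means a feature (or a species' contribution to
it) is transcribed above its genomic representation; $a < 0$ below it. The
motivating application is the oral microbiota sampled at three sites
(subgingival plaque, tongue, saliva) in periodontitis patients and healthy
controls — a repeated-measures design with site as the within-subject factor
and health status as the between-subject factor.

This package implements the full analysis around that statistic: parsing the
MetaPhlAn / HUMAnN2 table dialects, activity tables at community and
species-stratum resolution, contributional species diversity, compositional
(Aitchison) and ratio-based (weighted Jaccard) beta diversity with PCoA and a
Shepard fidelity check, subject-restricted permutation PERMANOVA plus
PERMDISP, a Dirichlet-Monte-Carlo CLR differential-abundance test, and a
repeated-measures log-linear model with Benjamini-Hochberg FDR control — all
exercised end to end on a synthetic-data generator with planted effects.

## Conventions and zero handling

- Taxonomic tables are percent-scale on input (MetaPhlAn convention) and
  proportions internally; stratified functional tables keep their input
  scale until renormalized.
- Community totals are always regenerated exactly from the species strata;
  totals carried in input files are used only to record the upstream tool's
  rounding discrepancy.
- `UNMAPPED` and `UNINTEGRATED` bookkeeping rows are removed (and the table
  renormalized) before any alpha/beta-diversity computation, but retained as
  features for linear modeling, where the unexplained mass damps artificial
  inflation of well-characterized functions in poorly characterized samples.
- Prevalence filtering keeps features nonzero in at least
  `ceiling(0.2 * n_samples)` samples ("at least 20% of the samples"; 12 of
  59). The threshold is applied once over all samples entering a given test,
  not per site stratum.
- **Zeros in the ratio.** The ratio is undefined when either layer is zero.
  The default policy (`half_min_nonzero`) adds half the smallest nonzero
  proportion of the respective table to both numerator and denominator of
  affected cells; cells that are zero in both layers stay masked. The policy
  is recorded in the table's `provenance` so results are auditable. With
  `none`, any zero masks the cell.
- **Zeros in CLR.** Aitchison distance uses per-sample multiplicative
  replacement: zeros become half that sample's minimum nonzero proportion,
  and the nonzero part is rescaled to keep the sample on the simplex. This is
  scale-respecting and standard where no other guidance exists.
- Species activity summaries average $\log_{10}$ ratios (never ratios) over
  the features where the species' stratum is nonzero in *both* layers;
  contributional diversity reports pathways expressed by fewer than two
  species as flagged, mirroring the usual display filter.
- Shannon indices are in natural log (the vegan default).

## Weighted Jaccard on signed log-ratio tables

Ruzicka (quantitative Jaccard) dissimilarity,
$d = 1 - \sum_i \min(x_i, y_i) / \sum_i \max(x_i, y_i)$, requires
nonnegative input, but activity tables are signed. How the original analyses
made log-ratio tables Jaccard-compatible is not stated anywhere we know of;
we adopt one defensible reading and flag it prominently: undefined cells are
imputed at 0 (neutral activity) and the whole table is shifted by its global
minimum before the dissimilarity. Distances are then invariant to adding any
constant to a fully defined table (a property the tests verify), but they do
depend on the imputation value; `ratio_beta_diversity()` records the
convention in the distance's `metric` attribute. This remains an open
methodological question rather than a settled choice.

## Restricted permutations and the subject effect

With three sites nested in every subject, unrestricted permutations would
overstate significance for between-subject factors and understate
within-subject structure. `permanova_restricted()` therefore uses:

- **within-subject exchange** for factors that vary inside subjects (site):
  labels are permuted independently within each subject;
- **between-subject exchange** for factors constant inside subjects (health
  status): whole subjects' label sets are exchanged.

The scheme is chosen automatically from the data and reported. The pseudo-F
uses Gower-centered sums of squares computed directly from squared
distances; $p = (1 + \#\{F^\pi \ge F\}) / (1 + n_\pi)$. PERMANOVA's
dispersion assumption is checked with `permdisp()` (distance to group
centroid in full PCoA space, with negative-eigenvalue axes contributing
negatively, as in the standard construction).

For the per-feature linear model, the repeated-measures structure is handled
by fixed-effects absorption rather than REML mixed models: deterministic,
dependency-light, and exact for this balanced design. Because absorbing
subject annihilates between-subject contrasts, the model is a split-plot:
terms varying within subjects (site) are tested in a model containing
subject indicators (equivalent to within-subject centering of response and
design), while terms constant within subjects (status, smoking) are tested
on per-subject means — the whole-plot stratum. Abundance tables are
log10-transformed after a half-minimum pseudocount; ratio tables are already
on the log scale and enter as-is. BH correction is applied per term across
features, per operation call.

The Dirichlet-Monte-Carlo CLR test follows the ALDEx2 construction: per
instance, per-sample proportions are drawn from Dirichlet(counts + 0.5)
(Jeffreys prior), CLR-transformed and compared by Welch's t; the reported p
is the across-instance mean ("expected p", conservative by design) with 128
instances by default, and the effect is the mean CLR median difference
scaled by pooled dispersion. Multi-group comparisons are pairwise two-group
tests under a single pooled BH correction.

## What the synthetic generator emulates

`generate_study()` reproduces the statistical structure the analysis
assumes, at desk scale:

- **Design**: 11 subjects per status group, three oral sites each
  (66 paired samples), matching the motivating study's design.
- **Composition**: species log-abundances = baseline (SD 1) + per-site
  preference (SD 1.0, giving strong site separation) + subject effect
  (SD 0.4) + residual noise (SD 0.2), closed by softmax. Eight "pathogen"
  species gain a disease shift largest in plaque (1.5 on the log scale),
  intermediate in saliva (1.0) and smallest in tongue (0.5), mirroring the
  observed site ordering of periodontal pathogens.
- **Function**: a fixed sparse species-pathway incidence matrix (every
  pathway carried by at least two species, lognormal weights) converts
  species abundance into stratified DNA pathway means, plus a 5%
  "unclassified" stratum per pathway.
- **Activity**: species baselines (SD 0.3) and cell-level noise (SD 0.2)
  redistribute transcription among a pathway's species, while the
  pathway-level total obeys RNA = DNA x 10^(pathway baseline + planted shift
  + noise, SD 0.2) *exactly*. This construction makes the planted truth
  well-defined at the community level: 10 of 200 target pathways carry a
  -0.5 log10 shift in disease and every other pathway carries exactly zero,
  regardless of how disease reshuffles the species mix. (A model in which
  pathway activity is the abundance-weighted mix of species activities would
  leak composition effects into pathway activity and make "null pathway" an
  ill-defined notion.)
- **Measurement**: Dirichlet-multinomial counts at 1e5 (DNA) and 2e5 (RNA)
  expected reads (the study's RNA libraries were deeper than its DNA
  libraries after filtering), concentration 1e6 (`dispersion = 1e-6`) over
  the ~1200 stratified cells — a mild counting-layer overdispersion (~10%
  variance inflation over multinomial at these depths). The biological
  overdispersion lives explicitly in the hierarchical layers above; a much
  smaller concentration would give per-cell Dirichlet shapes of order one,
  i.e. log-scale counting noise that dominates any plantable signal.
  A Beta-distributed UNMAPPED fraction (mean 0.2) per sample and layer
  exercises the strip/renormalize path, and truly present strata drop out of
  a sample with probability 0.05.

What it does *not* emulate: strain-level variation, read-level artifacts
(mapping bias, length/quality normalization), longitudinal dynamics,
covariation between smoking and status, and the long-tailed species
abundance distributions of real oral communities. Passing recovery tests on
this generator therefore demonstrates that the statistical machinery is
correct and calibrated under the declared model — not that real data meet
that model.

## Numerical and design choices

- PCoA reports all eigenvalues, including negative ones; no Lingoes/Cailliez
  correction is applied. Axes are scaled by the square root of the positive
  eigenvalues; `shepard_r` is the Pearson correlation between input and
  ordination distances.
- A taxonomic percent table is converted to pseudo-counts for the
  Dirichlet-CLR test via a configurable depth constant (1e4 in the
  pipeline), since the test consumes counts while MetaPhlAn emits relative
  abundances.
- All stochastic stages take explicit seeds; `run_pipeline()` derives
  per-stage seeds from one master seed with a fixed scheme (`child_seed`),
  so any stage can be rerun in isolation. Same config + seed gives
  byte-identical output tables.
- Degenerate inputs are handled explicitly: all-constant Kruskal-Wallis
  input returns H = 0, p = 1 with a warning; all-zero sample pairs get
  Jaccard distance 0 with a warning; zero-variance features are flagged
  `degenerate` with effect 0 and p = 1; an all-zero composition is an error
  for CLR.

## Problem sizes used in the tests

The validation suite runs at deliberately small scale: oracle and analytic
checks on fixtures of at most ten samples; type-I calibration on 1000-2000
effect-free replicates of 12-30 observations; FDR calibration on 40
replicates of 500 null features; and planted-effect recovery on ten
replicate studies at the full default design (66 samples, 200 pathways).
These sizes give stable Monte-Carlo estimates while keeping the default
suite fast on a single CPU.

## Known limitations

- The split-plot absorption model assumes a balanced design; heavily
  unbalanced data would warrant the REML mixed-model route instead.
- The shift convention for signed-table Jaccard is one of several defensible
  choices (see above) and materially affects the geometry when activity
  ranges differ strongly between samples.
- The expected-p of the Dirichlet-CLR test is conservative; its FDR is well
  below nominal on null data, at some cost in power.
- Activity ratios inherit all compositional caveats of both layers;
  absolute-abundance calibration and within-species gene normalization are
  out of scope.
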