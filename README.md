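# oralactivity

Species-specific transcriptional activity of microbial communities from
paired shotgun metagenomes (DNA) and metatranscriptomes (RNA).

## The problem

A metagenome tells you which functions a community *could* perform; a
metatranscriptome tells you which it is *actually* performing. When both are
profiled from the same sample on the same feature space (MetaCyc pathways,
EC numbers, KEGG orthologs, stratified by contributing species), their ratio

    a_fj = log10( RNA_fj / DNA_fj )

is a per-feature, per-sample activity measure: `a > 0` means a feature — or
one species' contribution to it — is transcribed above its genomic
representation, `a < 0` below it. The motivating setting is the oral
microbiota sampled at three sites (subgingival plaque, tongue, saliva) in
periodontitis patients and healthy controls: a repeated-measures design with
site within subject and health status between subjects.

The package provides, around that statistic:

- **I/O** — MetaPhlAn merged taxonomic tables and HUMAnN2-style stratified
  functional tables (UNMAPPED/UNINTEGRATED handling, both stratum dialects,
  exact community-total regeneration), metadata pairing, regrouping of gene
  families to EC/KO, 20%-prevalence filtering.
- **Activity** — community- and species-stratum-level log10(RNA/DNA) tables
  with explicit zero-handling policies, per-species activity summaries, and
  contributional species diversity (richness / Shannon of species
  contributing to each pathway, per omic layer).
- **Diversity** — observed richness, Shannon, Pielou; Aitchison (CLR)
  distance with multiplicative zero replacement; weighted/binary Jaccard
  (Ruzicka); a shift convention for Jaccard on signed log-ratio tables;
  PCoA reporting negative eigenvalues, with Shepard fidelity.
- **Inference** — Kruskal-Wallis; PERMANOVA with subject-restricted
  permutations (within-subject exchange for site, whole-subject exchange for
  status) and PERMDISP; an ALDEx2-style Dirichlet-Monte-Carlo CLR test; a
  MaAsLin2-style repeated-measures log-linear model via split-plot subject
  absorption; Benjamini-Hochberg FDR.
- **Simulation** — a generator for the full paired study with planted
  site/disease/activity effects and a ground-truth record, used for
  calibration and power validation.

## Worked example

Simulate the default study (11 + 11 subjects x 3 sites, 200 pathways of
which 10 carry a planted -0.5 log10 activity reduction in disease), then run
the core analyses:

```r
library(oralactivity)

gen    <- generate_study(simulation_config(seed = 1))
paired <- gen$dataset
md     <- paired$metadata

act <- compute_activity_table(paired, level = "community_feature")
act
#> <activity_table level=community_feature policy=half_min_nonzero> 200 rows x 66 samples (100.0% defined)

taxa <- sweep(paired$taxa$abundance, 2, colSums(paired$taxa$abundance), "/")
d    <- aitchison_distance(taxa)
permanova_restricted(d, md$site,   strata = md$subject_id, seed = 2, term = "site")
#> PERMANOVA [site, within_subject permutations]: pseudo-F = 79.009, R2 = 0.715, p = 0.001 (999 perms)
permanova_restricted(d, md$status, strata = md$subject_id, seed = 3, term = "status")
#> PERMANOVA [status, between_subject permutations]: pseudo-F = 2.553, R2 = 0.038, p = 0.001 (999 perms)

v <- act$value; v[!act$mask] <- NA
tt <- loglinear_differential(v, md, transform = "ratio")
st <- tt[tt$term == "statusperiodontitis", ]
head(st[order(st$q), c("feature", "effect", "p", "q")], 3)
#>     feature effect        p        q
#> 401 PWY0007 -0.458 4.71e-10 9.41e-08
#> 402 PWY0008 -0.471 1.38e-08 1.26e-06
#> 403 PWY0003 -0.454 2.39e-08 1.26e-06
sum(st$q < 0.05)
#> [1] 13
```

Reading the output: oral site dominates taxonomic community structure
(R2 = 0.71) while health status explains a small but significant fraction
(R2 = 0.04) — the site >> status ordering expected of this design. The
log-linear model recovers the planted activity reduction: the top hits are
target pathways with effects near -0.5 (the planted shift), and 10 of the 13
q < 0.05 pathways are reduced in disease.

The same analysis runs end to end from one configuration:

```r
res <- run_pipeline(pipeline_config(simulation = simulation_config(),
                                    master_seed = 1, out_dir = "results/pipeline"))
```

which writes activity tables, alpha-diversity, distance matrices,
ordinations, test tables, a machine-readable manifest and a plain-text
summary. The numbered drivers under `analysis/` walk the same stages
step by step (`01_simulate.R` ... `05_full_pipeline.R`), writing their
tables under `results/`.

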