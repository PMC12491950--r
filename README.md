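# ibdmb

Baseline fecal-microbiome analysis for inflammatory bowel disease (IBD)
inception cohorts profiled with genus-level 16S amplicon counts.

Newly diagnosed ulcerative colitis (UC) and Crohn's disease (CD) present
with altered gut microbiomes, but small studies and lenient statistics have
made the literature inconsistent. This package implements the conservative
analysis stack such cohorts call for, end to end:

- **Core data handling** — validated count containers (S4, extending
  `SummarizedExperiment`), TSV/BIOM ingest, clinical metadata with
  controlled vocabularies (Montreal location codes, assay-range clamping of
  fecal calprotectin), a ≥10 000-read sample filter, and seeded
  without-replacement rarefaction (default depth 9503).
- **Diversity** — Shannon (nats) and observed-taxon richness with
  covariate-adjusted group comparison; Bray-Curtis beta diversity with
  PERMANOVA (location) and PERMDISP (dispersion) permutation tests,
  including exact enumeration on small designs.
- **Consensus differential abundance** — three independently implemented
  log-linear model families (bias-corrected log-linear / ANCOM-BC style,
  CLR linear with mode correction / LinDA style, TSS log-linear / MaAsLin
  style) sharing one covariate and sequencing-library random-intercept
  interface. A genus is reported only when BH-adjusted *q* < 0.05 in **all
  three** models with concordant direction.
- **UC-CD index** — from a UC-vs-CD consensus, the per-sample score

  `I = ln( (Σ_{t ∈ up} x_t + ε) / (Σ_{t ∈ down} x_t + ε) )`

  where `x_t` are relative abundances, `up`/`down` are the genera over- and
  under-represented in UC, and `ε = 1e-6`. The index transfers to external
  cohorts via genus-name normalization (coverage reported), discriminates
  UC from CD by AUC, and is tested for the ileal→colonic disease-location
  gradient.
- **Outcome prediction** — the composite 1-year severe-disease-course
  endpoint (hospitalization, surgery, stoma, >2 corticosteroid courses,
  biologic switch after failure; plus new fistula/abscess/stricture in CD)
  and Monte Carlo cross-validated gradient-boosted classification comparing
  feature sets (microbiome, biochemistry, clinical) with paired splits,
  signed-rank comparison and SHAP feature attribution.
- **Synthetic cohorts** — a log-normal-multinomial generator emulating the
  cohort structure (group sizes, covariates, library batches, depth
  heterogeneity, planted group/severity effects) so the whole pipeline is
  testable without patient data.

## Worked example

Generate a UC/CD cohort with three genera planted up and two down in UC,
run the three-model consensus, build and apply the index:

```r
library(ibdmb)

spec <- CohortSpec(
    nPerGroup = c(UC = 200, CD = 200),
    groupEffects = list(UC = c(g040 = log(4), g045 = log(4), g050 = log(4),
                               g065 = -log(4), g070 = -log(4))))
coh <- generateCohort(spec, seed = 42)
x <- filterSamples(coh$experiment, minDepth = 10000)
x
#> MicrobiomeExperiment: 150 taxa x 400 samples
#>   depth: median 30161 range [ 10025 , 86263 ]
#>   metadata: sample_id, diagnosis, age, sex, bmi, antibiotics, library, ...

cons <- consensusDA(list(
    daBiasCorrectedLogLinear(x, contrast = "UC", reference = "CD"),
    daClrLinear(x, contrast = "UC", reference = "CD"),
    daTssLogLinear(x, contrast = "UC", reference = "CD")), alpha = 0.05)
cons
#> DAConsensus: UC vs CD (reference), alpha = 0.05
#>   148 taxa assessed, 5 consensus hits
#>   hits: g040, g045, g050, g065, g070

def <- buildIndex(cons)
def
#> UC-CD IndexDefinition: 3 up / 2 down taxa, epsilon = 1e-06
#>   provenance: UC vs CD, alpha = 0.05

scores <- applyIndex(def, x)
md <- sampleData(x)
aucScore(scores@scores, md$diagnosis, positive = "UC")
#> [1] 0.977
```

The consensus recovered exactly the five planted genera; the resulting
log-ratio index separates UC from CD samples with AUC 0.977 in this
synthetic cohort (two taxa were dropped by the 10% prevalence filter,
hence 148 of 150 assessed).

A full run (ingest → filter → rarefy → diversity → consensus DA → index →
severe-course prediction) is driven by one config:

```r
runPipeline(list(
    generate = list(nPerGroup = c(UC = 120, CD = 120),
                    groupEffects = list(UC = c(g040 = log(4),
                                               g065 = -log(4)))),
    seed = 7, outdir = "run1"))
```

which writes every intermediate table plus `manifest.json` (stage status,
output checksums, warnings); reruns with the same config are
bit-identical. `inst/scripts/run_pipeline.R` exposes the same entry point
from the shell.

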