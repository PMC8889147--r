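# steatoscreen

Signature-reversion drug repositioning and in vitro screening analytics
for hepatic steatosis (NAFLD/NASH).

## What it is for

Non-alcoholic fatty liver disease progresses from simple steatosis (NAFL)
to steatohepatitis (NASH) with no approved pharmacological treatment.
One route to candidate therapies is the *signature-reversion principle*:
if a compound's transcriptional signature opposes the signature of the
disease, the compound may reverse the disease phenotype. `steatoscreen`
implements, as a tested and reusable R package, the computational side of
an integrated repositioning-and-validation campaign built on that
principle, for computational biologists who want to run, audit or extend
such a screen:

1. **Gene-level statistics** — per-gene two-group contrasts on log2
   expression with empirical-Bayes variance shrinkage: the moderated
   statistic is `t̃_g = (x̄_test − x̄_ctrl) / (s̃_g √(1/n₁ + 1/n₂))` with
   posterior variance `s̃²_g = (d₀s₀² + d_g s²_g)/(d₀ + d_g)`, the prior
   `(d₀, s₀²)` estimated by moment matching on the log variances.
   Volcano calls use `|log2FC| > 1` and `p ≤ 0.05`.
2. **Directional gene-set analysis** — nine set statistics (mean, median,
   sum, maxmean on signed t; Fisher, Stouffer, reporter, tail strength on
   gene p-values; Wilcoxon rank-sum), gene-sampling permutation nulls,
   five directionality classes (*distinct up*, *mixed up*,
   *non-directional*, *mixed down*, *distinct down*), and median-based
   cross-method consensus ranking.
3. **Connectivity scoring** — a signed Kolmogorov–Smirnov enrichment
   score in [−1, 1] of query up/down tags against ranked compound
   profiles (`a = max_j(j/t − V_j/n)`, `b = max_j(V_j/n − (j−1)/t)`,
   `ES = a` if `a ≥ b` else `−b`), combined up/down score with the
   same-sign-zero rule, permutation p-values, library screening.
4. **Repositioning** — the three pathway groups (clinical, steatogenic,
   and their intersection: the *pathways-to-target*), candidate selection
   by significant connectivity plus pathway overlap, toxicity exclusion,
   compound–gene–pathway network export, and screening summaries with the
   floored one-decimal hit-rate convention.
5. **Phenotype quantification** — lipid-droplet and nuclei segmentation
   (median filter → top-hat → Otsu → size filters → watershed), lipid
   fold change per cell, ROS normalization per µg protein (BCA standard
   curve), 4PL dose–response fitting with closed-form IC10, and one-way
   ANOVA with Tukey HSD.
6. **Proteomic clustering** — fold-change assembly, [0, 1] fraction
   normalization, PCA, k-means, silhouette-based model selection and
   adjusted-Rand concordance.
7. **Synthetic universe** — seeded generators for every input (cohorts,
   gene sets, signature libraries, knowledgebases, microscopy images,
   plates, panels) with ground-truth manifests, so the full pipeline is
   testable offline.

See `vignettes/steatoscreen-methods.Rmd` for the models, parameter
conventions and design decisions.

## Worked example

A seeded synthetic universe, repositioned end to end:

```r
library(steatoscreen)

cfg <- sim_config(seed = 1)          # 2000 genes, 10+10+10 cohort,
uni <- gen_universe(cfg)             # 11 planted pathways, 110 compounds

st  <- gene_stats(uni$dataset, c("NASH", "Healthy"))
table(st$de_class)
#> down  not   up
#>   55 1880   65

res <- run_gsa(st, uni$sets, B = 999, seed = 1)
sig <- significant_pathways(res)     # 11 pathways, all planted

mim    <- names(uni$truth$roles)[uni$truth$roles == "mimicker"]
groups <- build_pathway_groups(list(sig), mim, uni$kb, uni$sets)
length(groups$target)                # the pathways-to-target
#> [1] 11

query <- query_signature(st, tag_size = 50)
scr   <- screen_library(uni$library, query, B = 999, seed = 1)
cand  <- select_candidates(list(scr), uni$kb, uni$sets, groups)
filt  <- apply_tox_filter(cand)
head(filt$table[, c("compound", "score", "p", "n_overlap", "status")], 4)
#>   compound    score     p n_overlap       status
#> 1 cmpd_002 -0.92250 0.001        11    candidate
#> 2 cmpd_006  0.92175 0.001        11    candidate
#> 3 cmpd_003 -0.92150 0.001        11 excluded-tox
#> 4 cmpd_007  0.92100 0.001        11 excluded-tox
```

All ten planted actives score near |0.92| with the permutation-floor
p-value of 0.001 and overlap all 11 pathways-to-target; reversers carry
negative scores (signature reversal), mimickers positive ones, and
tox-flagged compounds are excluded before in vitro screening. The
screening summary applies the floored one-decimal convention:

```r
screening_summary(data.frame(
  compound = sprintf("c%02d", 1:21),
  outcome  = c(rep("positive", 6), rep("negative", 15))))$hit_rate
#> [1] 28.5
```

The same stages run as one reproducible, hash-stamped pipeline:

```r
run_pipeline(pipeline_config(mode = "all", seed = 1), "runs/demo")
```

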