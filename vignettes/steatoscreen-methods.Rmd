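---
title: "Methods: signature-reversion repositioning and screening analytics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: signature-reversion repositioning and screening analytics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(steatoscreen)
```

# Overview

`steatoscreen` implements a computational drug-repositioning pipeline for
non-alcoholic fatty liver disease (NAFLD) built on the signature-reversion
principle: a compound whose transcriptional signature opposes the disease
signature is a candidate for reversing the disease phenotype. The pipeline
runs from patient-cohort differential expression, through directional
pathway analysis, to connectivity scoring against a compound-signature
library, pathway-group intersection and candidate ranking with toxicity
exclusion. A second arm covers the analytics of the in vitro validation
campaign: lipid-droplet image quantification, ROS and viability readouts
with four-parameter logistic (4PL) dose–response fitting, and proteomic
mode-of-action clustering.

Every stage can be exercised against a synthetic universe with known
ground truth, generated by the `gen_*()` family, so the statistical
behavior of the whole chain is testable without any external downloads.

# Gene-level statistics

For a two-group contrast (e.g. NASH vs Healthy) on log2-intensity data,
`fit_gene_models()` computes per gene the effect
$\widehat\beta_g = \bar x_{g,\text{test}} - \bar x_{g,\text{ctrl}}$
(the log2 fold change), the pooled residual variance $s_g^2$ on
$d_g = n_1 + n_2 - 2$ degrees of freedom, and the unscaled contrast
variance $v = 1/n_1 + 1/n_2$.

`squeeze_variances()` places the classical hierarchical model on the
residual variances: $\sigma_g^2 \sim s_0^2\, d_0 / \chi^2_{d_0}$ (a scaled
inverse chi-square prior). The hyperparameters are estimated by moment
matching on $\log s_g^2$: the excess spread of the log variances beyond
the $\chi^2_{d_g}$ sampling noise determines $d_0$ through the trigamma
equation, inverted by Newton iteration (tolerance $10^{-8}$, at most 100
iterations), and the location then determines $s_0^2$ through the digamma
correction. The posterior (shrunken) variance is
$\tilde s_g^2 = (d_0 s_0^2 + d_g s_g^2)/(d_0 + d_g)$, which always lies
between $s_g^2$ and $s_0^2$. Degenerate inputs are resolved
deterministically: when the log variances have no excess spread (or no
spread at all) the prior degrees of freedom are flagged infinite and every
posterior equals the common prior variance; genes with $s_g^2 = 0$ take
part in the posterior formula but are excluded from the log-moment
estimation (the logarithm is undefined there).

The moderated statistic $\tilde t_g = \widehat\beta_g/(\tilde s_g
\sqrt v)$ is referred to Student's t on $d_0 + d_g$ degrees of freedom.
When $d_0$ is infinite the reference degrees of freedom are capped at
$10^6$ rather than switching to a Normal reference, which keeps one
continuous family of reference distributions. Benjamini–Hochberg
adjustment is applied across genes. A log-posterior-odds column (prior
differential-expression proportion 0.01, alternative scaling the t by a
fixed factor) is reported as a diagnostic; no downstream decision uses it.

Volcano classification calls a gene `up` when $\log_2\mathrm{FC} > 1$
(strict) and $p \le 0.05$ (inclusive), `down` symmetrically, else `not`.
The raw p-value, not the adjusted one, feeds this rule; the adjusted
p-value is carried for downstream use. The inequality forms (strict on the
fold change, inclusive on the p-value) follow the stated limits verbatim.

# Directional gene-set analysis

Pathway analysis is functional class scoring with nine set-level
statistics, chosen as the canonical directional-GSA families:

* signed-t statistics: mean, median, sum, and maxmean (the larger of the
  mean positive part and the mean negative part, signed by the winner);
* p-value combiners: Fisher's $-2\sum \ln p$, Stouffer's
  $\sum z_i/\sqrt m$, a reporter-style median z-score, and tail strength;
* a rank statistic: the standardized Wilcoxon rank-sum of the member
  t-ranks against the complement.

The null model samples random gene sets of matched size from the analyzed
universe (gene sampling, not sample permutation: the patient cohorts this
design targets are far too small for sample permutation to have
resolution). Each set receives five class p-values: distinct-up and
distinct-down from the statistic evaluated on $t$ and $-t$; the
non-directional p from the $|t|$ (or two-sided-p) variant; and mixed-up /
mixed-down from the non-directional statistic restricted to the up-moving
($t > 0$) / down-moving members against subset-size-matched nulls.
One-sided gene p-values are reconstructed from the two-sided p and the
sign of t, and the null index draws are keyed only by (seed, set size)
and shared across methods and classes — both choices make the sign-flip
symmetry exact: negating every gene t swaps the up/down p-values
identically and leaves the non-directional p unchanged.

Empirical p-values are $(1 + \#\{\text{null} \ge \text{obs}\})/(B+1)$,
floored at $1/(B+1)$. For small universes an exact mode enumerates every
same-size subset instead of sampling.

Consensus across methods is deliberately simple: within each class, sets
are ranked per method by p (average ranks on ties); the consensus rank and
consensus p are the medians across methods. A set's class is the argmin of
its consensus p over the five classes. Because strong sets hit the
$1/(B+1)$ floor in several classes at once, a pure "tie goes to
non-directional" rule would mislabel exactly the strongest pathways; ties
are therefore resolved by directional specificity: a tie containing
exactly one distinct class takes it, else exactly one mixed class takes
it, and any direction-ambiguous tie (both distinct, both mixed, or
neither) falls back to non-directional. Balanced sets (half up, half
down) still classify non-directional under this rule, and a coherently
up-regulated set classifies distinct-up.

Size bounds default to `min_size = 5` and half the universe; sets outside
the bounds are skipped with a warning rather than an error. Significance
is a BH adjustment of the consensus p within each class, at
`alpha = 0.05`.

# Connectivity scoring

A compound profile is a complete ranking of the gene universe (rank 1 =
most up-regulated under the compound). For a query tag of size $t$ with
sorted profile ranks $V_{(1..t)}$ in a universe of $n$,

$$a = \max_j\left(\frac{j}{t} - \frac{V_{(j)}}{n}\right), \qquad
  b = \max_j\left(\frac{V_{(j)}}{n} - \frac{j-1}{t}\right),$$

and the enrichment score is $a$ if $a \ge b$, else $-b$ — a signed
Kolmogorov–Smirnov statistic in $[-1, 1]$, positive when the tag
concentrates at the top of the ranking. The two maxima can tie to within
floating-point error; ties resolve to $a$ with a $10^{-12}$ guard so the
sign is deterministic.

The combined connectivity score scores the up- and down-tags separately;
if the two enrichment scores share a sign (or either is zero) the query
shows no coherent relation to the profile and the score is 0, otherwise
the score is $(ES_{up} - ES_{down})/2$, still in $[-1, 1]$ and exactly
antisymmetric under swapping the tags. The permutation null redraws
disjoint random tag sets of the same sizes; the p-value is the two-sided
tail on $|score|$. Because every profile is a permutation of the same
universe, this null is identical for all compounds, so the library screen
draws it once and shares it — a pure computational saving with no
statistical consequence. Profiles must be strict rankings; real-world
profiles with tied expression values should be pre-ranked (average rank,
then stable order) before import.

Query signatures default to the top and bottom 50 genes by moderated t
(`tag_size = 50`), the conventional tag size for signature queries against
perturbational databases.

# Pathway groups and candidate selection

Three pathway groups drive selection: the clinically deregulated pathways
(significant GSA sets, combined across datasets/contrasts by union by
default — both disease states contribute; intersection is available), the
pathways affected by the in vitro steatogens (every set containing at
least one of a steatogen's target genes — membership, not enrichment,
because a drug-target lookup implies membership), and their intersection,
the *pathways-to-target*. The pathways-to-target depend only on the
clinical and steatogen inputs, never on the screened library.

A screened compound becomes a candidate when it is selected in at least
one connectivity screen (significant non-zero score, both signs retained)
and its own affected pathways intersect the pathways-to-target; selected
compounds without overlap are kept as `rejected` rows for audit.
Candidates are ranked by best absolute score, then overlap size, then
identifier — the keys are a deterministic convention, since no ranking
rule is prescribed by the underlying design. Toxicity flags are input
data (a knowledgebase column standing in for hepatotoxicity database
review); flagged candidates get status `excluded-tox`. The screening
summary reports the hit rate as $100 \times
\text{positives}/\text{screened}$ truncated (floored) to one decimal
place, the printed convention for screening hit rates (6 of 21 prints as
28.5, not 28.6).

# Image quantification

The segmentation chain is fixed as standard high-content-screening
practice: for nuclei, a 3×3 median filter, white top-hat background
subtraction (disk radius 25 px), Otsu threshold, hole filling, removal of
objects under 100 px, and a distance-transform watershed to split touching
nuclei; for lipid droplets, a small-radius top-hat (5 px), Otsu threshold
and an area filter of 2–500 px. All radii and areas are configuration.
Integrated droplet intensity is the sum of the *original* pixel values
under the droplet mask, dilated by 2 px so the smoothed droplet edges
below the threshold still contribute (without the dilation roughly a
fifth of a soft-edged droplet's mass is lost). Counts are invariant to
intensity rescaling up to Otsu quantization.

"Lipid droplet intensity per cell" is read as integrated droplet
intensity divided by the nuclei count; normalization by integrated
nuclear intensity is exposed as an option since the phrase is ambiguous.
The fold change of a treatment over its control is the ratio of the mean
per-image metrics; images without detected nuclei are excluded with a
warning. An optional per-nucleus circular association step assigns each
droplet to the nearest nucleus within a configurable radius; it is off by
default and drives no reported quantity.

# Dose–response and group comparison

Viability curves are fitted to the 4PL model
$y = d + (a - d)/(1 + (x/c)^b)$ by bounded Levenberg–Marquardt least
squares ($a \in [50, 150]$, $d \in [-20, 80]$, $b > 0$, $c$ within the
tested dose range ×[0.01, 100]). A partial F-test against the constant
model at the 5% level declares a flat response, in which case no IC10 is
reported. IC10 is defined at 90% *absolute* viability of control (not 90%
of the fitted top asymptote; configurable) and solved in closed form,
$x = c\,((a - 90)/(90 - d))^{1/b}$; an IC10 outside the tested dose range
is flagged as extrapolated. Group comparisons use ordinary one-way ANOVA
with Tukey's HSD (studentized-range adjustment), the standard analysis
for plate-based treatment-vs-control designs.

# Proteomic mode-of-action clustering

Analyte readings are converted to fold changes over each treatment's
designated control, assembled with the lipid and ROS fold changes into a
treatment × feature matrix, and fraction-normalized per column to
$[0, 1]$; a constant column carries no contrast and is set to zero (an
arbitrary but deterministic convention, documented rather than hidden).
PCA (centered, unscaled — the normalization already bounds the scale; the
component sign is fixed by making the largest-magnitude loading positive)
embeds the treatments, and k-means with 50 restarts clusters the first
two component scores, matching the visual analysis such clusterings
support; clustering on the full normalized matrix is available via a
flag. k defaults to 4 — the number of modes of action the validation
campaign distinguishes (negative controls, steatosis induction, rescued
co-treatments, compounds alone) — and a silhouette scan over k = 2..8 is
reported alongside. Concordance with a reference labeling is the adjusted
Rand index.

# The synthetic universe

The generators produce every input with known ground truth, and all are
pure functions of (configuration, seed):

* **Expression cohort.** Log2-scale values for a Healthy/NAFL/NASH cohort
  (no probe-level modeling — the downstream statistics consume only
  log-scale values). Per-gene true variances are drawn from the scaled
  inverse-chi-square law with configurable $(d_0, s_0^2)$, so the
  shrinkage estimator has a measurable target; planted genes are shifted
  by ±`effect_log2fc` in both disease groups. Defaults: 2000 genes, 10
  samples per group (the scale of the public liver-biopsy cohorts this
  emulates), $d_0 = 4$, $s_0^2 = 0.25$ (residual sd 0.5 on the log2
  scale, typical for microarray intensities), effect 1.5.
* **Gene sets.** 50 sets; 11 planted pathways (the scale of the
  pathways-to-target in the motivating study), each containing its 10
  planted DE genes plus 25% filler genes — planted pathways are
  predominantly shifted, which is what "distinctly deregulated" means;
  with majority-filler sets the truth would be mixed, not distinct.
  Decoy sets draw only non-planted genes, so planted-pathway recovery is
  scoreable exactly.
* **Signature library.** Each compound is a full ranking obtained by
  ordering per-gene scores; reversers subtract (and mimickers add) a
  large shift times the planted signature sign, plus Gaussian jitter —
  rank inversion of the planted signature, the simplest mechanism that
  makes the connectivity score sign-definite. Decoys are uniform random
  permutations. Defaults: 110 compounds, 5 reversers, 5 mimickers.
* **Compound knowledgebase.** Actives target one planted DE gene per
  planted pathway (so their affected-pathway sets cover the planted
  pathways); decoys target random non-planted genes;
  $\lfloor\text{tox\_fraction}\cdot n\rfloor$ compounds are flagged.
* **Microscopy images.** Two channels; nuclei are large smooth disks
  (logistic edge) with enforced minimum separation — or exactly one
  overlapping pair when the touching-pair flag is set — and droplets are
  small bright disks with enforced separation so that noise-free counts
  are exact; additive Gaussian noise, clipped to $[0, 1]$.
* **Dose–response plates and proteomic panels.** 4PL curves plus noise;
  treatment rows drawn from k centroids equally spaced on a circle inside
  a random 2-D subspace of analyte space (cluster structure is low-rank,
  as a PC1/PC2 mode-of-action plot depicts) with isotropic noise.

What the generators deliberately do **not** emulate: microarray platform
artifacts, batch effects, probe-level noise, the correlation structure of
real perturbational compendia, illumination gradients or 3-D cell
geometry, and bead-assay preprocessing. Passing the recovery suite
therefore demonstrates that the statistical machinery is correct and
calibrated under its stated model — not that real cohorts, real compound
libraries or real micrographs will behave as cleanly.

# Numerical conventions and problem sizes

All empirical p-values are floored at $1/(B+1)$ and every stochastic
routine takes an explicit seed; identical configuration and seed give
byte-identical pipeline outputs, stamped with a parameter hash. The test
and acceptance runs use, as the package's own choice of problem sizes:
null-calibration cohorts of 2000 genes × (5+5) samples with 200
replicates, prior recovery at 5000 genes, pathway recovery on the default
universe with B = 999 permutations, a 110-compound screen (100 decoys),
384×384 px images with 12 nuclei and 40 droplets, 7-dose viability curves
in triplicate, and a 24-treatment × 20-analyte panel. A full suite run
completes in well under an hour on a single CPU.

# Known limitations

* The nine GSA methods and the consensus rule are configurable
  conventions; no claim is made that they match any particular external
  implementation's method set.
* The gene-sampling null treats genes as exchangeable and ignores
  inter-gene correlation; on real cohorts its p-values are
  anti-conservative for strongly co-expressed sets.
* The connectivity score is the unweighted (build-1 style) K-S
  construction; no weighted-KS exponent and no cell-line aggregation of
  replicate profiles.
* Segmentation assumes roughly disk-shaped nuclei and droplets and a flat
  background; there is no illumination correction, no cell-boundary
  segmentation, and no 3-D support.
* The 4PL bounds assume viability expressed in percent of control;
  responses on other scales must be rescaled before fitting.
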