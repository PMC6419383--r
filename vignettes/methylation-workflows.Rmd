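---
title: "Methods and models behind methworks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and models behind methworks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methworks)
```

# Scope and data model

methworks analyses quantitative DNA methylation at single-CpG resolution.
The central container, `MethylationDataset`, holds a beta-value matrix
(sites x samples, values in $[0,1]$), an aligned read-coverage matrix
(all-missing for microarray-derived data), a sorted site table keyed by
`chrom:pos:strand`, and a typed sample sheet. Three invariants are enforced
on construction and preserved by every operation: betas lie in $[0,1]$ or
are missing, coverage entries are non-negative integers or missing, and a
cell with zero coverage carries no methylation call.

Coordinates follow the dominant dialect of each format: internal positions
are 1-based cytosine positions on the + strand; Bismark coverage files are
read as 1-based with `start == end`; bedGraph export/import uses 0-based
half-open intervals `[pos-1, pos)`. Beta values are always recomputed from
the methylated/unmethylated read counts; the percentage column of a
coverage file is only a consistency check (a disagreement beyond 0.5
percentage points warns, and the counts win) because counts are the primary
data and the percentage is derived, rounded output. Unstranded (`*`)
records are keyed like + strand records so that array- and
sequencing-derived datasets merge on the same CpGs; an optional
`merge_strands` flag collapses -strand calls at `pos + 1` onto the + strand
CpG by summing counts (off by default, since aggregating strands is a
design decision the analyst should make explicitly).

# Preprocessing

`filter_sites()` applies rules in a fixed order — annotation rules
(sex chromosomes, SNP-overlapping sites) before the coverage rule — so
that the per-rule removal counts in the `FilterReport` are reproducible.
The coverage rule retains a site iff **strictly more than** a fraction
`min_fraction_covered` of samples have **at least** `min_coverage` reads;
the strict/non-strict split mirrors the usual phrasing of such criteria
("at least 5 reads in more than 50% of samples"). For array data the
coverage rule is skipped with a notice rather than an error, so one
configuration can serve mixed-platform projects.

Six imputation strategies are provided. Sample-wise and CpG-wise
mean/median fill from the column or row of the missing cell; `random`
draws uniformly from the observed values of the same CpG row and requires
an explicit seed (no hidden global RNG state); `knn` works on CpG rows,
the convention of the expression-array literature this method descends
from. The KNN distance between two rows is the root-mean-square difference
over pairwise-complete columns (Euclidean scaled by $1/\sqrt{m}$ for $m$
shared columns), which keeps distances comparable when rows share
different numbers of observed samples. The imputed value is the unweighted
mean of the $k$ nearest rows observed in the target column; nearer rows
missing that column are skipped in favor of the next nearest. If no
comparable neighbor exists the row mean is used. Imputation never touches
observed cells and is idempotent.

# Region-level analysis

Region sets are 0-based half-open intervals (BED convention). A CpG at
position $p$ belongs to region $[s,e)$ iff $s \le p-1 < e$: membership is
by the cytosine point, strand-blind, and a CpG may contribute to several
overlapping regions. `aggregate_regions()` offers plain means and
coverage-weighted means of the member betas; both coincide when coverages
are equal, and the weighted mode is the natural choice for sequencing data
where a 50-read call is more trustworthy than a 2-read call. Regions with
fewer member CpGs than `min_cpgs` are reported all-missing; the default is
1 for arrays and 3 for sequencing platforms, where sparse coverage makes
single-CpG regions unstable.

# Covariate inference

**Epigenetic age.** `train_age_model()` fits an elastic net
($\alpha = 0.5$ by default) of chronological age on single-CpG betas, with
the penalty chosen by cross-validated MSE. Fold assignment is derived from
a hash of the sample ids (samples sorted by hash, folds round-robin), so
the chosen penalty and coefficients are invariant under sample
permutation — a property worth having when datasets are assembled from
multiple files in arbitrary order. The model stores only nonzero
coefficients plus their training-set mean betas; `predict_age()`
substitutes those means for model CpGs that are absent or missing in a new
dataset and reports the per-sample substitution count, refusing to predict
when fewer than half the model sites are present (configurable). No
pre-trained clock is shipped; coefficient tables import/export as TSV.

**Sex.** For sequencing data the features are
$f_X = \log_2\frac{\overline{cov}_{chrX} + \varepsilon}{\overline{cov}_{auto} + \varepsilon}$
and likewise $f_Y$, with $\varepsilon = 0.01$ guarding empty chromosomes;
for arrays a mean signal-intensity matrix enters the same formula. The
log2 ratio makes the features invariant to global sequencing depth.
A diploid XX sample sits near $(0, \ll 0)$, an XY sample near $(-1, -1)$.
Classification is ordinary logistic regression on $(f_X, f_Y)$ trained on
samples with known sex; predictions below a confidence threshold
(default 0.8) are reported as `"unknown"` rather than guessed.

**Genetic noise.** The mean deviation of autosomal genotyping-probe betas
from the diploid targets $\{0, 0.5, 1\}$, i.e.
$\mathrm{mean}_i \min(|b_i|, |b_i - 0.5|, |b_i - 1|) \in [0, 0.25]$.
It is symmetric under $b \mapsto 1-b$ and rises with cross-sample
contamination or aneuploidy.

**LUMP purity.** Over a user-supplied list of CpGs unmethylated in
leukocytes, purity $= \min(1, \overline{\beta}/0.85)$ and immune fraction
$= 1 - $ purity. The 0.85 scale constant follows the convention of the
algorithm this estimator descends from and is exposed as a parameter.

**Cell-type deconvolution.** Per sample, `deconvolve_celltypes()` solves
$\min_w \lVert b - Rw \rVert^2$ subject to $w \ge 0$ and $\sum w \le 1$
(or $= 1$) over the sites shared with the reference panel. Because
reference panels have few cell types, the quadratic program is solved
exactly by enumerating support sets (with and without the active sum
constraint), solving each reduced KKT system, and keeping the feasible
candidate with the smallest objective; the global optimum of the convex
program is always among the candidates, so recovery is exact to machine
precision on noiseless mixtures. Identical reference columns are rejected
by name as rank deficiency.

# Differential methylation and variability

`moderated_t_table()` implements the shared empirical-Bayes machinery.
Per-unit pooled variances $s_g^2$ (df $d_g = n_0 + n_1 - 2$) are shrunk
toward a prior $s_0^2$:
$s^2_{post} = \frac{d_0 s_0^2 + d_g s_g^2}{d_0 + d_g}$, and the
two-sample statistic is referred to $t_{d_0 + d_g}$. The hyperparameters
$(d_0, s_0^2)$ are estimated by moment matching on $\log s_g^2$ under the
scaled-F model $s_g^2 \sim s_0^2 F(d_g, d_0)$: the excess variance of the
log variances over $\psi'(d_g/2)$ identifies $\psi'(d_0/2)$ (inverted by
Newton iteration), and the mean equation then yields $s_0^2$. A
non-positive excess maps to $d_0 = \infty$ (all unit variances equal).
With the prior off ($d_0 = 0$) the statistic reduces exactly to the
classical Student t. Zero-variance units receive the smallest
representable p-value (with a warning) when a mean difference exists, and
p = 1 otherwise.

Two differential-variability tests are provided. The deviation-based test
computes $z_{ij} = |v_{ij} - \mathrm{median}(group_j)|$ and applies the
moderated machinery to $z$; a positive statistic means more variability in
group 1. Median centering (the Brown-Forsythe robustification) was chosen
over mean centering; it is mildly conservative at $n = 20$ per group
(empirical null $P(p < 0.05) \approx 0.04$, versus $\approx 0.06$
anti-conservative for mean centering on bounded beta-scale data).
The Bartlett-based test uses the two-group closed form
$T = \frac{(N-2)\ln s_p^2 - \sum_i (n_i - 1)\ln s_i^2}{1 + \frac13\left(\sum_i \frac{1}{n_i-1} - \frac{1}{N-2}\right)} \sim \chi^2_1$,
with Benjamini-Hochberg q-values and the usual regularization: a unit is
selected iff $q < 0.001$ and its plain t-test p $< 0.05$, selected units
ordered by the t-test p-value. Exactly equal group variances give $T = 0$,
$p = 1$ by construction.

**Worst-rank scoring.** Units are ranked separately by (i) the adjusted
p-value, (ii) the effect criterion, and (iii) the quotient criterion —
for methylation: mean difference and $\log_2$ mean quotient (pseudo-count
$\varepsilon = 0.01$ avoids division by zero near unmethylated sites); for
variability: variance difference and $\log_2$ variance ratio. Ties share
the minimal rank; the combined rank is the worst (maximum) of the three,
which makes the score invariant under any strictly monotone transform of a
criterion and demands that a top unit be strong on *every* criterion, not
just one. Output is ordered by combined rank, ties broken by adjusted p
then input order. The automatic selection cutoff is the number of units
with adjusted p below the FDR level (default 0.05) — a deliberately simple,
reproducible rule; the selected set is that many best units by combined
rank. Units with missing values are dropped from testing with a reported
count (`missing = "drop"`), since imputing inside a test conflates
measurement and inference; callers preferring imputation run
`impute_missing()` first.

# Exploration and enrichment

`pca_embed()` centers each unit and decomposes the sample x unit matrix;
component signs are fixed by making the largest-magnitude loading
positive, so embeddings are reproducible across platforms.
`associate_components()` tests each component against each annotation:
Pearson correlation for numeric annotations, Kruskal-Wallis across levels
for categorical ones (robust to non-normal score distributions), skipping
single-level annotations with a notice and flagging p below 0.01 by
default.

`region_enrichment()` counts at the level of universe regions: a universe
region is "in the query" if any base pair overlaps a query region, and "in
the set" likewise, giving a 2x2 table per catalogue entry. The one-sided
enrichment p-value is the hypergeometric upper tail (identical to the
one-sided Fisher exact test); odds ratios use a 0.5 Haldane correction
when any cell is zero, and entries are ordered by the worst of their
p-value, odds-ratio, and support ranks — the same worst-rank idiom as the
differential module, applied for consistency since only "a ranked list" is
required. Base-pair-resolution enrichment is out of scope.

# The synthetic cohort generator

`generate_fixture()` draws a complete two-group sequencing cohort with
recorded ground truth. Default conditions: 20 samples per group, 5000
CpGs across five autosomes plus chrX/chrY. Null-site mean betas follow a
bimodal beta mixture ($0.03 + 0.94\,\mathrm{Beta}(0.85, 0.85)$, matching
the characteristic two-humped methylation landscape), and per-sample
betas are Beta-distributed around the site mean with precision 50.
Planted effects: 100 differentially methylated CpGs (group-1 mean shift
$\delta = 0.3$, baselines drawn mid-range so the shift is realizable) in
blocks of 5 consecutive CpGs that define the emitted DMR BED regions, and
100 differentially variable CpGs (precision divided by 4, i.e. variance
ratio $\approx 4$) likewise in blocks. Ten causal CpGs carry uniform
betas and define age as $20 + 100 \cdot \overline{\beta}_{causal} +
N(0, 2^2)$ years; 50 autosomal SNP probes carry Hardy-Weinberg genotypes
($p = 0.4$) plus 0.01 noise; 100 LUMP sites track a per-sample purity
drawn from $U(0.5, 1)$ on the 0.85 scale. Coverage is negative binomial
(mean 30, size 8) with sex-linked structure — males at half coverage on
chrX and chrY, females at 1% of autosomal coverage on chrY — which gives
the sex features their bimodal geometry and produces realistic
zero-coverage missingness (~0.4% of cells). The generator is a pure
function of its seed.

What the fixture does *not* emulate: spatial correlation of methylation
along the genome, batch effects, cell-composition confounding of the
group contrast, and array-specific probe biases. Passing tests therefore
demonstrate correctness of the statistical machinery under a clean
generative model, not robustness to every artifact of real cohorts.

Companion simulators cover the inference modules:
`simulate_age_cohort()` (default 300 samples, 2000 sites — large enough
for stable elastic-net selection while keeping runtimes in seconds),
`simulate_sex_features()` (males at $(-1,-1)$, females at $(0,-6)$,
noise sd 0.05), and `simulate_mixtures()` (Dirichlet weights over a
5-type uniform reference, measurement noise sd 0.02 on 2000 sites).

# Numerical choices and degenerate inputs

* Pseudo-counts: $\varepsilon = 0.01$ in sex-feature and log-quotient
  ratios; Haldane 0.5 in odds ratios with empty cells.
* p-values are floored at the smallest representable double rather than
  reported as 0, keeping them in $(0, 1]$ for downstream log transforms.
* The trigamma inverse uses Newton iteration from the asymptotic
  starting point $x_0 = 0.5 + 1/y$, with closed-form limits for extreme
  arguments.
* Ties in KNN distances are broken by row order (stable), and the
  worst-rank sort breaks ties by adjusted p then input order, so outputs
  are reproducible bit for bit.
* Empty filter results, empty merge intersections (with per-input
  diagnostics), single-class sex training, constant ages, rank-deficient
  references, and queries disjoint from the enrichment universe all raise
  typed errors early instead of propagating NaNs.

# Pipeline and determinism

`run_pipeline()` executes import, preprocessing, region aggregation,
covariate inference, exploration, differential analysis, and enrichment
in a fixed order, writing TSVs, a log, and the verbatim effective
configuration into the run directory. Inference, exploration, and
enrichment failures are recorded and skipped; import and preprocessing
failures abort. Every stochastic step takes its seed from the
configuration, so a (config, input) pair determines every numeric output
byte for byte; `render_report()` is byte-stable except for its timestamp
line. The resource profile gates only optional extras and never changes
the numerics of enabled stages.

The test suite exercises the standard fixture at 5000 x 40 and the
companion simulators at their defaults, sizes chosen so the statistical
assertions (calibration bands, recovery rates) have small Monte Carlo
error while the whole suite runs in about a minute.

# Known limitations

* Differential models are two-group only; covariate-adjusted and paired
  designs are out of scope.
* A fourfold variance ratio at 20 samples per group is near the detection
  floor of both variability tests (deviation t $\approx 2.6$ in
  expectation; Bartlett $\chi^2 \approx 8$), so variability selections at
  FDR 0.05 recover only the strongest planted DVCs; the worst-rank top
  list still concentrates them far above chance.
* No IDAT parsing, microarray normalization, GEO import, or shipped
  annotation/clock/LUMP resources; users supply BED files, coefficient
  tables, and site lists.
* The probe-id ingestion scheme assigns synthetic coordinates on a
  pseudo-chromosome, which supports merging and differential analysis but
  not genomic region aggregation.
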