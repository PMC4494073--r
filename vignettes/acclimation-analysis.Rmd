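---
title: "Analysing short-term thermal acclimation: methods and design choices"
author: "coralAcclim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analysing short-term thermal acclimation: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coralAcclim)
```

# The experiment the package models

Reef-building corals can raise their tolerance to acute heat stress within
days of exposure to warmer or fluctuating water. The experimental design this
package analyses crosses three *acclimation treatments* (ambient 29 °C
control, stable 31 °C, and a diel-variable 29–33 °C regime), four
*acclimation durations* (0, 2, 7 and 11 days), and an *acute-stress assay*
(each colony contributes one branch pushed through a 29→34 °C ramp-and-hold
and one paired nonstressed branch). With six colonies per treatment this
gives the canonical 3 × 6 × 4 × 2 = 144-sample layout produced by
`canonicalDesign()`. Colonies assayed at days 0 and 2 come from a second
collection batch; tank and batch are recorded in the design but not modelled,
because the analysis models only treatment and day.

Two molecular readouts are analysed:

* a gene (contig) × sample read-count matrix, for the transcriptional
  response, and
* chlorophyll-a density per branch (µg/cm²), as the bleaching phenotype.

The scientific question is not merely *which genes respond to heat stress* —
the large majority do — but whether acclimation changes the *shape* of that
response: a **dampened** response (same baseline, smaller excursion under
stress) versus a **frontloaded** one (baseline already shifted before stress,
smaller further induction).

# Filtering, normalization, and what they assume

`filterContigs()` keeps a contig when its mean raw count exceeds 5 *and* its
sample standard deviation is below its mean, both as strict inequalities. The
SD rule removes contigs whose counts are dominated by a handful of samples,
which at assembly-contig resolution are usually mapping artifacts rather than
biology.

`medianOfRatios()` estimates one depth factor per sample: for each gene
positive in every sample, the ratio of its count to its geometric mean across
samples; the sample's factor is the median ratio. The estimator assumes
**most genes are not differentially expressed**. That assumption deserves
emphasis here, because an acute heat stress shifts a large fraction of the
transcriptome at once: when most genes move in one direction, part of the
shift is absorbed into the size factors and per-gene fold changes are
compressed toward zero. The package therefore never interprets absolute
per-gene stress responses on their own; cluster-level responses are always
compared against the *genome-wide resampling null* (below), which carries
exactly the same compression and so cancels it. The pseudocount used in all
log transforms defaults to 1 and is exposed everywhere.

## Outlier samples

The quality-control rule in `flagOutlierSamples()` operationalizes "obvious
outliers on a PCA plot": samples are scored on the first two principal
components of the gene-centred log2 matrix, given robust z-scores
|score − median| / (1.4826 · MAD), and flagged when either exceeds a
threshold (default 3). Two properties matter:

* a *planted* artifact — e.g. one acute-stress tank run multiplying 30 % of
  genes tenfold in nine samples — separates by an order of magnitude and is
  recovered exactly;
* on perfectly homogeneous data a robust-z cut at 3 still fires at roughly
  its nominal two-sided normal tail (~0.5 % per sample and component), i.e.
  one or two spurious flags per 144-sample run are *expected behaviour*, not
  a defect. Users should read the outlier report rather than treat the flag
  count as a purity certificate; removal is a separate, explicit step, and
  the pipeline logs it.

# The permutational ANOVA

Per gene, the package fits the additive categorical model

  y ~ treatment + day

on log2(normalized + 1) values and forms the **Type-II** F statistic for
each term (each term's sum of squares adjusted for the other), so the tests
do not depend on factor order in the mildly unbalanced design that remains
after outlier removal. Day is treated as categorical (4 levels): nothing in
the design suggests a linear dose in days, and day 2 demonstrably is not
(the transplantation spike).

Significance comes from permutations, not F tables: the response is
reshuffled against the fixed design (unrestricted, Manly-style), and
p = (1 + #{permuted F ≥ observed F}) / (B + 1). Unrestricted shuffling is
exact under the global null of no treatment and no day structure, which is
the hypothesis screened per gene. The same B permutations are applied to
every gene from one seeded stream; this makes the genome-wide null
exchangeable across genes and runs bit-reproducible. Defaults: B = 999, so
the attainable p floor is 1/1000, below the FDR 0.01 working threshold.
Benjamini–Hochberg q-values are computed per term and selection is inclusive
(q ≤ α).

One sizing subtlety: at B = 999 a screen of 500 genes with ~50 true
positives puts BH q-values of floor-level hits at exactly 0.01, so
recovery-rate experiments in this package use B = 1999; the floor halves
and selection no longer sits on an arithmetic knife edge. This is a property
of permutation resolution, not of the biology. For the same reason the
end-to-end pipeline (`runAcclimPipeline()`) defaults to B = 1999 wherever
its FDR 0.01 selection is made: at B = 999, a default-size simulation
yields dozens of genes at the p floor whose BH q-values land at 0.012 —
an empty discovery list produced entirely by resolution, not by the data.

`twoGroupTest()` reuses the machinery for the direct stable-versus-variable
contrast (|difference of group means| under label permutation, days 7 and 11
only). The synthetic generator plants *identical* effect parameters for the
two acclimated treatments, so this contrast is null by construction — the
expected outcome is zero discoveries, and that is what the acceptance suite
checks.

# Co-expression clusters and eigengenes

Genes passing the acclimation screen are clustered by average-linkage
hierarchical clustering on the dissimilarity 1 − ρ (Spearman, midranks),
with the tree cut at height 1 − 0.6. The correlation threshold is a given;
the linkage and cut rule are a package choice: with average linkage, cutting
at 1 − ρ\* makes "members of one cluster are linked at *mean* correlation
above ρ\*" approximately true. Complete linkage (every pair above the
threshold) is available via `linkage = "complete"`. Pairwise-threshold and
correlation-with-eigengene semantics are the two natural alternatives; they
produce nested/looser variants of the same structure. Clusters smaller than
`minSize = 10` are dissolved into "unassigned" — the experiment this
emulates reported only large clusters, and tiny clusters of screened genes
are mostly correlated noise.

Each cluster is summarized by its **eigengene**: genes are standardized
(centred, unit variance) so high-variance genes do not dominate, and the
first principal component over samples is taken and centred. An eigenvector
is defined only up to sign, so the package orients it to correlate
positively with the cluster's mean standardized profile; Figure-style plots
and downstream ANOVAs are then deterministic. The eigengene ANOVA adds the
treatment × day interaction, since divergence *over days* between
treatments is exactly the expected acclimation signature.

# Heat-stress response and the resampling null

The per-gene heat-stress response is

  log2((mean normalized stressed + 1) / (mean normalized nonstressed + 1)),

i.e. a log2 fold change of mean expression. The source protocol's verbal
definition ("log2 of the mean difference") is not computable as written — a
difference of means is routinely negative — while its figures are labelled
as log2 fold changes; the package implements the fold change and documents
the discrepancy here rather than silently.

`clusterNullTest()` compares a cluster's *mean* response with the same
summary for 1,000 gene sets of equal size drawn without replacement from all
filtered contigs. The reported p is two-sided in displacement from the null
mean: p = (1 + #{|null − null mean| ≥ |observed − null mean|}) / (B + 1),
and the 2.5/97.5 percentiles of the null form the envelope drawn in
response-density figures. Testing the mean (rather than, say, a KS distance
between the member-response distribution and the background) is the choice
that matches "is this cluster up- or down-regulated as a set"; a
distribution-level statistic would also react to variance differences, which
is a different question.

# Dampening versus frontloading

`dampeningIndex()` regresses acclimated per-gene responses on control
responses through the origin; a slope below 1 with a gene-resampling
bootstrap 95 % CI excluding 1 is called dampening. The through-origin form
is the right null ("acclimated response = d × control response"); an
intercept would absorb exactly the baseline-shift signal that belongs to the
frontloading axis. The default stratum is day 11, when acclimation
divergence is fully expressed.

Two estimator caveats, both visible in the validation numbers: the
pseudocount compresses large negative responses more than small ones, and
sampling noise in the control responses (the regressor) attenuates the
slope. Together they bias the recovered slope a few hundredths *below* the
planted dampening factor (e.g. planted 0.5 recovers ≈ 0.44). The acceptance
experiments therefore check recovery within ±0.1, not unbiasedness.

`classifyMechanism()` separates the two mechanisms per gene from four
stratum means: baseline shift Δbase = |log2 ratio of nonstressed means|
and per-arm responses (stressed − baseline, log2). Frontloading requires
Δbase > 0.5 with a reduced response; dampening requires Δbase ≤ 0.5 and a
response reduced by more than 0.25 log2 units; everything else is "none".
The thresholds are package defaults — no numeric rule exists in the source
protocol — chosen at half and a quarter of a doubling, and both are exposed.
Validation classifies with baseline and stressed means pooled over days 7
and 11 — the days at which planted dampening is expressed and baselines are
stationary — because pooling doubles the samples behind each stratum mean
and correspondingly tightens the baseline-shift estimate each label rests
on.

# The bleaching phenotype

Chlorophyll a is quantified from optical densities at four wavelengths via a
published chlorophyll-a-in-ethanol equation whose coefficients ship as
editable defaults (`chlCoefficients()`; µg/ml, multiplied by the 3 ml
extract volume). Field protocols sometimes list 655 nm where the calibration
is defined at 665 nm; the package documents the discrepancy and accepts any
coefficient vector rather than silently "correcting" either convention.
Branch surface area comes from the double wax-dip method: the first dip
seals the porous skeleton, so the *second* dip's weight gain is the
calibrated quantity, converted through an OLS standard curve fitted with an
intercept (reported, so users can check it is ≈ 0, rather than forced to
zero). Bleaching resistance is the retained chlorophyll fraction —
stressed-branch density over the paired nonstressed density — and is tested
with the same permutation engine (treatment, day, interaction), excluding
day 0 by default because the day-0 assay reflects transplantation stress,
not acclimation.

# The synthetic generator

`simulateCounts()` draws counts from a negative binomial with mean
sf·2^(baseline + colony effect + day-2 spike + treatment shifts + stress
response) and gene-wise dispersion log-uniform on [0.01, 0.5]. Defaults
encode the structure the analysis is meant to recover:

* baseline log2 means uniform on [3, 8] (mean counts 8–256, so ≥ 95 % of
  genes pass the abundance filter);
* per-sample size factors uniform on [0.5, 2]; per-colony multiplicative
  effects with SD 0.25 log2 — note a colony effect scales *every* gene of a
  sample and is therefore absorbed into estimated size factors, which is
  also how the truth is compared in validation;
* a 600-gene down-regulated and a 100-gene up-regulated stress-responsive
  module (|β| = 1.5 log2) whose response is multiplied by d = 0.4 in
  acclimated treatments at days 7/11 — dampening, with the two acclimated
  treatments sharing identical parameters so their direct comparison is
  null;
* 1,000 background stress-responsive genes with random sign and magnitude
  uniform on [0.5, 2] in *all* treatments, encoding the observation that
  the large majority of the transcriptome responds to acute heat stress;
* a +0.5 log2 transplantation spike at day 2 on the module genes in every
  treatment;
* **no frontloaded genes by default**: the default experiment has no
  baseline shifts, so its nonstressed arm is a true null — matching the
  headline finding that rapid acclimation leaves baseline expression
  unchanged. Frontloaded modules (baseline +1 log2 in acclimated
  treatments) are planted only in the classification experiments.

Planted treatment-effect genes (`acclim_DE`, used in power experiments) get
random signs so the planted signal stays balanced; a one-sided planted shift
would bias median-of-ratios depth estimation and convert normalization error
into false positives — an instructive failure mode, but not the one a power
experiment should measure.

What the generator does **not** emulate: read-level noise (no FASTQ, no
mapping ambiguity), GC/length bias, host–symbiont mixture, tank effects
beyond the planted artifact, and statistical dependence between branches of
the same colony across days (the analysis, like the protocol it follows,
models none of these). Passing tests on this generator therefore validate
the statistical machinery under its stated assumptions, not robustness to
every artifact of real sequencing data.

`simulatePhenotype()` inverts the phenotype pipeline exactly at zero noise:
planted densities (nonstressed 4 µg/cm² control / 5 µg/cm² acclimated;
retained fractions 0.35 at day 0, then 0.4 control vs 0.7 acclimated) are
converted to absorbances through the configured chlorophyll equation and to
wax weights through a planted 25 cm²/g slope, so the full
absorbance→area→density→ratio chain is testable against ground truth.

# Numerical conventions

* Permutation exceedance uses F ≥ F_obs − 1e-12·max(|F_obs|, 1), so exact
  ties (e.g. a constant gene, where every permutation reproduces the
  observed statistic) count as exceedances and p = 1.
* Sums of squares below 1e-10 of the centred total are treated as zero:
  constant responses give F = 0, and a term that fits exactly with nonzero
  SS gives F = +Inf rather than 0/0.
* Empirical p-values always use the (1 + exceed)/(B + 1) form; the floor
  1/(B + 1) is never rounded away.
* Size factors are computed in log space (median of log ratios,
  exponentiated), which is algebraically the median-of-ratios and
  numerically stable for large counts.
* `writeResultTable()` prints doubles with 17 significant digits so
  write→read round trips are exact to numerical precision.

# Validation problem sizes

The test suite and the acceptance script validate on: exhaustive permutation
enumeration at 6–8 samples (720–40,320 permutations); type-I error on 20
seeded null simulations of 500 genes × 144 samples at B = 999; power on
50 planted + 450 null genes at B = 1999; cluster recovery on 40-gene
two-block data over 20 seeds; resampling-null calibration over 500 seeded
gene sets; dampening recovery at 2,000 genes (600 dampened) over 20 seeds
per planted d; and 20 seeded phenotype simulations. These sizes give each
stochastic check a comfortable margin while keeping a full validation run in
the minutes range on a single core.

# Known limitations

* Colony is recorded but not modelled as a random effect; branches of one
  colony at different days are treated as independent, as in the protocol
  the package follows.
* The permutation null is the *global* null per gene; confounders that are
  exchangeable-breaking (e.g. tank) are flagged by QC, not modelled.
* Absolute per-gene fold changes are compressed when most of the
  transcriptome responds; only null-referenced cluster summaries are
  interpreted.
* The dampening slope is mildly attenuated by pseudocount and
  errors-in-variables effects (see above); it is a comparative index, not a
  calibrated physical quantity.
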