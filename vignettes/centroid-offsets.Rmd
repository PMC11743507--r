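---
title: "Quantifying gut-microbiota shifts with centroid offsets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying gut-microbiota shifts with centroid offsets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(microshift)
library(dplyr)
```

## The question and the statistic

Diet interventions in mouse models of type 2 diabetes reshape the gut
microbial community, and a recurring analysis problem is to say *how
much* a community moved between two experimental arms, or within one arm
between the start and end of an intervention, as a single interpretable
number.  microshift implements the centroid-offset approach: ordinate
the genus-level community table by classical principal-coordinates
analysis (PCoA) of Bray–Curtis dissimilarities, average each group's
coordinates on the first two axes to get a per-group "center point", and
report the Euclidean distance between two centers,

$$
\mathrm{GM}_{offset}(g_1\!-\!g_2) \;=\;
\sqrt{(\overline{PCo1}_{g_1}-\overline{PCo1}_{g_2})^2 +
      (\overline{PCo2}_{g_1}-\overline{PCo2}_{g_2})^2}.
$$

The statistic is in ordination-coordinate units (axes are scaled by the
square root of their eigenvalues, the classical PCoA convention, so
distances in the full embedding reproduce the input dissimilarities).
It is symmetric in the two groups and provably invariant under any
orthogonal transform — axis sign flips and in-plane rotations — of the
retained subspace, which is why the package's deterministic eigenvector
sign convention cannot affect it.

Around the statistic sit the stages such a study needs end to end:
alpha diversity (Shannon in nats, Gini–Simpson), the
Firmicutes/Bacteroidota ratio, ANOSIM for overall group separation,
per-genus differential abundance, core/specific genus partitions,
genus–phenotype correlation networks, and group-level body-weight and
fasting-glucose deltas
$\Delta = \overline{X}_{w_{end}} - \overline{X}_{w_{ref}}$.

## Inference: permutation null and bootstrap

The published form of the offset comes with no significance procedure,
so `gm_offset_test()` adds one.  The key observation is that the
ordination depends only on the dissimilarity matrix, never on the group
labels; permuting labels on the *fixed* coordinates is therefore an
exact exchangeable null and costs $O(Bn)$ rather than re-ordinating per
permutation.  The p-value uses the add-one estimator
$p = (1 + \#\{\text{null} \ge \text{obs}\})/(1 + B)$, which cannot
return zero; its smallest attainable value is $1/(B+1)$.  A percentile
bootstrap interval resamples samples within each group on the same
coordinates.

Two caveats are worth knowing.  First, with very small groups (5 + 5) a
sampled permutation occasionally recreates the original split exactly;
its tied statistic counts in the numerator, so the minimal p-value is
effectively reached only with somewhat larger groups.  Second, the
default two-axis truncation is deliberate fidelity to the statistic's
definition; `n_axes` can be raised, and the offset computed on all
positive axes upper-bounds the two-axis value.

## Ordination details and negative eigenvalues

`pcoa()` double-centers $-\tfrac12 D^2$ (Gower) and eigendecomposes.
Bray–Curtis is a semimetric, so negative eigenvalues are expected; the
default policy retains positive axes only and warns with the negative
eigenvalue mass fraction, matching common ecology-toolkit behaviour and
keeping the offset well defined.  Lingoes and Cailliez additive
corrections are available by flag.  Per-axis variance explained is
reported against the total *absolute* eigenvalue mass, so it sums to 1
exactly when the matrix is Euclidean and to less than 1 otherwise.
Because community ordinations are sometimes produced with a
principal-component routine applied to the relative-abundance table
rather than a true PCoA, `pca_relabund()` provides that mode explicitly,
flagged `method = "pca"`; which of the two a given published figure used
is often undeterminable, so neither is privileged.

## The synthetic study design

`sim_design()` encodes the four-arm intervention layout the package
models: a chow control (CD+SPSS), an untreated high-fat arm (HFD+SPSS),
and two treated high-fat arms (HFD+PA, HFD+Rutin), five mice per arm,
with the microbiome sampled at week 4 (model construction) and week 10
(end of intervention).  Counts are Dirichlet-multinomial: each sample's
composition is drawn from $\mathrm{Dirichlet}(\theta\,\mathrm{softmax}(b
+ e_{g,w}))$ and counts multinomially at a log-normal library size.
Choices and defaults:

* **Rank-abundance baseline** `base_log_abundance`: a geometric gradient
  from $+4$ to $-4$ over 66 genera, spanning roughly four orders of
  magnitude — a dominant genus near 12% and a tail of rare genera, the
  shape typical of mouse fecal genus tables.  Nine phyla are assigned
  with Firmicutes and Bacteroidota alternating through the abundant
  ranks so both carry substantial mass (the F/B "seesaw").
* **Overdispersion** $\theta = 50$ and **library size** log-mean 10.8
  (about 50k reads) with log-sd 0.3: stated configuration, since
  per-sample depths and dispersion are rarely published.
* **Effects** are multiplicative on the latent log scale, so shifting
  "key taxa" automatically renormalizes everything else — the
  compositional trade-off real interventions show.  All high-fat arms
  share one dysbiosis pattern at week 4; by week 10 the untreated arm
  keeps it while the treated arms partially revert it and add
  treatment-specific shifts, the rutin-like arm more strongly than the
  PA-like arm.  Patterns alternate in sign so the total latent mass
  stays roughly balanced.
* **Key taxa** default to abundance ranks 2–20 (every second rank).
  This is a power consideration made once at design time: planted
  shifts must be detectable by a two-sample test at the design's 5–20
  mice per group, and below roughly 0.5% relative abundance the
  Dirichlet noise at $\theta = 50$ swamps a one-log-fold effect.  The
  subset is fully configurable.
* **Phenotypes** follow baseline + group slope × weeks + noise, with
  per-group baselines and slopes defaulting to the published week-4/10
  group means of the four arms (slope = printed six-week change / 6).
  The untreated high-fat arm's fasting glucose stays above the
  9.5 mmol/L diabetic-model threshold in expectation.  An optional
  coupling $\kappa$ adds each mouse's realized community shift (the
  centered-log-ratio distance between its two drawn compositions) to
  its phenotype trajectory; the default is $\kappa = 0$ because the
  strength of that coupling in real cohorts is not identifiable from
  published summaries.

What the generator does *not* emulate: phylogenetic correlation between
genera, zero-inflation beyond what the Dirichlet-multinomial induces,
batch or cage effects, and weekly microbiome dynamics (only the two
analysis time points are simulated).  Passing tests on this generator
therefore demonstrate correctness of the statistics under a clean
overdispersed compositional model, not robustness to every artefact of
real amplicon data.

## Differential abundance and networks

`differential_genera()` applies Welch's t-test per genus on relative
abundances — the unequal-variance form is the safer default when only
"t-test" is specified — with Student's and Kruskal–Wallis variants by
flag.  Retention is raw $p < 0.05$ by default for fidelity to common
practice in this literature; Benjamini–Hochberg adjustment is available
and recommended.  "Key microbes" are the intersection of the
significant sets of the two treatment contrasts.  The correlation
network computes all genus–genus and genus–feature Pearson (or
Spearman) correlations with t-approximation p-values, skips constant
columns, and exports a Cytoscape-compatible edge table
(`source, target, method, r, p, q`).  The core/specific partition calls
a genus "present" in a group when its group-mean abundance exceeds a
threshold, default 0 — any nonzero mean — since published Venn analyses
rarely state their cutoff.

## Numerical choices and degenerate inputs

* Validation is total: malformed tables raise typed errors
  (`ms_format_error`, `ms_validation_error`, `ms_schema_error`,
  `ms_join_error`, `ms_parameter_error`, `ms_config_error`) naming the
  offending cell, column or sample; nothing is silently coerced.
* Zero-sum samples are rejected at normalization; a zero Bacteroidota
  total yields a flagged `NA` ratio, and a zero denominator in a delta
  contrast flags the percentage as undefined — both recorded rather
  than thrown, since they are legitimate data outcomes.
* Eigenvector signs follow a deterministic convention (largest-magnitude
  loading positive); eigenvalue tolerances are relative
  ($10^{-8}\,\lambda_{max}$).
* Identical values in both arms of a t-test are reported as $p = 1$
  (trivially non-significant) rather than an error.
* Every stochastic routine takes an explicit seed; `run_all()` derives
  per-stage seeds from one top-level seed by stage-name hashing, so
  stages re-run in isolation reproduce exactly.

## Problem sizes used by the test-suite experiments

Monte-Carlo checks run at sizes chosen to estimate each property
precisely while keeping the default suite quick: permutation type-I
error over 2,000 null datasets at 199 permutations (binomial standard
error about 0.005 at the 5% level); Welch and network-edge calibration
over about 2,000 exchangeable-null tests; effect-grid medians over 200
replicates per effect size at the study's 5 mice per group; recovery at
20 mice per group over 5 replicates.  The acceptance script repeats the
same computations at comparable sizes from a caller-supplied seed.

## Limitations

The offset lives on a two-axis projection: separation orthogonal to the
leading axes is invisible to it, and its units are dataset-specific, so
offsets are comparable within one ordination but not across studies.
The permutation test conditions on the observed ordination; with strong
library-size artefacts a dissimilarity other than Bray–Curtis may be
more appropriate upstream.  The published offset magnitudes of the
motivating cohort require its raw sequence data and upstream denoising
choices, and are therefore reference points rather than reproduction
targets for this package.
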