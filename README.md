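# microshift

Quantifying diet-induced shifts of the gut microbiota with a
centroid-offset statistic, for microbiome researchers analysing
group-versus-group intervention designs (for example mouse models of
type 2 diabetes under high-fat diet with dietary-supplement treatment
arms).

## What it computes

The core statistic is the **GM offset**: ordinate the genus-level count
table by classical principal-coordinates analysis (PCoA) of Bray–Curtis
dissimilarities, take each group's mean position on the first two axes
as its "center point", and report the Euclidean distance between two
centers:

```
GM_offset(g1 − g2) = sqrt( (mean PCo1_g1 − mean PCo1_g2)^2
                         + (mean PCo2_g1 − mean PCo2_g2)^2 )
```

microshift implements the statistic together with the inference it
needs (a label-permutation null on the fixed ordination, a within-group
bootstrap interval, ANOSIM for overall separation) and the surrounding
stages of such a study: alpha diversity (Shannon, Gini–Simpson), the
Firmicutes/Bacteroidota ratio, group-level body-weight and
fasting-glucose deltas (endpoint mean − reference mean) with contrasts,
glucose-tolerance AUCs, per-genus differential abundance (Welch
t-test), core/specific genus partitions, key-microbe intersections, and
genus–phenotype correlation networks exported as Cytoscape edge tables.
A Dirichlet-multinomial simulator reproduces the 4-group × 5-mouse ×
2-timepoint design with known ground truth so every stage is testable
end to end.

All user-facing functions take a data frame first and return tibbles,
so stages chain with the pipe; result objects have `tidy()`/`glance()`
methods and `autoplot()` diagnostics.

## Worked example

```r
library(microshift)
library(dplyr)

design <- sim_design(seed = 101)           # the 4-arm study layout
sim    <- simulate_counts(design)
pheno  <- simulate_phenotypes(design, sim$ground_truth)

rel      <- to_relative(sim$counts)
end_meta <- filter(sim$metadata, week == 10)
rel_end  <- rel[rel$sample_id %in% end_meta$sample_id, ]

d   <- bray_curtis(rel_end)
tst <- gm_offset_test(d, end_meta, "HFD+Rutin", "HFD+SPSS",
                      n_permutations = 999, seed = 7)
tst
#> <GM offset> HFD+Rutin vs HFD+SPSS: 0.2980 on 2 axes
#>   permutation p = 0.009 (999 permutations), bootstrap 95% CI [0.2667, 0.3792]
```

The rutin-like arm's endpoint community sits 0.298 ordination units
from the untreated high-fat arm's centroid; only 0.9% of label
permutations produce a centroid distance at least that large, so the
shift is not a small-sample artefact.

```r
gm_anosim(d, end_meta, seed = 7)
#> <ANOSIM> R = 0.5857, permutation p = 0.001 (999 permutations)

deltas <- group_delta(pheno)               # endpoint mean − reference mean
deltas |> select(group, delta_bw, delta_fbg)
#> 1 CD+SPSS     2.62   0.710
#> 2 HFD+PA     -3.40  -4.65
#> 3 HFD+Rutin  -0.911 -4.55
#> 4 HFD+SPSS    5.69  -0.264
```

Untreated high-fat mice gain 5.7 g over the six-week intervention while
both treated arms lose weight and drop about 4.6 mmol/L of fasting
glucose — the pattern the simulator's defaults encode, matching the
published group trajectories of the design it emulates.

```r
delta_contrast(filter(deltas, group == "HFD+SPSS"),
               filter(deltas, group == "CD+SPSS"))
#>   measure group_a  group_b absolute_excess percent_excess undefined
#> 1 bw      HFD+SPSS CD+SPSS            3.08           54.1 FALSE
```

`run_all()` executes the whole pipeline from a YAML config (or an
in-memory list) and writes per-stage TSV/JSON artifacts, a
machine-readable `run.log`, and an aggregated `report.json` that is
byte-identical across runs with the same seed:

```r
run_all(validate_config(list(design = list(), seed = 7,
                             out_dir = "run1")))
```

## Further reading

The methods vignette (`vignettes/centroid-offsets.Rmd`) documents the
model and its assumptions, the negative-eigenvalue policy, what the
synthetic design does and does not emulate, and the package's numerical
conventions.
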