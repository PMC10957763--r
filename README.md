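# mbne — multilayer brain-network embedding

`mbne` is an R package for joint analysis of structural and functional
brain connectivity.  Neuropsychiatric disorders such as schizophrenia and
bipolar disorder alter both the white-matter wiring (structural
connectivity, SC, from diffusion imaging) and the coordination of regional
activity (functional connectivity, FC, from resting-state fMRI).  The two
modalities carry complementary information, but most analyses treat them
separately.  `mbne` couples them into a single two-layer network per
subject, learns one representation per brain region from both layers at
once, and turns those representations into group-level statistics and a
classifier.  It is aimed at researchers who have per-subject connectivity
matrices (or regional time series and fiber counts) and want region-level
group comparisons and subject-level classification without deep-learning
infrastructure.

## The method

For each subject with matrices $W^s$ (SC) and $W^f$ (FC, Pearson
correlations with negatives zeroed):

1. **Beta refinement** — every edge strength $x \in [0,1]$ becomes
   $\psi(x) = x\,\mathrm{Beta}(x;\alpha,\beta)$.  With $\beta = 1$,
   $\psi(x) = \alpha x^\alpha$: weak edges are squeezed toward zero, strong
   ones expanded, $\psi(1)=\alpha$.
2. **Multilayer construction** — the structural layer keeps all positive
   refined edges; the functional layer keeps, per node, the
   $\max(1,\mathrm{round}(\theta\cdot\mathrm{avg}_s))$ strongest entries
   ($\mathrm{avg}_s = 2|E^s|/n$).  Inter-layer transitions are weighted by
   node informativeness $I_i = \ln(e + |T_i|)$, with $T_i$ the neighbours
   of $i$ attached by edges no stronger than the layer mean.
3. **Informativeness diffusion** — random walks choose a layer with
   probability $I^s_i/(I^s_i+I^f_i)$, then a neighbour by second-order
   $(p,q)$-biased, weight-proportional probabilities, in $O(1)$ per step
   via alias sampling.
4. **Skip-gram embedding** — the walk corpus trains an $n \times d$ node
   representation by negative sampling.
5. **Templates and distances** — per-subject PCA reconfigures the
   embedding to its top-$k$ score columns $A_{n\times k}$; group centroid
   templates give per-region cosine distances $L$ (nodewise two-tailed
   $t$-tests, Bonferroni $p < 0.05/n$) and whole-network distances $H$
   (linear SVM, stratified 10-fold × 10 cross-validation; ACC, SEN, SPE,
   AUC).

A synthetic cohort generator (shared structural backbone, community latent
signals, localized "dedifferentiation" patient effects) makes the whole
pipeline testable without any imaging data.  See the methods vignette
(`vignettes/multilayer-embedding.Rmd`) for assumptions, parameter
rationale and known limitations.

## Worked example

```r
library(mbne)

cfg <- synth_config(n_regions = 30,
                    n_per_group = c(control = 20, patient = 20),
                    affected_regions = c(3, 8, 15, 22, 27),
                    effect_size = 2, seed = 42)
cohort <- simulate_cohort(cfg)

fit <- mbne(cohort, alpha = 2, dim = 8, k = 4, walks_per_node = 30, seed = 1)
summary(fit)
#> mbne fit: 40 subjects, 30 regions
#>
#> control patient
#>      20      20
#>
#> Mean node distance (rows: group, cols: reference template):
#>          template
#> group     control patient
#>   control  0.4129  0.8164
#>   patient  0.8391  0.1985
```

Each group is much closer to its own template (diagonal, 0.41 and 0.20)
than to the other group's (0.82–0.84): the representations separate the
groups at the node level.  Region-wise statistics and classification:

```r
L <- node_distances(fit, "control")
stats <- nodewise_ttests(L, fit$groups, "control", "patient")
head(stats[order(stats$p), ], 3)
#>    region         t            p significant
#> 6      R6 -5.887839 1.178026e-06        TRUE
#> 18    R18 -5.473165 3.830315e-06        TRUE
#> 16    R16 -5.426682 4.135459e-06        TRUE

cross_validated_classify(fit$A, fit$groups, positive = "patient", seed = 1)
#> <classification_report> patient vs control (10-fold x 10)
#>   ACC 0.8000  SEN 0.9000  SPE 0.7000  AUC 0.8502
```

Negative $t$ means patients sit farther from the control template at that
region.  The flagged set overlaps the injected regions but also includes
their neighbours — the embedding smooths local effects over the graph, a
limitation quantified in the vignette.  `run_pipeline()` performs all of
the above from a cohort manifest and writes every stage to disk;
`inst/cli/mbne.R` exposes `synth` and `run` subcommands for shell use.

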