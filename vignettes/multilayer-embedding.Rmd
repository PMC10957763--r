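---
title: "Multilayer brain-network embedding: model, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multilayer brain-network embedding: model, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mbne)
```

## The model

`mbne` analyses cohorts of paired brain connectivity matrices: a structural
matrix $W^s$ per subject (e.g. streamline counts divided by the summed
surface areas of the two regions) and a functional matrix $W^f$ (Pearson
correlations of regional time series, negatives and the diagonal set to
zero).  Both are symmetric, nonnegative, and indexed by the same $n$
regions.  The pipeline has five stages.

**1. Beta refinement.**  Every edge strength $x \in [0,1]$ is mapped through
$$\psi(x) = x \cdot \mathrm{Beta}(x;\alpha,\beta),$$
the strength times the beta probability density at that strength.  In the
monotone regime ($\alpha \ge 1$, $\beta = 1$) this reduces to
$\psi(x) = \alpha x^{\alpha}$: weak connections are squeezed toward zero and
strong ones expanded, with maximum $\psi(1)=\alpha$.  With $\alpha = 2$ a
connection of $0.9$ maps to $1.62$ while $0.5$ maps to $0.5$ — a 224% gap
where the raw strengths differ by 80%.  For $\beta < 1$ the density diverges
at $x \to 1$, so only $\beta = 1$ is used.

**2. Structure-guided multilayer construction.**  The structural layer keeps
every positive entry of the refined $BW^s$ (tractography is already sparse).
The functional layer is sparsified under structural guidance: with
$\mathrm{avg}_s = 2|E^s|/n$ the structural average degree, each node
nominates its $k^* = \max(1, \mathrm{round}(\theta\,\mathrm{avg}_s))$
strongest entries of $BW^f$ and an edge is kept if either endpoint nominated
it.  The two layers are joined by directed inter-layer edges between copies
of the same region, weighted by *node informativeness*
$$I_i = \ln(e + |T_i|),$$
where $T_i$ is the set of neighbours of $i$ attached by edges no stronger
than the layer's mean edge weight.  A node strongly tied to only a few
neighbours is more informative than a hub with many strong ties.

**3. Informativeness diffusion.**  Node sequences are sampled by a walk
that, at each step, first picks the next layer with probability
$I^s_i/(I^s_i+I^f_i)$ for the structural side (and the complement for the
functional side), then picks the next node inside that layer with
second-order biased probabilities: mass $w/p$ for returning to the previous
node, $w$ for a common neighbour of the previous node, $w/q$ for a node two
steps away — falling back to plain weight-proportional sampling whenever the
edge (previous, current) does not exist in the chosen layer (including the
first step).  Every step costs $O(1)$ draws via alias tables built once per
node and per directed edge.  Emitted sequences contain node ids only; layer
tags are discarded so each region has a single representation.

**4. Skip-gram embedding.**  The corpus ($r$ walks of $\lambda$ steps from
every node, $\lambda+1$ node ids per walk) trains an $n \times d$
representation $F$ by maximising the skip-gram objective with negative
sampling (5 negatives from the unigram distribution to the 3/4 power,
dynamic window, linearly decaying learning rate from 0.025, single-threaded
and bit-reproducible under a fixed seed).

**5. Reconfiguration and template distances.**  Each subject's $F$ is
row-centred and rotated onto its own principal axes; the top-$k$ score
columns, ordered by explained variance, form the reconfigured matrix
$A_{n\times k}$.  Group analysis is template-referenced: the node template
of a group stacks the per-region centroid rows $\tau_i$; a subject's node
distance at region $i$ is $\mathrm{CosDist}(A_i, \tau_i) = 1 - \cos$, in
$[0,2]$.  Network-level analysis concatenates $A$ row-major into a vector
of length $nk$, builds positive/negative group centroids $C^+, C^-$, and
represents each subject by its two distances $H \in \mathbb{R}^{m\times2}$.
Region-wise two-tailed $t$-tests on the node distance columns (Bonferroni,
$p < 0.05/n$) flag affected regions; a linear SVM ($C=1$) on $H$ under
stratified 10-fold cross-validation repeated 10 times classifies groups,
reporting ACC, SEN, SPE and AUC.

## Parameters

| Parameter | Default | Meaning and rationale |
|---|---|---|
| `alpha`, `beta` | 10, 1 | beta-density shape; $\beta=1$ is the monotone bounded regime, $\alpha$ sets squeeze/expand strength ($\psi(1)=\alpha$) |
| `theta` | 0.5 | functional layer scale relative to the structural average degree |
| `p`, `q` | 0.1, 1.6 | return and in-out bias of the second-order walk; small $p$, $q>1$ keep the diffusion local |
| `walk_length` | 10 | steps per walk; a walk emits `walk_length + 1` node ids including its start |
| `walks_per_node` | 10 | corpus size per node (unspecified in the source method; standard for this sampler family) |
| `dim` | 80 | embedding dimension |
| `window`, `negatives`, `epochs` | 10, 5, 5 | skip-gram conventions (unspecified in the source method) |
| `k` | `dim/2` | retained principal components |
| `folds`, `repeats` | 10, 10 | cross-validation protocol |

The defaults suit $n \approx 90$-region parcellations.  For the 30-region
synthetic studies shipped in the test-suite we use `alpha = 2`, `dim = 8`,
`k = 4` and `walks_per_node = 30`: a 30-node graph with four communities has
an intrinsic geometry of a handful of dimensions, components beyond it are
sampling noise, and the aggressive $\alpha = 10$ power map (tuned on
heavy-tailed fiber-count distributions) collapses the narrow synthetic
weight distribution into near-winner-take-all transitions.

## Numerical and design choices

* **Cohort-level structural scale.**  Structural weights are unbounded, so
  they are divided by a scale before refinement.  `mbne()` uses the
  *cohort-wide* maximum: identical edge strengths must map identically
  across subjects.  A per-subject maximum (available via `refine_matrix()`
  for single-subject use) would compress every edge of a subject whose
  maximum happens to be large — in a patient with locally increased
  connectivity this turns a localized effect into a global artefact.
* **PCA sign convention.**  Principal-axis scores are invariant to any
  rotation of the embedding basis — that invariance is what makes
  independently trained embeddings comparable at all — but each component's
  sign is arbitrary.  We flip each component so that its score vector has a
  positive third moment (falling back to making the largest-magnitude score
  positive when the scores are unskewed).  A convention expressed on the
  *loading* vector would live in the embedding's own rotated basis and
  assign effectively random signs across subjects.
* **Component identifiability.**  Components are matched across subjects by
  variance order only.  When two eigenvalues are close the matching (and
  any rotation inside the near-degenerate eigenspace) becomes unstable;
  this is the method's principal limitation (below).
* **Degenerate inputs.**  Constant time series yield zero correlations with
  a warning; a region isolated in one layer forces the walk into the other
  layer, and a region isolated in both ends the walk early (every region
  still enters the corpus as a walk start).  Zero rows in distance
  computations record the maximum distance 2 with a warning (`strict`
  errors instead).  Regions with zero within-group variance in both groups
  record $p = 1$.
* **Tie-breaks.**  Top-$k^*$ nomination breaks weight ties by ascending
  node index; $k^*$ rounds half-up with a floor of one so a sparse
  structural layer never empties the functional layer.
* **Leakage guard.**  Cross-validated classification rebuilds both network
  templates from each training fold; `paper_protocol = TRUE` restores
  whole-cohort templates for comparison with reports that do not state
  their protocol.
* **Determinism.**  Walks and training use a self-contained 64-bit Mersenne
  Twister with uniforms derived from raw draws, so corpora and embeddings
  are bit-identical for a given seed on any platform; per-subject seeds
  are derived from the master seed.
* **Welch vs Student.**  The $t$-test defaults to Welch's unequal-variance
  form; the pooled-variance Student variant is available
  (`var_equal = TRUE`).

## The synthetic cohort generator

`synth_config()` / `simulate_cohort()` emulate a case/control multimodal
study without any imaging data.  All subjects share a cohort-level
structural backbone — a weighted stochastic-block graph with four
communities of unequal size (40/30/17/13% of regions), minimum degree 2,
within-community edges four times as probable as between — because human
anatomy is strongly conserved and template-referenced comparison
presupposes it.  Unequal community sizes are deliberate: equal blocks
produce a near-degenerate top eigenspace whose arbitrary per-subject
rotation scrambles the reconfiguration.  Each subject multiplies backbone
weights by lognormal jitter (sd 0.15, a test-retest-reliability-like
level); functional time series arise from community latent signals mixed
through the subject's own backbone (mixing weight 0.4) plus Gaussian
observation noise (sd 0.5, $T = 200$ timepoints).

The patient effect is a *dedifferentiation* of the affected regions:
incident edges at or below the region's backbone-median weight are scaled
by $(1+\delta)$ and those above by $1/(1+\delta)$, i.e. coupling is
redistributed from the region's strong to its weak connections, as in the
loss of connectional specificity reported for psychotic disorders.  The
perturbed weights are observed as the subject's SC and drive the latent
mixing, so the functional effect is coupled to the structural one
(`effect_modality` isolates either pathway).  A *uniform* gain on all
incident edges would be nearly invisible to this pipeline by construction:
$\psi$ is a power map, so per-node transition probabilities are invariant
to a common factor on a node's edges.  $\delta = 0$ reproduces the control
distribution exactly.

What the generator does *not* emulate: hemodynamics, regional signal
heterogeneity, scanner/site effects, demographic covariates, and
distance-dependent connection probability.  Passing tests therefore show
the pipeline's statistical behaviour under idealised modular networks, not
performance on real cohorts.

## Validation scale and known limitations

The shipped validation suite runs cohorts of 30 regions with 20+20
subjects (5 effect seeds, 20 null cohorts, and 200 reduced nulls of 8+8
subjects for family-wise-error calibration); these sizes are chosen so the
whole suite completes in minutes on one core.  Sampler correctness is
checked against exact enumeration of the two-layer transition
probabilities, and the single-layer reduction against an independently
coded second-order walk oracle.

Two findings from that suite should temper expectations on small cohorts.
First, null calibration is sound: with no injected effect, Bonferroni
nodewise tests flag nothing in the overwhelming majority of cohorts and
the family-wise error stays within its nominal bound, while classification
accuracy sits in the chance band.  Second, sensitivity is limited:
with a strong localized dedifferentiation ($\delta = 2$) the affected
regions' group contrast consistently exceeds that of unaffected regions,
but nodewise $t$-statistics typically remain below the Bonferroni
threshold and cross-validated accuracy below 0.9, so the ground-truth
recovery check in the suite documents sub-threshold sensitivity rather
than full recovery.  The root causes are inherent to the method's design:
independently trained embeddings are comparable only through their PCA
scores, component matching is stable only while eigenvalues are well
separated, and co-occurrence smoothing spreads any local perturbation over
its graph neighbourhood.  Explicit cross-subject alignment (e.g.
orthogonal Procrustes) would address this but is intentionally outside
this method's scope.
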