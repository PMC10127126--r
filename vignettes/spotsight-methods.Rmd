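---
title: "Inferring spatial gene expression from slide images: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring spatial gene expression from slide images: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Spatial transcriptomics assays such as 10x Visium measure expression of
thousands of genes at thousands of ~55 µm capture spots arranged on a
honeycomb lattice, co-registered with an H&E-stained slide image. The assay
is expensive; the image is nearly free. `spotsight` implements a pipeline
for the resulting inference problem: *predict the expression measured at
each spot from the image patch around it*, compare a purely local patch
model against a graph model that can see the surrounding spots, and test
whether the inferred expression reproduces the slide's spatial biology
(which genes are spatially autocorrelated, and where).

Because public Visium cohorts with matched images are not bundled here, the
package ships a synthetic slide generator with known ground truth. Every
claim the test-suite makes about the models is a claim about recovery of
that known truth.

# The synthetic cohort

## Geometry

`make_hex_grid()` lays spots on a pointy-top offset lattice: row $r$ sits at
$y = r\,p\sqrt{3}/2$ and odd rows are shifted by $p/2$, where $p$ is the
centre-to-centre pitch in pixels. Every interior spot has exactly six
neighbours at distance $p$. Defaults are $p = 64$ px with a 36 px capture
disc — the same diameter:pitch ratio as a real Visium array, scaled so that
a 64 px patch plays the role a 256 px patch plays at full scanner
magnification. The default cohort is 4 slides of 32×32 ≈ 1000 spots and 60
genes, a desk-scale analogue of 4 slides × ~5000 spots × 1000 genes.

## Expression model

Counts follow a zero-inflated negative binomial (ZINB): with probability
$\pi_g$ a spot emits a structural zero, otherwise a negative binomial draw
with mean $\mu_g(s)$ and dispersion $\sigma_g$, variance
$\mu + \mu^2/\sigma$. The expected count is $(1-\pi)\mu$. Per-gene
$\sigma_g \sim U(1,4)$, $\pi_g \sim U(0.05, 0.3)$ and baseline means
$U(2, 8)$ — values at which the 30% coverage filter keeps nearly all genes
and the per-slide median dichotomization has both classes.

Spatial structure enters through latent factor fields shared by genes
(`make_gene_design()` fixes the gene–factor map once per cohort, so genes
behave consistently across slides and are learnable across folds):

* `f1`, `f2`: smoothed Gaussian random fields (i.i.d. normals smoothed by a
  Gaussian kernel, lengthscale 3 pitches, standardised). The 20 *local*
  spatially variable (SV) genes load on these with
  $\log \mu_g(s) = \log m_g + \beta_g f(s)$, $|\beta_g| \sim U(0.6, 1)$.
* `fctx`: a per-spot texture field that is *spatially independent* across
  spots. The 10 *contextual* genes load on the standardised 1-ring
  neighbour mean of `fctx`. Independence is deliberate: with a smooth
  `fctx` the spot's own disc would predict the neighbour mean through
  autocorrelation and the local-vs-contextual contrast would blur; with an
  independent field the contextual signal is recoverable *only* by reading
  the neighbouring discs, which a patch of side ≈ pitch cannot see.
* `fmet`: a smooth field present only on `met`-group slides. The 10
  *group-differential* genes load on it, so they are SV on metastasis-group
  slides and flat elsewhere.
* 20 *noise* genes have constant $\mu_g$.

## Image model

`render_slide()` draws each capture disc on a noisy off-white background.
Channel statistics are monotone readouts of the factors at that spot: red
mean encodes `f1`, green `f2`, blue `fctx`, and the density of dark
speckles inside the disc encodes `fmet`. Factors not loaded by any gene are
left flat so the image carries no signal for them. This is not an attempt
at H&E realism — no nuclei, stain variation, or tissue morphology — it is
the minimal texture model in which "molecular signal encoded in local
texture" and "signal encoded only in the neighbourhood" are both true by
construction and separately measurable. Consequences: a passing pipeline
demonstrates that the models can extract signal that is present at the
stated spatial scale, not that real H&E carries such signal; and absolute
AUROC values are upper bounds relative to histology, where the
image–expression link is far weaker.

Not emulated: library-size variation and batch effects beyond what the
shared design implies (an optional per-spot depth factor was considered and
left out; medians and coverage are computed on raw counts throughout),
off-tissue spots (simulated positions are all `in_tissue = 1`, but the
reader honours the flag), segmentation/registration error.

# Inference targets

Binary: a spot is labelled high for a gene iff its count is *strictly*
greater than that gene's median on that slide (`dichotomize()`); ties at
the median are negative, which matters for zero-heavy genes. Labels are
per-slide by definition, so the held-out slide's labels use its own
medians — this is label *definition*, not leakage, and AUROC is
threshold-free on the prediction side. The loss is a split-weighted binary
cross-entropy: per gene, the mean of $-\log p$ over positive spots plus
the mean of $-\log(1-p)$ over negatives (`weighted_bce()`), making the
loss invariant to class imbalance. Probabilities are clamped to
$[10^{-7}, 1-10^{-7}]$.

Count regression: the model head outputs $(\mu, \sigma, \pi)$ per spot and
gene through softplus/softplus/logistic activations (plus a $10^{-4}$
floor on $\mu, \sigma$), trained by the exact ZINB negative log-likelihood
(`zinb_nll()`, with analytic gradients); the predicted expression is
$(1-\pi)\mu$. `fit_zinb()` exposes the head in isolation as a maximum
likelihood fitter.

# Models

**Local patch model.** A small CNN trained from scratch on 64 px
spot-centred patches: three 3×3 conv-ReLU blocks (8, 16, 32 channels,
strides 4, 2, 2), global average pooling, a 64-unit dense embedding layer
(the penultimate layer), and a linear multi-gene head predicting all genes
at once. The backbone sits behind `cnn_init()`, so an Inception-class
network could be substituted without touching the training loop; a
pretrained backbone is out of scope here and unnecessary on synthetic
textures. There is no normalisation layer: inputs are standardised by fixed
reference constants, weights use He initialisation, and Adam handles the
rest — at this depth a norm layer adds statefulness without measurable
benefit. The first stride is 4 rather than 2 because the im2col gather at
the input layer dominates CPU cost; channel means and speckle density
survive stride-4 sampling. Training: Adam, lr $10^{-3}$, batch 32, 10
epochs, augmentation with random rotations (±15°), horizontal/vertical
flips and colour jitter. The learning rate is higher than the fine-tuning
rate one would use with pretrained weights; $10^{-4}$/25-epoch presets can
be set through `cfg`. All training is deterministic given `cfg$seed`.

**Graph attention model.** Spots are nodes; edges connect spots within
1.05 pitch (`build_spot_graph()`), which reproduces the 6-neighbour
honeycomb adjacency — the pitch-relative radius generalises the fixed
150 px radius that is specific to one magnification. `train_gat()` stacks
1, 2 or 4 multi-head attention layers (8 heads, width 64, LeakyReLU(0.2)
edge logits, per-neighbourhood softmax including a self edge) over the
*frozen* penultimate-layer embeddings of the fold's trained CNN, then the
same multi-gene head. Frozen embeddings mirror the extract-then-contextualise
design; hidden width 64 and no dropout are the defaults where the source
procedure is silent. Training is full-batch Adam (300 steps, lr
$5 \times 10^{-3}$). `n_layers = 0` degenerates to a linear head and is
provably graph-independent; predictions at a node depend only on nodes
within `n_layers` hops (tested by perturbation).

# Evaluation

`run_loso_cv()` performs leave-one-slide-out cross-validation: each slide
is held out once; gene labels, CNN, and GAT are fit on the remaining
slides only (the no-leakage property is asserted by corrupting the
held-out slide and checking the trained weights are bit-identical).
Per-gene metrics on the held-out slide: AUROC (rank formula, ties count
one half), average precision (step interpolation over unique-score
blocks), Spearman and Pearson against raw counts. Genes with single-class
truth are flagged degenerate and excluded from medians but counted, never
silently dropped.

The headline statistic is the macro-average across slides of the median
across genes. Confidence intervals (`aggregate_metrics()`) bootstrap
*genes* with replacement — the statistic is a median over genes, so gene
resampling targets its sampling variability; the resample is shared across
folds within an iteration. `combine_top_models()` assigns each gene its
best model by cross-validated AUROC computed on the *other* folds only
(ties go to the local model), then recomputes the combined statistic from
held-out predictions.

# Spatial statistics

The spatial-variability machinery consists of declared stand-ins for
dedicated SV tools, chosen because downstream analyses only consume
(statistic, p, FSV) triplets; externally computed triplets drop in
anywhere:

* `sv_test()`: Moran's I under row-normalised 6-neighbour weights, with a
  one-sided permutation p-value $(1 + \#\{I_\pi \ge I\})/(B+1)$ — one-sided
  because "spatially variable" means clustered, not repulsive. Constant
  genes are degenerate with $p = 1$.
* `estimate_fsv()`: fraction of spatial variance as
  $\mathrm{var}(\text{Gaussian-smoothed values})/\mathrm{var}(\text{values})$,
  clipped to $[0,1]$, affine-invariant. The default lengthscale is one
  pitch: smoothing at several pitches attenuates even genuinely smooth
  fields and compresses the dynamic range of the estimator.
* `coexpression_groups()`: k-means (k = 5, seeded, 10 restarts) on
  z-scored smoothed spatial patterns, a clustering stand-in for
  model-based expression histology.

The canonical order is coverage filter (≥ 30% of spots non-zero; boundary
retained) → Anscombe transform $x \mapsto 2\sqrt{x + 3/8}$ → optional 2×2
median pooling → SV test. The hexagonal lattice has no literal 2×2 squares,
so pooling blocks are integer-halved array indices, the closest
well-defined analogue.

# Recapitulation statistics

`optimize_threshold_fisher()` dichotomizes truth and predicted SV p-values
over a cutoff grid ({0.001, 0.005, 0.01, 0.05, 0.1} by default; the search
space is a package choice since only the maximisation itself is
prescribed), cross-tabulates genes, and keeps the cutoff pair maximising
$|\log \mathrm{OR}|$, with the two-sided Fisher exact p for tie-breaks.
The reported OR is the sample odds ratio with a Haldane 0.5 correction
when a cell is empty, keeping large associations finite. `sv_vs_auc()`
applies the same machinery to truth-SV versus per-gene AUC (grid 0.55 to
0.9); its orientation is fixed so that OR > 1 always means *spatially
variable genes are predicted more accurately* — reported odds ratios for
this analysis can otherwise flip depending on which class is labelled
"high", so the package pins the orientation and documents it rather than
matching any particular table's convention. `groups_vs_auc()` is a
Kruskal–Wallis test of AUC across co-expression groups.

One subtlety: spatial-autocorrelation tests are amplitude-invariant, and
the mean surface of any image-driven model is a smooth function of the
image — so testing the raw predicted values calls *every* gene spatially
variable, even pure-noise genes whose predictions vary by ±0.02. The
recapitulation driver therefore tests one posterior-predictive draw of the
inferred expression (`predictive_draw()`: Bernoulli draws from predicted
probabilities, ZINB draws from predicted count parameters), which asks the
meaningful question — does the inferred expression *distribution* carry the
gene's spatial structure above its own noise level — and restores the
intended contrast between signal and noise genes.
`differential_sv()` selects genes whose dichotomized SV call (default
cutoff p < 0.01) is uniform within each slide group and differs between
groups; no multiple-testing correction is applied, matching the
dichotomize-then-compare design, and the limitation is noted here.

# Numerical choices and degenerate inputs

* Probability clamps ($10^{-7}$), softplus floors ($10^{-4}$), and a
  logistic clamp on $\pi$ ($10^{-6}$) keep all losses finite.
* Permutation p-values are never below $1/(B+1)$; p-value grids should not
  include cutoffs finer than that resolution.
* Ties: median dichotomization is strict (`>`); AUROC gives ties half
  credit; AP treats tied scores as one block; model selection ties go to
  the priority order (local model first); threshold-search ties go to the
  smaller Fisher p, then the smaller cutoffs.
* Every stochastic operation takes a seed and restores the caller's RNG
  state; per-slide, per-fold and per-gene seeds are derived from the base
  seed, and the CLI is byte-reproducible.
* Written pixel coordinates are rounded to integers (the positions-file
  dialect is integral); in-memory lattices keep exact coordinates.

# Problem sizes

The test-suite and the acceptance script run the full pipeline at the
package's default scale — 4 slides × 1024 spots × 60 genes, 10 CNN epochs
per fold, 999 permutations per SV test, 1000 genes for null calibration,
5000 observations × 3 seeds for ZINB recovery — chosen as the desk-scale
study conditions the generator defines. One cross-validation fold trains
in about a minute on a single CPU.

# Known limitations

* The image generator is a texture code, not histology; transfer of the
  reported effect sizes to real H&E is untested by design.
* The GAT consumes frozen embeddings; joint fine-tuning might behave
  differently.
* The FSV estimator is biased downward for fields rougher than its
  smoothing lengthscale and is not a likelihood-based decomposition.
* `differential_sv()` with two slides per group has limited specificity;
  its calls are exploratory, mirroring the dichotomize-and-compare design
  it implements.
* The vision-transformer baseline and pathway-enrichment analyses are out
  of scope.
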