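---
title: "Quantifying flower-shape modularity and its evolution with floramorph"
author: "floramorph authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying flower-shape modularity and its evolution with floramorph}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(floramorph)
```

# The problem

Flowers are built from four organ classes (sepals, petals, stamens,
carpels), and competing hypotheses predict different ways those parts
covary: as an attraction module versus a reproduction module, as modules
defined by pollination function (pollen deposition and receipt, or
reward-access restriction), or as one module per developmental organ class.
`floramorph` implements the quantitative machinery to test these hypotheses
on 3D landmark data sampled across a clade, and to ask how floral shape,
size and integration evolve when species differ in pollination syndrome
(generalist insect, bird, long-proboscid fly, wind).

The package covers the complete workflow: generalized Procrustes alignment,
shape principal components, an eigenvalue-variance integration coefficient,
allometric regression with permutation tests, RV-coefficient modularity
tests against random landmark partitions, random-forest syndrome
classification, equal-rates Markov reconstruction of ancestral syndromes
with stochastic character mapping, regime-dependent univariate
trait-evolution models selected by AICc, a penalized-likelihood
multivariate model comparison by GIC, ancestral shape reconstruction, and
thin-plate-spline warping.  A synthetic-data module generates full datasets
with known ground truth so that every stage can be validated by recovery
rather than by eyeballing.

# Shape: alignment and derived statistics

## Generalized Procrustes alignment

`gpa_align()` performs full Procrustes superimposition: each configuration
is centred, scaled to unit centroid size, and iteratively rotated (proper
rotations only — landmark configurations are chirality-bearing, so
reflections are never allowed) onto the running consensus until the RMS
consensus change falls below `tol` (default `1e-10`, `max_iter = 1000`).
After convergence the aligned shapes are projected orthogonally onto the
tangent space at the consensus, because every downstream statistic
(covariances, PCA, regressions) assumes a linear space.  Finally all
configurations are rotated so the consensus lies along its principal axes
with a fixed sign convention; without this canonicalisation the output
would be defined only up to a global rotation and reruns on rigidly moved
inputs would disagree.

Centroid size (`centroid_size()`) is the square root of the summed squared
landmark distances to the centroid; it is reported separately and is the
reason full (unit-size) rather than variance-preserving scaling is used.

`symmetric_component()` implements object symmetry: each flower is
mirrored, its paired landmarks swapped, originals and copies are jointly
re-superimposed and averaged.  The landmark pairing is a user input; the
synthetic template ships one.

## Covariances, PCA, integration, allometry

`pooled_covariance(group_by = "species")` sums within-species centred
cross-products and divides by the pooled degrees of freedom, so species
mean differences never enter; this is the covariance the modularity tests
use (variation pooled by species within a syndrome).  `shape_pca()` is an
eigendecomposition with a sign convention (largest-magnitude loading
positive).  Integration (`integration_vrel()`) is the relative eigenvalue
variance

$$V_{rel} = \frac{\sum_i (\lambda_i - \bar\lambda)^2 / p}
                 {\bar\lambda^2 (p - 1)},$$

zero for isotropic variation and one when all variation lies on a single
axis.  The denominator count `p_vars` defaults to the full 3L variable
count; whether a rank-based denominator is preferable is genuinely open, so
both are easily computed (pass `p_vars = rank`).

`allometric_regression()` regresses shape on `log10` centroid size
(log transformation is standard allometric practice; raw size is available
via `log_size = FALSE`), optionally within species ("pooled by species"),
and reports the percentage of shape variation predicted together with an
add-one permutation p-value, `p = (1 + #[perm >= obs]) / (n_perm + 1)`;
permutations shuffle sizes within species under pooling.

# Modularity: RV coefficients against random partitions

For two landmark sets the RV coefficient is
$\mathrm{RV} = \mathrm{tr}(S_{AB}S_{BA}) / \sqrt{\mathrm{tr}(S_{AA}^2)\,
\mathrm{tr}(S_{BB}^2)}$; for K > 2 modules `multiset_rv()` averages the
pairwise values.  A hypothesis is supported when few random partitions with
the same module sizes achieve a lower RV (`modularity_test()`); ties count
as not lower, a conservative choice.  The unit of partitioning is the
landmark — its three coordinates always travel together — and no spatial
contiguity constraint is imposed on the null partitions.

Because the test only needs sums of squared covariances within 3x3
landmark blocks, the null stream is evaluated from a precomputed L x L
block matrix: each random partition costs one L x K cross-product, which
makes 10^5 partitions (the default; larger values are configuration knobs)
a matter of seconds, with exact exhaustive enumeration swapped in
automatically whenever the number of distinct partitions does not exceed
the request.  Null partitions are sampled with replacement; at L = 33 the
collision probability is negligible.

# Syndrome classification

`train_and_predict()` wraps a random forest (500 trees, `mtry =
floor(sqrt(p))`, stratified bootstrap per class) over Procrustes
coordinates, centroid size and tube length, with permutation-based
out-of-bag importance (mean decrease in accuracy).  Training is on
individual flowers, since per-flower classifications are what species-level
vote tables (`species_assignment()`) aggregate; a species is flagged
ambiguous when its top class is tied or carries no majority.

# Evolution on the chronogram

## Discrete: syndromes

`mk_er_fit()` fits the single-rate (equal rates) Markov model by pruning,
with a uniform root prior (configurable design point; the data at 19 tips
cannot distinguish root priors meaningfully).  `marginal_states()` gives
empirical-Bayes node marginals; `stochastic_maps()` samples complete
histories conditional on tips, with branch histories drawn by
uniformization — exact and stable even at high rates because the Poisson
mixture is accumulated on the log scale.

## Univariate traits: BM and OU under syndrome regimes

`paint_regimes()` turns node states into per-branch regime segments.  The
default convention paints a branch with its parent node's state; the
pipeline instead uses the child-state convention (`mode = "child"`) so that
a syndrome observed only at terminal taxa still paints its terminal
branches.  Under the parent convention such a regime occupies zero branch
time, its optimum is structurally unidentifiable, and the richer OU models
are excluded by the Hessian diagnostic for every trait — the child
convention is the scientifically usable default at this sample size.

`model_loglik()` builds the Gaussian mean and covariance by per-segment
integration; for an Ornstein-Uhlenbeck process with pull $\alpha$ the
shared-path segments contribute
$\sigma^2_k\,(e^{-2\alpha(T-t_1)} - e^{-2\alpha(T-t_0)})/(2\alpha)$ and tip
expectations are path-weighted combinations of regime optima with weight
$e^{-\alpha T}$ left on the root regime's optimum (no separate root-state
parameter: at n = 19 it is not identifiable).  Five models are available —
BM1, BMS, OU1, OUM, OUMV — with parameter counts 2, 1+R, 3, 2+R, 1+2R.
`fit_model()` profiles the linear parameters (root value or optima, global
scale) by GLS and optimises only the remaining one to K+1 parameters with
bounded multi-start quasi-Newton search ($\alpha \in [10^{-8}, 100]/T$).
A numerical Hessian of the negative log-likelihood over all natural
parameters is computed at the optimum; a non-positive eigenvalue marks the
model as too rich for the data and `model_table()` excludes it before
computing AICc weights.

## High-dimensional shape: penalized likelihood and GIC

`penalized_fit()` fits BM, OU and EB to the n x p species-mean shape matrix
(p = 3L may exceed n) under a matrix-normal model whose trait covariance is
ridge-shrunk toward its diagonal, $R(\lambda) = (1-\lambda)S_{phylo} +
\lambda\,\mathrm{diag}(S_{phylo})$, with $\lambda$ selected on a 21-point
grid by leave-one-species-out predictive likelihood and the model parameter
optimised in an outer loop against the penalized likelihood.  The
restricted (REML) likelihood is the default: with the mean profiled by ML
the expected profile log-likelihood under Brownian data peaks at a
strictly positive pull, so ML-based selection systematically prefers OU on
BM data at n = 19; the restricted likelihood removes that bias.

Model comparison uses a generalized information criterion,
$\mathrm{GIC} = -2\ell + 2\,\mathrm{edf}$, with the covariance degrees of
freedom interpolated by the shrinkage weight,
$\mathrm{edf}_R = (1-\lambda)\,p(p+1)/2 + \lambda p$, and the OU/EB
parameter charged an effective cost $\hat\nu = \hat K/\hat J$ estimated
from per-species score contributions of the whitened rows.  $\hat\nu$ is
approximately 1 when the shrunk trait covariance is adequate and grows when
real trait correlations are flattened by the diagonal target, in which case
likelihood-ratio fluctuations are inflated and an extra parameter must cost
more than one unit.  This criterion is validated by model recovery on
synthetic data (multivariate BM recovered as best-GIC in 17 of 20
replicates at n = 19, p = 30, with OU power retained), not by numerical
equality with any particular published implementation.

`ancestral_shapes()` reconstructs internal-node trait vectors columnwise by
GLS/BLUP, $\hat a = \mu + C_{a,\mathrm{tips}}C^{-1}(Y - \mathbf 1\mu')$,
back-folding rows to L x 3 configurations; tips reproduce their observed
values exactly and the root equals the phylogenetic mean.  `tps_warp()`
solves the 3D thin-plate spline with kernel $U(r) = r$ by the null-space
method (better conditioned than the bordered system) and evaluates
distances by per-coordinate differences to avoid cancellation, so source
landmarks map onto their targets to ~1e-10 and affine targets are
reproduced with vanishing bending energy.

# The synthetic-data generator

`make_template()` builds a deterministic urn-shaped flower of 33 labelled
points (sepal tips, widest corolla ring, narrow mouth ring, petal-lobe
meeting points, anther tips, ovary/style transition, stigma), bilaterally
symmetric and of unit centroid size, together with the four canonical
module maps, the mirror pairing, and tube base/mouth indices.

`simulate_specimens()` mirrors the study design the package targets: 19
species with 10 flowers each and syndrome frequencies of 12 generalist, 4
bird, 2 long-proboscid-fly and 1 wind species.  Species means are the
template deformed by syndrome (tube elongation and mouth constriction —
the features that dominate the first shape principal component in real
ericoid flowers) plus a random species effect; flowers add an allometric
vector times a log-size draw and noise with planted block-modular
covariance (within-module correlation 0.6, between 0.1 by default, blocks =
developmental modules).  Each flower is finally re-expressed under a random
rotation, translation and scale tied to its size draw, so alignment is
genuinely exercised and observed centroid size carries the allometric
signal.  Default magnitudes (noise SD 0.012 in shape units, species effect
0.02, allometric coefficient 0.08) were chosen once so that the simulated
dataset reproduces the qualitative regime of real flower data — weak but
significant allometry (about 1–2% of shape variance), strong within-species
modular signal, and cleanly separable syndromes.

`simulate_tree_and_traits()` draws a pure-birth chronogram, evolves
syndrome regimes under the ER model (Gillespie along branches, so the true
segment history is recorded), and simulates traits by exact segment-wise
transition distributions.  The OUM/OUMV defaults place optima 0–3 apart
with $\alpha T = 2$ and stationary SD 0.25: a strong-selection,
well-separated design under which optimum recovery to within 0.5 is an
informative test.  Every generator is a pure function of its seed, and the
returned truth records are sufficient to score recovery at every stage.

What the generator does *not* emulate: digitisation error correlated along
the flower surface, within-genotype covariance structure beyond the planted
blocks, missing landmarks, and mesh-level detail.  Passing recovery tests
therefore validates the statistical machinery, not the biological claims
one might draw from any particular real dataset.

# Pipeline and reproducibility

`run_pipeline(default_config(seed))` executes the full workflow — align,
PCA, size and integration, per-syndrome modularity (4 syndromes x 4
hypotheses), allometry, classification, discrete ancestral reconstruction,
univariate model selection for PC1–PC5, centroid size and integration, and
the high-dimensional fit with ancestral shapes — writing CSV tables and a
JSON report in which every stage's seed and parameters are recorded.  The
run is byte-reproducible given the configuration; all stage seeds derive
from the single global seed.  The runner is single-shot (no content-hash
caching of intermediate stages): at the problem sizes involved a complete
rerun costs about a minute, which we judged cheaper than cache
invalidation.

Default problem sizes used by the test-suite and the acceptance script
(10^4–10^5 random partitions, 999 permutations, 500 trees, 1000 stochastic
maps, 20-replicate recovery experiments) were fixed as the package's
standard validation design; the partition count is a configuration knob
that scales to the 10^8 regime used in large studies since the null stream
costs one small matrix product per partition.

# Known limitations

- The GIC's covariance edf is a shrinkage interpolation, not the exact
  bias term of the originally published criterion; it is validated by model
  recovery, and absolute GIC values should not be compared across software.
- The univariate OU fits use ML (as the field's standard tools do), so
  pull estimates at n = 19 carry the usual small-sample upward bias;
  model selection is protected by AICc and the Hessian exclusion rule, but
  parameter values should be read with that bias in mind.
- Sliding semilandmarks, missing-landmark estimation and measurement-error
  variance terms are out of scope.
- The Mk machinery is equal-rates only; all-rates-different variants were
  deliberately excluded.
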