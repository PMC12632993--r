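---
title: "Lossy compression models of mnemonic discrimination: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Lossy compression models of mnemonic discrimination: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rdmem)
```

# The scientific question

In the Mnemonic Similarity Task a participant studies everyday object
images and must later call an exact repeat "old", a similar *lure*
"similar", and a novel foil "new". Correctly rejecting lures is the
canonical behavioral index of pattern separation. The classical account
holds that separation is achieved by *expanding* neural representations
until similar inputs become orthogonal. The account this package
implements is the opposite: separation is easier when the shared,
redundant content of a target–lure pair can be *discarded* — lossy
compression. Rate-distortion theory makes that intuition quantitative:
an optimal code transmits a source at the minimal information rate
$R(D)$ compatible with an expected distortion budget $D$, and the cost
function $d(x_1, x_2)$ of that code says how expensive it is to confuse
one item with another. The package estimates that cost structure from
representational geometry, measures the analogous trade-off in
variational autoencoders, scores the behavior it should predict, and
computes the neural statistics that lossy compression implies.

# The lossiness estimator

## Model

For a target embedding $x_t$ and lure embedding $x_l$ (any feature
space in which cosine distance is meaningful), retrieval is modeled as
traversal of the latent segment between them: `interpolate_path()`
places $k$ evenly spaced interior points (default $k = 10$, giving 12
path points) with the endpoints included exactly. The path points are
treated as the symbols of a perceptual identification channel:
`confusion_from_path()` converts pairwise cosine distances to
similarities ($1 - \text{distance}$, floored at zero), divides by the
global maximum, row-normalizes into identification probabilities, and
draws a fixed budget of identifications per input row (default 250,
multinomially), yielding a confusion count matrix.

`fit_cost_matrix()` then infers the cost matrix of a rate-distortion
optimal channel. The channel family is exponential,
$$q(j \mid i) \propto m_j \, e^{-s\, d_{ij}},$$
the form taken by the optimal channel at trade-off $s$
(`optimal_channel()` computes that optimum by the Blahut fixed point,
with the output marginal $m$ self-consistent,
$m_j = \sum_i p_i\, q(j \mid i)$). Fitting maximizes the multinomial
log-likelihood of the observed counts minus a symmetry prior
$\lambda_{\text{sym}} \sum_{ij} (d_{ij} - d_{ji})^2$
(default $\lambda_{\text{sym}} = 1$), with the diagonal constrained to
zero. The scalar *lossiness* is the mean off-diagonal fitted cost.

## Identifiability and the role of $s$

The channel depends on $(s, d)$ only through the product $s \cdot d$,
so the two are not separately identified; worse, the symmetry prior
alone would favor inflating $s$ and shrinking $d$ without changing the
likelihood. The package therefore fixes $s = 1$ during fitting and lets
the scale of $d$ carry the trade-off. With the diagonal pinned at zero
the costs are then identified, and lossiness is well defined.

## Optimization

A literal alternation — iterate the Blahut marginal to its fixed point
at the current costs, then update the costs — fails in an instructive
way: when the observed confusion structure is weak (nearly uniform
counts, as for very similar pairs), the rate-distortion optimal channel
at any small cost scale is the *zero-rate* solution whose output
marginal collapses onto a single symbol. The likelihood there is
abysmal and flat, and the fit never escapes. The implementation
therefore treats self-consistency of the marginal as an aspiration
rather than a constraint: each outer iteration proposes the Blahut
marginal update $m \leftarrow \sum_i p_i q(\cdot \mid i)$ but accepts
it (after up to six halvings toward the current marginal) only if the
penalized likelihood does not fall, then takes projected gradient
ascent steps over the off-diagonal costs at fixed marginal (the
gradient is analytic in this family). When the data are informative the
accepted updates converge to the genuinely self-consistent channel —
the planted-cost recovery test confirms exact ordering recovery — and
the penalized log-likelihood is non-decreasing across outer iterations
by construction. The outer budget is 100 iterations with early exit
after an eight-iteration stall; the initialization takes
$d \propto 1 - \text{similarity}$ with the overall scale chosen on a
doubling grid by likelihood, and 10 restarts jitter that start
multiplicatively, keeping the best final likelihood.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `k` | 10 | interior interpolants; 12 channel symbols total |
| `n_samples` | 250 | identifications drawn per input row |
| `lambda_sym` | 1 | weight of the squared asymmetry prior |
| `n_restarts` | 10 | jittered initializations per fit |
| `n_iter` | 100 | outer iteration budget per restart |
| `include_diagonal` | FALSE | whether the structural zeros enter the lossiness mean |

Twelve symbols keep the channel non-trivial while a single pair fit
stays around a second; the 250-per-row budget reads the sampling step
as one multinomial draw per input representation, which gives every row
an equal evidence budget (the alternative reading — 250 draws in total
— only rescales the evidence). Excluding the structurally zero diagonal
from the lossiness mean avoids diluting the summary by a constant
$(n-1)/n$ factor; a config switch restores the inclusive mean.
`set_lossiness()` applies one shared seed across pairs (common random
numbers), so cross-pair lossiness differences are not contaminated by
independent sampling noise.

# Variational rate-distortion curves

A β-VAE trained with loss
$\mathrm{BCE}(x, \hat{x}) + \beta \, \mathrm{KL}(q_\phi(z \mid x) \,\|\, N(0, I))$
traces a rate-distortion trade-off as $\beta$ varies: the KL term (in
nats per image, on a held-out split) is read as the rate and the binary
cross-entropy reconstruction error as the distortion. The networks here
are deliberately compact fully connected encoders/decoders (GELU hidden
layer, Gaussian bottleneck, sigmoid output) sized for small images —
scale is a configuration concern (`encoder_spec()`), not a code path —
and are trained by a hand-rolled Adam with manual backpropagation, so
training is exactly reproducible under a seed on one thread. An
optional L1 penalty on latent magnitudes gives the sparse variant. A
sweep (`estimate_rd_curve()`) uses a logarithmic β grid, because rates
span orders of magnitude, trains each (β, seed) pair, and keeps the
seed with the lowest held-out loss summed over the sweep; the held-out
fraction is 20% by random split under the training seed. The per-image
*variational lossiness* is the mean reconstruction error across the
whole β grid; `normalized_rate()` is the OLS slope of
$\log_{10} R$ on $D$. The deterministic autoencoder
(`train_autoencoder()`) uses mean-squared error and subtracts
per-channel dataset means from its inputs (normalization by a single
global scalar is the documented alternative; per-channel was chosen as
the more standard convention and the difference is a per-channel
intercept).

# Behavioral scoring

Probabilities condition on responding: missing responses are excluded
from denominators rather than counted as errors, and a condition with
no responded trials yields `NA`, never a silent zero. The QC cascade
runs trial filters first (responses faster than 0.3 s or slower than
3 s are dropped; the 3 s ceiling is exclusive, so a response at exactly
3.0 s survives), then participant filters on the post-trial-QC data:
more than 20% missing responses, LDI below 0, or recognition below 0.5
(both minima inclusive). For longitudinal tables the performance
thresholds are judged on the immediate session only, and exclusion
removes the participant from all sessions. The 20% missing rule counts
true non-responses by default; a config switch additionally counts
trial-QC removals, since the two readings cannot be distinguished from
the published description. Lure-bin labels are inputs (in the real task
they come from an independent normative sample); `bin_and_aggregate()`
joins per-item lossiness to the per-participant, per-bin indices to
build the modeling table.

# Neural signatures

Trial-wise evoked series are reconstructed as amplitude × HRF kernel at
each trial onset (`reconstruct_timeseries()`); the amplitudes and
kernel are consumed as inputs (they come from trial-wise GLM tooling in
real data). Dimensionality is the participation ratio
$(\sum_i \lambda_i)^2 / \sum_i \lambda_i^2$ over eigenvalues of the
voxel covariance (time-point observations, voxel-mean centering,
$1/(T-1)$ divisor) — scale- and rotation-invariant, between 1 and the
voxel count. ΔDimensionality is the correct-minus-incorrect difference
on lure trials; negative values mean dimensionality reduction with
correct discrimination. Mutual information uses a fixed-bin plug-in
estimator in nats (default 16 equal-width bins per variable spanning
each variable's observed range); target and lure voxel time courses are
concatenated in onset order, flattened voxel-major, truncated to the
common length so samples pair one-to-one, and split by outcome. Because
both metrics scale with region size, `region_signatures()` resamples a
fixed budget of voxels (default 100, without replacement when the
region is large enough) over a default 100 iterations and averages.
The plug-in MI estimator has the usual positive bias of roughly
$(B_x - 1)(B_y - 1) / (2n)$ nats; at the default bin count this stays
near 0.01 nats for $n = 10^4$, which the null-level test bounds at
0.02.

# Statistical layer

The bin-level mixed model is
`ldi ~ lossiness (+ age) + (1 | participant)`, fit by REML with
Satterthwaite p-values; it is applied to the per-bin aggregates because
the indices themselves are only defined across trials within a bin. A
singular random-effects fit is flagged and accompanied by a
fixed-effects least-squares fit reported separately. The GAM is
`ldi ~ s(lossiness, k = 4) + s(lossiness, by = age, k = 4)` with REML
smoothing selection: the main smooth captures the (possibly nonlinear)
lossiness effect and the continuous-by-age varying-coefficient smooth
its age modulation; with a purely linear planted relation the main
smooth's effective degrees of freedom shrink to about one and the age
term to zero. The bootstrap contrast resamples participants with
replacement (default 10,000 iterations), reports the percentile 95%
interval of the participant-mean difference between a reference region
and the mean of the others, and a two-sided percentile p-value (the
p-value convention is a package choice; one-sided or BCa variants would
be easy substitutions). Spearman correlations use average ranks and the
large-sample $t$ approximation for p.

# What the synthetic generators do and do not emulate

The generators plant exactly the quantities the estimators claim to
recover: angular separation of embedding pairs (cosine planted to
machine precision), generative factors of shape images, the published
design counts (128 study / 192 test trials; six blocks of 107 stimuli
— 32 first presentations, 16 repeats, 16 lures, 43 foils per block —
with geometric lags of configurable mean, default 19 trials, and every
repeat or lure scheduled after its first presentation), response
policies whose lure-correct probability is monotone in a planted
discriminability, and voxel covariance spectra whose participation
ratio equals a planted effective rank (a block of unit eigenvalues plus
one root-solved fractional eigenvalue). The response simulator is a
three-alternative mixture policy — a memory route with probability
equal to the item's discriminability plus a bias-vector guessing route
— because a recoverable link from planted lossiness to behavioral
indices is what the downstream models need; it makes no claim to
model RT dynamics or response confidence. The proportions of
repeat/lure/foil among the 192 test trials default to equal thirds as a
neutral choice, exposed as parameters. Voxel noise is Gaussian with a
planted covariance, the simplest model consistent with the
participation-ratio and mutual-information definitions; scanner
artifacts (drift, motion, physiology) and photograph statistics are
deliberately out of scope. Passing tests on these data therefore
demonstrate estimator correctness and recoverability, not robustness to
real-data nuisance structure.

# Numerical choices and degenerate inputs

* Blahut iterations run to a $10^{-12}$ marginal tolerance (public
  `optimal_channel`, which errors on non-convergence) and $10^{-9}$
  with a 500-iteration cap inside the fitting loop, warm-started from
  the previous marginal.
* Channel probabilities are floored at $10^{-300}$ inside log terms;
  zero counts contribute zero to the likelihood.
* Cosine similarities are clamped to $[-1, 1]$ before distances; a
  zero-norm representation raises an error rather than propagating NaN.
* Negative similarities (obtuse path angles) are floored at zero before
  row normalization so identification probabilities stay valid.
* Eigenvalues below zero by numerical error (within $-10^{-10}$
  relative) are clipped; genuinely negative spectra raise an error.
* A constant series occupies one bin and yields MI 0 with a warning; a
  rate-distortion curve point with $R \le 0$ is dropped with a warning
  before the semi-log fit.
* VAE log-variances are clamped to $[-10, 10]$; a non-finite training
  loss raises a divergence error, and a curve sweep fails only if every
  seed diverges.

# Problem sizes

The shipped tests and the reproduction script run at desk scale as a
deliberate design point: 16×16 shape images with latent width 16 and a
64-unit hidden layer (tens of epochs), 12-symbol channels, regions of
120–150 voxels, 100-voxel × 100-iteration subsampling, $10^4$ simulated
participants for chance-level checks, 200 mixed-model and 100 GAM
recovery replicates. The published-scale configuration (32×32 images,
latent 256/512, 200–250 epochs, batch 32/128, Adam at $10^{-3}$, a
22-point β grid from $10^{-6}$ to 10 over 5 seeds) is expressible
through the same `encoder_spec()` and sweep interfaces.

# Known limitations

* Lossiness inherits the cosine-geometry assumption of the retrieval
  path; it is a process model over a psychological space, not a
  geometry-free quantity.
* The cost scale is set by the $s = 1$ convention; absolute lossiness
  values are comparable within a configuration, not across different
  $k$, sampling budgets, or priors.
* The β-averaged variational lossiness averages over the entire β grid;
  whether a subset of the sweep would be preferable is untested here.
* The plug-in MI estimator is biased upward at small samples; adaptive
  discretization is out of scope.
* Whether MI should be computed on concatenated raw series (as here) or
  on trial-averaged patterns is a genuine degree of freedom; the
  concatenation convention, and the onset-order pairing it implies, are
  documented choices.
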