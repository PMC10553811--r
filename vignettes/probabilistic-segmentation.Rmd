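---
title: "Reconstructing probabilistic segmentation maps from same/different judgments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing probabilistic segmentation maps from same/different judgments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(probseg)
```

## The measurement problem

Classical psychophysics measures perceptual grouping with same/different
judgments on a handful of stimulus configurations, while segmentation
databases for computer vision rely on manual contour tracing, which
confounds perception with motor planning and offers no handle on the
variability of a single observer. `probseg` implements a protocol that
bridges the two: an image is covered by an $N \times N$ grid of cue
locations ($N \ge 3$), and on each trial the observer reports whether two
cued locations belong to the same perceptual segment. From many such
binary reports the package reconstructs *probabilistic segmentation
maps*: for every grid element $i$ a vector
$p_i = (p_i[1], \dots, p_i[K])$ on the $K$-simplex giving the probability
that the element belongs to each of $K$ segments. The hard segmentation
map is the per-element argmax, and the per-element Shannon entropy of
$p_i$ quantifies the measured perceptual uncertainty.

## Model and likelihood

Responses $r^{(n)}_{ij} \in \{0, 1\}$ ("same" = 1) collected over $N_b$
blocks are modelled as independent Bernoulli draws with success
probability $p_{ij}$. Assuming segment assignments are conditionally
independent across pixels given the maps, the probability that two
locations fall in the same segment is the dot product

$$p_{ij} = p_i \cdot p_j = \sum_{k=1}^K p_i[k]\, p_j[k].$$

Two objectives are supported, both exposed as plain functions and both
usable by the solver:

* **BCE** (`bce_loss`): the Bernoulli negative log-likelihood,
  $\sum_n \sum_{(i,j)} -r \log p_{ij} - (1-r)\log(1-p_{ij})$.
* **SE** (`se_loss`): the squared error to the empirical same-proportions
  $k_{ij}$, $\sum_{(i,j)} (k_{ij} - p_i \cdot p_j)^2$ — ordinary
  non-linear least squares on the sufficient statistics.

When, for every tested pixel, the family of partner probability vectors
is linearly independent, the two minimizers coincide. The package treats
this as an empirical property rather than re-deriving it: the
`loss_equivalence` study fits both objectives on the same simulated data
and compares final BCE, SE and reconstruction error with bootstrap
intervals.

The SE loss is the default, as it depends on the data only through the
per-pair proportions and behaves like classical least-squares regression.

## Choosing the tested pairs

The maps have $(K-1)N^2$ free parameters, so at least
$(K-1)N^2$ pairs must be tested (`minimal_trials`). `schedule_pairs`
produces a pseudo-random design of (by default) $K N^2$ pairs — one
spare equation per element, which helps preserve the linear-independence
condition — with three guarantees: every element is tested at least
once; no element appears more than $\lceil 2 n_t / N^2 \rceil + 1$ times
(load balancing); and partners are preferentially drawn at Chebyshev
distance at least $N/4$ grid units, since nearby pixels are a priori
more likely to share a segment and are therefore less informative.
`partner_span_fraction` reports, for a known ground-truth segmentation,
the fraction of pixels whose partners span all $K$ segments — the ideal
design tests each pixel against one same-segment partner and one in each
other segment. A pseudo-random minimal design can leave a few cells
data-ambiguous under a deterministic truth (all partners in one foreign
segment); the spatial prior below usually, but not provably, resolves
them.

## Spatial regularization

Nearby pixels tend to belong to the same segment. The package encodes
this Gestalt prior as a quadratic penalty on the deviation of each
probability value from its local kernel average,

$$\lambda \sum_i \sum_k \left(p_i[k] - (G * p)_i[k]\right)^2,$$

with replicate padding at the image edges. The default kernel
(`"laplacian4"`) averages the four neighbours with weight $1/4$ each and
has a zero centre, so $p - G * p$ is a discrete Laplacian residual; an
8-neighbour variant, a $3\times3$ Gaussian, and arbitrary odd-sized
kernels are accepted. The convolution is materialized as a sparse
operator, which gives the exact adjoint for the penalty gradient. The
kernel coefficients are a package choice: any local averaging kernel
yields a Laplacian-type residual, and nothing in the method depends on
the exact weights.

Following the validation studies, $\lambda = 10$ is the default for
simulation work; per-participant uncertainty analyses should use
$\lambda = 0$ to avoid biasing the entropy maps toward smoothness, and
parametric fits default to $\lambda = 0$ because the model family itself
regularizes.

## Solver

The non-parametric fit runs exponentiated gradient descent: from
independent uniform draws on the simplex (symmetric Dirichlet,
$\alpha = 1$), iterate

$$p \leftarrow p \odot \exp(-\eta \nabla \ell(p)), \qquad
  p \leftarrow p / \textstyle\sum_k p[k],$$

stopping when the objective changes by at most $\varepsilon$. The
multiplicative update preserves positivity and, after renormalization,
the simplex constraint at every iterate, so no projection is needed.
Numerical safeguards: the gradient is centred per row at its minimum
(per-row constants cancel after renormalization, and all multipliers
stay $\le 1$, so `exp` cannot overflow), iterates are floored at
$10^{-15}$ to stay in the simplex interior, and pair probabilities are
clipped at $\delta = 10^{-12}$ inside the BCE logs.

**Objective normalization.** The solver minimizes the data term averaged
over observations (pairs for SE; pair-block trials for BCE) plus
$\lambda$ times the penalty averaged over pixel-channel entries. This
makes $\lambda$ a scale-free trade-off between per-observation error and
per-pixel smoothness: the raw BCE sum grows linearly with $N_b$ and
would otherwise dilute the penalty $N_b$-fold, breaking the equivalence
of regularized BCE and SE fits. For SE with the default $K N^2$ design
the normalized and raw-sum minimizers coincide exactly, because the two
normalizing counts are equal. The exposed loss functions remain raw
sums.

**Defaults.** Learning rate 15 (on the normalized scale),
$\varepsilon = 10^{-8}$, 10&nbsp;000 iterations. The rate was chosen for
stability across $\lambda \in \{0, 10\}$: substantially larger steps
oscillate when the penalty gradient is strong. The loss trace is
reported so non-convergence is visible (`converged` flag).

Solutions are invariant to channel permutation, so fits are compared to
ground truth after `align_labels`, an exhaustive search over the $K!$
permutations minimizing the mean absolute error (MAE) — exact and fast
for the $K \le 8$ regime the protocol targets. Argmax ties in
`to_segmentation` break toward the smallest label index, for
reproducibility.

## Parametric maps over image features

Instead of treating each $p_i$ as free, the maps can be parametrized by
image features $x_i \in \mathbb{R}^D$ through a multinomial logistic
model

$$p_i[k](\omega, \beta) =
  \frac{\exp(\omega_k \cdot x_i + \beta_k)}
       {\sum_l \exp(\omega_l \cdot x_i + \beta_l)},$$

fitted by minimizing the same SE objective with
$p_{ij}(\theta) = p_i(\theta) \cdot p_j(\theta)$, using L-BFGS-B with
analytic gradients and optional multi-start. Only differences
$\omega_k - \omega_l$, $\beta_k - \beta_l$ are identifiable (softmax
shift invariance). For oriented-texture experiments a variance
reparametrization is provided: $\beta_k = 0$,
$\omega_k = -1/\sigma_k^2$ componentwise, with positivity enforced
through $\sigma^2 = e^s$; $\sigma_k^2[d]$ is then interpretable as the
average energy of feature band $d$ under segment $k$, and for $K = 2$
the identifiable quantity is the differential variance
$(\sigma_1^2 - \sigma_2^2)/(\sigma_1^2 \sigma_2^2)$ per band. Features
are deliberately not standardized by default, to preserve this energy
interpretation.

Two feature extractors are included: per-cell mean RGB ($D = 3$) and
oriented wavelet energy. The latter applies a log-Gabor filter bank —
36 orientation bands at 5° spacing, 4 octave-spaced scales by default —
squares the complex responses, and averages energies over scales and
over the pixels of each grid cell. The wavelet family, number of scales
and normalization are package choices; any bank measuring average
oriented energy across scales fits the method, and the bank is
configurable.

## Synthetic data

`sample_probmaps` generates ground-truth maps at a controlled
uncertainty: a Voronoi partition of the grid from $K$ farthest-point
seeds (compact regions of comparable size — purely random seeds can
produce degenerate slivers that no reconstruction handles gracefully),
one-hot indicators blurred by a Gaussian of width
`level * spatial_scale` grid units, then mixed toward the uniform vector
with weight `level`. Level 0 gives deterministic maps; mean entropy
rises monotonically with the level. The simulation studies define
"moderate uncertainty" as level 0.4 with a 1.5-cell spatial scale —
boundary bands a couple of cells wide with modest global softening —
fixed once as the study condition.

`simulate_responses` draws $N_b$ Bernoulli responses per pair with
success probability $p_i \cdot p_j$, reusing the same pair set across
blocks. `synthesize_composite_texture` builds two-region oriented
textures by filtering one white-noise image with two oriented log-radial
bandpass filters and compositing along a random smooth boundary
(`sample_boundary`, a random cosine series with an area-fraction
constraint); narrow versus broad orientation bandwidths give
low- versus high-uncertainty stimuli. The boundary transition is hard
(1 pixel) by default, with an optional cosine cross-fade.

What the generator does *not* emulate: natural-image statistics,
observer lapses or response biases, learning across blocks, and any
spatial correlation in the response noise. Passing the simulation
studies therefore validates the estimator under the stated generative
model, not the behaviour of human observers.

## Validation studies and problem sizes

`run_study` packages five studies, each bootstrapped over pair-design
resamples (50 by default, 1000 with `full_scale = TRUE`), on a
$10 \times 10$ grid with $K = 3$ and moderate uncertainty unless noted:

* `loss_equivalence` — BCE- versus SE-optimized fits at $N_b = 10$,
  $\lambda \in \{0, 10\}$, both run to tight convergence so optimizer
  error cannot masquerade as loss disagreement.
* `blocks_sweep` — MAE versus $N_b \in \{1, 2, 4, \dots, 128\}$ at
  $\lambda \in \{0, 10\}$, sharing simulations across $N_b$ within a
  resample for paired comparisons; reports the mean MAE ratio.
* `uncertainty_sweep` — MAE versus uncertainty level
  $\{0, .25, .5, .75, 1\}$ at $N_b = 10$; reports per-level ratios,
  excluding the deterministic level where the methods coincide.
* `unknown_K` — truth with $K = 5$ on a $12 \times 12$ grid, fits at
  $K = 3..7$ with $\lambda = 10$ and a tighter stopping rule (channel
  suppression requires near-convergence); reports non-empty channel
  counts.
* `resolution_sweep` — MAE versus $N \in \{6, 9, 12, 15\}$.

These desk-scale sizes keep each study in the seconds-to-minutes range
on one CPU while preserving the qualitative regime; the sweep studies
use $\varepsilon = 3\times10^{-10}$ and a 3000-iteration cap.

## Numerical and design choices

* **Empty-channel rule.** When fitting with more channels than the true
  segment count, regularized fits drive superfluous channels to
  near-zero mass. `count_nonempty_segments` calls a channel non-empty
  when its maximum exceeds 0.2: in the studies, superfluous channels
  retain only boundary-blur residue (maxima around 0.1) while genuine
  channels peak above 0.7, so the threshold sits in the gap between the
  two populations. The threshold is exposed for other regimes (e.g.
  0.99 to count strictly deterministic channels).
* **Penalty amplitude is superadditive in channels.** Because the
  penalty is quadratic, splitting a segment across two duplicate
  channels halves its smoothness cost; for very small segments this can
  genuinely beat concentration. Balanced region generation avoids the
  pathology in simulations; with real data, an implausible duplicated
  channel at roughly half amplitude is the signature to look for.
* **Entropy.** Natural-log Shannon entropy with $0 \log 0 = 0$; the
  summary reports the mean over elements with its standard error.
* **Coordinates.** Grid cells are addressed (row, col), 1-based, row
  major; cell centres map to pixel $(\text{idx} - 0.5) \cdot
  \text{image\_size}/N$. All CSV interfaces use 1-based coordinates.
* **Uncovered cells.** Fits proceed when some cells are never tested,
  leaving them at their initialization and flagging them, so partial
  datasets remain analyzable.

## A minimal session

```{r example, eval = FALSE}
g <- grid_spec(10)
truth <- sample_probmaps(g, K = 3, uncertainty_profile(0.4, 1.5), seed = 1)
pairs <- schedule_pairs(g, K = 3, seed = 2)
resp <- simulate_responses(truth, pairs, n_blocks = 10, seed = 3)

fit <- fit_nonparametric(resp, K = 3, reg = reg_config(lambda = 10))
mean_absolute_error(fit$maps, truth)
entropy_map(fit$maps)$mean
to_segmentation(fit$maps)
```

## Limitations

* Bernoulli (two-alternative) responses only; no multinomial extension.
* The quadratic local-average penalty is the only regularizer; no
  total-variation or graph priors.
* No adaptive pair selection: designs are fixed before data collection.
* Exhaustive label alignment limits comparisons to $K \le 8$.
* The texture generator and the feature bank share the oriented-energy
  vocabulary but not code paths, so feature-space conclusions about
  synthetic textures inherit the bank's discretization (5° bands).
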