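# probseg

Reconstruction of **probabilistic visual segmentation maps** from binary
same/different judgments on pairs of image locations.

## The problem

How do people segment an image, and how certain are they about it?
Contour-tracing databases confound perception with motor execution and
say nothing about the variability of a single observer. `probseg`
implements a psychophysical protocol that avoids both problems: an image
is covered by an N × N grid of cue locations, and on each trial the
observer reports whether two cued locations belong to the same
perceptual segment. From N_b blocks of such trials the package
reconstructs, for every grid element *i*, a probability vector
*p<sub>i</sub>* over K segments (a point on the K-simplex). The argmax
of *p<sub>i</sub>* gives the hard segmentation map; the Shannon entropy
of *p<sub>i</sub>* gives a per-location map of perceptual uncertainty.

## The model

Responses are Bernoulli with success probability equal to the dot
product of the simplex vectors,

> p<sub>ij</sub> = p<sub>i</sub> · p<sub>j</sub> = Σ<sub>k</sub> p<sub>i</sub>[k] p<sub>j</sub>[k],

which follows from conditionally independent segment assignments. The
maps are estimated by minimizing either the Bernoulli negative
log-likelihood (BCE) or the squared error to the empirical
same-proportions k<sub>ij</sub> (SE; the default — the two minimizers
coincide under a linear-independence condition on the tested pairs),
optionally plus a spatial smoothness penalty
λ Σ<sub>i,k</sub> (p<sub>i</sub>[k] − (G ∗ p)<sub>i</sub>[k])² with a
Laplacian-style local kernel G. Optimization uses exponentiated
gradient descent — p ← p ⊙ exp(−η∇ℓ), renormalized — which keeps every
iterate on the simplex; the inner loop is compiled (RcppArmadillo).
A parametric variant expresses the maps as a multinomial logistic
function of image features (mean RGB, or 36-band oriented wavelet
energy), fitted by L-BFGS-B, including the variance reparametrization
ω<sub>k</sub> = −1/σ<sub>k</sub>² used for texture experiments.

The package also provides the experimental design tools (minimal trial
count (K−1)N², scattered load-balanced pair scheduling, response CSV
I/O), generators for synthetic ground-truth maps at controlled
uncertainty and for composite oriented-texture stimuli, and canned
simulation studies with bootstrap confidence intervals.

## Worked example

Simulate an observer with moderate perceptual uncertainty on a 10 × 10
grid with K = 3 segments, collect 10 blocks of the default K·N² = 300
pairs, and reconstruct:

```r
library(probseg)

g     <- grid_spec(10)
truth <- sample_probmaps(g, K = 3, uncertainty_profile(0.4, 1.5), seed = 1)
pairs <- schedule_pairs(g, K = 3, seed = 2)
resp  <- simulate_responses(truth, pairs, n_blocks = 10, seed = 3)
resp
#> <response_dataset> 3000 trials, 10 block(s), 10 x 10 grid, mean(same) = 0.327

fit <- fit_nonparametric(resp, K = 3, reg = reg_config(lambda = 10))
fit
#> <fit_result> K = 3, 1502 iteration(s), converged, final loss 0.0217379

mean_absolute_error(fit$maps, truth)           # label-aligned L1, per pixel
#> 0.1698
mean_absolute_error(fit_nonparametric(resp, K = 3,
                    reg = reg_config(lambda = 0))$maps, truth)
#> 0.7037
entropy_map(fit$maps)$mean                     # measured uncertainty (nats)
#> 0.8066
```

The regularized reconstruction is several times closer to the ground
truth than the unregularized one (MAE 0.17 versus 0.70 here; the
theoretical maximum is 2), which is the core practical finding the
simulation studies quantify. `to_segmentation(fit$maps)` returns the
hard map, `write_probmaps()` serializes the channels as CSV/PNG, and
`run_pipeline()` wires the whole read–validate–fit–write chain behind
one call. `run_study("blocks_sweep")`, `"uncertainty_sweep"`,
`"loss_equivalence"`, `"unknown_K"` and `"resolution_sweep"` reproduce
the validation experiments; see the methods vignette
(`vignettes/probabilistic-segmentation.Rmd`) for the model, the solver
and every tunable choice.

A thin command-line front end is installed at `inst/cli/probseg.R`
(subcommands `schedule`, `simulate`, `fit`, `features`, `study`).

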