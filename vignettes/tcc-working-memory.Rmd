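---
title: "Modelling continuous-report working memory with similarity-based signal detection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling continuous-report working memory with similarity-based signal detection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(tccwm)
library(dplyr)
```

## The model

In a continuous-report task, a participant views a stimulus, retains it
over a delay, and then picks the best match from a *response wheel* of
360 evenly spaced alternatives — hues on a colour circle, oriented lines
on a half-turn circle, or naturalistic images morphing smoothly around a
circle drawn in a generative model's latent space. The target
confusability competition (TCC) account treats the response as a
signal-detection race among all 360 options. Everything the model knows
about the stimulus domain enters through one vector: the similarity
$s_j \in [-1, 1]$ between the remembered target and option $j$, with
$s_j = 1$ for an exact match. The response law is

$$ r = \arg\max_j \; (d' s_j + \varepsilon_j), \qquad
   \varepsilon_j \overset{iid}{\sim} \mathcal{N}(0, 1), $$

with a single free parameter $d'$, the memory strength. Scaling the
noise SD by a constant and $d'$ by the same constant leaves the law
unchanged, so unit variance is a convention. The probability that
option $j$ wins has the closed form

$$ P(r = j) = \int \phi(x - d's_j) \prod_{k \neq j} \Phi(x - d's_k)\,dx, $$

which `choice_probabilities()` evaluates by composite Simpson quadrature
on $[\min_j d's_j - 8,\ \max_j d's_j + 8]$ (Gaussian tails beyond 8 SD
are below machine-relevant mass), doubling the grid from 513 points
until the per-option change falls under `tol` and refusing to return
unless total mass is within $10^{-6}$ of 1. `simulate_responses()` draws
from the same law by brute force (the inner loop is compiled; ties,
possible only in floating point, break to the lowest index, and R's RNG
stream is used so a seed fixes every draw).

Similarity vectors can come from anywhere: `cosine_profile()` computes
them from a `feature_matrix` — raw pixels (`extract_pixels()`, the
length-$3 \times 256 \times 256$ baseline), channel means
(`extract_rgb_means()`), a plug-in encoder registered with
`register_feature_backend()`, or the synthetic latent-space wheels
described below. Because only cosine similarities reach the model,
feature scale is irrelevant; what matters is representational geometry.

## Fitting d'

`fit_dprime()` follows the estimation strategy the model was introduced
with: a grid search (default 0 to 10 in steps of 0.1 — from uniform
guessing to near-deterministic choice on a 360-option wheel) over
likelihoods approximated by a histogram of simulated responses, 8000 per
trial by default. Observed responses snap to the nearest wheel option
(rounding half up); trials that share a profile are pooled into response
counts, so cost scales with distinct profiles rather than trials. The
histogram is smoothed with a Jeffreys-style pseudocount
($\alpha = 0.5$ by default) so the log-likelihood stays finite for
response options the simulation never hit. Each grid point uses an
independent, counter-derived simulation stream: reusing one stream
across grid points would correlate the surface and produce spurious
local structure.

`exact_fit_dprime()` evaluates the same surface from the analytic choice
probabilities and acts as the arbiter for the approximation. By default
it applies the *same* pseudocount transform to the exact probabilities,
$(n\,p_j + \alpha)/(n + \alpha K)$ — the exact expectation of the
smoothed histogram estimator. This choice is deliberate: the raw
analytic likelihood dives to $\log p \approx -70$ at high $d'$ where the
smoothed histogram is floored near $\log(\alpha/(n + \alpha K)) \approx
-9.7$, so comparing the raw surface to the histogram surface mostly
measures the smoothing floor, not the approximation. With matched
smoothing the two surfaces correlate above 0.999 on recovery fixtures;
`alpha = 0` gives the pure analytic surface when that is what is wanted.

Fit scopes mirror standard practice: one pooled $d'$ across conditions
(the default — reproducing set-size effects *without* per-condition
noise parameters is the point of running the model on rich feature
spaces), `per_setsize` for the classical alternative, and `setsize1`
because strong bias structure at set size 1 washes out when noisier
large-set trials dominate a pooled fit.

## The synthetic observers

Real deposits (scene wheels, colour, orientation) are downloads; the
package instead ships a generator whose output has the same shape and
the same qualitative phenomena, with known ground truth. An
`observer_spec()` is:

* a circular von Mises-shaped similarity kernel
  $k(\Delta) \propto \exp(\kappa(\cos(2\pi\Delta/P) - 1))$, linearly
  rescaled to span $[-1, 1]$ with $k(0) = 1$. Default
  $\kappa = 5$: a smooth kernel whose high-similarity neighbourhood
  covers a few tens of degrees, comparable to psychophysical similarity
  functions on hue and orientation wheels.
* a true memory strength (default $d' = 2$, mid-range performance:
  mean absolute error of a few degrees at set size 1).
* an optional sinusoidal bias warp $w(x) = x + a\sin(\theta x)$ applied
  to target and options alike ($\theta$ even so the warp closes around
  the wheel). The warp leaves the profile's peak exactly on the target
  — an exact match still has similarity 1 — but makes the profile
  asymmetric, so the *mean* response is repelled from the warp's zero
  crossings. With $\theta = 4$ on the orientation half-circle this
  reproduces cardinal repulsion: computing the exact expected signed
  error via `choice_probabilities()` and fitting
  $y = A\sin(\theta x + b)$ gives $\theta = 4$ and phase $0$ (in phase
  with the warp), with a frequency-8 harmonic left in the residual.
* per-set-size compression $c_n \in [0, 1)$:
  $s_j = (1 - c_n)k(\Delta) + c_n$ shrinks the similarity range toward
  1 as displays fill up, without moving the peak. Under fixed-variance
  noise a compressed profile is easier to corrupt, so error grows with
  set size — the representational mechanism behind set-size effects in
  sparse deep-network layers, where fuller displays activate more units
  and squeeze the cosine-similarity range across wheel options
  (`activation_sparsity()` and `similarity_range_by_setsize()` are the
  matching diagnostics). Defaults $c = (0, 0.3, 0.6, 0.8)$ for set
  sizes $(1, 2, 4, 8)$ produce a clearly graded error curve.

Scene wheels are emulated in `make_scene_wheels()`: five centres, each
with a random 2D plane in a latent space, crossed with five radii;
360 points on each circle pass through a per-centre random Fourier
feature expansion, so cosine similarity between options falls off like a
Gaussian kernel in chord distance. Defaults (unit lengthscale, radii
0.2–1.0, 512 features, latent dimension 8) were picked once so the
minimum within-wheel similarity spans roughly 0.92 down to 0.14 across
radii — a difficulty gradient comfortably wider than the
$\mathcal{O}(1/\sqrt{512})$ embedding noise. Larger radii give more
distinct alternatives, exactly the difficulty manipulation the design
emulates.

`generate_trials()` draws **one** response per simulated trial at the
observer's true $d'$ (the 8000-draw simulation belongs to fitting, not
data generation), with a counter-derived seed per trial so tables are
byte-identical across runs. `generate_color_trials()` produces set-size
3 displays in which every item is probed in turn — the input shape the
inter-item analysis requires. `display_spec()`, `render_display()` and
`build_probe_wheel()` rasterise the artificial displays (discs for hue,
oriented segments for orientation) and expand a display into its 360
response-wheel variants with the unprobed items left intact; display
geometry and durations are exposed as configuration without any claim of
fidelity to the source experiments, which do not specify them here.

What the generator does *not* emulate: participant heterogeneity and
lapses, sequential effects, swap errors to unprobed items, focal-colour
attraction (only sinusoidal warps are built in), and the
image-level statistics of real GAN wheels. Passing tests therefore
demonstrate that the pipeline's machinery is correct and internally
consistent — not that any particular feature space explains human data.

## The analysis battery

* `circular_error()` wraps signed error to $(-P/2, P/2]$; orientation
  lives on $P = 180$ so errors repeat every half turn.
* `bin_mean_abs_error()` averages absolute error in 12 half-open target
  bins per wheel (binning makes trial difficulty estimable when unique
  stimuli outnumber responses); `spearman_difficulty()` rank-correlates
  matched bins between two sources and is invariant to monotone
  transforms of either side.
* `noise_ceiling()` resamples trials with replacement within each
  condition, recomputes binned errors, and correlates each resample
  against the original; the 5th/95th percentiles form the ceiling band.
  One caveat is worth knowing: each resample shares most of its trials
  with the original, so the band is biased upward relative to the
  correlation attainable by a genuinely independent replicate — under
  zero signal the resample-vs-original correlation concentrates near
  $1/\sqrt{2}$, not 0, and even a perfect model of the generating
  process tends to land slightly *below* the band's lower edge. The
  band is an optimistic ceiling, not a confidence interval for model
  fit.
* `error_by_condition()` gives mean absolute error per radius or set
  size with 90% percentile bootstrap CIs over trials (participant-level
  resampling is a flag, `by`).
* `bias_curve()` and `fit_sine()` summarise response inhomogeneity:
  mean signed error per target bin, fit by
  $y = A\sin(\theta x + b)$ with $\theta \in \{2, 4, 6\}$. Because the
  model is linear in $(A\cos b, A\sin b)$ for fixed $\theta$, each
  candidate frequency is solved by exact least squares — no
  initialisation or iteration — and the lowest-SSE frequency wins, ties
  to the smaller $\theta$. Fits are canonicalised to $A \ge 0$ with
  phase in $(-180°, 180°]$; a negative-amplitude representation
  $(-A, b)$ is the same curve as $(A, b \pm 180°)$, so sign-flipped
  bias curves (attraction rather than repulsion) remain representable.
* `interitem_variance_analysis()` correlates, across set-size 3 colour
  displays, the circular variance of the three display hues with that
  of the three responded hues, keeping only displays whose three
  absolute errors all exceed 45° (strictly). Circular variance is
  $1 - \|\text{mean unit vector}\|$: 0 for identical hues, 1 for hues
  120° apart, $2/3$ for $(0°, 0°, 180°)$. Pearson by default, Spearman
  by flag; p-values are two-sided and uncorrected throughout.

## Numerical choices and degenerate inputs

Ties in the argmax break to the lowest index (deterministic, testable).
Responses map to options by rounding half up on the shared lattice.
Zero-norm feature vectors are an error naming the offending option, not
a silent NaN. Empty bins are kept as `NA` rows rather than dropped.
Histogram smoothing keeps every grid point finite; quadrature failure
(mass off by more than $10^{-6}$) is an error carrying diagnostics
rather than a wrong answer. Profile scores are validated into $[-1, 1]$
with a $10^{-9}$ tolerance for floating-point spill from cosine
computations, and a profile whose declared target option is not at
similarity 1 is rejected. The warp amplitude is validated against
$|a|\theta\pi/180 < 1$ so the warp stays monotone and well-defined on
the circle.

## Validation settings

The test suite validates every operation against independent oracles:
a pure-R argmax reference that reproduces the compiled simulation draw
for draw; quadrature checked against Monte-Carlo frequencies (20 random
profiles $\times\ d' \in \{0, 0.5, 2, 5\}$ at $10^5$ draws, with
per-option binomial z-scores assessed in their normal regime and total
variation below 0.01 at $10^6$ draws); parameter recovery at
$d' \in \{0.5, 1, 2, 4\}$ from 2000-trial tables fit on the full 0–10
grid with 8000 simulations per trial (median absolute error below
0.15); exact sine recovery to $10^{-6}$ on noiseless curves and phase
recovery within 10° from 36,000 warped-observer trials; and a 25-wheel
split self-consistency analysis over 300 bins against the bootstrap
noise ceiling (500 resamples). These sizes are the package's validation
settings; `scripts/acceptance.R` recomputes the same quantities from
scratch for any seed.

## Limitations

The package implements the response model and its evaluation battery,
not the feature spaces that made the model interesting: deep-network
encoders are a plug-in contract (`extract_features()` with a registered
backend), and no pretrained weights are bundled. The exact choice law is
$O(n_x \times K)$ per profile and grid point, so exact fitting over
dense grids with thousands of distinct profiles is slower than the
histogram route — which is precisely why the histogram approximation
exists. Pooled fitting assumes one $d'$ per dataset; per-participant
estimation is deliberately out of scope.
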