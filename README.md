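# tccwm

Similarity-based signal-detection modelling of visual working memory
(VWM) for continuous-report tasks.

In continuous report, a participant views a stimulus, holds it over a
delay, and selects the best match on a **response wheel** of 360 evenly
spaced alternatives — hues, oriented lines, or naturalistic images
morphing around a circle in a generative model's latent space. The
**target confusability competition (TCC)** model explains the resulting
error distributions with a single parameter. Given similarities
`s_j ∈ [−1, 1]` between the remembered target and each wheel option
(an exact match has `s = 1`), the response is

    r = argmax_j ( d′ · s_j + ε_j ),   ε_j ~ N(0, 1) i.i.d.

where `d′` is memory strength. The model runs on *any* feature space
that yields a similarity — raw pixels, channel means, or deep-encoder
activations via cosine similarity — which makes it a tool for asking
whether a representation's geometry predicts human memory errors:
set-size effects, cardinal repulsion in orientation, trial-by-trial
difficulty on naturalistic scene wheels.

The package is for computational cognitive scientists who want to
simulate this model, fit `d′` to trial tables by likelihood grid
search, and run the standard evaluation battery — with a fully
synthetic data generator (known ground truth) so every stage is
testable without downloading datasets or network weights.

## What's inside

- **Model core** — `cosine_profile()`, `simulate_responses()` (compiled
  inner loop, seed-reproducible), `choice_probabilities()` (exact
  analytic law by adaptive quadrature — the oracle the simulation is
  validated against), `response_histogram()`.
- **Fitting** — `fit_dprime()` (grid search over histogram-approximated
  likelihoods, 8000 simulations/trial by default),
  `exact_fit_dprime()` (analytic cross-check), with pooled,
  per-set-size, and set-size-1 scopes; broom-style `tidy()`, `glance()`,
  `autoplot()`.
- **Feature extraction** — pixel and RGB-mean baselines on
  256×256×3 images, a plug-in backend registry for external encoders,
  `activation_sparsity()`.
- **Synthetic data** — `observer_spec()` (von Mises similarity kernel,
  true `d′`, sinusoidal bias warp, per-set-size similarity
  compression), `generate_trials()`, `generate_color_trials()`,
  `make_scene_wheels()` (25 latent-space wheels: 5 centres × 5 radii),
  display rendering and probe-wheel construction.
- **Analyses** — signed circular errors, 12-bin difficulty profiles,
  Spearman difficulty correlations with bootstrap noise ceilings,
  per-condition error curves with 90% CIs, bias curves with constrained
  sine fits (`y = A sin(θx + b)`, θ ∈ {2, 4, 6}), the inter-item
  circular-variance statistic, similarity-range diagnostics.
- **Pipeline** — `read_trials()` / `write_trials()` (validated CSV with
  column mapping for foreign dialects), `tcc_config()` and
  `run_pipeline()` (synthesis → profiles → fit → analyses, outputs
  stamped with seed and config hash, byte-identical on re-run).

## Worked example

Simulate an orientation observer with memory strength `d′ = 2` whose
similarity profiles compress with set size, then recover `d′` and the
set-size effect:

```r
library(tccwm)

obs <- observer_spec(dprime = 2, kappa = 5, period = 180,
                     compression = c("1" = 0, "2" = 0.3, "4" = 0.6, "8" = 0.8))
trials <- generate_trials(obs, 2000, targets = c(0, 45, 90, 135), seed = 42)

fit <- fit_dprime(trials, attr(trials, "profiles"),
                  grid = seq(0, 4, by = 0.1), n_sims = 4000, seed = 1)
glance(fit)
#> # A tibble: 1 × 5
#>   scope best_dprime log_lik method    n_trials
#>   <chr>       <dbl>   <dbl> <chr>        <int>
#> 1 all           2.1  -8813. histogram     2000

error_by_condition(trials, n_boot = 500, period = 180, seed = 2)
#> # A tibble: 4 × 5
#>   condition     n mean_abs_error lower upper
#>       <dbl> <int>          <dbl> <dbl> <dbl>
#> 1         1   518           3.46  3.30  3.64
#> 2         2   514           4.68  4.35  5.02
#> 3         4   480          10.9   9.76 12.1
#> 4         8   488          25.8  23.8  27.5
```

The fitted `d′` (2.1) recovers the generating value within one grid
step even though one pooled parameter serves all four set sizes; the
set-size effect (mean absolute error 3.5° → 26° from one to eight
items) emerges purely from similarity-range compression under
fixed-variance noise, with no per-condition noise parameters. The
`lower`/`upper` columns are 90% bootstrap CIs over trials.

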