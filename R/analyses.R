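# The evaluation battery: binned trial-difficulty statistics with
# bootstrap noise ceilings, condition-wise error curves, response-bias
# curves with constrained sine fits, the inter-item circular-variance
# statistic, and similarity-range diagnostics.

check_bins <- function(n_bins, period) {
  assert_count(n_bins, "n_bins")
  if ((360 %% n_bins) != 0) {
    abort("`n_bins` must divide 360 so bins tile the wheel evenly.",
          class = "tccwm_config_error")
  }
  period / n_bins
}

bin_index <- function(target_deg, width) {
  as.integer(floor(target_deg / width)) + 1L
}

#' Mean absolute error per target bin
#'
#' Divides each wheel into `n_bins` evenly sized, half-open target bins
#' (`[0, w), [w, 2w), ...`) and averages absolute circular error over the
#' trials whose target falls in each bin. Binning is what makes
#' trial-difficulty rank correlations estimable when there are many
#' unique stimuli relative to responses.
#'
#' @param trials Trial table with `wheel`, `target_deg`, `response_deg`
#'   columns.
#' @param n_bins Number of bins per wheel (default 12); must divide 360.
#' @param period Task period in degrees.
#' @return A tibble with one row per (wheel, bin): `wheel`, `bin`,
#'   `bin_center`, `n`, `mean_abs_error`. Bins with no trials appear with
#'   `n = 0` and `NA` error so gaps are visible, not silently dropped.
#' @export
bin_mean_abs_error <- function(trials, n_bins = 12, period = 360) {
  width <- check_bins(n_bins, period)
  trials |>
    dplyr::mutate(
      bin = bin_index(.data$target_deg, width),
      abs_err = abs(circular_error(.data$response_deg, .data$target_deg,
                                   period))) |>
    dplyr::group_by(.data$wheel, .data$bin) |>
    dplyr::summarise(n = dplyr::n(),
                     mean_abs_error = mean(.data$abs_err),
                     .groups = "drop") |>
    tidyr::complete(.data$wheel, bin = seq_len(n_bins),
                    fill = list(n = 0L)) |>
    dplyr::mutate(bin_center = (.data$bin - 0.5) * width) |>
    dplyr::select("wheel", "bin", "bin_center", "n", "mean_abs_error")
}

#' Rank correlation between human and model binned difficulty
#'
#' Spearman correlation between matched per-bin mean absolute errors,
#' joined on (wheel, bin). Invariant to monotone transforms of either
#' side, which is why it is the right comparison across feature spaces
#' whose similarity scales differ. Restrict `human_bins`/`model_bins` to
#' one radius before calling for the within-radius scope.
#'
#' @param human_bins,model_bins Binned error tables from
#'   [bin_mean_abs_error()] (or any tables with `wheel`, `bin`,
#'   `mean_abs_error`).
#' @return A one-row tibble: `rho`, `p_value`, `n_bins`.
#' @export
spearman_difficulty <- function(human_bins, model_bins) {
  joined <- dplyr::inner_join(
    dplyr::select(human_bins, "wheel", "bin", human = "mean_abs_error"),
    dplyr::select(model_bins, "wheel", "bin", model = "mean_abs_error"),
    by = c("wheel", "bin")) |>
    dplyr::filter(is.finite(.data$human), is.finite(.data$model))
  if (nrow(joined) < 3) {
    abort("Fewer than 3 matched bins: cannot estimate a rank correlation.",
          class = "tccwm_data_error")
  }
  ct <- cor.test(joined$human, joined$model, method = "spearman",
                 exact = FALSE)
  tibble::tibble(rho = unname(ct$estimate), p_value = ct$p.value,
                 n_bins = nrow(joined))
}

#' Bootstrap noise ceiling for the binned rank correlation
#'
#' Resamples trials with replacement within each scope group (by default
#' each condition, i.e. each radius), recomputes the binned errors, and
#' correlates each resample against the original data. The 5th and 95th
#' percentiles of the resampled Spearman rho estimate the band any model
#' could reach given response variability.
#'
#' @param trials Trial table.
#' @param n_boot Number of bootstrap resamples (>= 100).
#' @param n_bins Bins per wheel.
#' @param period Task period in degrees.
#' @param by Column defining the resampling scope (default `"condition"`).
#' @param seed Integer seed.
#' @return A one-row tibble: `lower`, `upper` (5th / 95th percentiles),
#'   `n_boot`.
#' @export
noise_ceiling <- function(trials, n_boot = 1000, n_bins = 12, period = 360,
                          by = "condition", seed = 1) {
  if (n_boot < 100) {
    abort("`n_boot` must be at least 100.", class = "tccwm_config_error")
  }
  original <- bin_mean_abs_error(trials, n_bins, period)
  groups <- split(seq_len(nrow(trials)), trials[[by]])
  rhos <- with_seed(mix_seed(seed, 7), vapply(seq_len(n_boot), function(b) {
    idx <- unlist(lapply(groups, function(g) sample(g, length(g),
                                                    replace = TRUE)))
    res <- bin_mean_abs_error(trials[idx, , drop = FALSE], n_bins, period)
    spearman_difficulty(original, res)$rho
  }, numeric(1)))
  tibble::tibble(lower = unname(quantile(rhos, 0.05)),
                 upper = unname(quantile(rhos, 0.95)),
                 n_boot = n_boot)
}

#' Mean absolute error per condition with bootstrap CIs
#'
#' Mean absolute circular error within each condition (wheel radius or
#' set size) with percentile bootstrap confidence intervals over trials
#' (default 90%).
#'
#' @param trials Trial table.
#' @param condition Name of the condition column (default `"condition"`).
#' @param n_boot Bootstrap resamples.
#' @param ci_level Confidence level (default 0.90: 5th/95th percentiles).
#' @param period Task period in degrees.
#' @param seed Integer seed.
#' @return A tibble with one row per condition: `condition`, `n`,
#'   `mean_abs_error`, `lower`, `upper`.
#' @export
error_by_condition <- function(trials, condition = "condition",
                               n_boot = 1000, ci_level = 0.90, period = 360,
                               seed = 1) {
  errs <- abs(circular_error(trials$response_deg, trials$target_deg, period))
  lev <- (1 - ci_level) / 2
  with_seed(mix_seed(seed, 8), {
    split(errs, trials[[condition]]) |>
      purrr::imap(function(e, cond) {
        boots <- vapply(seq_len(n_boot),
                        function(b) mean(sample(e, length(e), replace = TRUE)),
                        numeric(1))
        tibble::tibble(condition = as.numeric(cond), n = length(e),
                       mean_abs_error = mean(e),
                       lower = unname(quantile(boots, lev)),
                       upper = unname(quantile(boots, 1 - lev)))
      }) |>
      dplyr::bind_rows() |>
      dplyr::arrange(.data$condition)
  })
}

#' Binned response-bias curve
#'
#' Mean signed circular error as a function of binned target value: the
#' curve whose sinusoidal shape captures repulsion away from cardinal
#' orientations and attraction toward focal colours.
#'
#' @param trials Trial table sharing one task period.
#' @param n_bins Number of target bins (default 12).
#' @param period Task period (180 for orientation so the curve lives on
#'   the half-turn circle).
#' @return A `bias_curve`: tibble with `bin`, `bin_center`, `n`,
#'   `mean_error`, carrying the period as an attribute.
#' @export
bias_curve <- function(trials, n_bins = 12, period = 360) {
  width <- check_bins(n_bins, period)
  out <- trials |>
    dplyr::mutate(
      bin = bin_index(.data$target_deg, width),
      err = circular_error(.data$response_deg, .data$target_deg, period)) |>
    dplyr::group_by(.data$bin) |>
    dplyr::summarise(n = dplyr::n(), mean_error = mean(.data$err),
                     .groups = "drop") |>
    tidyr::complete(bin = seq_len(n_bins), fill = list(n = 0L)) |>
    dplyr::mutate(bin_center = (.data$bin - 0.5) * width) |>
    dplyr::select("bin", "bin_center", "n", "mean_error")
  class(out) <- c("bias_curve", class(out))
  attr(out, "period") <- period
  out
}

#' @rdname bias_curve
#' @param object A `bias_curve`.
#' @param ... Unused.
#' @export
autoplot.bias_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$bin_center,
                                       y = .data$mean_error)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey70") +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "target (deg)", y = "mean signed error (deg)") +
    ggplot2::theme_minimal()
}

#' Constrained sine fit to a bias curve
#'
#' Fits `y = A sin(theta * x + b)` (x in radians) by exact linear least
#' squares in the equivalent basis `a sin(theta x) + c cos(theta x)`,
#' separately for each candidate frequency, keeping the frequency with
#' the lowest residual SSE (ties to the smaller frequency). Because the
#' stimulus circle repeats every half turn for orientation, admissible
#' frequencies are even; the default candidates are 2, 4 and 6. The fit
#' is canonicalised to `A >= 0` with phase in `(-180, 180]` degrees; a
#' negative-amplitude fit `(-A, b)` is the same curve as
#' `(A, b + 180)` after wrapping.
#'
#' @param curve A [bias_curve()] (or tibble with `bin_center`,
#'   `mean_error`, optionally `n`).
#' @param frequencies Candidate even frequencies.
#' @return A `sine_fit` object with elements `amplitude`, `frequency`,
#'   `phase_deg`, `sse` and the per-frequency search table.
#' @export
fit_sine <- function(curve, frequencies = c(2, 4, 6)) {
  if (any(frequencies %% 2 != 0) || any(frequencies <= 0)) {
    abort("Candidate frequencies must be positive multiples of 2.",
          class = "tccwm_config_error")
  }
  keep <- is.finite(curve$mean_error)
  x <- curve$bin_center[keep] * pi / 180
  y <- curve$mean_error[keep]
  if (length(y) < 4) {
    abort("Need at least 4 non-empty bins to fit a sine.",
          class = "tccwm_data_error")
  }
  search <- purrr::map_dfr(frequencies, function(th) {
    X <- cbind(sin(th * x), cos(th * x))
    coef <- tryCatch(qr.solve(X, y), error = function(e) c(0, 0))
    resid <- y - X %*% coef
    tibble::tibble(frequency = th, a = coef[1], c = coef[2],
                   sse = sum(resid^2))
  })
  best <- search[which.min(search$sse), ] # ties: first = smallest frequency
  A <- sqrt(best$a^2 + best$c^2)
  phase <- if (A < 1e-12) 0 else atan2(best$c, best$a) * 180 / pi
  phase <- ((phase + 180) %% 360) - 180
  if (phase == -180) phase <- 180
  structure(list(amplitude = A, frequency = best$frequency,
                 phase_deg = phase, sse = best$sse, search = search,
                 n_bins = length(y)),
            class = "sine_fit")
}

#' @export
print.sine_fit <- function(x, ...) {
  cat(sprintf(
    "<sine_fit> y = %.3f * sin(%g x %+.2f deg), SSE = %.4g (%d bins)\n",
    x$amplitude, x$frequency, x$phase_deg, x$sse, x$n_bins))
  invisible(x)
}

#' Tidiers for sine fits
#'
#' @param x A `sine_fit`.
#' @param ... Unused.
#' @return `tidy()`: one row per parameter; `glance()`: a one-row summary.
#' @export
tidy.sine_fit <- function(x, ...) {
  tibble::tibble(term = c("amplitude", "frequency", "phase_deg"),
                 estimate = c(x$amplitude, x$frequency, x$phase_deg))
}

#' @rdname tidy.sine_fit
#' @export
glance.sine_fit <- function(x, ...) {
  tibble::tibble(amplitude = x$amplitude, frequency = x$frequency,
                 phase_deg = x$phase_deg, sse = x$sse, n_bins = x$n_bins)
}

#' Inter-item circular-variance correlation
#'
#' For colour displays in which every item was probed, correlates (1) the
#' circular variance of the three display hues with (2) the circular
#' variance of the three responded hues, across displays, keeping only
#' displays on which the participant was far off on all three responses
#' (absolute circular error strictly greater than `threshold`, default
#' 45 degrees). A positive correlation indicates that display-level
#' homogeneity is preserved in memory even when item-level detail is
#' lost.
#'
#' @param trials Colour trial table: 3 rows per `display`, columns
#'   `display`, `target_deg`, `response_deg`.
#' @param threshold Error filter in degrees (strictly greater than).
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return A one-row tibble: `r`, `p_value`, `n_included`.
#' @export
interitem_variance_analysis <- function(trials, threshold = 45,
                                        method = c("pearson", "spearman")) {
  method <- match.arg(method)
  per_display <- trials |>
    dplyr::group_by(.data$display) |>
    dplyr::summarise(
      n_items = dplyr::n(),
      all_far = all(abs(circular_error(.data$response_deg,
                                       .data$target_deg, 360)) > threshold),
      v_stim = circular_variance(.data$target_deg),
      v_resp = circular_variance(.data$response_deg),
      .groups = "drop")
  if (any(per_display$n_items != 3)) {
    abort("Every display must contribute exactly 3 probed responses.",
          class = "tccwm_data_error")
  }
  kept <- dplyr::filter(per_display, .data$all_far)
  if (nrow(kept) < 3) {
    abort(sprintf(
      "Only %d display(s) pass the >%g degree filter: too few to correlate.",
      nrow(kept), threshold),
      class = "tccwm_data_error")
  }
  ct <- cor.test(kept$v_stim, kept$v_resp, method = method, exact = FALSE)
  tibble::tibble(r = unname(ct$estimate), p_value = ct$p.value,
                 n_included = nrow(kept))
}

#' Similarity range per set size
#'
#' Mean (max - min) of the similarity profiles within each set size. A
#' shrinking range is the mechanism behind set-size effects here: noise
#' of fixed variance corrupts a compressed profile more easily.
#'
#' @param profiles List of `tcc_profile` objects whose `condition` labels
#'   the set size.
#' @return A tibble with `set_size`, `mean_range`, `n_profiles`, sorted
#'   by set size.
#' @export
similarity_range_by_setsize <- function(profiles) {
  purrr::map_dfr(profiles, function(p) {
    tibble::tibble(set_size = as.numeric(p$condition),
                   range = max(p$scores) - min(p$scores))
  }) |>
    dplyr::group_by(.data$set_size) |>
    dplyr::summarise(mean_range = mean(.data$range),
                     n_profiles = dplyr::n(), .groups = "drop") |>
    dplyr::arrange(.data$set_size)
}
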