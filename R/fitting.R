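# Grid-search maximum-likelihood fitting of the single memory-strength
# parameter d'. Likelihoods are approximated by smoothed histograms of
# simulated responses (the practical route for arbitrary feature spaces);
# an exact analytic counterpart over the same grid validates the
# approximation.

#' Log-likelihood of one trial under the TCC model
#'
#' Maps the observed response to its wheel option and returns the log of
#' the smoothed histogram probability of that option under `n_sims`
#' simulated model responses at the given d'.
#'
#' @param trial One trial: a list or one-row data frame with at least
#'   `response_deg` (and optionally `wheel`, checked against the profile).
#' @param profile The trial's `tcc_profile`.
#' @param dprime Non-negative memory-strength scalar.
#' @param n_sims Simulated responses used for the histogram (default 8000).
#' @param alpha Histogram smoothing pseudocount.
#' @param seed Optional integer seed for the simulation.
#' @return A single log-probability (finite whenever `alpha > 0`).
#' @export
trial_log_likelihood <- function(trial, profile, dprime, n_sims = 8000,
                                 alpha = 0.5, seed = NULL) {
  stopifnot(inherits(profile, "tcc_profile"))
  tw <- trial$wheel %||% NA
  if (!is.na(tw) && !is.na(profile$wheel) &&
      as.character(tw) != as.character(profile$wheel)) {
    abort(sprintf("Trial wheel '%s' does not match profile wheel '%s'.",
                  tw, profile$wheel),
          class = "tccwm_consistency_error")
  }
  k <- length(profile$scores)
  idx <- degree_to_option(trial$response_deg, k, profile$period)
  cnt <- simulate_counts(profile, dprime, n_sims, seed = seed)
  log(response_histogram(cnt, k, alpha, counts = TRUE)[idx])
}

resolve_scope <- function(trials, scope) {
  scope <- match.arg(scope, c("pooled", "per_setsize", "setsize1"))
  switch(scope,
    pooled = list(all = trials),
    per_setsize = split(trials, trials$condition),
    setsize1 = {
      sub <- trials[trials$condition == 1, , drop = FALSE]
      if (nrow(sub) == 0) {
        abort("No set-size 1 trials to fit.", class = "tccwm_data_error")
      }
      list(`setsize1` = sub)
    })
}

# Deduplicate trials over shared profiles: response counts per profile key.
observed_counts <- function(trials, profiles) {
  keys <- trials$profile
  missing <- setdiff(unique(keys), names(profiles))
  if (length(missing)) {
    abort(sprintf("No profile supplied for key(s): %s.",
                  paste(head(missing, 5), collapse = ", ")),
          class = "tccwm_data_error")
  }
  lapply(split(trials, keys), function(tr) {
    prof <- profiles[[tr$profile[1]]]
    k <- length(prof$scores)
    idx <- degree_to_option(tr$response_deg, k, prof$period)
    list(profile = prof, counts = tabulate(idx, nbins = k))
  })
}

fit_surface <- function(trials, profiles, grid, n_sims, alpha, seed, exact) {
  groups <- observed_counts(trials, profiles)
  ll <- numeric(length(grid))
  for (key in names(groups)) {
    g <- groups[[key]]
    k <- length(g$profile$scores)
    for (gi in seq_along(grid)) {
      probs <- if (exact) {
        p <- choice_probabilities(g$profile, grid[gi])
        # the exact expectation of the smoothed histogram estimator; with
        # alpha = 0 this is the pure analytic likelihood
        if (alpha > 0) (n_sims * p + alpha) / (n_sims + alpha * k) else p
      } else {
        cnt <- simulate_counts(g$profile, grid[gi], n_sims,
                               seed = mix_seed(seed, key, gi))
        response_histogram(cnt, k, alpha, counts = TRUE)
      }
      ll[gi] <- ll[gi] + sum(g$counts * log(probs))
    }
  }
  ll
}

#' Fit d' to a trial table by likelihood grid search
#'
#' Sums per-trial log-likelihoods at every candidate d' and returns the
#' grid maximiser (ties break to the smallest d'). `fit_dprime()` uses the
#' smoothed-histogram approximation with independent simulation streams
#' per grid point; [exact_fit_dprime()] evaluates the same surface with
#' the analytic choice probabilities and is the arbiter when the two
#' disagree. Trials sharing a profile are pooled into response counts, so
#' cost scales with the number of distinct profiles, not trials.
#'
#' @param trials Trial table (tibble/data frame) with columns `profile`
#'   (key into `profiles`), `response_deg` and `condition`.
#' @param profiles Named list of `tcc_profile` objects.
#' @param grid Strictly increasing vector of candidate d' values
#'   (default 0 to 10 in steps of 0.1, spanning uniform guessing to
#'   near-deterministic responding on a 360-option wheel).
#' @param n_sims Simulated responses per trial and grid point.
#' @param alpha Histogram smoothing pseudocount.
#' @param seed Integer base seed; per-(profile, grid point) streams are
#'   derived from it.
#' @param scope Fit scope: `"pooled"` (one d' across all conditions, the
#'   default), `"per_setsize"` (one d' per condition), or `"setsize1"`
#'   (set-size 1 trials alone).
#' @return A `tcc_fit` object; see [tidy.tcc_fit()] and
#'   [glance.tcc_fit()].
#' @export
fit_dprime <- function(trials, profiles, grid = seq(0, 10, by = 0.1),
                       n_sims = 8000, alpha = 0.5, seed = 1,
                       scope = "pooled") {
  new_tcc_fit(trials, profiles, grid, n_sims, alpha, seed, scope,
              exact = FALSE)
}

#' @rdname fit_dprime
#' @details
#' `exact_fit_dprime()` evaluates, by default, the exact expectation of
#' the smoothed histogram estimator, `(n_sims * p_j + alpha) / (n_sims +
#' alpha * n_options)` with `p_j` the analytic choice probability, so the
#' two surfaces are directly comparable point by point; set `alpha = 0`
#' for the pure analytic likelihood.
#' @export
exact_fit_dprime <- function(trials, profiles, grid = seq(0, 10, by = 0.1),
                             n_sims = 8000, alpha = 0.5, scope = "pooled") {
  new_tcc_fit(trials, profiles, grid, n_sims = n_sims, alpha = alpha,
              seed = NA, scope = scope, exact = TRUE)
}

new_tcc_fit <- function(trials, profiles, grid, n_sims, alpha, seed, scope,
                        exact) {
  if (is.null(trials) || nrow(trials) == 0) {
    abort("Empty trial table: nothing to fit.", class = "tccwm_data_error")
  }
  if (!length(grid) || any(diff(grid) <= 0) || any(grid < 0)) {
    abort("`grid` must be a non-empty, strictly increasing, non-negative vector.",
          class = "tccwm_config_error")
  }
  assert_count(n_sims, "n_sims")
  scopes <- resolve_scope(trials, scope)
  surface <- purrr::map_dfr(names(scopes), function(sc) {
    ll <- fit_surface(scopes[[sc]], profiles, grid, n_sims, alpha,
                      mix_seed(seed %||% 0, sc), exact)
    tibble::tibble(scope = sc, dprime = grid, log_lik = ll)
  })
  best <- surface |>
    dplyr::group_by(.data$scope) |>
    dplyr::slice(which.max(.data$log_lik)) |> # which.max: first (smallest d') on ties
    dplyr::ungroup() |>
    dplyr::rename(best_dprime = "dprime")
  structure(
    list(surface = surface, best = best, grid = grid,
         scope = scope, method = if (exact) "exact" else "histogram",
         n_trials = nrow(trials),
         config = list(n_sims = n_sims, alpha = alpha, seed = seed)),
    class = "tcc_fit"
  )
}

#' @export
print.tcc_fit <- function(x, ...) {
  cat(sprintf("<tcc_fit> %s likelihood, scope '%s', %d trials\n",
              x$method, x$scope, x$n_trials))
  print(x$best)
  invisible(x)
}

#' Tidiers for TCC fits
#'
#' `tidy()` returns the full likelihood surface (one row per scope and
#' grid point); `glance()` returns one row per scope with the best d' and
#' its log-likelihood.
#'
#' @param x A `tcc_fit` object.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.tcc_fit <- function(x, ...) x$surface

#' @rdname tidy.tcc_fit
#' @export
glance.tcc_fit <- function(x, ...) {
  dplyr::mutate(x$best, method = x$method, n_trials = x$n_trials)
}

#' @rdname tidy.tcc_fit
#' @param object A `tcc_fit` object.
#' @export
autoplot.tcc_fit <- function(object, ...) {
  ggplot2::ggplot(object$surface,
                  ggplot2::aes(x = .data$dprime, y = .data$log_lik)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(data = object$best,
                        ggplot2::aes(xintercept = .data$best_dprime),
                        linetype = "dashed") +
    ggplot2::facet_wrap(~scope, scales = "free_y") +
    ggplot2::labs(x = "d'", y = "log-likelihood",
                  title = sprintf("TCC %s likelihood surface",
                                  object$method)) +
    ggplot2::theme_minimal()
}
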