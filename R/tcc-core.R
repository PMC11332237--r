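# The TCC response model. A trial is summarised by the vector of
# similarities between the remembered target and each response-wheel
# option; the model scales these by a single memory-strength parameter d',
# corrupts each with independent unit-variance Gaussian noise, and
# responds with the option holding the maximum noisy score.

#' Construct and validate a similarity profile
#'
#' A similarity profile holds one similarity score per response-wheel
#' option, each in `[-1, 1]`. When the target coincides with an option,
#' that option's score must be 1 (an exact match has maximal similarity).
#'
#' @param scores Numeric vector of similarities in `[-1, 1]`.
#' @param target_index Optional 1-based index of the option equal to the
#'   target; its score must be 1 within 1e-6.
#' @param wheel Optional wheel identifier.
#' @param condition Optional condition label (wheel radius or set size).
#' @param period Task period in degrees (360 scenes/colour, 180
#'   orientation); used when converting option indices to degrees.
#' @return A `tcc_profile` object.
#' @export
similarity_profile <- function(scores, target_index = NA_integer_,
                               wheel = NA, condition = NA, period = 360) {
  scores <- as.numeric(scores)
  if (length(scores) < 2 || anyNA(scores) || !all(is.finite(scores))) {
    abort("Similarity scores must be finite and at least two options long.",
          class = "tccwm_value_error")
  }
  # tolerate floating-point spill from cosine computations
  if (min(scores) < -1 - 1e-9 || max(scores) > 1 + 1e-9) {
    abort("Similarity scores must lie in [-1, 1].",
          class = "tccwm_value_error")
  }
  scores <- pmin(1, pmax(-1, scores))
  if (!is.na(target_index)) {
    ti <- as.integer(target_index)
    if (ti < 1 || ti > length(scores)) {
      abort("`target_index` is outside the option range.",
            class = "tccwm_value_error")
    }
    if (abs(scores[ti] - 1) > 1e-6) {
      abort("The target option's similarity must equal 1.",
            class = "tccwm_value_error")
    }
    target_index <- ti
  }
  structure(
    list(scores = scores, target_index = target_index, wheel = wheel,
         condition = condition, period = period),
    class = "tcc_profile"
  )
}

#' @export
print.tcc_profile <- function(x, ...) {
  cat(sprintf(
    "<tcc_profile> %d options, wheel %s, condition %s, range [%.3f, %.3f]\n",
    length(x$scores), as.character(x$wheel), as.character(x$condition),
    min(x$scores), max(x$scores)))
  invisible(x)
}

profile_scores <- function(profile) {
  if (inherits(profile, "tcc_profile")) profile$scores else as.numeric(profile)
}

# Stable identifier used to deduplicate shared profiles during fitting.
profile_key <- function(wheel, target_index) {
  paste0(as.character(wheel), ":", as.integer(target_index))
}

#' Cosine similarity profile from a feature matrix
#'
#' Computes, for every wheel option, the cosine similarity between the
#' option's feature vector and the target's. This is the representational
#' geometry the response model runs on: feature spaces enter only through
#' these pairwise similarities.
#'
#' @param features A `feature_matrix` (one row per option).
#' @param target Target feature vector; defaults to the `target` attribute
#'   of `features`.
#' @param target_index Optional index of the option equal to the target.
#' @param condition Optional condition label stored on the profile.
#' @param period Task period in degrees.
#' @return A `tcc_profile` of length `nrow(features)`.
#' @export
cosine_profile <- function(features, target = NULL, target_index = NA,
                           condition = NA, period = 360) {
  mat <- as.matrix(features)
  target <- target %||% attr(features, "target")
  if (is.null(target)) {
    abort("No target vector: supply `target` or use a feature matrix built with one.",
          class = "tccwm_config_error")
  }
  if (length(target) != ncol(mat)) {
    abort("Target vector length does not match the option feature dimension.",
          class = "tccwm_dimension_error")
  }
  norms <- sqrt(rowSums(mat^2))
  tnorm <- sqrt(sum(target^2))
  bad <- which(norms == 0)
  if (tnorm == 0 || length(bad)) {
    abort(sprintf(
      "Zero-norm feature vector: cosine similarity undefined for %s.",
      if (tnorm == 0) "the target" else
        paste("option(s)", paste(head(bad, 5), collapse = ", "))),
      class = "tccwm_degenerate_error")
  }
  scores <- as.vector(mat %*% target) / (norms * tnorm)
  similarity_profile(scores, target_index = target_index,
                     wheel = attr(features, "wheel") %||% NA,
                     condition = condition, period = period)
}

#' Simulate TCC responses for one trial
#'
#' Draws `n_sims` model responses: each is the argmax over options of
#' `dprime * score + noise` with independent standard normal noise.
#' Deterministic given `seed` (floating-point ties break to the lowest
#' index). Scaling the noise SD by a constant and d' by the same constant
#' leaves the response law unchanged, so unit variance is a convention,
#' not an assumption.
#'
#' @param profile A `tcc_profile` (or bare numeric score vector).
#' @param dprime Non-negative memory-strength scalar.
#' @param n_sims Number of simulated responses (default 8000 per trial).
#' @param seed Optional integer seed; the ambient RNG state is preserved.
#' @return Integer vector of 1-based chosen option indices.
#' @export
simulate_responses <- function(profile, dprime, n_sims = 8000, seed = NULL) {
  scores <- profile_scores(profile)
  check_dprime(dprime)
  assert_count(n_sims, "n_sims")
  with_seed(seed, tcc_simulate_cpp(scores, dprime, as.integer(n_sims)))
}

# Counts over options rather than raw indices; chunked so very large
# n_sims (convergence checks) never materialise a draws-by-options matrix.
simulate_counts <- function(profile, dprime, n_sims, seed = NULL) {
  scores <- profile_scores(profile)
  check_dprime(dprime)
  with_seed(seed, tcc_simulate_counts_cpp(scores, dprime, n_sims))
}

check_dprime <- function(dprime) {
  if (!is.numeric(dprime) || length(dprime) != 1 || !is.finite(dprime) ||
      dprime < 0) {
    abort("`dprime` must be a single non-negative number.",
          class = "tccwm_config_error")
  }
}

#' Exact TCC choice probabilities
#'
#' Analytic law of the model's argmax response: option j is chosen with
#' probability \eqn{\int \phi(x - d's_j) \prod_{k \ne j} \Phi(x - d's_k)\,dx},
#' evaluated by composite Simpson quadrature over
#' `[min(d's) - 8, max(d's) + 8]` with successive grid doubling until the
#' distribution stabilises. Serves as the exact oracle against which the
#' histogram (Monte-Carlo) likelihood approximation is validated.
#'
#' @param profile A `tcc_profile` or numeric score vector.
#' @param dprime Non-negative memory-strength scalar.
#' @param tol Convergence tolerance on the max per-option probability
#'   change between successive refinements.
#' @return Numeric probability vector summing to 1.
#' @export
choice_probabilities <- function(profile, dprime, tol = 1e-9) {
  scores <- profile_scores(profile)
  check_dprime(dprime)
  mu <- dprime * scores
  lo <- min(mu) - 8
  hi <- max(mu) + 8
  n <- 513L # Simpson needs an odd point count
  prev <- NULL
  for (refine in 1:6) {
    x <- seq(lo, hi, length.out = n)
    h <- (hi - lo) / (n - 1)
    centred <- outer(x, mu, "-")            # n_x x n_options
    log_cdf <- pnorm(centred, log.p = TRUE)
    log_all <- rowSums(log_cdf)             # log prod_k Phi(x - mu_k)
    # integrand for option j: phi(x - mu_j) * prod_{k != j} Phi(x - mu_k)
    log_int <- dnorm(centred, log = TRUE) + (log_all - log_cdf)
    w <- c(1, rep(c(4, 2), length.out = n - 2), 1)
    w[n] <- 1
    probs <- as.vector(crossprod(exp(log_int), w)) * h / 3
    if (!is.null(prev) && max(abs(probs - prev)) < tol) break
    prev <- probs
    n <- 2L * n - 1L
  }
  total <- sum(probs)
  if (abs(total - 1) > 1e-6 || anyNA(probs)) {
    abort(sprintf(
      "Choice-probability quadrature failed to converge (mass %.8f at %d points).",
      total, n),
      class = "tccwm_numerical_error")
  }
  probs / total
}

#' Smoothed histogram of simulated responses
#'
#' Turns simulated response indices into a choice distribution with
#' additive (pseudocount) smoothing:
#' `(count_j + alpha) / (n + alpha * n_options)`. The default
#' `alpha = 0.5` (Jeffreys-style) keeps log-likelihoods finite for
#' response options never hit by the simulation.
#'
#' @param indices Integer vector of 1-based option indices, or a
#'   precomputed counts vector of length `n_options` (see `counts`).
#' @param n_options Number of wheel options.
#' @param alpha Non-negative smoothing pseudocount.
#' @param counts If `TRUE`, `indices` is already a counts vector.
#' @return Numeric probability vector of length `n_options`.
#' @export
response_histogram <- function(indices, n_options = 360, alpha = 0.5,
                               counts = FALSE) {
  assert_count(n_options, "n_options")
  stopifnot(is.numeric(alpha), length(alpha) == 1, alpha >= 0)
  if (counts) {
    cnt <- as.numeric(indices)
    if (length(cnt) != n_options || any(cnt < 0)) {
      abort("`indices` is not a valid counts vector.",
            class = "tccwm_data_error")
    }
  } else {
    idx <- as.integer(indices)
    if (length(idx) && (anyNA(idx) || min(idx) < 1 || max(idx) > n_options)) {
      abort(sprintf("Response indices must lie in 1..%d.", n_options),
            class = "tccwm_data_error")
    }
    cnt <- tabulate(idx, nbins = n_options)
  }
  n <- sum(cnt)
  if (n + alpha * n_options == 0) {
    abort("Empty histogram with zero smoothing has no distribution.",
          class = "tccwm_data_error")
  }
  (cnt + alpha) / (n + alpha * n_options)
}
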