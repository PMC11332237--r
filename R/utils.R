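# Shared helpers: circular arithmetic, seeded evaluation, option lattices.

#' Signed circular error between a response and a target
#'
#' Computes `response - target` wrapped onto `(-period/2, period/2]`, the
#' signed-error convention used throughout the analysis battery: positive
#' errors are clockwise of the target. Vectorised over `response` and
#' `target`.
#'
#' @param response,target Numeric vectors of angles in degrees, in
#'   `[0, period)`. Recycled against each other.
#' @param period Task period in degrees: 360 for hue and scene wheels,
#'   180 for orientation (which repeats every half turn).
#' @return Numeric vector of signed errors in degrees.
#' @examples
#' circular_error(350, 10)          # -20: wraps the short way
#' circular_error(178, 5, period = 180)
#' @export
circular_error <- function(response, target, period = 360) {
  if (!is.numeric(period) || length(period) != 1 || !is.finite(period) ||
      period <= 0) {
    abort("`period` must be a single positive number.",
          class = "tccwm_config_error")
  }
  d <- (response - target) %% period
  ifelse(d > period / 2, d - period, d)
}

# Absolute circular distance on a circle of the given period.
circ_dist <- function(a, b, period = 360) {
  abs(circular_error(a, b, period))
}

#' Circular variance of a set of angles
#'
#' One minus the length of the mean unit vector: 0 when all angles
#' coincide, 1 when they are maximally dispersed (e.g. three angles at
#' 0, 120 and 240 degrees).
#'
#' @param degrees Numeric vector of angles in degrees.
#' @param period Period in degrees over which the angles live.
#' @return A single number in `[0, 1]`.
#' @examples
#' circular_variance(c(0, 120, 240))  # 1
#' circular_variance(c(0, 0, 180))    # 2/3
#' @export
circular_variance <- function(degrees, period = 360) {
  theta <- degrees * 2 * pi / period
  1 - sqrt(mean(cos(theta))^2 + mean(sin(theta))^2)
}

#' Map degrees to the nearest response-wheel option
#'
#' Response wheels carry `n_options` evenly spaced options over the task
#' period, option `j` sitting at `(j - 1) * period / n_options` degrees.
#' Responses are snapped to the nearest option, rounding half up, wrapping
#' at the period.
#'
#' @param degrees Numeric vector of angles in `[0, period)`.
#' @param n_options Number of wheel options (default 360).
#' @param period Task period in degrees.
#' @return Integer vector of 1-based option indices.
#' @export
degree_to_option <- function(degrees, n_options = 360, period = 360) {
  as.integer(floor(degrees * n_options / period + 0.5) %% n_options) + 1L
}

#' @rdname degree_to_option
#' @param index Integer vector of 1-based option indices.
#' @export
option_to_degree <- function(index, n_options = 360, period = 360) {
  (index - 1) * period / n_options
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`; the
# caller's RNG state is untouched. A NULL seed runs in the ambient stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) {
    return(force(expr))
  }
  has_old <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", globalenv(), inherits = FALSE)
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

# Deterministic counter-based seed derivation: mixes a base seed with any
# number of integer-like labels (trial index, grid index, hashed keys) so
# per-trial simulation streams are independent and reproducible. The
# multiplier keeps intermediate products below 2^53 so the arithmetic is
# exact in doubles; results stay below 2^31.
mix_seed <- function(seed, ...) {
  ids <- c(seed, ...)
  h <- 17
  for (v in ids) {
    if (is.character(v)) v <- sum(utf8ToInt(v) * seq_along(utf8ToInt(v)))
    h <- (h * 69069 + as.double(v) + 1) %% 2147483629
  }
  as.integer(h)
}

# Guard for strictly positive scalar integers.
assert_count <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || x < 1 ||
      x != floor(x)) {
    abort(sprintf("`%s` must be a single positive integer.", name),
          class = "tccwm_config_error")
  }
  invisible(x)
}
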