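# Synthetic data: ground-truth observers, scene wheels in a latent space,
# and artificial colour / orientation displays. Everything here emulates
# the statistical structure of continuous-report datasets (360-option
# wheels; 25 scene wheels as 5 centres x 5 radii; colour displays at set
# size 3; orientation displays at set sizes 1/2/4/8) so that every
# pipeline stage can be exercised against known ground truth.

#' Define a ground-truth synthetic observer
#'
#' An observer is a similarity kernel over the response wheel plus the
#' response-model parameters that generate behaviour from it:
#' * a circular von Mises-shaped kernel with concentration `kappa`,
#'   rescaled so similarity is 1 at an exact match and spans down to -1;
#' * a true memory strength `dprime`;
#' * an optional sinusoidal bias warp `x -> x + bias_amp * sin(bias_freq
#'   * x * pi / 180)` applied to both target and options, producing
#'   repulsion away from the warp's zero crossings (e.g. the cardinal
#'   orientations for frequency 4);
#' * per-set-size compression coefficients `c_n` in `[0, 1)` that shrink
#'   the similarity range toward 1 as displays get fuller, the mechanism
#'   by which fixed-variance noise yields set-size effects.
#'
#' @param dprime True memory-strength scalar (non-negative).
#' @param kappa Kernel concentration (> 0); larger is more peaked.
#' @param bias_amp Warp amplitude in degrees (0 disables the warp).
#' @param bias_freq Warp frequency, an even integer (cycles per 360
#'   degrees of warp argument), matching the sine-fit convention.
#' @param compression Named numeric vector of `c_n` per set size, e.g.
#'   `c("1" = 0, "2" = 0.3, "4" = 0.6, "8" = 0.8)`; values in `[0, 1)`,
#'   non-decreasing in set size.
#' @param period Task period in degrees (360 colour/scenes, 180
#'   orientation).
#' @param n_options Number of wheel options (default 360).
#' @return An `observer_spec` object.
#' @export
observer_spec <- function(dprime = 2, kappa = 5, bias_amp = 0, bias_freq = 4,
                          compression = c("1" = 0), period = 360,
                          n_options = 360) {
  check_dprime(dprime)
  if (!is.numeric(kappa) || kappa <= 0) {
    abort("`kappa` must be positive.", class = "tccwm_config_error")
  }
  if (bias_freq %% 2 != 0 || bias_freq < 0) {
    abort("`bias_freq` must be an even non-negative integer (the warp must close around the wheel).",
          class = "tccwm_config_error")
  }
  if (abs(bias_amp) * bias_freq * pi / 180 >= 1) {
    abort("Bias warp too strong: |bias_amp| * bias_freq * pi/180 must be < 1 so the warp stays monotone.",
          class = "tccwm_config_error")
  }
  if (is.null(names(compression)) || anyNA(suppressWarnings(as.numeric(names(compression))))) {
    abort("`compression` must be named by set size, e.g. c(`1` = 0, `2` = 0.3).",
          class = "tccwm_config_error")
  }
  if (any(compression < 0) || any(compression >= 1)) {
    abort("Compression coefficients must lie in [0, 1).",
          class = "tccwm_config_error")
  }
  ord <- order(as.numeric(names(compression)))
  if (is.unsorted(compression[ord])) {
    abort("Compression must be non-decreasing in set size.",
          class = "tccwm_config_error")
  }
  structure(
    list(dprime = dprime, kappa = kappa, bias_amp = bias_amp,
         bias_freq = bias_freq, compression = compression[ord],
         period = period, n_options = n_options),
    class = "observer_spec"
  )
}

#' @export
print.observer_spec <- function(x, ...) {
  cat(sprintf(
    "<observer_spec> d' = %g, kappa = %g, warp %g deg @ freq %g, period %g\n",
    x$dprime, x$kappa, x$bias_amp, x$bias_freq, x$period))
  cat("  compression:",
      paste(sprintf("n=%s: %g", names(x$compression), x$compression),
            collapse = ", "), "\n")
  invisible(x)
}

# Sinusoidal bias warp in degrees; argument convention matches the
# sine-fit parameterisation y = A sin(theta * x_rad + b).
warp_degrees <- function(x, amp, freq) {
  x + amp * sin(freq * x * pi / 180)
}

# Von Mises-shaped circular kernel rescaled to [-1, 1] with k(0) = 1.
vm_kernel <- function(delta, kappa, period) {
  raw <- exp(kappa * (cos(2 * pi * delta / period) - 1))
  m <- exp(-2 * kappa)
  2 * (raw - m) / (1 - m) - 1
}

#' Ground-truth similarity profile of a synthetic observer
#'
#' Evaluates `s_j = (1 - c_n) * k(dist(w(target), w(option_j))) + c_n`:
#' the observer's kernel over warped circular distance, compressed toward
#' 1 by the set-size coefficient `c_n`. Compression shrinks the range of
#' similarities across options without moving the peak, so responses
#' become more noise-prone at larger set sizes under fixed-variance noise.
#'
#' @param observer An [observer_spec()].
#' @param target_deg Target value in degrees; must sit on the wheel
#'   lattice.
#' @param set_size Set size whose compression coefficient applies; must
#'   name an entry of `observer$compression`.
#' @param wheel Wheel identifier stored on the profile.
#' @return A `tcc_profile` of length `observer$n_options`.
#' @export
observer_profile <- function(observer, target_deg, set_size = NULL,
                             wheel = "synthetic") {
  stopifnot(inherits(observer, "observer_spec"))
  set_size <- set_size %||% as.numeric(names(observer$compression)[1])
  cn <- observer$compression[as.character(set_size)]
  if (is.na(cn)) {
    abort(sprintf("No compression coefficient for set size %s.", set_size),
          class = "tccwm_config_error")
  }
  k <- observer$n_options
  opt_deg <- option_to_degree(seq_len(k), k, observer$period)
  ti <- degree_to_option(target_deg, k, observer$period)
  if (circ_dist(target_deg, opt_deg[ti], observer$period) > 1e-9) {
    abort("`target_deg` must lie on the wheel lattice.",
          class = "tccwm_value_error")
  }
  wt <- warp_degrees(target_deg, observer$bias_amp, observer$bias_freq)
  wo <- warp_degrees(opt_deg, observer$bias_amp, observer$bias_freq)
  delta <- circ_dist(wt, wo, observer$period)
  scores <- (1 - cn) * vm_kernel(delta, observer$kappa, observer$period) + cn
  similarity_profile(scores, target_index = ti, wheel = wheel,
                     condition = set_size, period = observer$period)
}

#' Generate a synthetic continuous-report trial table
#'
#' Draws one model response per trial (the 8000-draw simulation belongs to
#' fitting, not data generation) from the observer's true d', using a
#' counter-based seed per trial so tables are byte-identical across runs
#' with the same seed.
#'
#' @param observer An [observer_spec()].
#' @param n_trials Number of trials.
#' @param targets Candidate target degrees (on the wheel lattice); each
#'   trial samples one uniformly. Defaults to the full lattice.
#' @param set_sizes Candidate set sizes; sampled uniformly per trial.
#'   Defaults to the set sizes named in `observer$compression`.
#' @param dataset Dataset label written to the table.
#' @param wheel Wheel identifier.
#' @param participant Participant identifier.
#' @param seed Integer seed.
#' @return A tibble of trials with columns `participant`, `dataset`,
#'   `display`, `wheel`, `condition`, `target_deg`, `response_deg`,
#'   `unprobed`, `profile`, plus the profiles used, as attribute
#'   `"profiles"` (a named list keyed like the `profile` column).
#' @export
generate_trials <- function(observer, n_trials, targets = NULL,
                            set_sizes = NULL, dataset = "synthetic",
                            wheel = "wheel1", participant = "obs1",
                            seed = 1) {
  stopifnot(inherits(observer, "observer_spec"))
  assert_count(n_trials, "n_trials")
  k <- observer$n_options
  targets <- targets %||% option_to_degree(seq_len(k), k, observer$period)
  set_sizes <- set_sizes %||% as.numeric(names(observer$compression))
  # sample.int avoids sample()'s scalar expansion when one candidate is given
  draws <- with_seed(mix_seed(seed, 1), tibble::tibble(
    target_deg = targets[sample.int(length(targets), n_trials, replace = TRUE)],
    condition = set_sizes[sample.int(length(set_sizes), n_trials,
                                     replace = TRUE)]
  ))
  profiles <- list()
  response_deg <- numeric(n_trials)
  keys <- character(n_trials)
  for (i in seq_len(n_trials)) {
    key <- paste0(profile_key(wheel, degree_to_option(
      draws$target_deg[i], k, observer$period)), "@", draws$condition[i])
    if (is.null(profiles[[key]])) {
      profiles[[key]] <- observer_profile(observer, draws$target_deg[i],
                                          draws$condition[i], wheel = wheel)
    }
    idx <- simulate_responses(profiles[[key]], observer$dprime, n_sims = 1,
                              seed = mix_seed(seed, 2, i))
    response_deg[i] <- option_to_degree(idx, k, observer$period)
    keys[i] <- key
  }
  out <- tibble::tibble(
    participant = participant,
    dataset = dataset,
    display = seq_len(n_trials),
    wheel = wheel,
    condition = draws$condition,
    target_deg = draws$target_deg,
    response_deg = response_deg,
    unprobed = "",
    profile = keys
  )
  attr(out, "profiles") <- profiles
  out
}

#' Generate colour displays with every item probed
#'
#' Emulates the colour working-memory design: set-size 3 displays of hues,
#' each item probed in turn, yielding three trials per display that share
#' a `display` id. This is the input shape required by
#' [interitem_variance_analysis()].
#'
#' @param observer An [observer_spec()] with period 360 and a compression
#'   entry for set size 3.
#' @param n_displays Number of displays (3 trials each).
#' @param seed Integer seed.
#' @inheritParams generate_trials
#' @return A tibble of `3 * n_displays` trials (schema as
#'   [generate_trials()]).
#' @export
generate_color_trials <- function(observer, n_displays, wheel = "hue_wheel",
                                  participant = "obs1", seed = 1) {
  stopifnot(inherits(observer, "observer_spec"))
  assert_count(n_displays, "n_displays")
  k <- observer$n_options
  hues <- with_seed(mix_seed(seed, 3),
                    matrix(sample(0:(k - 1), 3 * n_displays, replace = TRUE),
                           ncol = 3))
  profiles <- list()
  rows <- vector("list", n_displays * 3)
  for (d in seq_len(n_displays)) {
    for (p in 1:3) {
      target <- hues[d, p]
      key <- paste0(profile_key(wheel, degree_to_option(target, k, 360)), "@3")
      if (is.null(profiles[[key]])) {
        profiles[[key]] <- observer_profile(observer, target, 3,
                                            wheel = wheel)
      }
      idx <- simulate_responses(profiles[[key]], observer$dprime, 1,
                                seed = mix_seed(seed, 4, d, p))
      rows[[(d - 1) * 3 + p]] <- tibble::tibble(
        participant = participant, dataset = "color", display = d,
        wheel = wheel, condition = 3, target_deg = target,
        response_deg = option_to_degree(idx, k, 360),
        unprobed = paste(hues[d, -p], collapse = ";"),
        profile = key)
    }
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "profiles") <- profiles
  out
}

#' Build synthetic scene wheels in a latent space
#'
#' Emulates scene-wheel stimulus construction: each wheel is a circle of
#' 360 evenly spaced points in a random 2D plane of a latent space, one
#' plane per centre, crossed with a set of radii. Points are embedded
#' through a smooth random nonlinearity (a random Fourier feature
#' expansion, seeded per centre), so cosine similarity between options
#' falls off with arc distance, and falls off faster for larger radii --
#' larger radii give more distinct response alternatives.
#'
#' @param n_centers Number of centre points / planes (default 5).
#' @param radii Increasing positive radii (default 5 values), in units of
#'   the embedding lengthscale.
#' @param latent_dim Latent dimensionality (>= 2).
#' @param n_features Embedding dimensionality of the random feature map.
#' @param lengthscale Gaussian lengthscale of the embedding kernel.
#' @param seed Integer seed.
#' @return A list with `wheels`, a tibble (`wheel`, `center`, `radius`),
#'   and `features`, a named list of `feature_matrix` objects (360 x
#'   `n_features`), one per wheel.
#' @export
make_scene_wheels <- function(n_centers = 5,
                              radii = c(0.2, 0.4, 0.6, 0.8, 1),
                              latent_dim = 8, n_features = 512,
                              lengthscale = 1, seed = 1) {
  if (latent_dim < 2) {
    abort("`latent_dim` must be at least 2 (wheels live in a 2D plane).",
          class = "tccwm_config_error")
  }
  if (any(radii < 0) || any(diff(radii) <= 0)) {
    abort("`radii` must be non-negative and strictly increasing.",
          class = "tccwm_config_error")
  }
  theta <- (0:359) * 2 * pi / 360
  wheels <- list()
  features <- list()
  for (ci in seq_len(n_centers)) {
    plane <- with_seed(mix_seed(seed, 10, ci), {
      center <- rnorm(latent_dim)
      basis <- qr.Q(qr(matrix(rnorm(latent_dim * 2), ncol = 2)))
      # random Fourier features of a Gaussian kernel with the given
      # lengthscale; one fixed map per centre
      W <- matrix(rnorm(n_features * latent_dim, sd = 1 / lengthscale),
                  nrow = n_features)
      b <- runif(n_features, 0, 2 * pi)
      list(center = center, basis = basis, W = W, b = b)
    })
    for (ri in seq_along(radii)) {
      r <- radii[ri]
      pts <- outer(r * cos(theta), plane$basis[, 1]) +
        outer(r * sin(theta), plane$basis[, 2])
      pts <- sweep(pts, 2, plane$center, "+")      # 360 x latent_dim
      emb <- sqrt(2 / n_features) *
        cos(pts %*% t(plane$W) + matrix(plane$b, 360, n_features,
                                        byrow = TRUE))
      id <- sprintf("c%d_r%g", ci, r)
      wheels[[id]] <- tibble::tibble(wheel = id, center = ci, radius = r)
      features[[id]] <- feature_matrix(emb, extractor = "scene_latent",
                                       wheel = id)
    }
  }
  list(wheels = dplyr::bind_rows(wheels), features = features)
}

#' Specify an artificial stimulus display
#'
#' A display is a small set of feature values (hues or orientations in
#' degrees) at canvas positions, one of which is probed. Positions default
#' to a ring around the canvas centre.
#'
#' @param values Item feature values in degrees (`[0, 360)` for colour,
#'   `[0, 180)` for orientation).
#' @param probed 1-based index of the probed item.
#' @param task `"color"` or `"orientation"`.
#' @param positions Optional `n x 2` matrix of item centres in `[0, 1]`
#'   canvas coordinates.
#' @return A `display_spec` object.
#' @export
display_spec <- function(values, probed = 1,
                         task = c("color", "orientation"),
                         positions = NULL) {
  task <- match.arg(task)
  n <- length(values)
  allowed <- if (task == "orientation") c(1, 2, 4, 8) else 3
  if (!n %in% allowed) {
    abort(sprintf("Set size %d invalid for task '%s' (allowed: %s).",
                  n, task, paste(allowed, collapse = ", ")),
          class = "tccwm_config_error")
  }
  period <- if (task == "orientation") 180 else 360
  if (any(values < 0) || any(values >= period)) {
    abort(sprintf("Item values must lie in [0, %d).", period),
          class = "tccwm_value_error")
  }
  if (probed < 1 || probed > n) {
    abort("`probed` index out of range.", class = "tccwm_config_error")
  }
  if (is.null(positions)) {
    ang <- 2 * pi * (seq_len(n) - 1) / n - pi / 2
    positions <- cbind(0.5 + 0.33 * cos(ang), 0.5 + 0.33 * sin(ang))
  }
  structure(list(values = values, probed = probed, task = task,
                 period = period, positions = positions,
                 set_size = n),
            class = "display_spec")
}

#' Render a display specification to an image
#'
#' Deterministically rasterises a display onto a square canvas: filled
#' coloured discs for the colour task, oriented coloured line segments for
#' the orientation task. The probed index has no visual consequence, so
#' two specs differing only in `probed` render identically.
#'
#' @param spec A [display_spec()].
#' @param size Canvas side in pixels (default 256).
#' @param item_radius Disc radius / half line length as a fraction of the
#'   canvas.
#' @param background Background grey level in `[0, 1]`.
#' @return A [stimulus_image()] of shape `size x size x 3`.
#' @export
render_display <- function(spec, size = 256, item_radius = 0.08,
                           background = 0.5) {
  stopifnot(inherits(spec, "display_spec"))
  pos <- spec$positions
  if (nrow(pos) > 1) {
    dmin <- min(stats::dist(pos))
    if (dmin < 2 * item_radius) {
      abort("Display layout error: item positions overlap.",
            class = "tccwm_layout_error")
    }
  }
  img <- array(background, dim = c(size, size, 3))
  gx <- matrix(rep((seq_len(size) - 0.5) / size, each = size), size)  # col
  gy <- matrix(rep((seq_len(size) - 0.5) / size, times = size), size) # row
  for (i in seq_len(spec$set_size)) {
    col <- grDevices::col2rgb(
      grDevices::hsv((spec$values[i] %% 360) / 360, 1, 1))[, 1] / 255
    dx <- gx - pos[i, 1]
    dy <- gy - pos[i, 2]
    mask <- if (spec$task == "color") {
      dx^2 + dy^2 <= item_radius^2
    } else {
      # line segment at the item's orientation (0 deg = horizontal)
      a <- spec$values[i] * pi / 180
      u <- dx * cos(a) + dy * sin(a)   # along the segment
      v <- -dx * sin(a) + dy * cos(a)  # across it
      abs(u) <= item_radius & abs(v) <= 0.012
    }
    for (ch in 1:3) {
      plane <- img[, , ch]
      plane[mask] <- col[ch]
      img[, , ch] <- plane
    }
  }
  stimulus_image(img)
}

#' Expand a display into its 360 response-wheel probes
#'
#' Returns one display per wheel option: the unprobed items are left
#' intact and the probed item takes each wheel value in turn. Rendering
#' these and extracting features gives the option rows of a
#' `feature_matrix` for artificial tasks.
#'
#' @param spec A [display_spec()].
#' @param n_options Number of wheel options (default 360).
#' @return A list of `n_options` `display_spec` objects.
#' @export
build_probe_wheel <- function(spec, n_options = 360) {
  stopifnot(inherits(spec, "display_spec"))
  wheel_values <- option_to_degree(seq_len(n_options), n_options, spec$period)
  lapply(wheel_values, function(v) {
    vals <- spec$values
    vals[spec$probed] <- v
    display_spec(vals, probed = spec$probed, task = spec$task,
                 positions = spec$positions)
  })
}
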