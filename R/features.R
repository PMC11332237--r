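# Feature extraction: built-in baselines over stimulus images plus a
# registry contract for plug-in encoders (e.g. deep network layers).

#' Construct and validate a stimulus image
#'
#' A stimulus image is a `height x width x 3` numeric array with values in
#' `[0, 1]`. The default canvas is 256 x 256.
#'
#' @param pixels Numeric array, `height x width x 3`.
#' @param display Optional display-spec identifier carried as an attribute.
#' @return The validated array with class `stimulus_image`.
#' @export
stimulus_image <- function(pixels, display = NA_character_) {
  if (!is.array(pixels) || length(dim(pixels)) != 3 || dim(pixels)[3] != 3) {
    abort("A stimulus image must be a height x width x 3 array.",
          class = "tccwm_dimension_error")
  }
  if (anyNA(pixels) || !all(is.finite(pixels))) {
    abort("Stimulus image contains non-finite values.",
          class = "tccwm_value_error")
  }
  if (min(pixels) < 0 || max(pixels) > 1) {
    abort("Stimulus image values must lie in [0, 1].",
          class = "tccwm_value_error")
  }
  structure(pixels, display = display,
            class = c("stimulus_image", class(pixels)))
}

#' Flatten an image into the raw-pixel baseline feature vector
#'
#' Flattens a 256 x 256 x 3 image into a vector of length 196608
#' (3 x 256 x 256) in channel-first, row-major order: the width index
#' varies fastest, then height, then channel. Reshaping the output back
#' recovers the image exactly.
#'
#' @param image A `stimulus_image` or plain 256 x 256 x 3 array.
#' @return Numeric vector of length 196608.
#' @export
extract_pixels <- function(image) {
  d <- dim(image)
  if (is.null(d) || length(d) != 3 || !all(d == c(256, 256, 3))) {
    abort(sprintf(
      "extract_pixels() expects a 256 x 256 x 3 image, got %s.",
      paste(d %||% length(image), collapse = " x ")),
      class = "tccwm_dimension_error")
  }
  # dims (width, height, channel) with width fastest = channel-first
  # row-major flattening of the (channel, height, width) tensor
  as.vector(aperm(unclass(image), c(2, 1, 3)))
}

#' Per-channel mean baseline features
#'
#' Averages each colour channel over all pixels, giving a length-3 vector.
#' Invariant to any spatial permutation of the pixels.
#'
#' @param image A `stimulus_image` or any `h x w x 3` array.
#' @return Numeric vector of length 3 (R, G, B means).
#' @export
extract_rgb_means <- function(image) {
  d <- dim(image)
  if (is.null(d) || length(d) != 3 || d[3] != 3) {
    abort("extract_rgb_means() expects a 3-channel (h x w x 3) image.",
          class = "tccwm_dimension_error")
  }
  apply(unclass(image), 3, mean)
}

# Registry of named feature backends lives in the package namespace.
.backends <- new.env(parent = emptyenv())

#' Register or look up a feature-extraction backend
#'
#' Backends make external encoders pluggable: any function mapping one
#' image to a numeric feature vector can be registered under an id and
#' used by [extract_features()]. Preprocessing (normalisation, resizing)
#' is the backend's responsibility.
#'
#' @param id Character backend identifier.
#' @param fun Function taking an image and returning a numeric vector.
#' @return `register_feature_backend()` returns `id` invisibly;
#'   `feature_backend()` returns the registered function.
#' @export
register_feature_backend <- function(id, fun) {
  stopifnot(is.character(id), length(id) == 1, is.function(fun))
  assign(id, fun, envir = .backends)
  invisible(id)
}

#' @rdname register_feature_backend
#' @export
feature_backend <- function(id) {
  if (!exists(id, envir = .backends, inherits = FALSE)) {
    abort(sprintf(
      "No feature backend registered under '%s'. Known backends: %s.",
      id, paste(ls(.backends), collapse = ", ")),
      class = "tccwm_config_error")
  }
  get(id, envir = .backends, inherits = FALSE)
}

#' Build a feature matrix for a set of images
#'
#' Applies a backend to each image and stacks the results, one row per
#' image, validating that every row is finite and all rows agree in
#' dimension.
#'
#' @param images List of images (response-wheel options, in wheel order).
#' @param backend A registered backend id (see
#'   [register_feature_backend()]) or a function image -> numeric vector.
#' @param target Optional target image; its features are attached to the
#'   result so [cosine_profile()] can use them directly.
#' @param wheel Optional wheel identifier.
#' @return A `feature_matrix`: numeric matrix `n_options x d` with
#'   attributes `target`, `extractor` and `wheel`.
#' @export
extract_features <- function(images, backend, target = NULL, wheel = NA) {
  extractor_id <- if (is.character(backend)) backend else "custom"
  fun <- if (is.character(backend)) feature_backend(backend) else backend
  rows <- lapply(images, fun)
  lens <- lengths(rows)
  if (length(unique(lens)) != 1) {
    abort(sprintf(
      "Backend returned inconsistent feature dimensions: %s.",
      paste(unique(lens), collapse = ", ")),
      class = "tccwm_consistency_error")
  }
  mat <- do.call(rbind, rows)
  bad <- which(!apply(mat, 1, function(r) all(is.finite(r))))
  if (length(bad)) {
    abort(sprintf("Backend produced non-finite features for option(s) %s.",
                  paste(head(bad, 5), collapse = ", ")),
          class = "tccwm_consistency_error")
  }
  tvec <- if (!is.null(target)) fun(target)
  if (!is.null(tvec) && (length(tvec) != ncol(mat) || !all(is.finite(tvec)))) {
    abort("Target features are non-finite or mismatch the option dimension.",
          class = "tccwm_consistency_error")
  }
  feature_matrix(mat, target = tvec, extractor = extractor_id, wheel = wheel)
}

#' @rdname extract_features
#' @param options Numeric matrix `n_options x d` of option features.
#' @param extractor Extractor identifier stored with the matrix.
#' @export
feature_matrix <- function(options, target = NULL, extractor = "custom",
                           wheel = NA) {
  options <- as.matrix(options)
  if (nrow(options) < 1 || ncol(options) < 1) {
    abort("Feature matrix must be non-empty.", class = "tccwm_value_error")
  }
  if (!all(is.finite(options))) {
    abort("Feature matrix contains non-finite values.",
          class = "tccwm_consistency_error")
  }
  structure(options, target = target, extractor = extractor, wheel = wheel,
            class = c("feature_matrix", "matrix", "array"))
}

#' Fraction of zero activations per option
#'
#' For each row of a feature matrix, the fraction of entries whose absolute
#' value is at or below `tol` (default exactly zero, matching ReLU-style
#' activations; baselines may need a small epsilon). Sparse layers compress
#' the range of cosine similarities across wheel options, the mechanism
#' behind set-size effects in similarity-based response models.
#'
#' @param features A `feature_matrix` or plain numeric matrix.
#' @param tol Non-negative tolerance below which an entry counts as zero.
#' @return A tibble with columns `option` and `sparsity` (each in `[0, 1]`).
#' @export
activation_sparsity <- function(features, tol = 0) {
  mat <- as.matrix(features)
  if (nrow(mat) < 1 || ncol(mat) < 1) {
    abort("Feature matrix must be non-empty.", class = "tccwm_value_error")
  }
  stopifnot(is.numeric(tol), length(tol) == 1, tol >= 0)
  tibble::tibble(
    option = seq_len(nrow(mat)),
    sparsity = rowMeans(abs(mat) <= tol)
  )
}

.onLoad <- function(libname, pkgname) {
  register_feature_backend("pixels", extract_pixels)
  register_feature_backend("rgb_means", extract_rgb_means)
}
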