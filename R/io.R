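# Trial-table and profile I/O plus the end-to-end pipeline runner.

trial_required_cols <- c("participant", "dataset", "wheel", "condition",
                         "target_deg", "response_deg")

dataset_period <- function(dataset) {
  if (identical(as.character(dataset[1]), "orientation")) 180 else 360
}

#' Read and validate a continuous-report trial table
#'
#' Reads a CSV with one row per trial. Required columns: `participant`,
#' `dataset`, `wheel`, `condition`, `target_deg`, `response_deg`;
#' optional: `display`, `unprobed` (semicolon-separated degrees of the
#' unprobed items), `profile`. Deposited datasets name their columns
#' differently, so a `column_map` (`c(theirs = "ours", ...)`) renames on
#' the way in rather than hard-coding any one dialect.
#'
#' Validation reports offending CSV line numbers: degrees must lie in
#' `[0, 360)` (`[0, 180)` for orientation rows), orientation set sizes
#' must be 1, 2, 4 or 8, and colour set sizes 3.
#'
#' @param path CSV path.
#' @param column_map Optional named character vector renaming input
#'   columns to the schema above.
#' @return A validated tibble of trials.
#' @export
read_trials <- function(path, column_map = NULL) {
  raw <- tryCatch(read.csv(path, stringsAsFactors = FALSE),
                  error = function(e) {
                    abort(sprintf("Cannot read a trial table from '%s': %s",
                                  path, conditionMessage(e)),
                          class = "tccwm_schema_error")
                  })
  if (!is.null(column_map)) {
    hit <- names(column_map)[names(column_map) %in% names(raw)]
    names(raw)[match(hit, names(raw))] <- column_map[hit]
  }
  missing <- setdiff(trial_required_cols, names(raw))
  if (length(missing)) {
    abort(sprintf("Trial table is missing required column(s): %s.",
                  paste(missing, collapse = ", ")),
          class = "tccwm_schema_error")
  }
  if (nrow(raw) == 0) {
    abort("Trial table contains a header but no trials.",
          class = "tccwm_schema_error")
  }
  trials <- tibble::as_tibble(raw)
  if (!"unprobed" %in% names(trials)) trials$unprobed <- ""
  trials$unprobed[is.na(trials$unprobed)] <- ""
  # line 1 is the header, so data row i sits on line i + 1
  lines <- seq_len(nrow(trials)) + 1L
  period <- vapply(trials$dataset, dataset_period, numeric(1))
  bad_deg <- which(!is.finite(trials$target_deg) |
                     !is.finite(trials$response_deg) |
                     trials$target_deg < 0 | trials$target_deg >= period |
                     trials$response_deg < 0 | trials$response_deg >= period)
  if (length(bad_deg)) {
    abort(sprintf(
      "Degrees out of range on line(s) %s (must be in [0, period)).",
      paste(head(lines[bad_deg], 10), collapse = ", ")),
      class = "tccwm_validation_error")
  }
  bad_cond <- which(
    (trials$dataset == "orientation" & !trials$condition %in% c(1, 2, 4, 8)) |
      (trials$dataset == "color" & trials$condition != 3))
  if (length(bad_cond)) {
    abort(sprintf(
      "Condition inconsistent with dataset on line(s) %s (orientation: set size 1/2/4/8; color: 3).",
      paste(head(lines[bad_cond], 10), collapse = ", ")),
      class = "tccwm_validation_error")
  }
  trials
}

#' @rdname read_trials
#' @param trials A trial table.
#' @return `write_trials()` returns `path` invisibly.
#' @export
write_trials <- function(trials, path) {
  write.csv(trials[, intersect(
    c(trial_required_cols, "display", "unprobed", "profile"),
    names(trials))], path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Serialise similarity profiles as delimited text
#'
#' One row per profile: wheel id, condition, period, target index, then
#' the per-option scores.
#'
#' @param profiles Named list of `tcc_profile` objects.
#' @param path Output CSV path.
#' @return `path`, invisibly (`read_profiles()` returns the named list).
#' @export
write_profiles <- function(profiles, path) {
  rows <- purrr::imap(profiles, function(p, key) {
    c(key = key, wheel = as.character(p$wheel),
      condition = as.character(p$condition), period = p$period,
      target_index = p$target_index, setNames(p$scores,
        paste0("s", seq_along(p$scores))))
  })
  df <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_profiles
#' @export
read_profiles <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  out <- lapply(seq_len(nrow(df)), function(i) {
    scores <- as.numeric(df[i, grep("^s[0-9]+$", names(df))])
    similarity_profile(scores,
                       target_index = as.integer(df$target_index[i]),
                       wheel = df$wheel[i], condition = df$condition[i],
                       period = as.numeric(df$period[i]))
  })
  setNames(out, df$key)
}

#' Store and load feature matrices as delimited text
#'
#' The matrix goes to CSV (one row per wheel option, in wheel order, with
#' a final `target` row when a target vector is attached); extractor id,
#' wheel id and option ordering go to a JSON sidecar at `<path>.meta.json`.
#'
#' @param features A `feature_matrix`.
#' @param path Output CSV path.
#' @return `path` invisibly; `read_features()` returns the
#'   `feature_matrix`.
#' @export
write_features <- function(features, path) {
  stopifnot(inherits(features, "feature_matrix"))
  mat <- as.matrix(features)
  target <- attr(features, "target")
  out <- if (is.null(target)) mat else rbind(mat, target)
  write.csv(out, path, row.names = FALSE)
  jsonlite::write_json(
    list(extractor = attr(features, "extractor"),
         wheel = attr(features, "wheel"),
         n_options = nrow(mat), has_target = !is.null(target),
         option_order = "wheel order, option 1 first"),
    paste0(path, ".meta.json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".meta.json"))
  mat <- as.matrix(read.csv(path))
  target <- NULL
  if (isTRUE(meta$has_target)) {
    target <- as.numeric(mat[nrow(mat), ])
    mat <- mat[-nrow(mat), , drop = FALSE]
  }
  dimnames(mat) <- NULL
  feature_matrix(mat, target = target, extractor = meta$extractor,
                 wheel = if (is.null(meta$wheel)) NA else meta$wheel)
}

#' Read and write stimulus images as PNG
#'
#' Thin wrappers around the png package for moving [stimulus_image()]
#' arrays to disk and back.
#'
#' @param image A `stimulus_image` (or `h x w x 3` array in `[0, 1]`).
#' @param path PNG path.
#' @return `write_image_png()` returns `path` invisibly;
#'   `read_image_png()` returns a `stimulus_image`.
#' @export
write_image_png <- function(image, path) {
  if (!requireNamespace("png", quietly = TRUE)) {
    abort("PNG support needs the 'png' package.",
          class = "tccwm_config_error")
  }
  png::writePNG(unclass(stimulus_image(unclass(image))), path)
  invisible(path)
}

#' @rdname write_image_png
#' @export
read_image_png <- function(path) {
  if (!requireNamespace("png", quietly = TRUE)) {
    abort("PNG support needs the 'png' package.",
          class = "tccwm_config_error")
  }
  px <- png::readPNG(path)
  if (length(dim(px)) == 3 && dim(px)[3] == 4) px <- px[, , 1:3]
  stimulus_image(px)
}

#' Assemble a validated pipeline configuration
#'
#' Collects every knob the pipeline uses -- dataset, generator settings,
#' the d' grid, simulation and smoothing settings, bin counts, bootstrap
#' settings and seeds -- applying defaults for anything unspecified. The
#' configuration's hash is embedded in every output file so a run can be
#' reconstructed from its outputs.
#'
#' @param dataset `"scenes"`, `"color"` or `"orientation"`.
#' @param out_dir Output directory (created if absent).
#' @param seed Integer master seed.
#' @param ... Overrides for the defaults (see the returned list).
#' @return A `tcc_config` list with a `hash` field.
#' @export
tcc_config <- function(dataset = c("orientation", "color", "scenes"),
                       out_dir = tempfile("tccwm_run_"), seed = 1, ...) {
  dataset <- match.arg(dataset)
  defaults <- list(
    dataset = dataset, out_dir = out_dir, seed = seed,
    dprime_true = 2, kappa = 5, bias_amp = 0, bias_freq = 4,
    compression = switch(dataset,
      orientation = c("1" = 0, "2" = 0.3, "4" = 0.6, "8" = 0.8),
      color = c("3" = 0.3),
      scenes = NULL),
    n_trials = 600, grid = seq(0, 10, by = 0.25), n_sims = 2000,
    alpha = 0.5, n_bins = 12, n_boot = 200, ci_level = 0.90,
    fit_scope = "pooled",
    # scene-wheel generator settings
    n_centers = 2, radii = c(0.3, 0.6, 1), n_features = 256,
    targets_per_wheel = 4)
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(defaults))
  if (length(unknown)) {
    abort(sprintf("Unknown configuration field(s): %s.",
                  paste(unknown, collapse = ", ")),
          class = "tccwm_config_error")
  }
  cfg <- utils::modifyList(defaults, overrides)
  cfg$hash <- rlang::hash(cfg[setdiff(names(cfg), "out_dir")])
  structure(cfg, class = c("tcc_config", "list"))
}

#' Read a pipeline configuration from YAML or JSON
#'
#' Loads a configuration file and validates it through [tcc_config()];
#' the file holds the same fields that function accepts.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` configuration file.
#' @return A validated `tcc_config`.
#' @export
read_config <- function(path) {
  fields <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  if (!is.list(fields) || is.null(fields$dataset)) {
    abort("Configuration file must define at least `dataset`.",
          class = "tccwm_config_error")
  }
  if (!is.null(fields$compression)) {
    fields$compression <- unlist(fields$compression)
  }
  do.call(tcc_config, fields)
}

pipeline_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    abort(sprintf("Pipeline stage '%s' failed: %s", name,
                  conditionMessage(e)),
          class = "tccwm_pipeline_error")
  })
}

# Scene-wheel forward model: cosine profiles from the latent embeddings,
# responses simulated at the configured true d'.
synth_scenes <- function(cfg) {
  sw <- make_scene_wheels(n_centers = cfg$n_centers, radii = cfg$radii,
                          n_features = cfg$n_features, seed = cfg$seed)
  profiles <- list()
  rows <- list()
  t_idx <- round(seq(1, 360, length.out = cfg$targets_per_wheel + 1))[
    seq_len(cfg$targets_per_wheel)]
  per_wheel <- max(1, round(cfg$n_trials / nrow(sw$wheels)))
  trial <- 0
  for (w in sw$wheels$wheel) {
    radius <- sw$wheels$radius[sw$wheels$wheel == w]
    for (ti in t_idx) {
      feats <- sw$features[[w]]
      prof <- cosine_profile(feats, target = feats[ti, ], target_index = ti,
                             condition = radius)
      key <- profile_key(w, ti)
      profiles[[key]] <- prof
      n_here <- max(1, round(per_wheel / length(t_idx)))
      idx <- simulate_responses(prof, cfg$dprime_true, n_sims = n_here,
                                seed = mix_seed(cfg$seed, 20, w, ti))
      rows[[key]] <- tibble::tibble(
        participant = "obs1", dataset = "scenes",
        display = trial + seq_len(n_here), wheel = w, condition = radius,
        target_deg = option_to_degree(ti, 360, 360),
        response_deg = option_to_degree(idx, 360, 360),
        unprobed = "", profile = key)
      trial <- trial + n_here
    }
  }
  trials <- dplyr::bind_rows(rows)
  attr(trials, "profiles") <- profiles
  trials
}

synth_artificial <- function(cfg) {
  obs <- observer_spec(dprime = cfg$dprime_true, kappa = cfg$kappa,
                       bias_amp = cfg$bias_amp, bias_freq = cfg$bias_freq,
                       compression = cfg$compression,
                       period = dataset_period(cfg$dataset))
  if (cfg$dataset == "color") {
    generate_color_trials(obs, n_displays = max(3, cfg$n_trials %/% 3),
                          seed = cfg$seed)
  } else {
    generate_trials(obs, n_trials = cfg$n_trials, dataset = cfg$dataset,
                    seed = cfg$seed)
  }
}

#' Run the full modelling pipeline
#'
#' Executes synthesis -> similarity profiles -> d' fit -> analysis
#' battery for one configuration, writing a trial table, profile table,
#' fit JSON, tidy analysis CSVs and a run log (all embedding the seed and
#' configuration hash) into `config$out_dir`. Re-running with the same
#' configuration reproduces every output byte for byte. On a stage
#' failure, outputs already written are left in place and the error names
#' the stage.
#'
#' @param config A [tcc_config()].
#' @return Invisibly, a list with the trial table, fit, analysis tibbles
#'   and output paths.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "tcc_config"))
  cfg <- config
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  path <- function(f) file.path(cfg$out_dir, f)
  log_lines <- c(sprintf("tccwm pipeline: dataset=%s seed=%d hash=%s",
                         cfg$dataset, cfg$seed, cfg$hash))

  trials <- pipeline_stage("synth", {
    if (cfg$dataset == "scenes") synth_scenes(cfg) else synth_artificial(cfg)
  })
  profiles <- attr(trials, "profiles")
  write_trials(trials, path("trials.csv"))
  write_profiles(profiles, path("profiles.csv"))
  log_lines <- c(log_lines, sprintf("synth: %d trials, %d profiles",
                                    nrow(trials), length(profiles)))

  fit <- pipeline_stage("fit", {
    fit_dprime(trials, profiles, grid = cfg$grid, n_sims = cfg$n_sims,
               alpha = cfg$alpha, seed = cfg$seed, scope = cfg$fit_scope)
  })
  jsonlite::write_json(
    list(seed = cfg$seed, config_hash = cfg$hash, scope = fit$scope,
         method = fit$method, n_trials = fit$n_trials,
         grid = fit$grid, best = fit$best,
         log_likelihoods = fit$surface$log_lik),
    path("fit.json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)
  log_lines <- c(log_lines, sprintf("fit: best d' = %s",
                                    paste(fit$best$best_dprime,
                                          collapse = ", ")))

  period <- dataset_period(cfg$dataset)
  analyses <- pipeline_stage("analyze", {
    out <- list(
      binned = bin_mean_abs_error(trials, cfg$n_bins, period),
      by_condition = error_by_condition(trials, n_boot = cfg$n_boot,
                                        ci_level = cfg$ci_level,
                                        period = period, seed = cfg$seed),
      bias = bias_curve(trials, cfg$n_bins, period))
    # scenes runs with few distinct targets can leave too few non-empty
    # bins for a sine fit; the bias curve itself is still reported
    out$sine <- tryCatch(fit_sine(out$bias), error = function(e) NULL)
    if (cfg$dataset == "color") {
      out$interitem <- tryCatch(interitem_variance_analysis(trials),
                                error = function(e) NULL)
    }
    out
  })
  meta <- sprintf("# seed=%d hash=%s", cfg$seed, cfg$hash)
  write_csv_meta <- function(df, file) {
    con <- file(path(file), "w")
    writeLines(meta, con)
    write.csv(df, con, row.names = FALSE)
    close(con)
  }
  write_csv_meta(analyses$binned, "binned_errors.csv")
  write_csv_meta(analyses$by_condition, "error_by_condition.csv")
  write_csv_meta(as.data.frame(analyses$bias), "bias_curve.csv")
  summary <- list(seed = cfg$seed, config_hash = cfg$hash,
                  dataset = cfg$dataset,
                  best_dprime = fit$best$best_dprime)
  if (!is.null(analyses$sine)) summary$sine <- glance(analyses$sine)
  if (!is.null(analyses$interitem)) summary$interitem <- analyses$interitem
  jsonlite::write_json(summary, path("summary.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  writeLines(c(log_lines, "done"), path("log.txt"))

  invisible(list(trials = trials, profiles = profiles, fit = fit,
                 analyses = analyses,
                 paths = vapply(c("trials.csv", "profiles.csv", "fit.json",
                                  "binned_errors.csv",
                                  "error_by_condition.csv",
                                  "bias_curve.csv", "summary.json",
                                  "log.txt"),
                                path, character(1))))
}
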