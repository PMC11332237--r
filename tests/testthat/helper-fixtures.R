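# Shared fixtures and independent reference implementations.

# Pure-R reference for the noisy-argmax response rule. Draws the per-option
# normals in the same order as the compiled routine, so the two must agree
# draw for draw under the same seed; which.max shares the lowest-index
# tie-break.
simulate_argmax_r <- function(scores, dprime, n_sims, seed) {
  set.seed(seed)
  vapply(seq_len(n_sims), function(i) {
    which.max(dprime * scores + rnorm(length(scores)))
  }, integer(1))
}

# Random unstructured similarity profile.
random_scores <- function(n_options = 360, seed = 1) {
  set.seed(seed)
  runif(n_options, -1, 1)
}

# Solid-colour stimulus image.
uniform_image <- function(value = 0.5, size = 256) {
  stimulus_image(array(rep(value, length.out = size * size * 3),
                       dim = c(size, size, 3)))
}

# Minimal valid trial tibble around explicit target/response pairs.
toy_trials <- function(target, response, wheel = "w1", condition = 1,
                       dataset = "synthetic") {
  tibble::tibble(participant = "p1", dataset = dataset, wheel = wheel,
                 display = seq_along(target), condition = condition,
                 target_deg = target, response_deg = response,
                 unprobed = "")
}
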