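test_that("cosine profiles hit the identity, orthogonal and antipodal cases", {
  mat <- rbind(c(1, 0, 0), c(0, 1, 0), c(-1, 0, 0), c(0.5, 0, 0))
  prof <- cosine_profile(feature_matrix(mat), target = c(1, 0, 0),
                         target_index = 1)
  expect_equal(prof$scores, c(1, 0, -1, 1))

  bad <- feature_matrix(rbind(c(1, 0), c(1e-300 * 0, 0)))
  expect_error(cosine_profile(bad, target = c(1, 0)),
               "option", class = "tccwm_degenerate_error")
  expect_error(cosine_profile(feature_matrix(rbind(c(1, 0), c(0, 1))),
                              target = c(0, 0)),
               class = "tccwm_degenerate_error")
})

test_that("similarity profiles enforce range and exact-match invariants", {
  expect_error(similarity_profile(c(0.5, 1.2)), class = "tccwm_value_error")
  expect_error(similarity_profile(c(0.5, 0.9), target_index = 1),
               class = "tccwm_value_error")
  p <- similarity_profile(c(1, 0.3, -0.2), target_index = 1)
  expect_equal(p$scores[p$target_index], 1)
})

test_that("compiled simulation matches the pure-R reference draw for draw", {
  scores <- random_scores(60, seed = 3)
  for (d in c(0, 1.5, 4)) {
    got <- simulate_responses(similarity_profile(scores), d, n_sims = 200,
                              seed = 99)
    want <- simulate_argmax_r(scores, d, 200, seed = 99)
    expect_identical(got, want)
  }
  # counts variant agrees with tabulated indices
  cnt <- tccwm:::simulate_counts(similarity_profile(scores), 1.5, 200,
                                 seed = 99)
  expect_identical(as.integer(cnt),
                   tabulate(simulate_argmax_r(scores, 1.5, 200, 99), 60))
})

test_that("simulation is deterministic given a seed and leaves the RNG alone", {
  prof <- similarity_profile(random_scores(360, 5))
  a <- simulate_responses(prof, 2, 1000, seed = 7)
  set.seed(123)
  before <- rnorm(1)
  b <- simulate_responses(prof, 2, 1000, seed = 7)
  set.seed(123)
  expect_identical(before, rnorm(1)) # ambient stream untouched
  expect_identical(a, b)
})

test_that("zero memory strength yields uniform responding", {
  prof <- similarity_profile(random_scores(360, 11))
  idx <- simulate_responses(prof, 0, n_sims = 1e5, seed = 2026)
  cs <- suppressWarnings(chisq.test(tabulate(idx, 360)))
  expect_gt(cs$p.value, 0.01)
})

test_that("analytic choice probabilities respect symmetry and normalisation", {
  expect_equal(choice_probabilities(c(0.4, 0.4), 3), c(0.5, 0.5))
  p <- choice_probabilities(rep(0.2, 360), 2)
  expect_equal(p, rep(1 / 360, 360), tolerance = 1e-9)
  expect_equal(sum(choice_probabilities(random_scores(360, 2), 2)), 1,
               tolerance = 1e-9)
})

test_that("choice probabilities are shift-invariant and permutation-equivariant", {
  s <- random_scores(40, seed = 8)
  p1 <- choice_probabilities(s, 1.7)
  p2 <- choice_probabilities(s - 0.37, 1.7)
  expect_equal(p1, p2, tolerance = 1e-7)

  set.seed(4)
  perm <- sample(40)
  expect_equal(choice_probabilities(s[perm], 1.7), p1[perm],
               tolerance = 1e-7)

  # scaling scores by c and d' by 1/c leaves the response law unchanged
  expect_equal(choice_probabilities(s * 0.5, 2 * 1.7), p1, tolerance = 1e-7)
})

test_that("the top option's probability is monotone in d' with limit 1", {
  set.seed(9)
  s <- c(1, runif(119, -1, 0.8)) # unique maximum with a clear gap
  top <- 1L
  probs <- vapply(c(0, 0.5, 1, 2, 4, 8, 16, 32),
                  function(d) choice_probabilities(s, d)[top], numeric(1))
  expect_true(all(diff(probs) > -1e-10))
  expect_gt(probs[length(probs)], 0.999)
})

test_that("a dominant target at high d' is chosen almost surely", {
  scores <- c(1, rep(-1, 359))
  prof <- similarity_profile(scores, target_index = 1)
  p <- choice_probabilities(prof, 20)
  idx <- simulate_responses(prof, 20, n_sims = 5000, seed = 31)
  phat <- mean(idx == 1)
  se <- sqrt(p[1] * (1 - p[1]) / 5000 + 1e-12)
  expect_lt(abs(phat - p[1]), 3 * se + 1e-6)
  expect_gt(p[1], 0.999)
})

test_that("Monte-Carlo frequencies converge to the analytic law", {
  prof <- observer_spec(kappa = 5) |> observer_profile(100)
  p <- choice_probabilities(prof, 2)
  cnt <- tccwm:::simulate_counts(prof, 2, 2e5, seed = 17)
  expect_lt(sum(abs(cnt / 2e5 - p)) / 2, 0.02) # total variation
})

test_that("response histograms apply pseudocount smoothing correctly", {
  expect_equal(response_histogram(rep(1L, 50), 4, alpha = 0),
               c(1, 0, 0, 0))
  expect_equal(response_histogram(integer(0), 5, alpha = 1), rep(1 / 5, 5))
  # counts (3,1,0,0), alpha 1 -> (4,2,1,1)/8
  expect_equal(response_histogram(c(3, 1, 0, 0), 4, alpha = 1,
                                  counts = TRUE), c(4, 2, 1, 1) / 8)
  expect_error(response_histogram(c(0L, 5L), 4),
               class = "tccwm_data_error")
  expect_error(response_histogram(integer(0), 5, alpha = 0),
               class = "tccwm_data_error")
})
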