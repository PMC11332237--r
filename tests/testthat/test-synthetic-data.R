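test_that("observer kernels are symmetric, peaked at the target, and compressible", {
  obs <- observer_spec(dprime = 2, kappa = 5)
  prof <- observer_profile(obs, 100)
  ti <- prof$target_index
  expect_equal(prof$scores[ti], 1)
  # symmetry s(delta) = s(-delta) around the target when unwarped
  for (k in c(1, 10, 90, 179)) {
    expect_equal(prof$scores[(ti - 1 + k) %% 360 + 1],
                 prof$scores[(ti - 1 - k) %% 360 + 1], tolerance = 1e-12)
  }
  expect_equal(range(prof$scores), c(-1, 1)) # rescaled kernel spans [-1, 1]

  # compression: c = 0.9 shrinks the range to a tenth, peak untouched
  obs9 <- observer_spec(dprime = 2, kappa = 5, compression = c("1" = 0.9))
  p9 <- observer_profile(obs9, 100)
  expect_equal(p9$scores[ti], 1)
  expect_equal(diff(range(p9$scores)), 0.1 * diff(range(prof$scores)),
               tolerance = 1e-12)

  # warped observers still score 1 at the target option
  obsw <- observer_spec(dprime = 2, kappa = 5, bias_amp = 5, bias_freq = 4,
                        period = 180)
  pw <- observer_profile(obsw, 33)
  expect_equal(pw$scores[pw$target_index], 1)

  expect_error(observer_profile(obs, 0.37), class = "tccwm_value_error")
  expect_error(observer_spec(kappa = -1), class = "tccwm_config_error")
  expect_error(observer_spec(compression = c("1" = 0.5, "2" = 0.2)),
               class = "tccwm_config_error")
  expect_error(observer_spec(bias_freq = 3), class = "tccwm_config_error")
})

test_that("scene wheels come as centres x radii with radius-graded difficulty", {
  sw <- make_scene_wheels(seed = 2)
  expect_equal(nrow(sw$wheels), 25) # five centres, five radii
  expect_equal(length(sw$features), 25)
  expect_true(all(vapply(sw$features, nrow, numeric(1)) == 360))

  # degenerate radius: all options identical, similarity profile all ones
  sw0 <- make_scene_wheels(n_centers = 1, radii = c(0, 0.5), seed = 3)
  w0 <- sw0$features[[1]]
  prof0 <- cosine_profile(w0, target = w0[1, ], target_index = 1)
  expect_equal(prof0$scores, rep(1, 360), tolerance = 1e-9)

  # minimum similarity falls monotonically with radius, per centre
  for (ci in 1:2) {
    mins <- vapply(sw$features[sw$wheels$center == ci], function(f) {
      min(cosine_profile(f, target = f[1, ], target_index = 1)$scores)
    }, numeric(1))
    expect_true(all(diff(mins) < 0))
  }

  expect_error(make_scene_wheels(latent_dim = 1),
               class = "tccwm_config_error")
  expect_error(make_scene_wheels(radii = c(0.5, 0.2)),
               class = "tccwm_config_error")
})

test_that("display rendering is deterministic and blind to the probe index", {
  spec <- display_spec(c(30, 150, 270), probed = 1, task = "color")
  img1 <- render_display(spec, size = 64)
  img2 <- render_display(spec, size = 64)
  expect_identical(img1, img2)

  spec2 <- display_spec(c(30, 150, 270), probed = 3, task = "color")
  expect_identical(unclass(img1), unclass(render_display(spec2, size = 64)))

  # three discs: three distinct non-background colours
  px <- matrix(unclass(img1), ncol = 3)
  cols <- unique(px[px[, 1] != 0.5 | px[, 2] != 0.5 | px[, 3] != 0.5, ,
                    drop = FALSE])
  expect_equal(nrow(cols), 3)

  # horizontal line: wide, flat footprint
  h <- render_display(display_spec(0, task = "orientation"), size = 64)
  mask <- which(unclass(h)[, , 1] != 0.5, arr.ind = TRUE)
  expect_gt(diff(range(mask[, "col"])), 3 * diff(range(mask[, "row"])))

  overlap <- display_spec(c(10, 20, 30), task = "color",
                          positions = cbind(c(0.5, 0.5, 0.51),
                                            c(0.5, 0.5, 0.5)))
  expect_error(render_display(overlap), class = "tccwm_layout_error")
})

test_that("probe wheels vary only the probed item across all 360 options", {
  spec <- display_spec(c(12, 30, 77, 100, 140, 2, 66, 90),
                       probed = 3, task = "orientation")
  wheel <- build_probe_wheel(spec)
  expect_length(wheel, 360)
  probed_vals <- vapply(wheel, function(d) d$values[3], numeric(1))
  expect_equal(probed_vals, seq(0, 179.5, by = 0.5))
  # unprobed items intact in every display
  for (d in wheel[c(1, 100, 360)]) {
    expect_equal(d$values[-3], spec$values[-3])
  }
  # option equal to the original value reproduces the stimulus
  back <- wheel[[degree_to_option(77, 360, 180)]]
  expect_equal(back$values, spec$values)

  single <- build_probe_wheel(display_spec(90, task = "orientation"))
  expect_equal(vapply(single, function(d) d$values, numeric(1)),
               seq(0, 179.5, by = 0.5))
})

test_that("trial generation is reproducible and respects the observer", {
  obs <- observer_spec(dprime = 4, kappa = 5)
  t1 <- generate_trials(obs, 300, targets = c(0, 45, 90), seed = 12)
  t2 <- generate_trials(obs, 300, targets = c(0, 45, 90), seed = 12)
  expect_identical(t1, t2)
  expect_false(identical(
    t1$response_deg,
    generate_trials(obs, 300, targets = c(0, 45, 90), seed = 13)$response_deg))

  # strong memory, no bias: small mean absolute error
  err <- abs(circular_error(t1$response_deg, t1$target_deg, 360))
  expect_lt(mean(err), 5)

  # zero memory strength: responses uniform over the wheel
  obs0 <- observer_spec(dprime = 0, kappa = 5, n_options = 36)
  t0 <- generate_trials(obs0, 10000, seed = 14)
  cs <- suppressWarnings(
    chisq.test(tabulate(degree_to_option(t0$response_deg, 36), 36)))
  expect_gt(cs$p.value, 0.01)
})

test_that("colour displays probe every item and carry the unprobed hues", {
  obs <- observer_spec(dprime = 2, kappa = 5, compression = c("3" = 0.2))
  tr <- generate_color_trials(obs, 40, seed = 15)
  expect_equal(nrow(tr), 120)
  expect_true(all(table(tr$display) == 3))
  expect_true(all(tr$condition == 3))
  first <- tr[tr$display == 1, ]
  # each row's unprobed field lists the other two targets
  for (i in 1:3) {
    others <- sort(as.numeric(strsplit(first$unprobed[i], ";")[[1]]))
    expect_equal(others, sort(first$target_deg[-i]))
  }
})
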