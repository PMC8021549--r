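test_that("sub-threshold impacts are refused: the device would never record them", {
  expect_error(simulate_true_impact(impact_params(peak_lin_acc = 0), seed = 1),
               "trigger threshold")
  expect_error(simulate_true_impact(impact_params(peak_lin_acc = 9), seed = 1),
               "never recorded")
  expect_error(simulate_false_event(
    artifact_params("CHEW", peak_lin_acc = 5), seed = 1), "below")
})

test_that("impact peak matches the closed-form haversine maximum plus noise bound", {
  ev <- simulate_true_impact(
    impact_params(peak_lin_acc = 30, pulse_width = 10), seed = 7)
  res <- sqrt(colSums(ev$samples[[1]][1:3, ]^2))
  # noise-free pulse max on the 1 ms grid is 30 * sin^2(pi * u / 10) at the
  # grid point nearest the pulse center; band-limited noise sd 0.5 g
  expect_gte(max(res), 29)
  expect_lte(max(res), 31)
  # noise-free: equals the grid maximum of the closed form
  clean <- clean_impact(peak = 30, width = 10)
  u <- (10 / pi) * asin(sqrt(10 / 30))
  grid_max <- max(30 * sin(pi * ((-50:149) + u) / 10)^2 *
                    ((-50:149) + u >= 0 & (-50:149) + u <= 10))
  expect_equal(max(sqrt(colSums(clean$samples[[1]][1:3, ]^2))), grid_max,
               tolerance = 1e-10)
})

test_that("the seeding contract holds: same seed identical, new seed different", {
  a <- simulate_true_impact(impact_params(), seed = 7)
  b <- simulate_true_impact(impact_params(), seed = 7)
  c <- simulate_true_impact(impact_params(), seed = 8)
  expect_identical(a$samples[[1]], b$samples[[1]])
  expect_false(identical(a$samples[[1]], c$samples[[1]]))
  for (kind in c("CHEW", "BITE_SPIKE", "HANDLING")) {
    x <- simulate_false_event(artifact_params(kind), seed = 3)
    y <- simulate_false_event(artifact_params(kind), seed = 3)
    expect_identical(x$samples[[1]], y$samples[[1]])
  }
})

test_that("chew artifacts carry their fundamental frequency", {
  # least-squares single-sinusoid fit recovers the generating frequency
  # (the 200 ms window holds under one period, so fit rather than
  # autocorrelate)
  for (f0 in c(1.5, 2, 3)) {
    ev <- simulate_false_event(
      artifact_params("CHEW", peak_lin_acc = 25, fundamental_freq = f0),
      seed = 11, noise_lin_sd = 0)
    res <- sqrt(colSums(ev$samples[[1]][1:3, ]^2))
    t_s <- event_time_ms() / 1000
    rss <- vapply(seq(0.5, 5, by = 0.05), function(f) {
      X <- cbind(1, sin(2 * pi * f * t_s), cos(2 * pi * f * t_s))
      sum(stats::lm.fit(X, res)$residuals^2)
    }, numeric(1))
    f_hat <- seq(0.5, 5, by = 0.05)[which.min(rss)]
    expect_lt(abs(f_hat - f0), 0.5)
  }
})

test_that("bite spikes have weak rotation bounded by the coupling parameter", {
  p <- artifact_params("BITE_SPIKE", peak_lin_acc = 30, ang_coupling = 0.15)
  ev <- simulate_false_event(p, seed = 5, noise_ang_sd = 0)
  ang_max <- max(sqrt(colSums(ev$samples[[1]][4:6, ]^2)))
  expect_lte(ang_max, 0.15 * 30 * 10)   # coupling x peak x 10 dps/g reference
  # and the spike is narrow: linear resultant exceeds half-max for < 4 ms
  res <- sqrt(colSums(ev$samples[[1]][1:3, ]^2))
  expect_lt(sum(res > max(res) / 2), 4)
})

test_that("handling bursts concentrate energy in the post-trigger burst window", {
  ev <- simulate_false_event(
    artifact_params("HANDLING", peak_lin_acc = 25), seed = 9,
    noise_lin_sd = 0)
  x <- ev$samples[[1]][1:3, ]
  t <- event_time_ms()
  e_burst <- sum(x[, t >= 0 & t <= 60]^2)
  expect_gt(e_burst / sum(x^2), 0.99)
})

test_that("generate_dataset hits exact class counts at the study ratios", {
  ds <- generate_dataset(n_true = 20, n_false = 28, seed = 1)
  expect_equal(sum(ds$label == "TRUE_IMPACT"), 20)
  expect_equal(sum(ds$label == "FALSE_EVENT"), 28)
  expect_equal(nrow(generate_dataset(0, 0, seed = 1)), 0L)
  # group keys come in blocks of at most 20
  expect_lte(max(table(ds$group_key)), 20)
  expect_gt(length(unique(ds$group_key)), 1)
})

test_that("dataset generation is a pure function of counts and seed", {
  a <- generate_dataset(8, 9, seed = 123)
  b <- generate_dataset(8, 9, seed = 123)
  expect_identical(a, b)
  c <- generate_dataset(8, 9, seed = 124)
  expect_false(identical(a, c))
})

test_that("every generated event satisfies the kinematic-event invariants", {
  # 1000 seeded draws across both classes and all artifact kinds
  ds <- generate_dataset(n_true = 500, n_false = 500, seed = 77)
  expect_silent(validate_events(ds))
})

test_that("two trivial features separate the classes without being degenerate", {
  ds <- generate_dataset(150, 150, seed = 31)
  feat <- purrr::map_dfr(seq_len(nrow(ds)), function(i) {
    m <- ds$samples[[i]]
    res <- sqrt(colSums(m[1:3, ]^2))
    tibble::tibble(
      width_proxy = sum(res > max(res) / 2),
      ang_lin = log1p(sum(m[4:6, ]^2) / (sum(m[1:3, ]^2) + 1e-9)),
      y = ds$label[i] == "TRUE_IMPACT")
  })
  tr <- seq_len(150); te <- 151:300
  fit <- suppressWarnings(
    stats::glm(y ~ width_proxy + ang_lin, data = feat[tr, ],
               family = stats::binomial()))
  acc <- mean((stats::predict(fit, feat[te, ], type = "response") >= 0.5) ==
                feat$y[te])
  expect_gt(acc, 0.8)
})

test_that("simulated sessions are recovered exactly by the trigger emulator", {
  sim <- simulate_session(n_impacts = 3, n_artifacts = 2, duration = 60,
                          seed = 1)
  ev <- detect_events(sim$trace)
  expect_equal(nrow(ev), 5L)
  expect_equal(sort(ev$trigger_time_s), sort(sim$truth$time_s),
               tolerance = 1e-3)   # within 1 ms

  empty <- simulate_session(0, 0, duration = 10, seed = 2)
  expect_equal(nrow(detect_events(empty$trace)), 0L)
  expect_lt(max(abs(empty$trace$lin_acc)), 10)

  expect_error(simulate_session(50, 50, duration = 10, seed = 3),
               "cannot pack")
})
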