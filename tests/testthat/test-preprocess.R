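test_that("default augmentation yields 5 right-shifted copies, verified index by index", {
  ev <- clean_impact(seed = 3)
  aug <- augment_time_shift(ev)
  expect_equal(nrow(aug), 5L)
  m <- ev$samples[[1]]
  for (k in 1:5) {
    mk <- aug$samples[[k]]
    for (ch in 1:6) {
      expect_equal(mk[ch, (k + 1):200], m[ch, 1:(200 - k)])
      expect_equal(mk[ch, 1:k], rep(m[ch, 1], k))  # leading edge padding
    }
  }
  expect_equal(aug$label, rep(ev$label, 5))
  expect_equal(aug$group_key, rep(ev$group_key, 5))
  expect_equal(aug$event_id, paste0(ev$event_id, "_shift", 1:5))
})

test_that("a constant signal is invariant under time shifts", {
  m <- matrix(12, 6, 200)
  ev <- kinematic_event(m, "const")
  aug <- augment_time_shift(ev)
  for (k in 1:5) expect_equal(aug$samples[[k]], m)
})

test_that("non-integer-sample shifts are refused", {
  ev <- clean_impact(seed = 4)
  expect_error(augment_time_shift(ev, n_copies = 6, max_shift = 5),
               "exceeds max_shift")
  expect_equal(nrow(augment_time_shift(ev, n_copies = 3, max_shift = 3)), 3L)
})

test_that("augmenting a dataset multiplies its size by 1 + n_copies, labels intact", {
  ds <- tiny_dataset(4, 5, seed = 6)
  aug <- augment_dataset(ds, n_copies = 5)
  expect_equal(nrow(aug), 9L * 6L)
  expect_equal(sum(aug$label == "TRUE_IMPACT"), 4L * 6L)
  expect_equal(augment_dataset(ds, n_copies = 0), ds)
})

test_that("class weights are inverse-frequency with equal per-class mass", {
  w <- compute_class_weights(rep(c("TRUE_IMPACT", "FALSE_EVENT"), c(50, 50)))
  expect_equal(unname(w), c(1, 1))

  labels <- rep(c("TRUE_IMPACT", "FALSE_EVENT"), c(358, 500))
  w2 <- compute_class_weights(labels)
  expect_equal(unname(w2["TRUE_IMPACT"]), 858 / 716)
  expect_equal(unname(w2["FALSE_EVENT"]), 858 / 1000)
  # equal total weight per class
  expect_lt(abs(358 * w2["TRUE_IMPACT"] - 500 * w2["FALSE_EVENT"]), 1e-9)
  # mean weight over examples is 1
  expect_equal(mean(w2[labels]), 1)

  expect_error(compute_class_weights(rep("TRUE_IMPACT", 5)), "both classes")
  expect_error(compute_class_weights(c("TRUE_IMPACT", "UNVERIFIED")),
               "labels must be")
})

test_that("normalization standardizes train channels and transfers to held-out data", {
  ds <- tiny_dataset(6, 6, seed = 8)
  nr <- normalize_events(ds)
  x <- mignet:::events_to_array(nr$events)
  for (ch in 1:6) {
    expect_lt(abs(mean(x[, , ch])), 1e-6)
    expect_lt(abs(sd(as.vector(x[, , ch])) - 1), 1e-6)
  }
  # held-out set normalized with train stats: finite, generally nonzero mean
  te <- tiny_dataset(3, 3, seed = 9)
  nt <- normalize_events(te, nr$stats)
  expect_true(all(purrr::map_lgl(nt$events$samples, ~ all(is.finite(.x)))))
})

test_that("a zero-variance channel is centered but not scaled, with warning", {
  ds <- tiny_dataset(2, 2, seed = 10)
  ds$samples <- purrr::map(ds$samples, function(m) { m[6, ] <- 7; m })
  expect_warning(nr <- normalize_events(ds), "ang_vel_z")
  expect_true(all(purrr::map_lgl(nr$events$samples,
                                 ~ all(.x[6, ] == 0))))
})

test_that("group-aware splits keep whole groups and honor the fractions", {
  # 10 groups of 10 events
  ds <- generate_dataset(50, 50, seed = 12, group_size = 10L)
  parts <- split_events(ds, split_spec(0.6, 0.2, group_aware = TRUE, seed = 5))
  expect_equal(nrow(parts$train), 60L)
  expect_equal(nrow(parts$val), 20L)
  expect_equal(nrow(parts$test), 20L)
  # no group spans partitions
  gs <- purrr::map(parts, ~ unique(.x$group_key))
  expect_length(intersect(gs$train, gs$val), 0)
  expect_length(intersect(gs$train, gs$test), 0)
  expect_length(intersect(gs$val, gs$test), 0)
  # partition: disjoint and exhaustive
  ids <- sort(unname(unlist(purrr::map(parts, "event_id"))))
  expect_equal(ids, sort(ds$event_id))

  same <- split_events(ds, split_spec(0.6, 0.2, group_aware = TRUE, seed = 5))
  expect_identical(parts, same)

  one_group <- ds
  one_group$group_key <- "g1"
  expect_error(split_events(one_group, split_spec()), "infeasible")
})

test_that("plain splits partition exactly at the requested sizes", {
  ds <- tiny_dataset(10, 10, seed = 13)
  parts <- split_events(ds, split_spec(0.5, 0.25, group_aware = FALSE,
                                       seed = 1))
  expect_equal(purrr::map_int(parts, nrow), c(train = 10L, val = 5L,
                                              test = 5L))
  expect_equal(sort(unname(unlist(purrr::map(parts, "event_id")))),
               sort(ds$event_id))
})

test_that("augment-after-split keeps augmented lineage out of the test set", {
  ds <- generate_dataset(30, 30, seed = 14, group_size = 6L)
  parts <- split_events(ds, split_spec(seed = 3))
  train_aug <- augment_dataset(parts$train)
  parents <- sub("_shift[0-9]+$", "", train_aug$event_id)
  expect_length(intersect(parents, parts$test$event_id), 0)
  expect_length(intersect(train_aug$event_id, parts$test$event_id), 0)
})
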