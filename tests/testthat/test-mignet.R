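test_that("training defaults follow the published recipe", {
  cfg <- mignet_config("M4")
  expect_equal(cfg$batch_size, 32L)
  expect_equal(cfg$epochs, 20L)
  expect_equal(cfg$learning_rate, 0.01)
  expect_equal(cfg$momentum, 0.9)
  expect_equal(unname(cfg$input_shape), c(6L, 200L))
})

test_that("unknown architectures are rejected with the valid ids listed", {
  expect_error(mignet_config("M9"), "M1, M2, M3, M4")
})

test_that("all four heads emit valid probabilities on random probes", {
  set.seed(99)
  for (arch in c("M1", "M2", "M3", "M4")) {
    model <- build_mignet(mignet_config(arch, seed = 4))
    X <- array(rnorm(200 * 25 * 6), c(200, 25, 6))
    p <- mignet:::mignet_prob(model, X)
    expect_valid_probability(p)
    # all-zero input is handled too
    p0 <- mignet:::mignet_prob(model, array(0, c(200, 2, 6)))
    expect_valid_probability(p0)
  }
  # softmax head outputs are an explicit two-class distribution
  Z <- matrix(rnorm(20), 10, 2)
  P <- mignet:::softmax2(Z)
  expect_true(all(P >= 0))
  expect_equal(rowSums(P), rep(1, 10), tolerance = 1e-12)
})

test_that("the compiled engine matches the double-precision reference forward", {
  set.seed(5)
  X <- array(rnorm(200 * 8 * 6), c(200, 8, 6))
  for (arch in c("M1", "M2", "M3", "M4")) {
    model <- build_mignet(mignet_config(arch, seed = 2))
    p_ref <- mignet:::mignet_prob_ref(model, X)
    p_cpp <- mignet:::mignet_prob(model, X)
    expect_lt(max(abs(p_ref - p_cpp)), 1e-5)
  }
})

test_that("reference-engine gradients agree with finite differences", {
  set.seed(42)
  ns <- asNamespace("mignet")
  for (arch in c("M1", "M4")) {
    m <- build_mignet(mignet_config(arch, seed = 3))
    X <- array(rnorm(200 * 4 * 6), c(200, 4, 6))
    y <- c(0, 1, 1, 0); w <- c(1.2, 0.9, 1.1, 1.0)
    act <- ns$head_activation(m)
    loss_of <- function(params) {
      m2 <- m; m2$params <- params
      f <- ns$mignet_forward(m2, X, train = FALSE)
      ns$head_loss(f$Z, y, w, act)$loss
    }
    f0 <- ns$mignet_forward(m, X, train = FALSE)
    hl <- ns$head_loss(f0$Z, y, w, act)
    gr <- ns$mignet_backward(m, f0, hl$dZ)
    for (nm in sample(names(gr), 4)) {
      g <- gr[[nm]]
      i <- sample(length(g), 1)
      eps <- 1e-6
      p1 <- m$params; p1[[nm]][i] <- p1[[nm]][i] + eps
      p2 <- m$params; p2[[nm]][i] <- p2[[nm]][i] - eps
      fd <- (loss_of(p1) - loss_of(p2)) / (2 * eps)
      expect_lt(abs(fd - g[i]) / max(1e-6, abs(fd) + abs(g[i])), 1e-3)
    }
  }
})

test_that("M4's built stack matches its published layer inventory", {
  lay <- mignet_layers(build_mignet(mignet_config("M4")))
  conv1 <- lay[lay$op == "conv1d", ]
  expect_equal(nrow(conv1), 2L)
  expect_equal(conv1$filters, c(64L, 128L))
  expect_equal(conv1$kernel, c("5", "10"))
  conv2 <- lay[lay$op == "conv2d", ]
  expect_equal(nrow(conv2), 1L)
  expect_equal(conv2$filters, 64L)
  expect_equal(conv2$kernel, "3x15")
  expect_equal(sum(lay$op == "maxpool1d"), 2L)
  expect_equal(sum(lay$op == "batchnorm"), 3L)
  expect_equal(lay$rate[lay$op == "dropout"], rep(0.4, 3))
  expect_equal(sum(lay$op == "gap"), 1L)
  expect_equal(lay$activation[lay$op == "head"], "softmax")
})

test_that("M1-M3 stacks match their published inventories", {
  l1 <- mignet_layers(build_mignet(mignet_config("M1")))
  expect_equal(sum(l1$op == "conv1d"), 4L)
  expect_equal(l1$filters[l1$op == "conv1d"], c(64L, 64L, 128L, 128L))
  expect_true(all(l1$kernel[l1$op == "conv1d"] == "3"))
  expect_equal(l1$rate[l1$op == "dropout"], 0.5)
  expect_equal(l1$activation[l1$op == "head"], "sigmoid")

  l2 <- mignet_layers(build_mignet(mignet_config("M2")))
  expect_equal(l2$filters[l2$op == "conv1d"], rep(128L, 3))
  expect_equal(l2$kernel[l2$op == "conv1d"], c("8", "5", "3"))
  expect_equal(sum(l2$op == "batchnorm"), 3L)
  expect_equal(sum(l2$op == "maxpool1d"), 0L)
  expect_equal(l2$activation[l2$op == "head"], "softmax")

  l3 <- mignet_layers(build_mignet(mignet_config("M3")))
  expect_equal(l3$filters[l3$op == "conv1d"], c(48L, 96L))
  expect_equal(l3$kernel[l3$op == "conv1d"], c("15", "15"))
  expect_equal(l3$filters[l3$op == "conv2d"], 96L)
  expect_equal(l3$kernel[l3$op == "conv2d"], "3x15")
  expect_equal(l3$rate[l3$op == "dropout"], rep(0.4, 3))
  expect_equal(l3$activation[l3$op == "head"], "sigmoid")
})

test_that("training separates a separable toy problem and is seed-reproducible", {
  # classes differ by a 20 g mean offset: separable by construction
  set.seed(1)
  mk <- function(offset, n, id0) {
    purrr::map_dfr(seq_len(n), function(i) {
      m <- matrix(rnorm(1200, sd = 1), 6, 200)
      m[1, 51:80] <- m[1, 51:80] + offset
      kinematic_event(m, sprintf("t%s%03d", id0, i),
                      label = if (offset > 15) "TRUE_IMPACT" else "FALSE_EVENT",
                      group_key = sprintf("g%d", i %% 7), check = "shape")
    })
  }
  train <- dplyr::bind_rows(mk(20, 100, "a"), mk(0, 100, "b"))
  cfg <- mignet_config("M1", epochs = 20, seed = 6)
  fit <- train_mignet(build_mignet(cfg), train)
  expect_gte(dplyr::last(tidy(fit)$train_acc), 0.99)

  fit2 <- train_mignet(build_mignet(cfg), train)
  expect_identical(tidy(fit), tidy(fit2))
  expect_identical(predict(fit, train), predict(fit2, train))
})

test_that("duplicating minority events equals doubling their class weight", {
  ds <- tiny_dataset(6, 9, seed = 21)
  model <- train_mignet(
    build_mignet(mignet_config("M4", epochs = 1, seed = 2)),
    ds, shuffle = FALSE)
  dup <- dplyr::bind_rows(ds, ds[ds$label == "TRUE_IMPACT", ])
  w <- c(TRUE_IMPACT = 1.3, FALSE_EVENT = 0.7)
  w2 <- c(TRUE_IMPACT = 2 * 1.3, FALSE_EVENT = 0.7)
  loss_dup <- mignet_loss(model, dup, class_weights = w, reduce = "sum")
  loss_wtd <- mignet_loss(model, ds, class_weights = w2, reduce = "sum")
  expect_lt(abs(loss_dup - loss_wtd), 1e-6)
})

test_that("degenerate training inputs are rejected", {
  ds <- tiny_dataset(5, 0, seed = 22)
  expect_error(train_mignet(build_mignet(mignet_config("M1")), ds),
               "single class")
})

test_that("prediction applies the 0.5 threshold with ties called impacts", {
  model <- build_mignet(mignet_config("M1", seed = 1))
  # zero all parameters: sigmoid(0) = 0.5 exactly
  model$params <- purrr::map(model$params, function(p) {
    if (is.null(dim(p))) 0 * p else p * 0
  })
  ev <- tiny_dataset(2, 2, seed = 23)
  pr <- predict(model, ev)
  expect_equal(pr$p_true, rep(0.5, 4))
  expect_equal(pr$pred_label, rep("TRUE_IMPACT", 4))
})

test_that("predictions are equivariant under batch permutation", {
  ds <- tiny_dataset(8, 8, seed = 24)
  model <- train_mignet(
    build_mignet(mignet_config("M4", epochs = 1, seed = 3)), ds)
  perm <- sample(nrow(ds))
  p1 <- predict(model, ds)
  p2 <- predict(model, ds[perm, ])
  expect_equal(p2$p_true, p1$p_true[perm], tolerance = 1e-6)
})

test_that("model persistence round-trips predictions and refuses bad artifacts", {
  ds <- tiny_dataset(4, 4, seed = 25)
  model <- train_mignet(
    build_mignet(mignet_config("M2", epochs = 1, seed = 4)), ds)
  path <- withr::local_tempfile(fileext = ".rds")
  save_mignet(model, path)
  back <- load_mignet(path)
  expect_identical(predict(back, ds), predict(model, ds))

  expect_error(load_mignet("/nonexistent.rds"), "no such file")

  junk <- withr::local_tempfile(fileext = ".rds")
  writeLines("not an rds", junk)
  expect_error(load_mignet(junk), "corrupt")

  wrongver <- withr::local_tempfile(fileext = ".rds")
  saveRDS(list(format = "mignet_model", format_version = 99L, model = NULL),
          wrongver)
  expect_error(load_mignet(wrongver), "format version")
})

test_that("tidy and glance summarize fitted models", {
  ds <- tiny_dataset(4, 4, seed = 26)
  model <- train_mignet(
    build_mignet(mignet_config("M1", epochs = 2, seed = 5)), ds, ds[1:4, ])
  h <- tidy(model)
  expect_equal(nrow(h), 2L)
  expect_true(all(c("train_loss", "val_acc") %in% names(h)))
  g <- glance(model)
  expect_equal(g$architecture, "M1")
  expect_true(g$trained)
  expect_gt(g$n_parameters, 1000)
})
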