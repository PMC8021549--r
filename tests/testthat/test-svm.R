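test_that("features of a clean axis-aligned pulse match the closed form", {
  ev <- clean_impact(peak = 30, width = 10, axis = c(1, 0, 0))
  f <- extract_features(ev)
  # noise-free peak: haversine max on the 1 ms grid, within 0.1 g of 30
  expect_equal(f$lin_res_peak_abs, 30, tolerance = 0.005)
  expect_equal(f$lin_acc_x_peak_abs, f$lin_res_peak_abs)
  # time to peak = pulse center: -u* + W/2 rounded to the grid
  u <- (10 / pi) * asin(sqrt(10 / 30))
  expect_equal(f$lin_res_time_to_peak_ms, round(-u + 5))
  # the pulse body sits after the trigger; only its sub-threshold onset tail
  # (one sample) precedes it
  expect_lt(f$lin_acc_x_pre_post_energy_ratio, 0.01)
  # y and z carry nothing
  expect_equal(f$lin_acc_y_peak_abs, 0)
  expect_equal(f$lin_acc_z_power, 0)
})

test_that("an all-zero window yields all-zero peaks, power and crossings", {
  m <- matrix(0, 6, 200)
  ev <- kinematic_event(m, "zero", check = "shape")
  f <- extract_features(ev)
  expect_equal(f$lin_res_peak_abs, 0)
  expect_equal(f$ang_res_power, 0)
  expect_equal(f$lin_acc_x_n_crossings, 0)
  expect_equal(f$ang_lin_energy_ratio, 0)
})

test_that("axis permutation permutes per-axis features and fixes the resultant", {
  ev <- simulate_true_impact(
    impact_params(direction = c(0.2, 0.5, 0.8), peak_ang_vel = 900),
    seed = 17)
  m <- ev$samples[[1]]
  perm <- m[c(2, 3, 1, 5, 6, 4), ]
  ev2 <- kinematic_event(perm, "perm", check = "shape")
  f1 <- extract_features(ev)
  f2 <- extract_features(ev2)
  expect_equal(f2$lin_acc_x_peak_abs, f1$lin_acc_y_peak_abs)
  expect_equal(f2$lin_acc_y_power, f1$lin_acc_z_power)
  expect_equal(f2$ang_vel_z_peak_abs, f1$ang_vel_x_peak_abs)
  expect_equal(f2$lin_res_peak_abs, f1$lin_res_peak_abs)
  expect_equal(f2$ang_res_power, f1$ang_res_power)
  expect_equal(f2$ang_lin_energy_ratio, f1$ang_lin_energy_ratio)
})

test_that("forward selection finds the informative feature first", {
  set.seed(33)
  n <- 120
  X <- matrix(rnorm(n * 5), n, 5,
              dimnames = list(NULL, paste0("f", 1:5)))
  y <- ifelse(X[, 3] > 0, "TRUE_IMPACT", "FALSE_EVENT")
  sel <- select_features(X, y, k_max = 3, kernel = "linear", seed = 1)
  expect_equal(sel$selected[1], 3L)
  expect_equal(sel$path$feature[1], "f3")
  # error path is non-increasing
  expect_true(all(diff(sel$path$cv_error) <= 0))

  expect_length(select_features(X, y, k_max = 0)$selected, 0)
})

test_that("greedy selection matches exhaustive search on a tiny problem", {
  set.seed(44)
  n <- 80
  X <- matrix(rnorm(n * 4), n, 4)
  y <- ifelse(X[, 2] + 0.8 * X[, 4] + rnorm(n, sd = 0.3) > 0,
              "TRUE_IMPACT", "FALSE_EVENT")
  ns <- asNamespace("mignet")
  fold <- ns$strat_folds(y, 5, seed = 2)
  Xs <- scale(X)
  # greedy path, k_max = 2
  sel <- select_features(Xs, y, k_max = 2, kernel = "linear", folds = 5,
                         seed = 2)
  # exhaustive: best single, then best pair containing it
  errs1 <- sapply(1:4, function(j) ns$svm_cv_error(Xs, y, j, fold, "linear", 1))
  best1 <- which.min(errs1)
  expect_equal(sel$selected[1], best1)
  if (length(sel$selected) > 1) {
    cand <- setdiff(1:4, best1)
    errs2 <- sapply(cand, function(j) {
      ns$svm_cv_error(Xs, y, c(best1, j), fold, "linear", 1)
    })
    expect_equal(sel$selected[2], cand[which.min(errs2)])
  }
})

test_that("constant features are skipped, not fatal", {
  set.seed(55)
  X <- cbind(const = rep(1, 60), sig = rnorm(60))
  y <- ifelse(X[, "sig"] > 0, "TRUE_IMPACT", "FALSE_EVENT")
  sel <- select_features(X, y, k_max = 2, kernel = "linear")
  expect_equal(sel$feature_names, "sig")
})

test_that("the SVM fits separable data perfectly and deterministically", {
  set.seed(66)
  X <- rbind(matrix(rnorm(100, 3), 50, 2), matrix(rnorm(100, -3), 50, 2))
  colnames(X) <- c("a", "b")
  y <- rep(c("TRUE_IMPACT", "FALSE_EVENT"), each = 50)
  clf <- train_svm(X, y, kernel = "linear")
  pr <- predict_svm(clf, X)
  expect_equal(mean(pr$pred_label == y), 1)
  expect_true(all(pr$score[1:50] > 0), info = "positive scores toward impacts")

  clf2 <- train_svm(X, y, kernel = "linear")
  expect_equal(predict_svm(clf2, X)$score, pr$score)
})

test_that("zero-variance features are rejected at SVM training", {
  X <- cbind(a = rnorm(40), z = rep(2, 40))
  y <- rep(c("TRUE_IMPACT", "FALSE_EVENT"), 20)
  expect_error(train_svm(X, y), "zero-variance")
  expect_error(train_svm(X[, 1, drop = FALSE], rep("TRUE_IMPACT", 40)),
               "single-class")
})

test_that("the full baseline pipeline learns the synthetic task", {
  tr <- generate_dataset(40, 50, seed = 71)
  te <- generate_dataset(20, 25, seed = 72)
  clf <- svm_pipeline(tr, k_max = 5, seed = 1)
  expect_gt(length(clf$sfs$selected), 0)
  pr <- predict_svm(clf, extract_features(te))
  cm <- confusion(pr$pred_label, te$label)
  expect_gt(cm$accuracy, 0.8)
})
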