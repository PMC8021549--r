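# Hand-engineered features + sequential forward selection + soft-margin SVM:
# the comparison classifier. Feature set version "features_v1": for each of
# the six channels and the two resultants (linear, angular), peak absolute
# value, time to peak, mean power, threshold up-crossings, spectral centroid
# and pre/post-trigger energy ratio; plus the angular-to-linear energy ratio.
# 49 features total, fixed order.

feature_series <- function(m) {
  list(lin_acc_x = m[1, ], lin_acc_y = m[2, ], lin_acc_z = m[3, ],
       ang_vel_x = m[4, ], ang_vel_y = m[5, ], ang_vel_z = m[6, ],
       lin_res = sqrt(colSums(m[1:3, ]^2)),
       ang_res = sqrt(colSums(m[4:6, ]^2)))
}

series_features <- function(x, t_ms, level, fs = 1000) {
  ax <- abs(x)
  pk <- which.max(ax)
  up <- sum(diff(ax > level) == 1L)
  P <- abs(stats::fft(x))[1:(length(x) %/% 2 + 1L)]^2
  fr <- seq(0, fs / 2, length.out = length(P))
  centroid <- if (sum(P) > 0) sum(fr * P) / sum(P) else 0
  pre <- sum(x[t_ms < 0]^2)
  post <- sum(x[t_ms >= 0]^2)
  c(peak_abs = ax[pk],
    time_to_peak_ms = t_ms[pk],
    power = mean(x^2),
    n_crossings = up,
    spectral_centroid_hz = centroid,
    pre_post_energy_ratio = pre / (post + 1e-12))
}

#' Extract the engineered feature vector of each event
#'
#' Deterministic, unit-documented features ("features_v1", 49 values) per
#' event: for each channel and for the Euclidean resultants of the linear
#' and angular triplets — peak absolute value (g or deg/s), time to peak
#' (ms, relative to the trigger), mean signal power, number of threshold
#' up-crossings (10 g for linear series, 100 deg/s for angular), spectral
#' centroid (Hz), and the pre/post-trigger energy ratio — plus the
#' angular-to-linear total energy ratio.
#'
#' @param events An event tibble.
#' @return A tibble with `event_id`, `label`, and one column per feature.
#' @export
#' @examples
#' ev <- simulate_true_impact(impact_params(), seed = 1)
#' names(extract_features(ev))[1:6]
extract_features <- function(events) {
  validate_events(events, shape_only = TRUE)
  t_ms <- event_time_ms()
  rows <- purrr::map(seq_len(nrow(events)), function(i) {
    ser <- feature_series(events$samples[[i]])
    vals <- purrr::imap(ser, function(x, nm) {
      level <- if (grepl("^lin", nm)) mg_const$trigger_g else 100
      v <- series_features(x, t_ms, level)
      stats::setNames(v, paste0(nm, "_", names(v)))
    })
    v <- unlist(unname(vals))   # keep inner names, drop list-name prefixes
    e_ang <- sum(ser$ang_res^2); e_lin <- sum(ser$lin_res^2)
    c(v, ang_lin_energy_ratio = e_ang / (e_lin + 1e-12))
  })
  feat <- tibble::as_tibble(do.call(rbind, rows))
  dplyr::bind_cols(tibble::tibble(event_id = events$event_id,
                                  label = events$label), feat)
}

feature_matrix <- function(features) {
  as.matrix(features[, setdiff(names(features), c("event_id", "label"))])
}

# stratified seeded fold ids
strat_folds <- function(labels, k, seed) {
  fold <- integer(length(labels))
  with_seed_mg(seed, {
    for (cl in unique(labels)) {
      idx <- which(labels == cl)
      fold[idx] <- sample(rep(seq_len(k), length.out = length(idx)))
    }
  })
  fold
}

svm_cv_error <- function(X, y, cols, fold, kernel, cost) {
  k <- max(fold)
  err <- 0
  for (f in seq_len(k)) {
    tr <- fold != f
    fit <- e1071::svm(X[tr, cols, drop = FALSE], factor(y[tr]),
                      kernel = kernel, cost = cost, scale = FALSE)
    pr <- stats::predict(fit, X[!tr, cols, drop = FALSE])
    err <- err + sum(pr != y[!tr])
  }
  err / length(y)
}

#' Greedy sequential forward feature selection
#'
#' Starting from the empty set, repeatedly adds the feature whose addition
#' minimizes the k-fold cross-validated misclassification rate of the SVM,
#' stopping when no addition improves the error or `k_max` features are
#' selected. Fold assignment is stratified and seeded; ties go to the lowest
#' feature index, so the selection is deterministic. Constant (zero-variance)
#' features are skipped, not fatal.
#'
#' @param features Feature tibble from [extract_features()] (or a numeric
#'   matrix).
#' @param labels Class labels (taken from `features$label` when omitted).
#' @param k_max Maximum number of features to select.
#' @param kernel,cost SVM kernel (`"radial"` or `"linear"`) and box
#'   constraint used by the selection criterion.
#' @param folds Number of CV folds (default 5).
#' @param seed Seed for fold assignment.
#' @return A `mignet_sfs` object: `selected` (ordered feature indices),
#'   `feature_names`, and `path` (per-step CV error).
#' @export
select_features <- function(features, labels = NULL, k_max = 10,
                            kernel = c("radial", "linear"), cost = 1,
                            folds = 5, seed = 1) {
  kernel <- match.arg(kernel)
  if (is.data.frame(features)) {
    if (is.null(labels)) labels <- features$label
    X <- feature_matrix(features)
  } else {
    X <- as.matrix(features)
  }
  stopifnot(!is.null(labels), length(labels) == nrow(X))
  if (length(unique(labels)) < 2) {
    stop("need at least two classes for feature selection", call. = FALSE)
  }
  nm <- colnames(X) %||% paste0("f", seq_len(ncol(X)))
  sds <- apply(X, 2, stats::sd)
  usable <- which(is.finite(sds) & sds > 1e-12)
  Xs <- scale(X[, usable, drop = FALSE])
  fold <- strat_folds(labels, folds, seed)

  selected <- integer(0)
  path <- list()
  best_err <- Inf
  if (k_max >= 1) {
    repeat {
      cand <- setdiff(seq_along(usable), selected)
      if (length(cand) == 0 || length(selected) >= k_max) break
      errs <- vapply(cand, function(j) {
        svm_cv_error(Xs, labels, c(selected, j), fold, kernel, cost)
      }, numeric(1))
      j_best <- cand[which.min(errs)]      # which.min -> lowest index on ties
      e_best <- min(errs)
      if (e_best >= best_err) break
      selected <- c(selected, j_best)
      best_err <- e_best
      path[[length(path) + 1L]] <- tibble::tibble(
        step = length(selected), feature = nm[usable[j_best]],
        cv_error = e_best)
    }
  }
  structure(list(selected = unname(usable[selected]),
                 feature_names = unname(nm[usable[selected]]),
                 path = if (length(path)) dplyr::bind_rows(path)
                        else tibble::tibble(step = integer(0),
                                            feature = character(0),
                                            cv_error = numeric(0)),
                 kernel = kernel, cost = cost, folds = folds, seed = seed),
            class = "mignet_sfs")
}

#' @export
print.mignet_sfs <- function(x, ...) {
  cat(sprintf("<sequential forward selection> %d feature(s): %s\n",
              length(x$selected), paste(x$feature_names, collapse = ", ")))
  invisible(x)
}

#' @rdname select_features
#' @param x A `mignet_sfs` object.
#' @param ... Unused.
#' @method tidy mignet_sfs
#' @export
tidy.mignet_sfs <- function(x, ...) x$path

#' Train / apply the support-vector baseline
#'
#' `train_svm()` fits a soft-margin SVM on standardized features
#' (standardization statistics from the training features only; zero-variance
#' features rejected). `predict_svm()` applies the stored standardization and
#' returns predicted labels. The fit is deterministic for fixed data and
#' hyperparameters.
#'
#' @param features Feature tibble/matrix (training set).
#' @param labels Class labels (default `features$label`).
#' @param kernel `"radial"` or `"linear"`.
#' @param cost Box constraint (default 1).
#' @param feature_idx Optional column indices to restrict to (e.g. from
#'   [select_features()]).
#' @return An `svm_baseline` classifier.
#' @export
train_svm <- function(features, labels = NULL, kernel = c("radial", "linear"),
                      cost = 1, feature_idx = NULL) {
  kernel <- match.arg(kernel)
  if (is.data.frame(features)) {
    if (is.null(labels)) labels <- features$label
    X <- feature_matrix(features)
  } else X <- as.matrix(features)
  if (length(unique(labels)) < 2) {
    stop("single-class training set; cannot fit a classifier", call. = FALSE)
  }
  if (!is.null(feature_idx)) X <- X[, feature_idx, drop = FALSE]
  mu <- colMeans(X)
  sds <- apply(X, 2, stats::sd)
  if (any(!is.finite(sds) | sds < 1e-12)) {
    stop("zero-variance feature(s) in the training matrix: ",
         paste(colnames(X)[!is.finite(sds) | sds < 1e-12], collapse = ", "),
         call. = FALSE)
  }
  Xs <- sweep(sweep(X, 2, mu), 2, sds, `/`)
  fit <- e1071::svm(Xs, factor(labels), kernel = kernel, cost = cost,
                    scale = FALSE)
  structure(list(fit = fit, mu = mu, sd = sds,
                 feature_names = colnames(X), feature_idx = feature_idx,
                 kernel = kernel, cost = cost),
            class = "svm_baseline")
}

#' @rdname train_svm
#' @param object An `svm_baseline`.
#' @param newdata Feature tibble/matrix to classify.
#' @return For `predict_svm()`: tibble `event_id` (when available), `score`
#'   (uncalibrated decision value, positive toward `TRUE_IMPACT`) and
#'   `pred_label`.
#' @export
predict_svm <- function(object, newdata) {
  stopifnot(inherits(object, "svm_baseline"))
  ids <- if (is.data.frame(newdata) && "event_id" %in% names(newdata)) {
    newdata$event_id
  } else NA_character_
  X <- if (is.data.frame(newdata)) feature_matrix(newdata) else as.matrix(newdata)
  if (!is.null(object$feature_idx)) {
    X <- X[, object$feature_idx, drop = FALSE]
  }
  Xs <- sweep(sweep(X, 2, object$mu), 2, object$sd, `/`)
  pr <- stats::predict(object$fit, Xs, decision.values = TRUE)
  dv <- as.numeric(attr(pr, "decision.values"))
  # orient the decision value so positive favors TRUE_IMPACT
  if (!startsWith(colnames(attr(pr, "decision.values"))[1], "TRUE_IMPACT")) {
    dv <- -dv
  }
  tibble::tibble(event_id = ids, score = dv,
                 pred_label = as.character(pr))
}

#' End-to-end support-vector pipeline on events
#'
#' Convenience wrapper chaining [extract_features()], [select_features()] and
#' [train_svm()] on a training event set.
#'
#' @param train_events Labeled event tibble.
#' @inheritParams select_features
#' @return An `svm_baseline` with the selection stored in `$sfs`.
#' @export
svm_pipeline <- function(train_events, k_max = 10,
                         kernel = c("radial", "linear"), cost = 1,
                         folds = 5, seed = 1) {
  kernel <- match.arg(kernel)
  feats <- extract_features(train_events)
  sfs <- select_features(feats, k_max = k_max, kernel = kernel, cost = cost,
                         folds = folds, seed = seed)
  idx <- if (length(sfs$selected) > 0) sfs$selected else NULL
  clf <- train_svm(feats, kernel = kernel, cost = cost, feature_idx = idx)
  clf$sfs <- sfs
  clf
}
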