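#' Run the end-to-end synthetic impact-detection experiment
#'
#' Reproduces the study design on simulated data: generate a labeled event
#' set at the field study's class ratio (358 true / 500 false by default),
#' split it group-aware into train/validation/test, augment the training
#' partition with 5 time-shifted copies per event, train the selected network
#' with the published recipe (SGD, batch 32, 20 epochs, learning rate 0.01,
#' momentum 0.9, inverse-frequency class weights), and score the held-out
#' test partition. Optionally fits the support-vector baseline
#' (feature extraction + sequential forward selection + SVM) on the same
#' unaugmented training partition and scores it on the same test events.
#'
#' All randomness derives from `seed`; identical seeds reproduce the
#' experiment exactly.
#'
#' @param seed Integer master seed.
#' @param n_true,n_false Class counts of the simulated dataset.
#' @param architecture Network architecture id (default `"M4"`).
#' @param epochs,batch_size,learning_rate,momentum Training recipe.
#' @param n_augment Time-shift copies per training event (default 5).
#' @param include_svm Also run the SVM baseline (default `TRUE`).
#' @param svm_k_max Feature cap for sequential forward selection.
#' @param verbose Print per-epoch training metrics.
#' @return A list: `model` (trained `mignet_model`), `mignet_metrics` and
#'   (optionally) `svm_metrics` (`confusion_metrics` on the test partition),
#'   `svm` (the fitted baseline), `splits` (partition sizes), and `test`
#'   (the test event tibble).
#' @export
#' @examples
#' \donttest{
#' ex <- impact_experiment(seed = 1, n_true = 30, n_false = 40, epochs = 2,
#'                         include_svm = FALSE)
#' tidy(ex$mignet_metrics)
#' }
impact_experiment <- function(seed, n_true = 358, n_false = 500,
                              architecture = "M4", epochs = 20,
                              batch_size = 32, learning_rate = 0.01,
                              momentum = 0.9, n_augment = 5,
                              include_svm = TRUE, svm_k_max = 10,
                              verbose = FALSE) {
  seed <- as.integer(seed)
  events <- generate_dataset(n_true, n_false, seed = seed)
  parts <- split_events(events, split_spec(train_fraction = 0.6,
                                           val_fraction = 0.2,
                                           group_aware = TRUE,
                                           seed = seed + 1L))
  train_aug <- augment_dataset(parts$train, n_copies = n_augment)
  cfg <- mignet_config(architecture, batch_size = batch_size,
                       epochs = epochs, learning_rate = learning_rate,
                       momentum = momentum, seed = seed + 2L)
  model <- train_mignet(build_mignet(cfg), train_aug, parts$val,
                        verbose = verbose)
  pred <- stats::predict(model, parts$test)
  out <- list(
    model = model,
    mignet_metrics = confusion(pred$pred_label, parts$test$label),
    splits = c(train = nrow(parts$train), val = nrow(parts$val),
               test = nrow(parts$test)),
    test = parts$test)
  if (include_svm) {
    clf <- svm_pipeline(parts$train, k_max = svm_k_max, seed = seed + 3L)
    sp <- predict_svm(clf, extract_features(parts$test))
    out$svm <- clf
    out$svm_metrics <- confusion(sp$pred_label, parts$test$label)
  }
  out
}
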