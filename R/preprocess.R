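#' Time-shift augmentation of an event window
#'
#' Returns `n_copies` shifted versions of the event: copy *k* is the original
#' window shifted right by *k* samples (1 ms per sample at 1 kHz), with the
#' leading edge padded by the first column's values. The pre-trigger region
#' is near baseline, so edge padding introduces no artificial structure.
#' Labels and group key are inherited; copies carry ids `<id>_shift<k>` and
#' the original is not included in the return. Only whole-sample shifts are
#' supported, so `n_copies` may not exceed `max_shift` ms at 1 kHz.
#'
#' @param event A one-row event tibble.
#' @param n_copies Number of augmented copies (default 5, shifts 1..5 ms).
#' @param max_shift Largest allowed shift, ms (default 5).
#' @return An event tibble of `n_copies` rows.
#' @export
#' @examples
#' ev <- simulate_true_impact(impact_params(), seed = 1)
#' aug <- augment_time_shift(ev)
#' nrow(aug)
augment_time_shift <- function(event, n_copies = 5, max_shift = 5) {
  stopifnot(is.data.frame(event), nrow(event) == 1L)
  max_shift_samples <- floor(max_shift * mg_const$fs_lin / 1000)
  if (n_copies > max_shift_samples) {
    stop(sprintf(
      "n_copies = %d exceeds max_shift = %g ms at 1 kHz (non-integer shifts unsupported)",
      n_copies, max_shift), call. = FALSE)
  }
  m <- event$samples[[1]]
  purrr::map_dfr(seq_len(n_copies), function(k) {
    shifted <- cbind(m[, rep(1L, k), drop = FALSE],
                     m[, 1:(ncol(m) - k), drop = FALSE])
    out <- event
    out$event_id <- sprintf("%s_shift%d", event$event_id, k)
    out$samples <- list(shifted)
    out
  })
}

#' Augment every event of a set, appending the shifted copies
#'
#' Convenience wrapper applying [augment_time_shift()] to every row of an
#' event tibble; originals are kept, so the result holds
#' `(1 + n_copies) * nrow(events)` rows. Apply to the training partition
#' only, after splitting.
#'
#' @inheritParams augment_time_shift
#' @param events An event tibble.
#' @return The augmented event tibble.
#' @export
augment_dataset <- function(events, n_copies = 5, max_shift = 5) {
  if (n_copies == 0 || nrow(events) == 0) return(events)
  copies <- purrr::map_dfr(seq_len(nrow(events)), function(i) {
    augment_time_shift(events[i, ], n_copies, max_shift)
  })
  dplyr::bind_rows(events, copies)
}

#' Inverse-frequency class weights
#'
#' Computes `w_c = N / (2 * N_c)` for each of the two classes so that the
#' summed weight per class is equal and both classes contribute equally to a
#' weighted loss; the mean weight over examples is 1.
#'
#' @param labels Character vector of `TRUE_IMPACT` / `FALSE_EVENT` labels.
#' @return Named numeric vector of per-class weights.
#' @export
#' @examples
#' compute_class_weights(rep(c("TRUE_IMPACT", "FALSE_EVENT"), c(358, 500)))
compute_class_weights <- function(labels) {
  classes <- c("TRUE_IMPACT", "FALSE_EVENT")
  bad <- setdiff(unique(labels), classes)
  if (length(bad) > 0) {
    stop("labels must be TRUE_IMPACT/FALSE_EVENT; got: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  n_c <- table(factor(labels, levels = classes))
  if (any(n_c == 0)) {
    stop("both classes must be present to compute class weights", call. = FALSE)
  }
  w <- length(labels) / (2 * as.numeric(n_c))
  stats::setNames(w, classes)
}

#' Per-channel standardization statistics
#'
#' Mean and standard deviation of each of the six channels pooled over all
#' events and time points of `events` — computed on the training partition
#' and reused for validation/test so no test information leaks into scaling.
#'
#' @param events An event tibble.
#' @return A `channel_stats` tibble (`channel`, `mean`, `sd`).
#' @export
channel_stats <- function(events) {
  stopifnot(nrow(events) > 0)
  x <- events_to_array(events)            # (time, event, channel)
  mu <- apply(x, 3, mean)
  sd <- apply(x, 3, stats::sd)
  structure(tibble::tibble(channel = mg_channels(), mean = mu, sd = sd),
            class = c("channel_stats", class(tibble::tibble())))
}

#' Standardize event windows channel-wise
#'
#' Centers and scales every channel using the supplied statistics (or, when
#' `stats` is omitted, statistics computed from `events` themselves).
#' Channels with (near-)zero variance are centered only, with a warning.
#'
#' @param events An event tibble.
#' @param stats A [channel_stats()] tibble, normally from the training set.
#' @return A list: `events` (standardized tibble) and `stats` (the statistics
#'   used, for reuse on held-out data).
#' @export
normalize_events <- function(events, stats = NULL) {
  stopifnot(nrow(events) > 0)
  if (is.null(stats)) stats <- channel_stats(events)
  sds <- stats$sd
  degenerate <- !is.finite(sds) | sds < 1e-12
  if (any(degenerate)) {
    warning("zero-variance channel(s) ",
            paste(stats$channel[degenerate], collapse = ", "),
            ": centered but not scaled")
    sds[degenerate] <- 1
  }
  out <- events
  out$samples <- purrr::map(events$samples, function(m) {
    (m - stats$mean) / sds
  })
  list(events = out, stats = stats)
}

#' Specification of a train/validation/test split
#'
#' @param train_fraction,val_fraction Partition fractions in (0,1); the
#'   remainder is the test set, so they must sum to less than 1.
#' @param group_aware Keep all events sharing a `group_key` in the same
#'   partition (default `TRUE`), preventing recording-level leakage.
#' @param seed Integer seed for the (group) shuffle.
#' @return A `split_spec` list.
#' @export
split_spec <- function(train_fraction = 0.6, val_fraction = 0.2,
                       group_aware = TRUE, seed = 1) {
  stopifnot(train_fraction > 0, train_fraction < 1,
            val_fraction > 0, val_fraction < 1,
            train_fraction + val_fraction < 1)
  structure(list(train_fraction = train_fraction, val_fraction = val_fraction,
                 group_aware = group_aware, seed = as.integer(seed)),
            class = "split_spec")
}

#' Partition an event dataset into train/validation/test
#'
#' Produces disjoint, exhaustive partitions. With `group_aware`, whole
#' `group_key` groups are shuffled and assigned greedily until each
#' partition's event quota is reached, so no group ever spans partitions.
#' The test (and validation) sets are returned untouched — augmentation is
#' applied after splitting and only to the training partition (see
#' [augment_time_shift()]), so augmented copies never leak into evaluation.
#'
#' @param events An event tibble.
#' @param spec A [split_spec()].
#' @return A list of event tibbles: `train`, `val`, `test`.
#' @export
split_events <- function(events, spec = split_spec()) {
  stopifnot(nrow(events) > 0, inherits(spec, "split_spec"))
  n <- nrow(events)
  n_train <- round(spec$train_fraction * n)
  n_val <- round(spec$val_fraction * n)
  with_seed_mg(spec$seed, {
    if (spec$group_aware) {
      groups <- unique(events$group_key)
      if (length(groups) < 3) {
        stop("group-aware split infeasible: fewer than 3 distinct groups",
             call. = FALSE)
      }
      groups <- sample(groups)
      sizes <- table(events$group_key)[groups]
      cum <- cumsum(as.numeric(sizes))
      # greedy: fill train to quota, then val, remainder test
      k_train <- which.min(abs(cum - n_train))
      if (cum[k_train] >= n) k_train <- length(groups) - 2L
      cum2 <- cum - cum[k_train]
      k_val <- which.min(abs(cum2 - n_val))
      if (k_val <= k_train) k_val <- k_train + 1L
      if (k_val >= length(groups)) k_val <- length(groups) - 1L
      part <- list(train = groups[seq_len(k_train)],
                   val = groups[(k_train + 1L):k_val],
                   test = groups[(k_val + 1L):length(groups)])
      out <- purrr::map(part, function(g) {
        events[events$group_key %in% g, , drop = FALSE]
      })
    } else {
      idx <- sample.int(n)
      out <- list(train = events[idx[seq_len(n_train)], ],
                  val = events[idx[(n_train + 1L):(n_train + n_val)], ],
                  test = events[idx[(n_train + n_val + 1L):n], ])
    }
    out
  })
}
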