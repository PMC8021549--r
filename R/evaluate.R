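# Binary-classification evaluation with TRUE_IMPACT as the positive class:
#   Sensitivity = TP/(TP+FN)   Specificity = TN/(TN+FP)
#   Accuracy = (TP+TN)/(TP+FP+TN+FN)   Precision (PPV) = TP/(TP+FP)
#   NPV = TN/(TN+FN)
# Zero-denominator metrics are NA with a flag, never silently zero.

safe_ratio <- function(num, den) if (den == 0) NA_real_ else num / den

# round half away from zero (printed-table convention)
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Confusion-matrix metrics for impact detection
#'
#' Tallies predictions against truth with `TRUE_IMPACT` as the positive
#' class: a true positive is an impact classified as an impact, a true
#' negative a non-impact classified as a non-impact. Derived rates follow
#' the standard definitions (sensitivity `TP/(TP+FN)`, specificity
#' `TN/(TN+FP)`, accuracy `(TP+TN)/n`, precision/PPV `TP/(TP+FP)`, NPV
#' `TN/(TN+FN)`). Counts may also be supplied directly via `counts` to
#' evaluate a published confusion table. Ratios with a zero denominator are
#' reported as `NA` and flagged in `undefined`.
#'
#' @param predictions Character vector of predicted labels (or a prediction
#'   tibble from [predict.mignet_model()], whose `pred_label` is used).
#' @param truth Character vector of true labels (`TRUE_IMPACT` /
#'   `FALSE_EVENT`; `UNVERIFIED` is an error).
#' @param counts Alternatively, a named vector/list with `tp`, `fp`, `tn`,
#'   `fn`.
#' @return A `confusion_metrics` object; see [tidy.confusion_metrics()].
#' @export
#' @examples
#' confusion(counts = c(tp = 38, fp = 6, tn = 409, fn = 12))
confusion <- function(predictions = NULL, truth = NULL, counts = NULL) {
  if (is.null(counts)) {
    if (is.data.frame(predictions)) predictions <- predictions$pred_label
    if (length(predictions) != length(truth)) {
      stop("predictions and truth have different lengths", call. = FALSE)
    }
    if (any(truth == "UNVERIFIED")) {
      stop("truth labels contain UNVERIFIED events; verify or drop them first",
           call. = FALSE)
    }
    bad <- setdiff(unique(c(predictions, truth)),
                   c("TRUE_IMPACT", "FALSE_EVENT"))
    if (length(bad) > 0) {
      stop("unknown label(s): ", paste(bad, collapse = ", "), call. = FALSE)
    }
    tp <- sum(predictions == "TRUE_IMPACT" & truth == "TRUE_IMPACT")
    fp <- sum(predictions == "TRUE_IMPACT" & truth == "FALSE_EVENT")
    tn <- sum(predictions == "FALSE_EVENT" & truth == "FALSE_EVENT")
    fn <- sum(predictions == "FALSE_EVENT" & truth == "TRUE_IMPACT")
  } else {
    counts <- as.list(counts)
    stopifnot(all(c("tp", "fp", "tn", "fn") %in% names(counts)))
    tp <- counts$tp; fp <- counts$fp; tn <- counts$tn; fn <- counts$fn
  }
  m <- list(
    tp = tp, fp = fp, tn = tn, fn = fn,
    n = tp + fp + tn + fn,
    sensitivity = safe_ratio(tp, tp + fn),
    specificity = safe_ratio(tn, tn + fp),
    accuracy = safe_ratio(tp + tn, tp + fp + tn + fn),
    precision = safe_ratio(tp, tp + fp),
    npv = safe_ratio(tn, tn + fn))
  m$undefined <- names(which(vapply(
    m[c("sensitivity", "specificity", "accuracy", "precision", "npv")],
    is.na, logical(1))))
  structure(m, class = "confusion_metrics")
}

#' @export
print.confusion_metrics <- function(x, ...) {
  cat(sprintf("<confusion_metrics> n = %d (TP %d, FP %d, TN %d, FN %d)\n",
              x$n, x$tp, x$fp, x$tn, x$fn))
  cat(format_metrics_line(x), "\n")
  invisible(x)
}

# printed-table style: rates as integer percent, predictive values 2 dp
format_metrics_line <- function(x) {
  pct <- function(v) if (is.na(v)) "NA" else
    sprintf("%d%%", as.integer(round_half_up(100 * v)))
  dec <- function(v) if (is.na(v)) "NA" else
    sprintf("%.2f", round_half_up(v, 2))
  sprintf("sensitivity %s, specificity %s, accuracy %s, PPV %s, NPV %s",
          pct(x$sensitivity), pct(x$specificity), pct(x$accuracy),
          dec(x$precision), dec(x$npv))
}

#' Tidy confusion metrics
#'
#' @param x A `confusion_metrics` object.
#' @param ... Unused.
#' @return A one-row tibble of counts and derived metrics (proportions).
#' @method tidy confusion_metrics
#' @export
tidy.confusion_metrics <- function(x, ...) {
  tibble::tibble(tp = x$tp, fp = x$fp, tn = x$tn, fn = x$fn, n = x$n,
                 sensitivity = x$sensitivity, specificity = x$specificity,
                 accuracy = x$accuracy, precision = x$precision, npv = x$npv)
}

#' Rounded, table-style rendering of confusion metrics
#'
#' Rates (sensitivity, specificity, accuracy) are rendered as integer
#' percentages and predictive values (PPV, NPV) to two decimals, matching the
#' conventional reporting style; undefined cells render as `"NA"`.
#'
#' @param x A `confusion_metrics` object.
#' @return A one-row tibble of character cells plus the raw counts.
#' @export
format_confusion <- function(x) {
  stopifnot(inherits(x, "confusion_metrics"))
  pct <- function(v) if (is.na(v)) "NA" else
    sprintf("%d%%", as.integer(round_half_up(100 * v)))
  dec <- function(v) if (is.na(v)) "NA" else
    sprintf("%.2f", round_half_up(v, 2))
  tibble::tibble(
    TP = x$tp, FP = x$fp, TN = x$tn, FN = x$fn,
    Sensitivity = pct(x$sensitivity), Specificity = pct(x$specificity),
    Accuracy = pct(x$accuracy), PPV = dec(x$precision), NPV = dec(x$npv))
}

#' Side-by-side comparison of model evaluation reports
#'
#' @param reports Named list of `confusion_metrics` objects, one per
#'   (model, test-set) pair.
#' @return A tibble with one row per report: counts, the four headline
#'   metrics and NPV, rendered in the printed-table style (integer-percent
#'   rates, two-decimal predictive values).
#' @export
#' @examples
#' compare_models(list(
#'   m4 = confusion(counts = c(tp = 38, fp = 6, tn = 409, fn = 12)),
#'   m1 = confusion(counts = c(tp = 35, fp = 5, tn = 410, fn = 15))))
compare_models <- function(reports) {
  stopifnot(is.list(reports), length(reports) >= 1)
  if (is.null(names(reports)) || any(names(reports) == "")) {
    names(reports) <- paste0("model_", seq_along(reports))
  }
  purrr::map_dfr(names(reports), function(nm) {
    dplyr::bind_cols(tibble::tibble(model = nm),
                     format_confusion(reports[[nm]]))
  })
}
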