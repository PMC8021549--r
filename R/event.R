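# Channel order is fixed package-wide: linear acceleration in g, then angular
# velocity in deg/s. Windows are 200 columns on a 1 kHz grid spanning
# [-50, +150) ms around the trigger, trigger at 0-based column 50.
mg_channels <- function() {
  c("lin_acc_x", "lin_acc_y", "lin_acc_z", "ang_vel_x", "ang_vel_y", "ang_vel_z")
}

mg_const <- list(
  n_samples     = 200L,
  fs_lin        = 1000,   # Hz, accelerometer
  fs_ang        = 8000,   # Hz, gyroscope
  pre_ms        = 50,
  post_ms       = 150,
  trigger_col   = 51L,    # 1-based; 0-based column 50
  trigger_g     = 10,
  lin_range_g   = 400,    # sensor clip, +/- g
  ang_range_dps = 4000    # sensor clip, +/- deg/s
)

mg_labels <- function() c("TRUE_IMPACT", "FALSE_EVENT", "UNVERIFIED")

#' Construct a single kinematic event
#'
#' A kinematic event is one triggered recording from an instrumented
#' mouthguard: a 6 x 200 matrix of head kinematics (rows `lin_acc_x/y/z` in g,
#' `ang_vel_x/y/z` in deg/s) on a uniform 1 kHz grid spanning 50 ms before to
#' 150 ms after the trigger, plus identifying metadata and a verification
#' label. Events are represented as rows of a tibble with the matrix held in a
#' `samples` list-column, so collections of events pipe through dplyr verbs.
#'
#' @param samples Numeric 6 x 200 matrix; rows ordered `lin_acc_x`,
#'   `lin_acc_y`, `lin_acc_z` (g), `ang_vel_x`, `ang_vel_y`, `ang_vel_z`
#'   (deg/s); columns on the 1 kHz grid with the trigger at column 51
#'   (0-based 50).
#' @param event_id,device_id Opaque identifier strings.
#' @param trigger_time_s Trigger time in seconds, session-relative.
#' @param label One of `"TRUE_IMPACT"`, `"FALSE_EVENT"`, `"UNVERIFIED"`.
#' @param group_key Opaque string identifying the originating recording
#'   (player/session); used for leakage-safe splits.
#' @param check Validate invariants (default `TRUE`). Events read from files
#'   are shape-checked only (`check = "shape"`), since a stored window need
#'   not retain a super-threshold sample.
#'
#' @return A one-row event tibble.
#' @seealso [validate_events()], [generate_dataset()]
#' @export
#' @examples
#' ev <- simulate_true_impact(impact_params(peak_lin_acc = 30), seed = 1)
#' ev$samples[[1]][1:3, 48:54]
kinematic_event <- function(samples, event_id, device_id = "sim",
                            trigger_time_s = 0, label = "UNVERIFIED",
                            group_key = event_id, check = TRUE) {
  tbl <- tibble::tibble(
    event_id       = as.character(event_id),
    device_id      = as.character(device_id),
    trigger_time_s = as.numeric(trigger_time_s),
    label          = as.character(label),
    group_key      = as.character(group_key),
    samples        = list(unname(as.matrix(samples)))
  )
  if (!isFALSE(check)) {
    validate_events(tbl, shape_only = identical(check, "shape"))
  }
  tbl
}

#' Validate an event tibble against the kinematic-event invariants
#'
#' Checks, for every event: a finite 6 x 200 `samples` matrix; linear
#' acceleration within the +/- 400 g sensor range and angular velocity within
#' +/- 4000 deg/s; a known label; and (unless `shape_only`) at least one
#' linear-acceleration sample at or after the trigger column exceeding the
#' 10 g trigger threshold in absolute value.
#'
#' @param events An event tibble (see [kinematic_event()]).
#' @param shape_only Only enforce shape/finiteness/range, not the trigger
#'   invariant; used for events reconstructed from files.
#' @param threshold Trigger threshold in g for the trigger invariant.
#'
#' @return `events`, invisibly, if valid; otherwise an error naming the first
#'   offending event.
#' @export
validate_events <- function(events, shape_only = FALSE,
                            threshold = mg_const$trigger_g) {
  stopifnot(is.data.frame(events))
  need <- c("event_id", "device_id", "trigger_time_s", "label", "group_key",
            "samples")
  miss <- setdiff(need, names(events))
  if (length(miss) > 0) {
    stop("event tibble is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  bad_label <- setdiff(unique(events$label), mg_labels())
  if (length(bad_label) > 0) {
    stop("unknown label(s): ", paste(bad_label, collapse = ", "), call. = FALSE)
  }
  for (i in seq_len(nrow(events))) {
    m  <- events$samples[[i]]
    id <- events$event_id[i]
    if (!is.matrix(m) || !is.numeric(m) ||
        nrow(m) != 6L || ncol(m) != mg_const$n_samples) {
      stop(sprintf("event '%s': samples must be a numeric 6 x %d matrix", id,
                   mg_const$n_samples), call. = FALSE)
    }
    if (!all(is.finite(m))) {
      stop(sprintf("event '%s': non-finite sample values", id), call. = FALSE)
    }
    if (max(abs(m[1:3, ])) > mg_const$lin_range_g + 1e-9) {
      stop(sprintf("event '%s': linear acceleration outside +/- %g g", id,
                   mg_const$lin_range_g), call. = FALSE)
    }
    if (max(abs(m[4:6, ])) > mg_const$ang_range_dps + 1e-9) {
      stop(sprintf("event '%s': angular velocity outside +/- %g deg/s", id,
                   mg_const$ang_range_dps), call. = FALSE)
    }
    if (!shape_only) {
      post <- m[1:3, mg_const$trigger_col:mg_const$n_samples, drop = FALSE]
      if (max(abs(post)) <= threshold) {
        stop(sprintf(
          "event '%s': no linear-acceleration sample at/after the trigger column exceeds %g g",
          id, threshold), call. = FALSE)
      }
    }
  }
  invisible(events)
}

#' Millisecond time axis of an event window
#'
#' @param pre_ms,post_ms Window extent in ms (defaults 50 pre / 150 post).
#' @return Numeric vector of sample times in ms relative to the trigger
#'   (half-open `[-pre_ms, post_ms)` at 1 kHz).
#' @export
event_time_ms <- function(pre_ms = mg_const$pre_ms, post_ms = mg_const$post_ms) {
  seq(-pre_ms, post_ms - 1)
}

# Stack an event tibble into a (time, event, channel) array for the network.
events_to_array <- function(events) {
  n <- nrow(events)
  x <- array(0, dim = c(mg_const$n_samples, n, 6L))
  for (i in seq_len(n)) x[, i, ] <- t(events$samples[[i]])
  x
}

# 0/1 targets with TRUE_IMPACT as the positive class.
events_to_target <- function(events) {
  if (any(events$label == "UNVERIFIED")) {
    stop("events carry UNVERIFIED labels; label them before training/evaluation",
         call. = FALSE)
  }
  as.integer(events$label == "TRUE_IMPACT")
}
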