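#' Construct a continuous dual-rate session trace
#'
#' A session trace is the continuous recording the onboard trigger watches:
#' linear acceleration sampled at 1000 Hz and angular velocity at 8000 Hz
#' over the same duration, so the angular block always holds exactly eight
#' times as many samples per channel as the linear block.
#'
#' @param lin_acc Numeric 3 x N matrix, g, 1000 Hz.
#' @param ang_vel Numeric 3 x (8 N) matrix, deg/s, 8000 Hz.
#' @param start_time Session start in seconds.
#' @param device_id Opaque device identifier.
#'
#' @return A `session_trace` object.
#' @seealso [detect_events()], [simulate_session()]
#' @export
session_trace <- function(lin_acc, ang_vel, start_time = 0, device_id = "sim") {
  lin_acc <- as.matrix(lin_acc)
  ang_vel <- as.matrix(ang_vel)
  stopifnot(nrow(lin_acc) == 3L, nrow(ang_vel) == 3L)
  if (ncol(ang_vel) != 8L * ncol(lin_acc)) {
    stop("dual-rate misalignment: angular block must hold 8 samples per linear sample",
         call. = FALSE)
  }
  structure(
    list(lin_acc = unname(lin_acc), ang_vel = unname(ang_vel),
         start_time = as.numeric(start_time), device_id = as.character(device_id),
         fs_lin = mg_const$fs_lin, fs_ang = mg_const$fs_ang),
    class = "session_trace"
  )
}

#' @export
print.session_trace <- function(x, ...) {
  cat(sprintf(
    "<session_trace> device %s: %.3f s (%d samples @ %g Hz linear, %d @ %g Hz angular)\n",
    x$device_id, ncol(x$lin_acc) / x$fs_lin, ncol(x$lin_acc), x$fs_lin,
    ncol(x$ang_vel), x$fs_ang))
  invisible(x)
}

#' Trigger/windowing configuration for the onboard recorder
#'
#' The recorder stores an event when any linear-acceleration component
#' exceeds `threshold` in absolute value, retaining `pre_window` ms before and
#' `post_window` ms after the trigger. `refractory` suppresses re-triggering
#' for that many ms after a stored trigger, so a single oscillating transient
#' does not spawn overlapping duplicate windows.
#'
#' @param threshold Trigger level in g (default 10).
#' @param pre_window,post_window Retained window before/after the trigger, ms
#'   (defaults 50 and 150; together the standard 200-sample window at 1 kHz).
#' @param refractory Dead time after a trigger, ms (default 200, one window).
#'
#' @return A `trigger_config` list.
#' @export
trigger_config <- function(threshold = 10, pre_window = 50, post_window = 150,
                           refractory = 200) {
  stopifnot(threshold > 0, pre_window >= 0, post_window > 0, refractory >= 0)
  structure(list(threshold = threshold, pre_window = pre_window,
                 post_window = post_window, refractory = refractory),
            class = "trigger_config")
}

# 8 kHz -> 1 kHz: 8-sample boxcar anti-alias then take every 8th mean.
# Implemented as non-overlapping block means (phase-aligned with the linear grid).
decimate_ang <- function(ang_vel) {
  n1 <- ncol(ang_vel) %/% 8L
  out <- matrix(0, 3L, n1)
  for (r in 1:3) {
    out[r, ] <- colMeans(matrix(ang_vel[r, seq_len(8L * n1)], nrow = 8L))
  }
  out
}

#' Emulate the onboard trigger on a continuous trace
#'
#' Scans the 1 kHz linear-acceleration stream sample by sample; a trigger
#' fires at the first sample where any component exceeds the threshold in
#' absolute value, provided no trigger fired within the preceding refractory
#' interval. Each trigger yields one 6 x 200 event window
#' (`[-pre_window, +post_window)` on the 1 kHz grid); the 8 kHz angular stream
#' is anti-aliased with an 8-sample boxcar and decimated onto the same grid so
#' all six channels share the 200 columns. Windows that would extend past
#' either end of the trace are dropped (with a warning) rather than padded.
#'
#' @param trace A [session_trace()].
#' @param cfg A [trigger_config()].
#'
#' @return An event tibble (possibly zero rows) of `UNVERIFIED` events, one
#'   per trigger, with `trigger_time_s` session-relative.
#' @export
#' @examples
#' sim <- simulate_session(n_impacts = 2, n_artifacts = 1, duration = 30, seed = 1)
#' detect_events(sim$trace, trigger_config())
detect_events <- function(trace, cfg = trigger_config()) {
  stopifnot(inherits(trace, "session_trace"), inherits(cfg, "trigger_config"))
  if (!all(is.finite(trace$lin_acc)) || !all(is.finite(trace$ang_vel))) {
    stop("trace contains non-finite samples; refusing to scan", call. = FALSE)
  }
  fs <- trace$fs_lin
  pre  <- round(cfg$pre_window * fs / 1000)
  post <- round(cfg$post_window * fs / 1000)
  wlen <- pre + post
  n <- ncol(trace$lin_acc)
  empty <- kinematic_event(matrix(0, 6, mg_const$n_samples), "x", check = FALSE)[0, ]
  if (n < wlen) {
    warning("trace shorter than one full window; no events emitted")
    return(empty)
  }

  crossing <- matrixStats_colmax_abs(trace$lin_acc) > cfg$threshold
  refr <- round(cfg$refractory * fs / 1000)
  trig <- integer(0)
  last <- -Inf
  for (i in which(crossing)) {
    if (i - last > refr) {
      trig <- c(trig, i)
      last <- i
    }
  }
  if (length(trig) == 0) return(empty)

  ang1k <- decimate_ang(trace$ang_vel)
  dropped <- 0L
  rows <- list()
  for (t0 in trig) {
    lo <- t0 - pre
    hi <- t0 + post - 1L
    if (lo < 1L || hi > n) {
      dropped <- dropped + 1L
      next
    }
    m <- rbind(trace$lin_acc[, lo:hi, drop = FALSE],
               ang1k[, lo:hi, drop = FALSE])
    rows[[length(rows) + 1L]] <- kinematic_event(
      m,
      event_id = sprintf("%s_evt%04d", trace$device_id, length(rows) + 1L),
      device_id = trace$device_id,
      trigger_time_s = trace$start_time + (t0 - 1L) / fs,
      label = "UNVERIFIED",
      group_key = trace$device_id,
      check = "shape"
    )
  }
  if (dropped > 0) {
    warning(sprintf("%d trigger(s) dropped: window extends beyond the trace", dropped))
  }
  if (length(rows) == 0) empty else dplyr::bind_rows(rows)
}

# max |value| per column across the 3 axes, without allocating abs() twice
matrixStats_colmax_abs <- function(m) {
  pmax(abs(m[1, ]), abs(m[2, ]), abs(m[3, ]))
}
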