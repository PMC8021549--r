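# Event CSVs are long format: one row per sample, 200 rows per event.
# Numeric cells are written with 6 significant digits, so a write/read round
# trip is the identity up to that text precision.

raw_cols <- function() {
  c("event_id", "device_id", "trigger_time_s", "sample_index", "t_ms",
    "lin_acc_x_g", "lin_acc_y_g", "lin_acc_z_g",
    "ang_vel_x_dps", "ang_vel_y_dps", "ang_vel_z_dps", "label", "group_key")
}

# Harmonized (common-data-element style) names for the cde schema. The exact
# NINDS CDE identifiers for raw kinematic samples are not public; these names
# follow the CDE naming style and ship with a sidecar data dictionary.
cde_map <- function() {
  c(event_id       = "HeadImpactEventID",
    device_id      = "SensorDeviceID",
    trigger_time_s = "EventTriggerTimeVal",
    sample_index   = "SampleIndexVal",
    t_ms           = "SampleRelativeTimeVal",
    lin_acc_x_g    = "LinearAccelerationXVal",
    lin_acc_y_g    = "LinearAccelerationYVal",
    lin_acc_z_g    = "LinearAccelerationZVal",
    ang_vel_x_dps  = "AngularVelocityXVal",
    ang_vel_y_dps  = "AngularVelocityYVal",
    ang_vel_z_dps  = "AngularVelocityZVal",
    label          = "ImpactVideoConfirmationTyp",
    group_key      = "RecordingGroupID")
}

cde_dictionary <- function() {
  tibble::tibble(
    cde_name    = unname(cde_map()),
    raw_name    = names(cde_map()),
    description = c(
      "Unique identifier of the triggered event",
      "Identifier of the recording mouthguard device",
      "Session-relative trigger time",
      "0-based sample index within the event window",
      "Sample time relative to the trigger",
      "Linear acceleration, device x axis",
      "Linear acceleration, device y axis",
      "Linear acceleration, device z axis",
      "Angular velocity, device x axis",
      "Angular velocity, device y axis",
      "Angular velocity, device z axis",
      "Event verification label (TRUE_IMPACT / FALSE_EVENT / UNVERIFIED)",
      "Identifier of the originating recording, for grouped splits"),
    units = c("", "", "s", "", "ms", "g", "g", "g",
              "deg/s", "deg/s", "deg/s", "", "")
  )
}

fmt_num <- function(x) {
  out <- formatC(signif(x, 6), format = "g", digits = 6)
  gsub(" ", "", out)
}

#' Write an event dataset to CSV
#'
#' Long format, one row per sample (200 rows per event), deterministic column
#' order and 6-significant-digit numeric formatting, so identical input
#' produces byte-identical files. The `raw` schema uses plain unit-suffixed
#' column names; the `cde` schema writes the same data under harmonized
#' common-data-element style names and drops a sidecar data dictionary
#' (`<path>.dictionary.csv`) mapping every column to a description and unit.
#' Device/subject identifiers pass through as given; anonymization is the
#' caller's responsibility.
#'
#' @param events An event tibble.
#' @param path Output file path.
#' @param schema `"raw"` or `"cde"`.
#'
#' @return `path`, invisibly.
#' @seealso [read_events_csv()]
#' @export
write_events_csv <- function(events, path, schema = c("raw", "cde")) {
  schema <- match.arg(schema)
  validate_events(events, shape_only = TRUE)
  t_ms <- event_time_ms()
  long <- purrr::map_dfr(seq_len(nrow(events)), function(i) {
    m <- events$samples[[i]]
    tibble::tibble(
      event_id = events$event_id[i], device_id = events$device_id[i],
      trigger_time_s = fmt_num(rep(events$trigger_time_s[i], ncol(m))),
      sample_index = 0:(ncol(m) - 1L), t_ms = t_ms,
      lin_acc_x_g = fmt_num(m[1, ]), lin_acc_y_g = fmt_num(m[2, ]),
      lin_acc_z_g = fmt_num(m[3, ]),
      ang_vel_x_dps = fmt_num(m[4, ]), ang_vel_y_dps = fmt_num(m[5, ]),
      ang_vel_z_dps = fmt_num(m[6, ]),
      label = events$label[i], group_key = events$group_key[i])
  })
  if (nrow(events) == 0) {
    long <- tibble::as_tibble(stats::setNames(
      rep(list(character(0)), length(raw_cols())), raw_cols()))
  }
  if (schema == "cde") {
    names(long) <- unname(cde_map()[names(long)])
    readr::write_csv(cde_dictionary(), paste0(path, ".dictionary.csv"),
                     progress = FALSE)
  }
  readr::write_csv(long, path, progress = FALSE)
  invisible(path)
}

#' Read an event dataset from CSV
#'
#' Reads files produced by [write_events_csv()] (either schema). Windows are
#' shape-validated (6 channels x 200 samples); the label column is optional
#' and defaults to `UNVERIFIED`; a missing group key defaults to the event id.
#' Malformed input — wrong columns, non-numeric cells, or an event with a
#' window of other than 200 rows — raises a parse error naming the offending
#' event and line.
#'
#' @param path CSV file path.
#' @param schema `"raw"` or `"cde"`.
#'
#' @return An event tibble.
#' @export
read_events_csv <- function(path, schema = c("raw", "cde")) {
  schema <- match.arg(schema)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                        progress = FALSE)
  if (schema == "cde") {
    rev_map <- stats::setNames(names(cde_map()), unname(cde_map()))
    known <- names(df) %in% names(rev_map)
    names(df)[known] <- rev_map[names(df)[known]]
  }
  required <- setdiff(raw_cols(), c("label", "group_key"))
  miss <- setdiff(required, names(df))
  if (length(miss) > 0) {
    stop("event CSV is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (!"label" %in% names(df)) df$label <- "UNVERIFIED"
  if (!"group_key" %in% names(df)) df$group_key <- df$event_id
  if (nrow(df) == 0) {
    return(kinematic_event(matrix(0, 6, mg_const$n_samples), "x", check = FALSE)[0, ])
  }

  num_cols <- c("trigger_time_s", "sample_index",
                "lin_acc_x_g", "lin_acc_y_g", "lin_acc_z_g",
                "ang_vel_x_dps", "ang_vel_y_dps", "ang_vel_z_dps")
  for (cl in num_cols) {
    v <- suppressWarnings(as.numeric(df[[cl]]))
    bad <- which(is.na(v) & !is.na(df[[cl]]) | is.na(df[[cl]]))
    if (length(bad) > 0) {
      stop(sprintf("event '%s', line %d: non-numeric value in column '%s'",
                   df$event_id[bad[1]], bad[1] + 1L, cl), call. = FALSE)
    }
    df[[cl]] <- v
  }

  ids <- unique(df$event_id)
  rows <- purrr::map(ids, function(id) {
    sub <- df[df$event_id == id, ]
    if (nrow(sub) != mg_const$n_samples) {
      first_line <- which(df$event_id == id)[1] + 1L
      stop(sprintf("event '%s' (line %d): window has %d rows, expected %d",
                   id, first_line, nrow(sub), mg_const$n_samples), call. = FALSE)
    }
    sub <- sub[order(sub$sample_index), ]
    m <- t(as.matrix(sub[, c("lin_acc_x_g", "lin_acc_y_g", "lin_acc_z_g",
                             "ang_vel_x_dps", "ang_vel_y_dps", "ang_vel_z_dps")]))
    kinematic_event(m, event_id = id, device_id = sub$device_id[1],
                    trigger_time_s = sub$trigger_time_s[1],
                    label = sub$label[1], group_key = sub$group_key[1],
                    check = "shape")
  })
  out <- dplyr::bind_rows(rows)
  validate_events(out, shape_only = TRUE)
  out
}

#' Write / read a session trace as a pair of CSV files
#'
#' The dual-rate trace is stored as two plain CSVs sharing a basename:
#' `<path>_lin1000hz.csv` (`t_s, lin_acc_x_g, lin_acc_y_g, lin_acc_z_g`) and
#' `<path>_ang8000hz.csv` (`t_s, ang_vel_x_dps, ang_vel_y_dps, ang_vel_z_dps`).
#'
#' @param trace A [session_trace()].
#' @param path Basename (no extension) for the file pair.
#' @return `path` invisibly (write) or a `session_trace` (read).
#' @export
write_session_csv <- function(trace, path) {
  stopifnot(inherits(trace, "session_trace"))
  n <- ncol(trace$lin_acc)
  lin <- tibble::tibble(
    t_s = fmt_num(trace$start_time + (0:(n - 1)) / trace$fs_lin),
    lin_acc_x_g = fmt_num(trace$lin_acc[1, ]),
    lin_acc_y_g = fmt_num(trace$lin_acc[2, ]),
    lin_acc_z_g = fmt_num(trace$lin_acc[3, ]))
  m <- ncol(trace$ang_vel)
  ang <- tibble::tibble(
    t_s = fmt_num(trace$start_time + (0:(m - 1)) / trace$fs_ang),
    ang_vel_x_dps = fmt_num(trace$ang_vel[1, ]),
    ang_vel_y_dps = fmt_num(trace$ang_vel[2, ]),
    ang_vel_z_dps = fmt_num(trace$ang_vel[3, ]))
  readr::write_csv(lin, paste0(path, "_lin1000hz.csv"), progress = FALSE)
  readr::write_csv(ang, paste0(path, "_ang8000hz.csv"), progress = FALSE)
  invisible(path)
}

#' @rdname write_session_csv
#' @param device_id Device identifier to attach on read.
#' @export
read_session_csv <- function(path, device_id = "file") {
  lin <- readr::read_csv(paste0(path, "_lin1000hz.csv"),
                         col_types = "dddd", progress = FALSE)
  ang <- readr::read_csv(paste0(path, "_ang8000hz.csv"),
                         col_types = "dddd", progress = FALSE)
  session_trace(t(as.matrix(lin[, 2:4])), t(as.matrix(ang[, 2:4])),
                start_time = lin$t_s[1], device_id = device_id)
}
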