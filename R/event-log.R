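#' Read an annotation event log
#'
#' An event log is a UTF-8 CSV with one row per coded interval and columns
#' `session_id, participant_id, coder_id, group, behavior, modifier,
#' start_s, stop_s`. Within one `(session, participant, coder, group)` stream
#' the events are mutually exclusive timed states; exhaustiveness is achieved
#' through each group's "none" behavior. Intervals are half-open
#' `[start_s, stop_s)`: a boundary instant belongs to the following event.
#'
#' Rows that do not conform are reported, never silently dropped: an unknown
#' behavior code or a non-positive interval raises an error naming the row.
#' An empty modifier defaults to `"neutral"`, and modifiers on "none"
#' behaviors are forced to neutral (affect is only coded on directional
#' behaviors).
#'
#' @param path CSV file path.
#' @param scheme An [elicse_scheme()].
#' @return A tibble of events sorted by stream key and `start_s`.
#' @export
read_event_log <- function(path, scheme = elicse_scheme()) {
  df <- readr::read_csv(path, col_types = readr::cols(
    session_id = readr::col_character(),
    participant_id = readr::col_character(),
    coder_id = readr::col_character(),
    group = readr::col_character(),
    behavior = readr::col_character(),
    modifier = readr::col_character(),
    start_s = readr::col_double(),
    stop_s = readr::col_double()
  ))
  as_event_log(df, scheme)
}

#' Validate and normalize a data frame of annotation events
#'
#' @param x Data frame with the eight event-log columns.
#' @inheritParams read_event_log
#' @return A tibble of events sorted by stream key and `start_s`.
#' @export
as_event_log <- function(x, scheme = elicse_scheme()) {
  required <- c(
    "session_id", "participant_id", "coder_id", "group",
    "behavior", "modifier", "start_s", "stop_s"
  )
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols) > 0) {
    abort(paste0("event log lacks columns: ", paste(missing_cols, collapse = ", ")))
  }
  ev <- tibble::as_tibble(x)[, required]
  ev$modifier[is.na(ev$modifier) | ev$modifier == ""] <- "neutral"

  bad_mod <- !ev$modifier %in% scheme$modifiers
  if (any(bad_mod)) {
    abort(paste0(
      "unknown modifier in rows: ",
      paste(utils::head(which(bad_mod), 5), collapse = ", ")
    ))
  }
  grp_map <- scheme_group_map(scheme)
  unknown <- !ev$behavior %in% names(grp_map)
  if (any(unknown)) {
    abort(paste0(
      "unknown behavior code(s) ",
      paste(unique(ev$behavior[unknown]), collapse = ", "),
      " in rows: ", paste(utils::head(which(unknown), 5), collapse = ", ")
    ))
  }
  wrong_group <- grp_map[ev$behavior] != ev$group
  if (any(wrong_group)) {
    abort(paste0(
      "behavior declared in the wrong group in rows: ",
      paste(utils::head(which(wrong_group), 5), collapse = ", ")
    ))
  }
  bad_iv <- !(ev$stop_s > ev$start_s) | ev$start_s < 0 | is.na(ev$start_s) | is.na(ev$stop_s)
  if (any(bad_iv)) {
    abort(paste0(
      "invalid interval (need 0 <= start_s < stop_s) in rows: ",
      paste(utils::head(which(bad_iv), 5), collapse = ", ")
    ))
  }
  # affect is only coded on directional behaviors
  none_codes <- scheme_none_codes(scheme)
  ev$modifier[ev$behavior %in% none_codes] <- "neutral"

  dplyr::arrange(
    ev, .data$session_id, .data$participant_id, .data$coder_id,
    .data$group, .data$start_s
  )
}

#' @rdname read_event_log
#' @param events An event-log tibble.
#' @export
write_event_log <- function(events, path) {
  readr::write_csv(events, path)
  invisible(path)
}

#' Observation duration per session
#'
#' If no duration table is supplied to downstream operations, the session
#' duration is taken as the latest `stop_s` recorded in any stream of the
#' session.
#'
#' @param events Event-log tibble.
#' @return Tibble with columns `session_id`, `duration_s`.
#' @export
session_durations <- function(events) {
  events %>%
    group_by(.data$session_id) %>%
    summarise(duration_s = max(.data$stop_s), .groups = "drop")
}

resolve_durations <- function(events, durations = NULL) {
  if (is.null(durations)) {
    return(session_durations(events))
  }
  stopifnot(all(c("session_id", "duration_s") %in% names(durations)))
  tibble::as_tibble(durations)[, c("session_id", "duration_s")]
}

#' Validate behavior streams
#'
#' Checks the two stream invariants: mutual exclusivity (no overlapping
#' events within one `(session, participant, coder, group)` stream) and
#' exhaustiveness (the events cover `[0, duration_s]`). Every overlap and
#' every gap wider than `gap_tolerance_s` is reported as an error; narrower
#' gaps are reported as warnings. Nothing is auto-filled: coding errors must
#' surface.
#'
#' @param events Event-log tibble.
#' @param scheme An [elicse_scheme()].
#' @param durations Optional tibble `(session_id, duration_s)`; defaults to
#'   [session_durations()].
#' @param gap_tolerance_s Maximum tolerated coverage gap, in seconds.
#' @return A `stream_validation` object: a tibble of problems with columns
#'   `session_id, participant_id, coder_id, group, kind, start_s, stop_s,
#'   severity`, with attributes. Use [is_valid()] to test for absence of
#'   errors.
#' @export
validate_streams <- function(events, scheme = elicse_scheme(), durations = NULL,
                             gap_tolerance_s = 0.04) {
  stopifnot(gap_tolerance_s >= 0)
  durations <- resolve_durations(events, durations)
  keys <- c("session_id", "participant_id", "coder_id", "group")

  problems <- events %>%
    left_join(durations, by = "session_id") %>%
    group_by(across(all_of(keys))) %>%
    group_split() %>%
    purrr::map(stream_problems, gap_tolerance_s = gap_tolerance_s) %>%
    bind_rows()

  if (nrow(problems) == 0) {
    problems <- tibble(
      session_id = character(), participant_id = character(),
      coder_id = character(), group = character(), kind = character(),
      start_s = double(), stop_s = double(), severity = character()
    )
  }
  problems <- dplyr::arrange(
    problems, .data$session_id, .data$participant_id, .data$coder_id,
    .data$group, .data$start_s
  )
  structure(problems,
    gap_tolerance_s = gap_tolerance_s,
    class = c("stream_validation", class(problems))
  )
}

stream_problems <- function(stream, gap_tolerance_s) {
  stream <- dplyr::arrange(stream, .data$start_s, .data$stop_s)
  key <- stream[1, c("session_id", "participant_id", "coder_id", "group")]
  duration <- stream$duration_s[1]
  eps <- 1e-9

  out <- list()
  # overlaps: running maximum of stop vs next start
  run_stop <- cummax(stream$stop_s)
  ov <- which(stream$start_s[-1] < run_stop[-nrow(stream)] - eps)
  for (i in ov) {
    out[[length(out) + 1L]] <- mutate(key,
      kind = "overlap",
      start_s = stream$start_s[i + 1L],
      stop_s = min(run_stop[i], stream$stop_s[i + 1L]),
      severity = "error"
    )
  }
  # coverage gaps over [0, duration]
  bounds_lo <- c(0, run_stop)
  bounds_hi <- c(stream$start_s, duration)
  gaps <- which(bounds_hi - bounds_lo > eps)
  for (i in gaps) {
    width <- bounds_hi[i] - bounds_lo[i]
    out[[length(out) + 1L]] <- mutate(key,
      kind = "gap",
      start_s = bounds_lo[i],
      stop_s = bounds_hi[i],
      severity = if (width > gap_tolerance_s) "error" else "warning"
    )
  }
  bind_rows(out)
}

#' @rdname validate_streams
#' @param report A `stream_validation` object.
#' @return `is_valid()`: `TRUE` iff the report contains no errors.
#' @export
is_valid <- function(report) {
  stopifnot(inherits(report, "stream_validation"))
  !any(report$severity == "error")
}

#' @export
print.stream_validation <- function(x, ...) {
  n_err <- sum(x$severity == "error")
  n_warn <- sum(x$severity == "warning")
  cat("<stream_validation> ", n_err, " error(s), ", n_warn, " warning(s)\n", sep = "")
  if (nrow(x) > 0) print(tibble::as_tibble(x), ...)
  invisible(x)
}

#' Discretize streams into fixed-resolution state sequences
#'
#' Each stream is sampled on a regular grid of `ceiling(duration /
#' resolution)` bins; a bin is labeled with the state active at its midpoint
#' (half-open event intervals, so a midpoint on an event boundary takes the
#' later event). If a midpoint falls inside a sub-tolerance coverage gap the
#' label of the most recent preceding event is carried forward.
#'
#' @inheritParams validate_streams
#' @param resolution_s Bin width in seconds.
#' @return Tibble with one row per stream bin: the four key columns, `bin`
#'   (1-based), `t` (bin start time), `behavior`, `modifier`.
#' @export
discretize_streams <- function(events, resolution_s = 0.5, durations = NULL) {
  stopifnot(resolution_s > 0)
  durations <- resolve_durations(events, durations)
  keys <- c("session_id", "participant_id", "coder_id", "group")
  events %>%
    left_join(durations, by = "session_id") %>%
    group_by(across(all_of(keys))) %>%
    group_split() %>%
    purrr::map(discretize_one, resolution_s = resolution_s) %>%
    bind_rows()
}

discretize_one <- function(stream, resolution_s) {
  stream <- dplyr::arrange(stream, .data$start_s)
  duration <- stream$duration_s[1]
  n_bins <- ceiling(duration / resolution_s - 1e-9)
  mids <- (seq_len(n_bins) - 0.5) * resolution_s
  # index of last event with start_s <= mid; half-open [start, stop)
  idx <- findInterval(mids, stream$start_s)
  idx[idx == 0L] <- 1L # midpoint before the first event: use the first state
  tibble(
    session_id = stream$session_id[1],
    participant_id = stream$participant_id[1],
    coder_id = stream$coder_id[1],
    group = stream$group[1],
    bin = seq_len(n_bins),
    t = (seq_len(n_bins) - 1) * resolution_s,
    behavior = stream$behavior[idx],
    modifier = stream$modifier[idx]
  )
}
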