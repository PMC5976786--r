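#' Detect Laban body-part-organization patterns
#'
#' Scans each participant-session for episodes where the head turns toward a
#' focus and the torso and arms/hands follow, classifying the organization:
#'
#' * `successive` — adjacent parts recruit one after the other (head, then
#'   torso within `lag_s`, then arms/hands within `lag_s` of the torso);
#' * `sequential` — non-adjacent recruitment (head, then arms/hands within
#'   `lag_s`, with no torso onset in between);
#' * `simultaneous` — all onsets within `epsilon_s` of one another;
#' * `space_hold` — appended after any of the above when every recruited
#'   part keeps the focus for at least `hold_min_s` (the canonical
#'   successive — space hold (with gestures) — successive phrasing: head and
#'   torso locked in space while the arms/hands keep gesturing).
#'
#' @param events Event-log tibble for a single coder.
#' @param scheme An [elicse_scheme()].
#' @param focus Focus label(s) to scan for; defaults to both engaged foci.
#' @param epsilon_s Simultaneity window, seconds.
#' @param lag_s Maximum inter-part onset lag, seconds.
#' @param hold_min_s Minimum space-hold duration, seconds.
#' @param durations Optional `(session_id, duration_s)` tibble.
#' @return Tibble of organization events: `session_id, participant_id, kind,
#'   focus, parts, head_onset_s, torso_onset_s, arms_onset_s, duration_s`.
#' @export
detect_patterns <- function(events, scheme = elicse_scheme(),
                            focus = c("game", "partner"),
                            epsilon_s = 0.5, lag_s = 3, hold_min_s = 5,
                            durations = NULL) {
  stopifnot(epsilon_s < lag_s)
  focus_map <- scheme_focus_map(scheme)
  ev <- events %>%
    mutate(focus = unname(focus_map[.data$behavior])) %>%
    group_by(.data$session_id, .data$participant_id) %>%
    group_split()
  purrr::map(ev, function(ps) {
    purrr::map(focus, function(f) {
      detect_patterns_one(ps, f, epsilon_s, lag_s, hold_min_s)
    }) %>% bind_rows()
  }) %>%
    bind_rows()
}

# merge consecutive same-focus events of one group into focus runs
focus_runs <- function(ps, grp) {
  x <- ps %>%
    filter(.data$group == grp) %>%
    dplyr::arrange(.data$start_s)
  if (nrow(x) == 0) {
    return(tibble(focus = character(), start_s = double(), stop_s = double()))
  }
  new_run <- c(TRUE, x$focus[-1] != x$focus[-nrow(x)] |
    x$start_s[-1] > x$stop_s[-nrow(x)] + 1e-9)
  run_id <- cumsum(new_run)
  x %>%
    mutate(run = run_id) %>%
    group_by(.data$run) %>%
    summarise(
      focus = first(.data$focus), start_s = min(.data$start_s),
      stop_s = max(.data$stop_s), .groups = "drop"
    ) %>%
    select(-"run")
}

detect_patterns_one <- function(ps, f, epsilon_s, lag_s, hold_min_s) {
  head_runs <- filter(focus_runs(ps, "head"), .data$focus == f)
  torso_runs <- filter(focus_runs(ps, "torso"), .data$focus == f)
  arms_runs <- filter(focus_runs(ps, "arms_hands"), .data$focus == f)

  out <- list()
  for (i in seq_len(nrow(head_runs))) {
    h0 <- head_runs$start_s[i]
    h1 <- head_runs$stop_s[i]
    t_cand <- filter(
      torso_runs,
      .data$start_s >= h0 - epsilon_s, .data$start_s <= h0 + lag_s
    )
    a_cand <- filter(
      arms_runs,
      .data$start_s >= h0 - epsilon_s, .data$start_s <= h0 + 2 * lag_s
    )
    t_on <- if (nrow(t_cand) > 0) t_cand$start_s[1] else NA_real_
    t_end <- if (nrow(t_cand) > 0) t_cand$stop_s[1] else NA_real_

    kind <- NA_character_
    a_on <- NA_real_
    a_end <- NA_real_
    parts <- NA_character_

    pick_arms <- function(lo, hi) {
      j <- which(a_cand$start_s > lo & a_cand$start_s <= hi)
      if (length(j) > 0) j[1] else NA_integer_
    }

    if (!is.na(t_on)) {
      ja <- which(abs(a_cand$start_s - h0) <= epsilon_s)
      if (abs(t_on - h0) <= epsilon_s && length(ja) > 0 &&
        abs(a_cand$start_s[ja[1]] - t_on) <= epsilon_s) {
        kind <- "simultaneous"
        a_on <- a_cand$start_s[ja[1]]
        a_end <- a_cand$stop_s[ja[1]]
        parts <- "head+torso+arms_hands"
      } else if (t_on > h0) {
        j <- pick_arms(t_on, t_on + lag_s)
        if (!is.na(j)) {
          kind <- "successive"
          a_on <- a_cand$start_s[j]
          a_end <- a_cand$stop_s[j]
          parts <- "head>torso>arms_hands"
        }
      }
    } else {
      j <- pick_arms(h0, h0 + lag_s)
      if (!is.na(j)) {
        kind <- "sequential"
        a_on <- a_cand$start_s[j]
        a_end <- a_cand$stop_s[j]
        parts <- "head>arms_hands"
      }
    }
    if (is.na(kind)) next

    out[[length(out) + 1L]] <- tibble(
      session_id = ps$session_id[1],
      participant_id = ps$participant_id[1],
      kind = kind, focus = f, parts = parts,
      head_onset_s = h0, torso_onset_s = t_on, arms_onset_s = a_on,
      duration_s = NA_real_
    )

    # space hold: every recruited part keeps f for >= hold_min_s after the
    # organization completes
    t_complete <- max(c(h0, t_on, a_on), na.rm = TRUE)
    hold_end <- min(c(h1, t_end, a_end), na.rm = TRUE)
    if (hold_end - t_complete >= hold_min_s) {
      out[[length(out) + 1L]] <- tibble(
        session_id = ps$session_id[1],
        participant_id = ps$participant_id[1],
        kind = "space_hold", focus = f, parts = parts,
        head_onset_s = h0, torso_onset_s = t_on, arms_onset_s = a_on,
        duration_s = hold_end - t_complete
      )
    }
  }
  bind_rows(out)
}
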