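#' Duration percentages per behavior and modifier
#'
#' For every `(session, participant)` with complete coverage of the three
#' body-part groups, computes the percentage of the observation duration
#' spent in each behavior of the scheme, and the percentage carrying a
#' positive or negative affect modifier. Percentages are taken over the full
#' observation duration, so within each group the behavior percentages sum
#' to 100.
#'
#' @param events Event-log tibble for a single coder.
#' @param scheme An [elicse_scheme()].
#' @param durations Optional `(session_id, duration_s)` tibble.
#' @param activities Optional `(session_id, activity)` tibble with activity
#'   labels (`"cognitive_games"` or `"robot_play"`).
#' @return A tibble with one row per `(session, participant, behavior)`:
#'   `session_id, participant_id, activity, group, behavior, pct,
#'   pct_positive, pct_negative`. Zero-filled over the scheme inventory.
#' @export
duration_table <- function(events, scheme = elicse_scheme(), durations = NULL,
                           activities = NULL) {
  if (dplyr::n_distinct(events$coder_id) > 1) {
    abort("duration_table expects a single coder; filter the log first")
  }
  durations <- resolve_durations(events, durations)

  # completeness: all three groups present for every participant-session
  have <- distinct(events[, c("session_id", "participant_id", "group")])
  need <- tidyr::expand_grid(
    distinct(events[, c("session_id", "participant_id")]),
    group = scheme$groups
  )
  missing <- anti_join(need, have, by = names(need))
  if (nrow(missing) > 0) {
    abort(paste0(
      "missing group stream(s): ",
      paste(missing$session_id, missing$participant_id, missing$group,
        sep = "/", collapse = "; "
      )
    ))
  }

  obs <- events %>%
    left_join(durations, by = "session_id") %>%
    mutate(dur = .data$stop_s - .data$start_s) %>%
    group_by(.data$session_id, .data$participant_id, .data$behavior) %>%
    summarise(
      pct = 100 * sum(.data$dur) / first(.data$duration_s),
      pct_positive = 100 * sum(.data$dur[.data$modifier == "positive"]) /
        first(.data$duration_s),
      pct_negative = 100 * sum(.data$dur[.data$modifier == "negative"]) /
        first(.data$duration_s),
      .groups = "drop"
    )

  frame <- tidyr::expand_grid(
    distinct(events[, c("session_id", "participant_id")]),
    scheme$behaviors[, c("code", "group")]
  ) %>% rename(behavior = "code")

  out <- frame %>%
    left_join(obs, by = c("session_id", "participant_id", "behavior")) %>%
    mutate(across(
      c("pct", "pct_positive", "pct_negative"),
      ~ dplyr::coalesce(.x, 0)
    ))
  out$activity <- if (is.null(activities)) {
    NA_character_
  } else {
    activities$activity[match(out$session_id, activities$session_id)]
  }
  select(
    out, "session_id", "participant_id", "activity", "group", "behavior",
    "pct", "pct_positive", "pct_negative"
  )
}

#' Reduce duration percentages to the six EMODEB engagement scores
#'
#' Applies the fixed data-reduction formulas: behaviors directed toward the
#' game or the partner count as engagement-related, behaviors toward the
#' facilitator/experimenter or toward none of the foci as
#' disengagement-related, yielding one score in `[-100, 100]` per body part;
#' the three affect scores subtract negatively-modified from
#' positively-modified engagement time:
#'
#' * `GAct  = (GP + GG) - (GFE + NoneH)`
#' * `LTAct = (LIP + NRLTG) - NoneT`
#' * `RoAct = (RoP + MG) - (RoFE + NoneAH)`
#' * `GAct_gsup = (GP_pos + GG_pos) - (GP_neg + GG_neg)`
#' * `LTAct_postsup = (LIP_pos + NRLTG_pos) - (LIP_neg + NRLTG_neg)`
#' * `RoAct_qogest = (RoP_pos + MG_pos + SOApos) - (RoP_neg + MG_neg + SOAneg)`
#'
#' The signs-of-affection behaviors (SOApos/SOAneg) enter `RoAct_qogest` as
#' whole-behavior percentages but do not enter `RoAct`; neutral modifier
#' time never enters an affect score.
#'
#' @param dt A duration table from [duration_table()].
#' @return Tibble with one row per `(session, participant)`: `session_id,
#'   participant_id, activity, GAct, LTAct, RoAct, GAct_gsup, LTAct_postsup,
#'   RoAct_qogest`.
#' @export
reduce_scores <- function(dt) {
  p <- function(w, b, col) {
    v <- w[[col]][match(b, w$behavior)]
    if_else(is.na(v), 0, v)
  }
  dt %>%
    group_by(.data$session_id, .data$participant_id, .data$activity) %>%
    group_split() %>%
    purrr::map(function(w) {
      tibble(
        session_id = w$session_id[1],
        participant_id = w$participant_id[1],
        activity = w$activity[1],
        GAct = (p(w, "GP", "pct") + p(w, "GG", "pct")) -
          (p(w, "GFE", "pct") + p(w, "NoneH", "pct")),
        LTAct = (p(w, "LIP", "pct") + p(w, "NRLTG", "pct")) -
          p(w, "NoneT", "pct"),
        RoAct = (p(w, "RoP", "pct") + p(w, "MG", "pct")) -
          (p(w, "RoFE", "pct") + p(w, "NoneAH", "pct")),
        GAct_gsup = (p(w, "GP", "pct_positive") + p(w, "GG", "pct_positive")) -
          (p(w, "GP", "pct_negative") + p(w, "GG", "pct_negative")),
        LTAct_postsup = (p(w, "LIP", "pct_positive") + p(w, "NRLTG", "pct_positive")) -
          (p(w, "LIP", "pct_negative") + p(w, "NRLTG", "pct_negative")),
        RoAct_qogest = (p(w, "RoP", "pct_positive") + p(w, "MG", "pct_positive") +
          p(w, "SOApos", "pct")) -
          (p(w, "RoP", "pct_negative") + p(w, "MG", "pct_negative") +
            p(w, "SOAneg", "pct"))
      )
    }) %>%
    bind_rows()
}

#' Score a whole cohort of participant-sessions
#'
#' Convenience pipeline `duration_table() |> reduce_scores()` with an
#' integrity check that `(session_id, participant_id)` keys are unique.
#'
#' @inheritParams duration_table
#' @return A score table: one row per participant-session with the six
#'   EMODEB scores.
#' @export
score_table <- function(events, scheme = elicse_scheme(), durations = NULL,
                        activities = NULL) {
  out <- reduce_scores(duration_table(events, scheme, durations, activities))
  if (anyDuplicated(out[, c("session_id", "participant_id")])) {
    abort("duplicate (session_id, participant_id) keys in score table")
  }
  out
}

emodeb_score_names <- function() {
  c("GAct", "LTAct", "RoAct", "GAct_gsup", "LTAct_postsup", "RoAct_qogest")
}
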