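#' Engagement weights for the weighted engagement score
#'
#' Default weights reflect the leading role of the head in
#' engagement-related behavior, followed by the arms/hands, with the torso
#' contributing least: head 0.50, torso 0.10, arms/hands 0.40.
#'
#' @param head,torso,arms_hands Non-negative weights summing to 1.
#' @return A named numeric vector of class `engagement_weights`.
#' @export
engagement_weights <- function(head = 0.50, torso = 0.10, arms_hands = 0.40) {
  w <- c(head = head, torso = torso, arms_hands = arms_hands)
  if (any(w < 0) || abs(sum(w) - 1) > 1e-8) {
    abort("engagement weights must be non-negative and sum to 1")
  }
  structure(w, class = c("engagement_weights", "numeric"))
}

engaged_foci <- function() c("game", "partner")

#' Classify an instant of behavior into an engagement level
#'
#' The head leads: a focus counts as engaged only when the head addresses
#' the game or the partner; otherwise the instant is level 0 (no
#' engagement), whatever the torso and arms/hands do. Given an engaged head
#' focus, the level counts the body parts recruited toward it:
#' level 1 head only (passive), level 2 head + torso (readiness),
#' level 3 head + arms/hands (reduced active), level 4 all three (full
#' active) — each with a task variant (game-directed) and a social variant
#' (partner-directed).
#'
#' All arguments are vectorized and recycled to a common length.
#'
#' @param head_focus,torso_focus,arms_focus Focus labels per instant; any of
#'   `partner`, `facilitator_experimenter`, `game`, `none` (and
#'   `affect_gesture` for the arms, which never counts as directed at the
#'   engaged focus).
#' @return Tibble with columns `level` (0–4), `focus` (the engaged focus or
#'   `"none"`), `variant`.
#' @examples
#' classify_instant("game", "game", "game") # full_active_participation
#' @export
classify_instant <- function(head_focus, torso_focus, arms_focus) {
  n <- max(length(head_focus), length(torso_focus), length(arms_focus))
  head_focus <- rep_len(head_focus, n)
  torso_focus <- rep_len(torso_focus, n)
  arms_focus <- rep_len(arms_focus, n)

  engaged <- head_focus %in% engaged_foci()
  torso_at <- engaged & torso_focus == head_focus
  arms_at <- engaged & arms_focus == head_focus
  level <- ifelse(!engaged, 0L,
    ifelse(torso_at & arms_at, 4L,
      ifelse(arms_at, 3L, ifelse(torso_at, 2L, 1L))
    )
  )
  social <- head_focus == "partner"
  variant <- dplyr::case_when(
    level == 0L ~ "no_engagement",
    level == 1L & !social ~ "passive_attention",
    level == 1L & social ~ "social_acknowledgement",
    level == 2L & !social ~ "attentional_readiness",
    level == 2L & social ~ "social_readiness",
    level == 3L & !social ~ "reduced_active_participation",
    level == 3L & social ~ "reduced_active_social_engagement",
    level == 4L & !social ~ "full_active_participation",
    level == 4L & social ~ "full_active_social_engagement"
  )
  tibble(
    level = as.integer(level),
    focus = ifelse(engaged, head_focus, "none"),
    variant = variant
  )
}

#' Affect intensity of an instant
#'
#' Counts +1 for every body part directed at the engaged focus whose affect
#' modifier is positive and -1 for every such part with a negative modifier,
#' giving an integer in `[-3, 3]`: -3 is negative engagement expressed with
#' all three body parts, +3 positive engagement with all three. An instant
#' at level 0 has intensity 0; affect toward non-engaged foci is ignored
#' here.
#'
#' @inheritParams classify_instant
#' @param head_val,torso_val,arms_val Modifier per part:
#'   `positive`/`negative`/`neutral`.
#' @return Integer vector in `[-3, 3]`.
#' @export
affect_intensity <- function(head_focus, torso_focus, arms_focus,
                             head_val, torso_val, arms_val) {
  n <- max(
    length(head_focus), length(torso_focus), length(arms_focus),
    length(head_val), length(torso_val), length(arms_val)
  )
  head_focus <- rep_len(head_focus, n)
  torso_focus <- rep_len(torso_focus, n)
  arms_focus <- rep_len(arms_focus, n)
  head_val <- rep_len(head_val, n)
  torso_val <- rep_len(torso_val, n)
  arms_val <- rep_len(arms_val, n)

  engaged <- head_focus %in% engaged_foci()
  signed <- function(at, val) {
    as.integer(at & val == "positive") - as.integer(at & val == "negative")
  }
  out <- signed(engaged, head_val) +
    signed(engaged & torso_focus == head_focus, torso_val) +
    signed(engaged & arms_focus == head_focus, arms_val)
  as.integer(out)
}

#' Weighted engagement score of an instant
#'
#' Sum of the body-part weights of the parts directed at the engaged focus;
#' 0 when the head is not engaged. With the default weights the score is
#' monotone in level: 0.50 (level 1) < 0.60 (2) < 0.90 (3) < 1.00 (4).
#'
#' @inheritParams classify_instant
#' @param weights An [engagement_weights()] vector.
#' @return Numeric vector in `[0, 1]`.
#' @export
weighted_engagement <- function(head_focus, torso_focus, arms_focus,
                                weights = engagement_weights()) {
  n <- max(length(head_focus), length(torso_focus), length(arms_focus))
  head_focus <- rep_len(head_focus, n)
  torso_focus <- rep_len(torso_focus, n)
  arms_focus <- rep_len(arms_focus, n)
  engaged <- head_focus %in% engaged_foci()
  engaged * (weights[["head"]] +
    weights[["torso"]] * (torso_focus == head_focus) +
    weights[["arms_hands"]] * (arms_focus == head_focus))
}

#' Build a per-bin engagement timeline
#'
#' Discretizes the three body-part streams of each participant-session with
#' a time-sampling technique and classifies every bin: engagement level
#' (0–4) and variant, engaged focus, affect intensity (-3..+3), and weighted
#' engagement score.
#'
#' @param events Event-log tibble for a single coder, with all three groups
#'   per participant-session.
#' @param scheme An [elicse_scheme()].
#' @param resolution_s Sampling resolution, seconds.
#' @param weights An [engagement_weights()] vector.
#' @param durations Optional `(session_id, duration_s)` tibble.
#' @return An `engagement_timeline` tibble: `session_id, participant_id, t,
#'   level, variant, focus, affect, weighted_score`, with the resolution and
#'   weights stored as attributes.
#' @export
build_timeline <- function(events, scheme = elicse_scheme(), resolution_s = 0.5,
                           weights = engagement_weights(), durations = NULL) {
  if (dplyr::n_distinct(events$coder_id) > 1) {
    abort("build_timeline expects a single coder; filter the log first")
  }
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

  focus_map <- scheme_focus_map(scheme)
  bins <- discretize_streams(events, resolution_s, durations) %>%
    mutate(focus = unname(focus_map[.data$behavior])) %>%
    select(
      "session_id", "participant_id", "group", "bin", "t",
      "focus", "modifier"
    ) %>%
    tidyr::pivot_wider(
      names_from = "group",
      values_from = c("focus", "modifier")
    )

  cls <- classify_instant(bins$focus_head, bins$focus_torso, bins$focus_arms_hands)
  out <- bins %>%
    mutate(
      level = cls$level,
      variant = cls$variant,
      focus = cls$focus,
      affect = affect_intensity(
        bins$focus_head, bins$focus_torso, bins$focus_arms_hands,
        bins$modifier_head, bins$modifier_torso, bins$modifier_arms_hands
      ),
      weighted_score = weighted_engagement(
        bins$focus_head, bins$focus_torso, bins$focus_arms_hands, weights
      )
    ) %>%
    select(
      "session_id", "participant_id", "t", "level", "variant", "focus",
      "affect", "weighted_score"
    )
  structure(out,
    resolution_s = resolution_s, weights = weights,
    class = c("engagement_timeline", class(out))
  )
}

#' Summarize an engagement timeline
#'
#' @param timeline An [build_timeline()] result.
#' @return Tibble per `(session, participant)`: percentage of time at each
#'   level (`pct_level_0` .. `pct_level_4`), mean weighted engagement score
#'   and mean affect intensity.
#' @export
timeline_summary <- function(timeline) {
  timeline %>%
    tibble::as_tibble() %>%
    group_by(.data$session_id, .data$participant_id) %>%
    summarise(
      pct_level_0 = 100 * mean(.data$level == 0),
      pct_level_1 = 100 * mean(.data$level == 1),
      pct_level_2 = 100 * mean(.data$level == 2),
      pct_level_3 = 100 * mean(.data$level == 3),
      pct_level_4 = 100 * mean(.data$level == 4),
      mean_weighted = mean(.data$weighted_score),
      mean_affect = mean(.data$affect),
      .groups = "drop"
    )
}
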