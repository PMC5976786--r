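#' Study-design bookkeeping
#'
#' Summarizes a dyadic repeated-measures design: couples each attend
#' `sessions_per_couple` sessions alternating between the two activity
#' types, and a fraction of the recorded sessions is double-coded for
#' inter-rater reliability.
#'
#' @param n_couples Number of dyads.
#' @param sessions_per_couple Sessions per couple.
#' @param session_min Nominal session length, minutes.
#' @param n_irr_sessions Sessions scored by both coders.
#' @return One-row tibble: `n_couples, n_sessions, n_participant_sessions,
#'   footage_hours, irr_sessions, irr_pct`.
#' @examples
#' cohort_design() # 42 sessions, 17.5 h, IRR subset 29%
#' @export
cohort_design <- function(n_couples = 7, sessions_per_couple = 6,
                          session_min = 25, n_irr_sessions = 12) {
  n_sessions <- n_couples * sessions_per_couple
  tibble(
    n_couples = n_couples,
    n_sessions = n_sessions,
    n_participant_sessions = 2L * n_sessions,
    footage_hours = n_sessions * session_min / 60,
    irr_sessions = n_irr_sessions,
    irr_pct = 100 * n_irr_sessions / n_sessions
  )
}

#' Simulate a whole annotation cohort
#'
#' Generates the event log of a paper-sized cohort — 7 couples, 6 sessions
#' each (3 game-based cognitive stimulation, 3 robot-based free play in
#' alternating order), two participants per session, 42 session recordings
#' and 84 participant-sessions — or any other shape. Each participant gets a
#' persistent engagement propensity so that scores vary between subjects;
#' all randomness flows from the single seed.
#'
#' @param paper_sized If `TRUE`, use the 7 x 6 design regardless of
#'   `n_couples`/`sessions_per_couple`.
#' @param n_couples,sessions_per_couple Cohort shape when not paper-sized.
#' @param duration_s Session length in seconds.
#' @param propensity_sd SD (log scale) of the per-participant engagement
#'   propensity.
#' @param seed Integer seed.
#' @param ... Further arguments passed to [simulate_session_streams()].
#' @return List with `events` (one event log for the whole cohort),
#'   `sessions` (tibble `session_id, activity, duration_s`), and `truth`
#'   (per-participant propensities and the generator settings).
#' @export
simulate_cohort <- function(paper_sized = TRUE, n_couples = 7,
                            sessions_per_couple = 6, duration_s = 1320,
                            propensity_sd = 0.35, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  if (paper_sized) {
    n_couples <- 7
    sessions_per_couple <- 6
  }
  participants <- tibble(
    couple = rep(seq_len(n_couples), each = 2),
    participant_id = paste0(
      "c", rep(seq_len(n_couples), each = 2), "_p", rep(c("A", "B"), n_couples)
    ),
    propensity = exp(rnorm(2 * n_couples, 0, propensity_sd))
  )
  sessions <- tidyr::expand_grid(
    couple = seq_len(n_couples),
    session = seq_len(sessions_per_couple)
  ) %>%
    mutate(
      session_id = paste0("c", .data$couple, "_s", .data$session),
      activity = if_else(.data$session %% 2 == 1, "cognitive_games", "robot_play"),
      duration_s = duration_s
    )

  events <- purrr::pmap(
    sessions[, c("couple", "session_id", "activity")],
    function(couple, session_id, activity) {
      who <- filter(participants, .data$couple == .env$couple)
      purrr::map2(who$participant_id, who$propensity, function(pid, prop) {
        simulate_session_streams(
          session_id = session_id, participant_id = pid, coder_id = "c1",
          activity = activity, duration_s = duration_s,
          engagement_propensity = prop, ...
        )
      }) %>% bind_rows()
    }
  ) %>% bind_rows()

  list(
    events = events,
    sessions = sessions[, c("session_id", "activity", "duration_s")],
    truth = list(
      participants = participants,
      duration_s = duration_s,
      propensity_sd = propensity_sd
    )
  )
}
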