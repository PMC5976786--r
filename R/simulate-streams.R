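#' Simulate one participant-session's behavior streams
#'
#' Emulates a 20–25 minute dyadic activity session. The head focus follows a
#' semi-Markov chain over the four foci with gamma dwell times; whenever the
#' head turns to the game or the partner, the torso follows with probability
#' `p_torso` after a short lag and the arms/hands with probability `p_arms`
#' after a further lag (head-led successive organization; when the torso
#' does not follow, the arms may still follow the head directly, yielding
#' sequential organization). Affect bouts superimpose positive/negative
#' modifiers on directional states at an activity-dependent rate, and short
#' signs-of-affection gestures are occasionally carved into the arms/hands
#' stream. Default dwell means are calibrated so that time budgets match the
#' published mean duration percentages (head at game roughly 88% in
#' cognitive games and 73% in robot play).
#'
#' The construction guarantees the stream invariants: full coverage of
#' `[0, duration_s]` and no overlaps within a group.
#'
#' @param session_id,participant_id,coder_id Key labels.
#' @param activity `"cognitive_games"` or `"robot_play"`.
#' @param duration_s Session length, seconds (default 1320 = 22 min).
#' @param head_dwell_mean_s Named vector of mean dwell per focus; defaults
#'   depend on `activity`.
#' @param p_torso,p_arms Follow probabilities per engaged head episode.
#' @param lag_range_s Uniform bounds for inter-part onset lags, seconds.
#' @param affect_rate_per_min Affect bout rate; default 0.2/min in cognitive
#'   games (affect was very rare there) and 2/min in robot play.
#' @param affect_bout_mean_s Mean affect bout length, seconds.
#' @param p_positive Probability a bout (or gesture) is positive.
#' @param soa_rate_per_min Rate of signs-of-affection arm gestures.
#' @param engagement_propensity Multiplier on engaged (game/partner) dwell
#'   means; larger values tilt the session toward engagement.
#' @param dwell_shape Gamma shape of dwell times.
#' @param seed Optional integer seed.
#' @return Event-log tibble for the three group streams.
#' @export
simulate_session_streams <- function(session_id = "s1", participant_id = "p1",
                                     coder_id = "c1",
                                     activity = c("cognitive_games", "robot_play"),
                                     duration_s = 1320,
                                     head_dwell_mean_s = NULL,
                                     p_torso = 0.8, p_arms = 0.9,
                                     lag_range_s = c(0.5, 2.5),
                                     affect_rate_per_min = NULL,
                                     affect_bout_mean_s = 5,
                                     p_positive = 0.9,
                                     soa_rate_per_min = 0.05,
                                     engagement_propensity = 1,
                                     dwell_shape = 2,
                                     seed = NULL) {
  activity <- match.arg(activity)
  if (!is.null(seed)) set.seed(seed)
  stopifnot(duration_s > 0, p_torso >= 0, p_torso <= 1, p_arms >= 0, p_arms <= 1)
  if (is.null(head_dwell_mean_s)) {
    head_dwell_mean_s <- if (activity == "cognitive_games") {
      c(game = 70, partner = 2, facilitator_experimenter = 4, none = 3)
    } else {
      c(game = 55, partner = 10, facilitator_experimenter = 3.5, none = 6.5)
    }
  }
  if (is.null(affect_rate_per_min)) {
    affect_rate_per_min <- if (activity == "cognitive_games") 0.2 else 2
  }
  foci <- elicse_foci()
  stopifnot(all(foci %in% names(head_dwell_mean_s)), all(head_dwell_mean_s > 0))

  # --- head semi-Markov chain ------------------------------------------------
  t <- 0
  f <- "game"
  head_runs <- list()
  while (t < duration_s) {
    mu <- head_dwell_mean_s[[f]] *
      if (f %in% engaged_foci()) engagement_propensity else 1
    dwell <- rgamma(1, shape = dwell_shape, scale = mu / dwell_shape)
    dwell <- max(dwell, 0.25)
    head_runs[[length(head_runs) + 1L]] <-
      tibble(focus = f, start_s = t, stop_s = min(t + dwell, duration_s))
    t <- t + dwell
    f <- sample(setdiff(foci, f), 1)
  }
  head_runs <- bind_rows(head_runs)

  head_beh <- c(
    game = "GG", partner = "GP",
    facilitator_experimenter = "GFE", none = "NoneH"
  )
  torso_beh <- c(game = "NRLTG", partner = "LIP")
  arms_beh <- c(game = "MG", partner = "RoP")

  head_ev <- head_runs %>%
    mutate(behavior = unname(head_beh[.data$focus])) %>%
    select("behavior", "start_s", "stop_s")

  # --- torso / arms follow the head on engaged episodes ---------------------
  torso_iv <- list()
  arms_iv <- list()
  engaged <- filter(head_runs, .data$focus %in% engaged_foci())
  for (i in seq_len(nrow(engaged))) {
    f <- engaged$focus[i]
    h0 <- engaged$start_s[i]
    h1 <- engaged$stop_s[i]
    t_on <- NA_real_
    if (runif(1) < p_torso) {
      t_on <- h0 + runif(1, lag_range_s[1], lag_range_s[2])
      if (t_on < h1 - 0.25) {
        torso_iv[[length(torso_iv) + 1L]] <-
          tibble(behavior = unname(torso_beh[f]), start_s = t_on, stop_s = h1)
      } else {
        t_on <- NA_real_
      }
    }
    if (runif(1) < p_arms) {
      base <- if (!is.na(t_on)) t_on else h0
      a_on <- base + runif(1, lag_range_s[1], lag_range_s[2])
      if (a_on < h1 - 0.25) {
        arms_iv[[length(arms_iv) + 1L]] <-
          tibble(behavior = unname(arms_beh[f]), start_s = a_on, stop_s = h1)
      }
    }
  }
  torso_ev <- fill_complement(bind_rows(torso_iv), duration_s, "NoneT")
  arms_ev <- fill_complement(bind_rows(arms_iv), duration_s, "NoneAH")

  # --- signs-of-affection gestures carved into the arms stream --------------
  n_soa <- stats::rpois(1, soa_rate_per_min * duration_s / 60)
  if (n_soa > 0) {
    for (u in sort(runif(n_soa, 0, duration_s - 2))) {
      code <- if (runif(1) < p_positive) "SOApos" else "SOAneg"
      arms_ev <- carve_event(arms_ev, u, u + 2, code)
    }
  }

  # --- affect bouts set modifiers on directional states ---------------------
  n_bouts <- stats::rpois(1, affect_rate_per_min * duration_s / 60)
  bouts <- tibble(
    start_s = sort(runif(n_bouts, 0, duration_s)),
    valence = if_else(runif(n_bouts) < p_positive, "positive", "negative")
  ) %>% mutate(stop_s = pmin(.data$start_s + rexp(n_bouts, 1 / affect_bout_mean_s),
    duration_s
  ))

  none_codes <- c("NoneH", "NoneT", "NoneAH")
  finish <- function(ev, grp) {
    ev <- apply_bouts(ev, bouts, none_codes)
    tibble(
      session_id = session_id, participant_id = participant_id,
      coder_id = coder_id, group = grp,
      behavior = ev$behavior, modifier = ev$modifier,
      start_s = ev$start_s, stop_s = ev$stop_s
    )
  }
  bind_rows(
    finish(head_ev, "head"),
    finish(torso_ev, "torso"),
    finish(arms_ev, "arms_hands")
  )
}

# fill the complement of disjoint intervals on [0, T] with a "none" behavior
fill_complement <- function(iv, duration_s, none_code) {
  if (is.null(iv) || nrow(iv) == 0) {
    return(tibble(behavior = none_code, start_s = 0, stop_s = duration_s))
  }
  iv <- dplyr::arrange(iv, .data$start_s)
  out <- list()
  t <- 0
  for (i in seq_len(nrow(iv))) {
    if (iv$start_s[i] > t + 1e-9) {
      out[[length(out) + 1L]] <-
        tibble(behavior = none_code, start_s = t, stop_s = iv$start_s[i])
    }
    out[[length(out) + 1L]] <- iv[i, ]
    t <- max(t, iv$stop_s[i])
  }
  if (t < duration_s - 1e-9) {
    out[[length(out) + 1L]] <-
      tibble(behavior = none_code, start_s = t, stop_s = duration_s)
  }
  bind_rows(out)
}

# replace [from, to) with `code` inside whatever single event contains it
carve_event <- function(ev, from, to, code) {
  host <- which(ev$start_s <= from & ev$stop_s >= to)
  if (length(host) == 0) {
    return(ev)
  }
  h <- host[1]
  pieces <- list()
  if (from > ev$start_s[h] + 1e-9) {
    pieces[[length(pieces) + 1L]] <-
      tibble(behavior = ev$behavior[h], start_s = ev$start_s[h], stop_s = from)
  }
  pieces[[length(pieces) + 1L]] <- tibble(behavior = code, start_s = from, stop_s = to)
  if (ev$stop_s[h] > to + 1e-9) {
    pieces[[length(pieces) + 1L]] <-
      tibble(behavior = ev$behavior[h], start_s = to, stop_s = ev$stop_s[h])
  }
  bind_rows(ev[seq_len(h - 1), ], bind_rows(pieces), ev[-seq_len(h), ]) %>%
    dplyr::arrange(.data$start_s)
}

# split events at bout boundaries and set modifiers; none-states stay neutral
apply_bouts <- function(ev, bouts, none_codes) {
  ev$modifier <- "neutral"
  if (nrow(bouts) == 0) {
    return(ev)
  }
  cuts <- sort(unique(c(bouts$start_s, bouts$stop_s)))
  cuts <- cuts[cuts > 0]
  for (cu in cuts) {
    h <- which(ev$start_s < cu - 1e-9 & ev$stop_s > cu + 1e-9)
    if (length(h) == 1) {
      top <- ev[h, ]
      bot <- ev[h, ]
      top$stop_s <- cu
      bot$start_s <- cu
      ev <- bind_rows(ev[seq_len(h - 1), ], top, bot, ev[-seq_len(h), ])
    }
  }
  mids <- (ev$start_s + ev$stop_s) / 2
  for (i in seq_len(nrow(bouts))) {
    inside <- mids >= bouts$start_s[i] & mids < bouts$stop_s[i] &
      !ev$behavior %in% none_codes
    ev$modifier[inside] <- bouts$valence[i]
  }
  merge_identical_runs(ev)
}

# merge adjacent events with identical (behavior, modifier)
merge_identical_runs <- function(ev) {
  if (nrow(ev) <= 1) {
    return(ev)
  }
  same <- c(
    FALSE,
    ev$behavior[-1] == ev$behavior[-nrow(ev)] &
      ev$modifier[-1] == ev$modifier[-nrow(ev)] &
      abs(ev$start_s[-1] - ev$stop_s[-nrow(ev)]) < 1e-9
  )
  run <- cumsum(!same)
  ev %>%
    mutate(run = run) %>%
    group_by(.data$run) %>%
    summarise(
      behavior = first(.data$behavior), modifier = first(.data$modifier),
      start_s = min(.data$start_s), stop_s = max(.data$stop_s),
      .groups = "drop"
    ) %>%
    select("behavior", "modifier", "start_s", "stop_s")
}

#' Corrupt streams with a two-coder noise model
#'
#' Produces a plausible second coder from a reference coder's streams:
#' event boundaries are jittered by a Gaussian perturbation (order is
#' preserved by re-sorting and clamping within the session), whole-event
#' labels are substituted with probability `substitution_prob` by another
#' behavior of the same group, and events shorter than `miss_below_s` are
#' absorbed into their neighbor (missed short events). The output is
#' repaired to mutual exclusivity and full coverage, so it always validates.
#' With all noise parameters at zero the output equals the input.
#'
#' @param events Valid event-log tibble.
#' @param scheme An [elicse_scheme()].
#' @param jitter_sd_s Boundary jitter SD, seconds.
#' @param substitution_prob Per-event label substitution probability.
#' @param miss_below_s Events shorter than this are absorbed.
#' @param coder_id Coder label for the corrupted copy.
#' @param seed Optional integer seed.
#' @return Event-log tibble for the second coder.
#' @export
corrupt_streams <- function(events, scheme = elicse_scheme(),
                            jitter_sd_s = 1, substitution_prob = 0.05,
                            miss_below_s = 0.5, coder_id = "c2", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(jitter_sd_s >= 0, substitution_prob >= 0, miss_below_s >= 0)
  keys <- c("session_id", "participant_id", "coder_id", "group")
  grp_codes <- split(scheme$behaviors$code, scheme$behaviors$group)

  events %>%
    group_by(across(all_of(keys))) %>%
    group_split() %>%
    purrr::map(function(stream) {
      stream <- dplyr::arrange(stream, .data$start_s)
      t0 <- min(stream$start_s)
      t1 <- max(stream$stop_s)
      k <- nrow(stream)
      bounds <- stream$start_s[-1]
      if (jitter_sd_s > 0 && k > 1) {
        bounds <- sort(pmin(pmax(bounds + rnorm(k - 1, 0, jitter_sd_s), t0), t1))
      }
      out <- tibble(
        behavior = stream$behavior,
        modifier = stream$modifier,
        start_s = c(t0, bounds),
        stop_s = c(bounds, t1)
      ) %>% filter(.data$stop_s - .data$start_s > 1e-9)

      if (substitution_prob > 0) {
        codes <- grp_codes[[stream$group[1]]]
        swap <- runif(nrow(out)) < substitution_prob
        for (i in which(swap)) {
          alt <- setdiff(codes, out$behavior[i])
          out$behavior[i] <- sample(alt, 1)
        }
      }

      # absorb short events into the previous (or next) neighbor
      if (miss_below_s > 0) {
        repeat {
          short <- which(out$stop_s - out$start_s < miss_below_s)
          if (length(short) == 0 || nrow(out) == 1) break
          i <- short[1]
          if (i > 1) {
            out$stop_s[i - 1] <- out$stop_s[i]
          } else {
            out$start_s[i + 1] <- out$start_s[i]
          }
          out <- out[-i, ]
        }
      }
      # merge adjacent identical states
      same <- c(
        FALSE,
        out$behavior[-1] == out$behavior[-nrow(out)] &
          out$modifier[-1] == out$modifier[-nrow(out)]
      )
      run <- cumsum(!same)
      out <- out %>%
        mutate(run = run) %>%
        group_by(.data$run) %>%
        summarise(
          behavior = first(.data$behavior), modifier = first(.data$modifier),
          start_s = min(.data$start_s), stop_s = max(.data$stop_s),
          .groups = "drop"
        ) %>%
        select(-"run")

      tibble(
        session_id = stream$session_id[1],
        participant_id = stream$participant_id[1],
        coder_id = coder_id,
        group = stream$group[1],
        behavior = out$behavior, modifier = out$modifier,
        start_s = out$start_s, stop_s = out$stop_s
      )
    }) %>%
    bind_rows()
}
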