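# compact builders for event-log fixtures ------------------------------------

# one stream's rows from a compact spec: list(c(behavior, start, stop, [modifier]))
make_stream <- function(group, states, session = "s1", participant = "p1",
                        coder = "c1") {
  rows <- lapply(states, function(s) {
    tibble::tibble(
      session_id = session, participant_id = participant, coder_id = coder,
      group = group, behavior = s[[1]],
      modifier = if (length(s) >= 4) s[[4]] else "neutral",
      start_s = as.numeric(s[[2]]), stop_s = as.numeric(s[[3]])
    )
  })
  dplyr::bind_rows(rows)
}

# a fully covered 60 s participant-session with constant states
constant_session <- function(head = "GG", torso = "NRLTG", arms = "MG",
                             modifier = "neutral", duration = 60,
                             session = "s1", participant = "p1", coder = "c1") {
  dplyr::bind_rows(
    make_stream("head", list(list(head, 0, duration, modifier)),
      session, participant, coder),
    make_stream("torso", list(list(torso, 0, duration, modifier)),
      session, participant, coder),
    make_stream("arms_hands", list(list(arms, 0, duration, modifier)),
      session, participant, coder)
  )
}

dur60 <- function(session = "s1") {
  tibble::tibble(session_id = session, duration_s = 60)
}

# textbook (non-tolerant) kappa straight from two label vectors: the oracle
# for the w = 0 equivalence checks
raw_kappa <- function(a, b) {
  labels <- sort(unique(c(a, b)))
  m <- table(factor(a, labels), factor(b, labels))
  n <- sum(m)
  po <- sum(diag(m)) / n
  pe <- sum(rowSums(m) * colSums(m)) / n^2
  (po - pe) / (1 - pe)
}

# brute-force engagement rule table: the independent oracle for
# classify_instant / affect_intensity totality checks
brute_classify <- function(hf, tf, af) {
  if (!hf %in% c("game", "partner")) {
    return(list(level = 0L, focus = "none", variant = "no_engagement"))
  }
  t_at <- tf == hf
  a_at <- af == hf
  level <- if (t_at && a_at) 4L else if (a_at) 3L else if (t_at) 2L else 1L
  task <- hf == "game"
  variant <- switch(level,
    if (task) "passive_attention" else "social_acknowledgement",
    if (task) "attentional_readiness" else "social_readiness",
    if (task) "reduced_active_participation" else "reduced_active_social_engagement",
    if (task) "full_active_participation" else "full_active_social_engagement"
  )
  list(level = level, focus = hf, variant = variant)
}

brute_affect <- function(hf, tf, af, hv, tv, av) {
  if (!hf %in% c("game", "partner")) {
    return(0L)
  }
  s <- function(at, v) if (at && v == "positive") 1L else if (at && v == "negative") -1L else 0L
  s(TRUE, hv) + s(tf == hf, tv) + s(af == hf, av)
}

# per-node OLS oracle for ML path estimates
ols_oracle <- function(scores, model) {
  out <- model$edges
  out$estimate <- NA_real_
  for (v in unique(model$edges$to)) {
    pa <- model$edges$from[model$edges$to == v]
    fml <- stats::reformulate(pa, response = v)
    cf <- stats::coef(stats::lm(fml, data = scores))
    out$estimate[out$to == v] <- cf[pa]
  }
  out
}

random_dag_scores <- function(n, model = emodeb_model()) {
  co <- model$edges
  co$estimate <- stats::runif(nrow(co), -0.8, 0.8)
  simulate_scores(
    n = n, model = model, coefficients = co,
    error_sd = stats::setNames(
      stats::runif(5, 3, 20),
      setdiff(model$variables, model$exogenous)
    ),
    exo_mean = 0, exo_sd = stats::runif(1, 5, 20)
  )
}
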