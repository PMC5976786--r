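test_that("duration percentages follow the arithmetic", {
  ev <- dplyr::bind_rows(
    make_stream("head", list(
      list("GG", 0, 54), list("GFE", 54, 57), list("GP", 57, 58.2),
      list("NoneH", 58.2, 60)
    )),
    make_stream("torso", list(list("NoneT", 0, 60))),
    make_stream("arms_hands", list(
      list("MG", 0, 6, "positive"), list("MG", 6, 50), list("NoneAH", 50, 60)
    ))
  )
  dt <- duration_table(as_event_log(ev), durations = dur60())
  g <- function(b, col = "pct") dt[[col]][dt$behavior == b]
  expect_equal(g("GG"), 90)
  expect_equal(g("GFE"), 5)
  expect_equal(g("GP"), 2)
  expect_equal(g("NoneH"), 3)
  expect_equal(g("MG"), 83.33, tolerance = 1e-3)
  expect_equal(g("MG", "pct_positive"), 10)
  # all-none torso stream
  expect_equal(g("NoneT"), 100)
  expect_equal(g("LIP"), 0)
  # group sums are 100
  sums <- tapply(dt$pct, dt$group, sum)
  expect_equal(as.numeric(sums), c(100, 100, 100), tolerance = 1e-9)
})

test_that("a missing group stream is a completeness error naming the key", {
  ev <- as_event_log(dplyr::bind_rows(
    make_stream("head", list(list("GG", 0, 60))),
    make_stream("torso", list(list("NoneT", 0, 60)))
  ))
  expect_error(duration_table(ev, durations = dur60()), "s1/p1/arms_hands")
})

test_that("score reduction applies the six fixed formulas", {
  ref <- reference_duration_table()
  scores <- reduce_scores(ref)
  expect_equal(scores$GAct[scores$activity == "cognitive_games"], 81.30)
  expect_equal(scores$GAct[scores$activity == "robot_play"], 74.00)
  # the published arms/hands means are internally consistent
  expect_equal(
    sum(ref$pct[ref$activity == "cognitive_games" & ref$group == "arms_hands"]),
    100,
    tolerance = 1e-9
  )
})

test_that("a saturated all-engaged neutral session maxes the body scores", {
  ev <- as_event_log(constant_session())
  scores <- score_table(ev, durations = dur60())
  expect_equal(scores$GAct, 100)
  expect_equal(scores$LTAct, 100)
  expect_equal(scores$RoAct, 100)
  expect_equal(scores$GAct_gsup, 0)
  expect_equal(scores$LTAct_postsup, 0)
  expect_equal(scores$RoAct_qogest, 0)
})

test_that("scores stay in [-100, 100] for randomized valid duration tables", {
  set.seed(4)
  sch <- elicse_scheme()
  for (i in 1:50) {
    dt <- sch$behaviors[, c("code", "group")] |>
      dplyr::rename(behavior = code) |>
      dplyr::group_by(group) |>
      dplyr::mutate(pct = {
        w <- stats::rexp(dplyr::n())
        100 * w / sum(w)
      }) |>
      dplyr::ungroup() |>
      dplyr::mutate(
        session_id = "r", participant_id = "p", activity = NA_character_,
        pct_positive = pct * stats::runif(dplyr::n(), 0, 0.6),
        pct_negative = pmax(
          0, pct * stats::runif(dplyr::n(), 0, 0.4)
        )
      )
    s <- reduce_scores(dt)
    vals <- unlist(s[, c(
      "GAct", "LTAct", "RoAct", "GAct_gsup", "LTAct_postsup", "RoAct_qogest"
    )])
    expect_true(all(vals >= -100 - 1e-9 & vals <= 100 + 1e-9))
    # affect magnitude bounded by the directional coverage
    expect_lte(
      abs(s$GAct_gsup),
      sum(dt$pct[dt$behavior %in% c("GP", "GG")]) + 1e-9
    )
  }
})

test_that("SOA gestures feed RoAct_qogest but not RoAct", {
  ev <- as_event_log(dplyr::bind_rows(
    make_stream("head", list(list("GG", 0, 60))),
    make_stream("torso", list(list("NRLTG", 0, 60))),
    make_stream("arms_hands", list(
      list("MG", 0, 48), list("SOApos", 48, 54), list("SOAneg", 54, 57),
      list("NoneAH", 57, 60)
    ))
  ))
  s <- score_table(ev, durations = dur60())
  # RoAct = MG - NoneAH, SOA excluded from the directional score
  expect_equal(s$RoAct, 80 - 5)
  # RoAct_qogest = SOApos - SOAneg when no modifiers are present
  expect_equal(s$RoAct_qogest, 10 - 5)
})

test_that("cohort scoring yields one row per participant-session", {
  ev <- dplyr::bind_rows(
    constant_session(session = "s1"),
    constant_session(session = "s1", participant = "p2", head = "GP",
      torso = "LIP", arms = "RoP"),
    constant_session(session = "s2", head = "GP", torso = "LIP", arms = "RoP")
  ) |> as_event_log()
  s <- score_table(ev, durations = dplyr::bind_rows(dur60("s1"), dur60("s2")))
  expect_equal(nrow(s), 3)
  expect_false(anyDuplicated(s[, c("session_id", "participant_id")]) > 0)
  # empty cohort -> empty table
  empty <- ev[0, ]
  expect_equal(nrow(reduce_scores(duration_table(empty, durations = dur60()))), 0)
})
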