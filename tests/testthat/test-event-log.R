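test_that("a minimal well-formed log parses into one fully covering stream", {
  df <- make_stream("head", list(list("GG", 0, 60)))
  ev <- as_event_log(df)
  expect_equal(nrow(ev), 1)
  rep <- validate_streams(ev, durations = dur60())
  expect_true(is_valid(rep))
  expect_equal(nrow(rep), 0)
})

test_that("unknown codes, wrong groups and bad intervals are schema errors", {
  bad <- make_stream("head", list(list("XYZ", 0, 60)))
  expect_error(as_event_log(bad), "XYZ")
  wrong <- make_stream("torso", list(list("GG", 0, 60)))
  expect_error(as_event_log(wrong), "wrong group")
  rev <- make_stream("head", list(list("GG", 10, 5)))
  expect_error(as_event_log(rev), "interval")
})

test_that("empty modifiers default to neutral and none-states are forced neutral", {
  df <- dplyr::bind_rows(
    make_stream("head", list(list("GG", 0, 30, NA), list("NoneH", 30, 60, "positive")))
  )
  ev <- as_event_log(df)
  expect_equal(ev$modifier, c("neutral", "neutral"))
})

test_that("overlaps are reported as errors by the validator", {
  df <- make_stream("head", list(list("GG", 0, 30), list("GP", 20, 60)))
  ev <- as_event_log(df) # parse succeeds
  rep <- validate_streams(ev, durations = dur60())
  expect_false(is_valid(rep))
  ov <- rep[rep$kind == "overlap", ]
  expect_equal(nrow(ov), 1)
  expect_equal(c(ov$start_s, ov$stop_s), c(20, 30))
})

test_that("gap tolerance separates errors from warnings", {
  # covering [0, 55] of a 60 s session: 5 s gap is an error at 1 s tolerance
  ev <- as_event_log(make_stream("head", list(list("GG", 0, 55))))
  rep <- validate_streams(ev, durations = dur60(), gap_tolerance_s = 1)
  expect_false(is_valid(rep))
  expect_equal(rep$kind, "gap")
  expect_equal(c(rep$start_s, rep$stop_s), c(55, 60))
  # a 0.5 s interior gap at 1 s tolerance: warning, not error
  ev2 <- as_event_log(make_stream("head", list(
    list("GG", 0, 30), list("GP", 30.5, 60)
  )))
  rep2 <- validate_streams(ev2, durations = dur60(), gap_tolerance_s = 1)
  expect_true(is_valid(rep2))
  expect_equal(rep2$severity, "warning")
})

test_that("validation is complete: injected faults always surface", {
  set.seed(42)
  for (i in 1:20) {
    ev <- simulate_session_streams(duration_s = 120)
    expect_true(is_valid(validate_streams(ev)))
    # inject either an overlap or a wide gap into a random event
    stream <- ev[ev$group == "head", ]
    j <- sample(nrow(stream), 1)
    if (i %% 2 == 0) {
      stream$stop_s[j] <- stream$stop_s[j] + 2
    } else {
      stream$stop_s[j] <- max(stream$start_s[j] + 0.01, stream$stop_s[j] - 2)
    }
    broken <- dplyr::bind_rows(ev[ev$group != "head", ], stream)
    rep <- validate_streams(broken,
      durations = tibble::tibble(session_id = "s1", duration_s = 120)
    )
    expect_false(is_valid(rep))
  }
})

test_that("event logs round-trip through CSV", {
  ev <- simulate_session_streams(duration_s = 120, seed = 7)
  path <- withr::local_tempfile(fileext = ".csv")
  write_event_log(ev, path)
  back <- read_event_log(path)
  key <- function(x) dplyr::arrange(x, group, start_s)
  expect_equal(as.data.frame(key(back)), as.data.frame(key(ev)), tolerance = 1e-9)
})

test_that("discretization follows the midpoint and half-open conventions", {
  ev <- as_event_log(make_stream("head", list(list("GG", 0, 60))))
  bins <- discretize_streams(ev, resolution_s = 1, durations = dur60())
  expect_equal(nrow(bins), 60)
  expect_true(all(bins$behavior == "GG"))

  ev2 <- as_event_log(make_stream("head", list(
    list("GG", 0, 10), list("GP", 10, 60)
  )))
  bins2 <- discretize_streams(ev2, resolution_s = 1, durations = dur60())
  expect_equal(bins2$behavior[1:10], rep("GG", 10))
  expect_equal(bins2$behavior[11:60], rep("GP", 50))

  # boundary exactly at a bin midpoint belongs to the later event
  ev3 <- as_event_log(make_stream("head", list(
    list("GG", 0, 0.5), list("GP", 0.5, 60)
  )))
  bins3 <- discretize_streams(ev3, resolution_s = 1, durations = dur60())
  expect_equal(bins3$behavior[1], "GP")
})

test_that("bin counts times resolution reconstruct event durations", {
  set.seed(11)
  for (res in c(0.5, 1)) {
    ev <- simulate_session_streams(duration_s = 300)
    bins <- discretize_streams(ev, resolution_s = res)
    for (g in unique(ev$group)) {
      truth <- tapply(
        ev$stop_s[ev$group == g] - ev$start_s[ev$group == g],
        ev$behavior[ev$group == g], sum
      )
      got <- table(bins$behavior[bins$group == g]) * res
      n_bound <- sum(ev$group == g)
      for (b in names(truth)) {
        expect_lt(abs(truth[[b]] - got[[b]]), res * (n_bound + 1))
      }
    }
  }
})
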