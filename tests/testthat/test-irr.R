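test_that("cohen_kappa reproduces hand-computed values and edge cases", {
  k <- cohen_kappa(matrix(c(40, 10, 10, 40), 2, byrow = TRUE))
  expect_equal(k$po, 0.80)
  expect_equal(k$pe, 0.50)
  expect_equal(k$kappa, 0.60)

  expect_equal(cohen_kappa(diag(c(7, 3, 5)))$kappa, 1)

  # both coders one identical state throughout: pe = 1, kappa undefined
  degenerate <- matrix(c(50, 0, 0, 0), 2)
  k2 <- cohen_kappa(degenerate)
  expect_true(k2$undefined)
  expect_true(is.na(k2$kappa))

  expect_error(cohen_kappa(matrix(0, 2, 2)), "empty")
})

test_that("identical sequences give a diagonal matrix and kappa 1", {
  a <- rep(c("X", "Y", "Z"), times = c(10, 5, 5))
  cm <- tolerant_confusion(a, a, tolerance_s = 3, resolution_s = 1)
  expect_equal(sum(cm) - sum(diag(cm)), 0)
  expect_equal(cohen_kappa(cm)$kappa, 1)
})

test_that("zero tolerance reduces exactly to textbook kappa", {
  set.seed(5)
  for (i in 1:20) {
    n <- sample(50:200, 1)
    labs <- LETTERS[1:sample(2:4, 1)]
    a <- sample(labs, n, replace = TRUE)
    b <- sample(labs, n, replace = TRUE)
    cm <- tolerant_confusion(a, b, tolerance_s = 0, resolution_s = 1)
    k <- cohen_kappa(cm)$kappa
    expect_equal(k, raw_kappa(a, b), tolerance = 1e-12)
  }
})

test_that("the tolerance window absorbs small time offsets", {
  # A: X on [0,10); B: X on [2,12); Y elsewhere on [0,20); 1 s bins, w = 3 s
  a <- rep(c("X", "Y"), times = c(10, 10))
  b <- rep(c("Y", "X", "Y"), times = c(2, 10, 8))
  raw <- tolerant_confusion(a, b, tolerance_s = 0, resolution_s = 1)
  # without windowing the off-diagonal mass sits at bins 0-1 and 10-11
  expect_equal(sum(raw) - sum(diag(raw)), 4)
  tol <- tolerant_confusion(a, b, tolerance_s = 3, resolution_s = 1)
  # windowing recovers (at least) the reference-direction disagreements
  expect_gt(sum(diag(tol)), sum(diag(raw)))
  expect_gte(cohen_kappa(tol)$po, 0.9)
  # the A-vs-B directional tally agrees everywhere once windowed
  expect_equal(sum(diag(emodeb:::directional_tally(a, b, c("X", "Y"), 3))), 20)
})

test_that("tolerant comparison is symmetric in the coders", {
  set.seed(9)
  a <- sample(c("X", "Y", "Z"), 100, replace = TRUE)
  b <- sample(c("X", "Y", "Z"), 100, replace = TRUE)
  m1 <- tolerant_confusion(a, b, tolerance_s = 2, resolution_s = 1)
  m2 <- tolerant_confusion(b, a, tolerance_s = 2, resolution_s = 1)
  expect_equal(unclass(m1), t(unclass(m2)))
})

test_that("behavior_kappa collapses to 2x2 consistently with brute force", {
  set.seed(3)
  cm <- matrix(sample(0:20, 9, replace = TRUE), 3,
    dimnames = list(c("A", "B", "C"), c("A", "B", "C"))
  )
  for (lab in c("A", "B", "C")) {
    i <- rownames(cm) == lab
    brute <- matrix(c(
      sum(cm[i, i]), sum(cm[i, !i]),
      sum(cm[!i, i]), sum(cm[!i, !i])
    ), 2, byrow = TRUE)
    expect_equal(behavior_kappa(cm, lab), cohen_kappa(brute))
  }
  # behavior absent in both coders -> undefined flag
  cm2 <- matrix(c(10, 0, 0, 0), 2, dimnames = list(c("A", "B"), c("A", "B")))
  expect_true(behavior_kappa(cm2, "B")$undefined)
  expect_error(behavior_kappa(cm2, "Q"), "label")
})

test_that("irr_report gives kappa 1 on identical coders and flags rare behaviors", {
  ev <- simulate_session_streams(duration_s = 300, seed = 21)
  evb <- dplyr::mutate(ev, coder_id = "c2")
  rep <- irr_report(ev, evb)
  expect_equal(rep$global$kappa, 1)
  expect_true(all(rep$per_group$kappa == 1))
  # rare behaviors (< 1% mean duration) are excluded, not given a kappa
  rare <- rep$per_behavior[rep$per_behavior$mean_pct < 1, ]
  expect_true(all(rare$excluded))
  expect_true(all(is.na(rare$kappa)))
  common <- rep$per_behavior[!rep$per_behavior$excluded, ]
  expect_true(all(!is.na(common$kappa)))
  # caution flag for behaviors between 1% and 5%
  mid <- rep$per_behavior[rep$per_behavior$mean_pct >= 1 &
    rep$per_behavior$mean_pct < 5, ]
  expect_true(all(mid$caution))
})

test_that("independent random sequences give kappa near zero", {
  set.seed(17)
  a <- sample(c("GG", "GP", "GFE", "NoneH"), 1e4, replace = TRUE)
  b <- sample(c("GG", "GP", "GFE", "NoneH"), 1e4, replace = TRUE)
  k <- cohen_kappa(tolerant_confusion(a, b, tolerance_s = 0, resolution_s = 1))
  expect_lt(abs(k$kappa), 0.05)
})

test_that("coder key mismatches raise a pairing error", {
  ev <- simulate_session_streams(duration_s = 60, seed = 2)
  other <- dplyr::mutate(ev, session_id = "other", coder_id = "c2")
  expect_error(irr_report(ev, other), "same \\(session")
})
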