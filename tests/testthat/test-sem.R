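test_that("the EMODEB model has the fixed 9-edge head-led structure", {
  m <- emodeb_model()
  expect_equal(nrow(m$edges), 9)
  expect_equal(m$exogenous, "GAct")
  expect_setequal(
    m$edges$from[m$edges$to == "RoAct_qogest"],
    c("RoAct", "LTAct_postsup", "GAct_gsup")
  )
  expect_false(is.null(emodeb:::topological_order(m$variables, m$edges)))
  expect_error(
    path_model(tibble::tibble(from = c("A", "B"), to = c("B", "A"))),
    "cycle"
  )
})

test_that("degrees of freedom follow the moment accounting", {
  m <- emodeb_model()
  expect_equal(model_df(m), 6L)
  # free parameters + df = number of moments (21)
  expect_equal(nrow(m$edges) + length(m$variables) + model_df(m), 21L)
  # independence model on 6 variables
  m0 <- path_model(
    tibble::tibble(from = character(), to = character()),
    variables = m$variables
  )
  expect_equal(model_df(m0), 15L)
  # saturated recursive model: 15 edges
  sat_edges <- t(utils::combn(m$variables, 2))
  m_sat <- path_model(tibble::tibble(from = sat_edges[, 1], to = sat_edges[, 2]))
  expect_equal(model_df(m_sat), 0L)
})

test_that("Mahalanobis screening removes the farthest rows deterministically", {
  set.seed(44)
  base <- tibble::tibble(
    session_id = sprintf("s%d", 1:20), participant_id = "p",
    GAct = rnorm(20), LTAct = rnorm(20), RoAct = rnorm(20),
    GAct_gsup = rnorm(20), LTAct_postsup = rnorm(20), RoAct_qogest = rnorm(20)
  )
  # a row at the centroid has distance ~0 and is never excluded first
  centered <- base
  centered[1, emodeb:::emodeb_score_names()] <-
    as.list(colMeans(centered[, emodeb:::emodeb_score_names()]))
  mf <- mahalanobis_filter(centered, k = 3)
  expect_false(mf$report$excluded[1])
  expect_equal(nrow(mf$scores), 17)
  expect_equal(sum(mf$report$excluded), 3)
  # the k largest distances are exactly the excluded ones
  expect_equal(
    sort(mf$report$d2[mf$report$excluded]),
    sort(mf$report$d2, decreasing = TRUE)[3:1]
  )
})

test_that("Mahalanobis distance is affine invariant", {
  set.seed(8)
  x <- matrix(rnorm(200 * 6), 200)
  colnames(x) <- emodeb:::emodeb_score_names()
  sc <- tibble::as_tibble(x)
  d1 <- mahalanobis_filter(sc, k = 0)$report$d2
  A <- matrix(rnorm(36), 6)
  while (abs(det(A)) < 0.1) A <- matrix(rnorm(36), 6)
  y <- x %*% t(A)
  colnames(y) <- colnames(x)
  d2 <- mahalanobis_filter(tibble::as_tibble(y), k = 0)$report$d2
  expect_equal(d1, d2, tolerance = 1e-8)
})

test_that("ML estimates equal per-node OLS on a recursive DAG", {
  set.seed(12)
  for (i in 1:5) {
    sim <- random_dag_scores(n = sample(50:300, 1))
    fit <- fit_path_model(sim$scores, se = FALSE)
    ols <- ols_oracle(sim$scores, emodeb_model())
    expect_true(fit$converged)
    expect_lt(max(abs(fit$edges$estimate - ols$estimate)), 1e-6)
  }
})

test_that("a saturated recursive model fits perfectly", {
  set.seed(19)
  sim <- random_dag_scores(n = 100)
  vars <- emodeb_model()$variables
  sat_edges <- t(utils::combn(vars, 2))
  m_sat <- path_model(tibble::tibble(from = sat_edges[, 1], to = sat_edges[, 2]))
  fit <- fit_path_model(sim$scores, m_sat, se = FALSE)
  expect_equal(fit$df, 0L)
  expect_lt(fit$chi2, 1e-4)
})

test_that("fit indices reproduce hand arithmetic and their limits", {
  idx <- fit_indices(30, 6, 300, 15, 101)
  expect_equal(idx$rmsea, 0.200)
  expect_equal(idx$nfi, 0.900)
  # chi2 <= df: rmsea 0, cfi 1
  idx0 <- fit_indices(6, 6, 300, 15, 101)
  expect_equal(idx0$rmsea, 0)
  expect_equal(idx0$cfi, 1)
  # chi2 = 0: nfi = 1
  expect_equal(fit_indices(0, 6, 300, 15, 101)$nfi, 1)
  expect_equal(fit_indices(30, 6, 300, 15, 101)$pnfi, (6 / 15) * 0.9)
  expect_error(fit_indices(5, 6, 0, 15, 101), "degenerate")
})

test_that("standard errors and critical ratios are sane on simulated data", {
  sim <- simulate_scores(n = 500, seed = 22)
  fit <- fit_path_model(sim$scores)
  expect_true(all(fit$edges$se > 0))
  expect_true(all(is.finite(fit$edges$cr)))
  # strong generated paths should be clearly significant at n = 500
  strong <- fit$edges[fit$edges$from == "LTAct_postsup", ]
  expect_lt(strong$p_value, 1e-4)
  # standardized estimates bounded by 1 in magnitude for this structure
  expect_true(all(abs(fit$edges$std_estimate) <= 1))
})

test_that("follow-up regression matches its closed form", {
  # perfectly collinear variables
  sc <- tibble::tibble(x = rnorm(30))
  sc$y <- 2 * sc$x
  r <- follow_up_regression(sc, "x", "y")
  expect_equal(r$beta_std, 1, tolerance = 1e-9)
  expect_lt(r$p_value, 1e-12)
  # the reported standardized effect implies t = beta * sqrt(df/(1-beta^2))
  beta <- 0.246
  t_closed <- beta * sqrt(75 / (1 - beta^2))
  expect_equal(t_closed, 2.198, tolerance = 1e-3)
  # under independence the standardized slope is near zero
  set.seed(6)
  sc2 <- tibble::tibble(x = rnorm(1e4), y = rnorm(1e4))
  expect_lt(abs(follow_up_regression(sc2, "x", "y")$beta_std), 0.05)
  expect_error(
    follow_up_regression(tibble::tibble(x = rep(1, 10), y = rnorm(10)), "x", "y"),
    "zero-variance"
  )
})

test_that("tidy and glance expose the fit in broom shape", {
  sim <- simulate_scores(n = 100, seed = 2)
  fit <- fit_path_model(sim$scores)
  td <- tidy(fit)
  expect_equal(nrow(td), 9)
  expect_true(all(c("from", "to", "estimate", "std_estimate", "se", "cr", "p_value")
  %in% names(td)))
  gl <- glance(fit)
  expect_equal(nrow(gl), 1)
  expect_true(all(c("chi2", "df", "rmsea", "nfi", "cfi", "rfi", "pnfi") %in% names(gl)))
})
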