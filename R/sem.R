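#' Recursive path models on observed variables
#'
#' A path model is a directed acyclic graph over observed variables; every
#' variable carries one free variance parameter (the exogenous variance or
#' the residual error variance) and every edge one regression coefficient.
#' Errors are mutually uncorrelated, so the model is a linear Gaussian
#' recursive system.
#'
#' @param edges Tibble or data frame with columns `from`, `to`.
#' @param variables Optional variable ordering; defaults to a topological
#'   order of the edge set.
#' @return A `path_model`: list with `variables`, `edges` (tibble),
#'   `exogenous` (variables with no parents).
#' @export
path_model <- function(edges, variables = NULL) {
  edges <- tibble::as_tibble(edges)[, c("from", "to")]
  vars <- unique(c(variables, edges$from, edges$to))
  ord <- topological_order(vars, edges)
  if (is.null(ord)) abort("the edge set contains a cycle; path models must be acyclic")
  structure(
    list(
      variables = ord,
      edges = edges,
      exogenous = setdiff(ord, unique(edges$to))
    ),
    class = "path_model"
  )
}

topological_order <- function(vars, edges) {
  remaining <- vars
  ord <- character(0)
  e <- edges
  while (length(remaining) > 0) {
    free <- remaining[!remaining %in% e$to]
    if (length(free) == 0) {
      return(NULL)
    }
    ord <- c(ord, free)
    remaining <- setdiff(remaining, free)
    e <- e[!e$from %in% free, ]
  }
  ord
}

#' The fixed EMODEB path model
#'
#' Six observed engagement scores, nine directed paths, with gaze toward
#' activity (`GAct`) exogenous: GAct feeds the torso and arms/hands
#' engagement scores and its own gestural-support affect score; the three
#' affect scores form a parallel chain with cross-links into
#' `RoAct_qogest`.
#'
#' @return A [path_model()] with 6 variables and 9 edges.
#' @examples
#' m <- emodeb_model()
#' model_df(m) # 6
#' @export
emodeb_model <- function() {
  path_model(
    tibble::tribble(
      ~from,            ~to,
      "GAct",           "LTAct",
      "LTAct",          "RoAct",
      "GAct",           "RoAct",
      "GAct",           "GAct_gsup",
      "RoAct",          "RoAct_qogest",
      "GAct_gsup",      "LTAct_postsup",
      "LTAct_postsup",  "RoAct_qogest",
      "GAct_gsup",      "RoAct_qogest",
      "LTAct",          "LTAct_postsup"
    ),
    variables = emodeb_score_names()
  )
}

#' Published EMODEB path estimates
#'
#' The reported path coefficients of the EMODEB model, used as default
#' generating coefficients by [simulate_scores()].
#'
#' @return Tibble `from, to, estimate`.
#' @export
emodeb_estimates <- function() {
  est <- c(0.372, 0.122, 0.349, 0.240, -0.255, 0.390, 0.845, 0.112, -0.218)
  mutate(emodeb_model()$edges, estimate = est)
}

#' Degrees of freedom of a path model
#'
#' `df = p(p+1)/2 - (edges + p)`: the number of non-redundant covariance
#' moments minus the free parameters (one coefficient per edge, one variance
#' per variable).
#'
#' @param model A [path_model()].
#' @return Integer degrees of freedom.
#' @export
model_df <- function(model) {
  stopifnot(inherits(model, "path_model"))
  p <- length(model$variables)
  as.integer(p * (p + 1) / 2 - (nrow(model$edges) + p))
}

#' @export
print.path_model <- function(x, ...) {
  cat("<path_model> ", length(x$variables), " variables, ",
    nrow(x$edges), " edges, df = ", model_df(x), "\n",
    sep = ""
  )
  cat("exogenous:", paste(x$exogenous, collapse = ", "), "\n")
  print(x$edges, ...)
  invisible(x)
}

#' Mahalanobis outlier screening of a score table
#'
#' Computes each row's squared Mahalanobis distance from the multivariate
#' centroid of the six scores and removes either the `k` farthest rows
#' (`rule = "fixed_k"`, the default) or all rows beyond the chi-square
#' quantile `qchisq(1 - alpha, p)` (`rule = "chi2_quantile"`). Ties are
#' broken deterministically by row order.
#'
#' @param scores A score table (one row per participant-session).
#' @param k Number of rows to exclude under `fixed_k`.
#' @param rule Exclusion rule.
#' @param alpha Upper-tail probability for the chi-square rule.
#' @param columns Score columns; defaults to the six EMODEB scores.
#' @return List with `scores` (retained rows), `report` (tibble of all rows
#'   with `d2` and `excluded`), and `rule`.
#' @export
mahalanobis_filter <- function(scores, k = 7,
                               rule = c("fixed_k", "chi2_quantile"),
                               alpha = 0.001,
                               columns = emodeb_score_names()) {
  rule <- match.arg(rule)
  x <- as.matrix(scores[, columns])
  if (nrow(x) <= ncol(x)) abort("need more rows than score variables")
  S <- cov(x)
  if (rcond_sym(S) < 1e-12) abort("singular score covariance; cannot compute distances")
  d2 <- stats::mahalanobis(x, colMeans(x), S)
  excluded <- rep(FALSE, nrow(x))
  if (rule == "fixed_k") {
    if (k > 0) excluded[order(-d2, seq_along(d2))[seq_len(min(k, nrow(x)))]] <- TRUE
  } else {
    excluded <- d2 > qchisq(1 - alpha, df = ncol(x))
  }
  report <- scores %>%
    mutate(d2 = d2, excluded = excluded)
  list(
    scores = scores[!excluded, , drop = FALSE],
    report = report,
    rule = rule
  )
}

rcond_sym <- function(S) {
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (max(ev) <= 0) {
    return(0)
  }
  max(min(ev), 0) / max(ev)
}

# model-implied covariance: Sigma = (I - B)^-1 Psi (I - B)^-T
implied_sigma <- function(beta, psi, model, parent_idx, child_idx) {
  p <- length(model$variables)
  B <- matrix(0, p, p)
  B[cbind(child_idx, parent_idx)] <- beta
  A <- solve(diag(p) - B)
  A %*% (psi * t(A))
}

fml_value <- function(theta, S, logdetS, model, parent_idx, child_idx, n_beta) {
  beta <- theta[seq_len(n_beta)]
  psi <- exp(theta[-seq_len(n_beta)])
  sigma <- implied_sigma(beta, psi, model, parent_idx, child_idx)
  ld <- determinant(sigma, logarithm = TRUE)
  if (ld$sign <= 0) {
    return(1e10)
  }
  as.numeric(ld$modulus) + sum(diag(solve(sigma, S))) - logdetS - nrow(S)
}

#' Fit a recursive path model by maximum likelihood
#'
#' Minimizes the covariance-structure discrepancy
#' `F_ML = ln|Sigma(theta)| + tr(S Sigma(theta)^-1) - ln|S| - p`
#' over the edge coefficients and (log-parameterized) variances, with the
#' sample covariance `S` on the `n - 1` denominator; means are unstructured
#' and ignored. The model chi-square is `(n - 1) F_ML` at the optimum, with
#' df from [model_df()]. Standard errors come from the inverse observed
#' information `(n - 1)/2` times the Hessian of `F_ML`; critical ratios are
#' estimate/SE with two-sided normal p-values. Standardized estimates use
#' the model-implied standard deviations. Incremental fit indices compare
#' against the independence null (all covariances zero, variances free,
#' `df_null = p(p - 1)/2`).
#'
#' Optimization is quasi-Newton (BFGS) started from per-node least-squares
#' coefficients and marginal variances; convergence is declared when the
#' gradient norm falls below `1e-6`.
#'
#' @param scores A score table containing the model's variables.
#' @param model A [path_model()]; default [emodeb_model()].
#' @param se If `FALSE`, skip the Hessian-based standard errors (faster for
#'   simulation loops).
#' @return A `path_fit` object; see [tidy.path_fit()] and
#'   [glance.path_fit()].
#' @export
fit_path_model <- function(scores, model = emodeb_model(), se = TRUE) {
  vars <- model$variables
  miss <- setdiff(vars, names(scores))
  if (length(miss) > 0) {
    abort(paste0("score table lacks model variables: ", paste(miss, collapse = ", ")))
  }
  x <- as.matrix(scores[, vars])
  x <- x[complete.cases(x), , drop = FALSE]
  n <- nrow(x)
  p <- length(vars)
  n_beta <- nrow(model$edges)
  n_free <- n_beta + p
  if (n <= n_free) abort("too few observations for the number of free parameters")
  S <- cov(x)
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) abort("sample covariance is not positive definite")
  logdetS <- as.numeric(determinant(S, logarithm = TRUE)$modulus)

  parent_idx <- match(model$edges$from, vars)
  child_idx <- match(model$edges$to, vars)

  # start values: per-node least squares on S, marginal variances
  beta0 <- numeric(n_beta)
  for (v in unique(child_idx)) {
    pa <- parent_idx[child_idx == v]
    beta0[child_idx == v] <- solve(S[pa, pa, drop = FALSE], S[pa, v])
  }
  theta0 <- c(beta0, log(diag(S)))

  opt <- optim(theta0, fml_value,
    S = S, logdetS = logdetS, model = model,
    parent_idx = parent_idx, child_idx = child_idx, n_beta = n_beta,
    method = "BFGS", control = list(maxit = 1000, reltol = 1e-14)
  )
  theta <- opt$par
  grad <- numeric(length(theta))
  h <- 1e-6
  for (i in seq_along(theta)) {
    tp <- theta
    tm <- theta
    tp[i] <- tp[i] + h
    tm[i] <- tm[i] - h
    grad[i] <- (fml_value(tp, S, logdetS, model, parent_idx, child_idx, n_beta) -
      fml_value(tm, S, logdetS, model, parent_idx, child_idx, n_beta)) / (2 * h)
  }
  converged <- opt$convergence == 0 && sqrt(sum(grad^2)) < 1e-6

  beta <- theta[seq_len(n_beta)]
  psi <- exp(theta[-seq_len(n_beta)])
  sigma <- implied_sigma(beta, psi, model, parent_idx, child_idx)
  fmin <- fml_value(theta, S, logdetS, model, parent_idx, child_idx, n_beta)
  chi2 <- max((n - 1) * fmin, 0)
  df <- model_df(model)
  p_model <- if (df > 0) pchisq(chi2, df, lower.tail = FALSE) else NA_real_

  # independence null: Sigma = diag(S) at its own ML optimum
  f_null <- sum(log(diag(S))) - logdetS
  chi2_null <- (n - 1) * f_null
  df_null <- p * (p - 1) / 2

  se_beta <- rep(NA_real_, n_beta)
  se_psi <- rep(NA_real_, p)
  if (se) {
    H <- optimHess(theta, fml_value,
      S = S, logdetS = logdetS, model = model,
      parent_idx = parent_idx, child_idx = child_idx, n_beta = n_beta
    )
    info <- (n - 1) / 2 * H
    acov <- tryCatch(solve(info), error = function(e) NULL)
    if (!is.null(acov)) {
      d <- diag(acov)
      se_beta <- sqrt(pmax(d[seq_len(n_beta)], 0))
      # delta method: parameters are log-variances
      se_psi <- psi * sqrt(pmax(d[-seq_len(n_beta)], 0))
    }
  }

  sds <- sqrt(diag(sigma))
  std <- beta * sds[parent_idx] / sds[child_idx]
  cr <- beta / se_beta

  edges <- model$edges %>%
    mutate(
      estimate = beta,
      std_estimate = std,
      se = se_beta,
      cr = cr,
      p_value = 2 * pnorm(-abs(cr))
    )
  variances <- tibble(
    variable = vars,
    variance = psi,
    se = se_psi,
    kind = if_else(vars %in% model$exogenous, "exogenous", "error")
  )
  idx <- if (df > 0) {
    fit_indices(chi2, df, chi2_null, df_null, n)
  } else {
    tibble(
      rmsea = 0, nfi = (chi2_null - chi2) / chi2_null, cfi = 1,
      rfi = NA_real_, pnfi = 0
    )
  }

  structure(
    list(
      model = model, edges = edges, variances = variances,
      chi2 = chi2, df = df, p_value = p_model,
      chi2_null = chi2_null, df_null = df_null,
      rmsea = idx$rmsea, nfi = idx$nfi, cfi = idx$cfi, rfi = idx$rfi,
      pnfi = idx$pnfi,
      n_used = n, S = S, implied = sigma, converged = converged,
      notes = c(
        "unstandardized and standardized estimates both reported",
        "PNFI uses the James-Mulaik-Brent parsimony ratio df/df_null with df_null = p(p-1)/2"
      )
    ),
    class = "path_fit"
  )
}

#' Covariance-structure fit indices
#'
#' Given the fitted model's chi-square and df and the independence null's
#' chi-square and df, returns the usual absolute and incremental indices:
#' `rmsea = sqrt(max(chi2 - df, 0) / (df (n - 1)))`,
#' `nfi = (chi2_null - chi2) / chi2_null`,
#' `cfi = 1 - max(chi2 - df, 0) / max(chi2_null - df_null, chi2 - df, 0)`,
#' `rfi = 1 - (chi2/df) / (chi2_null/df_null)`,
#' `pnfi = (df / df_null) nfi`.
#'
#' @param chi2,df Fitted model chi-square and degrees of freedom.
#' @param chi2_null,df_null Independence-model chi-square and df.
#' @param n Sample size.
#' @return One-row tibble `rmsea, nfi, cfi, rfi, pnfi`.
#' @examples
#' fit_indices(30, 6, 300, 15, 101) # rmsea 0.2, nfi 0.9
#' @export
fit_indices <- function(chi2, df, chi2_null, df_null, n) {
  stopifnot(df > 0, df_null > 0, n > 1)
  if (chi2_null <= 0) abort("degenerate independence null (chi2_null <= 0)")
  excess <- max(chi2 - df, 0)
  denom <- max(chi2_null - df_null, chi2 - df, 0)
  tibble(
    rmsea = sqrt(excess / (df * (n - 1))),
    nfi = (chi2_null - chi2) / chi2_null,
    cfi = if (denom > 0) 1 - excess / denom else 1,
    rfi = 1 - (chi2 / df) / (chi2_null / df_null),
    pnfi = (df / df_null) * (chi2_null - chi2) / chi2_null
  )
}

#' Standardized follow-up simple regression
#'
#' Regresses `y` on `x` after standardizing both, reporting the
#' standardized coefficient, `t = beta sqrt(df / (1 - beta^2))` with
#' `df = n - 2`, and the two-sided p-value.
#'
#' @param scores Data frame holding the two variables.
#' @param x,y Column names of predictor and response.
#' @return One-row tibble `x, y, beta_std, t, df, p_value, n`.
#' @export
follow_up_regression <- function(scores, x, y) {
  xv <- scores[[x]]
  yv <- scores[[y]]
  keep <- stats::complete.cases(xv, yv)
  xv <- xv[keep]
  yv <- yv[keep]
  n <- length(xv)
  if (n < 3) abort("need at least 3 observations")
  if (sd(xv) == 0) abort("zero-variance predictor")
  fit <- lm(scale(yv) ~ scale(xv))
  beta <- unname(coef(fit)[2])
  df <- n - 2
  t <- beta * sqrt(df / (1 - beta^2))
  tibble(
    x = x, y = y, beta_std = beta, t = t, df = df,
    p_value = 2 * stats::pt(-abs(t), df), n = n
  )
}

#' @export
print.path_fit <- function(x, ...) {
  cat("<path_fit> ", length(x$model$variables), " variables, ",
    nrow(x$edges), " paths, n = ", x$n_used, "\n",
    sep = ""
  )
  cat(sprintf(
    "chi2(%d) = %.3f, p = %.3f | RMSEA %.3f, NFI %.3f, CFI %.3f, RFI %.3f, PNFI %.3f\n",
    x$df, x$chi2, x$p_value, x$rmsea, x$nfi, x$cfi, x$rfi, x$pnfi
  ))
  print(x$edges, ...)
  invisible(x)
}
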