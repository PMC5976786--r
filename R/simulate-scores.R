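#' Simulate score tables from the EMODEB linear structure
#'
#' Draws the exogenous gaze score from its marginal and generates each
#' endogenous score in topological order as
#' `intercept + sum(coefficient * parent) + Gaussian error`. This score-level
#' generator isolates estimator tests from the behavioral stream dynamics;
#' the default coefficients are the published EMODEB path estimates.
#'
#' @param n Number of participant-session rows.
#' @param model A [path_model()].
#' @param coefficients Tibble `from, to, estimate` of generating
#'   coefficients; default [emodeb_estimates()].
#' @param intercepts Named vector of per-variable intercepts (default 0).
#' @param error_sd Named vector of error standard deviations for the
#'   endogenous variables.
#' @param exo_mean,exo_sd Marginal mean and SD of the exogenous variable(s).
#' @param activity_mix Fraction of rows labeled `robot_play`.
#' @param activity_offsets Optional named vector of mean shifts added to
#'   `robot_play` rows (per variable). Default none: the plain linear
#'   structure.
#' @param clip Truncate scores to `[-100, 100]` (off by default; clipping
#'   bends the linear structure and is only appropriate when mimicking
#'   bounded observed scores).
#' @param seed Optional integer seed.
#' @return List with `scores` (tibble: `session_id, participant_id,
#'   activity`, one column per model variable) and `truth` (the generating
#'   parameters).
#' @export
simulate_scores <- function(n = 84, model = emodeb_model(),
                            coefficients = emodeb_estimates(),
                            intercepts = NULL, error_sd = NULL,
                            exo_mean = 77.65, exo_sd = 15,
                            activity_mix = 0.5, activity_offsets = NULL,
                            clip = FALSE, seed = NULL) {
  stopifnot(n >= 1, activity_mix >= 0, activity_mix <= 1)
  if (!is.null(seed)) set.seed(seed)
  vars <- model$variables
  if (is.null(error_sd)) {
    error_sd <- c(
      LTAct = 30, RoAct = 25, GAct_gsup = 6,
      LTAct_postsup = 6, RoAct_qogest = 6
    )
  }
  endo <- setdiff(vars, model$exogenous)
  missing_sd <- setdiff(endo, names(error_sd))
  if (length(missing_sd) > 0) {
    error_sd[missing_sd] <- 10
  }
  stopifnot(all(error_sd > 0))
  ic <- setNames(rep(0, length(vars)), vars)
  if (!is.null(intercepts)) ic[names(intercepts)] <- intercepts

  co <- left_join(model$edges, coefficients, by = c("from", "to"))
  if (anyNA(co$estimate)) abort("coefficients must cover every model edge")

  n_robot <- round(n * activity_mix)
  activity <- c(
    rep("robot_play", n_robot),
    rep("cognitive_games", n - n_robot)
  )
  off <- function(v) {
    o <- if (!is.null(activity_offsets) && v %in% names(activity_offsets)) {
      activity_offsets[[v]]
    } else {
      0
    }
    o * (activity == "robot_play")
  }

  x <- matrix(0, n, length(vars), dimnames = list(NULL, vars))
  for (v in vars) {
    if (v %in% model$exogenous) {
      x[, v] <- ic[v] + exo_mean + exo_sd * rnorm(n) + off(v)
    } else {
      pa <- co[co$to == v, ]
      x[, v] <- ic[v] + as.vector(x[, pa$from, drop = FALSE] %*% pa$estimate) +
        error_sd[[v]] * rnorm(n) + off(v)
    }
  }
  if (clip) x <- pmin(pmax(x, -100), 100)

  scores <- tibble(
    session_id = sprintf("sim_s%03d", seq_len(n)),
    participant_id = "sim_p1",
    activity = activity
  ) %>% bind_cols(as_tibble(x))

  list(
    scores = scores,
    truth = list(
      coefficients = co, intercepts = ic, error_sd = error_sd,
      exo_mean = exo_mean, exo_sd = exo_sd, activity_mix = activity_mix,
      activity_offsets = activity_offsets, clip = clip
    )
  )
}
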