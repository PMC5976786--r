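#' Tidy a fitted path model
#'
#' @param x A `path_fit` from [fit_path_model()].
#' @param ... Unused.
#' @return Tibble with one row per path: `from, to, estimate, std_estimate,
#'   se, cr, p_value`.
#' @export
tidy.path_fit <- function(x, ...) {
  x$edges
}

#' One-row fit summary of a path model
#'
#' @param x A `path_fit`.
#' @param ... Unused.
#' @return Tibble: `n_used, chi2, df, p_value, rmsea, nfi, cfi, rfi, pnfi,
#'   converged`.
#' @export
glance.path_fit <- function(x, ...) {
  tibble(
    n_used = x$n_used, chi2 = x$chi2, df = x$df, p_value = x$p_value,
    rmsea = x$rmsea, nfi = x$nfi, cfi = x$cfi, rfi = x$rfi, pnfi = x$pnfi,
    converged = x$converged
  )
}

#' Tidy an IRR report
#'
#' @param x An `irr_report`.
#' @param ... Unused.
#' @return The per-behavior tibble with the global and per-group rows bound
#'   on top (`behavior = NA` for aggregate rows).
#' @export
tidy.irr_report <- function(x, ...) {
  bind_rows(
    mutate(x$global, group = "global", behavior = NA_character_),
    mutate(x$per_group, behavior = NA_character_),
    x$per_behavior
  ) %>%
    select(any_of(c(
      "group", "behavior", "mean_pct", "min_pct", "max_pct",
      "po", "pe", "kappa", "excluded", "caution", "n", "undefined"
    )))
}

#' @export
glance.irr_report <- function(x, ...) {
  mutate(x$global,
    tolerance_s = x$config$tolerance_s,
    resolution_s = x$config$resolution_s
  )
}
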