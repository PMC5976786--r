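#' Published ELICSE mean duration percentages
#'
#' Mean/min/max duration percentages (and reported agreement where
#' available) per behavior and activity from the ELICSE development study,
#' shipped as a plain-text fixture. The loader checks internal consistency:
#' within each activity, every group's mean percentages sum to 100 (the
#' arms/hands group includes the rarely observed signs-of-affection
#' gestures; SOAneg, whose observed duration was essentially zero, is not
#' tabulated).
#'
#' @param scheme An [elicse_scheme()] used to attach group labels.
#' @return Tibble: `activity, group, behavior, mean_pct, min_pct, max_pct,
#'   prop, kappa`.
#' @export
elicse_reference_durations <- function(scheme = elicse_scheme()) {
  path <- system.file("extdata", "elicse_reference_durations.csv",
    package = "emodeb", mustWork = TRUE
  )
  x <- readr::read_csv(path, col_types = readr::cols(
    activity = readr::col_character(),
    behavior = readr::col_character(),
    .default = readr::col_double()
  ))
  x$group <- scheme_group_map(scheme)[x$behavior]
  sums <- x %>%
    group_by(.data$activity, .data$group) %>%
    summarise(total = sum(.data$mean_pct), .groups = "drop")
  if (any(abs(sums$total - 100) > 0.05)) {
    abort("reference durations are inconsistent: group means must sum to 100")
  }
  select(
    x, "activity", "group", "behavior", "mean_pct", "min_pct", "max_pct",
    "prop", "kappa"
  )
}

#' Reference durations as a duration table
#'
#' Reshapes the published mean duration percentages into the
#' [duration_table()] format (one pseudo participant-session per activity,
#' zero modifier percentages, SOAneg added at 0), so the score-reduction
#' formulas can be applied directly to the published means.
#'
#' @inheritParams elicse_reference_durations
#' @return A duration-table tibble.
#' @export
reference_duration_table <- function(scheme = elicse_scheme()) {
  ref <- elicse_reference_durations(scheme)
  frame <- tidyr::expand_grid(
    activity = unique(ref$activity),
    scheme$behaviors[, c("code", "group")]
  ) %>% rename(behavior = "code")
  frame %>%
    left_join(ref[, c("activity", "behavior", "mean_pct")],
      by = c("activity", "behavior")
    ) %>%
    mutate(
      session_id = .data$activity,
      participant_id = "reference",
      pct = dplyr::coalesce(.data$mean_pct, 0),
      pct_positive = 0,
      pct_negative = 0
    ) %>%
    select(
      "session_id", "participant_id", "activity", "group", "behavior",
      "pct", "pct_positive", "pct_negative"
    )
}
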