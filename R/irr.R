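#' Time-tolerant confusion matrix between two coders' state sequences
#'
#' Compares two equally discretized label sequences with a temporal
#' tolerance window: for each bin `t`, coder B is credited with coder A's
#' state if B shows that state anywhere within `t - w .. t + w` (with
#' `w = tolerance_s / resolution_s` bins); otherwise B's own state at `t` is
#' used. The matrix is symmetrized by averaging the A-vs-B tally with the
#' transpose of the B-vs-A tally, so the comparison does not depend on which
#' coder is called the reference. With `tolerance_s = 0` this reduces to the
#' plain per-bin confusion matrix.
#'
#' @param a,b Character vectors of per-bin labels, same length (same session,
#'   same group, same resolution).
#' @param labels Label universe for the matrix; defaults to the sorted union
#'   of the observed labels.
#' @param tolerance_s Temporal tolerance window half-width, seconds.
#' @param resolution_s Bin width used for the discretization, seconds.
#' @return A square matrix of class `confusion_matrix` with attribute `n`
#'   (total compared bins).
#' @export
tolerant_confusion <- function(a, b, labels = NULL, tolerance_s = 3,
                               resolution_s = 0.5) {
  if (length(a) != length(b)) {
    abort("coders' sequences have different bin counts; cannot align")
  }
  stopifnot(tolerance_s >= 0, resolution_s > 0)
  if (is.null(labels)) labels <- sort(unique(c(a, b)))
  w <- as.integer(round(tolerance_s / resolution_s))
  m_ab <- directional_tally(a, b, labels, w)
  m_ba <- directional_tally(b, a, labels, w)
  cm <- (m_ab + t(m_ba)) / 2
  structure(cm, n = length(a), class = c("confusion_matrix", class(cm)))
}

# tally (ref[t], best-match of other within +/- w bins)
directional_tally <- function(ref, other, labels, w) {
  n <- length(ref)
  hit <- ref == other
  if (w > 0) {
    for (o in seq_len(w)) {
      hit[(o + 1):n] <- hit[(o + 1):n] | ref[(o + 1):n] == other[1:(n - o)]
      hit[1:(n - o)] <- hit[1:(n - o)] | ref[1:(n - o)] == other[(o + 1):n]
    }
  }
  matched <- ifelse(hit, ref, other)
  m <- table(factor(ref, levels = labels), factor(matched, levels = labels))
  unclass(as.matrix(m))
}

#' Cohen's kappa from a confusion matrix
#'
#' `po` is the proportion of (tolerant) agreement, `pe` the chance agreement
#' from the marginals, and `kappa = (po - pe) / (1 - pe)`. When `pe = 1`
#' (both coders concentrated on the same single state) kappa is undefined and
#' reported as `NA` with `undefined = TRUE` — never coerced to 0 or 1.
#'
#' @param cm A square count matrix (e.g. from [tolerant_confusion()]).
#' @return One-row tibble: `po`, `pe`, `kappa`, `n`, `undefined`.
#' @examples
#' cohen_kappa(matrix(c(40, 10, 10, 40), 2)) # po 0.8, pe 0.5, kappa 0.6
#' @export
cohen_kappa <- function(cm) {
  cm <- unclass(as.matrix(cm))
  n <- sum(cm)
  if (n <= 0) abort("empty confusion matrix")
  po <- sum(diag(cm)) / n
  pe <- sum(rowSums(cm) * colSums(cm)) / n^2
  undefined <- abs(1 - pe) < 1e-12
  tibble(
    po = po,
    pe = pe,
    kappa = if (undefined) NA_real_ else (po - pe) / (1 - pe),
    n = n,
    undefined = undefined
  )
}

#' Per-behavior kappa by 2x2 collapse
#'
#' Collapses the confusion matrix to `behavior` vs. everything else, then
#' applies [cohen_kappa()]. A behavior absent in both coders yields an
#' undefined kappa.
#'
#' @param cm A labeled square count matrix.
#' @param behavior A label of `cm`.
#' @return One-row tibble as in [cohen_kappa()].
#' @export
behavior_kappa <- function(cm, behavior) {
  cm <- unclass(as.matrix(cm))
  labels <- rownames(cm)
  if (is.null(labels) || !behavior %in% labels) {
    abort(paste0("behavior '", behavior, "' is not a label of the matrix"))
  }
  i <- labels == behavior
  m2 <- matrix(c(
    sum(cm[i, i]), sum(cm[i, !i]),
    sum(cm[!i, i]), sum(cm[!i, !i])
  ), nrow = 2, byrow = TRUE)
  cohen_kappa(m2)
}

#' Inter-rater reliability report for two coders
#'
#' Computes the global kappa of the coding system, per-group kappas, and
#' per-behavior kappas between two coders' event logs, following the
#' development-study reporting rules: per-group matrices are pooled across
#' sessions; the global matrix is the block-diagonal pooling of the three
#' groups (behavior codes are disjoint across groups); behaviors with a mean
#' duration below `min_duration_pct` percent are excluded from per-behavior
#' kappa reporting, and behaviors under `caution_pct` percent are flagged for
#' cautious interpretation.
#'
#' @param events_a,events_b Event logs of the two coders covering the same
#'   `(session, participant, group)` keys.
#' @param scheme An [elicse_scheme()].
#' @param durations Optional `(session_id, duration_s)` tibble.
#' @param tolerance_s,resolution_s See [tolerant_confusion()].
#' @param compare_modifiers If `TRUE`, compare compound
#'   `(behavior, modifier)` labels instead of behavior labels.
#' @param min_duration_pct Mean-duration threshold (percent) below which a
#'   behavior is excluded from per-behavior kappa.
#' @param caution_pct Mean-duration threshold (percent) below which a
#'   reported kappa is flagged `caution`.
#' @return An `irr_report`: list with tibbles `global`, `per_group`,
#'   `per_behavior`, plus the pooled matrices in `matrices`.
#' @export
irr_report <- function(events_a, events_b, scheme = elicse_scheme(),
                       durations = NULL, tolerance_s = 3, resolution_s = 0.5,
                       compare_modifiers = FALSE,
                       min_duration_pct = 1, caution_pct = 5) {
  keys <- c("session_id", "participant_id", "group")
  ka <- distinct(events_a[, keys])
  kb <- distinct(events_b[, keys])
  if (nrow(anti_join(ka, kb, by = keys)) > 0 ||
    nrow(anti_join(kb, ka, by = keys)) > 0) {
    abort("coders do not cover the same (session, participant, group) keys")
  }
  durations <- resolve_durations(bind_rows(events_a, events_b), durations)

  bins_a <- discretize_streams(events_a, resolution_s, durations)
  bins_b <- discretize_streams(events_b, resolution_s, durations)
  lab <- function(d) {
    if (compare_modifiers) paste(d$behavior, d$modifier, sep = "/") else d$behavior
  }

  # pooled per-group confusion matrices (sum over sessions/participants)
  per_group_cm <- list()
  for (g in scheme$groups) {
    codes <- scheme$behaviors$code[scheme$behaviors$group == g]
    labels <- if (compare_modifiers) {
      as.vector(outer(codes, scheme$modifiers, paste, sep = "/"))
    } else {
      codes
    }
    da <- filter(bins_a, .data$group == g)
    db <- filter(bins_b, .data$group == g)
    cm <- matrix(0, length(labels), length(labels), dimnames = list(labels, labels))
    split_keys <- interaction(da$session_id, da$participant_id, drop = TRUE)
    for (k in levels(split_keys)) {
      sel <- split_keys == k
      sa <- da[sel, ]
      sb <- semi_join(db, sa[1, c("session_id", "participant_id")],
        by = c("session_id", "participant_id")
      )
      cm_k <- tolerant_confusion(lab(sa), lab(sb),
        labels = labels,
        tolerance_s = tolerance_s, resolution_s = resolution_s
      )
      cm <- cm + unclass(cm_k)
    }
    per_group_cm[[g]] <- cm
  }

  # global: block-diagonal pooling over the three groups
  all_labels <- unlist(lapply(per_group_cm, rownames), use.names = FALSE)
  global_cm <- matrix(0, length(all_labels), length(all_labels),
    dimnames = list(all_labels, all_labels)
  )
  for (g in names(per_group_cm)) {
    l <- rownames(per_group_cm[[g]])
    global_cm[l, l] <- per_group_cm[[g]]
  }

  per_group <- purrr::imap(per_group_cm, function(cm, g) {
    if (sum(cm) == 0) {
      return(tibble(
        group = g, po = NA_real_, pe = NA_real_, kappa = NA_real_,
        n = 0, undefined = NA
      ))
    }
    mutate(cohen_kappa(cm), group = g, .before = 1)
  }) %>% bind_rows()

  # per-behavior: duration % (mean of the two coders, across sessions)
  dur_pct <- bind_rows(events_a, events_b) %>%
    duration_pct_by_coder(scheme, durations) %>%
    group_by(.data$group, .data$behavior) %>%
    summarise(
      mean_pct = mean(.data$pct), min_pct = min(.data$pct),
      max_pct = max(.data$pct), .groups = "drop"
    )

  per_behavior <- dur_pct %>%
    mutate(
      excluded = .data$mean_pct < min_duration_pct,
      caution = !.data$excluded & .data$mean_pct < caution_pct
    )
  kap <- purrr::pmap(
    list(per_behavior$group, per_behavior$behavior, per_behavior$excluded),
    function(g, b, excl) {
      if (excl || compare_modifiers) {
        return(tibble(po = NA_real_, kappa = NA_real_))
      }
      k <- behavior_kappa(per_group_cm[[g]], b)
      tibble(po = k$po, kappa = k$kappa)
    }
  ) %>% bind_rows()
  per_behavior <- bind_cols(per_behavior, kap)

  structure(
    list(
      global = cohen_kappa(global_cm),
      per_group = per_group,
      per_behavior = per_behavior,
      matrices = c(per_group_cm, list(global = global_cm)),
      config = list(
        tolerance_s = tolerance_s, resolution_s = resolution_s,
        compare_modifiers = compare_modifiers,
        min_duration_pct = min_duration_pct, caution_pct = caution_pct
      )
    ),
    class = "irr_report"
  )
}

# per-(coder, session, participant, behavior) duration percentages,
# zero-filled over the scheme inventory
duration_pct_by_coder <- function(events, scheme, durations) {
  obs <- events %>%
    left_join(durations, by = "session_id") %>%
    group_by(
      .data$coder_id, .data$session_id, .data$participant_id,
      .data$behavior
    ) %>%
    summarise(
      pct = 100 * sum(.data$stop_s - .data$start_s) / first(.data$duration_s),
      .groups = "drop"
    )
  frame <- tidyr::expand_grid(
    distinct(events[, c("coder_id", "session_id", "participant_id")]),
    scheme$behaviors[, c("code", "group")]
  ) %>% rename(behavior = "code")
  frame %>%
    left_join(obs, by = c("coder_id", "session_id", "participant_id", "behavior")) %>%
    mutate(pct = dplyr::coalesce(.data$pct, 0))
}

#' @export
print.irr_report <- function(x, ...) {
  cat("<irr_report>  tolerance ", x$config$tolerance_s, " s, resolution ",
    x$config$resolution_s, " s\n",
    sep = ""
  )
  cat("global: po = ", round(x$global$po, 3), ", kappa = ",
    round(x$global$kappa, 3), "\n",
    sep = ""
  )
  cat("\nper group:\n")
  print(x$per_group, ...)
  cat("\nper behavior:\n")
  print(x$per_behavior, n = Inf, ...)
  invisible(x)
}
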