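#' The ELICSE coding scheme
#'
#' Constructs the default ELICSE scheme: three mutually exclusive behavior
#' groups corresponding to body parts (head, torso, arms/hands), each holding
#' directional behaviors addressed to one of four operational foci (partner,
#' facilitator/experimenter, game, none) plus — in the arms/hands group —
#' non-directional signs of affection with an intrinsic valence. Every
#' directional behavior may carry a positive/negative/neutral affect modifier.
#'
#' "game" denotes the board games during cognitive stimulation and the robot
#' during free play. Facilitator and experimenter are one operational focus
#' because every scored behavior merges them (GFE, RoFE). SOAneg is part of
#' the scheme even though its observed duration in the development study was
#' essentially zero.
#'
#' @return An object of class `elicse_scheme`: a list with
#'   * `behaviors`: tibble with columns `code`, `group`, `focus`,
#'     `intrinsic_valence`, `description`;
#'   * `groups`: the three group labels;
#'   * `modifiers`: `c("positive", "negative", "neutral")`.
#' @examples
#' sch <- elicse_scheme()
#' sch$behaviors
#' @export
elicse_scheme <- function() {
  behaviors <- tibble::tribble(
    ~code,     ~group,       ~focus,                      ~intrinsic_valence, ~description,
    "GP",      "head",       "partner",                   NA_character_, "Gaze toward partner",
    "GFE",     "head",       "facilitator_experimenter",  NA_character_, "Gaze toward facilitator/experimenter",
    "GG",      "head",       "game",                      NA_character_, "Gaze toward game",
    "NoneH",   "head",       "none",                      NA_character_, "None of the target head movements",
    "LIP",     "torso",      "partner",                   NA_character_, "Lean in partner",
    "NRLTG",   "torso",      "game",                      NA_character_, "Near reach/lean toward game",
    "NoneT",   "torso",      "none",                      NA_character_, "None of the target torso movements",
    "RoP",     "arms_hands", "partner",                   NA_character_, "Reach out partner",
    "RoFE",    "arms_hands", "facilitator_experimenter",  NA_character_, "Reach out facilitator/experimenter",
    "MG",      "arms_hands", "game",                      NA_character_, "Manipulate game",
    "SOApos",  "arms_hands", "affect_gesture",            "positive",    "Positive signs of affection involving arms/hands",
    "SOAneg",  "arms_hands", "affect_gesture",            "negative",    "Negative signs of affection involving arms/hands",
    "NoneAH",  "arms_hands", "none",                      NA_character_, "None of the target arms/hands movements"
  )
  new_elicse_scheme(
    behaviors = behaviors,
    groups = c("head", "torso", "arms_hands"),
    modifiers = c("positive", "negative", "neutral")
  )
}

#' The four operational foci of the scheme
#' @return Character vector of focus labels.
#' @export
elicse_foci <- function() {
  c("partner", "facilitator_experimenter", "game", "none")
}

new_elicse_scheme <- function(behaviors, groups, modifiers) {
  scheme <- structure(
    list(
      behaviors = tibble::as_tibble(behaviors),
      groups = groups,
      modifiers = modifiers
    ),
    class = "elicse_scheme"
  )
  validate_scheme(scheme)
  scheme
}

validate_scheme <- function(scheme) {
  b <- scheme$behaviors
  if (length(scheme$groups) != 3L) {
    abort("a coding scheme must declare exactly 3 body-part groups")
  }
  if (anyDuplicated(b$code)) {
    abort(paste0(
      "behavior codes must be unique within the scheme; duplicated: ",
      paste(unique(b$code[duplicated(b$code)]), collapse = ", ")
    ))
  }
  if (!all(b$group %in% scheme$groups)) {
    abort("every behavior must belong to a declared group")
  }
  ok_focus <- c(elicse_foci(), "affect_gesture")
  if (!all(b$focus %in% ok_focus)) {
    abort("behavior focus must be a declared focus or 'affect_gesture'")
  }
  # intrinsic valence set iff the behavior is an affect gesture
  has_val <- !is.na(b$intrinsic_valence)
  if (!all(has_val == (b$focus == "affect_gesture"))) {
    abort("intrinsic_valence must be set exactly for affect-gesture behaviors")
  }
  none_per_group <- tapply(b$focus == "none", b$group, sum)
  if (!all(none_per_group[scheme$groups] == 1L)) {
    abort("every group must contain exactly one 'none' behavior")
  }
  invisible(scheme)
}

#' @export
print.elicse_scheme <- function(x, ...) {
  cat("<elicse_scheme>\n")
  cat("  groups:    ", paste(x$groups, collapse = ", "), "\n")
  cat("  modifiers: ", paste(x$modifiers, collapse = ", "), "\n")
  cat("  behaviors: ", nrow(x$behaviors), "\n")
  print(x$behaviors, ...)
  invisible(x)
}

#' Coerce a list (e.g. parsed YAML/JSON) to a coding scheme
#'
#' The scheme is user-extensible: other activity settings can declare their
#' own behavior inventory as long as the structural invariants hold (three
#' groups, one "none" behavior per group, unique codes).
#'
#' @param x A list with elements `behaviors` (data frame or list of records),
#'   `groups`, `modifiers`.
#' @return An `elicse_scheme`.
#' @export
as_elicse_scheme <- function(x) {
  if (inherits(x, "elicse_scheme")) {
    return(x)
  }
  beh <- x$behaviors
  if (!is.data.frame(beh) && is.list(beh) && !is.null(beh$code)) {
    # column-list form (e.g. YAML serialization of a data frame)
    beh <- tibble::as_tibble(lapply(beh, function(col) {
      if (is.list(col)) {
        vapply(col, function(v) if (is.null(v)) NA_character_ else as.character(v), "")
      } else {
        col
      }
    }))
  }
  if (!is.data.frame(beh)) {
    beh <- dplyr::bind_rows(lapply(beh, function(r) {
      tibble(
        code = r$code,
        group = r$group,
        focus = r$focus,
        intrinsic_valence = r$intrinsic_valence %||% NA_character_,
        description = r$description %||% NA_character_
      )
    }))
  }
  beh <- tibble::as_tibble(beh)
  if (!"intrinsic_valence" %in% names(beh)) beh$intrinsic_valence <- NA_character_
  if (!"description" %in% names(beh)) beh$description <- NA_character_
  new_elicse_scheme(
    behaviors = beh[, c("code", "group", "focus", "intrinsic_valence", "description")],
    groups = as.character(x$groups),
    modifiers = as.character(x$modifiers %||% c("positive", "negative", "neutral"))
  )
}

#' Read / write a coding scheme
#'
#' Serialized as YAML (default) or JSON, chosen by file extension.
#'
#' @param path File path ending in `.yaml`, `.yml` or `.json`.
#' @return `read_scheme()` returns an `elicse_scheme`; `write_scheme()`
#'   returns `path` invisibly.
#' @export
read_scheme <- function(path) {
  x <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  as_elicse_scheme(x)
}

#' @rdname read_scheme
#' @param scheme An `elicse_scheme`.
#' @export
write_scheme <- function(scheme, path) {
  stopifnot(inherits(scheme, "elicse_scheme"))
  x <- list(
    groups = scheme$groups,
    modifiers = scheme$modifiers,
    behaviors = as.data.frame(scheme$behaviors)
  )
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(x, path, dataframe = "rows", auto_unbox = TRUE, na = "null")
  } else {
    yaml::write_yaml(x, path)
  }
  invisible(path)
}

# focus of each behavior code, as a named vector
scheme_focus_map <- function(scheme) {
  setNames(scheme$behaviors$focus, scheme$behaviors$code)
}

scheme_group_map <- function(scheme) {
  setNames(scheme$behaviors$group, scheme$behaviors$code)
}

scheme_none_codes <- function(scheme) {
  scheme$behaviors$code[scheme$behaviors$focus == "none"]
}

`%||%` <- function(a, b) if (is.null(a)) b else a
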