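## Scoring a patient assessment against a categorization matrix.

#' Assign the severity level of one assessment value
#'
#' Applies a variable's three severity criteria to a raw value. Numeric values
#' are matched against the printed intervals; a value falling in a gap between
#' two printed intervals is resolved by the variable's `gap_policy`
#' (`"nearest-worse"` assigns the more severe of the two adjacent levels,
#' `"error"` refuses). The not-measurable marker maps to the variable's
#' declared `not_measurable_level`. Compound variables (e.g. PEEP/FiO2) level
#' each component independently and keep the worst.
#'
#' @param variable a `cmcr_variable` (an element of `matrix$variables`).
#' @param value numeric value, label, [NOT_MEASURABLE], or for compound
#'   variables a named numeric vector or a `"a/b"` string in component order.
#' @param sex `"male"` or `"female"`; required for sex-conditional variables.
#' @return list with `level` (`"X"`, `"Y"` or `"Z"`) and `points` (1, 2 or 3).
#' @export
assign_level <- function(variable, value, sex = NULL) {
  stopifnot(inherits(variable, "cmcr_variable"))
  if (is_not_measurable(value)) {
    lv <- variable$not_measurable_level
    if (is.null(lv))
      stop("variable '", variable$name, "' has no not-measurable level",
           call. = FALSE)
    return(list(level = lv, points = LEVEL_POINTS[[lv]]))
  }
  if (variable$compound) {
    vals <- parse_compound_value(value, variable)
    lvs <- vapply(names(variable$components), function(k) {
      cp <- variable$components[[k]]
      if (vals[[k]] < cp$domain$min || vals[[k]] > cp$domain$max)
        stop("variable '", variable$name, "': component ", k, " value ",
             vals[[k]], " outside domain [", cp$domain$min, ", ",
             cp$domain$max, "]", call. = FALSE)
      level_numeric(vals[[k]], cp$criteria, cp$domain, "any",
                    variable$gap_policy, paste0(variable$name, ".", k))
    }, character(1))
    lv <- LEVELS[max(match(lvs, LEVELS))]  # worst component wins
    return(list(level = lv, points = LEVEL_POINTS[[lv]]))
  }
  if (variable$domain$type == "labels") {
    value <- as.character(value)
    if (!value %in% variable$domain$labels)
      stop("variable '", variable$name, "': label '", value,
           "' not in domain", call. = FALSE)
    for (lv in LEVELS) {
      if (value %in% variable$criteria[[lv]]$labels)
        return(list(level = lv, points = LEVEL_POINTS[[lv]]))
    }
    stop("variable '", variable$name, "': label '", value,
         "' not mapped by any level", call. = FALSE)  # unreachable if validated
  }
  x <- suppressWarnings(as.numeric(value))
  if (is.na(x))
    stop("variable '", variable$name, "': value '", value,
         "' is not numeric", call. = FALSE)
  if (x < variable$domain$min || x > variable$domain$max)
    stop("variable '", variable$name, "': value ", x, " outside domain [",
         variable$domain$min, ", ", variable$domain$max, "]", call. = FALSE)
  key <- "any"
  if (variable$sex_conditional) {
    if (is.null(sex) || !sex %in% c("male", "female"))
      stop("variable '", variable$name,
           "' is sex-conditional; sex must be 'male' or 'female'", call. = FALSE)
    key <- sex
  }
  lv <- level_numeric(x, variable$criteria, variable$domain, key,
                      variable$gap_policy, variable$name)
  list(level = lv, points = LEVEL_POINTS[[lv]])
}

level_numeric <- function(x, criteria, domain, key, gap_policy, name) {
  hits <- LEVELS[vapply(LEVELS, function(lv)
    in_interval(x, criteria[[lv]]$intervals[[key]]), logical(1))]
  if (length(hits) == 1L) return(hits)
  if (length(hits) > 1L)
    stop("variable '", name, "': value ", x, " matches several levels (",
         paste(hits, collapse = ", "), ")", call. = FALSE)
  if (gap_policy == "error")
    stop("variable '", name, "': value ", x,
         " falls between printed intervals and gap_policy is 'error'",
         call. = FALSE)
  # nearest-worse: take the more severe of the two printed intervals adjacent
  # to the gap the value fell into
  below <- above <- NULL
  for (lv in LEVELS) {
    iv <- criteria[[lv]]$intervals[[key]]
    if (iv$max < x || (iv$max == x && iv$max_open)) {
      if (is.null(below) || iv$max > criteria[[below]]$intervals[[key]]$max) below <- lv
    }
    if (iv$min > x || (iv$min == x && iv$min_open)) {
      if (is.null(above) || iv$min < criteria[[above]]$intervals[[key]]$min) above <- lv
    }
  }
  cand <- c(below, above)
  if (length(cand) == 0L)
    stop("variable '", name, "': value ", x, " cannot be leveled", call. = FALSE)
  cand[which.max(LEVEL_POINTS[cand])]
}

parse_compound_value <- function(value, variable) {
  comp <- names(variable$components)
  if (is.character(value) && length(value) == 1L) {
    parts <- suppressWarnings(as.numeric(strsplit(value, "/", fixed = TRUE)[[1]]))
    if (length(parts) != length(comp) || anyNA(parts))
      stop("variable '", variable$name, "': compound value '", value,
           "' must be ", length(comp), " numbers separated by '/' (",
           paste(comp, collapse = "/"), ")", call. = FALSE)
    names(parts) <- comp
    return(as.list(parts))
  }
  if (is.numeric(value)) {
    if (is.null(names(value))) {
      if (length(value) != length(comp))
        stop("variable '", variable$name, "': compound value needs ",
             length(comp), " components", call. = FALSE)
      names(value) <- comp
    }
    if (!setequal(names(value), comp))
      stop("variable '", variable$name, "': compound components must be ",
           paste(comp, collapse = ", "), call. = FALSE)
    return(as.list(value[comp]))
  }
  stop("variable '", variable$name, "': unsupported compound value", call. = FALSE)
}

#' Categorize one patient assessment
#'
#' Scores every variable of the matrix, sums the points into the total score
#' TS and brackets TS into the low/medium/high complexity category. The
#' per-variable levels are retained so that two patients with the same
#' category but different clinical drivers remain distinguishable.
#'
#' @param assessment a list (or `cmcr_assessment`) with at least `values`, a
#'   named list giving one raw value per matrix variable; optionally
#'   `patient_id`, `timestamp`, `unit`, `sex`.
#' @param matrix a `cmcr_matrix`.
#' @param on_missing `"error"` (default) refuses incomplete assessments;
#'   `"worst"` imputes level Z for absent variables, mirroring the tables'
#'   treatment of unmeasurable values.
#' @return a `cmcr_result`: `per_variable` data frame (variable, level,
#'   points), `total_score`, `category`, `therapeutic_load` (if the matrix
#'   carries a load map), `timestamp`, `matrix_id`, `patient_id`.
#' @export
categorize <- function(assessment, matrix, on_missing = c("error", "worst")) {
  stopifnot(inherits(matrix, "cmcr_matrix"))
  on_missing <- match.arg(on_missing)
  values <- assessment$values
  if (is.null(values)) stop("assessment has no values", call. = FALSE)
  extra <- setdiff(names(values), names(matrix$variables))
  if (length(extra) > 0L)
    stop("assessment has values for unknown variable(s): ",
         paste(extra, collapse = ", "), call. = FALSE)
  missing <- setdiff(names(matrix$variables), names(values))
  if (length(missing) > 0L && on_missing == "error")
    stop("assessment incomplete; missing variable(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  per <- lapply(names(matrix$variables), function(nm) {
    if (nm %in% missing) {
      list(level = "Z", points = LEVEL_POINTS[["Z"]])
    } else {
      assign_level(matrix$variables[[nm]], values[[nm]], sex = assessment$sex)
    }
  })
  ts <- sum(vapply(per, `[[`, 0L, "points"))
  res <- list(
    patient_id = assessment$patient_id,
    matrix_id = matrix$id,
    timestamp = assessment$timestamp,
    unit = assessment$unit,
    per_variable = data.frame(
      variable = names(matrix$variables),
      level = vapply(per, `[[`, "", "level"),
      points = vapply(per, function(p) as.integer(p$points), 0L),
      imputed = names(matrix$variables) %in% missing,
      row.names = NULL
    ),
    total_score = as.integer(ts),
    category = category_of_score(ts, category_ranges(matrix))
  )
  if (!is.null(matrix$load_map))
    res$therapeutic_load <- assign_therapeutic_load(res$category, matrix$load_map)
  class(res) <- "cmcr_result"
  res
}

#' @export
print.cmcr_result <- function(x, ...) {
  cat(sprintf("TS = %d -> %s complexity  [matrix %s%s]\n",
              x$total_score, x$category, x$matrix_id,
              if (!is.null(x$patient_id)) paste0("; patient ", x$patient_id) else ""))
  print(x$per_variable, row.names = FALSE)
  if (!is.null(x$therapeutic_load))
    cat("therapeutic load:", x$therapeutic_load, "session(s)\n")
  invisible(x)
}

#' Therapeutic load for a complexity category
#'
#' The model associates each complexity category with a number of therapy
#' sessions. The published tables do not print these values, so the package
#' requires an explicit map and refuses to invent defaults; the map must be
#' non-decreasing from low to high.
#'
#' @param category `"low"`, `"medium"` or `"high"`, or a `cmcr_result`.
#' @param load_map named list/vector with numeric entries `low`, `medium`,
#'   `high`.
#' @return the number of sessions for the category.
#' @export
assign_therapeutic_load <- function(category, load_map) {
  if (inherits(category, "cmcr_result")) category <- category$category
  if (!category %in% CATEGORIES)
    stop("category must be one of ", paste(CATEGORIES, collapse = ", "),
         call. = FALSE)
  lm_ <- validate_load_map(load_map)
  lm_[[category]]
}

validate_load_map <- function(load_map) {
  if (is.null(load_map)) stop("a therapeutic load map is required", call. = FALSE)
  lm_ <- unlist(load_map)
  if (!setequal(names(lm_), CATEGORIES))
    stop("load map must have entries low, medium and high", call. = FALSE)
  lm_ <- lm_[CATEGORIES]
  if (any(diff(lm_) < 0))
    stop("load map must be non-decreasing from low to high complexity",
         call. = FALSE)
  as.list(lm_)
}

## ---- re-categorization schedule --------------------------------------------

WEEKDAYS <- c("Monday", "Tuesday", "Wednesday", "Thursday", "Friday",
              "Saturday", "Sunday")

#' Re-categorization policy
#'
#' Units re-categorize on different schedules: ICU patients daily (and
#' whenever their condition changes, e.g. extubation), neurorehabilitation
#' patients weekly on a fixed weekday (Wednesday at the originating hospital).
#'
#' @param mode `"daily"`, `"weekly-on-fixed-weekday"` or `"on-event"`.
#' @param weekday weekday name, required for the weekly mode.
#' @param event_kinds character vector of watched event kinds for
#'   `"on-event"` (e.g. `"ventilatory-support-change"`).
#' @return a `cmcr_recat_policy`.
#' @export
recat_policy <- function(mode = c("daily", "weekly-on-fixed-weekday", "on-event"),
                         weekday = NULL, event_kinds = NULL) {
  mode <- match.arg(mode)
  if (mode == "weekly-on-fixed-weekday") {
    if (is.null(weekday)) stop("weekly policy requires a weekday", call. = FALSE)
    weekday <- match.arg(weekday, WEEKDAYS)
  }
  structure(list(mode = mode, weekday = weekday,
                 event_kinds = unlist(event_kinds)),
            class = "cmcr_recat_policy")
}

weekday_of <- function(d) {
  # ISO weekday, locale-independent: 1 = Monday ... 7 = Sunday
  WEEKDAYS[((as.POSIXlt(d)$wday + 6L) %% 7L) + 1L]
}

#' Is a re-categorization due?
#'
#' @param last timestamp (Date or POSIXct) of the last categorization.
#' @param now current timestamp; must not precede `last`.
#' @param policy a `cmcr_recat_policy`.
#' @param events optional list of events, each a list with `kind` and `time`;
#'   consulted by the `"on-event"` mode.
#' @return `TRUE` if a new categorization is due at `now`.
#' @export
recategorization_due <- function(last, now, policy, events = NULL) {
  stopifnot(inherits(policy, "cmcr_recat_policy"))
  if (as.numeric(as.POSIXct(now)) < as.numeric(as.POSIXct(last)))
    stop("'now' precedes the last categorization", call. = FALSE)
  switch(policy$mode,
    "daily" = as.Date(now) > as.Date(last),
    "weekly-on-fixed-weekday" =
      weekday_of(now) == policy$weekday && as.Date(now) > as.Date(last),
    "on-event" = {
      if (length(events) == 0L) return(FALSE)
      any(vapply(events, function(ev) {
        (is.null(policy$event_kinds) || ev$kind %in% policy$event_kinds) &&
          as.numeric(as.POSIXct(ev$time)) > as.numeric(as.POSIXct(last)) &&
          as.numeric(as.POSIXct(ev$time)) <= as.numeric(as.POSIXct(now))
      }, logical(1)))
    })
}

## ---- batch scoring ----------------------------------------------------------

#' Categorize a long-format assessment table
#'
#' Takes the package's long assessment format (one row per variable per
#' assessment: `patient_id`, `matrix_id`, `timestamp`, `unit`, `variable`,
#' `value`, `sex`) and scores every assessment. Validation failures are
#' collected and reported per assessment rather than aborting on the first.
#'
#' @param df a data frame in the long assessment schema.
#' @param matrix a `cmcr_matrix`; rows with a different `matrix_id` are an
#'   error.
#' @param on_missing passed to [categorize()].
#' @return data frame with one row per assessment: `patient_id`, `matrix_id`,
#'   `timestamp`, `unit`, `total_score`, `category`, plus an `audit`
#'   attribute holding the per-variable breakdown.
#' @export
categorize_table <- function(df, matrix, on_missing = c("error", "worst")) {
  stopifnot(inherits(matrix, "cmcr_matrix"))
  on_missing <- match.arg(on_missing)
  need <- c("patient_id", "timestamp", "variable", "value")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L)
    stop("assessment table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if ("matrix_id" %in% names(df) && any(df$matrix_id != matrix$id))
    stop("assessment table references matrix_id other than '", matrix$id, "'",
         call. = FALSE)
  key <- paste(df$patient_id, df$timestamp, sep = "\r")
  groups <- split(seq_len(nrow(df)), key)
  rows <- list(); audits <- list(); errors <- character(0)
  for (g in groups) {
    sub <- df[g, , drop = FALSE]
    if (anyDuplicated(sub$variable)) {
      errors <- c(errors, sprintf("patient %s @ %s: duplicated variable rows",
                                  sub$patient_id[1], sub$timestamp[1]))
      next
    }
    a <- list(
      patient_id = sub$patient_id[1],
      timestamp = sub$timestamp[1],
      unit = if ("unit" %in% names(sub)) sub$unit[1] else NA_character_,
      sex = if ("sex" %in% names(sub) && any(!is.na(sub$sex) & nzchar(sub$sex)))
        sub$sex[which(!is.na(sub$sex) & nzchar(sub$sex))[1]] else NULL,
      values = stats::setNames(as.list(sub$value), sub$variable)
    )
    res <- tryCatch(categorize(a, matrix, on_missing = on_missing),
                    error = function(e)
                      sprintf("patient %s @ %s: %s", a$patient_id, a$timestamp,
                              conditionMessage(e)))
    if (is.character(res)) { errors <- c(errors, res); next }
    rows[[length(rows) + 1L]] <- data.frame(
      patient_id = res$patient_id, matrix_id = res$matrix_id,
      timestamp = res$timestamp, unit = a$unit,
      total_score = res$total_score, category = res$category,
      row.names = NULL)
    audits[[length(audits) + 1L]] <- cbind(
      patient_id = res$patient_id, timestamp = res$timestamp,
      res$per_variable)
  }
  if (length(errors) > 0L)
    stop("categorization failed for ", length(errors), " assessment(s):\n  ",
         paste(errors, collapse = "\n  "), call. = FALSE)
  out <- do.call(rbind, rows)
  out <- out[order(out$patient_id, out$timestamp), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "audit") <- do.call(rbind, audits)
  out
}
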