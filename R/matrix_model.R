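LEVELS <- c("X", "Y", "Z")
LEVEL_POINTS <- c(X = 1L, Y = 2L, Z = 3L)
CATEGORIES <- c("low", "medium", "high")

#' Marker used for assessments that could not be measured
#'
#' A clinical variable may be impossible to assess (e.g. muscle strength in a
#' sedated patient). Matrices declare, per variable, which severity level such
#' a value maps to; the motor variables place it in the 3-point column while
#' static compliance places it in the 1-point column.
#' @export
NOT_MEASURABLE <- "NM"

is_not_measurable <- function(x) {
  is.character(x) && length(x) == 1L &&
    tolower(gsub("[ _-]", "", x)) %in% c("nm", "notmeasurable")
}

## ---- interval helpers -------------------------------------------------------

new_interval <- function(min = -Inf, max = Inf, min_open = FALSE, max_open = FALSE) {
  if (min > max) stop("interval has lower bound above upper bound", call. = FALSE)
  list(min = as.numeric(min), max = as.numeric(max),
       min_open = isTRUE(min_open), max_open = isTRUE(max_open))
}

in_interval <- function(x, iv) {
  lower_ok <- if (iv$min_open) x > iv$min else x >= iv$min
  upper_ok <- if (iv$max_open) x < iv$max else x <= iv$max
  lower_ok && upper_ok
}

intervals_overlap <- function(a, b) {
  left_ok <- a$min < b$max || (a$min == b$max && !a$min_open && !b$max_open)
  right_ok <- b$min < a$max || (b$min == a$max && !b$min_open && !a$max_open)
  left_ok && right_ok
}

parse_interval <- function(spec, domain) {
  iv <- new_interval(
    min = if (!is.null(spec$min)) spec$min else domain$min,
    max = if (!is.null(spec$max)) spec$max else domain$max,
    min_open = isTRUE(spec$min_open),
    max_open = isTRUE(spec$max_open)
  )
  iv
}

## ---- variable parsing -------------------------------------------------------

parse_domain <- function(spec, name) {
  if (is.null(spec$type)) stop("variable '", name, "': domain needs a type", call. = FALSE)
  if (spec$type == "numeric") {
    list(type = "numeric",
         min = if (!is.null(spec$min)) as.numeric(spec$min) else -Inf,
         max = if (!is.null(spec$max)) as.numeric(spec$max) else Inf)
  } else if (spec$type == "labels") {
    labs <- as.character(unlist(spec$labels))
    if (length(labs) < 1L) stop("variable '", name, "': empty label domain", call. = FALSE)
    list(type = "labels", labels = labs, ordered = isTRUE(spec$ordered))
  } else {
    stop("variable '", name, "': unknown domain type '", spec$type, "'", call. = FALSE)
  }
}

# Normalize one criterion cell (the config fragment for one severity level of
# one variable) into either $labels or $intervals (keyed "any" or by sex).
parse_criterion <- function(spec, level, domain, sex_conditional, name) {
  if (!is.null(spec$points) && as.integer(spec$points) != LEVEL_POINTS[[level]]) {
    stop("variable '", name, "': level ", level, " must be worth ",
         LEVEL_POINTS[[level]], " point(s), config claims ", spec$points,
         call. = FALSE)
  }
  out <- list(level = level, points = LEVEL_POINTS[[level]],
              description = spec$description)
  if (domain$type == "labels") {
    labs <- as.character(unlist(spec$labels))
    bad <- setdiff(labs, domain$labels)
    if (length(bad) > 0L)
      stop("variable '", name, "': labels outside domain: ",
           paste(bad, collapse = ", "), call. = FALSE)
    out$labels <- labs
    return(out)
  }
  if (sex_conditional) {
    if (is.null(spec$male) || is.null(spec$female))
      stop("variable '", name, "': sex-conditional criterion for level ", level,
           " must define both male and female intervals", call. = FALSE)
    out$intervals <- list(male = parse_interval(spec$male, domain),
                          female = parse_interval(spec$female, domain))
  } else {
    out$intervals <- list(any = parse_interval(spec, domain))
  }
  out
}

# YAML 1.1 parses a bare key/value `Y` as the boolean TRUE; map it back.
normalize_level_name <- function(x) {
  x <- as.character(x)
  x[x %in% c("TRUE", "yes", "y")] <- "Y"
  x
}

parse_criteria_set <- function(spec, domain, sex_conditional, name) {
  names(spec) <- normalize_level_name(names(spec))
  if (!setequal(names(spec), LEVELS))
    stop("variable '", name, "': criteria must be exactly X, Y and Z", call. = FALSE)
  crit <- lapply(LEVELS, function(lv)
    parse_criterion(spec[[lv]], lv, domain, sex_conditional, name))
  names(crit) <- LEVELS
  validate_criteria_set(crit, domain, name)
  crit
}

validate_criteria_set <- function(crit, domain, name) {
  if (domain$type == "labels") {
    all_labs <- unlist(lapply(crit, `[[`, "labels"))
    if (anyDuplicated(all_labs))
      stop("variable '", name, "': a label is claimed by two severity levels",
           call. = FALSE)
    missing <- setdiff(domain$labels, all_labs)
    if (length(missing) > 0L)
      stop("variable '", name, "': domain labels not covered by any level: ",
           paste(missing, collapse = ", "), call. = FALSE)
    return(invisible(crit))
  }
  keys <- names(crit$X$intervals)
  for (key in keys) {
    for (i in 1:2) for (j in (i + 1):3) {
      a <- crit[[LEVELS[i]]]$intervals[[key]]
      b <- crit[[LEVELS[j]]]$intervals[[key]]
      if (intervals_overlap(a, b))
        stop("variable '", name, "': levels ", LEVELS[i], " and ", LEVELS[j],
             if (key != "any") paste0(" (", key, ")"),
             " have overlapping intervals", call. = FALSE)
    }
  }
  invisible(crit)
}

parse_variable <- function(spec) {
  name <- spec$name
  if (is.null(name) || !nzchar(name)) stop("variable without a name", call. = FALSE)
  v <- list(
    name = name,
    label = if (!is.null(spec$label)) spec$label else name,
    units = spec$units,
    sex_conditional = isTRUE(spec$sex_conditional),
    compound = isTRUE(spec$compound),
    not_measurable_level = if (!is.null(spec$not_measurable_level))
      normalize_level_name(spec$not_measurable_level) else NULL,
    gap_policy = if (!is.null(spec$gap_policy)) spec$gap_policy else "nearest-worse"
  )
  if (!v$gap_policy %in% c("nearest-worse", "error"))
    stop("variable '", name, "': unknown gap_policy '", v$gap_policy, "'", call. = FALSE)
  if (!is.null(v$not_measurable_level) && !v$not_measurable_level %in% LEVELS)
    stop("variable '", name, "': not_measurable_level must be X, Y or Z", call. = FALSE)
  if (v$compound) {
    if (is.null(spec$components) || length(spec$components) < 2L)
      stop("variable '", name, "': compound variable needs >= 2 components", call. = FALSE)
    v$combine <- if (!is.null(spec$combine)) spec$combine else "worst"
    if (v$combine != "worst")
      stop("variable '", name, "': only combine: worst is supported", call. = FALSE)
    v$components <- lapply(spec$components, function(cs) {
      dom <- parse_domain(cs$domain, paste0(name, ".", cs$name))
      list(name = cs$name, units = cs$units, domain = dom,
           criteria = parse_criteria_set(cs$criteria, dom, FALSE,
                                         paste0(name, ".", cs$name)))
    })
    names(v$components) <- vapply(v$components, `[[`, "", "name")
  } else {
    v$domain <- parse_domain(spec$domain, name)
    v$criteria <- parse_criteria_set(spec$criteria, v$domain, v$sex_conditional, name)
  }
  class(v) <- "cmcr_variable"
  v
}

## ---- matrix construction ----------------------------------------------------

#' Load a categorization matrix from a config file or list
#'
#' A categorization matrix maps a set of standardized clinical assessments to
#' three severity levels per variable (X worth 1 point, Y worth 2, Z worth 3).
#' The total score over \eqn{n} variables therefore lies in \eqn{[n, 3n]}, and
#' its position relative to the column sums \eqn{\Sigma x = n},
#' \eqn{\Sigma y = 2n}, \eqn{\Sigma z = 3n} determines the patient's
#' complexity category (low, medium, high).
#'
#' @param source path to a YAML or JSON matrix definition, or an equivalent
#'   named list already in memory.
#' @return a validated `cmcr_matrix` object with derived score bounds.
#' @seealso [cmcr_matrix()] for the two matrices shipped with the package,
#'   [score_bounds()], [category_ranges()].
#' @export
load_matrix <- function(source) {
  if (is.character(source) && length(source) == 1L) {
    if (!file.exists(source)) stop("matrix config not found: ", source, call. = FALSE)
    spec <- if (grepl("\\.json$", source, ignore.case = TRUE)) {
      jsonlite::read_json(source, simplifyVector = FALSE)
    } else {
      yaml::read_yaml(source)
    }
  } else if (is.list(source)) {
    spec <- source
  } else {
    stop("source must be a file path or a list", call. = FALSE)
  }
  build_matrix(spec)
}

build_matrix <- function(spec) {
  if (is.null(spec$id)) stop("matrix config needs an id", call. = FALSE)
  if (is.null(spec$variables) || length(spec$variables) < 1L)
    stop("matrix '", spec$id, "' has no variables", call. = FALSE)
  vars <- lapply(spec$variables, parse_variable)
  nms <- vapply(vars, `[[`, "", "name")
  if (anyDuplicated(nms))
    stop("matrix '", spec$id, "': duplicate variable names: ",
         paste(unique(nms[duplicated(nms)]), collapse = ", "), call. = FALSE)
  names(vars) <- nms
  n <- length(vars)
  m <- list(
    id = spec$id,
    name = if (!is.null(spec$name)) spec$name else spec$id,
    specialty = spec$specialty,
    variables = vars,
    n = n,
    sigma_x = n,
    sigma_y = 2L * n,
    sigma_z = 3L * n,
    load_map = if (!is.null(spec$load_map)) validate_load_map(spec$load_map) else NULL,
    recat_policy = if (!is.null(spec$recat_policy))
      do.call(recat_policy, spec$recat_policy) else NULL
  )
  class(m) <- "cmcr_matrix"
  m
}

#' Built-in categorization matrices
#'
#' The package ships the two matrices published with the model: the motor
#' rehabilitation matrix for ICU patients (`"icu_motor"`: MRC-Sum Score,
#' FSS-ICU, handgrip dynamometry, S5Q; n = 4) and the adult pulmonary
#' rehabilitation matrix for invasively ventilated patients
#' (`"pulmonary_imv"`: auscultation, ventilatory assistance, secretion,
#' minute volume, PEEP/FiO2, static compliance; n = 6).
#'
#' @param id one of `"icu_motor"`, `"pulmonary_imv"`.
#' @return a `cmcr_matrix`.
#' @export
cmcr_matrix <- function(id = c("icu_motor", "pulmonary_imv")) {
  id <- match.arg(id)
  path <- system.file("extdata", "matrices", paste0(id, ".yaml"),
                      package = "cmcr", mustWork = TRUE)
  load_matrix(path)
}

#' @export
print.cmcr_matrix <- function(x, ...) {
  cat("Categorization matrix:", x$name, sprintf("[%s]\n", x$id))
  if (!is.null(x$specialty)) cat("  specialty:", x$specialty, "\n")
  cat(sprintf("  %d variables; score bounds Sx=%d Sy=%d Sz=%d\n",
              x$n, x$sigma_x, x$sigma_y, x$sigma_z))
  r <- category_ranges(x)
  cat(sprintf("  low = %d, medium = %d-%d, high = %d-%d\n",
              r$low[1], r$medium[1], r$medium[2], r$high[1], r$high[2]))
  for (v in x$variables)
    cat("  -", v$label,
        if (v$compound) "(compound)" else if (v$sex_conditional) "(sex-conditional)" else "",
        "\n")
  invisible(x)
}

## ---- derived quantities -----------------------------------------------------

#' Score bounds of a matrix
#'
#' Returns the column sums \eqn{(\Sigma x, \Sigma y, \Sigma z) = (n, 2n, 3n)}
#' that anchor the complexity categories.
#'
#' @param matrix a `cmcr_matrix`.
#' @return named integer vector `c(sigma_x, sigma_y, sigma_z)`.
#' @export
score_bounds <- function(matrix) {
  stopifnot(inherits(matrix, "cmcr_matrix"))
  c(sigma_x = matrix$sigma_x, sigma_y = matrix$sigma_y, sigma_z = matrix$sigma_z)
}

#' Complexity category ranges of a matrix
#'
#' Low complexity is the single score \eqn{TS = \Sigma x}; medium complexity is
#' \eqn{\Sigma x + 1 \le TS \le \Sigma y}; high complexity is
#' \eqn{\Sigma y + 1 \le TS \le \Sigma z}. The three ranges tile the integers
#' \eqn{[\Sigma x, \Sigma z]} with no gap or overlap.
#'
#' @param matrix a `cmcr_matrix`, or a single integer taken as the number of
#'   variables `n`.
#' @return a `cmcr_ranges` object: list of inclusive integer ranges `low`,
#'   `medium`, `high`.
#' @export
category_ranges <- function(matrix) {
  if (inherits(matrix, "cmcr_matrix")) {
    n <- matrix$n
  } else if (is.numeric(matrix) && length(matrix) == 1L && matrix >= 1) {
    n <- as.integer(matrix)
  } else {
    stop("matrix must be a cmcr_matrix or a positive integer n", call. = FALSE)
  }
  out <- list(low = c(n, n),
              medium = c(n + 1L, 2L * n),
              high = c(2L * n + 1L, 3L * n))
  class(out) <- "cmcr_ranges"
  out
}

#' @export
print.cmcr_ranges <- function(x, ...) {
  cat(sprintf("low: TS = %d | medium: %d <= TS <= %d | high: %d <= TS <= %d\n",
              x$low[1], x$medium[1], x$medium[2], x$high[1], x$high[2]))
  invisible(x)
}

#' Map a total score to its complexity category
#'
#' @param ts integer total score(s).
#' @param ranges a `cmcr_ranges` (or a `cmcr_matrix`, converted internally).
#' @return character vector in `c("low", "medium", "high")`.
#' @export
category_of_score <- function(ts, ranges) {
  if (inherits(ranges, "cmcr_matrix")) ranges <- category_ranges(ranges)
  stopifnot(inherits(ranges, "cmcr_ranges"))
  vapply(ts, function(s) {
    for (cat in CATEGORIES) {
      r <- ranges[[cat]]
      if (s >= r[1] && s <= r[2]) return(cat)
    }
    stop("total score ", s, " outside [", ranges$low[1], ", ",
         ranges$high[2], "]", call. = FALSE)
  }, character(1))
}

## ---- serialization ----------------------------------------------------------

interval_to_spec <- function(iv, domain) {
  out <- list()
  if (is.finite(iv$min) && !(iv$min == domain$min && !iv$min_open)) out$min <- iv$min
  if (iv$min_open) out$min_open <- TRUE
  if (is.finite(iv$max) && !(iv$max == domain$max && !iv$max_open)) out$max <- iv$max
  if (iv$max_open) out$max_open <- TRUE
  if (length(out) == 0L) out$min <- iv$min  # degenerate: whole-domain interval
  out
}

criteria_to_spec <- function(crit, domain, sex_conditional) {
  out <- lapply(crit, function(cr) {
    if (!is.null(cr$labels)) {
      sp <- list(labels = cr$labels)
    } else if (sex_conditional) {
      sp <- list(male = interval_to_spec(cr$intervals$male, domain),
                 female = interval_to_spec(cr$intervals$female, domain))
    } else {
      sp <- interval_to_spec(cr$intervals$any, domain)
    }
    if (!is.null(cr$description)) sp$description <- cr$description
    sp
  })
  names(out) <- LEVELS
  out
}

domain_to_spec <- function(domain) {
  if (domain$type == "numeric") {
    sp <- list(type = "numeric")
    if (is.finite(domain$min)) sp$min <- domain$min
    if (is.finite(domain$max)) sp$max <- domain$max
    sp
  } else {
    list(type = "labels", labels = domain$labels, ordered = domain$ordered)
  }
}

#' Serialize a matrix back to its config representation
#'
#' `as_matrix_config()` produces a plain list that [load_matrix()] accepts and
#' that reloads to a matrix identical field-for-field; `save_matrix()` writes
#' it as YAML.
#'
#' @param matrix a `cmcr_matrix`.
#' @return a named list (config document).
#' @export
as_matrix_config <- function(matrix) {
  stopifnot(inherits(matrix, "cmcr_matrix"))
  vars <- lapply(matrix$variables, function(v) {
    sp <- list(name = v$name, label = v$label)
    if (!is.null(v$units)) sp$units <- v$units
    if (v$compound) {
      sp$compound <- TRUE
      sp$combine <- v$combine
      sp$components <- lapply(v$components, function(cp) {
        cs <- list(name = cp$name)
        if (!is.null(cp$units)) cs$units <- cp$units
        cs$domain <- domain_to_spec(cp$domain)
        cs$criteria <- criteria_to_spec(cp$criteria, cp$domain, FALSE)
        cs
      })
      names(sp$components) <- NULL
    } else {
      if (v$sex_conditional) sp$sex_conditional <- TRUE
      sp$domain <- domain_to_spec(v$domain)
      sp$criteria <- criteria_to_spec(v$criteria, v$domain, v$sex_conditional)
    }
    if (!is.null(v$not_measurable_level)) sp$not_measurable_level <- v$not_measurable_level
    sp$gap_policy <- v$gap_policy
    sp
  })
  names(vars) <- NULL
  out <- list(id = matrix$id, name = matrix$name, specialty = matrix$specialty,
              variables = vars)
  if (!is.null(matrix$load_map)) out$load_map <- as.list(matrix$load_map)
  if (!is.null(matrix$recat_policy)) {
    rp <- matrix$recat_policy
    out$recat_policy <- Filter(Negate(is.null),
                               list(mode = rp$mode, weekday = rp$weekday,
                                    event_kinds = rp$event_kinds))
  }
  out
}

#' @rdname as_matrix_config
#' @param path output file path (`.yaml`).
#' @export
save_matrix <- function(matrix, path) {
  yaml::write_yaml(as_matrix_config(matrix), path)
  invisible(path)
}
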