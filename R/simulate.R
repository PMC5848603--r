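## Synthetic patient-record generator: quarterly adherence processes with
## AR(1) noise, Bernoulli care-instance logs, and assessment tables that
## exercise the categorization matrices.

#' Simulation configuration
#'
#' Defaults reproduce the study conditions the package's analyses assume:
#' 17 calendar quarters starting 2011-Q3, an ICU group starting at 63%
#' adherence and gaining 1.28 percentage points per quarter, a non-ICU group
#' starting at 54% and gaining 1.62 pp/quarter, AR(1) disturbances with
#' coefficient 0.3, and Gaussian innovations with standard deviation 2 pp.
#' The default volume (430 instances per group per quarter) mirrors the
#' study's ~8,600 instances per quarter scaled down by a factor of ten and
#' split between the two groups.
#'
#' @param quarters number of quarters Q (>= 1).
#' @param groups named list; each element a list with `a0` (initial
#'   adherence, percent, at t = 1) and `slope` (pp per quarter). Names are
#'   used as unit labels.
#' @param rho AR(1) coefficient of the disturbance, |rho| < 1.
#' @param sd innovation standard deviation (pp).
#' @param instances_per_quarter instances per group per quarter (scalar or
#'   named per group).
#' @param prescribed_prob probability an instance carries a physical-therapy
#'   prescription; only prescribed instances can be categorized.
#' @param start first day of quarter t = 1.
#' @param seed optional integer seed; a given seed fully determines every
#'   generated table.
#' @return a `cmcr_sim_config`.
#' @export
sim_config <- function(quarters = 17L,
                       groups = list(
                         "ICU" = list(a0 = 63, slope = 1.28),
                         "non-ICU" = list(a0 = 54, slope = 1.62)),
                       rho = 0.3, sd = 2,
                       instances_per_quarter = 430L,
                       prescribed_prob = 1,
                       start = as.Date("2011-07-01"),
                       seed = NULL) {
  stopifnot(quarters >= 1, abs(rho) < 1, sd >= 0,
            prescribed_prob >= 0, prescribed_prob <= 1)
  for (g in names(groups)) {
    gr <- groups[[g]]
    if (is.null(gr$a0) || gr$a0 < 0 || gr$a0 > 100)
      stop("group '", g, "': a0 must lie in [0, 100]", call. = FALSE)
    if (is.null(gr$slope)) stop("group '", g, "': slope missing", call. = FALSE)
  }
  structure(list(quarters = as.integer(quarters), groups = groups,
                 rho = rho, sd = sd,
                 instances_per_quarter = instances_per_quarter,
                 prescribed_prob = prescribed_prob,
                 start = as.Date(start), seed = seed),
            class = "cmcr_sim_config")
}

#' Simulate per-quarter target adherence
#'
#' For each group, generates \eqn{y_t = a_0 + b (t - 1) + \epsilon_t} with
#' \eqn{\epsilon_t = \rho \epsilon_{t-1} + u_t}, \eqn{u_t \sim N(0, sd^2)},
#' the disturbance initialized at its stationary distribution, and the
#' result clipped to [0, 100].
#'
#' @param config a `cmcr_sim_config`.
#' @return data frame `group`, `t`, `target` (percent).
#' @export
simulate_adherence_series <- function(config) {
  stopifnot(inherits(config, "cmcr_sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  Q <- config$quarters
  out <- lapply(names(config$groups), function(g) {
    gr <- config$groups[[g]]
    eps <- numeric(Q)
    if (config$sd > 0) {
      eps[1] <- stats::rnorm(1, 0, config$sd / sqrt(1 - config$rho^2))
      if (Q > 1) {
        u <- stats::rnorm(Q - 1, 0, config$sd)
        for (t in 2:Q) eps[t] <- config$rho * eps[t - 1] + u[t - 1]
      }
    }
    y <- gr$a0 + gr$slope * (seq_len(Q) - 1) + eps
    data.frame(group = g, t = seq_len(Q),
               target = pmin(100, pmax(0, y)), row.names = NULL)
  })
  do.call(rbind, out)
}

#' Simulate a care-instance log from target adherence
#'
#' For every quarter and group, draws `instances_per_quarter` instances of
#' inpatient care with dates uniform within the calendar quarter; each
#' instance carries a physical-therapy prescription with probability
#' `prescribed_prob`, and each prescribed instance is categorized with
#' probability `target / 100`.
#'
#' @param series data frame `group`, `t`, `target` as produced by
#'   [simulate_adherence_series()].
#' @param instances_per_quarter scalar or named-per-group instance count.
#' @param start first day of quarter t = 1.
#' @param prescribed_prob see [sim_config()].
#' @param seed optional integer seed.
#' @return care-instance data frame: `patient_id`, `date`, `unit`,
#'   `pt_prescribed`, `categorized`.
#' @export
simulate_care_instances <- function(series, instances_per_quarter = 430L,
                                    start = as.Date("2011-07-01"),
                                    prescribed_prob = 1, seed = NULL) {
  if (!all(c("group", "t", "target") %in% names(series)))
    stop("series must have columns group, t, target", call. = FALSE)
  if (any(series$target < 0 | series$target > 100))
    stop("target adherence must lie in [0, 100]", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  start <- floor_quarter(as.Date(start))
  rows <- vector("list", nrow(series))
  id0 <- 0L
  for (i in seq_len(nrow(series))) {
    g <- series$group[i]; tt <- series$t[i]; y <- series$target[i]
    n <- if (!is.null(names(instances_per_quarter)) && g %in% names(instances_per_quarter))
      as.integer(instances_per_quarter[[g]]) else as.integer(instances_per_quarter[[1]])
    if (n < 1L) next
    q0 <- add_quarters(start, tt - 1L)
    q1 <- add_quarters(start, tt) - 1L
    dates <- q0 + sample.int(as.integer(q1 - q0) + 1L, n, replace = TRUE) - 1L
    presc <- stats::runif(n) < prescribed_prob
    categ <- presc & (stats::runif(n) < y / 100)
    rows[[i]] <- data.frame(
      patient_id = sprintf("P%07d", id0 + seq_len(n)),
      date = dates, unit = g, pt_prescribed = presc, categorized = categ,
      row.names = NULL)
    id0 <- id0 + n
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Simulate care instances straight from a configuration
#'
#' Convenience wrapper: draws the target adherence series and the instance
#' log in one seeded pass.
#'
#' @param config a `cmcr_sim_config`.
#' @return list with `series` (targets) and `instances` (care-instance log).
#' @export
simulate_epr <- function(config) {
  stopifnot(inherits(config, "cmcr_sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  cfg_noseed <- config; cfg_noseed$seed <- NULL
  series <- simulate_adherence_series(cfg_noseed)
  instances <- simulate_care_instances(
    series, instances_per_quarter = config$instances_per_quarter,
    start = config$start, prescribed_prob = config$prescribed_prob)
  list(series = series, instances = instances)
}

## ---- assessment simulation --------------------------------------------------

# All 3^n level combinations of a matrix with their total score and category.
level_combinations <- function(matrix) {
  n <- matrix$n
  grid <- do.call(expand.grid, rep(list(1:3), n))
  names(grid) <- names(matrix$variables)
  ts <- rowSums(grid)
  data.frame(grid, ts = ts,
             category = category_of_score(ts, category_ranges(matrix)))
}

sample_in_interval <- function(iv, domain, boundary_prob) {
  lo <- max(iv$min, domain$min); hi <- min(iv$max, domain$max)
  if (!is.finite(lo) || !is.finite(hi))
    stop("cannot sample from an unbounded interval; give the domain finite bounds",
         call. = FALSE)
  # shrink open ends so that rounding to one decimal cannot cross the bound
  if (iv$min_open) lo <- lo + 0.1
  if (iv$max_open) hi <- hi - 0.1
  if (lo > hi) stop("empty sampling interval", call. = FALSE)
  x <- if (stats::runif(1) < boundary_prob) {
    if (stats::runif(1) < 0.5) lo else hi
  } else {
    stats::runif(1, lo, hi)
  }
  round(x, 1)
}

sample_variable_value <- function(v, level, sex, boundary_prob, nm_prob) {
  if (!is.null(v$not_measurable_level) && v$not_measurable_level == level &&
      stats::runif(1) < nm_prob)
    return(NOT_MEASURABLE)
  if (v$compound) {
    comp <- names(v$components)
    li <- match(level, LEVELS)
    lvs <- stats::setNames(sample.int(li, length(comp), replace = TRUE), comp)
    lvs[[sample(comp, 1)]] <- li  # at least one component realizes the level
    vals <- vapply(comp, function(k) {
      cp <- v$components[[k]]
      sample_in_interval(cp$criteria[[LEVELS[lvs[[k]]]]]$intervals$any,
                         cp$domain, boundary_prob)
    }, numeric(1))
    return(paste(format(vals, trim = TRUE), collapse = "/"))
  }
  if (v$domain$type == "labels") {
    labs <- v$criteria[[level]]$labels
    return(labs[sample.int(length(labs), 1)])
  }
  key <- if (v$sex_conditional) sex else "any"
  as.character(sample_in_interval(v$criteria[[level]]$intervals[[key]],
                                  v$domain, boundary_prob))
}

#' Simulate patient assessments for a matrix
#'
#' Draws patients with a target complexity mix, picks for each patient a
#' level combination whose total score realizes the target category, and
#' samples a raw value inside each chosen criterion cell (interval endpoints
#' are drawn with probability `boundary_prob`; unmeasurable markers with
#' probability `nm_prob` where the matrix allows them). The output is the
#' package's long assessment format, ready for [categorize_table()].
#'
#' @param matrix a `cmcr_matrix`.
#' @param n_patients number of assessments to generate.
#' @param severity_mix named numeric `c(low=, medium=, high=)`, summing to 1.
#' @param seed optional integer seed.
#' @param boundary_prob probability a numeric draw sits on a cell boundary.
#' @param nm_prob probability an eligible variable is recorded unmeasurable.
#' @param unit unit label for the generated patients.
#' @param start date of the first assessment; patients are spread one per day.
#' @return long-format data frame (`patient_id`, `matrix_id`, `timestamp`,
#'   `unit`, `variable`, `value`, `sex`) with an `intended` attribute giving
#'   each patient's target category.
#' @export
simulate_assessments <- function(matrix, n_patients,
                                 severity_mix = c(low = 1/3, medium = 1/3, high = 1/3),
                                 seed = NULL, boundary_prob = 0.1, nm_prob = 0.1,
                                 unit = "ICU", start = as.Date("2011-07-01")) {
  stopifnot(inherits(matrix, "cmcr_matrix"), n_patients >= 1)
  if (!setequal(names(severity_mix), CATEGORIES) ||
      abs(sum(severity_mix) - 1) > 1e-8 || any(severity_mix < 0))
    stop("severity_mix must be non-negative over low/medium/high and sum to 1",
         call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  combos <- level_combinations(matrix)
  by_cat <- split(seq_len(nrow(combos)), combos$category)
  for (cat in names(severity_mix)[severity_mix > 0]) {
    if (length(by_cat[[cat]]) == 0L)
      stop("category '", cat, "' unreachable for this matrix", call. = FALSE)
  }
  cats <- sample(CATEGORIES, n_patients, replace = TRUE,
                 prob = severity_mix[CATEGORIES])
  any_sex <- any(vapply(matrix$variables, function(v) v$sex_conditional, logical(1)))
  rows <- vector("list", n_patients)
  for (i in seq_len(n_patients)) {
    pick <- by_cat[[cats[i]]][sample.int(length(by_cat[[cats[i]]]), 1)]
    sex <- if (any_sex) sample(c("male", "female"), 1) else NA_character_
    vals <- vapply(names(matrix$variables), function(nm) {
      sample_variable_value(matrix$variables[[nm]],
                            LEVELS[combos[pick, nm]], sex,
                            boundary_prob, nm_prob)
    }, character(1))
    rows[[i]] <- data.frame(
      patient_id = sprintf("P%05d", i),
      matrix_id = matrix$id,
      timestamp = format(start + (i - 1L) %% 92L, "%Y-%m-%dT09:00:00"),
      unit = unit,
      variable = names(matrix$variables),
      value = unname(vals),
      sex = sex, row.names = NULL)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "intended") <- data.frame(patient_id = sprintf("P%05d", seq_len(n_patients)),
                                      category = cats, row.names = NULL)
  out
}
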