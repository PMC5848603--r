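## Readers and writers for the package's delimited-table interfaces.

read_delim_guess <- function(path) {
  l1 <- readLines(path, n = 1L)
  sep <- if (grepl("\t", l1)) "\t" else ","
  utils::read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE,
                    colClasses = "character", check.names = TRUE)
}

#' Read a long-format assessment table
#'
#' Expects CSV/TSV with columns `patient_id`, `matrix_id`, `timestamp`
#' (ISO-8601), `unit`, `variable`, `value`, and optionally `sex`; one row per
#' variable of each assessment.
#'
#' @param path file path.
#' @return data frame (all columns character, as scored values may be labels,
#'   numbers, compound `"a/b"` pairs or the `"NM"` marker).
#' @export
read_assessments <- function(path) {
  df <- read_delim_guess(path)
  need <- c("patient_id", "timestamp", "variable", "value")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L)
    stop("assessment file lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  df
}

#' Read a care-instance log
#'
#' Reads the CSV/TSV schema `patient_id`, `date`, `unit`, `pt_prescribed`,
#' `categorized`. An XLSX sheet of identical layout is also accepted (the
#' supplementary-database style of export) when the readxl package is
#' available; `col_map` renames non-standard column headers, e.g.
#' `c(date = "Fecha")`.
#'
#' @param path file path (`.csv`, `.tsv` or `.xlsx`).
#' @param sheet sheet name or index for XLSX input.
#' @param col_map optional named character vector mapping schema names to the
#'   file's column names.
#' @return data frame with typed columns (`date` as Date, flags as logical).
#' @export
read_care_instances <- function(path, sheet = 1, col_map = NULL) {
  if (grepl("\\.xlsx?$", path, ignore.case = TRUE)) {
    if (!requireNamespace("readxl", quietly = TRUE))
      stop("reading XLSX needs the readxl package; export to CSV instead",
           call. = FALSE)
    df <- as.data.frame(readxl::read_excel(path, sheet = sheet))
  } else {
    df <- read_delim_guess(path)
  }
  if (!is.null(col_map)) {
    for (std in names(col_map)) {
      if (!col_map[[std]] %in% names(df))
        stop("col_map refers to absent column '", col_map[[std]], "'",
             call. = FALSE)
      names(df)[names(df) == col_map[[std]]] <- std
    }
  }
  need <- c("patient_id", "date", "unit", "pt_prescribed", "categorized")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L)
    stop("care-instance file lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  df$date <- as.Date(df$date)
  df$pt_prescribed <- to_logical(df$pt_prescribed)
  df$categorized <- to_logical(df$categorized)
  df
}

#' Write / read the tidy quarterly adherence table
#'
#' Columns `quarter_label`, `t`, `group`, `numerator`, `denominator`,
#' `adherence`; quarters with zero denominator carry an empty adherence
#' field. Adherence is stored unrounded.
#'
#' @param series a `cmcr_adherence` data frame.
#' @param path file path.
#' @export
write_adherence <- function(series, path) {
  utils::write.csv(as.data.frame(series), path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_adherence
#' @export
read_adherence <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("quarter_label", "t", "group", "numerator", "denominator", "adherence")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L)
    stop("adherence file lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  class(df) <- c("cmcr_adherence", "data.frame")
  df
}

#' Write categorization results with their audit trail
#'
#' Writes the per-assessment summary as CSV and, optionally, a JSON document
#' carrying the per-variable level breakdown so every total score can be
#' audited.
#'
#' @param results output of [categorize_table()].
#' @param path CSV output path.
#' @param json_path optional JSON audit output path.
#' @export
write_categorization <- function(results, path, json_path = NULL) {
  utils::write.csv(as.data.frame(results), path, row.names = FALSE)
  if (!is.null(json_path)) {
    audit <- attr(results, "audit")
    jsonlite::write_json(
      list(results = as.data.frame(results), per_variable = audit),
      json_path, dataframe = "rows", auto_unbox = TRUE, digits = NA,
      pretty = TRUE)
  }
  invisible(path)
}

#' Write a trend-fit report as JSON
#'
#' @param fit a `cmcr_pw_fit` or `cmcr_trend_comparison`.
#' @param path JSON output path.
#' @export
write_trend_report <- function(fit, path) {
  if (inherits(fit, "cmcr_pw_fit")) {
    rep <- list(
      model = "prais-winsten AR(1) linear trend",
      n = fit$n,
      coefficients = as.list(fit$coefficients),
      std_error = as.list(fit$se),
      p_value = as.list(fit$p.value),
      rho = fit$rho, iterations = fit$iterations, converged = fit$converged)
  } else if (inherits(fit, "cmcr_trend_comparison")) {
    rep <- list(
      model = "joint AR(1) group x time interaction",
      groups = fit$groups, n_per_group = fit$n_per_group,
      slopes = stats::setNames(
        lapply(fit$fit_per_group, function(f)
          list(estimate = f$coefficients[["t"]], p = f$p.value[["t"]],
               rho = f$rho)),
        fit$groups),
      slope_difference = fit$slope_difference,
      interaction_p = fit$interaction_p,
      mean_level_difference = fit$mean_level_difference,
      adjusted_level_difference = fit$adjusted_level_difference,
      rho = fit$rho, converged = fit$converged)
  } else {
    stop("fit must be a cmcr_pw_fit or cmcr_trend_comparison", call. = FALSE)
  }
  jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
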