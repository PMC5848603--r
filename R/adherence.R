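## Quarterly adherence quality indicator: percentage of inpatient-care
## instances with a recorded categorization.

UNITS <- c("ICU", "non-ICU")

floor_quarter <- function(d) {
  lt <- as.POSIXlt(d)
  lt$mday <- 1L
  lt$mon <- (lt$mon %/% 3L) * 3L
  as.Date(lt)
}

add_quarters <- function(d, k) {
  lt <- as.POSIXlt(d)
  m <- lt$mon + 3L * k
  lt$year <- lt$year + m %/% 12L
  lt$mon <- m %% 12L
  as.Date(lt)
}

quarter_label <- function(d) {
  lt <- as.POSIXlt(d)
  sprintf("%d-Q%d", lt$year + 1900L, lt$mon %/% 3L + 1L)
}

quarter_index <- function(d, anchor) {
  a <- as.POSIXlt(anchor); b <- as.POSIXlt(d)
  as.integer((b$year - a$year) * 4L + (b$mon %/% 3L - a$mon %/% 3L) + 1L)
}

#' Aggregate care instances into the quarterly adherence series
#'
#' The adherence quality indicator is the percentage of instances of
#' inpatient care per calendar quarter for which a categorization was
#' recorded. Aggregation is over instances, not patients: there is no
#' individual patient follow-up.
#'
#' Two denominator policies are supported because both framings occur in
#' practice: `"all-instances"` divides by every instance of care recorded in
#' the quarter; `"prescribed-only"` divides by the instances for which the
#' physician prescribed physical therapy (and requires that only those are
#' ever categorized).
#'
#' @param instances data frame with columns `patient_id`, `date` (Date or
#'   ISO-8601 text), `unit` (`"ICU"` / `"non-ICU"`), `pt_prescribed`
#'   (logical), `categorized` (logical).
#' @param window optional length-2 Date vector; defaults to the quarter span
#'   of the data. Instances outside a supplied window are an error. The first
#'   quarter of the window gets index `t = 1`.
#' @param denominator_policy `"all-instances"` (default) or
#'   `"prescribed-only"`.
#' @param grouping `"by-unit"` (default: rows for overall, ICU and non-ICU)
#'   or `"overall"`.
#' @return a `cmcr_adherence` data frame: `quarter_label`, `t`, `group`,
#'   `numerator`, `denominator`, `adherence` (percent; `NA` for quarters with
#'   zero denominator, which are emitted, never dropped).
#' @export
aggregate_quarters <- function(instances,
                               window = NULL,
                               denominator_policy = c("all-instances", "prescribed-only"),
                               grouping = c("by-unit", "overall")) {
  denominator_policy <- match.arg(denominator_policy)
  grouping <- match.arg(grouping)
  need <- c("date", "unit", "pt_prescribed", "categorized")
  miss <- setdiff(need, names(instances))
  if (length(miss) > 0L)
    stop("care-instance table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (nrow(instances) == 0L) stop("care-instance table is empty", call. = FALSE)
  date <- as.Date(instances$date)
  if (anyNA(date)) stop("unparseable dates in care-instance table", call. = FALSE)
  unit <- as.character(instances$unit)
  bad <- setdiff(unique(unit), UNITS)
  if (length(bad) > 0L)
    stop("unknown unit label(s): ", paste(bad, collapse = ", "),
         "; expected ", paste(UNITS, collapse = ", "), call. = FALSE)
  presc <- to_logical(instances$pt_prescribed)
  categ <- to_logical(instances$categorized)
  if (denominator_policy == "prescribed-only" && any(categ & !presc))
    stop("under the prescribed-only policy, categorized instances without a ",
         "physical-therapy prescription are not eligible (",
         sum(categ & !presc), " offending row(s))", call. = FALSE)
  if (is.null(window)) {
    window <- c(min(date), max(date))
  } else {
    window <- as.Date(window)
    if (window[1] > window[2]) stop("window start after window end", call. = FALSE)
    if (any(date < floor_quarter(window[1])) ||
        any(date >= add_quarters(floor_quarter(window[2]), 1L)))
      stop("care instances dated outside the aggregation window", call. = FALSE)
  }
  anchor <- floor_quarter(window[1])
  nq <- quarter_index(window[2], anchor)
  t_of_row <- quarter_index(date, anchor)

  groups <- if (grouping == "overall") "overall" else c("overall", UNITS)
  out <- expand.grid(t = seq_len(nq), group = groups,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  eligible <- if (denominator_policy == "prescribed-only") presc else rep(TRUE, length(presc))
  num_den <- function(sel) {
    c(num = sum(categ & eligible & sel), den = sum(eligible & sel))
  }
  nd <- t(mapply(function(tt, gg) {
    sel <- t_of_row == tt & (gg == "overall" | unit == gg)
    num_den(sel)
  }, out$t, out$group))
  out$numerator <- as.integer(nd[, "num"])
  out$denominator <- as.integer(nd[, "den"])
  out$adherence <- ifelse(out$denominator > 0,
                          100 * out$numerator / out$denominator, NA_real_)
  out$quarter_label <- quarter_label(add_quarters(anchor, out$t - 1L))
  out <- out[order(match(out$group, groups), out$t),
             c("quarter_label", "t", "group", "numerator", "denominator", "adherence")]
  rownames(out) <- NULL
  attr(out, "denominator_policy") <- denominator_policy
  attr(out, "anchor") <- anchor
  class(out) <- c("cmcr_adherence", "data.frame")
  out
}

#' Extract one group's adherence series
#'
#' @param series a `cmcr_adherence` data frame (or any data frame with `t`,
#'   `group`, `adherence`).
#' @param group `"overall"`, `"ICU"` or `"non-ICU"`.
#' @param allow_missing if `FALSE` (default), gaps in `t` or quarters with
#'   missing adherence are an error.
#' @return data frame with strictly increasing `t` and `adherence`.
#' @export
adherence_series <- function(series, group = "overall", allow_missing = FALSE) {
  if (!all(c("t", "group", "adherence") %in% names(series)))
    stop("series must have columns t, group, adherence", call. = FALSE)
  sub <- series[series$group == group, , drop = FALSE]
  if (nrow(sub) == 0L) stop("no rows for group '", group, "'", call. = FALSE)
  sub <- sub[order(sub$t), , drop = FALSE]
  if (anyDuplicated(sub$t))
    stop("duplicated quarter index for group '", group, "'", call. = FALSE)
  if (!allow_missing) {
    if (any(diff(sub$t) != 1L))
      stop("gaps in the quarter index for group '", group, "'", call. = FALSE)
    if (anyNA(sub$adherence))
      stop("missing adherence values for group '", group,
           "' (zero-denominator quarters)", call. = FALSE)
  }
  data.frame(t = sub$t, adherence = sub$adherence, row.names = NULL)
}

to_logical <- function(x) {
  if (is.logical(x)) return(x)
  if (is.numeric(x)) return(x != 0)
  v <- tolower(trimws(as.character(x)))
  out <- rep(NA, length(v))
  out[v %in% c("true", "t", "1", "yes", "y")] <- TRUE
  out[v %in% c("false", "f", "0", "no", "n")] <- FALSE
  if (anyNA(out)) stop("cannot interpret value(s) as logical: ",
                       paste(unique(v[is.na(out)]), collapse = ", "),
                       call. = FALSE)
  out
}
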