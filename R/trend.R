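## Linear trend estimation for quarterly adherence series with AR(1) errors
## (Prais-Winsten feasible GLS), and between-group trend comparison.

#' Lag-1 autocorrelation of a residual vector
#'
#' Computes \eqn{\hat\rho = \sum_{t\ge2} e_t e_{t-1} / \sum_{t\ge2} e_{t-1}^2},
#' the estimator used inside the Prais-Winsten iteration.
#'
#' @param residuals numeric vector, length >= 3, non-constant.
#' @return the lag-1 autocorrelation estimate; a warning is raised if it
#'   falls outside the stationary region (-1, 1).
#' @export
lag1_autocorrelation <- function(residuals) {
  e <- as.numeric(residuals)
  n <- length(e)
  if (n < 3L) stop("need at least 3 residuals", call. = FALSE)
  if (anyNA(e)) stop("residuals contain NA", call. = FALSE)
  if (stats::var(e) == 0)
    stop("zero-variance residuals: lag-1 autocorrelation undefined", call. = FALSE)
  rho <- sum(e[-1] * e[-n]) / sum(e[-n]^2)
  if (!is.finite(rho))
    stop("lag-1 autocorrelation undefined (zero lagged sum of squares)",
         call. = FALSE)
  if (abs(rho) >= 1)
    warning("lag-1 autocorrelation ", format(rho),
            " outside the stationary region (-1, 1)", call. = FALSE)
  rho
}

# Prais-Winsten transform: first row scaled by sqrt(1 - rho^2), later rows
# quasi-differenced. `first` marks the first observation of each run (so the
# stacked two-group design can be transformed per group).
pw_transform <- function(M, rho, first = c(TRUE, rep(FALSE, nrow(M) - 1L))) {
  M <- as.matrix(M)
  out <- M
  idx <- which(!first)
  out[idx, ] <- M[idx, , drop = FALSE] - rho * M[idx - 1L, , drop = FALSE]
  out[first, ] <- sqrt(1 - rho^2) * M[first, , drop = FALSE]
  out
}

ols_fit <- function(X, y) {
  qr.coef(qr(X), y)
}

# Shared iterated-FGLS engine: X is the design, `first` marks run starts,
# `lag_ok[i]` says rows i-1, i form a valid lag pair (same run).
pw_engine <- function(X, y, first, tol = 1e-6, max_iter = 100L) {
  n <- length(y)
  lag_ok <- !first
  beta <- ols_fit(X, y)
  rho <- 0
  converged <- FALSE
  clamped <- FALSE
  iter <- 0L
  repeat {
    iter <- iter + 1L
    e <- as.numeric(y - X %*% beta)
    denom <- sum(e[which(lag_ok) - 1L]^2)
    if (denom < 1e-10 * max(1, mean(y^2))) {
      # (near-)perfect fit: nothing left to whiten
      rho_new <- 0
      converged <- TRUE
    } else {
      rho_new <- sum(e[lag_ok] * e[which(lag_ok) - 1L]) / denom
      if (abs(rho_new) >= 1) {
        warning("estimated AR(1) coefficient left (-1, 1); clamped to ±0.999",
                call. = FALSE)
        rho_new <- sign(rho_new) * 0.999
        clamped <- TRUE
      }
    }
    Xt <- pw_transform(X, rho_new, first)
    yt <- as.numeric(pw_transform(matrix(y), rho_new, first))
    beta <- ols_fit(Xt, yt)
    if (converged || abs(rho_new - rho) < tol) {
      rho <- rho_new
      converged <- !clamped
      break
    }
    rho <- rho_new
    if (iter >= max_iter) break
  }
  Xt <- pw_transform(X, rho, first)
  yt <- as.numeric(pw_transform(matrix(y), rho, first))
  et <- yt - as.numeric(Xt %*% beta)
  p <- ncol(X)
  df <- n - p
  sigma2 <- sum(et^2) / df
  XtXinv <- chol2inv(chol(crossprod(Xt)))
  se <- sqrt(sigma2 * diag(XtXinv))
  stat <- ifelse(se > 0, beta / se, sign(beta) * Inf)
  pval <- 2 * stats::pt(-abs(stat), df)
  list(coefficients = beta, se = se, statistic = stat, p.value = pval,
       rho = rho, iterations = iter, converged = converged, df = df,
       sigma2 = sigma2, residuals_original = as.numeric(y - X %*% beta),
       residuals_transformed = et)
}

#' Prais-Winsten regression of an adherence series on time
#'
#' Fits \eqn{y_t = \beta_0 + \beta_1 t + \epsilon_t} with first-order
#' autoregressive errors \eqn{\epsilon_t = \rho \epsilon_{t-1} + u_t} by
#' iterated feasible GLS. Each iteration estimates \eqn{\rho} from the
#' current residuals as their lag-1 autocorrelation, transforms the data
#' (first observation scaled by \eqn{\sqrt{1-\rho^2}}, later observations
#' quasi-differenced) and refits, until \eqn{\hat\rho} moves by less than
#' `tol`. Inference uses the t distribution with \eqn{n - 2} degrees of
#' freedom on the transformed fit.
#'
#' @param series data frame with columns `t` and `adherence` (or `y`), as
#'   returned by [adherence_series()]; alternatively a numeric vector `y`
#'   with `t` supplied separately.
#' @param t optional time vector when `series` is a plain numeric vector.
#' @param tol convergence tolerance on \eqn{|\Delta\hat\rho|}.
#' @param max_iter iteration cap.
#' @return a `cmcr_pw_fit`: coefficient table for intercept and slope
#'   (percentage points per quarter), `rho`, `n`, `iterations`, `converged`.
#' @export
prais_winsten_fit <- function(series, t = NULL, tol = 1e-6, max_iter = 100L) {
  if (is.data.frame(series)) {
    ycol <- intersect(c("adherence", "y"), names(series))[1]
    if (is.na(ycol) || !"t" %in% names(series))
      stop("series must have columns t and adherence (or y)", call. = FALSE)
    t <- series$t
    y <- series[[ycol]]
  } else {
    y <- as.numeric(series)
    if (is.null(t)) t <- seq_along(y)
  }
  n <- length(y)
  if (n < 4L) stop("Prais-Winsten fit needs at least 4 observations", call. = FALSE)
  if (length(t) != n) stop("t and y lengths differ", call. = FALSE)
  if (anyNA(y) || anyNA(t)) stop("missing values in the series", call. = FALSE)
  if (stats::var(y) == 0) stop("constant series: trend undefined", call. = FALSE)
  X <- cbind(`(Intercept)` = 1, t = as.numeric(t))
  first <- c(TRUE, rep(FALSE, n - 1L))
  eng <- pw_engine(X, y, first, tol = tol, max_iter = max_iter)
  out <- list(
    coefficients = stats::setNames(as.numeric(eng$coefficients),
                                   c("(Intercept)", "t")),
    se = stats::setNames(as.numeric(eng$se), c("(Intercept)", "t")),
    statistic = stats::setNames(as.numeric(eng$statistic), c("(Intercept)", "t")),
    p.value = stats::setNames(as.numeric(eng$p.value), c("(Intercept)", "t")),
    rho = eng$rho, n = n, df = eng$df,
    iterations = eng$iterations, converged = eng$converged,
    residuals = eng$residuals_original,
    residuals_transformed = eng$residuals_transformed,
    t = as.numeric(t), y = y
  )
  class(out) <- "cmcr_pw_fit"
  out
}

#' Confidence interval for Prais-Winsten coefficients
#' @param object a `cmcr_pw_fit`.
#' @param parm coefficients to include (default all).
#' @param level confidence level.
#' @param ... unused.
#' @export
confint.cmcr_pw_fit <- function(object, parm = names(object$coefficients),
                                level = 0.95, ...) {
  q <- stats::qt(1 - (1 - level) / 2, df = object$df)
  est <- object$coefficients[parm]
  se <- object$se[parm]
  out <- cbind(est - q * se, est + q * se)
  colnames(out) <- sprintf("%.1f %%", 100 * c((1 - level) / 2, 1 - (1 - level) / 2))
  out
}

#' @export
coef.cmcr_pw_fit <- function(object, ...) object$coefficients

#' @export
print.cmcr_pw_fit <- function(x, digits = 4, ...) {
  cat("Prais-Winsten AR(1) trend fit  (n =", x$n, ")\n")
  tab <- cbind(Estimate = x$coefficients, `Std. Error` = x$se,
               `t value` = x$statistic, `Pr(>|t|)` = x$p.value)
  print(round(tab, digits))
  cat(sprintf("rho = %.4f; %d iteration(s); converged: %s\n",
              x$rho, x$iterations, x$converged))
  invisible(x)
}

#' Compare adherence trends between two groups
#'
#' Stacks the two series into the joint model
#' \eqn{y = \beta_0 + \beta_g g + \beta_t t + \beta_{gt} (g \times t) + \epsilon}
#' with a common AR(1) error coefficient estimated by the Prais-Winsten
#' transform applied within each group's run (each group's first observation
#' is scaled by \eqn{\sqrt{1-\rho^2}}). The interaction coefficient
#' \eqn{\beta_{gt}} is the slope difference (group A minus group B); its
#' t test (df = \eqn{N - 4}) is the trend comparison. Because the level
#' contrast depends on where along the series it is evaluated, both the raw
#' mean level difference \eqn{\bar y_A - \bar y_B} and the model contrast at
#' the mean quarter are reported.
#'
#' @param series_a,series_b data frames with columns `t` and `adherence` (or
#'   `y`) on identical quarter grids.
#' @param groups length-2 character: labels for A and B.
#' @param level significance level used when printing the interaction test.
#' @return a `cmcr_trend_comparison`: per-group [prais_winsten_fit()]s,
#'   `slope_difference` (A - B), `interaction_p`, `mean_level_difference`
#'   (raw), `adjusted_level_difference` (model contrast at mean t), `rho`.
#' @export
compare_trends <- function(series_a, series_b, groups = c("A", "B"),
                           level = 0.05) {
  get_ty <- function(s, nm) {
    if (is.data.frame(s)) {
      ycol <- intersect(c("adherence", "y"), names(s))[1]
      if (is.na(ycol) || !"t" %in% names(s))
        stop("series ", nm, " must have columns t and adherence (or y)",
             call. = FALSE)
      list(t = as.numeric(s$t), y = as.numeric(s[[ycol]]))
    } else {
      list(t = seq_along(s), y = as.numeric(s))
    }
  }
  a <- get_ty(series_a, "A"); b <- get_ty(series_b, "B")
  if (length(a$t) != length(b$t) || any(a$t != b$t))
    stop("the two series must share the same quarter grid", call. = FALSE)
  n <- length(a$y)
  if (n < 4L) stop("need at least 4 quarters per group", call. = FALSE)
  g <- c(rep(1, n), rep(0, n))
  tt <- c(a$t, b$t)
  y <- c(a$y, b$y)
  X <- cbind(`(Intercept)` = 1, group = g, t = tt, `group:t` = g * tt)
  first <- c(TRUE, rep(FALSE, n - 1L), TRUE, rep(FALSE, n - 1L))
  eng <- pw_engine(X, y, first)
  cf <- as.numeric(eng$coefficients)
  names(cf) <- colnames(X)
  out <- list(
    groups = groups,
    fit_per_group = stats::setNames(
      list(prais_winsten_fit(data.frame(t = a$t, y = a$y)),
           prais_winsten_fit(data.frame(t = b$t, y = b$y))),
      groups),
    joint_coefficients = cf,
    joint_se = stats::setNames(as.numeric(eng$se), colnames(X)),
    joint_p = stats::setNames(as.numeric(eng$p.value), colnames(X)),
    slope_difference = cf[["group:t"]],
    interaction_p = eng$p.value[[4]],
    mean_level_difference = mean(a$y) - mean(b$y),
    adjusted_level_difference = cf[["group"]] + cf[["group:t"]] * mean(a$t),
    rho = eng$rho, n_per_group = n, df = eng$df,
    converged = eng$converged, significance_level = level
  )
  class(out) <- "cmcr_trend_comparison"
  out
}

#' @export
print.cmcr_trend_comparison <- function(x, digits = 4, ...) {
  cat(sprintf("Trend comparison: %s vs %s  (%d quarters per group)\n",
              x$groups[1], x$groups[2], x$n_per_group))
  s1 <- x$fit_per_group[[1]]$coefficients[["t"]]
  s2 <- x$fit_per_group[[2]]$coefficients[["t"]]
  cat(sprintf("  slope %s: %.*f pp/quarter (p = %.3g)\n", x$groups[1], digits, s1,
              x$fit_per_group[[1]]$p.value[["t"]]))
  cat(sprintf("  slope %s: %.*f pp/quarter (p = %.3g)\n", x$groups[2], digits, s2,
              x$fit_per_group[[2]]$p.value[["t"]]))
  cat(sprintf("  slope difference (joint model): %.*f pp/quarter, interaction p = %.3g%s\n",
              digits, x$slope_difference, x$interaction_p,
              if (x$interaction_p < x$significance_level) " *" else ""))
  cat(sprintf("  mean level difference: %.*f pp (model contrast at mean quarter: %.*f pp)\n",
              digits, x$mean_level_difference, digits, x$adjusted_level_difference))
  cat(sprintf("  common rho = %.4f\n", x$rho))
  invisible(x)
}
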