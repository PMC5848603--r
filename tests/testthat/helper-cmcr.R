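# Shared fixtures and independent oracles for the test suite.

# Brute-force category bracket: enumerates the three ranges explicitly,
# independently of category_of_score().
brute_category <- function(ts, n) {
  ranges <- list(low = n:n, medium = seq.int(n + 1L, 2L * n),
                 high = seq.int(2L * n + 1L, 3L * n))
  hit <- names(ranges)[vapply(ranges, function(r) ts %in% r, logical(1))]
  if (length(hit) != 1L) stop("score ", ts, " not bracketed exactly once")
  hit
}

# Independent AR(1)-around-a-line generator (kept separate from the
# package's simulate_adherence_series on purpose).
oracle_ar1_line <- function(n, intercept, slope, rho, sd) {
  eps <- numeric(n)
  eps[1] <- stats::rnorm(1, 0, if (sd > 0) sd / sqrt(1 - rho^2) else 0)
  if (n > 1) for (t in 2:n) eps[t] <- rho * eps[t - 1] + stats::rnorm(1, 0, sd)
  intercept + slope * seq_len(n) + eps
}

# Deterministic representative raw value for one variable at one severity
# level (used to sweep every level combination of a matrix).
rep_interval_value <- function(iv, domain) {
  lo <- max(iv$min, domain$min)
  hi <- min(iv$max, domain$max)
  if (iv$min_open) lo <- lo + 0.1
  if (iv$max_open) hi <- hi - 0.1
  (lo + hi) / 2
}

rep_value <- function(v, level, sex = "male") {
  if (v$compound) {
    vals <- vapply(v$components, function(cp)
      rep_interval_value(cp$criteria[[level]]$intervals$any, cp$domain),
      numeric(1))
    return(paste(vals, collapse = "/"))
  }
  if (v$domain$type == "labels") return(v$criteria[[level]]$labels[1])
  key <- if (v$sex_conditional) sex else "any"
  as.character(rep_interval_value(v$criteria[[level]]$intervals[[key]], v$domain))
}

# Assessment hitting the given level for every variable of a matrix.
assessment_at_levels <- function(matrix, levels, sex = "male") {
  vals <- lapply(seq_along(matrix$variables), function(i)
    rep_value(matrix$variables[[i]], levels[i], sex = sex))
  names(vals) <- names(matrix$variables)
  list(values = vals, sex = sex)
}

# A minimal valid n-variable matrix config for structural tests.
simple_matrix_config <- function(n = 3L, id = "simple") {
  vars <- lapply(seq_len(n), function(i) {
    list(name = paste0("v", i),
         domain = list(type = "numeric", min = 0, max = 30),
         criteria = list(
           X = list(min = 0, max = 10),
           Y = list(min = 10, max = 20, min_open = TRUE),
           Z = list(min = 20, max = 30, min_open = TRUE)))
  })
  list(id = id, name = id, specialty = "test", variables = vars)
}
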