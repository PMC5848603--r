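icu <- cmcr_matrix("icu_motor")
pulm <- cmcr_matrix("pulmonary_imv")

test_that("assign_level follows the printed thresholds of the motor matrix", {
  expect_equal(assign_level(icu$variables$mrc_sum, 50)$level, "X")
  expect_equal(assign_level(icu$variables$mrc_sum, 48)$level, "X")
  expect_equal(assign_level(icu$variables$mrc_sum, 47)$level, "Y")
  expect_equal(assign_level(icu$variables$mrc_sum, 37)$level, "Y")
  expect_equal(assign_level(icu$variables$mrc_sum, 36)$level, "Z")
  expect_equal(assign_level(icu$variables$mrc_sum, NOT_MEASURABLE)$points, 3)
  expect_equal(assign_level(icu$variables$fss_icu, "not measurable")$level, "Z")

  # handgrip thresholds are sex-specific and the printed operators are strict
  expect_equal(assign_level(icu$variables$handgrip, 30, sex = "male")$level, "Y")
  expect_equal(assign_level(icu$variables$handgrip, 30.5, sex = "male")$level, "X")
  expect_equal(assign_level(icu$variables$handgrip, 26.9, sex = "male")$level, "Z")
  expect_equal(assign_level(icu$variables$handgrip, 18, sex = "female")$level, "Y")
  expect_equal(assign_level(icu$variables$handgrip, 14.9, sex = "female")$level, "Z")
  expect_error(assign_level(icu$variables$handgrip, 30), "sex-conditional")

  # S5Q "< 2" is read as <= 2 so the 0-5 scale has no hole
  expect_equal(assign_level(icu$variables$s5q, 5)$level, "X")
  expect_equal(assign_level(icu$variables$s5q, 3)$level, "Y")
  expect_equal(assign_level(icu$variables$s5q, 2)$level, "Z")

  expect_error(assign_level(icu$variables$mrc_sum, 70), "outside domain")
  expect_error(assign_level(icu$variables$s5q, NOT_MEASURABLE),
               "no not-measurable level")
})

test_that("assign_level follows the pulmonary matrix, including its asymmetric NM rule", {
  sc <- pulm$variables$static_compliance
  expect_equal(assign_level(sc, NOT_MEASURABLE)$level, "X")  # 1-point column
  expect_equal(assign_level(sc, 60)$level, "X")
  expect_equal(assign_level(sc, 49)$level, "Y")
  expect_equal(assign_level(sc, 35)$level, "Y")
  expect_equal(assign_level(sc, 20)$level, "Z")
  expect_equal(assign_level(pulm$variables$secretion, "++")$points, 2)
  expect_equal(assign_level(pulm$variables$ventilatory_assistance, "control")$level, "Z")
  expect_error(assign_level(pulm$variables$secretion, "++++"), "not in domain")
  expect_equal(assign_level(pulm$variables$minute_volume, 7)$level, "Y")
  expect_equal(assign_level(pulm$variables$minute_volume, 12.1)$level, "Z")
})

test_that("gap values between printed intervals resolve to the more severe neighbour", {
  sc <- pulm$variables$static_compliance
  expect_equal(assign_level(sc, 34.5)$level, "Z")  # between Z (<34) and Y (35-49)
  expect_equal(assign_level(sc, 49.5)$level, "Y")  # between Y and X (>50)
  # PEEP 6 and 10 fall in the printed holes; FiO2 30.5 likewise
  expect_equal(assign_level(pulm$variables$peep_fio2, "6/25")$level, "Y")
  expect_equal(assign_level(pulm$variables$peep_fio2, "10/25")$level, "Z")
  expect_equal(assign_level(pulm$variables$peep_fio2, "5/30.5")$level, "Y")
  # an explicit gap_policy of "error" refuses instead
  strict <- as_matrix_config(pulm)
  strict$variables[[6]]$gap_policy <- "error"
  m <- load_matrix(strict)
  expect_error(assign_level(m$variables$static_compliance, 34.5),
               "between printed intervals")
})

test_that("compound PEEP/FiO2 takes the worse of its two components", {
  v <- pulm$variables$peep_fio2
  expect_equal(assign_level(v, "5/25")$level, "X")
  expect_equal(assign_level(v, "5/60")$level, "Z")   # FiO2 drives severity
  expect_equal(assign_level(v, "12/25")$level, "Z")  # PEEP drives severity
  expect_equal(assign_level(v, "8/40")$level, "Y")
  expect_equal(assign_level(v, c(peep = 8, fio2 = 40))$level, "Y")
  expect_error(assign_level(v, "8"), "2 numbers")
})

test_that("categorize reproduces the worked examples of the motor matrix", {
  # all four variables at their mildest level
  low <- categorize(list(values = list(mrc_sum = 58, fss_icu = 33,
                                       handgrip = 35, s5q = 5),
                         sex = "male"), icu)
  expect_equal(low$total_score, 4L)
  expect_equal(low$category, "low")

  high <- categorize(list(values = list(mrc_sum = 30, fss_icu = 10,
                                        handgrip = 10, s5q = 1),
                          sex = "female"), icu)
  expect_equal(high$total_score, 12L)
  expect_equal(high$category, "high")

  med <- categorize(list(values = list(mrc_sum = 45, fss_icu = 30,
                                       handgrip = 33, s5q = 5),
                         sex = "male"), icu)
  expect_equal(med$total_score, 5L)  # 2 + 1 + 1 + 1
  expect_equal(med$category, "medium")
  expect_equal(med$per_variable$level, c("Y", "X", "X", "X"))
})

test_that("categorize is order-invariant and refuses or imputes missing variables", {
  vals <- list(mrc_sum = 45, fss_icu = 30, handgrip = 33, s5q = 5)
  a <- list(values = vals, sex = "male")
  b <- list(values = rev(vals), sex = "male")
  expect_equal(categorize(a, icu)$total_score, categorize(b, icu)$total_score)
  expect_equal(categorize(a, icu)$per_variable, categorize(b, icu)$per_variable)

  incomplete <- list(values = vals[c("mrc_sum", "s5q")], sex = "male")
  expect_error(categorize(incomplete, icu), "missing variable")
  imputed <- categorize(incomplete, icu, on_missing = "worst")
  expect_equal(imputed$total_score, 2L + 3L + 3L + 1L)  # absent -> Z
  expect_true(all(imputed$per_variable$imputed[
    imputed$per_variable$variable %in% c("fss_icu", "handgrip")]))

  expect_error(categorize(list(values = c(vals, list(bogus = 1)), sex = "male"), icu),
               "unknown variable")
})

test_that("worsening any single variable never lowers the total score or category", {
  cat_rank <- c(low = 1L, medium = 2L, high = 3L)
  for (m in list(icu, pulm)) {
    combos <- expand.grid(rep(list(1:3), m$n))
    set.seed(202)
    pick <- combos[sample(nrow(combos), 40), , drop = FALSE]
    for (k in seq_len(nrow(pick))) {
      base_levels <- c("X", "Y", "Z")[as.integer(pick[k, ])]
      base <- categorize(assessment_at_levels(m, base_levels), m)
      for (i in seq_len(m$n)) {
        if (base_levels[i] == "Z") next
        worse <- base_levels
        worse[i] <- c("X" = "Y", "Y" = "Z")[worse[i]]
        res <- categorize(assessment_at_levels(m, worse), m)
        expect_gte(res$total_score, base$total_score)
        expect_gte(cat_rank[res$category], cat_rank[base$category])
      }
    }
  }
})

test_that("every value in each variable's domain maps to exactly one level", {
  for (m in list(icu, pulm)) {
    for (v in m$variables) {
      if (isTRUE(v$compound)) {
        base <- vapply(v$components, function(cp)
          rep_interval_value(cp$criteria$X$intervals$any, cp$domain), numeric(1))
        for (k in names(v$components)) {
          cp <- v$components[[k]]
          for (x in seq(cp$domain$min, cp$domain$max, by = 0.25)) {
            val <- base; val[k] <- x
            expect_no_error(assign_level(v, val))
          }
        }
        next
      }
      if (v$domain$type == "labels") {
        for (lab in v$domain$labels)
          expect_no_error(assign_level(v, lab))
        next
      }
      for (x in seq(v$domain$min, v$domain$max, by = 0.25)) {
        if (v$sex_conditional) {
          expect_no_error(assign_level(v, x, sex = "male"))
          expect_no_error(assign_level(v, x, sex = "female"))
        } else {
          expect_no_error(assign_level(v, x))
        }
      }
      if (!is.null(v$not_measurable_level))
        expect_no_error(assign_level(v, NOT_MEASURABLE))
    }
  }
})

test_that("therapeutic load lookup enforces a monotone map and no defaults", {
  expect_equal(assign_therapeutic_load("high", list(low = 1, medium = 2, high = 3)), 3)
  expect_equal(assign_therapeutic_load("low", list(low = 1, medium = 2, high = 3)), 1)
  expect_error(assign_therapeutic_load("low", list(low = 3, medium = 1, high = 2)),
               "non-decreasing")
  expect_error(assign_therapeutic_load("low", NULL), "required")
  expect_error(assign_therapeutic_load("low", list(low = 1, medium = 2)),
               "low, medium and high")
  # a matrix carrying a load map propagates it into the result
  cfg <- simple_matrix_config(2L)
  cfg$load_map <- list(low = 1, medium = 2, high = 3)
  m <- load_matrix(cfg)
  res <- categorize(list(values = list(v1 = 25, v2 = 25)), m)
  expect_equal(res$category, "high")
  expect_equal(res$therapeutic_load, 3)
})

test_that("re-categorization schedules follow the unit's policy", {
  daily <- recat_policy("daily")
  expect_true(recategorization_due(as.POSIXct("2012-03-01 10:00", tz = "UTC"),
                                   as.POSIXct("2012-03-02 09:00", tz = "UTC"), daily))
  expect_false(recategorization_due(as.POSIXct("2012-03-01 08:00", tz = "UTC"),
                                    as.POSIXct("2012-03-01 19:00", tz = "UTC"), daily))

  weekly <- recat_policy("weekly-on-fixed-weekday", weekday = "Wednesday")
  wed <- as.Date("2012-03-07")  # a Wednesday
  expect_false(recategorization_due(wed, wed, weekly))
  expect_true(recategorization_due(wed, wed + 7, weekly))
  expect_false(recategorization_due(wed, wed + 1, weekly))  # Thursday
  expect_error(recat_policy("weekly-on-fixed-weekday"), "weekday")

  onev <- recat_policy("on-event", event_kinds = "ventilatory-support-change")
  last <- as.POSIXct("2012-03-01 09:00", tz = "UTC")
  now <- as.POSIXct("2012-03-01 15:00", tz = "UTC")
  extub <- list(kind = "ventilatory-support-change",
                time = as.POSIXct("2012-03-01 11:00", tz = "UTC"))
  expect_true(recategorization_due(last, now, onev, events = list(extub)))
  expect_false(recategorization_due(last, now, onev, events = list()))
  expect_false(recategorization_due(
    last, now, onev,
    events = list(list(kind = "transfer", time = extub$time))))
  expect_error(recategorization_due(now, last, daily), "precedes")
})
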