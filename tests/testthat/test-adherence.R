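mk_instances <- function(dates, unit = "ICU", categorized = TRUE,
                         prescribed = TRUE) {
  data.frame(patient_id = sprintf("P%04d", seq_along(dates)),
             date = as.Date(dates), unit = unit,
             pt_prescribed = prescribed, categorized = categorized)
}

test_that("quarterly adherence is the categorized share of instances", {
  inst <- mk_instances(rep("2011-08-15", 4), categorized = c(TRUE, TRUE, TRUE, FALSE))
  agg <- aggregate_quarters(inst, grouping = "overall")
  expect_equal(nrow(agg), 1L)
  expect_equal(agg$numerator, 3L)
  expect_equal(agg$denominator, 4L)
  expect_equal(agg$adherence, 75)
  expect_equal(agg$quarter_label, "2011-Q3")
  expect_equal(agg$t, 1L)

  none <- aggregate_quarters(mk_instances(rep("2011-08-15", 5), categorized = FALSE),
                             grouping = "overall")
  expect_equal(none$adherence, 0)
})

test_that("quarter indexing is anchored at the window's first calendar quarter", {
  inst <- mk_instances(c("2011-07-01", "2015-09-30"))
  agg <- aggregate_quarters(inst, grouping = "overall")
  expect_equal(nrow(agg), 17L)
  expect_equal(agg$quarter_label[1], "2011-Q3")
  expect_equal(agg$quarter_label[17], "2015-Q3")
  expect_equal(agg$t, 1:17)
  # a full Jul-2011..Dec-2015 window spans 18 contiguous calendar quarters
  agg18 <- aggregate_quarters(mk_instances(c("2011-07-01", "2015-12-31")),
                              grouping = "overall")
  expect_equal(nrow(agg18), 18L)
  expect_equal(agg18$quarter_label[18], "2015-Q4")
})

test_that("unit groups add up to the overall counts every quarter", {
  set.seed(5)
  cfg <- sim_config(quarters = 8, instances_per_quarter = 60, seed = 5)
  inst <- simulate_epr(cfg)$instances
  agg <- aggregate_quarters(inst)
  for (tt in unique(agg$t)) {
    sub <- agg[agg$t == tt, ]
    expect_equal(sub$numerator[sub$group == "overall"],
                 sum(sub$numerator[sub$group != "overall"]))
    expect_equal(sub$denominator[sub$group == "overall"],
                 sum(sub$denominator[sub$group != "overall"]))
  }
})

test_that("aggregation is idempotent and invariant under row shuffling", {
  cfg <- sim_config(quarters = 6, instances_per_quarter = 50, seed = 9)
  inst <- simulate_epr(cfg)$instances
  agg1 <- aggregate_quarters(inst)
  agg2 <- aggregate_quarters(inst[sample(nrow(inst)), ])
  expect_equal(agg1, agg2)
  expect_equal(aggregate_quarters(inst), agg1)
})

test_that("empty quarters are emitted with a missing adherence value, never dropped", {
  inst <- mk_instances(c("2011-07-10", "2012-02-10"))  # nothing in 2011-Q4
  agg <- aggregate_quarters(inst, grouping = "overall")
  expect_equal(nrow(agg), 3L)
  mid <- agg[agg$quarter_label == "2011-Q4", ]
  expect_equal(mid$denominator, 0L)
  expect_true(is.na(mid$adherence))
  expect_error(adherence_series(agg), "missing adherence|gaps")
  expect_equal(nrow(adherence_series(agg, allow_missing = TRUE)), 3L)
})

test_that("the two denominator policies count different instance sets", {
  inst <- mk_instances(rep("2013-05-01", 10),
                       prescribed = rep(c(TRUE, FALSE), each = 5),
                       categorized = c(TRUE, TRUE, TRUE, FALSE, FALSE,
                                       rep(FALSE, 5)))
  all_pol <- aggregate_quarters(inst, grouping = "overall")
  expect_equal(all_pol$adherence, 30)
  presc <- aggregate_quarters(inst, grouping = "overall",
                              denominator_policy = "prescribed-only")
  expect_equal(presc$denominator, 5L)
  expect_equal(presc$adherence, 60)
  # a categorized instance without a prescription violates the policy
  bad <- inst; bad$categorized[6] <- TRUE
  expect_error(aggregate_quarters(bad, denominator_policy = "prescribed-only"),
               "not eligible")
  expect_no_error(aggregate_quarters(bad))  # fine under all-instances
})

test_that("input validation: units, window, schema, duplicates", {
  inst <- mk_instances("2012-01-05", unit = "ward-7")
  expect_error(aggregate_quarters(inst), "unknown unit")
  inst2 <- mk_instances(c("2012-01-05", "2013-06-01"))
  expect_error(aggregate_quarters(inst2, window = as.Date(c("2012-01-01", "2012-12-31"))),
               "outside the aggregation window")
  expect_error(aggregate_quarters(inst2[, -2]), "lacks column")
  expect_error(aggregate_quarters(inst2[0, ]), "empty")

  agg <- aggregate_quarters(inst2, grouping = "overall")
  dup <- rbind(agg, agg[1, ])
  expect_error(adherence_series(dup), "duplicated quarter")
  expect_error(adherence_series(agg, group = "ICU"), "no rows")
})

test_that("a 17-quarter series extracts in order with values preserved", {
  cfg <- sim_config(seed = 3, instances_per_quarter = 40)
  inst <- simulate_epr(cfg)$instances
  agg <- aggregate_quarters(inst)
  s <- adherence_series(agg, "overall")
  expect_equal(nrow(s), 17L)
  expect_equal(s$t, 1:17)
  expect_equal(s$adherence,
               agg$adherence[agg$group == "overall"][order(agg$t[agg$group == "overall"])])
  one <- aggregate_quarters(mk_instances("2011-08-01"), grouping = "overall")
  expect_equal(nrow(adherence_series(one)), 1L)
})
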