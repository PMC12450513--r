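test_that("synthetic generation is deterministic and self-consistent", {
  p1 <- generate_synthetic_parameters(1)
  p2 <- generate_synthetic_parameters(1)
  expect_identical(p1, p2)
  expect_length(validate_parameters(p1), 0)

  expect_equal(p1$adherence_cds - p1$adherence_soc, p1$treatment_effect$mean,
               tolerance = 1e-12)
  # life table: Gompertz-shaped (non-decreasing) and closed at max_age
  expect_true(all(diff(p1$life_table$qx) >= 0))
  expect_equal(p1$life_table$qx[p1$life_table$age == p1$max_age], 1)
  # efficacy RRs below 1, bleeding RRs at or above 1
  for (tx in c("warfarin", "NOAC")) {
    expect_lt(p1$relative_risks[[tx]]$IS$mean, 1)
    expect_lt(p1$relative_risks[[tx]]$SE$mean, 1)
    expect_gte(p1$relative_risks[[tx]]$MB$mean, 1)
    expect_gte(p1$relative_risks[[tx]]$ICH$mean, 1)
  }
  expect_error(generate_synthetic_parameters(1, "no_such_profile"))
})

test_that("generator profiles adjust embolic risk and entry age", {
  lo <- generate_synthetic_parameters(1, "low_risk")
  hi <- generate_synthetic_parameters(1, "high_risk")
  base <- generate_synthetic_parameters(1)
  expect_equal(lo$start_age, 65L)
  expect_lt(lo$event_rates_untreated$IS$mean, base$event_rates_untreated$IS$mean)
  expect_equal(lo$event_rates_untreated$MI$mean,
               base$event_rates_untreated$MI$mean / 3)
  expect_gt(hi$event_rates_untreated$IS$mean, base$event_rates_untreated$IS$mean)
  expect_equal(hi$start_age, base$start_age)
  expect_length(validate_parameters(lo), 0)
  expect_length(validate_parameters(hi), 0)
})

test_that("lifetime event counts from synthetic defaults are plausible", {
  p <- base_params()
  trace <- run_quiet(run_cohort(p, "SoC"))
  counts <- count_events(trace, p$cohort_size)
  # order-of-magnitude bracket for ischaemic strokes per 1000 patients
  expect_gt(counts[["IS"]], 50)
  expect_lt(counts[["IS"]], 500)
})

test_that("config round trip preserves the parameter structure", {
  p <- base_params()
  cfg <- withr::local_tempfile(fileext = ".yaml")
  write_parameters(p, cfg)
  p2 <- load_parameters(cfg)
  expect_equal(p2$adherence_cds, p$adherence_cds)
  expect_equal(p2$treatment_effect$mean, p$treatment_effect$mean)
  expect_equal(p2$life_table, p$life_table, tolerance = 1e-9)
  expect_equal(p2$utilities, p$utilities, tolerance = 1e-9)
  for (fld in c("event_rates_untreated", "relative_risks", "case_fatality",
                "post_event_mortality_multiplier", "utility_decrements",
                "costs")) {
    expect_equal(p2[[fld]], p[[fld]], tolerance = 1e-9, info = fld)
  }
  # second round trip is exact
  cfg2 <- withr::local_tempfile(fileext = ".yaml")
  write_parameters(p2, cfg2)
  expect_identical(unclass(load_parameters(cfg2)), unclass(p2))
})

test_that("loading rejects malformed and out-of-range configs", {
  p <- base_params()
  cfg <- withr::local_tempfile(fileext = ".yaml")

  p_bad <- p
  p_bad$adherence_cds <- 1.5
  p_bad$treatment_effect$mean <- 1.5 - p$adherence_soc
  p_bad$treatment_effect$ci_low <- NA_real_
  p_bad$treatment_effect$ci_high <- NA_real_
  p_bad$treatment_effect$se <- 0.01
  write_parameters(p_bad, cfg)
  expect_error(load_parameters(cfg), "proportion out of \\[0,1\\]")

  cfg_missing <- withr::local_tempfile(fileext = ".yaml")
  y <- yaml::read_yaml({write_parameters(p, cfg); cfg})
  y$event_rates_untreated$IS <- NULL
  yaml::write_yaml(y, cfg_missing)
  expect_error(load_parameters(cfg_missing), "event_rates_untreated.IS")

  expect_error(load_parameters("does-not-exist.yaml"), "not found")
})

test_that("validate_parameters reports all violations without throwing", {
  p <- base_params()
  expect_identical(validate_parameters(p), character(0))

  p$costs$annual_noac$mean <- -5
  v <- validate_parameters(p)
  expect_true(any(grepl("annual_noac", v)))

  p2 <- base_params()
  p2$life_table <- p2$life_table[p2$life_table$age <= 90, ]
  v2 <- validate_parameters(p2)
  expect_true(any(grepl("life_table.*missing coverage", v2)))
  # the diff of required ages is reported, not thrown
  expect_true(any(grepl("91-110", v2)))
})

test_that("age profiles round trip through two-column CSV", {
  p <- base_params()
  csv <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(data.frame(age = p$life_table$age, qx = p$life_table$qx),
                   csv, row.names = FALSE)
  lt <- read_age_profile(csv, "qx")
  expect_equal(lt, p$life_table, tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("uncertain values enforce their invariants", {
  expect_equal(uv(100, family = "gamma_se_quarter")$se, 25)
  expect_error(uv(1, se = -1), "se")
  bad <- uv(0.5, ci_low = 0.6, ci_high = 0.9, family = "normal_from_ci")
  expect_match(uv_violations <- afcea:::uv_violations(bad, "x")[1],
               "does not bracket")
})
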