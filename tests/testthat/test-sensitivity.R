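test_that("one-way variation matches independent single-parameter reruns", {
  p <- base_params()
  tt <- run_quiet(one_way_analysis(p))

  # every varied parameter appears exactly once and rows are sorted by range
  expect_equal(anyDuplicated(tt$parameter), 0)
  expect_true(all(diff(tt$range) <= 0))
  expect_setequal(tt$parameter, names(afcea:::param_leaves(p)))

  # brute-force oracle on three parameters: rebuild the scaled set by hand
  # and rerun the full model
  checks <- list(
    annual_noac_cost = function(q, mult) {
      q$costs$annual_noac$mean <- q$costs$annual_noac$mean * mult
      q
    },
    rr_IS_warfarin = function(q, mult) {
      q$relative_risks$warfarin$IS$mean <-
        q$relative_risks$warfarin$IS$mean * mult
      q
    },
    event_rate_IS = function(q, mult) {
      q$event_rates_untreated$IS$mean <-
        q$event_rates_untreated$IS$mean * mult
      q
    }
  )
  for (nm in names(checks)) {
    row <- tt[tt$parameter == nm, ]
    for (side in c(0.5, 2)) {
      expected <- run_quiet(run_cea(checks[[nm]](p, side)))$icer
      got <- if (side == 0.5) row$icer_low else row$icer_high
      expect_equal(got, expected, tolerance = 1e-12, info = nm)
    }
  }

  # identity multiplier reproduces the base-case ICER for any parameter
  base <- run_quiet(run_cea(p))
  tt1 <- run_quiet(one_way_analysis(p, low_mult = 1, high_mult = 1))
  expect_true(all(abs(tt1$icer_low - base$icer) < 1e-9))
  expect_equal(attr(tt, "base_icer"), base$icer)

  # proportions are clipped to [0, 1] after scaling
  p_hi <- base_params()
  p_hi$case_fatality$ICH$mean <- 0.6
  tt2 <- run_quiet(one_way_analysis(p_hi))
  expect_equal(tt2$high_input[tt2$parameter == "case_fatality_ICH"], 1)
  expect_error(one_way_analysis(p, low_mult = 0), "multipliers")
})

test_that("time-horizon truncations behave consistently", {
  p <- base_params()
  scen <- run_quiet(time_horizon_analysis(p, c(5, 10, 15, 20)))
  s <- attr(scen, "summary")
  expect_equal(nrow(s), 4)
  # longer horizons let the stroke savings accumulate: ICER non-increasing
  expect_true(all(diff(s$icer) <= 0))

  # a horizon at or past the lifetime closure equals the base case
  base <- run_quiet(run_cea(p))
  long <- run_quiet(time_horizon_analysis(p, 500))[[1]]
  expect_equal(long$result$icer, base$icer)
  expect_error(time_horizon_analysis(p, c(5, 0)), "horizon")
})

test_that("treatment-effect sweep is anchored and monotone", {
  p <- base_params()
  base <- run_quiet(run_cea(p))
  sw <- run_quiet(treatment_effect_sweep(p, c(0.005, 0.016, 0.05, 0.1)))

  # the base effect is recovered up to floating-point addition of adherences
  i_base <- which.min(abs(sw$effect - 0.016))
  expect_equal(sw$effect[i_base], 0.016, tolerance = 1e-12)
  expect_equal(sw$icer[i_base], base$icer, tolerance = 1e-9)
  expect_true(all(diff(sw$icer) < 0))

  # the anticoagulation-cost increment is linear in the effect
  fit <- stats::lm(incremental_anticoagulation_cost ~ effect, data = sw)
  expect_lt(max(abs(stats::residuals(fit))),
            1e-6 * max(abs(sw$incremental_anticoagulation_cost)))

  # a null effect leaves the CDS dominated
  sw0 <- run_quiet(treatment_effect_sweep(null_effect_params(), 0))
  expect_equal(sw0$incremental_qalys, 0)
  expect_equal(sw0$classification, "dominated")

  w <- testthat::capture_warnings(treatment_effect_sweep(p, 0.5))
  expect_true(any(grepl("clipped", w)))
})

test_that("the development-cost scenario augments only the CDS fee", {
  p <- base_params()
  base <- run_quiet(run_cea(p))
  scen <- run_quiet(implementation_cost_scenario(p))
  extra <- p$costs$cds_development$mean / p$costs$trial_population *
    p$cohort_size
  expect_equal(scen$result$cds$cds_cost, base$cds$cds_cost + extra)
  expect_equal(scen$result$incremental_cost, base$incremental_cost + extra)
  expect_equal(scen$result$incremental_qalys, base$incremental_qalys)

  # zero development cost reduces to the base case
  p0 <- p
  p0$costs$cds_development$mean <- 0
  scen0 <- run_quiet(implementation_cost_scenario(p0))
  expect_equal(scen0$result$incremental_cost, base$incremental_cost)
})

test_that("max acceptable CDS cost: fixed point and bisection agreement", {
  p <- base_params()
  base <- run_quiet(run_cea(p))

  # threshold set to the base ICER returns the current CDS cost
  mc <- run_quiet(max_cds_cost(p, threshold = base$icer))
  expect_equal(mc$per_cohort, base$cds$cds_cost, tolerance = 1e-9)

  # at the threshold the closed form reproduces lambda * dQ - dC_excl
  mc50 <- run_quiet(max_cds_cost(p))
  d_excl <- base$incremental_cost - base$cds$cds_cost
  expect_equal(mc50$per_cohort,
               p$wtp_threshold * base$incremental_qalys - d_excl)
  expect_equal(mc50$per_patient, mc50$per_cohort / p$cohort_size)

  # closed form equals bisection on 20 random parameter sets
  set.seed(1234)
  for (i in 1:20) {
    pr <- random_valid_params()
    cf <- run_quiet(max_cds_cost(pr, method = "closed_form"))
    bi <- run_quiet(max_cds_cost(pr, method = "bisection"))
    expect_equal(bi$per_cohort, cf$per_cohort,
                 tolerance = 1e-5, info = sprintf("set %d", i))
  }

  # no QALY gain: reported as having no finite answer
  none <- run_quiet(max_cds_cost(null_effect_params()))
  expect_true(is.na(none$per_cohort))
  expect_match(none$reason, "no QALY gain")
})

test_that("risk-profile scenarios rewrite the intended rates", {
  p <- base_params()
  lo <- run_quiet(risk_profile_scenario(p, "scenario1_low_risk"))
  hi <- run_quiet(risk_profile_scenario(p, "scenario2_high_risk"))
  base <- run_quiet(run_cea(p))

  # lower embolic risk means less to gain: ICER rises; higher risk: falls
  expect_gt(lo$result$icer, base$icer)
  expect_true(hi$result$classification == "dominant" ||
                hi$result$icer < base$icer)
  expect_equal(lo$modifications$start_age, 65L)

  # a "scenario" whose rates equal the base rates reproduces the base case
  p_same <- p
  p_same$scenario_rates$high_risk <- list(
    IS = p$event_rates_untreated$IS$mean,
    SE = p$event_rates_untreated$SE$mean)
  same <- run_quiet(risk_profile_scenario(p_same, "scenario2_high_risk"))
  expect_equal(same$result$icer, base$icer, tolerance = 1e-12)

  p_missing <- p
  p_missing$scenario_rates <- NULL
  expect_error(risk_profile_scenario(p_missing, "scenario1_low_risk"),
               "scenario_rates")
})
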