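test_that("rate_to_probability matches its closed form and domain", {
  expect_equal(rate_to_probability(0), 0)
  expect_equal(rate_to_probability(log(2)), 0.5)
  expect_equal(rate_to_probability(0.0231), 1 - exp(-0.0231))
  r <- seq(0, 5, by = 0.25)
  expect_true(all(diff(rate_to_probability(r)) > 0))
  expect_true(all(rate_to_probability(r) >= 0 & rate_to_probability(r) < 1))
  expect_error(rate_to_probability(-0.1), "rate")
})

test_that("transition rows are stochastic at every age and state", {
  p <- base_params()
  A <- run_quiet(afcea:::build_transition_array(p))
  sums <- apply(A, c(1, 3), sum)
  expect_lt(max(abs(sums - 1)), 1e-12)
  expect_true(all(A >= 0))
})

test_that("absorbing and degenerate rows behave as specified", {
  p <- base_params()
  row <- build_transition_row(p, "Dead", 80)
  expect_equal(row[["Dead"]], 1)
  expect_equal(sum(row), 1)

  # no events: an AF row is stay/die with the life-table probability
  p0 <- base_params()
  for (e in names(p0$event_rates_untreated)) p0$event_rates_untreated[[e]]$mean <- 0
  q <- p0$life_table$qx[p0$life_table$age == 80]
  row <- build_transition_row(p0, "AF_NOAC", 80)
  expect_equal(row[["AF_NOAC"]], 1 - q)
  expect_equal(row[["Dead"]], q)
  expect_equal(sum(row != 0), 2)

  expect_error(build_transition_row(p, "no_such_state", 80), "unknown state")
})

test_that("competing-risk conversion agrees with a fine-time-step oracle", {
  p <- base_params()
  for (e in names(p$event_rates_untreated)) p$event_rates_untreated[[e]]$mean <- 0
  p$event_rates_untreated$IS$mean <- 0.02
  p$event_rates_untreated$MB$mean <- 0.05
  # neutralize treatment effects so the untreated rates apply directly
  for (tx in c("warfarin", "NOAC")) {
    for (e in names(p$relative_risks[[tx]])) p$relative_risks[[tx]][[e]]$mean <- 1
  }
  age <- 75
  p$life_table$qx[p$life_table$age == age] <- 0.01

  row <- build_transition_row(p, "AF_untreated", age)
  oracle <- fine_step_competing(c(IS = 0.02, MB = 0.05), 0.01)

  # the independent per-cause conversion differs from the continuous-time
  # solution only at second order in the rates
  expect_equal(row[["IS_acute_untreated"]], oracle[["IS"]], tolerance = 0.05)
  expect_lt(abs(row[["IS_acute_untreated"]] - oracle[["IS"]]), 1.5e-3)
  expect_lt(abs(row[["MB_acute_AF_untreated"]] - oracle[["MB"]]), 1.5e-3)
  expect_lt(abs(row[["Dead"]] - oracle[["death"]]), 1.5e-3)
  # the stay probability accumulates all three per-cause discrepancies
  expect_lt(abs(row[["AF_untreated"]] - oracle[["stay"]]), 3e-3)
})

test_that("event probabilities are rescaled with a warning when they overflow", {
  p <- base_params()
  p$event_rates_untreated$MB$mean <- 5 # extreme bleeding rate
  expect_warning(A <- afcea:::build_transition_array(p), "rescaled")
  sums <- apply(A, c(1, 3), sum)
  expect_lt(max(abs(sums - 1)), 1e-12)
})

test_that("an inert cohort keeps its initial split", {
  p <- inert_params()
  tr <- run_cohort(p, "CDS", horizon_years = 10)
  for (t in 1:11) expect_equal(tr$occupancy[t, ], tr$occupancy[1, ])
  expect_equal(unname(tr$occupancy[1, "AF_untreated"]), 1 - p$adherence_cds)
  expect_equal(unname(tr$occupancy[1, "AF_warfarin"]),
               p$adherence_soc * p$warfarin_fraction)
  # the adherence increment is placed entirely in the NOAC state
  tr_soc <- run_cohort(p, "SoC", horizon_years = 1)
  expect_equal(unname(tr$occupancy[1, "AF_NOAC"] -
                        tr_soc$occupancy[1, "AF_NOAC"]),
               p$treatment_effect$mean)
  expect_equal(unname(tr$occupancy[1, "AF_warfarin"]),
               unname(tr_soc$occupancy[1, "AF_warfarin"]))
})

test_that("cohort traces conserve probability and mortality is monotone", {
  p <- base_params()
  for (arm in c("SoC", "CDS")) {
    tr <- run_quiet(run_cohort(p, arm))
    expect_lt(max(abs(rowSums(tr$occupancy) - 1)), 1e-10)
    alive <- 1 - tr$occupancy[, "Dead"]
    expect_true(all(diff(alive) <= 1e-12))
    expect_true(all(tr$flows >= 0))
    expect_true(all(tr$flows <= alive + 1e-12))
    # lifetime horizon closes: everyone dead at the end
    expect_equal(unname(alive[length(alive)]), 0, tolerance = 1e-12)
    # only the first IS/ICH/SE/MI event is modelled
    first_mass <- sum(tr$flows[, c("IS", "ICH", "SE", "MI")])
    expect_lte(first_mass, 1)
  }
  expect_error(run_cohort(p, "SoC", horizon_years = 0), "horizon")
})

test_that("cohort trace equals the expectation of a microsimulation", {
  p <- base_params()
  tr <- run_quiet(run_cohort(p, "SoC"))
  n <- 2e5
  occ_hat <- run_quiet(microsimulate(p, "SoC", n = n, seed = 42))
  expect_true(microsim_within_mc_error(tr, occ_hat, n))
})

test_that("event counting reproduces hand arithmetic and zero cases", {
  p <- inert_params()
  tr <- run_cohort(p, "SoC", horizon_years = 10)
  expect_equal(unname(count_events(tr, 1000)), rep(0, 5))

  hand <- list(flows = matrix(0, nrow = 3, ncol = 5,
                              dimnames = list(0:2, c("IS", "ICH", "SE", "MI", "MB"))))
  hand$flows[2, "IS"] <- 0.01
  hand$flows[3, "IS"] <- 0.005
  class(hand) <- "afcea_trace"
  expect_equal(count_events(hand, 1000)[["IS"]], 15)
})

test_that("half-cycle correction is the start/end midpoint", {
  p <- base_params()
  tr <- run_quiet(run_cohort(p, "SoC"))
  hc <- half_cycle_corrected_occupancy(tr)
  expect_equal(nrow(hc), nrow(tr$occupancy) - 1L)

  # constant occupancy: identity
  tr0 <- run_cohort(inert_params(), "SoC", horizon_years = 5)
  hc0 <- half_cycle_corrected_occupancy(tr0)
  expect_equal(unname(hc0), unname(tr0$occupancy[1:5, ]))

  # 1 -> 0 occupancy gives 0.5, and the algebraic identity
  # sum(hc) = (start-counted + end-counted) / 2 holds exactly
  expect_equal(unname(hc[nrow(hc), "AF_NOAC"] /
                        tr$occupancy[nrow(hc), "AF_NOAC"]), 0.5)
  occ <- tr$occupancy
  expect_equal(sum(hc), (sum(occ[-nrow(occ), ]) + sum(occ[-1, ])) / 2)
  # corrected alive time lies strictly between start- and end-counted sums
  alive <- 1 - occ[, "Dead"]
  hc_alive <- sum(1 - hc[, "Dead"])
  expect_gt(hc_alive, sum(alive[-1]))
  expect_lt(hc_alive, sum(alive[-length(alive)]))
})

test_that("zero treatment effect makes both arms identical", {
  p <- null_effect_params()
  A <- run_quiet(afcea:::build_transition_array(p))
  tr_soc <- run_cohort(p, "SoC", transitions = A)
  tr_cds <- run_cohort(p, "CDS", transitions = A)
  expect_identical(tr_soc$occupancy, tr_cds$occupancy)
  expect_identical(tr_soc$flows, tr_cds$flows)
})

test_that("tidy trace export is complete and consistent", {
  p <- base_params()
  tr <- run_quiet(run_cohort(p, "SoC", horizon_years = 5))
  df <- as.data.frame(tr)
  expect_setequal(names(df), c("cycle", "age", "state", "occupancy"))
  expect_equal(nrow(df), 6 * nrow(state_space()))
  expect_equal(sum(df$occupancy), 6, tolerance = 1e-9)
})
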