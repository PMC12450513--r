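# Shared parameter-set builders for the test suite. Everything is generated
# in code; no fixture files.

base_params <- function(seed = 1L, profile = "default") {
  generate_synthetic_parameters(seed, profile)
}

# A parameter set with no clinical events and no mortality before max_age:
# the cohort occupancy must stay frozen at its initial split.
inert_params <- function() {
  p <- base_params()
  for (e in names(p$event_rates_untreated)) {
    p$event_rates_untreated[[e]]$mean <- 0
  }
  p$life_table$qx[] <- 0
  p$life_table$qx[p$life_table$age == p$max_age] <- 1
  p
}

# Degenerate uncertainty: every distribution family set to fixed, so PSA
# draws collapse onto the base case.
fix_all_families <- function(p) {
  fix_uv <- function(u) { u$family <- "fixed"; u }
  p$treatment_effect <- fix_uv(p$treatment_effect)
  p$mb_discontinue_prob <- fix_uv(p$mb_discontinue_prob)
  for (e in names(p$event_rates_untreated)) {
    p$event_rates_untreated[[e]] <- fix_uv(p$event_rates_untreated[[e]])
    p$case_fatality[[e]] <- fix_uv(p$case_fatality[[e]])
    p$utility_decrements$acute[[e]] <- fix_uv(p$utility_decrements$acute[[e]])
    p$costs$acute_event[[e]] <- fix_uv(p$costs$acute_event[[e]])
  }
  for (tx in c("warfarin", "NOAC")) {
    for (e in names(p$relative_risks[[tx]])) {
      p$relative_risks[[tx]][[e]] <- fix_uv(p$relative_risks[[tx]][[e]])
    }
    p$utility_decrements$anticoagulation[[tx]] <-
      fix_uv(p$utility_decrements$anticoagulation[[tx]])
  }
  for (e in names(p$post_event_mortality_multiplier)) {
    p$post_event_mortality_multiplier[[e]] <-
      fix_uv(p$post_event_mortality_multiplier[[e]])
    p$utility_decrements$post[[e]] <- fix_uv(p$utility_decrements$post[[e]])
    p$costs$annual_post_event[[e]] <- fix_uv(p$costs$annual_post_event[[e]])
  }
  p$costs$annual_warfarin <- fix_uv(p$costs$annual_warfarin)
  p$costs$annual_noac <- fix_uv(p$costs$annual_noac)
  p
}

# Remove the decision-support effect entirely: both arms share the SoC
# adherence.
null_effect_params <- function(p = base_params()) {
  p$adherence_cds <- p$adherence_soc
  p$treatment_effect$mean <- 0
  p$treatment_effect$ci_low <- NA_real_
  p$treatment_effect$ci_high <- NA_real_
  p$treatment_effect$se <- 0
  p$treatment_effect$family <- "fixed"
  p
}

# Random-but-valid parameter sets for property tests: perturb the synthetic
# base with moderate multiplicative noise using the current RNG.
random_valid_params <- function() {
  p <- base_params()
  jig <- function(x, lo = 0.5, hi = 1.6) x * stats::runif(1, lo, hi)
  for (e in names(p$event_rates_untreated)) {
    p$event_rates_untreated[[e]]$mean <- jig(p$event_rates_untreated[[e]]$mean)
    p$costs$acute_event[[e]]$mean <- jig(p$costs$acute_event[[e]]$mean)
  }
  p$costs$annual_noac$mean <- jig(p$costs$annual_noac$mean)
  p$costs$annual_warfarin$mean <- jig(p$costs$annual_warfarin$mean)
  for (e in names(p$costs$annual_post_event)) {
    p$costs$annual_post_event[[e]]$mean <- jig(p$costs$annual_post_event[[e]]$mean)
  }
  eff <- stats::runif(1, 0.002, 0.05)
  p$adherence_cds <- p$adherence_soc + eff
  p$treatment_effect$mean <- eff
  p$treatment_effect$ci_low <- eff / 4
  p$treatment_effect$ci_high <- eff * 1.8
  p
}

run_quiet <- function(expr) suppressWarnings(expr)
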