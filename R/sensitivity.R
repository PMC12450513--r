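# Registry of the one-way-variable inputs: every uncertain leaf of the
# parameter set except structural settings and the development cost (which
# is excluded from the base case entirely). Each entry is a path into the
# parameter list ending at an uncertain value.
param_leaves <- function(params) {
  paths <- list(treatment_effect = "treatment_effect",
                mb_discontinue_prob = "mb_discontinue_prob")
  for (e in EVENTS) {
    paths[[paste0("event_rate_", e)]] <- c("event_rates_untreated", e)
    paths[[paste0("case_fatality_", e)]] <- c("case_fatality", e)
    paths[[paste0("acute_cost_", e)]] <- c("costs", "acute_event", e)
    paths[[paste0("acute_utility_decrement_", e)]] <-
      c("utility_decrements", "acute", e)
    for (tx in c("warfarin", "NOAC")) {
      paths[[paste0("rr_", e, "_", tx)]] <- c("relative_risks", tx, e)
    }
  }
  for (e in FIRST_EVENTS) {
    paths[[paste0("post_event_mortality_", e)]] <-
      c("post_event_mortality_multiplier", e)
    paths[[paste0("post_event_cost_", e)]] <- c("costs", "annual_post_event", e)
    paths[[paste0("post_utility_decrement_", e)]] <-
      c("utility_decrements", "post", e)
  }
  for (tx in c("warfarin", "NOAC")) {
    paths[[paste0("anticoagulation_utility_decrement_", tx)]] <-
      c("utility_decrements", "anticoagulation", tx)
  }
  paths$annual_warfarin_cost <- c("costs", "annual_warfarin")
  paths$annual_noac_cost <- c("costs", "annual_noac")
  paths$cds_cost <- c("costs", "cds_per_cohort")
  paths
}

get_leaf <- function(params, path) {
  x <- params
  for (k in path) x <- x[[k]]
  x
}

# Scale one uncertain leaf by `mult` (proportion-like leaves are clipped to
# [0, 1]) and restore internal consistency of dependent fields.
set_leaf_mean <- function(params, path, value) {
  u <- get_leaf(params, path)
  if (u$family == "beta_se_quarter") value <- min(1, max(0, value))
  params[[c(path, "mean")]] <- value
  if (identical(path, "treatment_effect")) {
    params$adherence_cds <- min(1, max(0, params$adherence_soc + value))
    params$treatment_effect$mean <- params$adherence_cds - params$adherence_soc
  }
  params
}

#' One-way (tornado) sensitivity analysis
#'
#' Reruns the full deterministic model with each uncertain input scaled to
#' its low and high value in turn (by default halved and doubled), all other
#' inputs at base values. Proportions are clipped to \code{[0, 1]} after
#' scaling; changing the treatment effect moves the CDS-arm adherence with
#' it.
#'
#' @param params Model parameters.
#' @param low_mult,high_mult Positive multipliers applied to each input's
#'   point estimate.
#' @param horizon_years Horizon passed through to the model runs.
#' @return An \code{afcea_tornado} data frame with one row per varied input:
#'   \code{parameter}, \code{low_input}, \code{high_input},
#'   \code{icer_low}, \code{icer_high} and \code{range}
#'   (\code{|icer_high - icer_low|}), sorted by decreasing range. The base
#'   ICER is attached as attribute \code{base_icer}.
#' @export
one_way_analysis <- function(params, low_mult = 0.5, high_mult = 2.0,
                             horizon_years = Inf) {
  if (low_mult <= 0 || high_mult <= 0) stop("multipliers must be > 0")
  base <- run_cea(params, horizon_years)
  leaves <- param_leaves(params)
  rows <- lapply(names(leaves), function(nm) {
    path <- leaves[[nm]]
    m <- get_leaf(params, path)$mean
    vals <- vapply(c(low_mult, high_mult), function(mult) {
      p2 <- set_leaf_mean(params, path, m * mult)
      inp <- get_leaf(p2, path)$mean
      res <- suppressWarnings(run_cea(p2, horizon_years))
      c(inp, res$icer)
    }, numeric(2))
    data.frame(parameter = nm,
               low_input = vals[1L, 1L], high_input = vals[1L, 2L],
               icer_low = vals[2L, 1L], icer_high = vals[2L, 2L])
  })
  out <- do.call(rbind, rows)
  out$range <- abs(out$icer_high - out$icer_low)
  out <- out[order(-out$range), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "base_icer") <- base$icer
  class(out) <- c("afcea_tornado", "data.frame")
  out
}

scenario_result <- function(label, modifications, result) {
  structure(list(label = label, modifications = modifications,
                 result = result),
            class = "afcea_scenario")
}

#' @export
print.afcea_scenario <- function(x, ...) {
  cat(sprintf("<afcea_scenario> %s\n", x$label))
  if (length(x$modifications)) {
    cat("  modified:",
        paste(names(x$modifications), unlist(x$modifications), sep = " = ",
              collapse = ", "), "\n")
  }
  icer <- x$result$icer
  cat(sprintf("  ICER: %s (%s)\n",
              if (is.na(icer)) "undefined" else sprintf("%.2f", icer),
              x$result$classification))
  invisible(x)
}

#' Time-horizon analysis
#'
#' Reruns both strategies with the model truncated at each requested
#' horizon.
#'
#' @param params Model parameters.
#' @param horizons Integer vector of horizons in years (each \eqn{\ge 1}).
#' @return List of \code{afcea_scenario} objects, one per horizon, with a
#'   \code{summary} attribute data frame (horizon, ICER, incrementals).
#' @export
time_horizon_analysis <- function(params, horizons = c(5, 10, 15, 20)) {
  if (any(horizons < 1)) stop("each horizon must be >= 1")
  scen <- lapply(horizons, function(h) {
    res <- run_cea(params, horizon_years = h)
    scenario_result(sprintf("horizon_%d_years", h),
                    list(horizon_years = h), res)
  })
  attr(scen, "summary") <- data.frame(
    horizon_years = horizons,
    icer = vapply(scen, function(s) s$result$icer, numeric(1)),
    incremental_cost = vapply(scen, function(s) s$result$incremental_cost,
                              numeric(1)),
    incremental_qalys = vapply(scen, function(s) s$result$incremental_qalys,
                               numeric(1)),
    classification = vapply(scen, function(s) s$result$classification,
                            character(1))
  )
  scen
}

#' Treatment-effect sweep
#'
#' Varies the adherence gain attributable to the CDS over a grid, placing
#' the whole increment in the NOAC state, and records the ICER and the
#' CDS-related incremental costs at each value.
#'
#' @param params Model parameters.
#' @param effects Numeric grid of absolute adherence gains (default 0.001
#'   to 0.1).
#' @return Data frame with columns \code{effect}, \code{icer},
#'   \code{incremental_cost}, \code{incremental_qalys},
#'   \code{incremental_anticoagulation_cost}, \code{cds_cost} and
#'   \code{classification}.
#' @export
treatment_effect_sweep <- function(params,
                                   effects = seq(0.001, 0.1, by = 0.003)) {
  rows <- lapply(effects, function(eff) {
    cds <- params$adherence_soc + eff
    if (cds > 1) {
      warning(sprintf("effect %g pushes adherence above 1; clipped", eff),
              call. = FALSE)
      cds <- 1
    }
    p2 <- params
    p2$adherence_cds <- cds
    p2$treatment_effect$mean <- cds - p2$adherence_soc
    res <- run_cea(p2)
    data.frame(
      effect = cds - p2$adherence_soc,
      icer = res$icer,
      incremental_cost = res$incremental_cost,
      incremental_qalys = res$incremental_qalys,
      incremental_anticoagulation_cost =
        res$cds$anticoagulation_cost - res$soc$anticoagulation_cost,
      cds_cost = res$cds$cds_cost,
      classification = res$classification
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Development-and-implementation cost scenario
#'
#' Adds the one-time CDS development cost, spread over the trial AF
#' population and scaled to the cohort, to the cycle-0 CDS cost, and reruns
#' the full model.
#'
#' @param params Model parameters (with a positive
#'   \code{costs$cds_development}).
#' @return An \code{afcea_scenario}; its result's \code{cds$cds_cost} holds
#'   the augmented cohort CDS cost.
#' @export
implementation_cost_scenario <- function(params) {
  res <- run_cea(params, include_development = TRUE)
  scenario_result(
    "including_development_cost",
    list(cds_development = params$costs$cds_development$mean,
         trial_population = params$costs$trial_population),
    res)
}

#' Maximum acceptable CDS cost
#'
#' Finds the one-off CDS cost at which the ICER equals the willingness-to-
#' pay threshold. Because the CDS fee enters the incremental cost linearly,
#' the answer is available in closed form,
#' \eqn{c^* = \lambda \, \Delta Q - \Delta C_{-CDS}}, where
#' \eqn{\Delta C_{-CDS}} is the incremental cost excluding the CDS fee; a
#' bisection that reruns the full model is provided as a cross-check.
#'
#' @param params Model parameters.
#' @param threshold Willingness-to-pay threshold (euros/QALY).
#' @param method \code{"closed_form"} (default) or \code{"bisection"}
#'   (solved to 1e-6 relative tolerance by rerunning the model).
#' @return List with \code{per_cohort} and \code{per_patient} maximum
#'   acceptable CDS costs (\code{NA} with an explanatory \code{reason} when
#'   the intervention yields no QALY gain), plus the threshold and method.
#' @export
max_cds_cost <- function(params, threshold = params$wtp_threshold,
                         method = c("closed_form", "bisection")) {
  method <- match.arg(method)
  base <- run_cea(params)
  dq <- base$incremental_qalys
  if (dq <= 0) {
    return(list(per_cohort = NA_real_, per_patient = NA_real_,
                threshold = threshold, method = method,
                reason = "no QALY gain: no finite acceptable CDS cost"))
  }
  d_cost_excl <- base$incremental_cost - base$cds$cds_cost
  if (method == "closed_form") {
    per_cohort <- threshold * dq - d_cost_excl
  } else {
    scale <- params$cohort_size / params$costs$cds_reference_cohort
    f <- function(fee_per_cohort) {
      p2 <- params
      p2$costs$cds_per_cohort$mean <- fee_per_cohort / scale
      run_cea(p2)$icer - threshold
    }
    upper <- 2 * abs(threshold * dq - d_cost_excl) + 1
    per_cohort <- stats::uniroot(f, c(0, upper), tol = 1e-6 * upper)$root
  }
  list(per_cohort = per_cohort,
       per_patient = per_cohort / params$cohort_size,
       threshold = threshold, method = method)
}

#' Risk-profile scenarios
#'
#' Reruns the model for populations with a different embolic risk profile.
#' The low-risk scenario emulates a CHA2DS2-VASc ~1 cohort: patients start
#' at 65, the ischaemic stroke and systemic embolism rates are fixed at the
#' low-risk level for the entire run (they are not raised as the cohort
#' ages), and the MI, ICH and major-bleeding rates are reduced to one third;
#' background mortality still ages normally. The high-risk scenario raises
#' the IS and SE rates to a CHA2DS2-VASc ~6 level and changes nothing else.
#' The scenario rate values are taken from \code{params$scenario_rates}.
#'
#' @param params Model parameters with a populated \code{scenario_rates}.
#' @param scenario \code{"scenario1_low_risk"} or
#'   \code{"scenario2_high_risk"}.
#' @return An \code{afcea_scenario}.
#' @export
risk_profile_scenario <- function(params,
                                  scenario = c("scenario1_low_risk",
                                               "scenario2_high_risk")) {
  scenario <- match.arg(scenario)
  profile <- if (scenario == "scenario1_low_risk") "low_risk" else "high_risk"
  p2 <- apply_risk_profile(params, profile)
  res <- run_cea(p2)
  mods <- list(IS_rate = p2$event_rates_untreated$IS$mean,
               SE_rate = p2$event_rates_untreated$SE$mean)
  if (profile == "low_risk") {
    mods$start_age <- p2$start_age
    mods$other_rates <- "MI, ICH, MB reduced to 1/3"
  }
  scenario_result(scenario, mods, res)
}
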