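#' Discount factor for a model cycle
#'
#' Costs and QALYs accruing in cycle \code{t} are discounted by
#' \eqn{(1+r)^{-t}}; cycle 0 is undiscounted.
#'
#' @param cycle Non-negative integer cycle index (vectorized).
#' @param rate Annual discount rate (\eqn{\ge 0}).
#' @return Discount factor in \code{(0, 1]}.
#' @export
#' @examples
#' discount_factor(0:3, 0.03)
discount_factor <- function(cycle, rate) {
  if (any(cycle < 0)) stop("cycle must be >= 0")
  if (rate < 0) stop("rate must be >= 0")
  (1 + rate)^(-cycle)
}

# Per-state additive utility decrement, annual anticoagulation cost and
# annual post-event cost, aligned with state_space() order.
state_value_vectors <- function(params) {
  ss <- state_space()
  dec <- params$utility_decrements
  n <- nrow(ss)
  u_dec <- numeric(n)
  drug <- numeric(n)
  post_cost <- numeric(n)
  for (i in seq_len(n)) {
    if (ss$kind[i] == "dead") next
    tx <- ss$tx[i]
    if (tx != "untreated") {
      key <- if (tx == "warfarin") "warfarin" else "NOAC"
      u_dec[i] <- u_dec[i] + dec$anticoagulation[[key]]$mean
      drug[i] <- if (key == "warfarin") params$costs$annual_warfarin$mean
                 else params$costs$annual_noac$mean
    }
    if (ss$kind[i] %in% c("acute", "mb_acute")) {
      u_dec[i] <- u_dec[i] + dec$acute[[ss$event[i]]]$mean
    }
    # the chronic post-event condition keeps accruing its decrement and its
    # annual cost, also during a recurrent bleeding year
    cond <- ss$cond[i]
    if (ss$kind[i] %in% c("chronic", "mb_acute") && cond != "AF") {
      ev <- sub("post_", "", cond)
      u_dec[i] <- u_dec[i] + dec$post[[ev]]$mean
      post_cost[i] <- params$costs$annual_post_event[[ev]]$mean
    }
  }
  list(utility_decrement = u_dec, drug_cost = drug, post_event_cost = post_cost,
       states = ss)
}

#' Discounted quality-adjusted life years for one trace
#'
#' Each cycle contributes half-cycle-corrected occupancy times the state
#' utility (age-specific population weight minus the additive decrements for
#' anticoagulation, acute events and post-event sequelae, floored at zero)
#' times the discount factor; the total is scaled to the cohort size.
#'
#' @param trace An \code{afcea_trace}.
#' @param params Model parameters.
#' @param by_cycle If \code{TRUE}, return the per-cycle discounted QALY
#'   vector instead of the total.
#' @return Total discounted QALYs for the cohort (or a per-cycle vector).
#' @export
accumulate_qalys <- function(trace, params, by_cycle = FALSE) {
  hc <- half_cycle_corrected_occupancy(trace)
  n_cyc <- nrow(hc)
  sv <- state_value_vectors(params)
  u_pop <- utility_at(params, trace$ages[seq_len(n_cyc)])
  u <- outer(u_pop, rep(1, ncol(hc))) -
    matrix(sv$utility_decrement, nrow = n_cyc, ncol = ncol(hc), byrow = TRUE)
  if (any(u < 0 & hc > 0)) {
    warning("state utility below 0 after decrements; floored at 0",
            call. = FALSE)
  }
  u <- pmax(u, 0)
  u[, sv$states$kind == "dead"] <- 0
  df <- discount_factor(0:(n_cyc - 1L), params$discount_rate)
  per_cycle <- rowSums(hc * u) * df * params$cohort_size
  if (by_cycle) per_cycle else sum(per_cycle)
}

#' Discounted cost components for one trace
#'
#' Three components are accumulated for the cohort:
#' \describe{
#'   \item{cds_cost}{the one-off CDS running cost, applied undiscounted at
#'     cycle 0 in the CDS arm only, scaled from the reference cohort; when
#'     \code{include_development} is set the one-time development cost is
#'     added, spread over the trial AF population and scaled to the cohort.}
#'   \item{anticoagulation_cost}{annual drug and monitoring cost of the
#'     treated strata, half-cycle corrected and discounted.}
#'   \item{event_cost}{acute event costs attached to the incident flows at
#'     the cycle they occur (not half-cycle corrected), plus annual
#'     post-event costs on half-cycle-corrected post-event occupancy.}
#' }
#'
#' @param trace An \code{afcea_trace}.
#' @param params Model parameters.
#' @param arm \code{"CDS"} or \code{"SoC"}; defaults to the trace's arm.
#' @param include_development Include the amortized development cost in the
#'   cycle-0 CDS cost.
#' @return List with \code{cds_cost}, \code{anticoagulation_cost},
#'   \code{event_cost} and \code{total_cost} (euros, discounted).
#' @export
accumulate_costs <- function(trace, params, arm = trace$arm,
                             include_development = FALSE) {
  hc <- half_cycle_corrected_occupancy(trace)
  n_cyc <- nrow(hc)
  sv <- state_value_vectors(params)
  df <- discount_factor(0:(n_cyc - 1L), params$discount_rate)

  cds_cost <- 0
  if (arm == "CDS") {
    cds_cost <- params$costs$cds_per_cohort$mean /
      params$costs$cds_reference_cohort * params$cohort_size
    if (include_development) {
      cds_cost <- cds_cost + params$costs$cds_development$mean /
        params$costs$trial_population * params$cohort_size
    }
  }

  anticoag <- sum(hc %*% sv$drug_cost * df) * params$cohort_size

  acute_unit <- vapply(params$costs$acute_event, function(u) u$mean,
                       numeric(1))[EVENTS]
  flows <- trace$flows[-1L, , drop = FALSE] # incident at cycles 1..T
  df_flow <- discount_factor(seq_len(nrow(flows)), params$discount_rate)
  acute_cost <- sum((flows %*% acute_unit) * df_flow)
  post_cost <- sum(hc %*% sv$post_event_cost * df)
  event_cost <- (acute_cost + post_cost) * params$cohort_size

  list(cds_cost = cds_cost,
       anticoagulation_cost = anticoag,
       event_cost = event_cost,
       total_cost = cds_cost + anticoag + event_cost)
}

#' Incremental cost-effectiveness comparison of the two strategies
#'
#' @param soc,cds Per-arm outcome lists holding at least \code{total_cost}
#'   and \code{total_qalys} (as produced inside [run_cea()]).
#' @return An \code{afcea_cea} result: per-arm outcomes, incremental cost
#'   and QALYs, the ICER (\code{NA} when incremental QALYs are zero) and a
#'   classification among \code{dominant} (cheaper and more effective),
#'   \code{dominated} (costlier and no more effective) and
#'   \code{tradeoff_icer}.
#' @export
compute_icer <- function(soc, cds) {
  d_cost <- cds$total_cost - soc$total_cost
  d_qaly <- cds$total_qalys - soc$total_qalys
  icer <- if (d_qaly != 0) d_cost / d_qaly else NA_real_
  classification <- if (d_cost < 0 && d_qaly > 0) {
    "dominant"
  } else if (d_cost > 0 && d_qaly <= 0) {
    "dominated"
  } else {
    "tradeoff_icer"
  }
  structure(list(soc = soc, cds = cds,
                 incremental_cost = d_cost, incremental_qalys = d_qaly,
                 icer = icer, classification = classification),
            class = "afcea_cea")
}

#' Run the full two-arm cost-effectiveness analysis
#'
#' Builds the transition structure once, propagates the cohort under both
#' strategies, accumulates discounted costs and QALYs and undiscounted event
#' counts, and returns the incremental comparison.
#'
#' @param params Model parameters.
#' @param horizon_years Yearly cycles to run (\code{Inf} = lifetime).
#' @param include_development Include the amortized CDS development cost.
#' @return An \code{afcea_cea} object whose per-arm entries also carry
#'   \code{events} (expected undiscounted counts) and whose \code{events}
#'   element tabulates both arms with incrementals.
#' @export
#' @examples
#' res <- run_cea(generate_synthetic_parameters(1))
#' res$icer
run_cea <- function(params, horizon_years = Inf, include_development = FALSE) {
  A <- build_transition_array(params)
  arms <- lapply(c(SoC = "SoC", CDS = "CDS"), function(arm) {
    trace <- run_cohort(params, arm, horizon_years, transitions = A)
    out <- accumulate_costs(trace, params, arm, include_development)
    out$total_qalys <- accumulate_qalys(trace, params)
    out$events <- count_events(trace, params$cohort_size)
    out$trace <- trace
    out
  })
  res <- compute_icer(arms$SoC, arms$CDS)
  res$events <- data.frame(
    event = EVENTS,
    soc = as.numeric(arms$SoC$events[EVENTS]),
    cds = as.numeric(arms$CDS$events[EVENTS]),
    incremental = as.numeric(arms$CDS$events[EVENTS] -
                               arms$SoC$events[EVENTS])
  )
  res$horizon_years <- horizon_years
  res$include_development <- include_development
  res
}

#' @export
print.afcea_cea <- function(x, ...) {
  cat("<afcea_cea> CDS vs standard of care\n")
  if (!is.null(x$events)) {
    ev <- x$events
    cat(sprintf("  undiscounted events/%s patients (SoC -> CDS):\n", "cohort"))
    for (i in seq_len(nrow(ev))) {
      cat(sprintf("    %-3s %8.2f -> %8.2f (%+.2f)\n", ev$event[i],
                  ev$soc[i], ev$cds[i], ev$incremental[i]))
    }
  }
  cat(sprintf("  total cost:  SoC %14.2f  CDS %14.2f  (delta %+.2f)\n",
              x$soc$total_cost, x$cds$total_cost, x$incremental_cost))
  cat(sprintf("  total QALYs: SoC %14.1f  CDS %14.1f  (delta %+.3f)\n",
              x$soc$total_qalys, x$cds$total_qalys, x$incremental_qalys))
  if (is.na(x$icer)) {
    cat(sprintf("  ICER: undefined (%s)\n", x$classification))
  } else {
    cat(sprintf("  ICER: %.2f per QALY (%s)\n", x$icer, x$classification))
  }
  invisible(x)
}

# Tidy per-cycle ledger of discounted cost and QALY accrual for one arm.
cea_cycle_ledger <- function(trace, params, arm = trace$arm) {
  hc <- half_cycle_corrected_occupancy(trace)
  n_cyc <- nrow(hc)
  sv <- state_value_vectors(params)
  df <- discount_factor(0:(n_cyc - 1L), params$discount_rate)
  acute_unit <- vapply(params$costs$acute_event, function(u) u$mean,
                       numeric(1))[EVENTS]
  flows <- trace$flows[-1L, , drop = FALSE]
  df_flow <- discount_factor(seq_len(nrow(flows)), params$discount_rate)
  data.frame(
    cycle = 0:(n_cyc - 1L),
    age = trace$ages[seq_len(n_cyc)],
    arm = arm,
    discount = df,
    qalys = accumulate_qalys(trace, params, by_cycle = TRUE),
    anticoagulation_cost = as.numeric(hc %*% sv$drug_cost) * df *
      params$cohort_size,
    acute_event_cost = as.numeric(flows %*% acute_unit) * df_flow *
      params$cohort_size,
    post_event_cost = as.numeric(hc %*% sv$post_event_cost) * df *
      params$cohort_size
  )
}
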