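# Draw one value from an uncertain input using the current RNG state.
draw_uv <- function(u) {
  m <- u$mean
  se <- if (is.na(u$se)) abs(m) / 4 else u$se
  has_ci <- is.finite(u$ci_low) && is.finite(u$ci_high)
  switch(
    u$family,
    fixed = m,
    gamma_se_quarter = {
      if (m <= 0 || se == 0) return(m)
      shape <- (m / se)^2
      stats::rgamma(1L, shape = shape, rate = shape / m)
    },
    beta_se_quarter = {
      if (m <= 0 || m >= 1 || se == 0) return(m)
      v <- min(se^2, 0.95 * m * (1 - m)) # keep the beta parameterization valid
      k <- m * (1 - m) / v - 1
      stats::rbeta(1L, shape1 = m * k, shape2 = (1 - m) * k)
    },
    lognormal_from_ci = {
      if (m <= 0) stop("lognormal_from_ci requires a positive mean")
      sdlog <- if (has_ci) {
        if (u$ci_low <= 0) stop("lognormal_from_ci requires a positive ci_low")
        (log(u$ci_high) - log(u$ci_low)) / (2 * stats::qnorm(0.975))
      } else {
        sqrt(log(1 + (se / m)^2))
      }
      stats::rlnorm(1L, meanlog = log(m), sdlog = sdlog)
    },
    normal_from_ci = {
      sd <- if (has_ci) (u$ci_high - u$ci_low) / (2 * stats::qnorm(0.975))
            else se
      stats::rnorm(1L, mean = m, sd = sd)
    },
    stop(sprintf("unknown distribution family '%s'", u$family))
  )
}

# Replace every uncertain input of the parameter set with one random draw,
# using the current RNG state. Structural settings (ages, cohort size,
# discount rate, threshold, adherence baseline, warfarin fraction, the
# population life table and utility profile) stay fixed. The draw order is
# fixed so that a given RNG state always yields the same parameter set.
draw_parameters <- function(params) {
  p <- params

  eff <- draw_uv(p$treatment_effect)
  # truncate so both arm adherences stay within [0, 1]
  cds <- min(1, max(0, p$adherence_soc + eff))
  p$adherence_cds <- cds
  p$treatment_effect$mean <- cds - p$adherence_soc

  for (e in EVENTS) {
    p$event_rates_untreated[[e]]$mean <- draw_uv(params$event_rates_untreated[[e]])
  }
  for (tx in c("warfarin", "NOAC")) {
    for (e in EVENTS) {
      p$relative_risks[[tx]][[e]]$mean <- draw_uv(params$relative_risks[[tx]][[e]])
    }
  }
  for (e in EVENTS) {
    p$case_fatality[[e]]$mean <- draw_uv(params$case_fatality[[e]])
  }
  for (e in FIRST_EVENTS) {
    p$post_event_mortality_multiplier[[e]]$mean <-
      max(1, draw_uv(params$post_event_mortality_multiplier[[e]]))
  }
  p$mb_discontinue_prob$mean <- draw_uv(params$mb_discontinue_prob)

  dec <- params$utility_decrements
  for (tx in c("warfarin", "NOAC")) {
    p$utility_decrements$anticoagulation[[tx]]$mean <-
      draw_uv(dec$anticoagulation[[tx]])
  }
  for (e in EVENTS) {
    p$utility_decrements$acute[[e]]$mean <- draw_uv(dec$acute[[e]])
  }
  for (e in FIRST_EVENTS) {
    p$utility_decrements$post[[e]]$mean <- draw_uv(dec$post[[e]])
  }

  costs <- params$costs
  p$costs$cds_per_cohort$mean <- draw_uv(costs$cds_per_cohort)
  p$costs$cds_development$mean <- draw_uv(costs$cds_development)
  p$costs$annual_warfarin$mean <- draw_uv(costs$annual_warfarin)
  p$costs$annual_noac$mean <- draw_uv(costs$annual_noac)
  for (e in EVENTS) {
    p$costs$acute_event[[e]]$mean <- draw_uv(costs$acute_event[[e]])
  }
  for (e in FIRST_EVENTS) {
    p$costs$annual_post_event[[e]]$mean <- draw_uv(costs$annual_post_event[[e]])
  }
  p
}

#' Sample one probabilistic parameter set
#'
#' Draws every uncertain input from its distribution: relative risks are
#' lognormal with log-scale spread solved from their 95% CIs, rates, costs
#' and mortality multipliers gamma, proportions and utility decrements beta
#' (both with SE = mean/4 when no standard error is given), and the
#' adherence treatment effect normal from its CI, truncated so both arm
#' adherences remain in \code{[0, 1]}. Structural settings are left fixed,
#' as is anything with family \code{fixed}. All inputs are drawn
#' independently.
#'
#' @param params Base-case model parameters.
#' @param rng_seed Integer seed; the same seed always yields the same draw.
#' @return A parameter set with all means replaced by draws.
#' @export
sample_parameters <- function(params, rng_seed) {
  set.seed(rng_seed)
  draw_parameters(params)
}

#' Probabilistic sensitivity analysis
#'
#' Propagates parameter uncertainty through the model: for each draw, all
#' uncertain inputs are sampled (see [sample_parameters()]), both strategies
#' are rerun over the full horizon, and the incremental cost and QALY pair
#' is recorded. The mean ICER is defined as the ratio of the mean
#' incremental cost to the mean incremental QALYs across draws (robust to
#' near-zero per-draw denominators).
#'
#' @param params Base-case model parameters.
#' @param n_draws Number of Monte Carlo draws (\eqn{\ge 1}).
#' @param seed Integer seed governing the whole analysis.
#' @param threshold Willingness-to-pay threshold used for the summary;
#'   defaults to the one in \code{params}.
#' @return An \code{afcea_psa} object: \code{draws} (data frame of
#'   incremental cost/QALY pairs and per-draw net monetary benefit),
#'   \code{n_draws}, \code{seed}, \code{mean_icer},
#'   \code{prob_below_threshold}, \code{prob_dominant} and
#'   \code{threshold}.
#' @export
run_psa <- function(params, n_draws = 10000, seed = 1L,
                    threshold = params$wtp_threshold) {
  if (n_draws < 1) stop("n_draws must be >= 1")
  set.seed(seed)
  inc_cost <- numeric(n_draws)
  inc_qaly <- numeric(n_draws)
  for (i in seq_len(n_draws)) {
    p_i <- draw_parameters(params)
    res <- suppressWarnings(run_cea(p_i))
    inc_cost[i] <- res$incremental_cost
    inc_qaly[i] <- res$incremental_qalys
  }
  out <- structure(
    list(draws = data.frame(draw = seq_len(n_draws),
                            incremental_cost = inc_cost,
                            incremental_qalys = inc_qaly),
         n_draws = as.integer(n_draws), seed = as.integer(seed),
         threshold = threshold),
    class = "afcea_psa")
  s <- summarize_psa(out, threshold)
  out$draws$nmb <- s$nmb
  out$mean_icer <- s$mean_icer
  out$prob_below_threshold <- s$prob_below_threshold
  out$prob_dominant <- s$prob_dominant
  out
}

#' Summarize a probabilistic sensitivity analysis
#'
#' @param result An \code{afcea_psa} object (or any list with a
#'   \code{draws} data frame holding \code{incremental_cost} and
#'   \code{incremental_qalys}).
#' @param threshold Willingness-to-pay threshold (euros/QALY, \eqn{> 0}).
#' @return List with \code{mean_icer} (ratio of means),
#'   \code{mean_incremental_cost}, \code{mean_incremental_qalys},
#'   \code{prob_below_threshold} (fraction of draws that are dominant or
#'   have a positive QALY gain bought at no more than the threshold),
#'   \code{prob_dominant} and the per-draw net monetary benefit \code{nmb}
#'   (\eqn{\lambda \Delta Q - \Delta C}).
#' @export
summarize_psa <- function(result, threshold) {
  d <- result$draws
  if (is.null(d) || nrow(d) == 0L) stop("no PSA draws to summarize")
  if (threshold <= 0) stop("threshold must be > 0")
  dc <- d$incremental_cost
  dq <- d$incremental_qalys
  dominant <- dc < 0 & dq > 0
  below <- dominant | (dq > 0 & dc / dq <= threshold)
  list(
    mean_icer = mean(dc) / mean(dq),
    mean_incremental_cost = mean(dc),
    mean_incremental_qalys = mean(dq),
    prob_below_threshold = mean(below),
    prob_dominant = mean(dominant),
    nmb = threshold * dq - dc
  )
}

#' @export
print.afcea_psa <- function(x, ...) {
  cat(sprintf("<afcea_psa> %d draws (seed %d)\n", x$n_draws, x$seed))
  cat(sprintf("  mean ICER (ratio of means): %.2f per QALY\n", x$mean_icer))
  cat(sprintf("  P(cost-effective at %g/QALY): %.3f; P(dominant): %.3f\n",
              x$threshold, x$prob_below_threshold, x$prob_dominant))
  invisible(x)
}
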