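# Independent oracles used by the engine tests.

# Individual-level stochastic microsimulation with the same per-cycle
# transition rules as the cohort model. The cohort trace is the expectation
# of this process, so occupancy fractions must agree within Monte-Carlo
# error.
microsimulate <- function(params, arm = "SoC", n = 1e5, seed = 1L,
                          horizon = Inf) {
  set.seed(seed)
  ss <- state_space()
  S <- nrow(ss)
  A <- afcea:::build_transition_array(params)
  t_full <- params$max_age - params$start_age + 1L
  t_end <- as.integer(min(horizon, t_full))

  adh <- if (arm == "CDS") params$adherence_cds else params$adherence_soc
  base <- params$adherence_soc
  init_p <- numeric(S)
  names(init_p) <- ss$name
  init_p["AF_warfarin"] <- base * params$warfarin_fraction
  init_p["AF_NOAC"] <- base * (1 - params$warfarin_fraction) + (adh - base)
  init_p["AF_untreated"] <- 1 - adh

  state <- sample.int(S, n, replace = TRUE, prob = init_p)
  occ <- matrix(0L, nrow = t_end + 1L, ncol = S,
                dimnames = list(0:t_end, ss$name))
  occ[1L, ] <- tabulate(state, S)
  for (t in seq_len(t_end)) {
    new_state <- state
    for (s in unique(state)) {
      idx <- which(state == s)
      new_state[idx] <- sample.int(S, length(idx), replace = TRUE,
                                   prob = A[s, , t])
    }
    state <- new_state
    occ[t + 1L, ] <- tabulate(state, S)
  }
  occ / n
}

# Check a microsimulated occupancy matrix against the cohort trace within
# Monte-Carlo error: each cell's simulated count must fall inside an exact
# binomial band around the trace probability. The band's family-wise level
# matches a two-sided 3-sigma criterion (0.27%) across all cells, using
# exact binomial quantiles so that near-empty cells (where a normal
# +-3*SE band degenerates) are handled correctly.
microsim_within_mc_error <- function(trace, occ_hat, n,
                                     family_alpha = 0.0027) {
  p <- pmin(pmax(trace$occupancy, 0), 1)
  x <- round(occ_hat * n)
  # evaluate each band on the low-count side: qbinom is numerically unstable
  # in the extreme upper tail when p is close to 1
  flip <- p > 0.5
  p[flip] <- 1 - p[flip]
  x[flip] <- n - x[flip]
  alpha <- family_alpha / length(p)
  lo <- stats::qbinom(alpha / 2, n, p)
  hi <- stats::qbinom(1 - alpha / 2, n, p)
  ok <- x >= lo & x <= hi
  structure(all(ok), failures = which(!ok, arr.ind = TRUE))
}

# Continuous-time two-event competing-risk probabilities over one year,
# evaluated by exhaustive propagation over fine sub-steps. Within each step
# every cause is converted independently and simultaneous-exit mass is
# allocated proportionally; with daily steps the discretization error is
# far below the tolerance it is used at.
fine_step_competing <- function(rates, annual_death_prob, n_steps = 365L) {
  haz_death <- -log(1 - annual_death_prob)
  haz <- c(rates, death = haz_death)
  p_step <- 1 - exp(-haz / n_steps)
  exited <- numeric(length(haz))
  names(exited) <- names(haz)
  surv <- 1
  for (k in seq_len(n_steps)) {
    stay <- prod(1 - p_step)
    exit_total <- 1 - stay
    share <- p_step / sum(p_step)
    exited <- exited + surv * exit_total * share
    surv <- surv * stay
  }
  c(exited, stay = surv)
}

# Plain-arithmetic re-accumulation of discounted QALYs from a trace,
# written without any package accumulation helpers.
naive_qalys <- function(trace, params) {
  occ <- trace$occupancy
  ss <- state_space()
  total <- 0
  for (t in seq_len(nrow(occ) - 1L)) {
    age <- trace$ages[t]
    u_pop <- params$utilities$utility[match(min(age, max(params$utilities$age)),
                                            params$utilities$age)]
    for (s in seq_len(nrow(ss))) {
      if (ss$kind[s] == "dead") next
      u <- u_pop
      if (ss$tx[s] != "untreated") {
        u <- u - params$utility_decrements$anticoagulation[[ss$tx[s]]]$mean
      }
      if (ss$kind[s] %in% c("acute", "mb_acute")) {
        u <- u - params$utility_decrements$acute[[ss$event[s]]]$mean
      }
      if (ss$kind[s] %in% c("chronic", "mb_acute") && ss$cond[s] != "AF") {
        u <- u - params$utility_decrements$post[[sub("post_", "", ss$cond[s])]]$mean
      }
      u <- max(0, u)
      hc <- (occ[t, s] + occ[t + 1L, s]) / 2
      total <- total + hc * u * (1 + params$discount_rate)^(-(t - 1L))
    }
  }
  total * params$cohort_size
}
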