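#' Enumerate the model state space
#'
#' The cohort moves between chronic states (atrial fibrillation or a
#' post-event condition, each stratified by the anticoagulation held:
#' untreated, warfarin or NOAC), transient acute-event states occupied for
#' exactly one cycle, and an absorbing Dead state. First events (IS, ICH,
#' SE, MI) can only occur from the AF states; major bleeding (MB) can occur
#' from any alive chronic state and may recur, so its acute states carry the
#' underlying chronic condition so that survivors can return to it (with or
#' without their anticoagulant, depending on the discontinuation
#' probability).
#'
#' @return Data frame with one row per state and columns \code{name},
#'   \code{kind} (\code{chronic}, \code{acute}, \code{mb_acute},
#'   \code{dead}), \code{cond} (the chronic condition, or for acute states
#'   the condition the survivor moves to), \code{tx} (treatment stratum) and
#'   \code{event} (for transient states).
#' @export
state_space <- function() {
  if (!is.null(.afcea_cache$state_space)) return(.afcea_cache$state_space)
  conds <- c("AF", paste0("post_", FIRST_EVENTS))
  chronic_cond <- rep(conds, each = length(TREATMENTS))
  chronic_tx <- rep(TREATMENTS, times = length(conds))
  acute_event <- rep(FIRST_EVENTS, each = length(TREATMENTS))
  acute_tx <- rep(TREATMENTS, times = length(FIRST_EVENTS))
  ss <- data.frame(
    name = c(paste(chronic_cond, chronic_tx, sep = "_"),
             paste0(acute_event, "_acute_", acute_tx),
             paste0("MB_acute_", chronic_cond, "_", chronic_tx),
             "Dead"),
    kind = c(rep("chronic", length(chronic_cond)),
             rep("acute", length(acute_event)),
             rep("mb_acute", length(chronic_cond)),
             "dead"),
    cond = c(chronic_cond, paste0("post_", acute_event), chronic_cond,
             NA_character_),
    tx = c(chronic_tx, acute_tx, chronic_tx, NA_character_),
    event = c(rep(NA_character_, length(chronic_cond)), acute_event,
              rep("MB", length(chronic_cond)), NA_character_)
  )
  .afcea_cache$state_space <- ss
  ss
}

.afcea_cache <- new.env(parent = emptyenv())

#' Convert an annual event rate to an annual transition probability
#'
#' Uses the standard constant-hazard conversion \eqn{p = 1 - e^{-r}}.
#'
#' @param annual_rate Non-negative annual rate (vectorized).
#' @return Probability in \code{[0, 1)}, monotone increasing in the rate.
#' @export
#' @examples
#' rate_to_probability(log(2)) # 0.5
rate_to_probability <- function(annual_rate) {
  if (any(!is.finite(annual_rate)) || any(annual_rate < 0)) {
    stop("rate_to_probability(): rate must be finite and >= 0")
  }
  1 - exp(-annual_rate)
}

lifetable_qx <- function(params, ages) {
  lt <- params$life_table
  i <- match(pmin(ages, max(lt$age)), lt$age)
  if (anyNA(i)) {
    stop(sprintf("life table does not cover ages %s",
                 paste(ages[is.na(i)], collapse = ", ")))
  }
  lt$qx[i]
}

utility_at <- function(params, ages) {
  ut <- params$utilities
  i <- match(pmin(ages, max(ut$age)), ut$age)
  if (anyNA(i)) {
    stop(sprintf("utility profile does not cover ages %s",
                 paste(ages[is.na(i)], collapse = ", ")))
  }
  ut$utility[i]
}

# Full transition structure as an S x S x n_ages array. Competing risks are
# handled by converting each annual rate independently; if the event
# probabilities plus background death exceed 1 the event probabilities are
# rescaled proportionally into the remaining mass (a warning names the state
# and age, except at max_age where the forced q = 1 closes the horizon).
build_transition_array <- function(params, ages = NULL) {
  ss <- state_space()
  S <- nrow(ss)
  if (is.null(ages)) ages <- params$start_age:params$max_age
  nT <- length(ages)
  q <- lifetable_qx(params, ages)
  A <- array(0, dim = c(S, S, nT), dimnames = list(ss$name, ss$name, ages))
  idx <- stats::setNames(seq_len(S), ss$name)
  dead <- idx[["Dead"]]

  rr_of <- function(e, tx) {
    if (tx == "untreated") 1 else params$relative_risks[[tx]][[e]]$mean
  }
  mult_of <- function(cond) {
    if (cond == "AF") 1
    else params$post_event_mortality_multiplier[[sub("post_", "", cond)]]$mean
  }
  cf <- vapply(params$case_fatality, function(u) u$mean, numeric(1))
  disc <- params$mb_discontinue_prob$mean
  rescaled <- character(0)

  for (i in which(ss$kind == "chronic")) {
    cond <- ss$cond[i]; tx <- ss$tx[i]
    events <- if (cond == "AF") EVENTS else "MB"
    p_e <- vapply(events, function(e) {
      rate_to_probability(params$event_rates_untreated[[e]]$mean * rr_of(e, tx))
    }, numeric(1))
    p_die <- pmin(1, q * mult_of(cond))
    sum_pe <- sum(p_e)
    scale <- if (sum_pe > 0) pmin(1, (1 - p_die) / sum_pe) else rep(1, nT)
    over <- scale < 1 & ages < params$max_age
    if (any(over)) {
      rescaled <- c(rescaled, sprintf("%s at age %s", ss$name[i],
                                      paste(ages[over], collapse = ",")))
    }
    for (e in events) {
      col <- if (e == "MB") paste0("MB_acute_", cond, "_", tx)
             else paste0(e, "_acute_", tx)
      A[i, idx[[col]], ] <- p_e[[e]] * scale
    }
    A[i, dead, ] <- p_die
    A[i, i, ] <- pmax(0, 1 - p_die - sum_pe * scale)
  }

  for (i in which(ss$kind == "acute")) {
    e <- ss$event[i]
    survive <- (1 - cf[[e]]) * (1 - q)
    A[i, idx[[paste(ss$cond[i], ss$tx[i], sep = "_")]], ] <- survive
    A[i, dead, ] <- 1 - survive
  }

  for (i in which(ss$kind == "mb_acute")) {
    cond <- ss$cond[i]; tx <- ss$tx[i]
    q_eff <- pmin(1, q * mult_of(cond))
    survive <- (1 - cf[["MB"]]) * (1 - q_eff)
    resume_col <- idx[[paste(cond, tx, sep = "_")]]
    stop_col <- idx[[paste(cond, "untreated", sep = "_")]]
    if (tx == "untreated") {
      A[i, stop_col, ] <- survive
    } else {
      A[i, stop_col, ] <- survive * disc
      A[i, resume_col, ] <- survive * (1 - disc)
    }
    A[i, dead, ] <- 1 - survive
  }

  A[dead, dead, ] <- 1

  if (length(rescaled)) {
    warning("event probabilities rescaled to fit the cycle in: ",
            paste(rescaled, collapse = "; "), call. = FALSE)
  }
  A
}

#' One row of the annual transition matrix
#'
#' Exposes the per-state, per-age transition probabilities for inspection
#' and testing. Rows sum to one.
#'
#' @param params Model parameters.
#' @param state A state name from [state_space()].
#' @param age Cohort age (years) within life-table coverage.
#' @return Named probability vector over all states.
#' @export
build_transition_row <- function(params, state, age) {
  ss <- state_space()
  if (!state %in% ss$name) stop(sprintf("unknown state '%s'", state))
  A <- build_transition_array(params, ages = age)
  A[state, , 1L]
}

#' Run the cohort through the Markov model for one strategy
#'
#' Starts the cohort split across the three AF states according to the
#' arm-specific adherence: a fraction \code{warfarin_fraction} of the
#' SoC-level adherent patients take warfarin, the rest NOAC, and the entire
#' CDS-minus-SoC adherence increment is placed in the NOAC state. The cohort
#' is then propagated through yearly cycles until the horizon or until
#' everyone has died (age \code{max_age + 1} at the latest, since the life
#' table closes with certain death at \code{max_age}).
#'
#' @param params Model parameters.
#' @param arm \code{"CDS"} or \code{"SoC"}.
#' @param horizon_years Number of yearly cycles to run, or \code{Inf} for
#'   the lifetime horizon.
#' @param transitions Optional precomputed result of an internal transition
#'   build, reused across arms for speed.
#' @return An \code{afcea_trace}: list with \code{occupancy} (cycle-by-state
#'   matrix of cohort fractions, cycle 0 first), \code{flows}
#'   (cycle-by-event matrix of incident masses entering each acute state),
#'   \code{ages}, \code{arm} and \code{states}.
#' @export
run_cohort <- function(params, arm = c("SoC", "CDS"), horizon_years = Inf,
                       transitions = NULL) {
  arm <- match.arg(arm)
  if (is.na(horizon_years) || horizon_years < 1) {
    stop("horizon_years must be >= 1")
  }
  ss <- state_space()
  S <- nrow(ss)
  t_full <- params$max_age - params$start_age + 1L
  t_end <- as.integer(min(horizon_years, t_full))
  A <- if (is.null(transitions)) build_transition_array(params) else transitions

  adh <- if (arm == "CDS") params$adherence_cds else params$adherence_soc
  base <- params$adherence_soc
  init <- stats::setNames(numeric(S), ss$name)
  init["AF_warfarin"] <- base * params$warfarin_fraction
  init["AF_NOAC"] <- base * (1 - params$warfarin_fraction) + (adh - base)
  init["AF_untreated"] <- 1 - adh

  occ <- matrix(0, nrow = t_end + 1L, ncol = S,
                dimnames = list(0:t_end, ss$name))
  occ[1L, ] <- init
  for (t in seq_len(t_end)) {
    occ[t + 1L, ] <- occ[t, ] %*% A[, , t]
  }

  flows <- matrix(0, nrow = t_end + 1L, ncol = length(EVENTS),
                  dimnames = list(0:t_end, EVENTS))
  for (e in EVENTS) {
    cols <- ss$name[ss$kind %in% c("acute", "mb_acute") & ss$event == e]
    cols <- cols[!is.na(cols)]
    flows[, e] <- if (length(cols) > 1L) rowSums(occ[, cols, drop = FALSE])
                  else occ[, cols]
  }

  structure(list(occupancy = occ, flows = flows,
                 ages = params$start_age + 0:t_end,
                 arm = arm, states = ss, horizon = t_end),
            class = "afcea_trace")
}

#' @export
print.afcea_trace <- function(x, ...) {
  alive <- 1 - x$occupancy[, "Dead"]
  cat(sprintf("<afcea_trace> arm %s, %d cycles (ages %d-%d), final alive %.4f\n",
              x$arm, x$horizon, min(x$ages), max(x$ages),
              alive[length(alive)]))
  invisible(x)
}

#' Tidy export of a cohort trace
#'
#' @param x An \code{afcea_trace}.
#' @param row.names,optional,... Ignored; present for method compatibility.
#' @return Data frame with columns \code{cycle}, \code{age}, \code{state},
#'   \code{occupancy}.
#' @export
as.data.frame.afcea_trace <- function(x, row.names = NULL, optional = FALSE,
                                      ...) {
  occ <- x$occupancy
  data.frame(
    cycle = rep(as.integer(rownames(occ)), times = ncol(occ)),
    age = rep(x$ages, times = ncol(occ)),
    state = rep(colnames(occ), each = nrow(occ)),
    occupancy = as.vector(occ)
  )
}

#' Expected undiscounted clinical event counts
#'
#' Sums the incident flows into each acute event state over the whole trace
#' and scales to the cohort size. Counts are raw expectations: undiscounted
#' and without half-cycle adjustment. First events (IS, ICH, SE, MI) can
#' occur at most once per patient; major bleedings may recur and every
#' occurrence is counted.
#'
#' @param trace An \code{afcea_trace}.
#' @param cohort_size Number of patients the trace fractions refer to.
#' @return Named numeric vector of expected event counts (IS, ICH, SE, MI,
#'   MB).
#' @export
count_events <- function(trace, cohort_size) {
  colSums(trace$flows) * cohort_size
}

#' Half-cycle corrected occupancy
#'
#' Treats transitions as happening on average mid-cycle by averaging the
#' occupancy at the start and the end of each cycle. The corrected total
#' time in any state therefore lies between the start-counted and
#' end-counted sums.
#'
#' @param trace An \code{afcea_trace} with at least one completed cycle.
#' @return Matrix with one row per cycle lived (cycle 0 first) and one
#'   column per state.
#' @export
half_cycle_corrected_occupancy <- function(trace) {
  occ <- trace$occupancy
  if (nrow(occ) < 2L) stop("trace must contain at least one completed cycle")
  hc <- (occ[-nrow(occ), , drop = FALSE] + occ[-1L, , drop = FALSE]) / 2
  rownames(hc) <- rownames(occ)[-nrow(occ)]
  hc
}
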