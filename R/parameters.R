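EVENTS <- c("IS", "ICH", "SE", "MI", "MB")
FIRST_EVENTS <- c("IS", "ICH", "SE", "MI")
TREATMENTS <- c("untreated", "warfarin", "NOAC")

#' Assemble a full model parameter set
#'
#' Builds the complete input set of the disease-progression model: cohort
#' demographics, arm-specific anticoagulation adherence, untreated annual
#' event rates, treatment-specific relative risks, acute case fatality and
#' post-event mortality multipliers, a general-population life table,
#' age-specific utilities with additive decrements, and unit costs.
#' Inputs subject to uncertainty are [uv()] objects; structural settings are
#' plain numbers.
#'
#' @param adherence_soc,adherence_cds Proportion of the cohort on
#'   guideline-recommended anticoagulation in each arm. Their difference must
#'   equal \code{treatment_effect$mean}; the increment is assumed to consist
#'   entirely of NOAC-treated patients.
#' @param treatment_effect [uv()]: the absolute adherence gain attributable
#'   to the decision support system.
#' @param warfarin_fraction Fraction of the \emph{baseline} (SoC-level)
#'   treated patients on warfarin; the remainder are on NOAC.
#' @param start_age,max_age Cohort age at entry and the age at which the life
#'   table closes (death probability forced to 1).
#' @param cohort_size Number of patients in the simulated cohort.
#' @param discount_rate Annual discount rate applied to costs and QALYs.
#' @param wtp_threshold Willingness-to-pay threshold in euros per QALY.
#' @param event_rates_untreated Named list (IS, ICH, SE, MI, MB) of [uv()]
#'   annual event rates in untreated patients.
#' @param relative_risks Nested named list
#'   \code{list(warfarin = list(IS = uv, ...), NOAC = ...)} of relative risks
#'   versus no treatment.
#' @param case_fatality Named list per event of [uv()] proportions dying
#'   during the acute event year.
#' @param post_event_mortality_multiplier Named list (IS, ICH, SE, MI) of
#'   [uv()] multipliers (\eqn{\ge 1}) on background mortality after the event.
#' @param mb_discontinue_prob [uv()]: probability of permanently stopping
#'   anticoagulation after a major bleeding.
#' @param life_table Data frame with columns \code{age}, \code{qx} covering
#'   every integer age in \code{[start_age, max_age]}.
#' @param utilities Data frame with columns \code{age}, \code{utility}
#'   (population QALY weights in \code{[0, 1]}) with the same coverage.
#' @param utility_decrements List with components \code{anticoagulation}
#'   (per treatment), \code{acute} (per event) and \code{post} (per
#'   first-event type), each a named list of [uv()] additive decrements.
#' @param costs List with [uv()] components \code{cds_per_cohort} (one-off
#'   CDS running cost for \code{cds_reference_cohort} patients),
#'   \code{cds_development}, \code{annual_warfarin}, \code{annual_noac},
#'   \code{acute_event} (per event), \code{annual_post_event} (per
#'   first-event type), plus plain numbers \code{cds_reference_cohort} and
#'   \code{trial_population} (the divisor used to spread the development
#'   cost per patient).
#' @param scenario_rates Optional list with \code{low_risk} and
#'   \code{high_risk} components, each holding plain IS and SE annual rates
#'   for the risk-profile scenarios.
#' @param schema_version Config schema version tag.
#' @return An object of class \code{afcea_parameters}.
#' @seealso [generate_synthetic_parameters()], [load_parameters()],
#'   [validate_parameters()]
#' @export
model_parameters <- function(adherence_soc, adherence_cds, treatment_effect,
                             warfarin_fraction,
                             start_age = 75, max_age = 110, cohort_size = 1000,
                             discount_rate = 0.03, wtp_threshold = 50000,
                             event_rates_untreated, relative_risks,
                             case_fatality, post_event_mortality_multiplier,
                             mb_discontinue_prob,
                             life_table, utilities, utility_decrements, costs,
                             scenario_rates = NULL, schema_version = 1L) {
  p <- list(
    schema_version = schema_version,
    adherence_soc = adherence_soc,
    adherence_cds = adherence_cds,
    treatment_effect = treatment_effect,
    warfarin_fraction = warfarin_fraction,
    start_age = as.integer(start_age),
    max_age = as.integer(max_age),
    cohort_size = cohort_size,
    discount_rate = discount_rate,
    wtp_threshold = wtp_threshold,
    event_rates_untreated = event_rates_untreated,
    relative_risks = relative_risks,
    case_fatality = case_fatality,
    post_event_mortality_multiplier = post_event_mortality_multiplier,
    mb_discontinue_prob = mb_discontinue_prob,
    life_table = life_table,
    utilities = utilities,
    utility_decrements = utility_decrements,
    costs = costs,
    scenario_rates = scenario_rates
  )
  class(p) <- "afcea_parameters"
  p
}

#' @export
print.afcea_parameters <- function(x, ...) {
  cat("<afcea_parameters>\n")
  cat(sprintf("  cohort: %d patients, start age %d, horizon to age %d\n",
              x$cohort_size, x$start_age, x$max_age))
  cat(sprintf("  adherence: SoC %.3f, CDS %.3f (effect %.3f)\n",
              x$adherence_soc, x$adherence_cds, x$treatment_effect$mean))
  cat(sprintf("  discounting %.1f%%/yr, threshold EUR %g/QALY\n",
              100 * x$discount_rate, x$wtp_threshold))
  rates <- vapply(x$event_rates_untreated, function(u) u$mean, numeric(1))
  cat("  untreated annual rates:",
      paste(sprintf("%s %.4f", names(rates), rates), collapse = ", "), "\n")
  invisible(x)
}

#' Validate a model parameter set
#'
#' Checks every type invariant of the parameter set and reports violations as
#' human-readable messages. Never throws: an empty character vector means the
#' set is valid.
#'
#' @param params An \code{afcea_parameters} object.
#' @return Character vector of violation descriptions (empty when valid).
#' @export
validate_parameters <- function(params) {
  v <- character(0)
  add <- function(...) v <<- c(v, sprintf(...))
  prop <- function(x, name) {
    if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
      add("%s: proportion out of [0,1] (got %s)", name, format(x))
    }
  }

  prop(params$adherence_soc, "adherence_soc")
  prop(params$adherence_cds, "adherence_cds")
  prop(params$warfarin_fraction, "warfarin_fraction")
  v <- c(v, uv_violations(params$treatment_effect, "treatment_effect"))
  d <- params$adherence_cds - params$adherence_soc
  if (abs(d - params$treatment_effect$mean) > 1e-9) {
    add("treatment_effect: adherence_cds - adherence_soc = %g but mean is %g",
        d, params$treatment_effect$mean)
  }

  if (params$start_age >= params$max_age) add("start_age: must be < max_age")
  if (params$cohort_size < 1) add("cohort_size: must be >= 1")
  if (params$discount_rate < 0) add("discount_rate: must be >= 0")
  if (params$wtp_threshold <= 0) add("wtp_threshold: must be > 0")

  check_uv_map <- function(map, path, events, lower = 0, strict = FALSE) {
    for (e in events) {
      nm <- paste0(path, ".", e)
      if (is.null(map[[e]])) {
        add("%s: missing", nm)
        next
      }
      v <<- c(v, uv_violations(map[[e]], nm))
      m <- map[[e]]$mean
      if (strict && m <= lower) add("%s: must be > %g (got %g)", nm, lower, m)
      if (!strict && m < lower) add("%s: must be >= %g (got %g)", nm, lower, m)
    }
  }

  check_uv_map(params$event_rates_untreated, "event_rates_untreated", EVENTS)
  for (tx in c("warfarin", "NOAC")) {
    check_uv_map(params$relative_risks[[tx]],
                 paste0("relative_risks.", tx), EVENTS, lower = 0,
                 strict = TRUE)
  }
  check_uv_map(params$case_fatality, "case_fatality", EVENTS)
  for (e in EVENTS) {
    cf <- params$case_fatality[[e]]
    if (!is.null(cf) && is_uv(cf) && (cf$mean < 0 || cf$mean > 1)) {
      add("case_fatality.%s: proportion out of [0,1]", e)
    }
  }
  check_uv_map(params$post_event_mortality_multiplier,
               "post_event_mortality_multiplier", FIRST_EVENTS, lower = 1)
  v <- c(v, uv_violations(params$mb_discontinue_prob, "mb_discontinue_prob"))
  if (params$mb_discontinue_prob$mean < 0 || params$mb_discontinue_prob$mean > 1) {
    add("mb_discontinue_prob: proportion out of [0,1]")
  }

  ages_needed <- params$start_age:params$max_age
  check_profile <- function(df, path, value_col, require_close = FALSE) {
    if (!is.data.frame(df) || !all(c("age", value_col) %in% names(df))) {
      add("%s: must be a data frame with columns age, %s", path, value_col)
      return(invisible(NULL))
    }
    missing_ages <- setdiff(ages_needed, df$age)
    if (length(missing_ages)) {
      add("%s: missing coverage for ages %s", path,
          paste(range(missing_ages), collapse = "-"))
    }
    vals <- df[[value_col]]
    if (any(!is.finite(vals)) || any(vals < 0 | vals > 1)) {
      add("%s: values outside [0,1]", path)
    }
    if (require_close && params$max_age %in% df$age) {
      q_last <- df[[value_col]][match(params$max_age, df$age)]
      if (abs(q_last - 1) > 1e-12) {
        add("%s: probability at max_age %d must be 1 (got %g)",
            path, params$max_age, q_last)
      }
    }
  }
  check_profile(params$life_table, "life_table", "qx", require_close = TRUE)
  check_profile(params$utilities, "utilities", "utility")

  dec <- params$utility_decrements
  check_uv_map(dec$anticoagulation, "utility_decrements.anticoagulation",
               c("warfarin", "NOAC"))
  check_uv_map(dec$acute, "utility_decrements.acute", EVENTS)
  check_uv_map(dec$post, "utility_decrements.post", FIRST_EVENTS)

  costs <- params$costs
  for (nm in c("cds_per_cohort", "cds_development", "annual_warfarin",
               "annual_noac")) {
    if (is.null(costs[[nm]])) {
      add("costs.%s: missing", nm)
    } else {
      v <- c(v, uv_violations(costs[[nm]], paste0("costs.", nm)))
      if (costs[[nm]]$mean < 0) add("costs.%s: must be >= 0", nm)
    }
  }
  check_uv_map(costs$acute_event, "costs.acute_event", EVENTS)
  check_uv_map(costs$annual_post_event, "costs.annual_post_event", FIRST_EVENTS)
  if (is.null(costs$cds_reference_cohort) || costs$cds_reference_cohort <= 0) {
    add("costs.cds_reference_cohort: must be a positive count")
  }
  if (is.null(costs$trial_population) || costs$trial_population <= 0) {
    add("costs.trial_population: must be a positive count")
  }

  v
}

stop_if_invalid <- function(params) {
  v <- validate_parameters(params)
  if (length(v)) {
    stop("invalid model parameters:\n  ", paste(v, collapse = "\n  "),
         call. = FALSE)
  }
  invisible(params)
}

#' Read a two-column age profile from CSV
#'
#' Life tables and utility profiles are exchanged as plain two-column CSV
#' files (age, value).
#'
#' @param path CSV file path.
#' @param value_col Name to give the value column (\code{"qx"} or
#'   \code{"utility"}).
#' @return Data frame with columns \code{age} and \code{value_col}.
#' @export
read_age_profile <- function(path, value_col = "qx") {
  df <- utils::read.csv(path)
  if (ncol(df) < 2L) stop("age profile CSV needs two columns (age, value)")
  out <- data.frame(age = as.integer(df[[1L]]), value = as.numeric(df[[2L]]))
  names(out)[2L] <- value_col
  out
}

## ---- YAML configuration -------------------------------------------------

uv_to_config <- function(x) as.list(x)

profile_to_config <- function(df, value_col) {
  list(age = as.integer(df$age), value = as.numeric(df[[value_col]]))
}

config_to_profile <- function(x, value_col, dir = ".") {
  if (!is.null(x$csv)) {
    path <- x$csv
    if (!file.exists(path)) path <- file.path(dir, x$csv)
    return(read_age_profile(path, value_col))
  }
  vals <- if (!is.null(x$value)) x$value else x[[value_col]]
  if (is.null(x$age) || is.null(vals)) {
    stop(sprintf("profile needs 'age' and 'value' entries (or a 'csv' path)"))
  }
  out <- data.frame(age = as.integer(unlist(x$age)),
                    value = as.numeric(unlist(vals)))
  names(out)[2L] <- value_col
  out
}

uv_map_from_config <- function(x, keys, family, path) {
  if (is.null(x)) stop(sprintf("missing required key: %s", path))
  out <- list()
  for (k in keys) {
    if (is.null(x[[k]])) stop(sprintf("missing required key: %s.%s", path, k))
    out[[k]] <- uv_from_list(x[[k]], default_family = family,
                             field = paste0(path, ".", k))
  }
  out
}

#' Load model parameters from a YAML configuration file
#'
#' Parses the documented YAML schema, fills optional fields with defaults,
#' validates the result and aborts with a full list of violations if any
#' invariant fails. Life table and utility profile may be given inline
#' (\code{age}/\code{value} vectors) or as a relative \code{csv} path.
#'
#' @param config_path Path to the YAML file.
#' @return A validated \code{afcea_parameters} object.
#' @seealso [write_parameters()] for the inverse operation.
#' @export
load_parameters <- function(config_path) {
  if (!file.exists(config_path)) {
    stop(sprintf("config file not found: %s", config_path))
  }
  cfg <- yaml::read_yaml(config_path)
  dir <- dirname(config_path)
  need <- function(x, key) {
    if (is.null(x)) stop(sprintf("missing required key: %s", key))
    x
  }
  adher <- need(cfg$adherence, "adherence")
  demo <- need(cfg$demographics, "demographics")
  sett <- if (is.null(cfg$settings)) list() else cfg$settings
  costs_cfg <- need(cfg$costs, "costs")

  costs <- c(
    list(
      cds_per_cohort = uv_from_list(need(costs_cfg$cds_per_cohort,
                                         "costs.cds_per_cohort"),
                                    "fixed", "costs.cds_per_cohort"),
      cds_development = uv_from_list(
        if (is.null(costs_cfg$cds_development)) 0 else costs_cfg$cds_development,
        "fixed", "costs.cds_development"),
      annual_warfarin = uv_from_list(need(costs_cfg$annual_warfarin,
                                          "costs.annual_warfarin"),
                                     "gamma_se_quarter", "costs.annual_warfarin"),
      annual_noac = uv_from_list(need(costs_cfg$annual_noac,
                                      "costs.annual_noac"),
                                 "gamma_se_quarter", "costs.annual_noac"),
      cds_reference_cohort =
        if (is.null(costs_cfg$cds_reference_cohort)) 1000
        else costs_cfg$cds_reference_cohort,
      trial_population =
        if (is.null(costs_cfg$trial_population)) 14134
        else costs_cfg$trial_population
    ),
    list(
      acute_event = uv_map_from_config(costs_cfg$acute_event, EVENTS,
                                       "gamma_se_quarter", "costs.acute_event"),
      annual_post_event = uv_map_from_config(costs_cfg$annual_post_event,
                                             FIRST_EVENTS, "gamma_se_quarter",
                                             "costs.annual_post_event")
    )
  )

  scen <- NULL
  if (!is.null(cfg$scenario_rates)) {
    scen <- lapply(cfg$scenario_rates, function(s) {
      list(IS = as.numeric(s$IS), SE = as.numeric(s$SE))
    })
  }

  params <- model_parameters(
    adherence_soc = need(adher$soc, "adherence.soc"),
    adherence_cds = need(adher$cds, "adherence.cds"),
    treatment_effect = uv_from_list(need(cfg$treatment_effect,
                                         "treatment_effect"),
                                    "normal_from_ci", "treatment_effect"),
    warfarin_fraction = need(adher$warfarin_fraction,
                             "adherence.warfarin_fraction"),
    start_age = need(demo$start_age, "demographics.start_age"),
    max_age = if (is.null(demo$max_age)) 110 else demo$max_age,
    cohort_size = if (is.null(demo$cohort_size)) 1000 else demo$cohort_size,
    discount_rate = if (is.null(sett$discount_rate)) 0.03 else sett$discount_rate,
    wtp_threshold = if (is.null(sett$wtp_threshold)) 50000 else sett$wtp_threshold,
    event_rates_untreated = uv_map_from_config(cfg$event_rates_untreated,
                                               EVENTS, "gamma_se_quarter",
                                               "event_rates_untreated"),
    relative_risks = list(
      warfarin = uv_map_from_config(need(cfg$relative_risks,
                                         "relative_risks")$warfarin,
                                    EVENTS, "lognormal_from_ci",
                                    "relative_risks.warfarin"),
      NOAC = uv_map_from_config(cfg$relative_risks$NOAC, EVENTS,
                                "lognormal_from_ci", "relative_risks.NOAC")
    ),
    case_fatality = uv_map_from_config(cfg$case_fatality, EVENTS,
                                       "beta_se_quarter", "case_fatality"),
    post_event_mortality_multiplier = uv_map_from_config(
      cfg$post_event_mortality_multiplier, FIRST_EVENTS,
      "gamma_se_quarter", "post_event_mortality_multiplier"),
    mb_discontinue_prob = uv_from_list(need(cfg$mb_discontinue_prob,
                                            "mb_discontinue_prob"),
                                       "beta_se_quarter",
                                       "mb_discontinue_prob"),
    life_table = config_to_profile(need(cfg$life_table, "life_table"),
                                   "qx", dir),
    utilities = config_to_profile(need(cfg$utilities, "utilities"),
                                  "utility", dir),
    utility_decrements = list(
      anticoagulation = uv_map_from_config(
        need(cfg$utility_decrements, "utility_decrements")$anticoagulation,
        c("warfarin", "NOAC"), "beta_se_quarter",
        "utility_decrements.anticoagulation"),
      acute = uv_map_from_config(cfg$utility_decrements$acute, EVENTS,
                                 "beta_se_quarter", "utility_decrements.acute"),
      post = uv_map_from_config(cfg$utility_decrements$post, FIRST_EVENTS,
                                "beta_se_quarter", "utility_decrements.post")
    ),
    costs = costs,
    scenario_rates = scen,
    schema_version = if (is.null(cfg$schema_version)) 1L else cfg$schema_version
  )
  stop_if_invalid(params)
}

#' Write model parameters back to a YAML configuration file
#'
#' Serializes a parameter set to the same schema [load_parameters()] reads,
#' so that a load/write/load round trip reproduces the structure.
#'
#' @param params An \code{afcea_parameters} object.
#' @param config_path Output file path.
#' @return Invisibly, \code{config_path}.
#' @export
write_parameters <- function(params, config_path) {
  uv_map <- function(m) lapply(m, uv_to_config)
  cfg <- list(
    schema_version = params$schema_version,
    demographics = list(start_age = params$start_age,
                        max_age = params$max_age,
                        cohort_size = params$cohort_size),
    settings = list(discount_rate = params$discount_rate,
                    wtp_threshold = params$wtp_threshold),
    adherence = list(soc = params$adherence_soc,
                     cds = params$adherence_cds,
                     warfarin_fraction = params$warfarin_fraction),
    treatment_effect = uv_to_config(params$treatment_effect),
    event_rates_untreated = uv_map(params$event_rates_untreated),
    relative_risks = list(warfarin = uv_map(params$relative_risks$warfarin),
                          NOAC = uv_map(params$relative_risks$NOAC)),
    case_fatality = uv_map(params$case_fatality),
    post_event_mortality_multiplier =
      uv_map(params$post_event_mortality_multiplier),
    mb_discontinue_prob = uv_to_config(params$mb_discontinue_prob),
    life_table = profile_to_config(params$life_table, "qx"),
    utilities = profile_to_config(params$utilities, "utility"),
    utility_decrements = list(
      anticoagulation = uv_map(params$utility_decrements$anticoagulation),
      acute = uv_map(params$utility_decrements$acute),
      post = uv_map(params$utility_decrements$post)
    ),
    costs = c(
      list(cds_per_cohort = uv_to_config(params$costs$cds_per_cohort),
           cds_development = uv_to_config(params$costs$cds_development),
           annual_warfarin = uv_to_config(params$costs$annual_warfarin),
           annual_noac = uv_to_config(params$costs$annual_noac),
           cds_reference_cohort = params$costs$cds_reference_cohort,
           trial_population = params$costs$trial_population),
      list(acute_event = uv_map(params$costs$acute_event),
           annual_post_event = uv_map(params$costs$annual_post_event))
    ),
    scenario_rates = params$scenario_rates
  )
  yaml::write_yaml(cfg, config_path, precision = 15L)
  invisible(config_path)
}
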