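#' Uncertain model input
#'
#' Container for a single numeric model input together with the information
#' needed to sample it in probabilistic sensitivity analysis: a point
#' estimate, an optional standard error and/or 95% confidence interval, and a
#' distribution family.
#'
#' Families follow the usual health-economic conventions:
#' \describe{
#'   \item{\code{lognormal_from_ci}}{relative risks; log-scale spread solved
#'     from the 95% CI.}
#'   \item{\code{gamma_se_quarter}}{rates, costs and multipliers; when no
#'     standard error is given it defaults to mean/4.}
#'   \item{\code{beta_se_quarter}}{proportions and utility decrements; same
#'     mean/4 default.}
#'   \item{\code{normal_from_ci}}{additive effects (the adherence treatment
#'     effect); spread solved from the 95% CI.}
#'   \item{\code{fixed}}{never varied.}
#' }
#'
#' @param mean Point estimate.
#' @param se Standard error; for the \code{*_se_quarter} families it defaults
#'   to \code{mean / 4} when omitted.
#' @param ci_low,ci_high Optional 95% confidence limits; required for the
#'   \code{*_from_ci} families.
#' @param family Distribution family, one of the five listed above.
#' @return An object of class \code{afcea_uv}.
#' @export
#' @examples
#' uv(0.016, ci_low = 0.003, ci_high = 0.028, family = "normal_from_ci")
#' uv(1000, family = "gamma_se_quarter") # se defaults to 250
uv <- function(mean, se = NULL, ci_low = NULL, ci_high = NULL,
               family = c("fixed", "gamma_se_quarter", "beta_se_quarter",
                          "lognormal_from_ci", "normal_from_ci")) {
  family <- match.arg(family)
  if (!is.numeric(mean) || length(mean) != 1L || !is.finite(mean)) {
    stop("uv(): 'mean' must be a single finite number")
  }
  if (is.null(se)) {
    se <- if (family %in% c("gamma_se_quarter", "beta_se_quarter")) {
      abs(mean) / 4
    } else {
      NA_real_
    }
  }
  if (!is.na(se) && se < 0) stop("uv(): 'se' must be >= 0")
  x <- list(
    mean = as.numeric(mean),
    se = as.numeric(se),
    ci_low = if (is.null(ci_low)) NA_real_ else as.numeric(ci_low),
    ci_high = if (is.null(ci_high)) NA_real_ else as.numeric(ci_high),
    family = family
  )
  class(x) <- "afcea_uv"
  x
}

#' @export
print.afcea_uv <- function(x, ...) {
  ci <- if (is.finite(x$ci_low) || is.finite(x$ci_high)) {
    sprintf(" [%g, %g]", x$ci_low, x$ci_high)
  } else ""
  cat(sprintf("<uv> %g%s (%s)\n", x$mean, ci, x$family))
  invisible(x)
}

is_uv <- function(x) inherits(x, "afcea_uv")

#' @export
as.list.afcea_uv <- function(x, ...) {
  out <- unclass(x)
  out[!vapply(out, function(v) is.numeric(v) && is.na(v), logical(1))]
}

uv_from_list <- function(x, default_family = "fixed", field = "<uv>") {
  if (is_uv(x)) return(x)
  if (is.numeric(x) && length(x) == 1L) {
    return(uv(x, family = default_family))
  }
  if (!is.list(x) || is.null(x$mean)) {
    stop(sprintf("parameter '%s' must be a number or a {mean, ...} map", field))
  }
  uv(x$mean,
     se = x$se, ci_low = x$ci_low, ci_high = x$ci_high,
     family = if (is.null(x$family)) default_family else x$family)
}

# Violations of the invariants of a single uncertain value, as messages
# prefixed with the parameter's name.
uv_violations <- function(x, name) {
  out <- character(0)
  add <- function(msg) out <<- c(out, sprintf("%s: %s", name, msg))
  if (!is_uv(x)) {
    return(sprintf("%s: not an uncertain value", name))
  }
  if (!is.finite(x$mean)) add("mean is not finite")
  if (!is.na(x$se) && x$se < 0) add("se < 0")
  has_ci <- is.finite(x$ci_low) && is.finite(x$ci_high)
  if (has_ci && !(x$ci_low < x$mean && x$mean < x$ci_high)) {
    add(sprintf("confidence interval [%g, %g] does not bracket mean %g",
                x$ci_low, x$ci_high, x$mean))
  }
  if (x$family %in% c("lognormal_from_ci", "normal_from_ci") && !has_ci &&
      (is.na(x$se) || x$se == 0)) {
    add(sprintf("family %s needs a confidence interval or se", x$family))
  }
  out
}
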