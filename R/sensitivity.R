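#' Perturb one source parameter and report the surface-temperature change
#'
#' One-at-a-time sensitivity study: the forward model is evaluated at the
#' base source and at a copy with one parameter perturbed (by a signed
#' fraction or to an explicit value), and the per-offset temperature
#' differences are reported together with the peak difference. Over the
#' usual study base case the surface temperature is most sensitive to depth:
#' a 20\% depth change moves the peak by more than a 20\% intensity or
#' radius change does.
#'
#' @param base a \code{\link{heat_source}}.
#' @param tissue a \code{\link{tissue_params}}.
#' @param param one of \code{"Q"}, \code{"d"}, \code{"R"}.
#' @param fraction signed relative change, e.g. \code{-0.2} for a 20\%
#'   decrease. Exactly one of \code{fraction} and \code{value} is given.
#' @param value explicit perturbed value (alternative to \code{fraction}).
#' @param offsets lateral offsets (m) over which to evaluate both profiles;
#'   should include 0 so the peak is observed.
#' @return a \code{perturbation_result} list: \code{param},
#'   \code{base_value}, \code{perturbed_value}, \code{fraction},
#'   \code{delta_Tmax} (absolute peak difference, degC) and
#'   \code{delta_profile} (perturbed minus base, per offset).
#' @examples
#' tp <- tissue_params()
#' base <- heat_source(0.045, 0.0105, 0.005)
#' perturb_parameter(base, tp, "Q", value = 0.036,
#'                   offsets = seq(-0.1, 0.1, by = 0.001))$delta_Tmax
#' @export
perturb_parameter <- function(base, tissue, param, fraction = NULL,
                              value = NULL, offsets = seq(-0.1, 0.1, by = 0.001)) {
  stopifnot(inherits(base, "heat_source"))
  if (!param %in% c("Q", "d", "R")) stop("param must be one of 'Q', 'd', 'R'")
  if (is.null(fraction) == is.null(value))
    stop("give exactly one of 'fraction' or 'value'")
  base_value <- base[[param]]
  perturbed_value <- if (is.null(value)) base_value * (1 + fraction) else value
  if (base_value != 0) fraction <- (perturbed_value - base_value) / base_value
  args <- list(Q = base$Q, d = base$d, R = base$R)
  args[[param]] <- perturbed_value
  pert <- tryCatch(do.call(heat_source, args),
                   error = function(e) stop("perturbation violates source ",
                                            "constraints: ", conditionMessage(e)))
  p0 <- surface_profile(base, tissue, offsets)
  p1 <- surface_profile(pert, tissue, offsets)
  delta <- p1$temps - p0$temps
  structure(list(param = param, base_value = base_value,
                 perturbed_value = perturbed_value, fraction = fraction,
                 delta_Tmax = abs(peak_temperature(p1) - peak_temperature(p0)),
                 delta_profile = delta, offsets = offsets),
            class = "perturbation_result")
}

#' Propagate a random temperature-measurement error through a profile
#'
#' Emulates an imperfectly calibrated camera by adding a seeded random error
#' of \eqn{\pm}\code{fraction} to a surface profile, in one of two modes:
#' \describe{
#'   \item{\code{absolute}}{each temperature (degC) is multiplied by
#'     \eqn{(1+u)}, \eqn{u \sim U(-f, f)} i.i.d. The worst-case peak
#'     deviation is \eqn{f \cdot \max T}.}
#'   \item{\code{range}}{each temperature is shifted by \eqn{u} times the
#'     profile span \eqn{T_{max}-T_{min}}, so every deviation is bounded by
#'     \eqn{f \cdot (T_{max}-T_{min})}.}
#' }
#'
#' @param profile a \code{\link{temperature_profile}}.
#' @param fraction error half-width as a fraction, in \eqn{[0, 1)}.
#' @param mode \code{"absolute"} or \code{"range"}.
#' @param seed integer seed for the uniform draws.
#' @return a list: \code{perturbed} (profile), \code{max_deviation}
#'   (max \eqn{|T'-T|}, degC), \code{worst_case_bound} (degC), \code{mode},
#'   \code{fraction}, \code{seed}.
#' @export
temperature_perturbation_study <- function(profile, fraction,
                                           mode = c("absolute", "range"),
                                           seed = 1L) {
  stopifnot(inherits(profile, "temperature_profile"))
  mode <- match.arg(mode)
  if (!is.numeric(fraction) || length(fraction) != 1L || fraction < 0 || fraction >= 1)
    stop("fraction must lie in [0, 1)")
  temps <- profile$temps
  u <- if (fraction == 0) numeric(length(temps)) else
    with_seed(seed, stats::runif(length(temps), -fraction, fraction))
  span <- max(temps) - min(temps)
  newt <- switch(mode,
                 absolute = temps * (1 + u),
                 range = temps + u * span)
  bound <- switch(mode,
                  absolute = fraction * max(temps),
                  range = fraction * span)
  list(perturbed = temperature_profile(profile$offsets, newt, profile$T_env),
       max_deviation = max(abs(newt - temps)),
       worst_case_bound = bound,
       mode = mode, fraction = fraction, seed = seed)
}

#' Relative-error table for estimated source parameters
#'
#' Per-parameter relative error of an estimate against the true source,
#' \eqn{100\,|est - true| / true}, with the true value as denominator.
#' Rows with a zero true value are flagged as undefined rather than divided.
#'
#' @param true_params true source: a \code{\link{heat_source}} or a named
#'   numeric vector.
#' @param estimated_params estimated source, same form.
#' @return a data.frame with columns \code{parameter}, \code{original_value},
#'   \code{optimized_value}, \code{error_percent} (rounded to 2 decimals;
#'   \code{NA} when undefined) and \code{defined}.
#' @examples
#' relative_error_table(c(d = 2, R = 5, Q = 0.37),
#'                      c(d = 2.03, R = 4.5, Q = 0.3559))
#' @export
relative_error_table <- function(true_params, estimated_params) {
  as_named <- function(x) {
    if (inherits(x, "heat_source")) c(Q = x$Q, d = x$d, R = x$R)
    else if (is.numeric(x) && !is.null(names(x))) x
    else stop("parameters must be a heat_source or a named numeric vector")
  }
  tv <- as_named(true_params)
  ev <- as_named(estimated_params)
  if (!setequal(names(tv), names(ev)))
    stop("true and estimated parameter names differ")
  ev <- ev[names(tv)]
  defined <- tv != 0
  err <- ifelse(defined, round(100 * abs(ev - tv) / tv, 2), NA_real_)
  data.frame(parameter = names(tv), original_value = unname(tv),
             optimized_value = unname(ev), error_percent = unname(err),
             defined = unname(defined), row.names = NULL)
}
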