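#' Surface temperature above an embedded heat source
#'
#' Closed-form steady-state skin-surface temperature at lateral offset
#' \code{a} from the point directly above the source center:
#' \deqn{T(a) = T_e + \frac{Q}{4\pi h_0\,[(d+R)^2 + a^2]}}
#' where \eqn{T_e} is the ambient temperature, \eqn{h_0} the surface heat
#' exchange coefficient and \eqn{d+R} the effective depth. The formula follows
#' from the point-source solution of the steady-state bioheat equation
#' combined with a surface energy balance; a spherical source of radius R at
#' depth d is exactly equivalent to a point source at depth d + R.
#'
#' @param source a \code{\link{heat_source}}.
#' @param tissue a \code{\link{tissue_params}} (supplies \code{h0} and the
#'   ambient temperature).
#' @param a lateral offset(s) along the surface, m; may be negative
#'   (the profile is symmetric in \code{a}).
#' @return surface temperature(s), degC.
#' @examples
#' tp <- tissue_params(T_env = celsius_to_kelvin(26.6))
#' src <- heat_source(Q = 0.045, d = 0.0105, R = 0.005)
#' surface_temperature(src, tp, a = 0)   # peak temperature
#' @export
surface_temperature <- function(source, tissue, a) {
  stopifnot(inherits(source, "heat_source"), inherits(tissue, "tissue_params"))
  if (!is.numeric(a) || length(a) < 1L || any(!is.finite(a)))
    stop("a must be finite numeric offset(s) in meters")
  d_eff <- source$d + source$R
  t_env_c(tissue) + source$Q / (4 * pi * tissue$h0 * (d_eff^2 + a^2))
}

#' Surface temperature profile along a line through the hotspot
#'
#' Evaluates \code{\link{surface_temperature}} over a strictly increasing set
#' of lateral offsets and returns a \code{\link{temperature_profile}}.
#'
#' @inheritParams surface_temperature
#' @param offsets strictly increasing lateral offsets, m.
#' @return a \code{temperature_profile}.
#' @export
surface_profile <- function(source, tissue, offsets) {
  if (!is.numeric(offsets) || length(offsets) == 0L)
    stop("offsets must be a non-empty numeric vector")
  temperature_profile(offsets = offsets,
                      temps = surface_temperature(source, tissue, offsets),
                      T_env = t_env_c(tissue))
}

#' Radial temperature field of a point source in an infinite medium
#'
#' The three-dimensional steady-state temperature distribution around a point
#' source of power Q in tissue of conductivity k:
#' \deqn{T(r) = \frac{Q}{4\pi k r} + T_0.}
#' Decreasing in r, approaching the far-field temperature \eqn{T_0} as
#' \eqn{r \to \infty}; singular at the origin.
#'
#' @param Q source power, W.
#' @param k thermal conductivity, W/(m K).
#' @param T0 far-field temperature, degC.
#' @param r radial distance(s) from the source, m; must be positive.
#' @return temperature(s), degC.
#' @export
point_source_field <- function(Q, k, T0, r) {
  if (!is.numeric(r) || any(!is.finite(r)) || any(r <= 0))
    stop("r must be positive (the point-source field is singular at the origin)")
  if (!is.numeric(k) || length(k) != 1L || k <= 0)
    stop("k must be a single positive conductivity")
  if (!is.numeric(Q) || length(Q) != 1L || Q < 0)
    stop("Q must be a single non-negative power")
  Q / (4 * pi * k * r) + T0
}

#' One-at-a-time parameter sweep of the forward model
#'
#' Varies a single source parameter (Q, d or R) over a set of values while
#' holding the other two at their base values, and returns the surface
#' profile for each value. This is the standard parametric study showing that
#' the peak temperature rises with intensity and falls with depth (and with
#' radius, through the effective depth d + R).
#'
#' @param base a \code{\link{heat_source}} providing the held-fixed values.
#' @param tissue a \code{\link{tissue_params}}.
#' @param param one of \code{"Q"}, \code{"d"}, \code{"R"}.
#' @param values values the chosen parameter takes, one profile each.
#' @param offsets lateral offsets for every profile, m.
#' @return a named list of \code{temperature_profile}s, one per value.
#' @export
parameter_sweep <- function(base, tissue, param, values, offsets) {
  stopifnot(inherits(base, "heat_source"))
  if (!is.character(param) || length(param) != 1L || !param %in% c("Q", "d", "R"))
    stop("param must be one of 'Q', 'd', 'R'")
  if (!is.numeric(values) || length(values) == 0L)
    stop("values must be a non-empty numeric vector")
  out <- lapply(values, function(v) {
    args <- list(Q = base$Q, d = base$d, R = base$R)
    args[[param]] <- v
    surface_profile(do.call(heat_source, args), tissue, offsets)
  })
  names(out) <- paste0(param, "=", format(values, trim = TRUE))
  out
}
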