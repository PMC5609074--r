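#' Estimate source intensity from three clinical temperatures
#'
#' Screening-style workflow needing only three scalars: the room (ambient)
#' temperature, the normal skin temperature away from the hotspot, and the
#' peak temperature of the hotspot. Because only superficially conducted
#' heat reaches the surface, the source depth is specified as a plausible
#' range rather than a point; the peak relation
#' \eqn{Q = 4\pi h_0 (d+R)^2 (T_{max}-T_e)} then gives an intensity for
#' every depth on a uniform grid, and their mean is reported as the working
#' estimate. For each depth the offset at which the modelled surface cools
#' to the normal skin temperature,
#' \eqn{a = (d+R)\sqrt{(T_{max}-T_{skin})/(T_{skin}-T_e)}}, bounds the
#' visibly warm region.
#'
#' @param T_env ambient (room) temperature, degC.
#' @param T_max peak surface temperature of the hotspot, degC.
#' @param T_skin normal skin temperature, degC (\code{T_env < T_skin < T_max}).
#' @param depth_range \code{c(lo, hi)} of source-top depths considered, m.
#' @param R assumed source radius, m (near-negligible by default).
#' @param tissue a \code{\link{tissue_params}}; its stored ambient is
#'   overridden by \code{T_env}.
#' @param n_depths number of depths on the uniform grid.
#' @param profile_offsets offsets (m) of the returned modelled profile.
#' @return an \code{application_estimate} list: \code{depths},
#'   \code{Q_by_depth} (W), \code{Q_mean} (W), \code{skin_radius_by_depth}
#'   (m), and the modelled \code{profile} at the mid-range depth (whose peak
#'   equals \code{T_max} by construction).
#' @examples
#' estimate_source(T_env = 20, T_max = 35.2, T_skin = 30)$Q_mean
#' @export
estimate_source <- function(T_env, T_max, T_skin,
                            depth_range = c(0.006, 0.01), R = 0.001,
                            tissue = tissue_params(), n_depths = 9L,
                            profile_offsets = seq(-0.1, 0.1, by = 0.0005)) {
  if (!(T_env < T_skin && T_skin < T_max))
    stop("temperatures must satisfy T_env < T_skin < T_max")
  if (!is.numeric(depth_range) || length(depth_range) != 2L ||
      depth_range[1] <= 0 || depth_range[1] > depth_range[2])
    stop("depth_range must be positive with lo <= hi")
  depths <- seq(depth_range[1], depth_range[2], length.out = n_depths)
  d_eff <- depths + R
  Q <- 4 * pi * tissue$h0 * d_eff^2 * (T_max - T_env)
  a_skin <- d_eff * sqrt((T_max - T_skin) / (T_skin - T_env))
  d_mid <- depths[ceiling(n_depths / 2)]
  tis <- tissue
  tis$T_env <- celsius_to_kelvin(T_env)
  prof <- surface_profile(heat_source(Q[ceiling(n_depths / 2)], d_mid, R),
                          tis, profile_offsets)
  structure(list(depths = depths, Q_by_depth = Q, Q_mean = mean(Q),
                 skin_radius_by_depth = a_skin, R = R,
                 T_env = T_env, T_max = T_max, T_skin = T_skin,
                 profile = prof),
            class = "application_estimate")
}

#' @export
print.application_estimate <- function(x, ...) {
  cat("Intensity estimate from (T_env, T_skin, T_max) = (",
      x$T_env, ", ", x$T_skin, ", ", x$T_max, ") degC\n", sep = "")
  cat(sprintf("  depths %g-%g m (R = %g m): Q in [%.4g, %.4g] W, mean %.4g W\n",
              min(x$depths), max(x$depths), x$R,
              min(x$Q_by_depth), max(x$Q_by_depth), x$Q_mean))
  cat(sprintf("  warm-region radius (to T_skin): %.4g-%.4g m\n",
              min(x$skin_radius_by_depth), max(x$skin_radius_by_depth)))
  invisible(x)
}
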