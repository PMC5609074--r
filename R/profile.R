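#' One-dimensional surface temperature profile
#'
#' Ordered lateral offsets (m) from the point above the source center,
#' surface temperatures (degC) at those offsets, and the ambient reference.
#'
#' @param offsets strictly increasing lateral distances, m (may be negative).
#' @param temps surface temperatures at the offsets, degC.
#' @param T_env ambient temperature, degC.
#' @return an object of class \code{temperature_profile}.
#' @export
temperature_profile <- function(offsets, temps, T_env) {
  if (!is.numeric(offsets) || length(offsets) == 0L || any(!is.finite(offsets)))
    stop("offsets must be non-empty finite numerics")
  if (any(diff(offsets) <= 0))
    stop("offsets must be strictly increasing")
  if (!is.numeric(temps) || length(temps) != length(offsets))
    stop("temps must match offsets in length")
  if (!is.numeric(T_env) || length(T_env) != 1L || !is.finite(T_env))
    stop("T_env must be a single finite temperature (degC)")
  structure(list(offsets = as.numeric(offsets), temps = as.numeric(temps),
                 T_env = as.numeric(T_env)),
            class = "temperature_profile")
}

#' Peak temperature of a profile, degC
#' @param profile a \code{temperature_profile}.
#' @export
peak_temperature <- function(profile) {
  stopifnot(inherits(profile, "temperature_profile"))
  max(profile$temps)
}

#' @export
print.temperature_profile <- function(x, ...) {
  cat(sprintf("Temperature profile: %d points, offsets [%g, %g] m\n",
              length(x$offsets), min(x$offsets), max(x$offsets)))
  cat(sprintf("  T_env = %g degC, peak = %.4f degC at a = %g m\n",
              x$T_env, max(x$temps), x$offsets[which.max(x$temps)]))
  invisible(x)
}

#' @export
as.data.frame.temperature_profile <- function(x, ...) {
  data.frame(offset_m = x$offsets, temp_C = x$temps)
}
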