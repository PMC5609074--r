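#' Convert between Kelvin and degrees Celsius
#'
#' The tissue parameter table stores the arterial and environmental
#' temperatures in Kelvin; all surface-temperature computations work in
#' degrees Celsius. Because the model output depends only on temperature
#' differences, the choice of scale is observationally neutral.
#'
#' @param x numeric temperature(s).
#' @return numeric vector of converted temperatures.
#' @export
kelvin_to_celsius <- function(x) x - 273.15

#' @rdname kelvin_to_celsius
#' @export
celsius_to_kelvin <- function(x) x + 273.15

#' Thermal and biological tissue parameters
#'
#' Bundle of the physical constants entering the steady-state bioheat model
#' of breast tissue. Defaults are the standard literature values for sound
#' breast tissue.
#'
#' @param k thermal conductivity, W/(m K).
#' @param h0 heat exchange (convective) coefficient coupling the skin surface
#'   to ambient air, W/(m^2 K).
#' @param c_b blood specific heat, J/(kg K).
#' @param rho_b blood density, kg/m^3.
#' @param q_m metabolic heat generation of sound breast tissue, W/m^3.
#' @param Q_t_range interval of tumor metabolic heat generation, W/m^3.
#' @param omega_b blood perfusion rate, 1/s.
#' @param T_arterial arterial blood temperature, K.
#' @param T_env environmental (ambient) temperature, K. Use
#'   \code{celsius_to_kelvin()} to set it from a Celsius reading.
#' @param rho tissue density, kg/m^3 (optional; unused by the steady-state
#'   model, retained for completeness).
#' @param c tissue specific heat, J/(kg K) (optional; unused in steady state).
#' @return an object of class \code{tissue_params}.
#' @examples
#' tp <- tissue_params()
#' t_env_c(tp)   # 27 degC ambient
#' @export
tissue_params <- function(k = 0.52, h0 = 8.77, c_b = 4186, rho_b = 1000,
                          q_m = 700, Q_t_range = c(25000, 90000),
                          omega_b = 0.00052, T_arterial = 310.15,
                          T_env = 300.15, rho = NULL, c = NULL) {
  scalars <- list(k = k, h0 = h0, c_b = c_b, rho_b = rho_b, q_m = q_m,
                  omega_b = omega_b, T_arterial = T_arterial, T_env = T_env)
  for (nm in names(scalars)) {
    v <- scalars[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop("tissue parameter '", nm, "' must be a single positive number")
  }
  if (!is.numeric(Q_t_range) || length(Q_t_range) != 2L ||
      any(Q_t_range <= 0) || Q_t_range[1] >= Q_t_range[2])
    stop("Q_t_range must be a positive interval with lower < upper")
  for (nm in c("rho", "c")) {
    v <- get(nm)
    if (!is.null(v) && (!is.numeric(v) || length(v) != 1L || v <= 0))
      stop("tissue parameter '", nm, "' must be positive when supplied")
  }
  structure(c(scalars, list(Q_t_range = Q_t_range, rho = rho, c = c)),
            class = "tissue_params")
}

#' Ambient temperature of a tissue parameter set, in degrees Celsius
#'
#' @param tissue a \code{tissue_params} object.
#' @return ambient temperature, degC.
#' @export
t_env_c <- function(tissue) {
  stopifnot(inherits(tissue, "tissue_params"))
  kelvin_to_celsius(tissue$T_env)
}

#' @export
print.tissue_params <- function(x, ...) {
  cat("Tissue parameters (steady-state bioheat model)\n")
  cat(sprintf("  k        = %g W/(m K)\n", x$k))
  cat(sprintf("  h0       = %g W/(m^2 K)\n", x$h0))
  cat(sprintf("  q_m      = %g W/m^3\n", x$q_m))
  cat(sprintf("  Q_t      = [%g, %g] W/m^3\n", x$Q_t_range[1], x$Q_t_range[2]))
  cat(sprintf("  c_b      = %g J/(kg K), rho_b = %g kg/m^3, omega_b = %g 1/s\n",
              x$c_b, x$rho_b, x$omega_b))
  cat(sprintf("  T_arterial = %.2f K (%.2f degC), T_env = %.2f K (%.2f degC)\n",
              x$T_arterial, kelvin_to_celsius(x$T_arterial),
              x$T_env, kelvin_to_celsius(x$T_env)))
  invisible(x)
}
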