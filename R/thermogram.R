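#' Noise specification for synthetic thermograms
#'
#' The measurement-error models applied to synthetic surface temperatures:
#' \describe{
#'   \item{\code{none}}{noiseless forward model.}
#'   \item{\code{elevation_percent}}{multiplicative uniform error of
#'     \eqn{\pm}\code{magnitude} applied to the temperature elevation above
#'     ambient, keeping the ambient reference exact (the "10\% random noise"
#'     model used for noisy training data).}
#'   \item{\code{absolute_percent}}{multiplicative uniform error of
#'     \eqn{\pm}\code{magnitude} applied to the absolute Celsius temperature
#'     (the "\eqn{\pm}5\% temperature error" model).}
#'   \item{\code{gaussian_additive}}{additive Gaussian error with standard
#'     deviation \code{magnitude} degC.}
#' }
#' All random kinds require a seed and are exactly reproducible.
#'
#' @param kind one of \code{"none"}, \code{"elevation_percent"},
#'   \code{"absolute_percent"}, \code{"gaussian_additive"}.
#' @param magnitude fraction (percent kinds) or degC (gaussian); non-negative.
#' @param seed integer seed; mandatory unless \code{kind = "none"}.
#' @return an object of class \code{noise_spec}.
#' @export
noise_spec <- function(kind = c("none", "elevation_percent", "absolute_percent",
                                "gaussian_additive"),
                       magnitude = 0, seed = NULL) {
  kind <- match.arg(kind)
  if (!is.numeric(magnitude) || length(magnitude) != 1L || magnitude < 0)
    stop("noise magnitude must be a single non-negative number")
  if (kind != "none" && is.null(seed))
    stop("a seed is mandatory for any noise kind other than 'none'")
  structure(list(kind = kind, magnitude = magnitude, seed = seed),
            class = "noise_spec")
}

apply_noise <- function(temps, T_env, noise) {
  if (noise$kind == "none") return(temps)
  with_seed(noise$seed, {
    u <- switch(noise$kind,
      elevation_percent = ,
      absolute_percent = stats::runif(length(temps), -noise$magnitude, noise$magnitude),
      gaussian_additive = stats::rnorm(length(temps), 0, noise$magnitude))
    out <- switch(noise$kind,
      elevation_percent = T_env + (temps - T_env) * (1 + u),
      absolute_percent = temps * (1 + u),
      gaussian_additive = temps + u)
    if (is.matrix(temps)) out <- matrix(out, nrow(temps), ncol(temps))
    out
  })
}

#' Two-dimensional surface thermogram
#'
#' A rectangular grid of surface temperatures (degC) with its spatial
#' metadata: isotropic pixel pitch (m/pixel), the physical coordinates of
#' pixel (1,1) and the ambient reference. Synthetic grids carry full
#' generation provenance (source, surface parameters, noise, seed) so that
#' they can be regenerated exactly.
#'
#' @param temps numeric matrix, degC; row-major image convention with pixel
#'   (1,1) at the top-left.
#' @param pixel_pitch meters per pixel, positive.
#' @param T_env ambient temperature, degC.
#' @param origin physical coordinates (m) of pixel (1,1), length 2.
#' @param provenance list of generator parameters, or \code{"measured"}.
#' @return an object of class \code{thermogram_grid}.
#' @export
thermogram_grid <- function(temps, pixel_pitch, T_env, origin = c(0, 0),
                            provenance = "measured") {
  if (!is.matrix(temps) || !is.numeric(temps) || any(dim(temps) == 0L))
    stop("temps must be a non-empty numeric matrix")
  if (!is.numeric(pixel_pitch) || length(pixel_pitch) != 1L || pixel_pitch <= 0)
    stop("pixel_pitch must be a single positive number (m)")
  if (!is.numeric(T_env) || length(T_env) != 1L || !is.finite(T_env))
    stop("T_env must be a single finite temperature (degC)")
  if (!is.numeric(origin) || length(origin) != 2L)
    stop("origin must be two physical coordinates (m)")
  structure(list(temps = temps, pixel_pitch = pixel_pitch,
                 T_env = T_env, origin = as.numeric(origin),
                 provenance = provenance),
            class = "thermogram_grid")
}

#' @export
print.thermogram_grid <- function(x, ...) {
  cat(sprintf("Thermogram grid: %d x %d pixels, pitch %g m, T_env %g degC\n",
              nrow(x$temps), ncol(x$temps), x$pixel_pitch, x$T_env))
  cat(sprintf("  temperatures in [%.4f, %.4f] degC; provenance: %s\n",
              min(x$temps), max(x$temps),
              if (is.character(x$provenance)) x$provenance else "synthetic"))
  invisible(x)
}

#' Generate a synthetic thermogram from the forward model
#'
#' Evaluates the surface-temperature model on a pixel lattice — each pixel
#' takes the temperature at its radial distance from the hotspot center —
#' and optionally applies a seeded noise model. The returned grid records
#' its full provenance and is reproducible bit-for-bit from it.
#'
#' @param source a \code{\link{heat_source}}.
#' @param tissue a \code{\link{tissue_params}}.
#' @param shape grid dimensions \code{c(rows, cols)}.
#' @param pixel_pitch meters per pixel.
#' @param center physical coordinates (m) of the point directly above the
#'   source; defaults to the grid center.
#' @param noise a \code{\link{noise_spec}} (default: none).
#' @param origin physical coordinates of pixel (1,1); default \code{c(0,0)}.
#' @return a \code{\link{thermogram_grid}}.
#' @examples
#' g <- generate_synthetic_thermogram(heat_source(0.1, 0.014), tissue_params(),
#'                                    shape = c(21, 21), pixel_pitch = 0.005)
#' @export
generate_synthetic_thermogram <- function(source, tissue, shape, pixel_pitch,
                                          center = NULL,
                                          noise = noise_spec("none"),
                                          origin = c(0, 0)) {
  stopifnot(inherits(source, "heat_source"), inherits(tissue, "tissue_params"),
            inherits(noise, "noise_spec"))
  if (!is.numeric(shape) || length(shape) != 2L || any(shape < 1))
    stop("shape must be c(rows, cols) with both at least 1")
  shape <- as.integer(shape)
  if (is.null(center))
    center <- origin + (shape - 1) / 2 * pixel_pitch
  ys <- origin[1] + (seq_len(shape[1]) - 1) * pixel_pitch
  xs <- origin[2] + (seq_len(shape[2]) - 1) * pixel_pitch
  r <- sqrt(outer((ys - center[1])^2, (xs - center[2])^2, "+"))
  temps <- matrix(surface_temperature(source, tissue, as.vector(r)),
                  shape[1], shape[2])
  temps <- apply_noise(temps, t_env_c(tissue), noise)
  thermogram_grid(
    temps, pixel_pitch = pixel_pitch, T_env = t_env_c(tissue), origin = origin,
    provenance = list(Q = source$Q, d = source$d, R = source$R,
                      h0 = tissue$h0, T_env_C = t_env_c(tissue),
                      shape = shape, pixel_pitch = pixel_pitch,
                      center = center, origin = origin,
                      noise_kind = noise$kind, noise_magnitude = noise$magnitude,
                      noise_seed = noise$seed))
}

#' Regenerate a synthetic thermogram from its recorded provenance
#'
#' @param grid a synthetic \code{\link{thermogram_grid}}.
#' @return a freshly generated \code{thermogram_grid}, identical to the input.
#' @export
regenerate_thermogram <- function(grid) {
  stopifnot(inherits(grid, "thermogram_grid"))
  p <- grid$provenance
  if (!is.list(p)) stop("grid has no synthetic provenance to regenerate from")
  generate_synthetic_thermogram(
    source = heat_source(p$Q, p$d, p$R),
    tissue = tissue_params(h0 = p$h0, T_env = celsius_to_kelvin(p$T_env_C)),
    shape = p$shape, pixel_pitch = p$pixel_pitch, center = p$center,
    noise = if (p$noise_kind == "none") noise_spec("none")
            else noise_spec(p$noise_kind, p$noise_magnitude, p$noise_seed),
    origin = p$origin)
}
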