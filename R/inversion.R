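#' Observation pair for analytic inversion
#'
#' The two surface readings the closed-form inversion needs: the peak
#' temperature above the source and one local reading at a known lateral
#' offset, together with the ambient reference.
#'
#' @param T_max peak surface temperature, degC.
#' @param T_a local surface temperature at offset \code{a}, degC.
#' @param a lateral offset of the local reading, m (positive).
#' @param T_env ambient temperature, degC.
#' @return an object of class \code{observation_pair}.
#' @export
observation_pair <- function(T_max, T_a, a, T_env) {
  for (nm in c("T_max", "T_a", "a", "T_env")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("'", nm, "' must be a single finite number")
  }
  if (a <= 0) stop("offset a must be positive")
  if (T_a <= T_env)
    stop("local temperature T_a must exceed ambient T_env (degenerate observation)")
  if (T_max <= T_a)
    stop("peak temperature T_max must exceed the local reading T_a")
  structure(list(T_max = T_max, T_a = T_a, a = a, T_env = T_env),
            class = "observation_pair")
}

#' Effective source depth from two surface temperatures
#'
#' Closed-form depth inversion
#' \deqn{d_{\mathrm{eff}} = a\,\sqrt{\frac{T(a)-T_e}{T_{max}-T(a)}}.}
#' On noiseless forward-model data this recovers the effective depth d + R
#' exactly, for any choice of offset a. When the local reading sits at half
#' the peak elevation, the formula reduces to \eqn{d_{\mathrm{eff}} = a}.
#'
#' @param obs an \code{\link{observation_pair}}.
#' @return estimated effective depth d + R, m.
#' @export
depth_from_temps <- function(obs) {
  stopifnot(inherits(obs, "observation_pair"))
  obs$a * sqrt((obs$T_a - obs$T_env) / (obs$T_max - obs$T_a))
}

#' Source intensity from two surface temperatures
#'
#' Closed-form intensity inversion
#' \deqn{Q = 4\pi h_0\,a^2\,\frac{(T(a)-T_e)(T_{max}-T_e)}{T_{max}-T(a)}}
#' which is algebraically \eqn{4\pi h_0 (T(a)-T_e)(d_{\mathrm{eff}}^2+a^2)}.
#' Exact on noiseless forward-model data, independently of the offset used.
#'
#' @param obs an \code{\link{observation_pair}}.
#' @param h0 surface heat exchange coefficient, W/(m^2 K).
#' @return estimated intensity, W.
#' @export
intensity_from_temps <- function(obs, h0) {
  stopifnot(inherits(obs, "observation_pair"))
  if (!is.numeric(h0) || length(h0) != 1L || h0 <= 0)
    stop("h0 must be a single positive number")
  4 * pi * h0 * obs$a^2 *
    (obs$T_a - obs$T_env) * (obs$T_max - obs$T_env) / (obs$T_max - obs$T_a)
}

#' Source radius from intensity and volumetric heat generation
#'
#' \deqn{R = \left(\frac{Q}{Q_m A_t}\right)^{1/3}} with \eqn{Q_m} the
#' volumetric metabolic heat generation (W/m^3) and \eqn{A_t} a volume
#' constant, by convention \eqn{10^{-6}}. The formula is applied exactly as
#' stated; its units do not cohere dimensionally, so the result is a
#' conventional radius score rather than a physically calibrated length
#' (see the package vignette).
#'
#' @param Q source intensity, W.
#' @param Q_m volumetric metabolic heat generation, W/m^3.
#' @param A_t volume constant (default \code{1e-6}).
#' @return radius estimate.
#' @export
radius_from_intensity <- function(Q, Q_m, A_t = 1e-6) {
  if (!is.numeric(Q) || length(Q) != 1L || Q < 0) stop("Q must be non-negative")
  if (!is.numeric(Q_m) || length(Q_m) != 1L || Q_m <= 0) stop("Q_m must be positive")
  if (!is.numeric(A_t) || length(A_t) != 1L || A_t <= 0) stop("A_t must be positive")
  (Q / (Q_m * A_t))^(1 / 3)
}

#' Source radius directly from surface temperatures (intensity-free)
#'
#' Radius relation that bypasses the explicit intensity estimate:
#' \deqn{R^3 = \frac{(T(a)-T_e)\,(a^2+d^2)\,4\pi h_0}{q_m\,10^{-6}}}
#' where d is the effective depth. This is exactly the composition of
#' \code{\link{radius_from_intensity}} with
#' \code{\link{intensity_from_temps}} using \eqn{A_t = 10^{-6}}, and the two
#' routes agree to machine precision on noiseless data.
#'
#' @param T_a local surface temperature, degC.
#' @param T_env ambient temperature, degC.
#' @param a lateral offset of the local reading, m.
#' @param d effective source depth, m.
#' @param h0 surface heat exchange coefficient, W/(m^2 K).
#' @param q_m volumetric metabolic heat generation, W/m^3.
#' @return radius estimate.
#' @export
radius_depth_relation <- function(T_a, T_env, a, d, h0, q_m) {
  if (!is.numeric(q_m) || length(q_m) != 1L || q_m <= 0) stop("q_m must be positive")
  if (T_a < T_env) stop("T_a must not be below ambient T_env")
  if (T_a == T_env) return(0)
  ((T_a - T_env) * (a^2 + d^2) * 4 * pi * h0 / (q_m * 1e-6))^(1 / 3)
}

new_inversion_result <- function(d_eff, Q, R, d, observations, method_flags,
                                 warnings = character()) {
  structure(list(d_eff = d_eff, Q = Q, R = R, d = d,
                 observations = observations, method_flags = method_flags,
                 warnings = warnings),
            class = "inversion_result")
}

#' @export
print.inversion_result <- function(x, ...) {
  cat("Heat-source inversion result\n")
  cat(sprintf("  effective depth d+R = %.6g m\n", x$d_eff))
  cat(sprintf("  intensity Q         = %.6g W\n", x$Q))
  cat(sprintf("  radius R (%s)     = %.6g\n", x$method_flags$radius_method, x$R))
  cat(sprintf("  decomposed depth d  = %.6g m\n", x$d))
  cat(sprintf("  observations used   = %d offset(s)\n", length(x$observations)))
  if (length(x$warnings)) cat("  warnings:", paste(x$warnings, collapse = "; "), "\n")
  invisible(x)
}

# Pick observation pairs out of a 1D profile: peak + readings at the chosen
# offsets (exact measured distances from the peak location are used as `a`).
obs_from_profile <- function(profile, offsets = NULL, n_default = 5L) {
  temps <- profile$temps
  T_env <- profile$T_env
  if (max(temps) <= T_env + sqrt(.Machine$double.eps) * max(1, abs(T_env)))
    stop("no source detected: profile shows no elevation above ambient")
  imax <- which(temps == max(temps))
  peak_x <- mean(profile$offsets[imax])
  T_max <- max(temps)
  warn <- character()
  if (min(imax) == 1L || max(imax) == length(temps))
    warn <- c(warn, "peak lies on the profile boundary")
  a_all <- abs(profile$offsets - peak_x)
  usable <- which(a_all > 0 & temps > T_env & temps < T_max)
  if (is.null(offsets)) {
    # spread the default readings over the usable flank, nearest-first
    ord <- usable[order(a_all[usable])]
    pick <- ord[unique(round(seq(1, length(ord), length.out = min(n_default, length(ord)))))]
  } else {
    pick <- vapply(offsets, function(a) {
      cand <- usable[which.min(abs(a_all[usable] - a))]
      if (length(cand) == 0L) NA_integer_ else cand
    }, integer(1))
    pick <- unique(pick[!is.na(pick)])
  }
  if (length(pick) == 0L)
    stop("no usable off-peak readings between ambient and the peak")
  obs <- lapply(pick, function(i)
    observation_pair(T_max = T_max, T_a = temps[i], a = a_all[i], T_env = T_env))
  list(obs = obs, warnings = warn, peak = c(x = peak_x), T_max = T_max)
}

# As above for a 2D grid: peak = centroid of the argmax pixel set; readings
# are taken along the grid row through the peak, at their exact radial
# distances from the centroid.
obs_from_grid <- function(grid, offsets = NULL, n_default = 5L) {
  temps <- grid$temps
  T_env <- grid$T_env
  if (max(temps) <= T_env + sqrt(.Machine$double.eps) * max(1, abs(T_env)))
    stop("no source detected: thermogram shows no elevation above ambient")
  T_max <- max(temps)
  idx <- which(temps == T_max, arr.ind = TRUE)
  ctr_ij <- colMeans(idx)  # centroid of the maximal region, pixel units
  warn <- character()
  if (any(idx[, 1] %in% c(1L, nrow(temps))) || any(idx[, 2] %in% c(1L, ncol(temps))))
    warn <- c(warn, "peak lies on the thermogram boundary")
  row_i <- as.integer(round(ctr_ij[1]))
  cols <- seq_len(ncol(temps))
  a_all <- abs(cols - ctr_ij[2]) * grid$pixel_pitch
  trow <- temps[row_i, ]
  usable <- which(a_all > 0 & trow > T_env & trow < T_max)
  if (is.null(offsets)) {
    ord <- usable[order(a_all[usable])]
    pick <- ord[unique(round(seq(1, length(ord), length.out = min(n_default, length(ord)))))]
  } else {
    pick <- unique(vapply(offsets, function(a)
      usable[which.min(abs(a_all[usable] - a))], integer(1)))
  }
  if (length(pick) == 0L)
    stop("no usable off-peak readings between ambient and the peak")
  obs <- lapply(pick, function(j)
    observation_pair(T_max = T_max, T_a = trow[j], a = a_all[j], T_env = T_env))
  ctr_phys <- grid$origin + (ctr_ij - 1) * grid$pixel_pitch
  list(obs = obs, warnings = warn, peak = ctr_phys, T_max = T_max)
}

#' Localize a heat source from a thermogram
#'
#' Full analytic inversion workflow: locate the surface hotspot, form
#' peak/local observation pairs at one or more lateral offsets, estimate the
#' effective depth and intensity by the closed-form relations (median across
#' offsets), estimate the radius either intensity-free (\code{"eq_radius_temps"},
#' the default, via \code{\link{radius_depth_relation}}) or through the
#' intensity (\code{"eq_radius_intensity"}), and decompose the depth as
#' \eqn{d = \max(d_{\mathrm{eff}} - R, 0)}.
#'
#' @param x a \code{\link{temperature_profile}} or \code{\link{thermogram_grid}}.
#' @param tissue a \code{\link{tissue_params}} (supplies h0 and q_m).
#' @param offsets optional lateral offsets (m) at which to take the local
#'   readings; by default up to five measured points spread over the flank of
#'   the hotspot are used, at their exact measured distances.
#' @param radius_method \code{"eq_radius_temps"} (intensity-free relation) or
#'   \code{"eq_radius_intensity"} (cube-root of intensity).
#' @param A_t volume constant of \code{\link{radius_from_intensity}}.
#' @return an \code{inversion_result} with elements \code{d_eff}, \code{Q},
#'   \code{R}, \code{d}, the observation pairs used, method flags and any
#'   warnings (e.g. a boundary peak).
#' @examples
#' tp <- tissue_params()
#' src <- heat_source(Q = 0.1, d = 0.014, R = 0)
#' prof <- surface_profile(src, tp, seq(-0.05, 0.05, by = 0.0025))
#' localize_from_thermogram(prof, tp)
#' @export
localize_from_thermogram <- function(x, tissue, offsets = NULL,
                                     radius_method = c("eq_radius_temps",
                                                       "eq_radius_intensity"),
                                     A_t = 1e-6) {
  stopifnot(inherits(tissue, "tissue_params"))
  radius_method <- match.arg(radius_method)
  picked <- if (inherits(x, "temperature_profile")) {
    obs_from_profile(x, offsets)
  } else if (inherits(x, "thermogram_grid")) {
    obs_from_grid(x, offsets)
  } else stop("x must be a temperature_profile or a thermogram_grid")

  d_hat <- vapply(picked$obs, depth_from_temps, numeric(1))
  q_hat <- vapply(picked$obs, intensity_from_temps, numeric(1), h0 = tissue$h0)
  d_eff <- stats::median(d_hat)
  Q <- stats::median(q_hat)
  R <- if (radius_method == "eq_radius_temps") {
    stats::median(vapply(picked$obs, function(o)
      radius_depth_relation(o$T_a, o$T_env, o$a, d_eff, tissue$h0, tissue$q_m),
      numeric(1)))
  } else {
    radius_from_intensity(Q, tissue$q_m, A_t)
  }
  new_inversion_result(
    d_eff = d_eff, Q = Q, R = R, d = max(d_eff - R, 0),
    observations = picked$obs,
    method_flags = list(radius_method = radius_method, A_t = A_t,
                        peak = picked$peak, n_offsets = length(picked$obs)),
    warnings = picked$warnings)
}
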