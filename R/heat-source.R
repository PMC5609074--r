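#' Embedded heat source
#'
#' The unknown triple describing the equivalent spherical heat source: total
#' emitted power Q, depth d of the source top below the skin surface, and
#' source radius R. A sphere of radius R at depth d is equivalent, seen from
#' the surface, to a point source at the effective depth d + R.
#'
#' @param Q heat intensity, W (non-negative).
#' @param d depth of the source top below the surface, m.
#' @param R source radius, m (0 for a point source).
#' @return an object of class \code{heat_source}.
#' @examples
#' heat_source(Q = 0.045, d = 0.0105, R = 0.005)
#' @export
heat_source <- function(Q, d, R = 0) {
  if (!is.numeric(Q) || length(Q) != 1L || !is.finite(Q) || Q < 0)
    stop("Q must be a single non-negative number (W)")
  if (!is.numeric(d) || length(d) != 1L || !is.finite(d) || d < 0)
    stop("d must be a single non-negative number (m)")
  if (!is.numeric(R) || length(R) != 1L || !is.finite(R) || R < 0)
    stop("R must be a single non-negative number (m)")
  if (d + R <= 0)
    stop("effective depth d + R must be positive (a source at the surface is singular)")
  structure(list(Q = Q, d = d, R = R), class = "heat_source")
}

#' Effective depth of a heat source
#'
#' Distance from the skin surface to the equivalent point source, d + R.
#' This is the quantity the depth inversion recovers.
#'
#' @param source a \code{heat_source}.
#' @return effective depth, m.
#' @export
effective_depth <- function(source) {
  stopifnot(inherits(source, "heat_source"))
  source$d + source$R
}

#' @export
print.heat_source <- function(x, ...) {
  cat(sprintf("Heat source: Q = %g W, d = %g m, R = %g m (effective depth %g m)\n",
              x$Q, x$d, x$R, x$d + x$R))
  invisible(x)
}
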