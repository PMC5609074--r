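#' Write and read thermograms and profiles as annotated CSV
#'
#' The on-disk dialect is a plain numeric CSV matrix preceded by metadata
#' header lines of the form \code{# key = value}. Grids carry the mandatory
#' keys \code{T_env_C}, \code{pixel_pitch_m}, \code{origin_m} and
#' \code{provenance} (JSON); 1D profiles carry \code{T_env_C} and
#' \code{offsets_m} with a single temperature row. All physical lengths are
#' meters, temperatures degC, pixel (1,1) at the top-left with physical
#' coordinates \code{origin + (index - 1) * pixel_pitch}.
#'
#' @param grid a \code{\link{thermogram_grid}}.
#' @param path file path.
#' @param digits number of decimal places written (default 10, which
#'   round-trips to well below 1e-9 degC; use 4 for printed-precision export).
#' @return \code{write_thermogram} returns \code{path} invisibly;
#'   \code{read_thermogram} returns a \code{thermogram_grid} or, for a
#'   profile-dialect file, a \code{\link{temperature_profile}}.
#' @export
write_thermogram <- function(grid, path, digits = 10) {
  stopifnot(inherits(grid, "thermogram_grid"))
  prov <- if (is.character(grid$provenance)) grid$provenance else
    as.character(jsonlite::toJSON(grid$provenance, auto_unbox = TRUE, digits = NA))
  hdr <- c(
    sprintf("# T_env_C = %.*f", digits, grid$T_env),
    sprintf("# pixel_pitch_m = %s", format(grid$pixel_pitch, digits = 15)),
    sprintf("# origin_m = %s", paste(format(grid$origin, digits = 15), collapse = ",")),
    sprintf("# provenance = %s", prov))
  rows <- apply(grid$temps, 1, function(r)
    paste(sprintf("%.*f", digits, r), collapse = ","))
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' @rdname write_thermogram
#' @param profile a \code{\link{temperature_profile}}.
#' @export
write_temperature_profile <- function(profile, path, digits = 10) {
  stopifnot(inherits(profile, "temperature_profile"))
  hdr <- c(
    sprintf("# T_env_C = %.*f", digits, profile$T_env),
    sprintf("# offsets_m = %s",
            paste(format(profile$offsets, digits = 15), collapse = ",")))
  writeLines(c(hdr, paste(sprintf("%.*f", digits, profile$temps), collapse = ",")),
             path)
  invisible(path)
}

parse_header <- function(lines) {
  hdr_lines <- grep("^#", lines, value = TRUE)
  kv <- list()
  for (h in hdr_lines) {
    m <- regmatches(h, regexec("^#\\s*([A-Za-z_]+)\\s*=\\s*(.*)$", h))[[1]]
    if (length(m) == 3L) kv[[m[2]]] <- trimws(m[3])
  }
  kv
}

parse_matrix <- function(lines, path) {
  body <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  if (length(body) == 0L) stop("no numeric data found in ", path)
  rows <- lapply(strsplit(body, ","), function(x) suppressWarnings(as.numeric(trimws(x))))
  lens <- lengths(rows)
  if (length(unique(lens)) != 1L)
    stop("ragged rows in ", path, ": row ", which(lens != lens[1])[1],
         " has ", lens[which(lens != lens[1])[1]], " values, expected ", lens[1])
  bad <- which(vapply(rows, function(r) any(is.na(r)), logical(1)))
  if (length(bad)) stop("non-numeric value in ", path, " at row ", bad[1])
  do.call(rbind, rows)
}

#' @rdname write_thermogram
#' @export
read_thermogram <- function(path) {
  lines <- readLines(path)
  kv <- parse_header(lines)
  if (is.null(kv$T_env_C))
    stop("missing mandatory header key 'T_env_C' in ", path)
  if (!is.null(kv$offsets_m)) {         # 1D profile dialect
    offsets <- as.numeric(strsplit(kv$offsets_m, ",")[[1]])
    m <- parse_matrix(lines, path)
    if (nrow(m) != 1L)
      stop("profile-dialect file must contain a single temperature row: ", path)
    return(temperature_profile(offsets, as.numeric(m[1, ]),
                               T_env = as.numeric(kv$T_env_C)))
  }
  for (key in c("pixel_pitch_m", "origin_m", "provenance"))
    if (is.null(kv[[key]]))
      stop("missing mandatory header key '", key, "' in ", path)
  prov <- if (identical(kv$provenance, "measured")) "measured" else {
    p <- jsonlite::fromJSON(kv$provenance)
    p$shape <- as.integer(p$shape)
    p
  }
  thermogram_grid(parse_matrix(lines, path),
                  pixel_pitch = as.numeric(kv$pixel_pitch_m),
                  T_env = as.numeric(kv$T_env_C),
                  origin = as.numeric(strsplit(kv$origin_m, ",")[[1]]),
                  provenance = prov)
}
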