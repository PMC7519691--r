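# Smoothing and first derivatives.
#
# Derivatives require a uniform grid: finite differences only have a clean
# per-nm meaning at constant spacing, so non-uniform spectra must be
# resampled explicitly by the caller first.

grid_spacing <- function(w, tol = 1e-9) {
  d <- diff(w)
  if (max(d) - min(d) > tol) {
    stop("non-uniform wavelength grid (spacing varies by more than ", tol,
         " nm); resample() onto a uniform grid first")
  }
  mean(d)
}

#' Savitzky-Golay smoothing of a spectrum
#'
#' Local least-squares polynomial smoothing on a uniform grid. Endpoints are
#' handled by the asymmetric polynomial fits of the Savitzky-Golay projection
#' matrix, so polynomials up to `polyorder` (in particular constants and
#' straight lines) are reproduced exactly over the whole support.
#'
#' Smoothing is optional everywhere in this package and off by default: the
#' exact arithmetic identities of the derivative features hold on unsmoothed
#' spectra.
#'
#' @param spec A `"spectrum"` on a uniform grid.
#' @param window Odd window length, `3 <= window <= length(grid)`.
#' @param polyorder Polynomial order, `< window`.
#' @return The smoothed `"spectrum"`.
#' @export
smooth_spectrum <- function(spec, window = 11L, polyorder = 2L) {
  stopifnot(inherits(spec, "spectrum"))
  window <- as.integer(window)
  polyorder <- as.integer(polyorder)
  if (window %% 2L == 0L) stop("window must be odd")
  if (window < 3L || window > length(spec$wavelengths_nm)) {
    stop("window must be between 3 and the number of grid points")
  }
  if (polyorder >= window) stop("polyorder must be smaller than window")
  if (polyorder < 0L) stop("polyorder must be non-negative")
  grid_spacing(spec$wavelengths_nm)
  sm <- signal::sgolayfilt(spec$reflectance, p = polyorder, n = window)
  withCallingHandlers(
    new_spectrum(spec$sample_id, spec$wavelengths_nm, pmax(sm, 0)),
    warning = function(w) invokeRestart("muffleWarning")
  )
}

#' First-derivative spectrum by finite differences
#'
#' On a uniform grid with spacing `dl`:
#' * `forward`: `D(l_i) = (R(l_{i+1}) - R(l_i)) / dl`, attributed to the left
#'   node `l_i` (last node dropped). This is the default; it makes the
#'   red-edge index telescoping identity `sum(D * dl) = R(750) - R(680)`
#'   exact.
#' * `central`: `D(l_i) = (R(l_{i+1}) - R(l_{i-1})) / (2 dl)` on interior
#'   nodes (both ends dropped), offered for sensitivity checks.
#'
#' @param spec A `"spectrum"` on a uniform grid with at least 3 points.
#' @param method `"forward"` (default) or `"central"`.
#' @return An object of class `"deriv_spectrum"` with fields `sample_id`,
#'   `wavelengths_nm`, `d_reflectance` (per nm), `method`, `delta_nm`.
#' @export
first_derivative <- function(spec, method = c("forward", "central")) {
  stopifnot(inherits(spec, "spectrum"))
  method <- match.arg(method)
  w <- spec$wavelengths_nm
  r <- spec$reflectance
  if (length(w) < 3L) stop("need at least 3 points for a derivative spectrum")
  dl <- grid_spacing(w)
  if (method == "forward") {
    d <- diff(r) / dl
    wl <- w[-length(w)]
  } else {
    n <- length(r)
    d <- (r[3L:n] - r[1L:(n - 2L)]) / (2 * dl)
    wl <- w[2L:(n - 1L)]
  }
  structure(
    list(sample_id = spec$sample_id, wavelengths_nm = wl,
         d_reflectance = d, method = method, delta_nm = dl),
    class = "deriv_spectrum"
  )
}

#' @export
print.deriv_spectrum <- function(x, ...) {
  cat(sprintf("<deriv_spectrum> %s (%s): %d nodes, %.6g-%.6g nm\n",
              x$sample_id, x$method, length(x$wavelengths_nm),
              min(x$wavelengths_nm), max(x$wavelengths_nm)))
  invisible(x)
}

#' First derivatives for every sample of a collection
#'
#' @param collection A `"spectrum_collection"` on a uniform grid.
#' @param method Passed to [first_derivative()].
#' @return An object of class `"deriv_collection"` with the derivative grid,
#'   a wavelength x sample matrix `d_reflectance`, `sample_ids`, `method`
#'   and `delta_nm`.
#' @export
first_derivative_collection <- function(collection,
                                        method = c("forward", "central")) {
  stopifnot(inherits(collection, "spectrum_collection"))
  method <- match.arg(method)
  w <- collection$grid_nm
  if (length(w) < 3L) stop("need at least 3 points for a derivative spectrum")
  dl <- grid_spacing(w)
  mat <- collection$reflectance
  if (method == "forward") {
    d <- (mat[-1L, , drop = FALSE] - mat[-nrow(mat), , drop = FALSE]) / dl
    wl <- w[-length(w)]
  } else {
    n <- nrow(mat)
    d <- (mat[3L:n, , drop = FALSE] - mat[1L:(n - 2L), , drop = FALSE]) / (2 * dl)
    wl <- w[2L:(n - 1L)]
  }
  structure(
    list(grid_nm = wl, d_reflectance = d,
         sample_ids = collection$sample_ids, method = method, delta_nm = dl),
    class = "deriv_collection"
  )
}

#' Extract one sample's derivative spectrum from a derivative collection
#' @param deriv_collection A `"deriv_collection"`.
#' @param sample_id Sample identifier.
#' @return A `"deriv_spectrum"`.
#' @export
get_derivative <- function(deriv_collection, sample_id) {
  j <- match(sample_id, deriv_collection$sample_ids)
  if (is.na(j)) stop("unknown sample id: ", sample_id)
  structure(
    list(sample_id = sample_id,
         wavelengths_nm = deriv_collection$grid_nm,
         d_reflectance = deriv_collection$d_reflectance[, j],
         method = deriv_collection$method,
         delta_nm = deriv_collection$delta_nm),
    class = "deriv_spectrum"
  )
}

#' Write derivative spectra in the wide CSV dialect
#' @param deriv_collection A `"deriv_collection"`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_derivatives <- function(deriv_collection, path) {
  stopifnot(inherits(deriv_collection, "deriv_collection"))
  header <- paste(c("wavelength_nm", deriv_collection$sample_ids),
                  collapse = ",")
  body <- apply(
    cbind(deriv_collection$grid_nm, deriv_collection$d_reflectance), 1L,
    function(row) paste(fmt_full(row), collapse = ",")
  )
  writeLines(c(header, body), path)
  invisible(path)
}
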