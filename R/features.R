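# Vegetation indices and trilateral (red/blue/yellow edge) parameters.
#
# Index definitions (R_x = reflectance at x nm):
#   LWI = R970 / R900                 leaf water content index
#   REI = sum of first-derivative reflectance over the red edge 680-750 nm
#   NDI = (R750 - R705) / (R750 + R705 + 2 R445)
#   SRI = R706 / R809                 simple ratio index
#   PRI = (R570 - R531) / (R570 + R531)
#
# Edge windows: red 680-750 nm, blue 490-530 nm, yellow 560-640 nm. Edge
# position = wavelength of the window extremum of the first derivative, edge
# slope = the extremum value. The yellow-edge derivative of green vegetation
# is negative, so its classical feature is the window minimum (configurable).

EDGE_WINDOWS <- list(red = c(680, 750), blue = c(490, 530),
                     yellow = c(560, 640))

#' Reflectance at a single wavelength
#'
#' Exact at grid nodes; linear interpolation between bracketing nodes
#' otherwise. Errors outside the spectrum's range.
#'
#' @param spec A `"spectrum"`.
#' @param wavelength_nm Wavelength to look up (nm).
#' @return Reflectance value.
#' @export
band <- function(spec, wavelength_nm) {
  stopifnot(inherits(spec, "spectrum"), length(wavelength_nm) >= 1L)
  w <- spec$wavelengths_nm
  if (any(wavelength_nm < w[1L]) || any(wavelength_nm > w[length(w)])) {
    stop("wavelength outside the spectrum range")
  }
  stats::approx(w, spec$reflectance, xout = wavelength_nm,
                method = "linear", ties = "ordered")$y
}

# division that yields NA (undefined marker) instead of Inf/NaN
safe_div <- function(num, den) if (!is.finite(den) || den == 0) NA_real_ else num / den

#' The five vegetation indices of the dust-retention model set
#'
#' The red edge index (REI) depends on the derivative method:
#' * forward path: left-closed right-open node sum
#'   `sum(D(l) * dl)` over `l in [680, 750)`, which telescopes exactly to
#'   `R(750) - R(680)` on a grid containing both endpoints;
#' * central path: the plain node sum of `D` over `[680, 750]`.
#'
#' Zero denominators yield `NA` for the affected index only.
#'
#' @param spec A `"spectrum"` covering at least 445-970 nm.
#' @param deriv Matching `"deriv_spectrum"` covering the red edge.
#' @return List of class `"vegetation_indices"` with elements `lwi`, `rei`,
#'   `ndi`, `sri`, `pri`.
#' @export
vegetation_indices <- function(spec, deriv) {
  stopifnot(inherits(spec, "spectrum"), inherits(deriv, "deriv_spectrum"))
  if (!identical(spec$sample_id, deriv$sample_id)) {
    stop("spectrum and derivative belong to different samples")
  }
  w <- spec$wavelengths_nm
  if (w[1L] > 445 || w[length(w)] < 970) {
    stop("spectrum must cover 445-970 nm for the full index set")
  }
  R <- function(x) band(spec, x)
  lwi <- safe_div(R(970), R(900))
  ndi <- safe_div(R(750) - R(705), R(750) + R(705) + 2 * R(445))
  sri <- safe_div(R(706), R(809))
  pri <- safe_div(R(570) - R(531), R(570) + R(531))

  dw <- deriv$wavelengths_nm
  if (deriv$method == "forward") {
    # forward nodes represent [l, l + dl); need nodes spanning [680, 750)
    if (dw[1L] > 680 || (dw[length(dw)] + deriv$delta_nm) < 750) {
      stop("derivative does not cover the red edge 680-750 nm")
    }
    sel <- dw >= 680 & dw < 750
    rei <- sum(deriv$d_reflectance[sel]) * deriv$delta_nm
  } else {
    if (dw[1L] > 680 || dw[length(dw)] < 750) {
      stop("derivative does not cover the red edge 680-750 nm")
    }
    sel <- dw >= 680 & dw <= 750
    rei <- sum(deriv$d_reflectance[sel])
  }
  structure(list(lwi = lwi, rei = rei, ndi = ndi, sri = sri, pri = pri),
            class = "vegetation_indices")
}

#' Trilateral (edge) parameters from a derivative spectrum
#'
#' Positions are grid-node arg-extrema (no sub-nm fitting), ties broken toward
#' the shortest wavelength. Red and blue edges take the window maximum; the
#' yellow edge takes the window minimum by default (`yellow_edge_mode`),
#' since the first derivative of green vegetation is negative there.
#'
#' @param deriv A `"deriv_spectrum"` whose grid covers 490-750 nm.
#' @param yellow_edge_mode `"min"` (default) or `"max"`.
#' @return List of class `"trilateral_parameters"` with `rep`, `res`, `bep`,
#'   `bes`, `yep`, `yes` (positions in nm, slopes per nm).
#' @export
trilateral <- function(deriv, yellow_edge_mode = c("min", "max")) {
  stopifnot(inherits(deriv, "deriv_spectrum"))
  yellow_edge_mode <- match.arg(yellow_edge_mode)
  w <- deriv$wavelengths_nm
  d <- deriv$d_reflectance
  pick <- function(window, maximum) {
    if (w[1L] > window[1L] || w[length(w)] < window[2L]) {
      stop(sprintf("derivative grid does not cover the %g-%g nm window",
                   window[1L], window[2L]))
    }
    idx <- which(w >= window[1L] & w <= window[2L])
    i <- idx[if (maximum) which.max(d[idx]) else which.min(d[idx])]
    c(position = w[i], slope = d[i])
  }
  red <- pick(EDGE_WINDOWS$red, TRUE)
  blue <- pick(EDGE_WINDOWS$blue, TRUE)
  yellow <- pick(EDGE_WINDOWS$yellow, yellow_edge_mode == "max")
  structure(
    list(rep = red[["position"]], res = red[["slope"]],
         bep = blue[["position"]], bes = blue[["slope"]],
         yep = yellow[["position"]], yes = yellow[["slope"]]),
    class = "trilateral_parameters"
  )
}

#' Per-sample feature table for a spectral library
#'
#' Computes all eleven features (five indices, six edge parameters) for every
#' sample. Per-sample failures (e.g. a truncated spectrum) do not abort the
#' batch: whole-sample failures are recorded in the `error` column, and a
#' feature whose own bands are unavailable is simply `NA`.
#'
#' @param collection A `"spectrum_collection"` on a uniform grid.
#' @param window,polyorder Optional Savitzky-Golay smoothing before
#'   differentiation; `window = NULL` (default) disables smoothing.
#' @param deriv_method Passed to [first_derivative()].
#' @param yellow_edge_mode Passed to [trilateral()].
#' @return Data frame: `sample_id`, `LWI`, `REI`, `NDI`, `SRI`, `PRI`, `REP`,
#'   `RES`, `BEP`, `BES`, `YEP`, `YES`, `error` (NA when clean).
#' @export
feature_table <- function(collection, window = NULL, polyorder = 2L,
                          deriv_method = c("forward", "central"),
                          yellow_edge_mode = c("min", "max")) {
  stopifnot(inherits(collection, "spectrum_collection"))
  deriv_method <- match.arg(deriv_method)
  yellow_edge_mode <- match.arg(yellow_edge_mode)
  ids <- collection$sample_ids
  rows <- lapply(ids, function(id) {
    vals <- stats::setNames(rep(NA_real_, length(FEATURE_NAMES)),
                            FEATURE_NAMES)
    err <- NA_character_
    tryCatch({
      spec <- get_spectrum(collection, id)
      if (!is.null(window)) {
        spec <- smooth_spectrum(spec, window = window, polyorder = polyorder)
      }
      deriv <- first_derivative(spec, method = deriv_method)
      vi <- tryCatch(vegetation_indices(spec, deriv), error = function(e) NULL)
      if (is.null(vi)) {
        # partial coverage: recover the indices whose bands are present
        vals[["LWI"]] <- try_index(function() safe_div(band(spec, 970), band(spec, 900)))
        vals[["NDI"]] <- try_index(function() {
          safe_div(band(spec, 750) - band(spec, 705),
                   band(spec, 750) + band(spec, 705) + 2 * band(spec, 445))
        })
        vals[["SRI"]] <- try_index(function() safe_div(band(spec, 706), band(spec, 809)))
        vals[["PRI"]] <- try_index(function() {
          safe_div(band(spec, 570) - band(spec, 531),
                   band(spec, 570) + band(spec, 531))
        })
        vals[["REI"]] <- try_index(function() red_edge_sum(deriv))
      } else {
        vals[["LWI"]] <- vi$lwi; vals[["REI"]] <- vi$rei
        vals[["NDI"]] <- vi$ndi; vals[["SRI"]] <- vi$sri
        vals[["PRI"]] <- vi$pri
      }
      tri <- tryCatch(trilateral(deriv, yellow_edge_mode = yellow_edge_mode),
                      error = function(e) NULL)
      if (!is.null(tri)) {
        vals[["REP"]] <- tri$rep; vals[["RES"]] <- tri$res
        vals[["BEP"]] <- tri$bep; vals[["BES"]] <- tri$bes
        vals[["YEP"]] <- tri$yep; vals[["YES"]] <- tri$yes
      }
    }, error = function(e) err <<- conditionMessage(e))
    c(list(sample_id = id), as.list(vals), list(error = err))
  })
  out <- do.call(rbind, lapply(rows, function(r) {
    as.data.frame(r, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

try_index <- function(f) tryCatch(f(), error = function(e) NA_real_)

red_edge_sum <- function(deriv) {
  dw <- deriv$wavelengths_nm
  if (deriv$method == "forward") {
    if (dw[1L] > 680 || (dw[length(dw)] + deriv$delta_nm) < 750) {
      stop("derivative does not cover the red edge")
    }
    sum(deriv$d_reflectance[dw >= 680 & dw < 750]) * deriv$delta_nm
  } else {
    if (dw[1L] > 680 || dw[length(dw)] < 750) {
      stop("derivative does not cover the red edge")
    }
    sum(deriv$d_reflectance[dw >= 680 & dw <= 750])
  }
}
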