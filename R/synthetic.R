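# Seeded simulator of dusted-leaf reflectance spectra.
#
# The leaf endmember is a closed-form curve: a visible baseline with a green
# reflectance peak (557 nm) and a chlorophyll absorption well (~675 nm),
# joined to the NIR plateau by a logistic red-edge rise, minus Gaussian
# water/SWIR absorption wells and a smooth dry-matter depression shaping the
# 1660 / 2215 nm SWIR maxima. Dust deposition follows exponential-saturation
# coverage f = 1 - exp(-k * load) with linear area mixing
# R_mix = (1 - f) R_leaf + f R_dust.

gauss_bump <- function(l, center, sd) exp(-0.5 * ((l - center) / sd)^2)

# cubic smoothstep: 0 at x0, 1 at x1, zero slope at both ends
smoothstep <- function(l, x0, x1) {
  t <- pmin(pmax((l - x0) / (x1 - x0), 0), 1)
  t * t * (3 - 2 * t)
}

#' Leaf optical model parameters
#'
#' Defaults are tuned so the clean-leaf curve shows its six local reflectance
#' maxima within +/- 10 nm of 557, 780, 1000, 1282, 1660 and 2215 nm and
#' stays inside (0, 1) on 350-2500 nm.
#'
#' @param visible_base Visible baseline reflectance.
#' @param green_peak_amp Amplitude of the 557 nm green peak.
#' @param chlorophyll_depth Depth of the ~675 nm chlorophyll well.
#' @param nir_plateau NIR plateau reflectance.
#' @param red_edge_center_nm,red_edge_width_nm Logistic red-edge rise.
#' @param water_band_depths Named vector of absorption depths for the 970,
#'   1200, 1450 and 1940 nm water bands.
#' @param swir_peak_levels Named vector: target reflectance of the 1660 and
#'   2215 nm SWIR maxima (implemented as a smooth dry-matter depression of
#'   the plateau; set both to `nir_plateau` for no depression).
#' @return List of class `"leaf_model_params"`.
#' @export
leaf_model_params <- function(visible_base = 0.08,
                              green_peak_amp = 0.05,
                              chlorophyll_depth = 0.035,
                              nir_plateau = 0.48,
                              red_edge_center_nm = 715,
                              red_edge_width_nm = 12,
                              water_band_depths = c("970" = 0.04,
                                                    "1200" = 0.08,
                                                    "1450" = 0.16,
                                                    "1940" = 0.16),
                              swir_peak_levels = c("1660" = 0.30,
                                                   "2215" = 0.22)) {
  stopifnot(all(c("970", "1200", "1450", "1940") %in% names(water_band_depths)),
            all(c("1660", "2215") %in% names(swir_peak_levels)),
            all(water_band_depths >= 0), visible_base > 0, nir_plateau > 0,
            green_peak_amp >= 0, chlorophyll_depth >= 0,
            red_edge_width_nm > 0)
  structure(
    list(visible_base = visible_base, green_peak_amp = green_peak_amp,
         chlorophyll_depth = chlorophyll_depth, nir_plateau = nir_plateau,
         red_edge_center_nm = red_edge_center_nm,
         red_edge_width_nm = red_edge_width_nm,
         water_band_depths = water_band_depths,
         swir_peak_levels = swir_peak_levels),
    class = "leaf_model_params"
  )
}

#' Evaluate the leaf optical model on a wavelength grid
#'
#' With `cv = 0` the curve is deterministic. With `cv > 0`, lognormal
#' multipliers (unit mean, coefficient of variation `cv`) drawn from the
#' current RNG stream are applied to the green peak, chlorophyll depth, the
#' common water-depth scale and the plateau contrast, emulating leaf-to-leaf
#' variability.
#'
#' @param params A `"leaf_model_params"`.
#' @param grid_nm Wavelength grid (default the canonical 1 nm grid).
#' @param cv Leaf-to-leaf coefficient of variation of the amplitudes.
#' @param sample_id Sample id for the returned spectrum.
#' @return A `"spectrum"`; attribute `multipliers` records the drawn
#'   lognormal factors.
#' @export
leaf_spectrum <- function(params = leaf_model_params(), grid_nm = 350:2500,
                          cv = 0, sample_id = "leaf") {
  stopifnot(inherits(params, "leaf_model_params"), cv >= 0)
  m <- c(green = 1, chl = 1, water = 1, plateau = 1)
  if (cv > 0) {
    sdlog <- sqrt(log(1 + cv^2))
    m[] <- stats::rlnorm(4L, meanlog = -sdlog^2 / 2, sdlog = sdlog)
  }
  l <- as.numeric(grid_nm)
  vis <- params$visible_base
  nir <- vis + (params$nir_plateau - vis) * m[["plateau"]]
  wd <- params$water_band_depths * m[["water"]]
  lv <- params$swir_peak_levels

  R <- vis + (nir - vis) *
    stats::plogis((l - params$red_edge_center_nm) / params$red_edge_width_nm)
  R <- R + params$green_peak_amp * m[["green"]] * gauss_bump(l, 557, 25)
  R <- R - params$chlorophyll_depth * m[["chl"]] * gauss_bump(l, 672, 30)
  # 970 nm water band: narrow core plus the broad short-NIR wing that ends
  # the plateau rise just before 780 nm
  R <- R - wd[["970"]] * (0.7 * gauss_bump(l, 968, 18) +
                            1.6 * gauss_bump(l, 995, 95))
  R <- R - 0.5 * wd[["970"]] * gauss_bump(l, 1015, 14)
  R <- R - wd[["1200"]] * gauss_bump(l, 1185, 40)
  R <- R - wd[["1450"]] * gauss_bump(l, 1440, 60)
  R <- R - wd[["1940"]] * gauss_bump(l, 1930, 70)
  # dry-matter depression: smooth plateau-to-plateau steps whose ramps sit
  # inside the water wells, flat (zero slope) at the SWIR peak wavelengths so
  # the 1660 / 2215 nm maxima are set by the well tails alone
  d1 <- (nir - lv[["1660"]] * m[["plateau"]])
  d2 <- (nir - lv[["2215"]] * m[["plateau"]])
  d3 <- d2 * 1.25
  R <- R - d1 * smoothstep(l, 1340, 1550) -
    (d2 - d1) * smoothstep(l, 1700, 2100) -
    (d3 - d2) * smoothstep(l, 2210, 2500)

  if (any(R < -0.02) || any(R > 1.02)) {
    stop("leaf model parameters drive reflectance outside (0, 1) by more ",
         "than the 0.02 tolerance; not silently clipping")
  }
  R <- pmin(pmax(R, 0.001), 0.999)
  out <- new_spectrum(sample_id, l, R)
  attr(out, "multipliers") <- m
  out
}

#' Dust endmember optical parameters
#'
#' Defaults per dust type. The NIR brightness ordering is
#' coal < cement < soil, so the reflectance *drop* caused by deposition is
#' coal > cement > soil there; cement and soil carry a broad blue-green
#' absorption feature (mineral / iron-oxide coloration) giving them the
#' rising visible slope typical of mineral dusts.
#'
#' @param dust_type `"coal"`, `"cement"` or `"soil"`.
#' @param level Mean reflectance (anchored at 1000 nm).
#' @param tilt Linear slope per nm around 1000 nm.
#' @param feature_depths Optional list of absorption features, each a numeric
#'   vector `c(center, sd, depth)`.
#' @return List of class `"dust_optical_params"`.
#' @export
dust_optical_params <- function(dust_type = c("coal", "cement", "soil"),
                                level = NULL, tilt = NULL,
                                feature_depths = NULL) {
  dust_type <- match.arg(dust_type)
  defaults <- list(
    coal = list(level = 0.08, tilt = 8e-5, feature_depths = list()),
    cement = list(level = 0.25, tilt = 6e-5,
                  feature_depths = list(c(center = 480, sd = 70, depth = 0.10))),
    soil = list(level = 0.28, tilt = 6e-5,
                feature_depths = list(c(center = 500, sd = 80, depth = 0.16)))
  )
  d <- defaults[[dust_type]]
  structure(
    list(dust_type = dust_type,
         level = if (is.null(level)) d$level else level,
         tilt = if (is.null(tilt)) d$tilt else tilt,
         feature_depths = if (is.null(feature_depths)) d$feature_depths
                          else feature_depths),
    class = "dust_optical_params"
  )
}

#' Dust endmember spectrum
#'
#' `R(l) = level + tilt * (l - 1000) - sum(depth_i * gaussian_i(l))`, checked
#' to stay inside (0, 1) on the grid.
#'
#' @param params A `"dust_optical_params"`.
#' @param grid_nm Wavelength grid.
#' @return A `"spectrum"` named after the dust type.
#' @export
dust_endmember <- function(params, grid_nm = 350:2500) {
  stopifnot(inherits(params, "dust_optical_params"))
  l <- as.numeric(grid_nm)
  R <- params$level + params$tilt * (l - 1000)
  for (f in params$feature_depths) {
    R <- R - f[["depth"]] * gauss_bump(l, f[["center"]], f[["sd"]])
  }
  if (any(R <= 0) || any(R >= 1)) {
    stop("dust endmember reflectance outside (0, 1)")
  }
  new_spectrum(paste0("dust_", params$dust_type), l, R)
}

#' Mix a dust layer onto a leaf spectrum
#'
#' Coverage follows the exponential-saturation law `f = 1 - exp(-k * load)`
#' (identity at zero load, saturating at the dust endmember), and the mixed
#' spectrum is the areal convex combination
#' `R_mix = (1 - f) * R_leaf + f * R_dust`.
#'
#' @param leaf,dust `"spectrum"` objects on the same grid.
#' @param load_g_per_m2 Dust load (g m^-2, >= 0).
#' @param k Deposition rate (m^2 g^-1, > 0); default 1.
#' @return A `"spectrum"`; attribute `coverage_f` records `f`.
#' @export
deposit <- function(leaf, dust, load_g_per_m2, k = 1) {
  stopifnot(inherits(leaf, "spectrum"), inherits(dust, "spectrum"),
            load_g_per_m2 >= 0, k > 0)
  if (!identical(leaf$wavelengths_nm, dust$wavelengths_nm)) {
    stop("leaf and dust spectra are on different grids")
  }
  f <- 1 - exp(-k * load_g_per_m2)
  R <- (1 - f) * leaf$reflectance + f * dust$reflectance
  out <- withCallingHandlers(
    new_spectrum(leaf$sample_id, leaf$wavelengths_nm, R),
    warning = function(w) invokeRestart("muffleWarning")
  )
  attr(out, "coverage_f") <- f
  out
}

# the six-step load series of the laboratory deposition protocol (g m^-2)
DEFAULT_LOAD_SERIES <- list(
  coal = c(0.1139, 0.1596, 0.2366, 0.2674, 0.2863, 0.3453),
  cement = c(0.1047, 0.1420, 0.1836, 0.2294, 0.2693, 0.3477),
  soil = c(0.0372, 0.0977, 0.1371, 0.1798, 0.2208, 0.2624)
)

#' Configuration for a synthetic dusted-leaf dataset
#'
#' @param seed Integer RNG seed (mandatory).
#' @param n_leaves Number of leaves; dust types are assigned round-robin.
#' @param load_series_g_per_m2 Named list (`coal`, `cement`, `soil`) of load
#'   step series; defaults to the six-step laboratory series per type.
#' @param deposition_rate_k Coverage rate k (m^2 g^-1).
#' @param noise_sd Additive Gaussian noise sd (absolute reflectance),
#'   independent across wavelengths, applied after mixing.
#' @param leaf_variability_cv Leaf-to-leaf amplitude CV (see
#'   [leaf_spectrum()]).
#' @param load_jitter_cv Multiplicative lognormal jitter CV of the realized
#'   loads around the nominal series.
#' @param grid_nm Wavelength grid.
#' @param leaf_params,dust_params Optical models (defaults as documented).
#' @return List of class `"synthetic_config"`.
#' @export
synthetic_config <- function(seed,
                             n_leaves = 30L,
                             load_series_g_per_m2 = DEFAULT_LOAD_SERIES,
                             deposition_rate_k = 1.0,
                             noise_sd = 0.005,
                             leaf_variability_cv = 0.05,
                             load_jitter_cv = 0.03,
                             grid_nm = 350:2500,
                             leaf_params = leaf_model_params(),
                             dust_params = NULL) {
  if (missing(seed)) stop("seed is mandatory")
  if (n_leaves < 1L) stop("n_leaves must be at least 1")
  if (!length(load_series_g_per_m2) ||
      any(!vapply(load_series_g_per_m2, length, integer(1L)))) {
    stop("empty load series")
  }
  if (any(unlist(load_series_g_per_m2) < 0)) stop("loads must be >= 0")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (is.null(dust_params)) {
    dust_params <- lapply(names(load_series_g_per_m2), dust_optical_params)
    names(dust_params) <- names(load_series_g_per_m2)
  }
  structure(
    list(seed = as.integer(seed), n_leaves = as.integer(n_leaves),
         load_series_g_per_m2 = load_series_g_per_m2,
         deposition_rate_k = deposition_rate_k, noise_sd = noise_sd,
         leaf_variability_cv = leaf_variability_cv,
         load_jitter_cv = load_jitter_cv,
         grid_nm = grid_nm, leaf_params = leaf_params,
         dust_params = dust_params),
    class = "synthetic_config"
  )
}

#' Generate a synthetic dusted-leaf dataset
#'
#' Emulates the laboratory measurement design: per leaf, one clean spectrum
#' (load 0, typed by its later treatment) plus one spectrum per load step of
#' its assigned dust type. Realized loads are jittered around the nominal
#' series; additive Gaussian noise is applied after mixing and the result is
#' floored at a small positive reflectance. Fully reproducible from the seed.
#'
#' @param config A `"synthetic_config"`.
#' @return List with `collection` (a `"spectrum_collection"`), `dust`
#'   (dust table: `sample_id`, `dust_type`, `load_g_per_m2`) and `truth`
#'   (data frame `sample_id`, `leaf_id`, `dust_type`, `load_true`,
#'   `coverage_f` plus the per-leaf amplitude multipliers).
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  grid <- as.numeric(config$grid_nm)
  types <- names(config$load_series_g_per_m2)
  endmembers <- lapply(config$dust_params, dust_endmember, grid_nm = grid)

  specs <- list()
  dust_rows <- list()
  truth_rows <- list()
  for (i in seq_len(config$n_leaves)) {
    type <- types[((i - 1L) %% length(types)) + 1L]
    leaf_id <- sprintf("leaf%03d", i)
    leaf <- leaf_spectrum(config$leaf_params, grid_nm = grid,
                          cv = config$leaf_variability_cv,
                          sample_id = leaf_id)
    mult <- attr(leaf, "multipliers")
    series <- c(0, config$load_series_g_per_m2[[type]])
    for (s in seq_along(series)) {
      sid <- sprintf("%s_T%d", leaf_id, s - 1L)
      nominal <- series[s]
      load <- if (nominal > 0 && config$load_jitter_cv > 0) {
        sdlog <- sqrt(log(1 + config$load_jitter_cv^2))
        nominal * stats::rlnorm(1L, meanlog = -sdlog^2 / 2, sdlog = sdlog)
      } else {
        nominal
      }
      mixed <- deposit(leaf, endmembers[[type]], load,
                       k = config$deposition_rate_k)
      f <- attr(mixed, "coverage_f")
      R <- mixed$reflectance
      if (config$noise_sd > 0) {
        R <- R + stats::rnorm(length(R), sd = config$noise_sd)
        R <- pmax(R, 1e-4)  # measurement floor
      }
      specs[[sid]] <- withCallingHandlers(
        new_spectrum(sid, grid, R),
        warning = function(w) invokeRestart("muffleWarning")
      )
      dust_rows[[sid]] <- data.frame(
        sample_id = sid, dust_type = type, load_g_per_m2 = load,
        stringsAsFactors = FALSE)
      truth_rows[[sid]] <- data.frame(
        sample_id = sid, leaf_id = leaf_id, dust_type = type,
        load_true = load, coverage_f = f,
        mult_green = mult[["green"]], mult_chl = mult[["chl"]],
        mult_water = mult[["water"]], mult_plateau = mult[["plateau"]],
        stringsAsFactors = FALSE)
    }
  }
  dust <- do.call(rbind, dust_rows)
  truth <- do.call(rbind, truth_rows)
  rownames(dust) <- rownames(truth) <- NULL
  list(collection = collect_spectra(specs), dust = dust, truth = truth)
}

#' Write a generated dataset to disk
#'
#' Emits the wide-CSV spectra file, the dust table and the truth table in the
#' formats consumed by the analysis pipeline.
#'
#' @param dataset Result of [generate_dataset()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of the written paths, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    spectra = file.path(dir, "spectra.csv"),
    dust = file.path(dir, "dust.csv"),
    truth = file.path(dir, "truth.csv")
  )
  write_spectra(dataset$collection, paths[["spectra"]])
  write_dust_table(dataset$dust, paths[["dust"]])
  tr <- dataset$truth
  lines <- c(
    paste(names(tr), collapse = ","),
    do.call(paste, c(list(tr$sample_id, tr$leaf_id, tr$dust_type),
                     lapply(tr[vapply(tr, is.numeric, logical(1L))], fmt_full),
                     sep = ","))
  )
  writeLines(lines, paths[["truth"]])
  invisible(paths)
}
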