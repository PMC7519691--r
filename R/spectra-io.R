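# Spectrum containers and text I/O.
#
# A "spectrum" is one sample's reflectance on an ordered wavelength grid; a
# "spectrum_collection" holds many samples sharing one grid (stored as a
# wavelength x sample matrix). All file formats are plain text so spectral
# libraries survive version control and diffing.

DUST_TYPES <- c("coal", "cement", "soil", "none")

#' Construct a reflectance spectrum
#'
#' @param sample_id Single character string identifying the sample.
#' @param wavelengths_nm Strictly increasing numeric vector of wavelengths in
#'   nanometres, all within 300-2500 nm.
#' @param reflectance Numeric vector of reflectance fractions (same length).
#'   Negative values are an error; values above 1 are kept but flagged with a
#'   warning (attribute `over_unity`), since slightly super-unity readings do
#'   occur with imperfect white references.
#' @return An object of class `"spectrum"`.
#' @export
new_spectrum <- function(sample_id, wavelengths_nm, reflectance) {
  if (!is.character(sample_id) || length(sample_id) != 1L || is.na(sample_id)) {
    stop("sample_id must be a single character string")
  }
  w <- as.numeric(wavelengths_nm)
  r <- as.numeric(reflectance)
  if (length(w) != length(r)) {
    stop("wavelengths_nm and reflectance must have the same length")
  }
  if (length(w) < 2L) stop("a spectrum needs at least 2 points")
  if (any(!is.finite(w)) || any(!is.finite(r))) {
    stop("non-finite wavelength or reflectance value")
  }
  if (is.unsorted(w, strictly = TRUE)) {
    stop("wavelengths must be strictly increasing")
  }
  if (w[1L] < 300 || w[length(w)] > 2500) {
    stop("wavelengths outside the supported 300-2500 nm range")
  }
  if (any(r < 0)) stop("negative reflectance value")
  over <- any(r > 1)
  if (over) {
    warning("reflectance values above 1 for sample '", sample_id,
            "'; kept, but flagged (attribute over_unity)")
  }
  structure(
    list(sample_id = sample_id, wavelengths_nm = w, reflectance = r),
    over_unity = over,
    class = "spectrum"
  )
}

#' @export
print.spectrum <- function(x, ...) {
  cat(sprintf("<spectrum> %s: %d bands, %.6g-%.6g nm, R in [%.4g, %.4g]\n",
              x$sample_id, length(x$wavelengths_nm),
              min(x$wavelengths_nm), max(x$wavelengths_nm),
              min(x$reflectance), max(x$reflectance)))
  invisible(x)
}

#' Construct a spectrum collection from a matrix
#'
#' @param grid_nm Shared wavelength grid (strictly increasing).
#' @param reflectance Numeric matrix, `length(grid_nm)` rows, one column per
#'   sample.
#' @param sample_ids Unique character vector of column identifiers.
#' @return An object of class `"spectrum_collection"`.
#' @export
new_spectrum_collection <- function(grid_nm, reflectance, sample_ids) {
  grid_nm <- as.numeric(grid_nm)
  reflectance <- as.matrix(reflectance)
  sample_ids <- as.character(sample_ids)
  if (nrow(reflectance) != length(grid_nm)) {
    stop("reflectance must have one row per grid wavelength")
  }
  if (ncol(reflectance) != length(sample_ids)) {
    stop("reflectance must have one column per sample id")
  }
  if (anyDuplicated(sample_ids)) {
    stop("duplicate sample id: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  }
  # constructor-level validation via the single-spectrum path
  for (j in seq_along(sample_ids)) {
    withCallingHandlers(
      new_spectrum(sample_ids[j], grid_nm, reflectance[, j]),
      warning = function(w) invokeRestart("muffleWarning")
    )
  }
  over <- any(reflectance > 1)
  if (over) warning("collection contains reflectance values above 1")
  dimnames(reflectance) <- list(NULL, sample_ids)
  structure(
    list(grid_nm = grid_nm, reflectance = reflectance,
         sample_ids = sample_ids),
    over_unity = over,
    class = "spectrum_collection"
  )
}

#' Assemble a collection from individual spectra
#'
#' All spectra must share a bitwise-identical wavelength grid; resample first
#' if they do not.
#'
#' @param spectra List of `"spectrum"` objects.
#' @return A `"spectrum_collection"`.
#' @export
collect_spectra <- function(spectra) {
  if (!length(spectra)) stop("empty list of spectra")
  grids <- lapply(spectra, `[[`, "wavelengths_nm")
  for (g in grids[-1L]) {
    if (!identical(g, grids[[1L]])) {
      stop("all spectra in a collection must share an identical grid")
    }
  }
  mat <- vapply(spectra, `[[`, numeric(length(grids[[1L]])), "reflectance")
  ids <- vapply(spectra, `[[`, character(1L), "sample_id")
  new_spectrum_collection(grids[[1L]], mat, ids)
}

#' @export
print.spectrum_collection <- function(x, ...) {
  cat(sprintf("<spectrum_collection> %d samples x %d bands (%.6g-%.6g nm)\n",
              length(x$sample_ids), length(x$grid_nm),
              min(x$grid_nm), max(x$grid_nm)))
  invisible(x)
}

#' Number of samples in a collection
#' @param collection A `"spectrum_collection"`.
#' @return Integer count.
#' @export
n_samples <- function(collection) length(collection$sample_ids)

#' Extract one sample from a collection
#' @param collection A `"spectrum_collection"`.
#' @param sample_id Sample identifier.
#' @return A `"spectrum"`.
#' @export
get_spectrum <- function(collection, sample_id) {
  j <- match(sample_id, collection$sample_ids)
  if (is.na(j)) stop("unknown sample id: ", sample_id)
  withCallingHandlers(
    new_spectrum(sample_id, collection$grid_nm, collection$reflectance[, j]),
    warning = function(w) invokeRestart("muffleWarning")
  )
}

# full-precision number formatting for lossless text round trips
fmt_full <- function(x) {
  out <- formatC(x, format = "g", digits = 17)
  gsub(" ", "", out, fixed = TRUE)
}

#' Read a spectral library from a wide CSV file
#'
#' Expected layout: a header `wavelength_nm,<id1>,<id2>,...`, one row per
#' wavelength. Rows are sorted ascending by wavelength on read. If any value
#' exceeds 1.5 the whole file is assumed to be in percent reflectance and is
#' divided by 100 with a warning.
#'
#' @param path Path to the CSV file.
#' @param dialect Input dialect; only `"wide_csv"` is supported.
#' @return A `"spectrum_collection"`.
#' @export
read_spectra <- function(path, dialect = "wide_csv") {
  dialect <- match.arg(dialect, "wide_csv")
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("wide CSV needs a wavelength column plus samples")
  for (j in seq_len(ncol(df))) {
    if (!is.numeric(df[[j]])) {
      stop("non-numeric cell in column '", names(df)[j], "'")
    }
  }
  w <- df[[1L]]
  if (anyDuplicated(w)) stop("duplicate wavelength row in ", path)
  ids <- names(df)[-1L]
  if (anyDuplicated(ids)) stop("duplicate sample id in ", path)
  o <- order(w)
  mat <- as.matrix(df[o, -1L, drop = FALSE])
  w <- w[o]
  if (any(!is.finite(mat))) stop("non-finite reflectance value in ", path)
  if (max(mat) > 1.5) {
    warning("values above 1.5 detected; interpreting file as percent ",
            "reflectance and rescaling to fractions")
    mat <- mat / 100
  }
  new_spectrum_collection(w, mat, ids)
}

#' Write a spectral library to a wide CSV file
#'
#' Numbers are written with 17 significant digits so that
#' `read_spectra(write_spectra(x))` reproduces `x` exactly.
#'
#' @param collection A `"spectrum_collection"`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_spectra <- function(collection, path) {
  stopifnot(inherits(collection, "spectrum_collection"))
  header <- paste(c("wavelength_nm", collection$sample_ids), collapse = ",")
  body <- apply(
    cbind(collection$grid_nm, collection$reflectance), 1L,
    function(row) paste(fmt_full(row), collapse = ",")
  )
  writeLines(c(header, body), path)
  invisible(path)
}

#' Resample a spectrum by linear interpolation
#'
#' Exact at wavelengths shared with the native grid; no extrapolation beyond
#' the native range.
#'
#' @param spec A `"spectrum"`.
#' @param grid_nm Target wavelengths, all inside the native range.
#' @return A `"spectrum"` on the new grid.
#' @export
resample <- function(spec, grid_nm) {
  stopifnot(inherits(spec, "spectrum"))
  grid_nm <- as.numeric(grid_nm)
  w <- spec$wavelengths_nm
  if (any(grid_nm < w[1L]) || any(grid_nm > w[length(w)])) {
    stop("grid point outside the native wavelength range; no extrapolation")
  }
  r <- stats::approx(w, spec$reflectance, xout = grid_nm, method = "linear",
                     ties = "ordered")$y
  if (length(grid_nm) == 1L) {
    # a single-point query cannot pass through the >= 2 point constructor
    return(structure(
      list(sample_id = spec$sample_id, wavelengths_nm = grid_nm,
           reflectance = r),
      over_unity = any(r > 1), class = "spectrum"
    ))
  }
  withCallingHandlers(
    new_spectrum(spec$sample_id, grid_nm, r),
    warning = function(w) invokeRestart("muffleWarning")
  )
}

#' Read a dust-load table
#'
#' CSV with header `sample_id,dust_type,dust_g_per_m2`. Dust type must be one
#' of `coal`, `cement`, `soil`, `none`; loads must be finite and non-negative.
#'
#' @param path Path to the CSV file.
#' @return Data frame with columns `sample_id`, `dust_type`, `load_g_per_m2`.
#' @export
read_dust_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "dust_type", "dust_g_per_m2")
  if (!identical(names(df)[seq_along(need)], need)) {
    stop("dust table header must be: ", paste(need, collapse = ","))
  }
  if (anyDuplicated(df$sample_id)) stop("duplicate sample id in dust table")
  bad <- setdiff(unique(df$dust_type), DUST_TYPES)
  if (length(bad)) {
    stop("unknown dust_type token: ", paste(bad, collapse = ", "))
  }
  load <- df$dust_g_per_m2
  if (!is.numeric(load) || any(!is.finite(load))) {
    stop("malformed row: dust_g_per_m2 must be finite numeric")
  }
  if (any(load < 0)) stop("negative load in dust table")
  data.frame(sample_id = as.character(df$sample_id),
             dust_type = df$dust_type,
             load_g_per_m2 = load,
             stringsAsFactors = FALSE)
}

#' Write a dust-load table
#' @param dust Data frame with `sample_id`, `dust_type`, `load_g_per_m2`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_dust_table <- function(dust, path) {
  stopifnot(all(c("sample_id", "dust_type", "load_g_per_m2") %in% names(dust)))
  lines <- c("sample_id,dust_type,dust_g_per_m2",
             paste(dust$sample_id, dust$dust_type,
                   fmt_full(dust$load_g_per_m2), sep = ","))
  writeLines(lines, path)
  invisible(path)
}

FEATURE_NAMES <- c("LWI", "REI", "NDI", "SRI", "PRI",
                   "REP", "RES", "BEP", "BES", "YEP", "YES")

#' Write a per-sample feature table
#'
#' Fixed column order `sample_id,LWI,REI,NDI,SRI,PRI,REP,RES,BEP,BES,YEP,YES`;
#' undefined features are written as empty cells.
#'
#' @param features Data frame as returned by [feature_table()].
#' @param path Output file path.
#' @param digits Significant digits to write (default 17: lossless).
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(features, path, digits = 17) {
  cols <- c("sample_id", FEATURE_NAMES)
  stopifnot(all(cols %in% names(features)))
  fmt1 <- function(x) {
    out <- ifelse(is.na(x), "",
                  gsub(" ", "", formatC(x, format = "g", digits = digits)))
    out
  }
  body <- do.call(paste, c(
    list(features$sample_id),
    lapply(features[FEATURE_NAMES], fmt1),
    sep = ","
  ))
  writeLines(c(paste(cols, collapse = ","), body), path)
  invisible(path)
}

#' Read a per-sample feature table written by [write_feature_table()]
#' @param path Path to the CSV file.
#' @return Data frame with `sample_id` plus the eleven feature columns.
#' @export
read_feature_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("sample_id", FEATURE_NAMES) %in% names(df)))
  df$sample_id <- as.character(df$sample_id)
  df
}

#' Save a calibration model as a flat key=value text file
#' @param model A `"calibration_model"` (see [fit_linear()]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "calibration_model"))
  num <- function(x) if (is.na(x)) "NA" else fmt_full(x)
  lines <- c(
    paste0("predictor=", model$predictor),
    paste0("slope=", num(model$slope)),
    paste0("intercept=", num(model$intercept)),
    paste0("r2=", num(model$r2)),
    paste0("rmse=", num(model$rmse)),
    paste0("n=", model$n),
    paste0("grid_hash=", if (is.null(model$grid_hash)) "" else model$grid_hash)
  )
  writeLines(lines, path)
  invisible(path)
}

#' Load a calibration model saved by [save_model()]
#' @param path Path to the model file.
#' @return A `"calibration_model"`.
#' @export
load_model <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  kv <- strsplit(lines, "=", fixed = TRUE)
  keys <- vapply(kv, `[`, character(1L), 1L)
  vals <- vapply(kv, function(x) {
    if (length(x) < 2L) "" else paste(x[-1L], collapse = "=")
  }, character(1L))
  names(vals) <- keys
  need <- c("predictor", "slope", "intercept", "r2", "rmse", "n")
  if (!all(need %in% keys)) {
    stop("malformed model file; missing keys: ",
         paste(setdiff(need, keys), collapse = ", "))
  }
  num <- function(s) if (identical(s, "NA")) NA_real_ else as.numeric(s)
  new_calibration_model(
    predictor = vals[["predictor"]],
    slope = num(vals[["slope"]]),
    intercept = num(vals[["intercept"]]),
    r2 = num(vals[["r2"]]),
    rmse = num(vals[["rmse"]]),
    n = as.integer(vals[["n"]]),
    grid_hash = if (nzchar(vals["grid_hash"] %||% "")) vals[["grid_hash"]] else NULL
  )
}

`%||%` <- function(a, b) if (is.null(a) || is.na(a)) b else a

#' Short fingerprint of a wavelength grid
#'
#' Recorded in model files so that a model is not silently applied to features
#' computed on a different grid.
#'
#' @param grid_nm Numeric wavelength grid.
#' @return Single character string.
#' @export
grid_hash <- function(grid_nm) {
  sprintf("n%d_%.6g_%.6g_s%.6g", length(grid_nm), min(grid_nm), max(grid_nm),
          sum(grid_nm) %% 1e6)
}
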