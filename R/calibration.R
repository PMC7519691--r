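# Correlation screening and univariate linear calibration of dust load.
#
# The calibration chain mirrors the usual spectroscopic workflow: per-band
# Pearson screening of reflectance (raw and derivative) against load, the
# same screening for the eleven scalar features, ordinary least squares
# y = slope * x + intercept per candidate predictor, ranking by R^2, and a
# per-dust-type validation report on held-out samples.

#' Pearson correlation with a two-sided t-test p-value
#'
#' @param x,y Numeric vectors of equal length `n >= 3`, both non-constant.
#'   A constant vector yields `r = NA` (undefined marker), not an error.
#' @return List with `r`, `p_value`, `n`.
#' @export
pearson <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop("length mismatch between x and y")
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3L) stop("need at least 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(list(r = NA_real_, p_value = NA_real_, n = n))
  }
  r <- stats::cor(x, y)
  if (abs(r) >= 1) {
    p <- 0
  } else {
    tstat <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  }
  list(r = r, p_value = p, n = n)
}

sig_stars <- function(p) {
  if (is.na(p)) "" else if (p < 0.01) "**" else if (p < 0.05) "*" else ""
}

match_loads <- function(sample_ids, dust) {
  i <- match(sample_ids, dust$sample_id)
  if (anyNA(i)) {
    stop("missing dust record for sample id(s): ",
         paste(sample_ids[is.na(i)], collapse = ", "))
  }
  dust$load_g_per_m2[i]
}

#' Per-band Pearson correlation of reflectance against dust load
#'
#' @param collection A `"spectrum_collection"`.
#' @param dust Dust table (see [read_dust_table()]) with a record for every
#'   sample in the collection.
#' @param deriv_collection Optional `"deriv_collection"` for the
#'   first-derivative correlogram.
#' @return Object of class `"band_correlation_profile"`: a list with
#'   `raw` (data frame `wavelength_nm`, `r`), `deriv` (same or `NULL`),
#'   and `n`.
#' @export
band_correlations <- function(collection, dust, deriv_collection = NULL) {
  stopifnot(inherits(collection, "spectrum_collection"))
  load <- match_loads(collection$sample_ids, dust)
  if (length(load) < 3L) stop("need at least 3 samples")
  if (stats::sd(load) == 0) stop("dust loads are constant; no correlation")
  # a band that is constant across samples has an undefined r -> NA
  r_raw <- as.vector(suppressWarnings(
    stats::cor(t(collection$reflectance), load)))
  out <- list(
    raw = data.frame(wavelength_nm = collection$grid_nm, r = r_raw),
    deriv = NULL,
    n = length(load)
  )
  if (!is.null(deriv_collection)) {
    stopifnot(inherits(deriv_collection, "deriv_collection"))
    load_d <- match_loads(deriv_collection$sample_ids, dust)
    r_d <- as.vector(suppressWarnings(
      stats::cor(t(deriv_collection$d_reflectance), load_d)))
    out$deriv <- data.frame(wavelength_nm = deriv_collection$grid_nm, r = r_d)
  }
  structure(out, class = "band_correlation_profile")
}

#' @export
print.band_correlation_profile <- function(x, ...) {
  cat(sprintf("<band_correlation_profile> n = %d, %d raw bands%s\n",
              x$n, nrow(x$raw),
              if (is.null(x$deriv)) "" else
                sprintf(", %d derivative bands", nrow(x$deriv))))
  invisible(x)
}

#' Extremal correlation within wavelength windows
#'
#' Reports, per window, the wavelength where `|r|` is largest (ties toward the
#' shortest wavelength) together with the signed `r` there -- the "peak"
#' summary conventionally quoted for band correlograms.
#'
#' @param profile A `"band_correlation_profile"`.
#' @param windows Named list of `c(lo, hi)` wavelength windows (nm).
#' @param which `"raw"` or `"deriv"` correlogram.
#' @return Data frame `window`, `wavelength_nm`, `r`.
#' @export
correlation_peaks <- function(profile, windows, which = c("raw", "deriv")) {
  stopifnot(inherits(profile, "band_correlation_profile"))
  which <- match.arg(which)
  tab <- if (which == "raw") profile$raw else profile$deriv
  if (is.null(tab)) stop("profile has no derivative correlogram")
  rows <- lapply(names(windows), function(nm) {
    win <- windows[[nm]]
    idx <- which(tab$wavelength_nm >= win[1L] & tab$wavelength_nm <= win[2L])
    if (!length(idx)) stop("window ", nm, " contains no bands")
    i <- idx[which.max(abs(tab$r[idx]))]
    data.frame(window = nm, wavelength_nm = tab$wavelength_nm[i],
               r = tab$r[i], stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Pearson screening of the eleven features against dust load
#'
#' @param features Feature table (see [feature_table()]).
#' @param dust Dust table with a record per sample.
#' @return Data frame with 11 rows in the fixed feature order: `parameter`,
#'   `r`, `p_value`, `stars` (`**` for p < 0.01, `*` for p < 0.05), `n`.
#'   A constant feature column has `r = NA` and empty stars.
#' @export
parameter_correlations <- function(features, dust) {
  load <- match_loads(features$sample_id, dust)
  rows <- lapply(FEATURE_NAMES, function(nm) {
    x <- features[[nm]]
    keep <- is.finite(x) & is.finite(load)
    res <- if (sum(keep) < 3L) {
      list(r = NA_real_, p_value = NA_real_, n = sum(keep))
    } else {
      pearson(x[keep], load[keep])
    }
    data.frame(parameter = nm, r = res$r, p_value = res$p_value,
               stars = sig_stars(res$p_value), n = res$n,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Construct a calibration model object
#'
#' @param predictor Feature name (or `NA` for an anonymous model).
#' @param slope,intercept OLS coefficients of `load = slope * x + intercept`.
#' @param r2 Training coefficient of determination.
#' @param rmse Training root mean square error, divisor `n`, in g m^-2.
#' @param n Training sample count.
#' @param grid_hash Optional wavelength-grid fingerprint (see [grid_hash()]).
#' @return Object of class `"calibration_model"`.
#' @export
new_calibration_model <- function(predictor, slope, intercept, r2, rmse, n,
                                  grid_hash = NULL) {
  structure(
    list(predictor = as.character(predictor), slope = slope,
         intercept = intercept, r2 = r2, rmse = rmse, n = as.integer(n),
         grid_hash = grid_hash),
    class = "calibration_model"
  )
}

#' @export
print.calibration_model <- function(x, ...) {
  cat(sprintf(
    "<calibration_model> load = %.6g * %s + %.6g  (R2 = %.4f, RMSE = %.4g, n = %d)\n",
    x$slope, x$predictor, x$intercept,
    if (is.na(x$r2)) NA else x$r2, x$rmse, x$n))
  invisible(x)
}

#' Univariate ordinary least squares calibration
#'
#' Fits `y = slope * x + intercept` by OLS and records training diagnostics
#' `r2 = 1 - SSE/SST` and `rmse = sqrt(SSE/n)` (divisor `n`; `n` is stored so
#' other conventions are recomputable). A constant target gives `r2 = NA`
#' (SST = 0 is treated as undefined, not as a perfect fit).
#'
#' @param x Predictor values (non-constant, `n >= 3` complete pairs).
#' @param y Dust loads (g m^-2).
#' @param predictor Optional predictor name stored in the model.
#' @return A `"calibration_model"`.
#' @export
fit_linear <- function(x, y, predictor = NA_character_) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop("length mismatch between x and y")
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3L) stop("need at least 3 complete pairs")
  if (stats::sd(x) == 0) stop("constant predictor; cannot fit")
  fit <- stats::lm(y ~ x)
  beta <- stats::coef(fit)
  sse <- sum(stats::residuals(fit)^2)
  sst <- sum((y - mean(y))^2)
  r2 <- if (sst > 0) 1 - sse / sst else NA_real_
  new_calibration_model(
    predictor = predictor,
    slope = unname(beta[["x"]]),
    intercept = unname(beta[["(Intercept)"]]),
    r2 = r2,
    rmse = sqrt(sse / n),
    n = n
  )
}

#' Predict dust load from a calibration model
#' @param object A `"calibration_model"`.
#' @param x Predictor values.
#' @param ... Unused.
#' @return Predicted loads (g m^-2).
#' @export
predict.calibration_model <- function(object, x, ...) {
  object$slope * as.numeric(x) + object$intercept
}

#' Fit and rank one model per candidate predictor
#'
#' Models are ordered by descending training `r2`, ties broken by smaller
#' `rmse`, then by the fixed feature-column order -- so the ranking does not
#' depend on the input order of `predictors`.
#'
#' @param features Feature table.
#' @param dust Dust table.
#' @param predictors Character vector of feature names (default: all eleven).
#' @return List of `"calibration_model"` objects, best first.
#' @export
rank_models <- function(features, dust, predictors = FEATURE_NAMES) {
  if (!length(predictors)) stop("predictors must be non-empty")
  bad <- setdiff(predictors, FEATURE_NAMES)
  if (length(bad)) stop("unknown predictor name: ", paste(bad, collapse = ", "))
  load <- match_loads(features$sample_id, dust)
  models <- lapply(predictors, function(nm) {
    fit_linear(features[[nm]], load, predictor = nm)
  })
  r2 <- vapply(models, function(m) if (is.na(m$r2)) -Inf else m$r2, numeric(1L))
  rmse <- vapply(models, `[[`, numeric(1L), "rmse")
  ord <- order(-r2, rmse, match(predictors, FEATURE_NAMES))
  models[ord]
}

#' Ranked models as a data frame
#' @param models List of `"calibration_model"` objects.
#' @return Data frame `predictor`, `slope`, `intercept`, `r2`, `rmse`, `n`.
#' @export
models_table <- function(models) {
  out <- do.call(rbind, lapply(models, function(m) {
    data.frame(predictor = m$predictor, slope = m$slope,
               intercept = m$intercept, r2 = m$r2, rmse = m$rmse, n = m$n,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Per-dust-type validation of a calibration model on held-out samples
#'
#' For each dust type present in `dust_test`: Pearson r between predicted and
#' measured load, RMSE (divisor n), and prediction accuracy
#' `100 * (1 - mean(|pred - obs| / obs))` over samples with positive measured
#' load (100 minus the mean absolute percentage error). Groups containing
#' zero-load samples have those samples excluded from the accuracy mean and
#' are flagged; constant predictions give `r = NA` and a flag.
#'
#' @param model A `"calibration_model"`.
#' @param features_test Feature table of the held-out samples.
#' @param dust_test Dust table of the held-out samples.
#' @return Data frame `dust_type`, `n`, `r_pred_obs`, `rmse`, `accuracy_pct`,
#'   `flag`.
#' @export
validate_model <- function(model, features_test, dust_test) {
  stopifnot(inherits(model, "calibration_model"))
  if (!model$predictor %in% names(features_test)) {
    stop("feature table lacks predictor column '", model$predictor, "'")
  }
  idx <- match(features_test$sample_id, dust_test$sample_id)
  if (anyNA(idx)) {
    stop("missing dust record for sample id(s): ",
         paste(features_test$sample_id[is.na(idx)], collapse = ", "))
  }
  x <- features_test[[model$predictor]]
  y <- dust_test$load_g_per_m2[idx]
  type <- dust_test$dust_type[idx]
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]; type <- type[keep]
  yhat <- predict(model, x)
  rows <- lapply(sort(unique(type)), function(tp) {
    sel <- type == tp
    n <- sum(sel)
    if (n < 3L) stop("dust type '", tp, "' has fewer than 3 test samples")
    flags <- character(0)
    r <- if (stats::sd(yhat[sel]) == 0) {
      flags <- c(flags, "constant_predictions")
      NA_real_
    } else if (stats::sd(y[sel]) == 0) {
      flags <- c(flags, "constant_observations")
      NA_real_
    } else {
      stats::cor(yhat[sel], y[sel])
    }
    rmse <- sqrt(mean((yhat[sel] - y[sel])^2))
    pos <- sel & y > 0
    if (any(sel & y == 0)) flags <- c(flags, "zero_load_excluded_from_accuracy")
    acc <- if (any(pos)) {
      100 * (1 - mean(abs(yhat[pos] - y[pos]) / y[pos]))
    } else {
      flags <- c(flags, "no_positive_loads")
      NA_real_
    }
    data.frame(dust_type = tp, n = n, r_pred_obs = r, rmse = rmse,
               accuracy_pct = acc,
               flag = paste(flags, collapse = ";"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Seeded train / correlation / validation split
#'
#' Draws `n_train` sample ids for model fitting, `n_corr` of those for the
#' correlation screening subset, and leaves the remainder for validation --
#' the sizes default to the 120 / 50 / rest design of the dust-retention
#' study protocol.
#'
#' @param sample_ids Character vector of all sample ids.
#' @param n_train Number of training samples (default 120).
#' @param n_corr Number of correlation-screening samples, drawn from the
#'   training set (default 50).
#' @param seed Integer RNG seed (mandatory: the split must be reproducible).
#' @return List with character vectors `train`, `corr`, `validation`.
#' @export
split_samples <- function(sample_ids, n_train = 120L, n_corr = 50L, seed) {
  if (missing(seed)) stop("seed is mandatory for a reproducible split")
  sample_ids <- as.character(sample_ids)
  n <- length(sample_ids)
  if (n_train >= n) stop("n_train must leave at least one validation sample")
  if (n_corr > n_train) stop("n_corr cannot exceed n_train")
  set.seed(as.integer(seed))
  train <- sort(sample(sample_ids, n_train))
  corr <- sort(sample(train, n_corr))
  list(train = train, corr = corr,
       validation = sort(setdiff(sample_ids, train)))
}
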