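test_that("pearson handles perfect, hand-computed and degenerate cases", {
  x <- 1:10
  expect_equal(pearson(x, 2 * x + 1)$r, 1)
  expect_equal(pearson(x, 2 * x + 1)$p_value, 0)
  expect_equal(pearson(x, -x)$r, -1)

  res <- pearson(c(1, 2, 3, 4), c(1, 3, 2, 4))
  expect_equal(res$r, 0.8, tolerance = 1e-12)

  expect_true(is.na(pearson(rep(1, 5), 1:5)$r))
  expect_error(pearson(1:4, 1:5), "length mismatch")
  expect_error(pearson(1:2, 1:2), "at least 3")
})

test_that("pearson agrees with cor.test on random data", {
  set.seed(31)
  for (i in 1:20) {
    n <- sample(5:60, 1)
    x <- rnorm(n)
    y <- 0.5 * x + rnorm(n)
    mine <- pearson(x, y)
    ref <- cor.test(x, y)
    expect_equal(mine$r, unname(ref$estimate), tolerance = 1e-12)
    expect_equal(mine$p_value, ref$p.value, tolerance = 1e-10)
  }
})

test_that("fit_linear reproduces a generating line exactly", {
  x <- seq(0.5, 2, length.out = 20)
  y <- 1.5019 * x - 1.4791
  m <- fit_linear(x, y)
  expect_equal(m$slope, 1.5019, tolerance = 1e-10)
  expect_equal(m$intercept, -1.4791, tolerance = 1e-10)
  expect_equal(m$r2, 1, tolerance = 1e-12)
  expect_lt(m$rmse, 1e-12)
})

test_that("fit_linear equals the normal-equations closed form", {
  set.seed(37)
  for (i in 1:100) {
    n <- sample(5:80, 1)
    x <- rnorm(n, sd = runif(1, 0.1, 10))
    y <- rnorm(1, 0, 2) * x + rnorm(1) + rnorm(n, sd = runif(1, 0.01, 2))
    m <- fit_linear(x, y)
    sxx <- sum((x - mean(x))^2)
    slope_o <- sum((x - mean(x)) * (y - mean(y))) / sxx
    int_o <- mean(y) - slope_o * mean(x)
    expect_equal(m$slope, slope_o, tolerance = 1e-10)
    expect_equal(m$intercept, int_o, tolerance = 1e-10)
    # univariate OLS: r2 equals squared Pearson correlation
    expect_equal(m$r2, pearson(x, y)$r^2, tolerance = 1e-10)
    # rmse definition: divisor n
    pred <- predict(m, x)
    expect_equal(m$rmse, sqrt(mean((pred - y)^2)), tolerance = 1e-12)
  }
})

test_that("fit_linear is scale-equivariant and flags degenerate targets", {
  set.seed(41)
  x <- rnorm(30)
  y <- 2 * x + rnorm(30, sd = 0.3)
  m1 <- fit_linear(x, y)
  m2 <- fit_linear(10 * x, y)
  expect_equal(m2$slope, m1$slope / 10, tolerance = 1e-10)
  expect_equal(m2$r2, m1$r2, tolerance = 1e-10)

  mc <- fit_linear(x, rep(0.2, 30))
  expect_true(is.na(mc$r2))
  expect_equal(mc$slope, 0, tolerance = 1e-12)
  expect_error(fit_linear(rep(1, 10), rnorm(10)), "constant predictor")
})

test_that("band correlations recover constructed relationships", {
  # R(600) = 0.5 - 0.4 * load exactly -> r(600) = -1
  loads <- seq(0.05, 0.35, length.out = 10)
  specs <- lapply(seq_along(loads), function(i) {
    grid <- 500:700
    r <- rep(0.3, length(grid))
    r[grid == 600] <- 0.5 - 0.4 * loads[i] + 0  # perfect anticorrelation
    r[grid == 550] <- 0.1 + 0.9 * loads[i]      # perfect correlation
    new_spectrum(sprintf("s%02d", i), grid, r)
  })
  coll <- collect_spectra(specs)
  dust <- data.frame(sample_id = coll$sample_ids, dust_type = "coal",
                     load_g_per_m2 = loads, stringsAsFactors = FALSE)
  prof <- band_correlations(coll, dust)
  expect_equal(nrow(prof$raw), length(coll$grid_nm))
  expect_equal(prof$raw$r[prof$raw$wavelength_nm == 600], -1, tolerance = 1e-12)
  expect_equal(prof$raw$r[prof$raw$wavelength_nm == 550], 1, tolerance = 1e-12)
  pk <- correlation_peaks(prof, list(low = c(500, 580), high = c(590, 700)))
  expect_equal(pk$wavelength_nm, c(550, 600))

  dust_bad <- dust[-1, ]
  expect_error(band_correlations(coll, dust_bad), "missing dust record")
})

test_that("shuffled loads show no systematic band correlation", {
  set.seed(43)
  n <- 50
  specs <- lapply(seq_len(n), function(i) random_spectrum(sprintf("s%02d", i),
                                                          grid = 600:650))
  coll <- collect_spectra(specs)
  loads <- sample(seq(0.01, 0.5, length.out = n))
  dust <- data.frame(sample_id = coll$sample_ids, dust_type = "soil",
                     load_g_per_m2 = loads, stringsAsFactors = FALSE)
  prof <- band_correlations(coll, dust)
  expect_lt(mean(abs(prof$raw$r)), 0.2)
  expect_lt(abs(mean(prof$raw$r)), 0.1)
})

test_that("parameter correlations report the fixed 11 rows with stars", {
  set.seed(47)
  n <- 40
  loads <- runif(n, 0.03, 0.35)
  ft <- data.frame(sample_id = sprintf("s%02d", 1:n))
  for (nm in feature_names()) ft[[nm]] <- rnorm(n)
  ft$LWI <- loads                    # identical to the target
  ft$SRI <- 3 * loads + rnorm(n, sd = 2)
  ft$REP <- rep(715, n)              # constant column
  dust <- data.frame(sample_id = ft$sample_id, dust_type = "coal",
                     load_g_per_m2 = loads, stringsAsFactors = FALSE)
  pc <- parameter_correlations(ft, dust)
  expect_equal(pc$parameter, feature_names())
  expect_equal(pc$r[pc$parameter == "LWI"], 1)
  expect_equal(pc$stars[pc$parameter == "LWI"], "**")
  expect_true(is.na(pc$r[pc$parameter == "REP"]))
  expect_identical(pc$stars[pc$parameter == "REP"], "")
})

test_that("independent features rarely earn stars (null simulation)", {
  set.seed(53)
  n <- 50
  reps <- 200L
  small_r <- 0L
  starred <- 0L
  for (i in seq_len(reps)) {
    x <- rnorm(n)
    load <- runif(n, 0.03, 0.35)
    res <- pearson(x, load)
    if (abs(res$r) < 0.4) small_r <- small_r + 1L
    if (res$p_value < 0.05) starred <- starred + 1L
  }
  # |r| < 0.4 at n = 50 under the null is essentially certain
  expect_gte(small_r / reps, 0.95)
  # star rate = empirical type-I error: nominal 5% plus Monte-Carlo slack
  expect_lte(starred / reps, 0.05 + 3 * sqrt(0.05 * 0.95 / reps))
})

test_that("model ranking is deterministic and puts perfect predictors first", {
  set.seed(59)
  n <- 60
  loads <- runif(n, 0.03, 0.35)
  ft <- data.frame(sample_id = sprintf("s%02d", 1:n))
  for (nm in feature_names()) ft[[nm]] <- rnorm(n)
  ft$NDI <- 0.3 - 0.8 * loads        # noiseless linear transform of load
  dust <- data.frame(sample_id = ft$sample_id, dust_type = "cement",
                     load_g_per_m2 = loads, stringsAsFactors = FALSE)
  ms <- rank_models(ft, dust, predictors = c("LWI", "NDI", "PRI"))
  expect_equal(ms[[1]]$predictor, "NDI")
  expect_equal(ms[[1]]$r2, 1, tolerance = 1e-12)

  ms2 <- rank_models(ft, dust, predictors = c("PRI", "LWI", "NDI"))
  expect_identical(models_table(ms), models_table(ms2))
  expect_error(rank_models(ft, dust, predictors = "XYZ"), "unknown predictor")
  expect_error(rank_models(ft, dust, predictors = character(0)), "non-empty")
})

test_that("validation reports perfect and degenerate models correctly", {
  n <- 30
  loads <- seq(0.05, 0.35, length.out = n)
  ft <- data.frame(sample_id = sprintf("v%02d", 1:n))
  for (nm in feature_names()) ft[[nm]] <- rnorm(n)
  ft$LWI <- (loads + 1.4791) / 1.5019
  dust <- data.frame(sample_id = ft$sample_id,
                     dust_type = rep(c("coal", "cement", "soil"), each = 10),
                     load_g_per_m2 = loads, stringsAsFactors = FALSE)
  m <- new_calibration_model("LWI", 1.5019, -1.4791, 1, 0, n)
  rep_ <- validate_model(m, ft, dust)
  expect_equal(nrow(rep_), 3L)
  expect_equal(rep_$r_pred_obs, rep(1, 3), tolerance = 1e-9)
  expect_lt(max(rep_$rmse), 1e-12)
  expect_equal(rep_$accuracy_pct, rep(100, 3), tolerance = 1e-9)
  expect_identical(rep_$flag, rep("", 3))

  # constant predictions -> r undefined, flagged
  ft$REI <- rep(0.2, n)
  m2 <- new_calibration_model("REI", 1, 0, NA, NA, n)
  rep2 <- validate_model(m2, ft, dust)
  expect_true(all(is.na(rep2$r_pred_obs)))
  expect_true(all(grepl("constant_predictions", rep2$flag)))

  # zero loads excluded from accuracy and flagged
  dust$load_g_per_m2[1] <- 0
  rep3 <- validate_model(m, ft, dust)
  coal <- rep3[rep3$dust_type == "coal", ]
  expect_true(grepl("zero_load_excluded", coal$flag))
})

test_that("validation accuracy matches the folded-normal expectation under
           multiplicative load noise", {
  set.seed(61)
  n <- 200
  y_true <- runif(n, 0.1, 0.4)
  eps <- rnorm(n, 0, 0.05)
  y_obs <- y_true * (1 + eps)
  ft <- data.frame(sample_id = sprintf("m%03d", 1:n))
  for (nm in feature_names()) ft[[nm]] <- rnorm(n)
  ft$LWI <- y_true  # oracle predictor: model predicts the true load
  dust <- data.frame(sample_id = ft$sample_id, dust_type = "coal",
                     load_g_per_m2 = y_obs, stringsAsFactors = FALSE)
  m <- new_calibration_model("LWI", 1, 0, 1, 0, n)
  rep_ <- validate_model(m, ft, dust)
  # E|pred - obs| / obs = E|eps / (1 + eps)| ~ E|eps| = sd * sqrt(2/pi)
  expected <- 100 - 100 * 0.05 * sqrt(2 / pi)
  expect_equal(rep_$accuracy_pct, expected, tolerance = 0.01)
})

test_that("seeded splits are reproducible, disjoint and sized correctly", {
  ids <- sprintf("s%03d", 1:210)
  s1 <- split_samples(ids, seed = 99)
  s2 <- split_samples(ids, seed = 99)
  expect_identical(s1, s2)
  expect_length(s1$train, 120L)
  expect_length(s1$corr, 50L)
  expect_length(s1$validation, 90L)
  expect_length(intersect(s1$train, s1$validation), 0L)
  expect_true(all(s1$corr %in% s1$train))
  expect_error(split_samples(ids, n_train = 210, seed = 1), "validation")
  expect_error(split_samples(ids, seed = 1, n_corr = 130), "n_corr")
  expect_error(split_samples(ids), "seed")
})
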