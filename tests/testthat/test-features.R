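test_that("band lookup is exact on nodes and linear off-grid", {
  sp <- new_spectrum("a", c(900, 902, 970), c(0.4, 0.6, 0.42))
  expect_identical(band(sp, 970), 0.42)
  expect_equal(band(sp, 901), 0.5)
  expect_error(band(sp, 899), "outside")

  # closed-form oracle on a random piecewise-linear spectrum
  set.seed(21)
  knots <- sort(runif(8, 400, 1000))
  vals <- runif(8, 0, 1)
  sp2 <- new_spectrum("pl", knots, vals)
  for (q in runif(100, min(knots), max(knots))) {
    i <- findInterval(q, knots, rightmost.closed = TRUE)
    t <- (q - knots[i]) / (knots[i + 1] - knots[i])
    expect_equal(band(sp2, q), (1 - t) * vals[i] + t * vals[i + 1],
                 tolerance = 1e-12)
  }
})

test_that("flat spectra are fixed points of the index set", {
  grid <- 440:980
  sp <- new_spectrum("flat", grid, rep(0.5, length(grid)))
  vi <- vegetation_indices(sp, first_derivative(sp))
  expect_identical(vi$lwi, 1)
  expect_identical(vi$rei, 0)
  expect_identical(vi$ndi, 0)
  expect_identical(vi$sri, 1)
  expect_identical(vi$pri, 0)
})

test_that("indices match hand evaluation of their defining formulas", {
  anchors <- c("440" = 0.05, "445" = 0.05, "531" = 0.10, "570" = 0.14,
               "705" = 0.10, "706" = 0.11, "750" = 0.50, "809" = 0.44,
               "900" = 0.46, "970" = 0.40, "980" = 0.40)
  sp <- anchored_spectrum("hand", anchors)
  vi <- vegetation_indices(sp, first_derivative(sp))
  expect_equal(vi$ndi, (0.50 - 0.10) / (0.50 + 0.10 + 2 * 0.05),
               tolerance = 1e-10)  # 0.4 / 0.7
  expect_equal(vi$lwi, 0.40 / 0.46, tolerance = 1e-10)
  expect_equal(vi$sri, 0.11 / 0.44, tolerance = 1e-10)
  expect_equal(vi$pri, (0.14 - 0.10) / (0.14 + 0.10), tolerance = 1e-10)
  expect_equal(vi$rei, 0.50 - band(sp, 680), tolerance = 1e-12)
})

test_that("zero denominators give NA markers rather than crashing", {
  grid <- 440:980
  r <- rep(0.5, length(grid))
  r[grid >= 895 & grid <= 905] <- 0  # R900 = 0 kills LWI only
  sp <- new_spectrum("z", grid, r)
  vi <- vegetation_indices(sp, first_derivative(sp))
  expect_true(is.na(vi$lwi))
  expect_false(is.na(vi$sri))
})

test_that("forward-path REI telescopes to R(750) - R(680) on random spectra", {
  set.seed(5)
  for (i in 1:25) {
    sp <- random_spectrum(grid = 440:980)
    vi <- vegetation_indices(sp, first_derivative(sp, "forward"))
    expect_lt(abs(vi$rei - (band(sp, 750) - band(sp, 680))), 1e-12)
  }
})

test_that("trilateral parameters hit constructed extrema and break ties
           toward short wavelengths", {
  grid <- 480:760
  tri_d <- 0.02 * pmax(0, 1 - abs(grid - 715) / 35)  # triangle peak at 715
  d <- structure(list(sample_id = "t", wavelengths_nm = as.numeric(grid),
                      d_reflectance = tri_d, method = "forward",
                      delta_nm = 1), class = "deriv_spectrum")
  tp <- trilateral(d)
  expect_equal(tp$rep, 715)
  expect_equal(tp$res, 0.02)

  const <- structure(list(sample_id = "c", wavelengths_nm = as.numeric(grid),
                          d_reflectance = rep(0.003, length(grid)),
                          method = "forward", delta_nm = 1),
                     class = "deriv_spectrum")
  tp2 <- trilateral(const)
  expect_equal(tp2$rep, 680)
  expect_equal(tp2$bep, 490)
  expect_equal(tp2$yep, 560)  # tie in either mode -> shortest wavelength
  expect_equal(tp2$yes, 0.003)
})

test_that("edge extraction agrees with an independent brute-force scan", {
  set.seed(13)
  for (i in 1:100) {
    d <- random_deriv(grid = 480:760, smooth = (i %% 2 == 0))
    if (i %% 10 == 0) {
      # forced tie: duplicate the window maximum at a longer wavelength
      idx <- which(d$wavelengths_nm >= 680 & d$wavelengths_nm <= 750)
      mx <- max(d$d_reflectance[idx])
      d$d_reflectance[max(idx)] <- mx
    }
    tp <- trilateral(d)
    red <- brute_edge(d, 680, 750, TRUE)
    blue <- brute_edge(d, 490, 530, TRUE)
    yellow <- brute_edge(d, 560, 640, FALSE)
    expect_identical(tp$rep, red[["position"]])
    expect_identical(tp$res, red[["slope"]])
    expect_identical(tp$bep, blue[["position"]])
    expect_identical(tp$bes, blue[["slope"]])
    expect_identical(tp$yep, yellow[["position"]])
    expect_identical(tp$yes, yellow[["slope"]])
    # max mode must agree with a max brute scan too
    tp_max <- trilateral(d, yellow_edge_mode = "max")
    ymax <- brute_edge(d, 560, 640, TRUE)
    expect_identical(tp_max$yep, ymax[["position"]])
  }
})

test_that("index bounds and window containment hold on random spectra", {
  set.seed(17)
  for (i in 1:50) {
    sp <- random_spectrum(grid = 440:980)
    d <- first_derivative(sp)
    vi <- vegetation_indices(sp, d)
    expect_lte(abs(vi$ndi), 1)
    expect_lte(abs(vi$pri), 1)
    expect_gt(vi$sri, 0)
    expect_gt(vi$lwi, 0)
    tp <- trilateral(d)
    expect_true(tp$rep >= 680 && tp$rep <= 750)
    expect_true(tp$bep >= 490 && tp$bep <= 530)
    expect_true(tp$yep >= 560 && tp$yep <= 640)
    sel <- d$wavelengths_nm >= 680 & d$wavelengths_nm <= 750
    expect_true(all(tp$res >= d$d_reflectance[sel]))
  }
})

test_that("feature_table composes per-sample calls and survives partial
           coverage", {
  set.seed(23)
  sp1 <- random_smooth_spectrum("a", grid = 350:2500)
  sp2 <- new_spectrum("a2", sp1$wavelengths_nm, sp1$reflectance)
  coll <- collect_spectra(list(sp1, sp2))
  ft <- feature_table(coll)
  expect_equal(nrow(ft), 2L)
  expect_equal(unlist(ft[1, feature_names()]), unlist(ft[2, feature_names()]),
               ignore_attr = TRUE)

  # per-sample composition oracle
  d1 <- first_derivative(sp1)
  vi <- vegetation_indices(sp1, d1)
  tp <- trilateral(d1)
  expect_equal(ft$LWI[1], vi$lwi)
  expect_equal(ft$REI[1], vi$rei)
  expect_equal(ft$REP[1], tp$rep)
  expect_equal(ft$YES[1], tp$yes)

  # truncated library (grid ends at 900 nm): LWI missing, red-edge features
  # still present
  coll2 <- collect_spectra(list(resample(sp1, 350:900)))
  ft2 <- feature_table(coll2)
  expect_true(is.na(ft2$LWI[1]))
  expect_false(is.na(ft2$NDI[1]))
  expect_false(is.na(ft2$REI[1]))
  expect_false(is.na(ft2$REP[1]))
  expect_true(is.na(ft2$error[1]))
})
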