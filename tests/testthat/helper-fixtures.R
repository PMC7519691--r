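# In-code fixtures: all test spectra are generated, never stored.

feature_names <- function() c("LWI", "REI", "NDI", "SRI", "PRI",
                              "REP", "RES", "BEP", "BES", "YEP", "YES")

# random non-negative spectrum on a 1 nm grid (covers the 445-970 index set)
random_spectrum <- function(id = "s", grid = 440:980) {
  new_spectrum(id, grid, runif(length(grid), 0, 1))
}

# smooth random spectrum: logistic rise plus random Gaussian bumps, in (0, 1)
random_smooth_spectrum <- function(id = "s", grid = 350:2500, n_bumps = 6) {
  l <- as.numeric(grid)
  r <- 0.08 + 0.4 * plogis((l - 715) / 12)
  for (b in seq_len(n_bumps)) {
    r <- r + runif(1, -0.05, 0.05) *
      exp(-0.5 * ((l - runif(1, min(l), max(l))) / runif(1, 15, 120))^2)
  }
  new_spectrum(id, l, pmin(pmax(r, 0.01), 0.95))
}

# random derivative curve built directly (no parent spectrum needed)
random_deriv <- function(id = "d", grid = 400:800, smooth = TRUE) {
  l <- as.numeric(grid)
  if (smooth) {
    d <- 0.002 * sin(l / runif(1, 10, 40)) +
      0.01 * exp(-0.5 * ((l - runif(1, 600, 760)) / runif(1, 8, 30))^2) +
      rnorm(1, 0, 5e-4)
  } else {
    d <- rnorm(length(l), 0, 0.005)
  }
  structure(
    list(sample_id = id, wavelengths_nm = l, d_reflectance = d,
         method = "forward", delta_nm = 1),
    class = "deriv_spectrum"
  )
}

# independent brute-force edge scan (deliberately naive; the oracle)
brute_edge <- function(deriv, lo, hi, maximum) {
  best_w <- NA_real_
  best_d <- if (maximum) -Inf else Inf
  for (i in seq_along(deriv$wavelengths_nm)) {
    w <- deriv$wavelengths_nm[i]
    if (w < lo || w > hi) next
    d <- deriv$d_reflectance[i]
    if ((maximum && d > best_d) || (!maximum && d < best_d)) {
      best_d <- d
      best_w <- w
    }
  }
  c(position = best_w, slope = best_d)
}

# spectrum hitting prescribed reflectance values at prescribed bands,
# linearly interpolated between them
anchored_spectrum <- function(id, anchors) {
  w <- as.numeric(names(anchors))
  stopifnot(!is.unsorted(w, strictly = TRUE))
  grid <- seq(min(w), max(w), by = 1)
  r <- approx(w, anchors, xout = grid)$y
  suppressWarnings(new_spectrum(id, grid, r))
}
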