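make_epochs <- function(gen, n_epochs = 25, len = 1024, fs = 250) {
  epoch_set(lapply(seq_len(n_epochs), function(e) gen(len)), fs = fs)
}

test_that("auto-spectrum of a pure sinusoid peaks at the sinusoid frequency", {
  fs <- 250
  tgrid <- seq_len(1024) / fs
  es <- make_epochs(function(len) cbind(sin(2 * pi * 10 * tgrid)))
  cs <- estimate_cross_spectra(es)
  peak <- cs$freqs[which.max(Re(cs$S[1, 1, ]))]
  expect_lt(abs(peak - 10), fs / 1024 + 1e-9)
})

test_that("cross-spectra are Hermitian with real non-negative diagonals", {
  set.seed(41)
  es <- make_epochs(function(len) matrix(rnorm(len * 4), len, 4),
                    n_epochs = 5)
  cs <- estimate_cross_spectra(es)
  for (b in c(1, 10, 100)) {
    Sb <- cs$S[, , b]
    expect_equal(Sb, Conj(t(Sb)), tolerance = 1e-12)
    expect_true(all(Re(diag(Sb)) >= 0))
    expect_true(all(abs(Im(diag(Sb))) < 1e-12))
  }
  expect_equal(cs$freqs[2] - cs$freqs[1], 250 / 1024)
})

test_that("identical channels give cross = auto spectrum and zero lagged coherence", {
  set.seed(42)
  es <- make_epochs(function(len) {
    z <- rnorm(len)
    cbind(a = z, b = z)
  }, n_epochs = 10)
  cs <- estimate_cross_spectra(es)
  expect_equal(cs$S[1, 2, ], cs$S[1, 1, ], tolerance = 1e-10)
  expect_true(all(abs(Im(cs$S[1, 2, ])) < 1e-9))
  lc <- lagged_coherence(cs, default_bands()$alpha)
  expect_lt(lc[1, 2], 1e-12)
})

test_that("independent white noise has low coherence, decreasing with epoch count", {
  set.seed(43)
  band <- default_bands()$alpha
  mean_coh <- vapply(c(5, 25, 100), function(ne) {
    es <- make_epochs(function(len) matrix(rnorm(2 * len), len, 2),
                      n_epochs = ne)
    m <- msc(estimate_cross_spectra(es), band)
    m[1, 2]
  }, numeric(1))
  expect_true(all(diff(mean_coh) < 0))
  es25 <- make_epochs(function(len) matrix(rnorm(2 * len), len, 2))
  lc <- lagged_coherence(estimate_cross_spectra(es25), band)
  expect_lt(lc[1, 2], 0.1)
})

test_that("a quarter-cycle-delayed sinusoid pair has high lagged coherence at its frequency", {
  fs <- 250
  f0 <- 10                         # quarter cycle = 90 degrees of phase
  for (seed in 1:3) {
    set.seed(seed)
    tgrid <- seq_len(1024) / fs
    es <- make_epochs(function(len) {
      phi <- runif(1, 0, 2 * pi)
      s <- sin(2 * pi * f0 * tgrid + phi)
      s_del <- sin(2 * pi * f0 * tgrid + phi - pi / 2)
      cbind(s + 0.05 * rnorm(len), s_del + 0.05 * rnorm(len))
    })
    cs <- estimate_cross_spectra(es)
    # around the oscillation the lagged coupling dominates
    lc_peak <- lagged_coherence(cs, band_spec("peak", 9.5, 10.5))
    expect_gt(lc_peak[1, 2], 0.8)
    # the full alpha band dilutes it with noise-only bins but it stays
    # far above the independent-noise floor
    lc_alpha <- lagged_coherence(cs, default_bands()$alpha)
    expect_gt(lc_alpha[1, 2], 0.2)
  }
})

test_that("a band-limited signal delayed a quarter cycle drives band lagged coherence near 1", {
  es <- generate_coupled_timeseries(
    2, couplings = list(list(pair = c(1, 2), band = default_bands()$theta,
                             lag = 10, strength = 4)),
    n_epochs = 25, seed = 46)
  lc <- lagged_coherence(estimate_cross_spectra(es), default_bands()$theta)
  expect_gt(lc[1, 2], 0.9)
})

test_that("lagged coherence output is symmetric, bounded and zero-diagonal", {
  set.seed(44)
  es <- make_epochs(function(len) matrix(rnorm(len * 6), len, 6),
                    n_epochs = 8)
  cs <- estimate_cross_spectra(es)
  for (band in default_bands()) {
    lc <- lagged_coherence(cs, band)
    expect_lt(max(abs(lc - t(lc))), 1e-10)
    expect_true(all(lc >= 0 & lc <= 1))
    expect_true(all(diag(lc) == 0))
  }
})

test_that("zero-lag mixing is suppressed by lagged but not ordinary coherence", {
  es <- generate_coupled_timeseries(6, zero_lag_mixing = 2, n_epochs = 25,
                                    seed = 45)
  cs <- estimate_cross_spectra(es)
  for (band in default_bands()) {
    lc <- lagged_coherence(cs, band)
    mc <- msc(cs, band)
    expect_lt(mean(lc[upper.tri(lc)]), mean(mc[upper.tri(mc)]))
  }
})

test_that("epoch validation rejects malformed input", {
  expect_error(epoch_set(list()), "non-empty")
  expect_error(epoch_set(list(matrix(1, 1, 2))), "at least 2 samples")
  expect_error(epoch_set(list(matrix(1, 10, 2), matrix(1, 9, 2))),
               "same shape")
  expect_error(epoch_set(list(matrix(c(1, NA, 3, 4), 2, 2))), "non-finite")
  cs <- estimate_cross_spectra(
    epoch_set(list(matrix(rnorm(200), 100, 2)), fs = 250))
  expect_error(lagged_coherence(cs, band_spec("low", 0.1, 0.5)),
               "no frequency bins")
})
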