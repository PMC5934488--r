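test_that("generated matrices satisfy the connectivity invariants", {
  for (p in c(0, 0.3, 1)) {
    W <- generate_sw_matrix(p_rewire = p, seed = 10 + p * 10)
    expect_s3_class(W, "connectivity_matrix")
    expect_equal(dim(W), c(84L, 84L))
    expect_lt(max(abs(W - t(W))), 1e-12)
    expect_true(all(W >= 0 & W <= 1))
    expect_true(all(diag(W) == 0))
    expect_equal(rownames(W), build_roi_atlas()$label)
  }
})

test_that("rewiring ordering: lattice clusters most, permuted least", {
  cl <- vapply(c(0, 0.1, 1), function(p) {
    mean(vapply(1:5, function(s)
      weighted_clustering(generate_sw_matrix(p_rewire = p, seed = s)),
      numeric(1)))
  }, numeric(1))
  expect_gt(cl[1], cl[2])
  expect_gt(cl[2], cl[3])
})

test_that("cohort generation is byte-identical under the same seed", {
  c1 <- generate_cohort(n_case = 3, n_ctrl = 4, bands = "theta", seed = 11)
  c2 <- generate_cohort(n_case = 3, n_ctrl = 4, bands = "theta", seed = 11)
  expect_identical(c1$matrices, c2$matrices)
  expect_identical(c1$subjects, c2$subjects)
  c3 <- generate_cohort(n_case = 3, n_ctrl = 4, bands = "theta", seed = 12)
  expect_false(identical(c1$matrices, c3$matrices))
})

test_that("cohort defaults match the target study design", {
  coh <- generate_cohort(seed = 13)
  expect_equal(sum(coh$subjects$group == "case"), 19L)
  expect_equal(sum(coh$subjects$group == "control"), 52L)
  expect_equal(coh$bands, c("theta", "alpha", "beta1", "beta2"))
  expect_equal(length(coh$matrices[[1]]), 4L)
})

test_that("duplicate effect targets are rejected and unknown ROIs reported", {
  expect_error(generate_cohort(
    n_case = 2, n_ctrl = 2, bands = "theta", seed = 1,
    effects = list(effect_spec("theta", "clustering", 0.1),
                   effect_spec("theta", "clustering", 0.2))),
    "duplicate")
  expect_error(effect_spec("theta", "wiggle", 0.1), "unknown effect target")
  expect_error(effect_spec("theta", "nodal_bc", 0.1), "must name an ROI")
  expect_error(generate_cohort(
    n_case = 2, n_ctrl = 2, bands = "theta", seed = 1,
    effects = list(effect_spec("theta", "nodal_bc:BA99 Q", 0.5))),
    "unknown ROI")
})

test_that("injected effect magnitude moves the targeted index monotonically", {
  # clustering deficit at three magnitudes; |t| should increase
  tvals <- vapply(c(0.05, 0.1, 0.2), function(mag) {
    ts <- vapply(1:4, function(s) {
      coh <- generate_cohort(n_case = 8, n_ctrl = 12, bands = "theta",
                             effects = list(
                               effect_spec("theta", "clustering", mag, -1)),
                             seed = 400 + s)
      cvals <- vapply(coh$matrices,
                      function(m) weighted_clustering(m$theta), numeric(1))
      welch_t(cvals[coh$subjects$group == "case"],
              cvals[coh$subjects$group == "control"])
    }, numeric(1))
    mean(abs(ts))
  }, numeric(1))
  expect_true(all(diff(tvals) > 0))
})

test_that("path and diameter effects move their indices in the stated direction", {
  set.seed(402)
  coh <- generate_cohort(n_case = 6, n_ctrl = 8, bands = "theta",
                         effects = list(effect_spec("theta", "path", 0.3, 1),
                                        effect_spec("theta", "diameter", 0.8, 1)),
                         seed = 7)
  grp <- coh$subjects$group
  L <- vapply(coh$matrices, function(m) characteristic_path(m$theta),
              numeric(1))
  dia <- vapply(coh$matrices, function(m)
    tree_metrics(minimum_spanning_tree(m$theta))$diameter, numeric(1))
  expect_gt(mean(L[grp == "case"]), mean(L[grp == "control"]))
  expect_gt(mean(dia[grp == "case"]), mean(dia[grp == "control"]))
})

test_that("coupled time series: independence, lagged coupling, mixing", {
  bands <- default_bands()
  # no couplings: lagged coherence flat near zero
  es0 <- generate_coupled_timeseries(4, n_epochs = 20, seed = 500)
  lc0 <- lagged_coherence(estimate_cross_spectra(es0), bands$theta)
  expect_lt(max(lc0[upper.tri(lc0)]), 0.1)
  # one quarter-cycle-lagged theta coupling: that pair is the band maximum
  for (s in 1:3) {
    es <- generate_coupled_timeseries(
      6, couplings = list(list(pair = c(2, 5), band = bands$theta,
                               lag = 10, strength = 2)),
      n_epochs = 20, seed = 500 + s)
    lc <- lagged_coherence(estimate_cross_spectra(es), bands$theta)
    off <- lc[upper.tri(lc)]
    expect_equal(max(off), lc[2, 5])
    expect_gt(lc[2, 5], 0.5)
  }
  # time-series determinism
  e1 <- generate_coupled_timeseries(3, n_epochs = 2, seed = 42)
  e2 <- generate_coupled_timeseries(3, n_epochs = 2, seed = 42)
  expect_identical(e1$epochs, e2$epochs)
  expect_error(generate_coupled_timeseries(
    3, couplings = list(list(pair = c(1, 2), band = bands$theta,
                             lag = 0, strength = 1))))
})
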