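# Light/heavy pairing, envelope-overlap-corrected ratio estimation,
# replicate aggregation and change calls.

test_that("labeled pairs carry the right shift and cover both envelopes", {
  p26 <- build_pair(glycan(2, 6))
  expect_equal(p26$shift, 2 * 0.99703, tolerance = 1e-4)
  p77 <- build_pair(glycan(7, 7, 1))
  expect_equal(p77$shift, 7 * 0.99703, tolerance = 1e-4)
  for (pair in list(p26, p77)) {
    expect_lte(pair$window[1], min(pair$light$mz))
    expect_gte(pair$window[2], max(pair$heavy$mz))
  }
})

test_that("pure light signal yields an undefined, flagged ratio", {
  pk <- make_pair_peaks(glycan(2, 6), light_amt = 100, heavy_amt = 0)
  f <- fit_pair(pk, build_pair(glycan(2, 6)))
  expect_true(is.na(f$ratio))
  expect_true("undefined_ratio" %in% f$flags)
  expect_equal(f$heavy_amount, 0, tolerance = 1e-9)
  # empty window: low-signal flag
  f0 <- fit_pair(peak_list(1000, 5, 5), build_pair(glycan(2, 6)))
  expect_true("low_signal" %in% f0$flags)
})

test_that("noise-free 1:1 mixtures fit to ratio 1 within 1e-6", {
  for (s in skov3_panel()$composition[c(1, 5, 9, 17)]) {
    comp <- parse_glycan(s)
    pk <- make_pair_peaks(comp, 100, 100)
    f <- fit_pair(pk, build_pair(comp))
    expect_equal(f$ratio, 1, tolerance = 1e-6)
  }
})

test_that("overlap correction recovers a 2 Da-shift pair that the height ratio misses", {
  comp <- glycan(2, 6)  # label shift ~1.994 Da, strongly overlapping
  pair <- build_pair(comp)
  pk <- make_pair_peaks(comp, light_amt = 50, heavy_amt = 100)  # true 0.5
  nnls <- fit_pair(pk, pair, estimator = "nnls")
  expect_equal(nnls$ratio, 0.5, tolerance = 0.005 / 0.5)
  naive <- fit_pair(pk, pair, estimator = "monoisotopic")
  expect_gt(abs(naive$ratio / 0.5 - 1), 0.02)
  # the naive bias follows the analytic overlap form r / (1 + r * L2/H0):
  # the heavy monoisotopic cluster is contaminated by the light M+2 peak
  l2_h0 <- pair$light$abundance[3] / pair$heavy$abundance[1]
  expect_equal(naive$ratio, 0.5 / (1 + 0.5 * l2_h0), tolerance = 0.01)
})

test_that("the fit agrees with a grid-search oracle on random synthetic pairs", {
  set.seed(421)
  panel <- skov3_panel()
  for (k in 1:20) {
    comp <- parse_glycan(sample(panel$composition, 1))
    r <- exp(runif(1, log(0.1), log(10)))
    amt <- runif(1, 50, 200)
    pk <- make_pair_peaks(comp, amt * r, amt)
    # perturb intensities so the optimum is not exactly on a grid point
    pk$area <- pk$area * exp(rnorm(nrow(pk), 0, 0.02))
    pair <- build_pair(comp)
    got <- fit_pair(pk, pair)$ratio
    want <- oracle_grid_ratio(pk, pair)
    expect_lt(abs(got / want - 1), 0.005)
  }
})

test_that("well-separated pairs reduce to the summed-envelope intensity ratio", {
  comp <- glycan(7, 7, 1)  # shift ~6.98 Da
  pair <- build_pair(comp, n_peaks = 6)  # envelope span < shift
  pk <- make_pair_peaks(comp, 73, 100, n_peaks = 6)
  f <- fit_pair(pk, pair)
  light_sum <- sum(pk$area[pk$mz < pair$heavy$mz[1] - 0.5])
  heavy_sum <- sum(pk$area[pk$mz >= pair$heavy$mz[1] - 0.5])
  expect_equal(f$ratio, light_sum / heavy_sum, tolerance = 1e-6)
})

test_that("recovered ratio is strictly increasing in the true light fraction", {
  comp <- glycan(2, 6)
  pair <- build_pair(comp)
  fracs <- seq(0.1, 0.9, by = 0.1)
  est <- vapply(fracs, function(fr) {
    fit_pair(make_pair_peaks(comp, 100 * fr, 100 * (1 - fr)), pair)$ratio
  }, numeric(1))
  expect_true(all(diff(est) > 0))
})

test_that("ratios are invariant to rescaling the replicate intensities", {
  comp <- glycan(5, 5, 1)
  pair <- build_pair(comp)
  pk <- make_pair_peaks(comp, 12, 100)
  f1 <- fit_pair(pk, pair)$ratio
  scaled <- peak_list(pk$mz, pk$intensity * 37.5, pk$area * 37.5)
  f2 <- fit_pair(scaled, pair)$ratio
  expect_equal(f1, f2, tolerance = 1e-9)
  norm <- normalize_base_peak(pk)
  expect_equal(fit_pair(norm, pair)$ratio, f1, tolerance = 1e-9)
})

test_that("replicate aggregation gives the sample-sd CV and is permutation invariant", {
  a <- aggregate_ratios(rep(0.28, 9))
  expect_equal(a$mean, 0.28)
  expect_equal(a$cv_pct, 0)
  b <- aggregate_ratios(c(1, 1, 4))
  expect_equal(b$mean, 2)
  expect_equal(b$cv_pct, 100 * sqrt(3) / 2, tolerance = 1e-9)
  p <- aggregate_ratios(c(4, 1, 1))
  expect_equal(c(p$mean, p$cv_pct), c(b$mean, b$cv_pct))
  one <- aggregate_ratios(c(NA, 1.3))
  expect_true("cv_unavailable" %in% one$flags)
  expect_equal(one$mean, 1.3)
  none <- aggregate_ratios(numeric(0))
  expect_true("no_ratios" %in% none$flags)
})

test_that("change calls follow the 0.83/1.20 thresholds with inclusive bounds", {
  expect_identical(change_call(1.46), "up")
  expect_identical(change_call(0.95), "no")
  expect_identical(change_call(0.28), "down")
  expect_identical(change_call(c(0.83, 1.20)), c("no", "no"))
  expect_identical(change_call(c(0.8299, 1.2001)), c("down", "up"))
  expect_error(change_call(-1), "positive")
})

test_that("ratio recovery across the panel stays within the stated error envelope", {
  panel <- skov3_panel()
  errs <- c()
  for (r in c(0.1, 1/3, 1, 3, 10)) {
    spec <- scenario_spec(panel$composition, rep(r, 17),
                          output = "centroid", seed = 7000 + round(100 * r))
    sim <- simulate_experiment(spec)
    for (g in seq_len(17)) {
      pair <- build_pair(parse_glycan(panel$composition[g]))
      ratios <- vapply(sim$spectra, function(pk) {
        fit_pair(pk, pair)$ratio
      }, numeric(1))
      errs <- c(errs, abs(mean(ratios) / r - 1))
    }
  }
  expect_lt(median(errs), 0.05)
  expect_lt(quantile(errs, 0.95), 0.15)
})

test_that("quantify_experiment assembles records sorted by m/z with QC flags", {
  comps <- c("HexNAc2Hex6", "HexNAc5Hex5Fuc1")
  reps <- lapply(1:3, function(i) {
    pk1 <- make_pair_peaks(glycan(2, 6), 100 * c(1, 1.02, 0.98)[i], 100)
    pk2 <- make_pair_peaks(glycan(5, 5, 1), 12, 100)
    mz <- c(pk1$mz, pk2$mz); it <- c(pk1$intensity, pk2$intensity)
    peak_list(mz, it, it)
  })
  fit <- quantify_experiment(reps, comps, light_name = "ip", heavy_name = "par")
  expect_s3_class(fit, "glyco_quant")
  expect_identical(fit$table$composition, comps)  # already m/z sorted
  expect_true(!is.unsorted(fit$table$theoretical_mz))
  expect_equal(fit$table$mean_ratio[2], 0.12, tolerance = 0.01)
  expect_identical(fit$table$change, c("no", "down"))
  expect_identical(fit$table$glycan_class, c("High mannose", "Bisecting"))
  expect_identical(nrow(fit$replicates), 6L)
  expect_identical(coef(fit), setNames(fit$table$mean_ratio, comps))
  # empty spectra: every record flagged, no calls
  empty_fit <- quantify_experiment(list(peak_list(1000, 1, 1)), comps,
                                   light_name = "ip", heavy_name = "par")
  expect_true(all(grepl("low_signal|no_ratios", empty_fit$table$flags)))
  expect_true(all(is.na(empit <- empty_fit$table$change)))
})
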