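test_that("fitDecay recovers noiseless decay parameters to optimizer tolerance", {
  te <- seq(2.4, 24, by = 2.4)
  s <- 1000 * exp(-te / 17.5) + 20
  fit <- fitDecay(te, s, noise_floor = 20)
  expect_lt(abs(fit@t2star_ms - 17.5) / 17.5, 0.001)
  expect_equal(fit@s0, 1000, tolerance = 1e-3)
  expect_equal(fit@noise_offset, 20, tolerance = 1e-2)
  expect_equal(fit@n_used, 10L)
  # same without telling the fitter the floor
  fit0 <- fitDecay(te, s)
  expect_lt(abs(fit0@t2star_ms - 17.5) / 17.5, 0.001)
})

test_that("degenerate decay inputs raise errors", {
  te <- seq(2.4, 24, by = 2.4)
  expect_error(fitDecay(te, rep(500, 10)), "constant")
  expect_error(fitDecay(te[1:3], c(100, 50, 25)), ">= 4")
  expect_error(fitDecay(te, rev(seq(10, 100, length.out = 10)) * 0 +
                          c(100, 90, 80, 70, 60, 50, 40, 30, 20, 10),
                        noise_floor = 95), "noise floor")
  expect_error(fitDecay(c(1, 2, 2, 3), c(4, 3, 2, 1)), "increasing")
})

test_that("noise-floor truncation drops contaminated late echoes", {
  te <- seq(2.4, 24, by = 2.4)
  true_s <- 300 * exp(-te / 4) # falls below floor quickly
  floor <- 25
  observed <- pmax(true_s, floor)  # magnitude floor
  fit <- fitDecay(te, observed, noise_floor = floor)
  expect_gt(fit@n_excluded, 0)
  expect_lt(abs(fit@t2star_ms - 4) / 4, 0.05)
})

test_that("sub-floor echoes never degrade the offset fit below truncated accuracy", {
  # short-T2* decay whose tail sinks into a Rician-like noise floor: because
  # the offset C is part of the model, keeping the sub-floor echoes must not
  # increase the T2* bias relative to the truncated fit
  set.seed(77)
  te <- seq(2.4, 24, by = 2.4)
  t2_true <- 4
  sigma <- 20
  floor_level <- sigma * sqrt(pi / 2)
  bias_trunc <- bias_all <- numeric(30)
  for (i in 1:30) {
    clean <- 500 * exp(-te / t2_true)
    noisy <- sqrt((clean + rnorm(10, 0, sigma))^2 + rnorm(10, 0, sigma)^2)
    f_tr <- fitDecay(te, noisy, noise_floor = floor_level)
    f_all <- fitDecay(te, noisy, noise_floor = 0)
    bias_trunc[i] <- abs(f_tr@t2star_ms - t2_true)
    bias_all[i] <- abs(f_all@t2star_ms - t2_true)
  }
  expect_lte(median(bias_all), median(bias_trunc) + 0.02 * t2_true)
  # sanity in this deliberately harsh low-SNR regime (single noisy curve,
  # most of the decay inside the floor)
  expect_lte(median(bias_trunc) / t2_true, 0.25)
})

test_that("LM fit agrees with the exhaustive grid-search oracle", {
  set.seed(31)
  cases <- data.frame(
    t2 = c(3.5, 5, 8, 12, 17.5, 22, 26, 30, 6.2, 16.1),
    s0 = c(800, 1000, 900, 1100, 1000, 950, 1050, 1000, 980, 1020),
    c0 = c(10, 20, 15, 25, 20, 10, 30, 20, 18, 22)
  )
  te <- seq(2.4, 24, by = 2.4)
  for (i in seq_len(nrow(cases))) {
    cs <- cases[i, ]
    s <- cs$s0 * exp(-te / cs$t2) + cs$c0 + rnorm(10, 0, 0.05)
    fit <- fitDecay(te, s, noise_floor = cs$c0)
    grid <- gridSearchDecay(
      te, s,
      t2_grid = seq(max(1, cs$t2 - 2), cs$t2 + 2, by = 0.1),
      s0_grid = seq(cs$s0 * 0.99, cs$s0 * 1.01, by = cs$s0 * 0.001),
      c_grid = seq(0, 2 * cs$c0, by = cs$c0 / 40)
    )
    expect_lt(abs(fit@t2star_ms - grid$t2), 0.1 + 1e-9)
    expect_lte(fit@rss, grid$rss + 1e-6)  # LM at least as good as the lattice
  }
})

test_that("IP-only fitting is available for fatty livers", {
  te <- seq(2.4, 24, by = 2.4)
  phases <- classifyPhase(te, 1.5)
  s <- 1000 * exp(-te / 15) + 20
  # corrupt the OOP echoes with fat-water cancellation
  s_fatty <- ifelse(phases == "OPPOSED_PHASE", s * 0.6, s)
  fit_ip <- fitDecay(te, s_fatty, noise_floor = 20, phases = phases,
                     use_phases = "IP")
  expect_equal(fit_ip@n_used, 5L)
  expect_lt(abs(fit_ip@t2star_ms - 15) / 15, 0.01)
  expect_error(fitDecay(te, s_fatty, use_phases = "IP"), "phases")
})

test_that("licFromT2star reproduces the published conversions", {
  # 3 T worked example: T2* = 16.1 ms
  v <- licFromT2star(16.1, 3.0)
  expect_equal(v$lic_umol_g, 0.314 * 1000 / 16.1 - 0.96, tolerance = 1e-12)
  expect_equal(round(v$lic_umol_g, 2), 18.54)
  expect_equal(v$lic_rounded, 19)
  expect_false(v$approximate)
  # 1.5 T halving rule: T2* = 17.5 ms -> 34.9, published 34 (rounding-level)
  v15 <- licFromT2star(17.5, 1.5)
  expect_equal(v15$lic_umol_g, 0.314 * 2000 / 17.5 - 0.96, tolerance = 1e-12)
  expect_lt(abs(v15$lic_umol_g - 34.9), 0.05)
  expect_true(v15$approximate)
  expect_true("APPROXIMATE_LIC_1P5T" %in% v15$flags)
  # very long T2*: formula goes negative, clamped at zero with a flag
  inf_t2 <- licFromT2star(1e9, 3.0)
  expect_equal(inf_t2$lic_umol_g, 0)
  expect_true(inf_t2$clamped)
  expect_error(licFromT2star(10, 7.0), "field")
  expect_error(licFromT2star(-1, 3.0), "> 0")
})

test_that("licFromT2star is strictly decreasing in T2* at fixed field", {
  t2 <- seq(2, 60, by = 0.5)
  for (field in c(1.5, 3.0)) {
    lic <- vapply(t2, function(x) licFromT2star(x, field)$lic_umol_g,
                  numeric(1))
    expect_true(all(diff(lic) < 0))
  }
})

test_that("field consistency: T2* = 2*tau at 1.5T matches tau at 3T", {
  for (tau in c(2, 5, 10, 16.1, 25)) {
    l3 <- licFromT2star(tau, 3.0)$lic_umol_g
    l15 <- licFromT2star(2 * tau, 1.5)$lic_umol_g
    expect_equal(l15, l3, tolerance = 1e-12)
  }
})

test_that("iron grading uses the published LIC intervals", {
  expect_equal(gradeIron(c(19, 34, 95)), c("NONE", "NONE", "SEVERE"))
  expect_equal(gradeIron(36 - 1e-9), "NONE")
  expect_equal(gradeIron(36), "MILD")
  expect_equal(gradeIron(80), "MILD")
  expect_equal(gradeIron(80 + 1e-9), "SEVERE")
  expect_error(gradeIron(-5), ">= 0")
})

test_that("tissueDecayComparison detects the iron pattern against muscle", {
  ir <- tissueDecayComparison(liver = 6.2, spleen = 30, muscles = 25)
  expect_equal(ir$pattern, "IRON_PATTERN")
  expect_equal(ir$ordering[1], "liver")
  expect_equal(tissueDecayComparison(25, NULL, 25)$pattern, "NEUTRAL")
  expect_equal(tissueDecayComparison(30, NULL, 25)$pattern, "NO_IRON_PATTERN")
  # works on DecayFit objects too
  te <- seq(2.4, 24, 2.4)
  fl <- fitDecay(te, 1000 * exp(-te / 6.2) + 5)
  fm <- fitDecay(te, 800 * exp(-te / 25) + 5)
  expect_equal(tissueDecayComparison(fl, muscles = fm)$pattern, "IRON_PATTERN")
})

test_that("ironFromSeries runs the full arm on a synthetic series", {
  spec <- defaultPhantomSpec(field_t = 1.5, liver_t2star_ms = 6.2,
                             noise_sd = 20)
  gen <- makeMultiechoSeries(spec, seed = 12, noise_model = "rician")
  rois <- defaultROIs(spec)
  res <- ironFromSeries(gen$series, rois)
  expect_lt(abs(res@t2star_ms - 6.2) / 6.2, 0.05)
  expect_equal(res@grade, "SEVERE")
  expect_true(res@approximate)
  expect_equal(res@r2star_s * res@t2star_ms, 1000, tolerance = 1e-9)
  expect_error(ironFromSeries(gen$series, rois[c("SPLEEN", "NOISE")]),
               "missing ROI")
})
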