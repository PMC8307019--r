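test_that("generators are bit-identical under a fixed seed", {
  spec <- defaultPhantomSpec(noise_sd = 15)
  a <- makeMultiechoSeries(spec, seed = 123)
  b <- makeMultiechoSeries(spec, seed = 123)
  expect_identical(pixels(a$series[[3]]), pixels(b$series[[3]]))
  d1 <- makeDixonPair(spec, seed = 9)
  d2 <- makeDixonPair(spec, seed = 9)
  expect_identical(pixels(d1$pair@ip), pixels(d2$pair@ip))
  p1 <- makeHSAPhantomT1Map(noise_sd = 20, seed = 5)
  p2 <- makeHSAPhantomT1Map(noise_sd = 20, seed = 5)
  expect_identical(pixels(p1$frame), pixels(p2$frame))
  # different seed differs
  c1 <- makeMultiechoSeries(spec, seed = 124)
  expect_false(identical(pixels(a$series[[3]]), pixels(c1$series[[3]])))
})

test_that("every generator returns its ground truth", {
  spec <- defaultPhantomSpec(liver_t2star_ms = 12, liver_ff_percent = 8)
  g <- makeMultiechoSeries(spec, seed = 1)
  expect_equal(g$truth$liver_t2star_ms, 12)
  expect_equal(g$truth$layout$ff_percent[g$truth$layout$label == "LIVER"], 8)
  expect_equal(length(g$truth$te_ms), length(g$series))
  d <- makeDixonPair(spec, seed = 1)
  expect_true(all(c("w_map", "f_map", "ip_noiseless", "oop_noiseless") %in%
                    names(d$truth)))
  p <- makeHSAPhantomT1Map(seed = 1)
  expect_equal(p$truth$t1_true_ms, 1500 - 30 * p$truth$hsa_percent)
})

test_that("generated IP signal dominates OOP signal pre-noise", {
  # |W + F| >= |W - F| pixelwise for non-negative water/fat
  spec <- defaultPhantomSpec(liver_ff_percent = 30)
  d <- makeDixonPair(spec, te_ip = 4.8, te_oop = 2.4, seed = 2)
  w <- d$truth$w_map; f <- d$truth$f_map
  expect_true(all(abs(w + f) >= abs(w - f)))
})

test_that("phantom layout and TE validation reject bad inputs", {
  expect_error(makeHSAPhantomT1Map(radius = 20), "overlap")
  expect_error(makeHSAPhantomT1Map(concentrations = c(0, 25)), "\\[0, 20\\]")
  expect_error(makeHSAPhantomT1Map(true_slope = 10), "negative")
  spec <- defaultPhantomSpec()
  expect_error(makeDixonPair(spec, te_ip = 2.4, te_oop = 4.8),
               "classifies")
  expect_error(makeMultiechoSeries(spec, n_echoes = 3), ">= 4")
  # overlapping regions rejected by the class validity
  bad <- spec@layout
  bad$row[2] <- bad$row[1]; bad$col[2] <- bad$col[1]
  expect_error(PhantomSpec(layout = bad, dim = spec@dim, field_t = 1.5,
                           noise_sd = 0), "overlap")
})

test_that("field defaults follow the modelled acquisitions", {
  g15 <- makeMultiechoSeries(defaultPhantomSpec(field_t = 1.5, noise_sd = 0))
  expect_equal(length(g15$series), 10L)
  expect_equal(teTimes(g15$series), seq(2.4, 24, by = 2.4))
  g3 <- makeMultiechoSeries(defaultPhantomSpec(field_t = 3.0, noise_sd = 0))
  expect_equal(length(g3$series), 12L)
  expect_equal(teTimes(g3$series), seq(1.2, 14.4, by = 1.2), tolerance = 1e-12)
  # roles alternate OOP/IP starting opposed-phase
  roles <- vapply(seq_len(4), function(i) imageRole(g15$series[[i]]),
                  character(1))
  expect_equal(roles, c("OPPOSED_PHASE", "IN_PHASE", "OPPOSED_PHASE",
                        "IN_PHASE"))
})

test_that("noiseless zero-fat series recovers T2* to optimizer tolerance", {
  spec <- defaultPhantomSpec(field_t = 1.5, liver_t2star_ms = 17.5,
                             noise_sd = 0)
  gen <- makeMultiechoSeries(spec, seed = 1)
  fit <- fitDecay(gen$series, defaultROIs(spec)[["LIVER_IV"]])
  expect_lt(abs(fit@t2star_ms - 17.5) / 17.5, 1e-4)
})

test_that("3T no-iron series reproduces the LIC = 19 worked example", {
  spec <- defaultPhantomSpec(field_t = 3.0, liver_t2star_ms = 16.1,
                             noise_sd = 10)
  gen <- makeMultiechoSeries(spec, seed = 8, noise_model = "rician")
  res <- ironFromSeries(gen$series, defaultROIs(spec))
  expect_equal(res@lic_rounded, 19)
  expect_equal(res@grade, "NONE")
})

test_that("end-to-end severe steatosis grade is recovered from a Dixon pair", {
  spec <- defaultPhantomSpec(field_t = 1.5, liver_ff_percent = 24.8,
                             noise_sd = 10)
  spec@layout$t2star_ms[] <- 1e6
  gen <- makeDixonPair(spec, seed = 42)
  st <- steatosisFromPair(gen$pair, defaultROIs(spec))
  expect_equal(st@grade, "SEVERE")
  expect_lt(abs(st@ff_percent - 24.8), 1)
})

test_that("50% fat cancels the opposed-phase signal", {
  spec <- defaultPhantomSpec(field_t = 1.5, liver_ff_percent = 50,
                             noise_sd = 0)
  spec@layout$t2star_ms[] <- 1e6
  gen <- makeDixonPair(spec, seed = 1)
  liver_mask <- gen$truth$w_map > 0 & gen$truth$f_map == gen$truth$w_map
  expect_true(all(gen$truth$oop_noiseless[liver_mask] == 0))
})
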