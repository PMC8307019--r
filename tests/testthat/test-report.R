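test_that("cross-contamination warning rules follow the threshold table", {
  expect_equal(crossContaminationWarnings(3.1, 19), character(0))
  expect_setequal(crossContaminationWarnings(17.5, 95),
                  c("FAT_AFFECTS_T2STAR", "IRON_AFFECTS_FF", "OMIT_FF"))
  # boundary: both first warnings fire at the thresholds, OMIT_FF does not
  expect_setequal(crossContaminationWarnings(6.4, 36),
                  c("FAT_AFFECTS_T2STAR", "IRON_AFFECTS_FF"))
  expect_equal(crossContaminationWarnings(6.3, 35.9), character(0))
  expect_setequal(crossContaminationWarnings(1, 81), c("IRON_AFFECTS_FF", "OMIT_FF"))
})

test_that("no-disease synthetic subject reports clean grades and no warnings", {
  rois <- defaultROIs()
  spec_dx <- defaultPhantomSpec(field_t = 3.0, liver_ff_percent = 2,
                                noise_sd = 5)
  spec_dx@layout$t2star_ms[] <- 1e6
  dx <- makeDixonPair(spec_dx, seed = 21)
  spec_me <- defaultPhantomSpec(field_t = 3.0, liver_t2star_ms = 20,
                                noise_sd = 10)
  me <- makeMultiechoSeries(spec_me, seed = 22, noise_model = "rician")
  rep <- runPipeline("healthy", 3.0, rois, dixon = dx$pair,
                     series = me$series)
  expect_equal(rep@steatosis@grade, "NONE")
  expect_equal(rep@iron@grade, "NONE")
  expect_equal(rep@warnings, character(0))
})

test_that("severe steatosis with clean iron warns one way only", {
  rois <- defaultROIs()
  spec_dx <- defaultPhantomSpec(field_t = 1.5, liver_ff_percent = 24.8,
                                noise_sd = 5)
  spec_dx@layout$t2star_ms[] <- 1e6
  dx <- makeDixonPair(spec_dx, seed = 31)
  spec_me <- defaultPhantomSpec(field_t = 1.5, liver_t2star_ms = 40,
                                noise_sd = 10)
  me <- makeMultiechoSeries(spec_me, seed = 32, noise_model = "rician")
  rep <- runPipeline("fatty", 1.5, rois, dixon = dx$pair, series = me$series)
  expect_equal(rep@steatosis@grade, "SEVERE")
  expect_equal(rep@iron@grade, "NONE")
  expect_true("FAT_AFFECTS_T2STAR" %in% rep@warnings)
  expect_false("IRON_AFFECTS_FF" %in% rep@warnings)
  expect_false("OMIT_FF" %in% rep@warnings)
})

test_that("combined moderate steatosis + severe iron mirrors the worked case", {
  rois <- defaultROIs()
  spec_dx <- defaultPhantomSpec(field_t = 1.5, liver_ff_percent = 17.5,
                                noise_sd = 5)
  spec_dx@layout$t2star_ms[] <- 1e6
  dx <- makeDixonPair(spec_dx, seed = 41)
  spec_me <- defaultPhantomSpec(field_t = 1.5, liver_t2star_ms = 6.2,
                                noise_sd = 15)
  me <- makeMultiechoSeries(spec_me, seed = 42, noise_model = "rician")
  rep <- runPipeline("p5like", 1.5, rois, dixon = dx$pair, series = me$series)
  expect_equal(rep@steatosis@grade, "MODERATE")
  expect_equal(rep@iron@grade, "SEVERE")
  expect_true(all(c("FAT_AFFECTS_T2STAR", "IRON_AFFECTS_FF", "OMIT_FF",
                    "APPROXIMATE_LIC_1P5T") %in% rep@warnings))
})

test_that("fibrosis arm attaches T1 summary, HSA estimate and confound flags", {
  rois <- defaultROIs()
  cal <- fitCalibration(c(0, 5, 10, 15, 20), -30 * c(0, 5, 10, 15, 20) + 1500)
  rep <- runPipeline("fib", 3.0, rois, t1_means = c(1190, 1200, 1210),
                     calibration = cal)
  expect_equal(rep@t1$mean_ms, 1200)
  expect_equal(rep@t1$hsa_percent, (1200 - 1500) / -30, tolerance = 1e-9)
  expect_false(isTRUE(rep@t1$hsa_out_of_range))
  # T1 above the calibration intercept flags out-of-range
  rep2 <- runPipeline("fib2", 3.0, rois, t1_means = c(1600, 1600, 1600),
                      calibration = cal)
  expect_true("HSA_OUT_OF_RANGE" %in% rep2@warnings)
  expect_error(runPipeline("none", 3.0, rois), "no inputs")
})

test_that("report JSON round-trips losslessly and reruns are identical", {
  rois <- defaultROIs()
  spec_me <- defaultPhantomSpec(field_t = 1.5, liver_t2star_ms = 10,
                                noise_sd = 10)
  me <- makeMultiechoSeries(spec_me, seed = 5, noise_model = "rician")
  out1 <- file.path(tempdir(), "rep1")
  out2 <- file.path(tempdir(), "rep2")
  r1 <- runPipeline("s1", 1.5, rois, series = me$series, out_dir = out1)
  r2 <- runPipeline("s1", 1.5, rois, series = me$series, out_dir = out2)
  j1 <- file.path(out1, "report.json")
  j2 <- file.path(out2, "report.json")
  expect_identical(readLines(j1), readLines(j2))
  back <- readReport(j1)
  lst <- reportAsList(r1)
  expect_equal(back$iron$t2star_ms, lst$iron$t2star_ms)
  expect_equal(back$iron$lic_umol_g, lst$iron$lic_umol_g)
  expect_equal(back$subject_id, lst$subject_id)
  expect_equal(unlist(back$warnings), unlist(lst$warnings))
  expect_true(file.exists(file.path(out1, "decay_curve.csv")))
  unlink(c(out1, out2), recursive = TRUE)
})
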