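test_that("calibration fits exact lines and round-trips standards", {
  lv <- c(2.5, 5, 10, 25, 50, 100, 200)
  cur <- fit_calibration(lv, 2 * lv, analyte = "glucose", unit = "uM")
  expect_equal(cur$slope, 2)
  expect_equal(cur$intercept, 0, tolerance = 1e-12)
  expect_equal(cur$r_squared, 1)
  expect_equal(cur$range, c(2.5, 200))
  ## noiseless round trip: back-predicted levels equal the standards
  q <- quantify(predict(cur, lv), cur)
  expect_equal(q$quantity, lv, tolerance = 1e-10)
  expect_error(fit_calibration(c(1, 2), c(1, 2)), "at least 3")
  expect_error(fit_calibration(c(1, 1, 1), c(1, 2, 3)), "distinct")
  expect_warning(fit_calibration(c(0, 1, 2, 3), c(0, 2, 1.2, 3.4)), "R\\^2")
})

test_that("noisy calibration recovers the slope within 5% across seeds", {
  lv <- c(2.5, 5, 10, 25, 50, 100, 200)
  set.seed(123)
  slopes <- replicate(100, {
    resp <- 3 * lv * (1 + rnorm(length(lv), sd = 0.02))
    suppressWarnings(fit_calibration(lv, resp)$slope)
  })
  expect_true(all(abs(slopes / 3 - 1) < 0.05))
})

test_that("quantification is linear, clamped, and extrapolation-flagged", {
  cur <- fit_calibration(c(0, 1, 2), c(0.1, 1.1, 2.1))
  expect_equal(quantify(cur$intercept, cur)$quantity, 0)
  mid <- predict(cur, 1)
  expect_equal(quantify(mid, cur)$quantity, 1, tolerance = 1e-12)
  ## dilution and mass scaling
  expect_equal(quantify(mid, cur, dilution = 5)$quantity, 5, tolerance = 1e-12)
  expect_equal(quantify(mid, cur, mass = 2)$quantity, 0.5, tolerance = 1e-12)
  neg <- quantify(cur$intercept - 1, cur)
  expect_equal(neg$quantity, 0)
  expect_match(neg$flag, "clamped")
  far <- quantify(predict(cur, 10), cur)
  expect_match(far$flag, "extrapolated")
})

test_that("acetyl-bromide lignin follows Beer-Lambert exactly", {
  expect_equal(acetyl_bromide_lignin(0, 0.005, 0.005), 0)
  hand <- 100 * (0.910 / 18.19509) * 0.005 / 0.005
  expect_equal(acetyl_bromide_lignin(0.910, mass_g = 0.005, volume_l = 0.005),
               hand, tolerance = 1e-9)
  base <- acetyl_bromide_lignin(0.5, 0.005, 0.005)
  expect_equal(acetyl_bromide_lignin(0.5, 0.005, 0.010), 2 * base)
  expect_equal(acetyl_bromide_lignin(0.5, 0.010, 0.005), base / 2)
  expect_equal(acetyl_bromide_lignin(1.0, 0.005, 0.005), 2 * base)
  expect_equal(acetyl_bromide_lignin(0.5, 0.005, 0.005, path_cm = 2), base / 2)
  expect_error(acetyl_bromide_lignin(0.5, 0, 0.005), "positive")
  expect_error(acetyl_bromide_lignin(-0.1, 0.005, 0.005), "nonnegative")
})

test_that("saccharification series subtracts T0 and floors negatives", {
  glu <- fit_calibration(c(0, 0.5, 1, 1.5, 2), c(0.02, 0.52, 1.02, 1.52, 2.02),
                         analyte = "glucose", unit = "mg")
  flat <- setNames(rep(predict(glu, 0.8), 4), c(0, 24, 48, 72))
  out <- saccharification_efficiency(flat, glu, mass_mg = 5)
  expect_equal(out$net_release, rep(0, 4))
  ramp <- setNames(predict(glu, c(0.2, 0.5, 0.9, 1.4)), c(0, 24, 48, 72))
  out2 <- saccharification_efficiency(ramp, glu, mass_mg = 5)
  expect_true(all(diff(out2$net_release) >= 0))
  expect_equal(out2$net_release[4], (1.4 - 0.2) / 5, tolerance = 1e-10)
  ## dip below T0 is floored and flagged
  dip <- setNames(predict(glu, c(0.5, 0.3, 0.6, 0.7)), c(0, 24, 48, 72))
  out3 <- saccharification_efficiency(dip, glu, mass_mg = 5)
  expect_equal(out3$net_release[2], 0)
  expect_match(out3$flag[2], "floored")
  ## missing timepoint -> NA; absent T0 -> error
  part <- setNames(predict(glu, c(0.2, 0.9)), c(0, 48))
  out4 <- saccharification_efficiency(part, glu, mass_mg = 5)
  expect_true(is.na(out4$net_release[out4$time_h == 24]))
  expect_error(saccharification_efficiency(setNames(1, 24), glu, 5), "T0")
})

test_that("analyte tables round-trip and reject unit mismatches", {
  tab <- simulate_chem_dataset(seed = 6)$table
  tab$unit <- "nmol/mg"
  path <- withr::local_tempfile(fileext = ".tsv")
  write_analyte_table(tab, path)
  back <- read_analyte_table(path)
  expect_equal(back$quantity, tab$quantity)
  tab$unit[1] <- "ug/mg"
  write_analyte_table(tab, path)
  expect_error(read_analyte_table(path), "inconsistent units")
})
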