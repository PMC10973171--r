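test_that("single-reading Beer-Lambert arithmetic is exact", {
  mac <- fakeMac(1e6, mw = 3.2e5)
  rep0 <- concentrationFromA260(0, mac)
  expect_identical(rep0@molar_nM, 0)
  expect_identical(rep0@mass_ng_ul, 0)
  rep <- concentrationFromA260(0.25, mac, dilution = 20)
  expect_equal(rep@molar_nM, 5000, tolerance = 1e-12)
  # doubling the absorbance doubles every concentration field
  rep2 <- concentrationFromA260(0.5, mac, dilution = 20)
  expect_equal(rep2@molar_nM, 2 * rep@molar_nM, tolerance = 1e-12)
  expect_equal(rep2@mass_ng_ul, 2 * rep@mass_ng_ul, tolerance = 1e-12)
  expect_equal(rep2@legacy_ug_ml, 2 * rep@legacy_ug_ml, tolerance = 1e-12)
  # path length halves the concentration at fixed absorbance
  repl <- concentrationFromA260(0.25, mac, dilution = 20, path_length = 2)
  expect_equal(repl@molar_nM, rep@molar_nM / 2, tolerance = 1e-12)
  expect_error(concentrationFromA260(-1, mac),
               class = "rnaMAC_validation_error")
  expect_error(concentrationFromA260(1, fakeMac(1e6), dilution = 0.5),
               class = "rnaMAC_validation_error")
})

test_that("noise-free dilution series is recovered exactly with r = 1", {
  s <- randomSequence(800, seed = 31)
  mac <- macResult(seqComposition(s, "cap1"), TBL)
  ser <- simulateSeries(mac, stock_nM = 700, cv = 0, seed = 1)
  rep <- fitDilutionSeries(ser, mac)
  expect_equal(rep@molar_nM, 700, tolerance = 1e-9)
  expect_equal(rep@fit$r, 1, tolerance = 1e-9)
  expect_equal(rep@fit$intercept, 0, tolerance = 1e-9)
  expect_false(rep@fit$intercept_warning)
})

test_that("single-point series falls back to the direct computation", {
  mac <- fakeMac(5e5)
  ser <- dilutionSeries(10, 0.4)
  rep <- fitDilutionSeries(ser, mac)
  direct <- concentrationFromA260(0.4, mac, dilution = 10)
  expect_equal(rep@molar_nM, direct@molar_nM, tolerance = 1e-12)
  expect_length(rep@fit, 0)
})

test_that("baseline offsets trigger the intercept warning", {
  mac <- fakeMac(1e6)
  dil <- rep(c(2, 4, 8, 16), each = 2)
  clean <- 1e6 * (500e-9) / dil
  expect_warning(fitDilutionSeries(dilutionSeries(dil, clean + 0.02), mac),
                 "intercept")
  expect_silent(fitDilutionSeries(dilutionSeries(dil, clean), mac))
})

test_that("pooled and mean-replicate regressions agree on balanced data", {
  mac <- fakeMac(8e5)
  ser <- simulateSeries(mac, stock_nM = 400, replicates = 3, cv = 0.02,
                        seed = 9)
  r1 <- fitDilutionSeries(ser, mac)
  r2 <- fitDilutionSeries(ser, mac, pooled = TRUE)
  # balanced design: identical OLS slope whether replicates are averaged
  expect_equal(r1@molar_nM, r2@molar_nM, tolerance = 1e-9)
})

test_that("series validation rejects bad measurements", {
  expect_error(dilutionSeries(c(2, 4), c(0.1, -0.2)), "a260")
  expect_error(dilutionSeries(c(0.5, 4), c(0.1, 0.2)), "dilution")
  expect_error(dilutionSeries(numeric(0), numeric(0)), "at least one")
})

test_that("coefficient calibration recovers exact synthetic data", {
  conc <- seq(2e-5, 1e-4, length.out = 8)
  fit <- fitBeerLambert(conc, 9000 * conc)
  expect_equal(fit$epsilon_hat, 9000, tolerance = 1e-9)
  expect_gt(fit$r, 0.9999)
  # path length scales the coefficient
  fit2 <- fitBeerLambert(conc, 9000 * conc, path_length = 0.5)
  expect_equal(fit2$epsilon_hat, 18000, tolerance = 1e-9)
  expect_error(fitBeerLambert(rep(1e-5, 4), runif(4)), "degenerate",
               class = "rnaMAC_validation_error")
  expect_error(fitBeerLambert(conc, conc[-1]), "equal length",
               class = "rnaMAC_validation_error")
  expect_warning(fitBeerLambert(c(1e-4, 2e-4), c(0.9, 1.8)), "linear range")
})

test_that("calibration slope is unbiased under small noise", {
  conc <- seq(2e-5, 1e-4, length.out = 8)
  est <- vapply(1:100, function(seed) {
    set.seed(seed)
    abs <- 9000 * conc * (1 + rnorm(8, 0, 0.005))
    fitBeerLambert(conc, abs)$epsilon_hat
  }, 0)
  expect_lt(abs(median(est) - 9000) / 9000, 0.005)
})

test_that("totals multiply concentrations by the stock volume", {
  mac <- fakeMac(1e6, mw = 3.2e5)
  rep <- totals(concentrationFromA260(1, mac, dilution = 1000), 100)
  expect_equal(rep@total_umol, rep@molar_nM * 100 * 1e-9, tolerance = 1e-12)
  expect_equal(rep@total_ug, rep@mass_ng_ul * 100 * 1e-3, tolerance = 1e-12)
  # unit arithmetic anchors: 1000 nM over 100 uL is 1e-4 umol;
  # 50 ng/uL over 100 uL is 5 ug
  anchor <- totals(.quantReportForTest(1000, fakeMac(1e6, mw = 5e4)), 100)
  expect_equal(anchor@total_umol, 1e-4, tolerance = 1e-12)
  anchor2 <- totals(.quantReportForTest(1000, fakeMac(1e6, mw = 5e4)), 100)
  expect_equal(anchor2@mass_ng_ul, 50, tolerance = 1e-12)
  expect_equal(anchor2@total_ug, 5, tolerance = 1e-12)
  zero <- totals(concentrationFromA260(0, mac), 50)
  expect_identical(zero@total_umol, 0)
  expect_identical(zero@total_ug, 0)
  expect_error(totals(rep, 0), class = "rnaMAC_validation_error")
})

test_that("modified construct quantified with its own MAC matches the
           unmodified isosequence at ratio-scaled absorbance", {
  s <- randomSequence(500, seed = 77)
  comp <- seqComposition(s, "cap1")
  sch <- modScheme("U", "m1Y")
  macU <- macResult(comp, TBL)
  macM <- macResult(applyScheme(comp, sch), TBL)
  ratio <- macOf(macM) / macOf(macU)
  a <- 0.42
  repU <- concentrationFromA260(a, macU, dilution = 10)
  repM <- concentrationFromA260(a * ratio, macM, dilution = 10)
  expect_equal(repM@molar_nM, repU@molar_nM, tolerance = 1e-9)
})
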