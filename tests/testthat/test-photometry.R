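test_that("mac260 sums residue coefficients plus the cap contribution", {
  expect_identical(mac260(seqComposition(""), TBL), 0)
  expect_identical(mac260(composition(c(U = 1)), TBL),
                   getNucleoside(TBL, "U")$eps_260)
  cap <- getCap(TBL, "cap1")$eps_260_add
  expect_equal(mac260(seqComposition("AAAA", "cap1"), TBL),
               4 * getNucleoside(TBL, "A")$eps_260 + cap)
  expect_error(mac260(composition(c(ZZ = 1)), TBL), "ZZ",
               class = "rnaMAC_lookup_error")
})

test_that("mac260 agrees with the per-residue summation oracle", {
  for (i in 1:50) {
    s <- randomSequence(sample(1:500, 1), seed = i)
    cap <- sample(c("none", "cap0", "cap1"), 1)
    expect_equal(mac260(seqComposition(s, cap), TBL),
                 oracleMac260(s, TBL, cap), tolerance = 1e-9)
  }
})

test_that("mac260 is additive over concatenation and linear in fraction", {
  s1 <- randomSequence(200, seed = 21)
  s2 <- randomSequence(300, seed = 22)
  expect_equal(mac260(seqComposition(paste0(s1, s2)), TBL),
               mac260(seqComposition(s1), TBL) +
                 mac260(seqComposition(s2), TBL), tolerance = 1e-12)
  comp <- seqComposition(s1)
  m0 <- mac260(comp, TBL)
  m1 <- mac260(applyScheme(comp, modScheme("U", "m1Y", 1)), TBL)
  for (f in c(0, 0.123, 0.5, 0.87, 1)) {
    mf <- mac260(applyScheme(comp, modScheme("U", "m1Y", f)), TBL)
    expect_equal(mf, (1 - f) * m0 + f * m1, tolerance = 1e-12)
  }
})

test_that("molecular weight matches atomic-mass oracles and scales affinely", {
  # independent atomic-mass sums (average masses):
  adenosine <- 10 * 12.011 + 13 * 1.008 + 5 * 14.007 + 4 * 15.999  # C10H13N5O4
  amp <- adenosine + 79.980                                        # +HPO3
  compA <- composition(c(A = 1))
  expect_equal(molecularWeight(compA, TBL, "hydroxyl"), adenosine,
               tolerance = 0.02)
  expect_equal(molecularWeight(compA, TBL, "monophosphate"), amp,
               tolerance = 0.02)
  expect_equal(molecularWeight(compA, TBL, "triphosphate") -
                 molecularWeight(compA, TBL, "monophosphate"),
               2 * 79.980, tolerance = 1e-9)
  # affine in n with slope residue_mass(A)
  rm_A <- getNucleoside(TBL, "A")$residue_mass
  for (n in c(1, 10, 137)) {
    expect_equal(molecularWeight(composition(c(A = n)), TBL, "monophosphate"),
                 n * rm_A + 18.015, tolerance = 1e-9)
  }
  # cap1 vs cap0 differ by exactly one methyl group
  c0 <- molecularWeight(seqComposition("ACGU", "cap0"), TBL)
  c1 <- molecularWeight(seqComposition("ACGU", "cap1"), TBL)
  expect_equal(c1 - c0, 14.03, tolerance = 0.01)
})

test_that("mass extinction is consistent with MAC and MW on all fixtures", {
  for (i in 1:10) {
    s <- randomSequence(sample(10:1000, 1), seed = 100 + i)
    res <- macResult(seqComposition(s, sample(c("none", "cap0", "cap1"), 1)),
                     TBL)
    expect_equal(massExtinction(res) * macOf(res) / molWeight(res), 1000,
                 tolerance = 1e-9)
  }
})

test_that("hypochromicity ratio collapses to the coefficient ratio on poly-U", {
  sch <- modScheme("U", "m1Y")
  expect_identical(hypochromicityRatio("ACGU", modScheme(), "none", TBL), 1)
  expected <- getNucleoside(TBL, "m1Y")$eps_260 /
    getNucleoside(TBL, "U")$eps_260
  expect_equal(hypochromicityRatio("UUUU", sch, "none", TBL), expected,
               tolerance = 1e-12)
  expect_equal(underestimationPercent("UUUU", sch, "none", TBL), 39.8,
               tolerance = 0.05)
  expect_identical(underestimationPercent("ACGACG", sch, "none", TBL), 0)
  expect_error(hypochromicityRatio("", sch, "none", TBL), "undefined",
               class = "rnaMAC_validation_error")
})

test_that("hypochromicity deepens with uridine content", {
  sch <- modScheme("U", "m1Y")
  fracs <- c(0.1, 0.2, 0.3, 0.4, 0.5)
  ratios <- vapply(seq_along(fracs), function(i) {
    f <- fracs[i]
    s <- randomSequence(600, c(A = (1 - f) / 3, C = (1 - f) / 3,
                               G = (1 - f) / 3, U = f), seed = 400 + i)
    hypochromicityRatio(s, sch, "none", TBL)
  }, 0)
  expect_true(all(diff(ratios) < 0))
  expect_true(all(ratios <= 1))
})

test_that("legacy constant estimate follows 40 x A260 x dilution", {
  expect_identical(legacyMassConcentration(1.0, 1), 40)
  expect_identical(legacyMassConcentration(0, 17), 0)
  expect_identical(legacyMassConcentration(0.5, 2), 40)
  expect_error(legacyMassConcentration(-0.1), class = "rnaMAC_validation_error")
  expect_error(legacyMassConcentration(1, 0.5),
               class = "rnaMAC_validation_error")
})
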