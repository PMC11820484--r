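test_that("doublet-ratio estimator inverts the printed control enrichment", {
  # E4/E2 = 0.8210 on the 8-subunit palmitate model gives p = 0.19
  ev <- binomialExcessVector(0.4, 0.8210 / (3.5 + 0.8210), 8)
  pe <- estimatePrecursorEnrichment(ev, polymerModel("palmitate"))
  expect_equal(round(pe$p, 2), 0.19)
  expect_equal(pe$p, pe$ratio / (3.5 + pe$ratio), tolerance = 1e-15)
})

test_that("zero E4 maps to zero enrichment; nonpositive E2 is an error", {
  fr <- FragmentDefinition("poly", 0, 16, maxShift = 16)
  e <- numeric(16); e[2] <- 0.1
  ev <- new("ExcessVector", fragment = fr, sampleId = "s", excesses = e,
            flags = character())
  expect_equal(estimatePrecursorEnrichment(ev, polymerModel(8))$p, 0)
  e0 <- numeric(16)
  ev0 <- new("ExcessVector", fragment = fr, sampleId = "s", excesses = e0,
             flags = character())
  expect_error(estimatePrecursorEnrichment(ev0, polymerModel(8)),
               "no detectable new synthesis")
  # negative E4 beyond the noise floor: clamped with a flag
  en <- e; en[4] <- -0.02
  evn <- new("ExcessVector", fragment = fr, sampleId = "s", excesses = en,
             flags = character())
  pe <- estimatePrecursorEnrichment(evn, polymerModel(8))
  expect_equal(pe$p, 0)
  expect_match(pe$flags, "clamped")
})

test_that("(p, FNS) are recovered exactly over the noiseless grid", {
  for (N in c(8L, 9L)) {
    model <- polymerModel(N)
    for (p in seq(0.05, 0.45, by = 0.10)) {
      for (fns in seq(0.05, 0.95, by = 0.15)) {
        ev <- binomialExcessVector(fns, p, N)
        pe <- estimatePrecursorEnrichment(ev, model)
        fe <- estimateFns(ev, pe$p, model)
        expect_equal(pe$p, p, tolerance = 1e-10)
        expect_equal(fe$fns, fns, tolerance = 1e-10)
        expect_equal(fe$fnsFromE4, fns, tolerance = 1e-10)
      }
    }
  }
})

test_that("estimators recover truth from the simulator (round trip)", {
  for (fa in c("palmitate", "stearate", "oleate")) {
    model <- polymerModel(fa)
    mid <- simulateFattyAcidMid(0.37, 0.22, model)
    res <- midaAnalysis(excessMid(mid, unlabeledBaselineMid(fragmentOf(mid))))
    expect_equal(precursorEnrichment(res), 0.22, tolerance = 1e-12)
    expect_equal(fns(res), 0.37, tolerance = 1e-12)
  }
})

test_that("group-mean enrichment is recovered within 0.02 under 2% noise", {
  set.seed(2024)
  model <- polymerModel("palmitate")
  base <- unlabeledBaselineMid(fragmentOf(simulateFattyAcidMid(0, 0.19, model)))
  ps <- replicate(6, {
    mid <- simulateFattyAcidMid(0.40, 0.19, model, noiseCv = 0.02)
    precursorEnrichment(midaAnalysis(excessMid(mid, base)))
  })
  expect_lt(abs(mean(ps) - 0.19), 0.02)
})

test_that("E4/E2 is strictly increasing in p, so the estimator is well posed", {
  ratios <- vapply(seq(0.02, 0.6, by = 0.02), function(p) {
    ev <- binomialExcessVector(0.5, p, 8)
    e <- excesses(ev)
    unname(e[4] / e[2])
  }, numeric(1))
  expect_true(all(diff(ratios) > 0))
})

test_that("FNS is invariant to overall pool-size scaling", {
  # scaling all intensities leaves fractional excesses, hence FNS, unchanged
  model <- polymerModel("stearate")
  mid <- simulateFattyAcidMid(0.3, 0.2, model)
  fr <- fragmentOf(mid)
  for (s in c(1, 10, 1e4)) {
    scaled <- normalizeMid(abundances(mid) * s, fr)
    res <- midaAnalysis(excessMid(scaled, unlabeledBaselineMid(fr)), model)
    expect_equal(fns(res), 0.3, tolerance = 1e-12)
  }
})

test_that("an impossible singly-labeled excess triggers the model-violation error", {
  fr <- FragmentDefinition("poly", 0, 16, maxShift = 16)
  e <- numeric(16); e[2] <- 0.9; e[4] <- 0.01
  ev <- new("ExcessVector", fragment = fr, sampleId = "s", excesses = e,
            flags = character())
  p <- estimatePrecursorEnrichment(ev, polymerModel(8))$p
  expect_error(estimateFns(ev, p, polymerModel(8)), "model violation")
  expect_error(estimateFns(ev, 0, polymerModel(8)),
               "inconsistent enrichment")
})

test_that("desaturation and elongation indices reproduce the study table", {
  expect_equal(round(desaturationIndex(0.306, 0.200), 2), 1.53)
  expect_equal(round(desaturationIndex(0.020, 0.200), 2), 0.10)
  expect_equal(desaturationIndex(0.2, 0.2), 1.0)
  expect_true(is.na(desaturationIndex(0.3, 0)))
  expect_equal(round(elongationIndex(0.180, 0.250), 2), 0.72)
  expect_equal(round(elongationIndex(0.098, 0.250), 2), 0.39)
  expect_equal(elongationIndex(0, 0.25), 0)
  expect_true(is.na(elongationIndex(0.1, 0)))
})

test_that("fatty-acid profile returns percent of total", {
  expect_equal(unname(fattyAcidProfile(c("16:0" = 7))), 100)
  expect_equal(unname(fattyAcidProfile(c(a = 2, b = 1, c = 1))),
               c(50, 25, 25))
  # composition fixture with a 1.81% linoleate share
  areas <- c("16:0" = 30.19, "16:1n-7" = 8, "18:0" = 20, "18:1n-9" = 25,
             "18:1n-7" = 15, "18:2n-6" = 1.81)
  prof <- fattyAcidProfile(areas)
  expect_equal(sum(prof), 100, tolerance = 0.1)
  expect_equal(unname(prof[["18:2n-6"]]), 1.81, tolerance = 1e-6)
  expect_error(fattyAcidProfile(c(a = 0, b = 0)), "zero")
})
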