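test_that("SIGmn reproduces the printed glycogen and ribose enrichments", {
  expect_equal(sigmnValue(sigmn(simulateUnitLabeling(0.275, 6))), 1.65,
               tolerance = 1e-12)
  expect_equal(sigmnValue(sigmn(simulateUnitLabeling(0.308, 5))), 1.54,
               tolerance = 1e-12)
  expect_equal(sigmnValue(sigmn(simulateUnitLabeling(0, 6))), 0,
               tolerance = 1e-12)
})

test_that("SIGmn is linear in mixtures and bounded by the carbon count", {
  fr <- fragmentDefinition("ribose")
  mixAt <- function(f) simulateUnitLabeling(f, 5)
  s <- function(f) sigmnValue(sigmn(mixAt(f)))
  # linearity: mixture weight enters linearly
  expect_equal(s(0.5), (s(0.2) + s(0.8)) / 2, tolerance = 1e-12)
  for (f in seq(0, 1, by = 0.25)) {
    v <- s(f)
    expect_gte(v, 0); expect_lte(v, 5 + 1e-12)
  }
  expect_equal(s(1), 5, tolerance = 1e-12)  # bound attained iff fully labeled
})

test_that("SIGmn is invariant to the convolution/correction round trip", {
  mid <- simulateUnitLabeling(0.275, 6, applyNaturalAbundance = TRUE)
  M <- buildCorrectionMatrix(fragmentOf(mid))
  corrected <- correctNaturalAbundance(mid, M)
  expect_equal(sigmnValue(sigmn(corrected)), 1.65, tolerance = 1e-6)
})

test_that("group table mirrors the study layout and flags degenerate cases", {
  des <- studyDesign(data.frame(
    sample_id = c("a1", "a2", "b1", "b2"),
    group = c("control", "control", "oa_steatosis", "oa_steatosis")))
  mk <- function(f, sid) sigmn(simulateUnitLabeling(f, 6, sampleId = sid))
  # identical groups: ANOVA is degenerate (all values equal), flagged
  same <- list(mk(0.275, "a1"), mk(0.275, "a2"), mk(0.275, "b1"),
               mk(0.275, "b2"))
  outSame <- enrichmentGroupTable(same, des)
  expect_true(outSame$anova$degenerate)
  # complete separation with vanishing spread: p below machine noise
  set.seed(5)
  apart <- list(mk(0.0, "a1"), mk(0.001, "a2"), mk(0.83, "b1"),
                mk(0.831, "b2"))
  outApart <- enrichmentGroupTable(apart, des)
  expect_lt(outApart$anova$p, 1e-6)
  expect_equal(outApart$table$mean[outApart$table$group == "oa_steatosis"],
               mean(c(0.83, 0.831) * 6), tolerance = 1e-12)
  # empty group errors
  desBad <- studyDesign(data.frame(sample_id = c("a1", "a2", "x1"),
                                   group = c("control", "control",
                                             "oa_steatosis")))
  expect_error(
    enrichmentGroupTable(list(mk(0.2, "a1"), mk(0.2, "a2")), desBad),
    "sample|group")
})

test_that("seeded six-group study recovers group SIGmn means within 2 SE", {
  study <- simulateStudy(smallStudyConfig(seed = 17, replicates = 6,
                                          midCv = 0.02, absCv = 0))
  res <- runPipeline(study)
  truth <- unique(study$truth$perSample[, c("group", "sigmn_glycogen")])
  tab <- res$enrichmentGroups$glucose_glycogen$table
  for (g in truth$group) {
    row <- tab[tab$group == g, ]
    se <- row$sd / sqrt(row$n)
    # renormalization after multiplicative noise introduces a small bias,
    # so allow 1% of truth on top of the sampling band
    tol <- 2 * se + 0.01 * truth$sigmn_glycogen[truth$group == g]
    expect_lt(abs(row$mean - truth$sigmn_glycogen[truth$group == g]),
              tol, label = g)
  }
})
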