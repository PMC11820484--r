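test_that("PC/PDH ratio reproduces the printed group values", {
  cases <- list(c(0.300, 0.3665, 1.35),   # untreated control
                c(0.400, 0.3852, 0.94),   # OA steatosis
                c(0.300, 0.3991, 1.55))   # morin
  for (cs in cases) {
    pair <- simulateGlutamateFragments(cs[1], cs[2])
    expect_equal(round(pcPdh(pcPdhRatio(pair)), 2), cs[3])
  }
})

test_that("ratio equals the labeling-odds expression over a parameter grid", {
  for (a in seq(0.1, 0.6, by = 0.1)) {
    for (b in seq(0.1, 0.6, by = 0.1)) {
      pair <- simulateGlutamateFragments(a, b)
      expect_equal(pcPdh(pcPdhRatio(pair)), b * (1 - a) / (a * (1 - b)),
                   tolerance = 1e-12)
      # single-turn identity: m2(198) - m2(152) = a(1 - b)
      expect_equal(abundances(pair$mid198)[["m2"]] -
                   abundances(pair$mid152)[["m2"]], a * (1 - b),
                   tolerance = 1e-12)
    }
  }
})

test_that("ratio is increasing in PC labeling and decreasing in PDH labeling", {
  r <- function(a, b) pcPdh(pcPdhRatio(simulateGlutamateFragments(a, b)))
  bGrid <- seq(0.05, 0.9, by = 0.05)
  expect_true(all(diff(vapply(bGrid, function(b) r(0.3, b),
                              numeric(1))) > 0))
  aGrid <- seq(0.05, 0.9, by = 0.05)
  expect_true(all(diff(vapply(aGrid, function(a) r(a, 0.4),
                              numeric(1))) < 0))
})

test_that("pure-PDH labeling gives ratio 0; missing PDH signal is undefined", {
  res <- pcPdhRatio(simulateGlutamateFragments(0.4, 0))
  expect_equal(pcPdh(res), 0)
  expect_true(isDefined(res))
  resU <- pcPdhRatio(simulateGlutamateFragments(0, 0.4))
  expect_false(isDefined(resU))
  expect_true(is.na(pcPdh(resU)))
  expect_match(paste(diagnostics(resU)$flags, collapse = " "), "no PDH")
})

test_that("natural-abundance convolution plus correction leaves the ratio unchanged", {
  a <- 0.300; b <- 0.3665
  pair <- simulateGlutamateFragments(a, b, applyNaturalAbundance = TRUE)
  corr <- function(mid) correctNaturalAbundance(
    mid, buildCorrectionMatrix(fragmentOf(mid)))
  cpair <- glutamateFragmentPair(corr(pair$mid152), corr(pair$mid198))
  expect_equal(pcPdh(pcPdhRatio(cpair)), b * (1 - a) / (a * (1 - b)),
               tolerance = 1e-6)
})

test_that("double-labeled isotopomers are carried in diagnostics, not the ratio", {
  a <- 0.3; b <- 0.4
  res <- pcPdhRatio(simulateGlutamateFragments(a, b))
  expect_equal(diagnostics(res)$m3_152, a * b, tolerance = 1e-12)
  expect_equal(diagnostics(res)$m4_198, a * b, tolerance = 1e-12)
})

test_that("group summary excludes undefined ratios and reports hand statistics", {
  des <- studyDesign(data.frame(
    sample_id = c("c1", "c2", "c3", "o1", "o2"),
    group = c("control", "control", "control", "oa_steatosis",
              "oa_steatosis")))
  mk <- function(a, b, sid) {
    pr <- simulateGlutamateFragments(a, b, sampleId = sid)
    pcPdhRatio(pr)
  }
  # control replicates engineered to ratios 1.0, 1.2, 1.4
  solveB <- function(a, r) r * a / (1 - a + r * a)
  res <- list(mk(0.3, solveB(0.3, 1.0), "c1"),
              mk(0.3, solveB(0.3, 1.2), "c2"),
              mk(0.3, solveB(0.3, 1.4), "c3"),
              mk(0.4, 0.3852, "o1"),
              mk(0, 0.4, "o2"))          # undefined, must be excluded
  tab <- pcPdhGroupSummary(res, des)
  ctrl <- tab[tab$group == "control", ]
  expect_equal(ctrl$mean, 1.2, tolerance = 1e-10)
  expect_equal(ctrl$sd, 0.2, tolerance = 1e-10)
  expect_equal(ctrl$n, 3L)
  oa <- tab[tab$group == "oa_steatosis", ]
  expect_equal(oa$n_excluded, 1L)
  expect_match(oa$flag, "fewer than 2")
})

test_that("identical replicates give zero spread and noisy ones track truth", {
  des <- studyDesign(data.frame(
    sample_id = c(paste0("c", 1:6), "o1", "o2"),
    group = c(rep("control", 6), rep("oa_steatosis", 2))))
  set.seed(99)
  res <- c(lapply(paste0("c", 1:6), function(sid)
    pcPdhRatio(simulateGlutamateFragments(0.300, 0.3665, noiseCv = 0.02,
                                          sampleId = sid))),
    lapply(c("o1", "o2"), function(sid)
      pcPdhRatio(simulateGlutamateFragments(0.400, 0.3852, sampleId = sid))))
  tab <- pcPdhGroupSummary(res, des)
  expect_lt(abs(tab$mean[tab$group == "control"] - 1.35), 0.05)
  expect_equal(tab$sd[tab$group == "oa_steatosis"], 0, tolerance = 1e-12)
})
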