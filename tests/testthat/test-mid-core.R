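test_that("normalizeMid produces exact proportions and rejects bad input", {
  fr <- FragmentDefinition("t2c", 100, 2, c(C = 2L), maxShift = 2)
  expect_equal(unname(abundances(normalizeMid(c(100, 0, 0), fr))),
               c(1, 0, 0))
  expect_equal(unname(abundances(normalizeMid(c(50, 25, 25), fr))),
               c(0.5, 0.25, 0.25))
  fr5 <- FragmentDefinition("t4c", 100, 4, c(C = 4L), maxShift = 4)
  expect_equal(unname(abundances(normalizeMid(c(3, 1, 1, 0, 0), fr5))),
               c(0.6, 0.2, 0.2, 0, 0))
  expect_error(normalizeMid(c(0, 0, 0), fr), "empty spectrum")
  expect_error(normalizeMid(c(1, -1, 0), fr), "negative")
  expect_error(normalizeMid(c(1, 1), fr), "expected 3")
})

test_that("every normalized MID sums to 1 within 1e-9", {
  set.seed(41)
  for (an in supportedAnalytes()) {
    fr <- fragmentDefinition(an)
    raw <- runif(maxShift(fr) + 1)
    expect_equal(sum(abundances(normalizeMid(raw, fr))), 1,
                 tolerance = 1e-9)
  }
})

test_that("correction matrix: identity for a bare skeleton with no 13C background", {
  fr <- FragmentDefinition("bare", 10, 2, integer(), maxShift = 2)
  M <- buildCorrectionMatrix(fr, list(C = c(1, 0)), tracerPurity = 1)
  expect_equal(unname(M), diag(3))
})

test_that("correction matrix C2 column 0 matches the hand expansion", {
  # (0.989 + 0.011 x)^2: m1 coefficient = 2 * 0.011 * 0.989
  fr <- FragmentDefinition("c2", 24, 2, c(C = 2L), maxShift = 2)
  M <- buildCorrectionMatrix(fr, list(C = c(0.989, 0.011)))
  expect_equal(M["m1", "x0"], 2 * 0.011 * 0.989, tolerance = 1e-15)
  expect_equal(M["m0", "x0"], 0.989^2, tolerance = 1e-15)
  expect_equal(M["m2", "x0"], 0.011^2, tolerance = 1e-15)
})

test_that("correction-matrix columns match exhaustive isotope enumeration", {
  ab <- naturalAbundances()
  frags <- list(
    FragmentDefinition("c2", 24, 2, c(C = 2L), maxShift = 3),
    FragmentDefinition("c3h4o2", 72, 3, c(C = 3L, H = 4L, O = 2L),
                       maxShift = 5),
    FragmentDefinition("c2h3no", 57, 2, c(C = 2L, H = 3L, N = 1L, O = 1L),
                       maxShift = 4),
    FragmentDefinition("c4f3", 97, 4, c(C = 4L, F = 3L), maxShift = 6)
  )
  for (fr in frags) {
    M <- buildCorrectionMatrix(fr, ab)
    for (j in 0:nSkeletonCarbons(fr)) {
      expect_equal(unname(M[, j + 1L]),
                   enumerateMidColumn(fr, j, ab),
                   tolerance = 1e-12,
                   label = sprintf("%s column %d", analyteName(fr), j))
    }
    expect_true(all(M >= 0))
    expect_true(all(colSums(M) <= 1 + 1e-12))
  }
})

test_that("forward convolution then correction is the identity (round trip)", {
  set.seed(7)
  for (an in supportedAnalytes()) {
    fr <- fragmentDefinition(an)
    M <- buildCorrectionMatrix(fr)
    x <- runif(maxShift(fr) + 1)
    x[seq(nSkeletonCarbons(fr) + 2L, length.out = max(0, maxShift(fr) -
          nSkeletonCarbons(fr)))] <- 0  # impossible label counts
    ideal <- normalizeMid(x, fr)
    meas <- convolveNaturalAbundance(ideal, M)
    back <- correctNaturalAbundance(meas, M)
    expect_equal(unname(abundances(back)), unname(abundances(ideal)),
                 tolerance = 1e-8, label = an)
  }
})

test_that("correction recovers pure-unlabeled from the column-0 envelope", {
  fr <- fragmentDefinition("ribose")
  M <- buildCorrectionMatrix(fr)
  meas <- normalizeMid(M[, 1L], fr)
  out <- abundances(correctNaturalAbundance(meas, M))
  expect_equal(unname(out), c(1, rep(0, maxShift(fr))), tolerance = 1e-10)
})

test_that("excess vectors: self-baseline is zero; subtraction is exact", {
  fr <- fragmentDefinition("glucose_glycogen")
  base <- unlabeledBaselineMid(fr)
  expect_equal(unname(excesses(excessMid(base, base))),
               rep(0, maxShift(fr)))
  a <- normalizeMid(c(0.80, 0, 0.15, 0, 0, 0.05, 0, 0), fr, "s")
  b <- normalizeMid(c(0.90, 0, 0.05, 0, 0, 0.05, 0, 0), fr, "b")
  e <- excesses(excessMid(a, b))
  expect_equal(unname(e[2]), 0.10, tolerance = 1e-12)
  # algebraic identity: sum_{i>=1} E_i = -(E0 difference)
  expect_equal(sum(e), -(abundances(a)[1] - abundances(b)[1]),
               tolerance = 1e-12, ignore_attr = TRUE)
  frOther <- fragmentDefinition("ribose")
  expect_error(excessMid(a, unlabeledBaselineMid(frOther)),
               "fragment mismatch")
})

test_that("strongly negative excess entries are flagged, not dropped", {
  fr <- fragmentDefinition("ribose")
  hot <- normalizeMid(c(0.9, 0.1, 0, 0, 0, 0, 0), fr)
  cold <- normalizeMid(c(0.88, 0.12, 0, 0, 0, 0, 0), fr)
  ev <- excessMid(hot, cold)
  expect_match(ev@flags, "negative excess")
  expect_equal(unname(excesses(ev)[1]), -0.02, tolerance = 1e-12)
})
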