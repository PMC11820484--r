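# Independent oracles used across the suite. These deliberately avoid the
# package's convolution code paths.

# Brute-force natural-abundance envelope: enumerate every isotope
# assignment of every atom of the fragment (feasible for <= 12 atoms) and
# accumulate the probability of each total mass shift. `j` skeleton
# carbons carry tracer at the stated purity.
enumerateMidColumn <- function(fragment, j, abundances, tracerPurity = 0.99) {
  nSkel <- nSkeletonCarbons(fragment)
  stopifnot(j <= nSkel)
  ef <- elementalFormula(fragment)
  atomDists <- list()
  add <- function(d, times) for (i in seq_len(times))
    atomDists[[length(atomDists) + 1L]] <<- d
  add(c(1 - tracerPurity, tracerPurity), j)
  add(abundances$C, nSkel - j)
  for (el in names(ef)) {
    n <- ef[[el]]
    if (el == "C") n <- n - nSkel
    if (n > 0) add(abundances[[el]], n)
  }
  stopifnot(length(atomDists) <= 12)
  grid <- expand.grid(lapply(atomDists, function(d) seq_along(d) - 1L))
  probs <- apply(grid, 1, function(row)
    prod(mapply(function(d, s) d[s + 1L], atomDists, row)))
  shifts <- rowSums(grid)
  K <- maxShift(fragment)
  col <- numeric(K + 1L)
  for (k in 0:K) col[k + 1L] <- sum(probs[shifts == k])
  col
}

# Exact excess vector of a binomial polymerization mixture, built directly
# from the model definition (not via the simulator): a fraction `fns` of
# molecules is a polymer of N subunits each labeled (+2) with prob p.
binomialExcessVector <- function(fns, p, N, sampleId = "oracle") {
  K <- 2L * N
  fr <- midflux::FragmentDefinition(paste0("poly_N", N), 0L, K, maxShift = K)
  e <- numeric(K)
  for (k in 1:N) e[2L * k] <- fns * choose(N, k) * p^k * (1 - p)^(N - k)
  new("ExcessVector", fragment = fr, sampleId = sampleId, excesses = e,
      flags = character())
}

# default six-group config scaled for tests
smallStudyConfig <- function(seed = 1L, replicates = 2L, midCv = 0,
                             absCv = 0, applyNA = TRUE)
  simulationConfig(seed = seed, replicatesPerGroup = replicates,
                   midMultiplicativeCv = midCv, absorbanceCv = absCv,
                   applyNaturalAbundance = applyNA)
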