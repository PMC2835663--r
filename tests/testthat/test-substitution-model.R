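# Rate-matrix construction and equilibrium allele frequencies.

test_that("fixation flux factor has the neutral limit, identity and monotonicity", {
  expect_identical(fixationFluxFactor(0), 1)
  # series branch joins the direct formula smoothly
  expect_equal(fixationFluxFactor(1e-4), 1e-4 / (1 - exp(-1e-4)),
               tolerance = 1e-12)
  expect_equal(fixationFluxFactor(4), 4.0746294415, tolerance = 1e-9)
  S <- c(-8, -3, -0.5, -1e-6, 1e-6, 0.5, 3, 8)
  expect_equal(fixationFluxFactor(S) / fixationFluxFactor(-S), exp(S),
               tolerance = 1e-10)
  expect_true(all(diff(fixationFluxFactor(seq(-10, 10, by = 0.25))) > 0))
  expect_error(fixationFluxFactor(Inf), "finite")
  expect_error(fixationFluxFactor(NA_real_), "finite")
})

test_that("replacement rates reduce to mutation rates under neutrality", {
  rm <- rateMatrix(SiteModel(S = c(0, 0, 0, 0)))
  f <- replacementRates(rm)
  expect_equal(f[row(f) != col(f)], rep(1, 12))
  expect_true(all(abs(rowSums(generator(rm))) < 1e-12))
  # unequal neutral rates pass through unchanged
  m <- matrix(c(0, 2, 3, 0.5, 0, 1.5, 0.2, 0.7, 0), 3, 3, byrow = TRUE)
  f2 <- replacementRates(rateMatrix(SiteModel(S = c(1, 1, 1), mu = m,
                                              allowZeroRates = TRUE)))
  expect_equal(f2, m)
})

test_that("two-allele replacement rates match the selection asymmetry", {
  for (S in c(0.5, 2, 8)) {
    f <- replacementRates(rateMatrix(SiteModel(S = c(0, S))))
    expect_equal(f[1, 2], -S / (1 - exp(S)), tolerance = 1e-12)
    expect_equal(f[2, 1], S / (1 - exp(-S)), tolerance = 1e-12)
  }
  # strong-selection suppression of the deleterious direction
  f <- replacementRates(rateMatrix(SiteModel(S = c(0, 8))))
  expect_equal(f[1, 2], 8 * exp(-8) / (1 - exp(-8)), tolerance = 1e-12)
  expect_lt(f[1, 2], 3e-3)
})

test_that("equilibrium solves the stationary system and yields E", {
  eq <- equilibrium(SiteModel(S = c(0, 0, 0, 0)))
  expect_equal(stationaryFreqs(eq), rep(1 / 4, 4), tolerance = 1e-12)
  expect_equal(asymptoticDivergence(eq), 3 / 4, tolerance = 1e-12)

  for (S in c(-3, 0.5, 2, 6)) {
    eq2 <- equilibrium(SiteModel(S = c(0, S)))
    expect_equal(stationaryFreqs(eq2)[1], exp(S) / (exp(S) + 1),
                 tolerance = 1e-12)
  }

  eq3 <- equilibrium(SiteModel(S = c(0, 8, 8, 8)))
  expect_gt(stationaryFreqs(eq3)[1], 0.99)
  expect_lt(asymptoticDivergence(eq3), 0.02)
})

test_that("stationarity and detailed balance hold as properties", {
  set.seed(11)
  for (k in 1:20) {
    sym <- k %% 2 == 0
    m <- randomSiteModel(symmetric = sym)
    Q <- generator(rateMatrix(m))
    X <- stationaryFreqs(equilibrium(m))
    expect_lt(max(abs(X %*% Q)), 1e-10)
    if (sym) {
      f <- replacementRates(rateMatrix(m))
      expect_lt(max(abs(X * f - t(X * f))), 1e-10)
    }
  }
})

test_that("E is invariant under relabeling and shifting all S", {
  set.seed(3)
  S <- c(0, 1.3, 2.7, 5)
  m <- matrix(runif(16, 0.5, 1.5), 4, 4)
  m[lower.tri(m)] <- t(m)[lower.tri(m)]
  base <- asymptoticDivergence(equilibrium(SiteModel(S = S, mu = m)))
  perm <- c(3, 1, 4, 2)
  relab <- asymptoticDivergence(
    equilibrium(SiteModel(S = S[perm], mu = m[perm, perm])))
  expect_equal(relab, base, tolerance = 1e-12)
  shifted <- asymptoticDivergence(
    equilibrium(SiteModel(S = S + 2.5, mu = m)))
  expect_equal(shifted, base, tolerance = 1e-12)
})

test_that("two-allele E decreases strictly with |S|", {
  S <- c(0, 0.5, 1, 2, 4, 8)
  E <- vapply(S, function(s)
    asymptoticDivergence(equilibrium(SiteModel(S = c(0, s)))), numeric(1))
  expect_true(all(diff(E) < 0))
  Eneg <- vapply(-S, function(s)
    asymptoticDivergence(equilibrium(SiteModel(S = c(0, s)))), numeric(1))
  expect_equal(Eneg, E, tolerance = 1e-12)
})

test_that("reducible replacement graphs are refused with named alleles", {
  m <- matrix(0, 4, 4)
  m[1, 2] <- m[2, 1] <- 1   # {1,2} disconnected from {3,4}
  m[3, 4] <- m[4, 3] <- 1
  model <- SiteModel(S = rep(0, 4), mu = m, allowZeroRates = TRUE)
  expect_error(equilibrium(model), "\\{1,2\\}.*\\{3,4\\}")
  # zero rates are rejected outright unless explicitly allowed
  expect_error(SiteModel(S = rep(0, 4), mu = m), "allowZeroRates")
})

test_that("site models round-trip through the YAML config schema", {
  f <- tempfile(fileext = ".yaml")
  m1 <- SiteModel(S = c(0, 1, 2, 4))
  writeSiteModel(m1, f)
  back <- readSiteModel(f)
  expect_equal(selectionCoefficients(back), selectionCoefficients(m1))
  expect_equal(mutationRates(back), mutationRates(m1))

  mu <- matrix(runif(16, 0.5, 1.5), 4, 4)
  diag(mu) <- 0
  m2 <- SiteModel(S = c(0, 0.5, 3, 8), mu = mu)
  writeSiteModel(m2, f)
  expect_equal(mutationRates(readSiteModel(f)), mutationRates(m2),
               tolerance = 1e-12)
  expect_error(readSiteModel({
    g <- tempfile(); writeLines("n_alleles: 4", g); g
  }), "missing key 'S'")
})

test_that("infinite selection coefficients are rejected", {
  expect_error(SiteModel(S = c(0, Inf)), "finite")
})
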