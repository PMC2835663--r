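# Numerical pair dynamics: ODE route, matrix-exponential closed form,
# half-approach times and curve summaries.

test_that("the integrator recovers the neutral and two-allele closed forms", {
  tr4 <- integrateDivergence(SiteModel(S = rep(0, 4)), tMax = 1,
                             nSteps = 100L)
  expect_lt(max(abs(divergence(tr4) - neutralCurve(4, sampleTimes(tr4)))),
            1e-8)
  tr2 <- integrateDivergence(SiteModel(S = c(0, 3)), tMax = 1,
                             nSteps = 100L)
  expect_lt(max(abs(divergence(tr2) - twoAlleleCurve(3, sampleTimes(tr2)))),
            1e-8)
})

test_that("ODE integration agrees with the matrix-exponential closed form", {
  set.seed(42)
  for (k in 1:100) {
    m <- randomSiteModel(Smax = 8, muLow = 0.5, muHigh = 1.5,
                         symmetric = k %% 2 == 0)
    tr <- integrateDivergence(m, tMax = 1.2, nSteps = 6L)
    expect_lt(max(abs(divergence(tr) -
                        closedFormDivergence(m, sampleTimes(tr)))), 1e-7)
  }
})

test_that("closed form has the exact endpoints and saturates", {
  m <- SiteModel(S = c(0, 1, 2, 4))
  expect_identical(closedFormDivergence(m, 0), 0)
  E <- asymptoticDivergence(equilibrium(m))
  expect_equal(closedFormDivergence(m, 50), E, tolerance = 1e-10)
  # neutral half-approach point
  expect_equal(closedFormDivergence(SiteModel(S = rep(0, 4)), log(2) / 8),
               3 / 8, tolerance = 1e-10)
  # integrated curve is essentially saturated by t = 20/(4 mu)
  slow <- SiteModel(S = c(0, 0, 8, 8))
  Eslow <- asymptoticDivergence(equilibrium(slow))
  expect_lt(abs(closedFormDivergence(slow, 5) - Eslow), 1e-6 * Eslow)
})

test_that("pair-state distributions conserve probability and symmetry", {
  set.seed(7)
  for (k in 1:10) {
    m <- randomSiteModel()
    for (t in c(0.05, 0.3, 2)) {
      p <- pairStateDistribution(m, t)
      expect_equal(sum(p), 1, tolerance = 1e-10)
      expect_true(all(p >= -1e-12))
      expect_lt(max(abs(p - t(p))), 1e-10)   # unordered x_ij = 2 p_ij
      # match frequencies obey the bookkeeping identity
      # p(a,a) = X_a - (1/2) sum_{b != a} x_{a,b}, with x_{a,b} = 2 p(a,b)
      X <- stationaryFreqs(equilibrium(m))
      expect_equal(diag(p), X - (rowSums(p) - diag(p)), tolerance = 1e-9)
    }
  }
})

test_that("relabeling alleles leaves the divergence curve unchanged", {
  set.seed(5)
  m <- randomSiteModel()
  perm <- c(4, 2, 1, 3)
  mp <- SiteModel(S = selectionCoefficients(m)[perm],
                  mu = mutationRates(m)[perm, perm])
  tt <- c(0.03, 0.1, 0.4, 1)
  expect_equal(closedFormDivergence(mp, tt), closedFormDivergence(m, tt),
               tolerance = 1e-11)
})

test_that("half-approach times match the exponential closed forms", {
  expect_equal(halfApproachTime(SiteModel(S = rep(0, 4))), log(2) / 8,
               tolerance = 1e-8)
  expect_equal(halfApproachTime(SiteModel(S = c(0, 0))), log(2) / 4,
               tolerance = 1e-8)
  expect_equal(halfApproachTime(SiteModel(S = rep(0, 3)), 0.75),
               2 * log(2) / 6, tolerance = 1e-8)
  # continuity: tiny fractions give tiny times
  expect_lt(halfApproachTime(SiteModel(S = rep(0, 4)), 1e-5), 1e-5)
  expect_error(halfApproachTime(SiteModel(S = rep(0, 4)), 1.5),
               "fraction")
})

test_that("trajectory summaries detect exponential and decelerating approach", {
  # two permitted alleles: strictly exponential, decel = 0
  for (S in c(0, 2.5)) {
    s <- trajectorySummary(SiteModel(S = c(0, S)))
    expect_lt(abs(deceleration(s)), 1e-6)
  }
  s4 <- trajectorySummary(SiteModel(S = rep(0, 4)))
  expect_lt(abs(deceleration(s4)), 1e-6)
  expect_equal(effectiveRate(s4), 8, tolerance = 1e-8)

  mixed <- trajectorySummary(SiteModel(S = c(0, 1, 2, 4)))
  expect_gt(deceleration(mixed), 0)
  expect_lte(deceleration(mixed), 0.10)

  # the slowest regime: two neutral alleles, two effectively forbidden
  slow <- trajectorySummary(SiteModel(S = c(0, 0, 8, 8)))
  expect_equal(effectiveRate(slow), 4.0165268, tolerance = 1e-6)
  expect_equal(effectiveRate(slow), 4, tolerance = 0.02)
})

test_that("the deviation from E decays monotonically at a spectral rate", {
  set.seed(9)
  m <- randomSiteModel(Smax = 4)
  E <- asymptoticDivergence(equilibrium(m))
  tt <- seq(0.05, 2.5, length.out = 60)
  dev <- E - closedFormDivergence(m, tt)
  expect_true(all(diff(dev) < 0))
  # late log-slope equals a decay rate of the pair process (a sum of two
  # eigenvalue decay rates of Q), allowing for modes of zero amplitude
  Q <- generator(rateMatrix(m))
  lam <- -Re(eigen(Q, only.values = TRUE)$values)
  rates <- unique(round(as.vector(outer(lam, lam, "+")), 8))
  rates <- rates[rates > 1e-6]
  late <- tt > 1.5
  slope <- -coef(lm(log(dev[late]) ~ tt[late]))[[2]]
  expect_lt(min(abs(rates - slope) / slope), 0.01)
})

test_that("non-equilibrium starts require the explicit flag", {
  m <- SiteModel(S = c(0, 1, 2, 4))
  start <- diag(4) / 4
  expect_error(integrateDivergence(m, 1, start = start),
               "allowNonEquilibriumStart")
  tr <- integrateDivergence(m, 1, start = start,
                            allowNonEquilibriumStart = TRUE)
  expect_equal(divergence(tr)[1], 0)
  expect_error(integrateDivergence(m, -1), "tMax")
})
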