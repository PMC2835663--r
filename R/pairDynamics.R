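# Exact dynamics of pairwise divergence for an arbitrary SiteModel.
#
# Two lineages evolve independently from a common ancestor whose allele was
# an equilibrium draw. On ordered allele pairs (a, b) the joint
# distribution p(t) obeys the master equation dp/dt = Q^T p + p Q, and the
# divergence is D(t) = 1 - trace(p(t)). Because the lineages are
# conditionally independent given the ancestor,
#   p_t(a, b) = sum_c X_c P_t(c, a) P_t(c, b),  P_t = exp(Q t),
# which gives the closed form D(t) = 1 - sum_c X_c sum_a P_t(c, a)^2 used
# as the independent oracle for the ODE route. The six unordered mismatch
# frequencies of the four-allele bookkeeping are recovered as
# x_{i,j} = 2 p(i, j) for i < j.

# Eigen-decomposition-backed evaluator of D(t); one decomposition per
# model, validated against the matrix exponential, with a matexpo fallback
# when Q is close to defective.
.divergenceEvaluator <- function(model) {
  Q <- generator(rateMatrix(model))
  eq <- equilibrium(model)
  X <- stationaryFreqs(eq)
  E <- asymptoticDivergence(eq)
  ed <- eigen(Q)
  V <- ed$vectors
  lam <- ed$values
  rc <- tryCatch(rcond(V), error = function(e) 0)
  useEigen <- is.finite(rc) && rc > 1e-8
  if (useEigen) Vinv <- solve(V)
  Pt <- if (useEigen) {
    function(t) Re(V %*% (exp(lam * t) * Vinv))
  } else {
    function(t) ape::matexpo(Q * t)
  }
  Dfun <- function(t) {
    vapply(t, function(ti) {
      if (ti == 0) return(0)
      P <- Pt(ti)
      max(0, 1 - sum(X * rowSums(P^2)))
    }, numeric(1))
  }
  if (useEigen) {
    # cross-check the spectral route once against the matrix exponential
    tchk <- 0.25
    Pm <- ape::matexpo(Q * tchk)
    if (max(abs(Pt(tchk) - Pm)) > 1e-8) {
      Pt <- function(t) ape::matexpo(Q * t)
    }
  }
  # slowest decay rate of the pair process: the pair generator's spectrum
  # is {lam_i + lam_j}; the slowest nonzero mode pairs the stationary mode
  # with Q's slowest mode.
  dec <- -Re(lam)
  gap <- min(dec[dec > 1e-9])
  list(D = Dfun, E = E, X = X, Q = Q, spectralGap = gap)
}

#' Closed-form divergence via the matrix exponential
#'
#' Evaluates \eqn{D(t) = 1 - \sum_c X_c \sum_a P_t(c,a)^2} with
#' \eqn{P_t = e^{Q t}}: the exact divergence of two lineages evolving
#' independently by generator \eqn{Q} from an equilibrium ancestor. Serves
#' as the independent oracle for [integrateDivergence()].
#'
#' @param model a [SiteModel-class].
#' @param t numeric vector of times, \eqn{1/\mu} units, \eqn{\ge 0}.
#' @return numeric vector \eqn{D(t)}.
#' @examples
#' closedFormDivergence(SiteModel(S = c(0, 0, 0, 0)), log(2) / 8)  # 3/8
#' @export
closedFormDivergence <- function(model, t) {
  stopifnot(is(model, "SiteModel"))
  if (any(t < 0)) stop("t must be >= 0")
  Q <- generator(rateMatrix(model))
  X <- stationaryFreqs(equilibrium(model))
  vapply(t, function(ti) {
    if (ti == 0) return(0)
    P <- ape::matexpo(Q * ti)
    max(0, 1 - sum(X * rowSums(P^2)))
  }, numeric(1))
}

#' Time at which divergence reaches a fraction of its asymptote
#'
#' Locates the unique \eqn{t} with \eqn{D(t) = q E} on the monotone
#' divergence curve by geometric bracket growth followed by Brent's method,
#' to relative tolerance \eqn{10^{-8}}. With \eqn{q = 1/2} this is the
#' half-approach period \eqn{\tau = t_{0,1/2}}.
#'
#' @param model a [SiteModel-class].
#' @param fraction target fraction \eqn{q \in (0, 1)} of the asymptote.
#' @return time in \eqn{1/\mu} units.
#' @examples
#' halfApproachTime(SiteModel(S = c(0, 0, 0, 0)))  # ln2/8 ~ 0.0866
#' @export
halfApproachTime <- function(model, fraction = 0.5) {
  stopifnot(is(model, "SiteModel"))
  ev <- .divergenceEvaluator(model)
  .fractionTime(ev, fraction)
}

.fractionTime <- function(ev, fraction) {
  if (!is.numeric(fraction) || fraction <= 0 || fraction >= 1)
    stop("fraction must be in (0, 1)")
  target <- fraction * ev$E
  lo <- 0
  hi <- 1e-4
  while (ev$D(hi) < target) {
    lo <- hi
    hi <- hi * 2
    if (hi > 1e3)
      stop("failed to bracket the target divergence within t <= 1000/mu; ",
           "parameters are pathological (E may be numerically 0)")
  }
  stats::uniroot(function(t) ev$D(t) - target, c(lo, hi),
                 tol = max(1e-14, 1e-10 * hi))$root
}

# Shared summary construction from a cached evaluator.
.summaryFromEvaluator <- function(ev, nGrid = 101L) {
  tHalf <- .fractionTime(ev, 0.5)
  t34 <- .fractionTime(ev, 0.75)
  interval <- t34 - tHalf
  times <- seq(0, 4 * t34, length.out = nGrid)
  new("DivergenceTrajectory",
      times = times, D = ev$D(times), E = ev$E,
      tHalf = tHalf, tHalfToThreeQuarter = interval,
      rEff = log(2) / tHalf, rSpectral = ev$spectralGap,
      decel = interval / tHalf - 1)
}

#' Summarize the divergence curve of a site model
#'
#' Computes the asymptote \eqn{E}, the half-approach time
#' \eqn{t_{0,1/2}}, the second interval \eqn{t_{1/2,3/4}} (from \eqn{E/2}
#' to \eqn{3E/4}), the effective rate
#' \eqn{r_{\mathrm{eff}} = \ln 2/t_{0,1/2}}, the slowest spectral
#' relaxation rate of the pair process, and the deceleration ratio
#' \eqn{t_{1/2,3/4}/t_{0,1/2} - 1}, which is exactly 0 whenever the
#' approach is a pure exponential (all neutral alleles, or only two
#' permitted alleles) and stays below about 10\% across constant-selection
#' regimes.
#'
#' @param model a [SiteModel-class].
#' @param nGrid number of grid points of the returned sampled curve.
#' @return a [DivergenceTrajectory-class].
#' @examples
#' trajectorySummary(SiteModel(S = c(0, 1, 2, 4)))
#' @export
trajectorySummary <- function(model, nGrid = 101L) {
  stopifnot(is(model, "SiteModel"))
  .summaryFromEvaluator(.divergenceEvaluator(model), nGrid)
}

#' Integrate the pair dynamics of divergence
#'
#' Numerically integrates the master equation of the ordered pair process,
#' \eqn{dp/dt = Q^\top p + p Q} on \eqn{I^2} states (equivalently the six
#' unordered mismatch-frequency ODEs for four alleles), from the
#' equilibrium ancestor \eqn{p_0 = \mathrm{diag}(X)}, with adaptive
#' stiff integration at relative tolerance \eqn{10^{-10}}. Returns the
#' sampled \eqn{D(t) = 1 - \mathrm{tr}\, p(t)} plus the summaries of
#' [trajectorySummary()].
#'
#' @param model a [SiteModel-class].
#' @param tMax end of the time grid (\eqn{1/\mu} units), > 0.
#' @param nSteps number of grid intervals.
#' @param start optional \eqn{I \times I} initial pair distribution; using
#'   it requires \code{allowNonEquilibriumStart = TRUE}, and such runs are
#'   exploratory (the summary statistics still refer to the same model's
#'   equilibrium asymptote).
#' @param allowNonEquilibriumStart permit a non-equilibrium ancestor.
#' @return a [DivergenceTrajectory-class].
#' @examples
#' tr <- integrateDivergence(SiteModel(S = c(0, 0, 8, 8)), tMax = 1)
#' effectiveRate(tr)   # ~4: the slowest regime, two neutral + two forbidden
#' @export
integrateDivergence <- function(model, tMax, nSteps = 200L, start = NULL,
                                allowNonEquilibriumStart = FALSE) {
  stopifnot(is(model, "SiteModel"))
  if (tMax <= 0) stop("tMax must be > 0")
  I <- nAlleles(model)
  ev <- .divergenceEvaluator(model)
  if (!is.null(start) && !allowNonEquilibriumStart)
    stop("a non-equilibrium start requires allowNonEquilibriumStart = TRUE")
  p0 <- if (is.null(start)) diag(ev$X) else {
    start <- as.matrix(start)
    if (!all(dim(start) == c(I, I)) || abs(sum(start) - 1) > 1e-8)
      stop("start must be an I x I distribution summing to 1")
    start
  }
  Q <- ev$Q
  times <- seq(0, tMax, length.out = nSteps + 1L)
  rhs <- function(t, y, parms) {
    p <- matrix(y, I, I)
    list(as.vector(crossprod(Q, p) + p %*% Q))
  }
  sol <- deSolve::ode(y = as.vector(p0), times = times, func = rhs,
                      parms = NULL, method = "lsoda",
                      rtol = 1e-10, atol = 1e-12)
  D <- apply(sol[, -1, drop = FALSE], 1L, function(v)
    1 - sum(diag(matrix(v, I, I))))
  D[abs(D) < 1e-13] <- pmax(D[abs(D) < 1e-13], 0)
  s <- .summaryFromEvaluator(ev)
  new("DivergenceTrajectory",
      times = times, D = as.numeric(D), E = ev$E,
      tHalf = s@tHalf, tHalfToThreeQuarter = s@tHalfToThreeQuarter,
      rEff = s@rEff, rSpectral = s@rSpectral, decel = s@decel)
}

#' Pair-state distribution at a time point
#'
#' Returns the ordered pair distribution
#' \eqn{p_t(a,b) = \sum_c X_c P_t(c,a) P_t(c,b)}; its off-diagonal sum is
#' \eqn{D(t)} and the unordered mismatch frequencies are
#' \eqn{x_{i,j} = 2 p_t(i,j)} for \eqn{i < j}. The matched-pair
#' frequencies satisfy the bookkeeping identity
#' \eqn{p_t(a,a) = X_a - \frac12 \sum_{b \ne a} x_{a,b}}.
#'
#' @param model a [SiteModel-class].
#' @param t a single time, \eqn{\ge 0}.
#' @return an \eqn{I \times I} matrix summing to 1.
#' @export
pairStateDistribution <- function(model, t) {
  stopifnot(is(model, "SiteModel"), length(t) == 1L, t >= 0)
  Q <- generator(rateMatrix(model))
  X <- stationaryFreqs(equilibrium(model))
  P <- ape::matexpo(Q * t)
  crossprod(P * sqrt(X))   # sum_c X_c P(c,a) P(c,b)
}

#' @rdname DivergenceTrajectory-class
#' @export
setMethod("sampleTimes", "DivergenceTrajectory", function(x) x@times)

#' @rdname DivergenceTrajectory-class
#' @export
setMethod("divergence", "DivergenceTrajectory", function(x) x@D)

#' @rdname DivergenceTrajectory-class
#' @export
setMethod("asymptoticDivergence", "DivergenceTrajectory", function(x) x@E)

#' @rdname DivergenceTrajectory-class
#' @export
setMethod("halfTime", "DivergenceTrajectory", function(x) x@tHalf)

#' @rdname DivergenceTrajectory-class
#' @export
setMethod("effectiveRate", "DivergenceTrajectory", function(x) x@rEff)

#' @rdname DivergenceTrajectory-class
#' @export
setMethod("deceleration", "DivergenceTrajectory", function(x) x@decel)

setMethod("show", "DivergenceTrajectory", function(object) {
  cat("DivergenceTrajectory\n")
  cat(sprintf("  E = %.6f   t_half = %.6f (1/mu)   r_eff = %.4f mu\n",
              object@E, object@tHalf, object@rEff))
  cat(sprintf("  t_{1/2,3/4} = %.6f   deceleration = %.4f%%   r_spectral = %.4f mu\n",
              object@tHalfToThreeQuarter, 100 * object@decel,
              object@rSpectral))
  cat(sprintf("  curve sampled at %d times in [0, %.4g]\n",
              length(object@times), max(object@times)))
  invisible(object)
})
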