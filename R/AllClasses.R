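#' @import methods
NULL

#' SiteModel: parameterization of one site class
#'
#' A \code{SiteModel} holds the full parameterization of a single class of
#' sites evolving in the weak-mutation (origin-fixation) regime: the number
#' of alleles \eqn{I}, the matrix of per-allele mutation rates
#' \eqn{\mu_{ij}} (in units of a reference rate \eqn{\mu}, so a neutral
#' equal-rates model has all off-diagonal entries 1), and the scaled
#' selection coefficients \eqn{S_i = 4 N_e s_i} (diploid with codominance;
#' \eqn{2 N_e s_i} for haploids -- only the scaled product enters the
#' dynamics, so \eqn{N_e} and \eqn{s} are never supplied separately).
#'
#' Larger \eqn{S_i} means allele \eqn{i} is more strongly selected against;
#' by convention the reference allele has \eqn{S_1 = 0}, although only the
#' differences \eqn{S_i - S_j} matter. "Forbidden" alleles are represented
#' by a large finite coefficient (the conventional strong-selection endpoint
#' is \eqn{S = 8}); infinite coefficients are rejected. All off-diagonal
#' mutation rates must be strictly positive unless zeros are explicitly
#' permitted at construction.
#'
#' @slot nAlleles integer, number of alleles \eqn{I} (2 or more; nucleotide
#'   sites correspond to \eqn{I \le 4}).
#' @slot mu numeric \eqn{I \times I} matrix of mutation rates in units of
#'   the reference rate; the diagonal is unused and kept at 0.
#' @slot S numeric length-\eqn{I} vector of scaled selection coefficients.
#'
#' @seealso [SiteModel()] for the user constructor, [rateMatrix()],
#'   [equilibrium()].
#' @export
setClass("SiteModel",
  representation(nAlleles = "integer", mu = "matrix", S = "numeric"))

setValidity("SiteModel", function(object) {
  I <- object@nAlleles
  msg <- character()
  if (length(I) != 1L || is.na(I) || I < 2L)
    msg <- c(msg, "nAlleles must be a single integer >= 2")
  if (!all(dim(object@mu) == c(I, I)))
    msg <- c(msg, sprintf("mu must be a %d x %d matrix", I, I))
  off <- object@mu[row(object@mu) != col(object@mu)]
  if (any(!is.finite(off)) || any(off < 0))
    msg <- c(msg, "off-diagonal mutation rates must be finite and >= 0")
  if (length(object@S) != I)
    msg <- c(msg, sprintf("S must have length %d", I))
  if (any(!is.finite(object@S)))
    msg <- c(msg, "scaled selection coefficients must be finite; represent forbidden alleles by a large finite S (e.g. 8)")
  if (length(msg)) msg else TRUE
})

#' RateMatrix: allele-replacement rates and their generator
#'
#' Holds the origin-fixation replacement rates
#' \eqn{f_{ij} = \mu_{ij} \, g(S_i - S_j)} (the rate at which a population
#' fixed for allele \eqn{i} becomes fixed for allele \eqn{j}), together with
#' the continuous-time Markov generator \eqn{Q} having \eqn{Q_{ij} = f_{ij}}
#' off the diagonal and rows summing to zero. \eqn{-Q_{ii}} is the total
#' replacement rate of allele \eqn{i} into all others. All rates are in
#' units of the reference mutation rate \eqn{\mu}.
#'
#' @slot f numeric matrix of replacement rates (diagonal 0).
#' @slot generator numeric matrix \eqn{Q}, rows summing to 0.
#' @seealso [rateMatrix()], [fixationFluxFactor()].
#' @export
setClass("RateMatrix",
  representation(f = "matrix", generator = "matrix"))

setValidity("RateMatrix", function(object) {
  msg <- character()
  off <- object@f[row(object@f) != col(object@f)]
  if (any(off < 0)) msg <- c(msg, "replacement rates must be >= 0")
  if (any(abs(rowSums(object@generator)) > 1e-12))
    msg <- c(msg, "generator rows must sum to zero (tolerance 1e-12)")
  if (length(msg)) msg else TRUE
})

#' EquilibriumDistribution: stationary allele frequencies and asymptote
#'
#' The stationary distribution \eqn{X} of the replacement process
#' (\eqn{X Q = 0}, \eqn{\sum X_i = 1}) and the asymptotic divergence
#' \eqn{E = 1 - \sum_i X_i^2}: the limiting fraction of mismatched sites
#' between two sequences that have diverged for a long time, each site an
#' independent draw from \eqn{X} in each lineage.
#'
#' @slot X numeric probability vector of equilibrium allele frequencies.
#' @slot E numeric scalar in \eqn{[0, 1 - 1/I]}.
#' @seealso [equilibrium()].
#' @export
setClass("EquilibriumDistribution",
  representation(X = "numeric", E = "numeric"))

setValidity("EquilibriumDistribution", function(object) {
  msg <- character()
  if (abs(sum(object@X) - 1) > 1e-10 || any(object@X < -1e-12))
    msg <- c(msg, "X must be a probability vector")
  if (length(msg)) msg else TRUE
})

#' DivergenceTrajectory: a divergence curve and its summaries
#'
#' The divergence \eqn{D(t)} of two independently evolving sequences sampled
#' on a time grid (time in units of \eqn{1/\mu}), together with the derived
#' summaries: the asymptote \eqn{E}, the half-approach time \eqn{t_{0,1/2}}
#' at which \eqn{D = E/2}, the additional interval \eqn{t_{1/2,3/4}} needed
#' to reach \eqn{3E/4}, the effective relaxation rate
#' \eqn{r_{\mathrm{eff}} = \ln 2 / t_{0,1/2}} (in units of \eqn{\mu}), the
#' slowest spectral relaxation rate of the pair process, and the
#' deceleration ratio \eqn{t_{1/2,3/4}/t_{0,1/2} - 1} (zero for an exactly
#' exponential approach).
#'
#' @slot times increasing numeric grid, units \eqn{1/\mu}.
#' @slot D divergence at each grid time.
#' @slot E asymptotic divergence.
#' @slot tHalf time at which \eqn{D = E/2}.
#' @slot tHalfToThreeQuarter additional time from \eqn{E/2} to \eqn{3E/4}.
#' @slot rEff \eqn{\ln 2 / t_{0,1/2}}, units \eqn{\mu}.
#' @slot rSpectral slowest nonzero relaxation rate of the pair process
#'   (spectral gap), units \eqn{\mu}.
#' @slot decel deceleration ratio (dimensionless).
#' @seealso [integrateDivergence()], [trajectorySummary()].
#' @export
setClass("DivergenceTrajectory",
  representation(times = "numeric", D = "numeric", E = "numeric",
    tHalf = "numeric", tHalfToThreeQuarter = "numeric",
    rEff = "numeric", rSpectral = "numeric", decel = "numeric"))

setValidity("DivergenceTrajectory", function(object) {
  msg <- character()
  if (length(object@times) != length(object@D))
    msg <- c(msg, "times and D must have equal length")
  if (is.unsorted(object@times))
    msg <- c(msg, "times must be increasing")
  if (length(msg)) msg else TRUE
})

#' SimulationRun: Monte Carlo realization of many independent sites
#'
#' Result of simulating \code{nSites} independent sites as continuous-time
#' Markov chains along two lineages: the estimated divergence
#' \eqn{\hat D(t)} at each observation time with its binomial standard
#' error \eqn{\sqrt{\hat D (1-\hat D)/n}}, and (optionally) the full pair
#' of allele-index sequences at each observation time.
#'
#' @slot nSites number of simulated sites.
#' @slot times observation grid, units \eqn{1/\mu}.
#' @slot DHat estimated divergence per observation time.
#' @slot SE binomial standard error of each estimate.
#' @slot seed integer seed used (runs are bit-for-bit reproducible).
#' @slot sequences list (one element per observation time) of 2-row integer
#'   matrices of allele indices, or an empty list if not retained.
#' @seealso [simulateSites()], [writeAlignment()].
#' @export
setClass("SimulationRun",
  representation(nSites = "integer", times = "numeric", DHat = "numeric",
    SE = "numeric", seed = "integer", sequences = "list"))

#' SweepResult: tabulated divergence summaries over a parameter sweep
#'
#' One row per swept condition (a selection regime and/or a drawn mutation
#' matrix), with columns produced by [trajectorySummary()]. The
#' \code{provenance} list records the sweep specification (grids, number of
#' matrices, seed, symmetry flag) so results are reproducible.
#'
#' @slot table data.frame of per-condition summaries.
#' @slot provenance named list describing how the sweep was generated.
#' @seealso [selectionGridSweep()], [randomMuSweep()], [minRateSearch()].
#' @export
setClass("SweepResult",
  representation(table = "data.frame", provenance = "list"))

#' AlignedPair: two aligned nucleotide sequences
#'
#' A pair of equal-length upper-case sequences over the alphabet
#' \{A, C, G, T, N, -\} plus the per-site comparability mask (sites where
#' both characters are unambiguous bases). Divergence is computed only over
#' comparable sites.
#'
#' @slot seq1,seq2 character vectors of single upper-case characters.
#' @slot comparable logical mask; TRUE where both sites are in A/C/G/T.
#' @seealso [readFastaPair()], [observedDivergence()].
#' @export
setClass("AlignedPair",
  representation(seq1 = "character", seq2 = "character",
    comparable = "logical"))

setValidity("AlignedPair", function(object) {
  n <- length(object@seq1)
  if (length(object@seq2) != n || length(object@comparable) != n)
    "seq1, seq2 and comparable must have equal length"
  else TRUE
})
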