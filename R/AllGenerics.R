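#' @rdname SiteModel-class
#' @param object,x a \code{SiteModel} (or other object as documented).
#' @export
setGeneric("nAlleles", function(x) standardGeneric("nAlleles"))

#' @rdname SiteModel-class
#' @export
setGeneric("mutationRates", function(x) standardGeneric("mutationRates"))

#' @rdname SiteModel-class
#' @export
setGeneric("selectionCoefficients",
  function(x) standardGeneric("selectionCoefficients"))

#' Build the allele-replacement rate matrix of a site model
#'
#' @param model a [SiteModel-class] object.
#' @return a [RateMatrix-class] object.
#' @export
setGeneric("rateMatrix", function(model) standardGeneric("rateMatrix"))

#' Stationary allele frequencies and asymptotic divergence
#'
#' @param model a [SiteModel-class] object.
#' @return an [EquilibriumDistribution-class] object.
#' @export
setGeneric("equilibrium", function(model) standardGeneric("equilibrium"))

#' @rdname RateMatrix-class
#' @param x a \code{RateMatrix}.
#' @export
setGeneric("replacementRates", function(x) standardGeneric("replacementRates"))

#' @rdname RateMatrix-class
#' @export
setGeneric("generator", function(x) standardGeneric("generator"))

#' @rdname EquilibriumDistribution-class
#' @param x an \code{EquilibriumDistribution} or \code{DivergenceTrajectory}.
#' @export
setGeneric("stationaryFreqs", function(x) standardGeneric("stationaryFreqs"))

#' Asymptotic divergence accessor
#'
#' Returns the asymptote \eqn{E = 1 - \sum X_i^2} stored in an equilibrium
#' or trajectory object.
#' @param x an [EquilibriumDistribution-class] or
#'   [DivergenceTrajectory-class] object.
#' @export
setGeneric("asymptoticDivergence",
  function(x) standardGeneric("asymptoticDivergence"))

#' @rdname DivergenceTrajectory-class
#' @export
setGeneric("divergence", function(x) standardGeneric("divergence"))

#' @rdname DivergenceTrajectory-class
#' @export
setGeneric("sampleTimes", function(x) standardGeneric("sampleTimes"))

#' @rdname DivergenceTrajectory-class
#' @export
setGeneric("halfTime", function(x) standardGeneric("halfTime"))

#' @rdname DivergenceTrajectory-class
#' @export
setGeneric("effectiveRate", function(x) standardGeneric("effectiveRate"))

#' @rdname DivergenceTrajectory-class
#' @export
setGeneric("deceleration", function(x) standardGeneric("deceleration"))

#' @rdname SweepResult-class
#' @param x a \code{SweepResult}.
#' @export
setGeneric("sweepTable", function(x) standardGeneric("sweepTable"))

#' @rdname SweepResult-class
#' @export
setGeneric("provenance", function(x) standardGeneric("provenance"))
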