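#' Closed-form neutral divergence curve
#'
#' For \eqn{I} selectively neutral alleles with all mutation rates equal to
#' \eqn{\mu}, the mismatch probability of a site obeys
#' \eqn{dD/dt = 2(I-1)\mu (1 - D) - 2 \mu D} minus saturation terms, whose
#' solution from identical sequences is the pure exponential approach
#' \deqn{D(t) = E \,(1 - e^{-r t}), \qquad E = \frac{I-1}{I}, \quad
#'   r = 2 I \mu.}
#' So two, three and four neutral alleles give \eqn{E = 1/2, 2/3, 3/4} and
#' \eqn{r = 4\mu, 6\mu, 8\mu}.
#'
#' @param I allele count, one of 2, 3, 4.
#' @param t numeric vector of times in units of \eqn{1/\mu}; must be
#'   \eqn{\ge 0}.
#' @return numeric vector \eqn{D(t)}.
#' @seealso [neutralCurveParams()] for \eqn{(E, r, \tau)},
#'   [twoAlleleCurve()] for selection on two alleles.
#' @examples
#' neutralCurve(4, log(2) / 8)   # 3/8: half of the asymptote 3/4
#' @export
neutralCurve <- function(I, t) {
  p <- neutralCurveParams(I)
  if (any(t < 0)) stop("t must be >= 0")
  p$E * (1 - exp(-p$r * t))
}

#' @rdname neutralCurve
#' @return \code{neutralCurveParams} returns a list with the asymptote
#'   \code{E}, the relaxation rate \code{r} (units \eqn{\mu}) and the
#'   half-approach period \code{tau} \eqn{= \ln 2 / r} (units \eqn{1/\mu}).
#' @export
neutralCurveParams <- function(I) {
  if (!I %in% c(2L, 3L, 4L)) stop("I must be 2, 3 or 4")
  r <- 2 * I
  list(E = (I - 1) / I, r = r, tau = log(2) / r)
}

#' Closed-form two-allele divergence curve with selection
#'
#' With two alleles, equal reciprocal mutation rates \eqn{\mu} and scaled
#' selection coefficient \eqn{S} against the second allele, the divergence
#' of two sequences whose common ancestor was at the equilibrium
#' composition \eqn{X_1 = e^S/(e^S + 1)} approaches its asymptote exactly
#' exponentially:
#' \deqn{E(S) = \frac{2 e^S}{(1 + e^S)^2}, \qquad
#'   r(S) = 2\,(f_{1,2} + f_{2,1}) = 2 \mu S \frac{1 + e^S}{e^S - 1},}
#' with \eqn{r(0) = 4\mu} by continuous extension. \eqn{r(S)} has its
#' unique minimum at \eqn{S = 0}: selection on two alleles always
#' accelerates the approach while lowering the asymptote
#' (\eqn{E \to 0} and \eqn{r \to \infty} as \eqn{|S|} grows).
#'
#' @param S scaled selection coefficient (finite scalar).
#' @param t numeric vector of times in \eqn{1/\mu} units, \eqn{\ge 0}.
#' @return numeric vector \eqn{D(t)}.
#' @examples
#' twoAlleleCurveParams(0)   # neutral: E = 1/2, r = 4
#' twoAlleleCurveParams(2)   # E ~ 0.21, r ~ 5.25
#' @export
twoAlleleCurve <- function(S, t) {
  p <- twoAlleleCurveParams(S)
  if (any(t < 0)) stop("t must be >= 0")
  p$E * (1 - exp(-p$r * t))
}

#' @rdname twoAlleleCurve
#' @return \code{twoAlleleCurveParams} returns a list with \code{E},
#'   \code{r} (units \eqn{\mu}) and \code{tau} \eqn{= \ln 2 / r}.
#' @export
twoAlleleCurveParams <- function(S) {
  if (length(S) != 1L || !is.finite(S)) stop("S must be a finite scalar")
  E <- 2 * exp(S) / (1 + exp(S))^2
  # r = 2 (f12 + f21) = 2 mu (g(-S) + g(S)) = 2 mu S (1 + e^S)/(e^S - 1)
  r <- 2 * sum(fixationFluxFactor(c(S, -S)))
  list(E = E, r = r, tau = log(2) / r)
}

#' Jukes-Cantor correction between divergence and substitutions per site
#'
#' Converts a raw fraction of mismatched sites \eqn{D} into the expected
#' number of substitutions per site under the symmetric four-allele neutral
#' model:
#' \deqn{K = -\tfrac{3}{4} \ln\!\left(1 - \tfrac{4}{3} D\right),}
#' and back (\code{jcInverse}). The correction exactly linearizes the
#' neutral four-allele saturation curve: applied to
#' \code{neutralCurve(4, t)} it returns \eqn{6 \mu t}, the true number of
#' substitutions accumulated on the two lineages.
#'
#' @param D observed divergence, \eqn{0 \le D < 3/4}.
#' @return substitutions per site \eqn{K \ge 0}.
#' @examples
#' jukesCantor(3 / 8)            # 0.52: half-approach point of neutral sites
#' jcInverse(jukesCantor(0.2))   # round-trips
#' @export
jukesCantor <- function(D) {
  if (any(D < 0)) stop("D must be >= 0")
  if (any(D >= 3 / 4))
    stop("D >= 3/4: divergence at or beyond saturation, correction undefined")
  -0.75 * log(1 - 4 * D / 3)
}

#' @rdname jukesCantor
#' @param K substitutions per site, \eqn{K \ge 0}.
#' @export
jcInverse <- function(K) {
  if (any(K < 0)) stop("K must be >= 0")
  0.75 * (1 - exp(-4 * K / 3))
}

#' Substitutions accumulated at a neutral four-allele site
#'
#' Under neutrality the substitution rate equals the mutation rate: each
#' lineage leaves its current allele at total rate \eqn{3\mu}, so two
#' lineages separated for time \eqn{t} accumulate \eqn{K = 6 \mu t}
#' substitutions per site. At the neutral half-approach time
#' \eqn{\tau = \ln 2/(8\mu)} this gives \eqn{K_{1/2} \approx 0.52}, and at
#' \eqn{2\tau = \ln 2/(4\mu)} (the longest half-approach period any
#' constant selection permits) \eqn{K \approx 1.04}.
#'
#' @param t time in \eqn{1/\mu} units, \eqn{\ge 0}.
#' @return expected substitutions per neutral site.
#' @examples
#' neutralK(log(2) / 8)   # ~0.52
#' neutralK(log(2) / 4)   # ~1.04
#' @export
neutralK <- function(t) {
  if (any(t < 0)) stop("t must be >= 0")
  6 * t
}
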