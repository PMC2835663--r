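#' Relative fixation flux of a selected mutation
#'
#' The factor by which selection scales the substitution rate of an
#' incoming allele with scaled advantage \eqn{S} over the resident:
#' \deqn{g(S) = \frac{S}{1 - e^{-S}},}
#' the ratio of the fixation probability of a mutant with scaled selection
#' advantage \eqn{S = 4 N_e s} to that of a neutral mutant (Kimura's
#' diffusion result in the weak-mutation limit). \eqn{g(0) = 1} by
#' continuous extension, so a neutral substitution proceeds at the mutation
#' rate; \eqn{g} is strictly increasing and satisfies
#' \eqn{g(S)/g(-S) = e^S}.
#'
#' Near the origin the direct formula is a 0/0 cancellation, so for
#' \eqn{|S| < 10^{-4}} the Bernoulli series
#' \eqn{g(S) = 1 + S/2 + S^2/12 - S^4/720 + O(S^6)} is used instead, making
#' the neutral limit exact.
#'
#' @param S numeric vector of scaled selection advantages of the incoming
#'   allele (\eqn{S_i - S_j} for replacement of resident \eqn{i} by
#'   \eqn{j}). Must be finite.
#' @return numeric vector of dimensionless rate multipliers.
#' @examples
#' fixationFluxFactor(0)        # 1: neutral substitutions at mutation rate
#' fixationFluxFactor(4)        # ~4.075: favored allele fixes faster
#' fixationFluxFactor(-8)       # ~0.0027: strong suppression
#' @export
fixationFluxFactor <- function(S) {
  if (any(!is.finite(S)))
    stop("scaled selection advantage must be finite")
  out <- numeric(length(S))
  small <- abs(S) < 1e-4
  s <- S[small]
  out[small] <- 1 + s / 2 + s^2 / 12 - s^4 / 720
  s <- S[!small]
  out[!small] <- s / (1 - exp(-s))
  out
}

#' @describeIn rateMatrix Replacement rates
#'   \eqn{f_{ij} = \mu_{ij}\, g(S_i - S_j)} and the generator \eqn{Q} with
#'   zero row sums. In the neutral case (all \eqn{S_i} equal) the
#'   replacement rates reduce exactly to the mutation rates.
#' @examples
#' rm <- rateMatrix(SiteModel(S = c(0, 2)))
#' replacementRates(rm)   # f_{1,2} suppressed, f_{2,1} enhanced
#' @export
setMethod("rateMatrix", "SiteModel", function(model) {
  I <- model@nAlleles
  Sd <- outer(model@S, model@S, "-")      # advantage of incoming allele j
  f <- model@mu * matrix(fixationFluxFactor(as.vector(Sd)), I, I)
  diag(f) <- 0
  Q <- f
  diag(Q) <- -rowSums(f)
  new("RateMatrix", f = f, generator = Q)
})

#' @rdname RateMatrix-class
#' @export
setMethod("replacementRates", "RateMatrix", function(x) x@f)

#' @rdname RateMatrix-class
#' @export
setMethod("generator", "RateMatrix", function(x) x@generator)

setMethod("show", "RateMatrix", function(object) {
  cat(sprintf("RateMatrix over %d alleles (units of reference mu)\n",
              nrow(object@f)))
  print(round(object@generator, 5))
  invisible(object)
})

# Strongly-connected components of the directed graph with edges f_ij > 0;
# used to give an informative error for reducible chains.
.connectedClasses <- function(f) {
  I <- nrow(f)
  A <- (f > 0) | diag(I) > 0
  # transitive closure by repeated boolean squaring
  R <- A
  for (k in seq_len(ceiling(log2(I)) + 1L)) R <- (R %*% R) > 0
  comm <- R & t(R)
  classes <- rep(NA_integer_, I)
  cl <- 0L
  for (i in seq_len(I)) {
    if (is.na(classes[i])) {
      cl <- cl + 1L
      classes[which(comm[i, ])] <- cl
    }
  }
  classes
}

#' @describeIn equilibrium Solves the stationary linear system
#'   \eqn{X Q = 0}, \eqn{\sum_i X_i = 1} directly (one balance equation is
#'   replaced by the normalization constraint; deterministic and
#'   well-conditioned for small \eqn{I}) and computes
#'   \eqn{E = 1 - \sum_i X_i^2}. Errors if the replacement graph is not
#'   strongly connected (possible only when zero mutation rates were
#'   explicitly allowed), naming the disconnected alleles.
#' @examples
#' eq <- equilibrium(SiteModel(S = c(0, 0, 0, 0)))
#' stationaryFreqs(eq)       # 1/4 each
#' asymptoticDivergence(eq)  # 3/4
#' @export
setMethod("equilibrium", "SiteModel", function(model) {
  Q <- generator(rateMatrix(model))
  I <- model@nAlleles
  cls <- .connectedClasses(replacementRates(rateMatrix(model)))
  if (length(unique(cls)) > 1L) {
    grp <- split(seq_len(I), cls)
    stop("replacement graph is reducible; disconnected allele groups: ",
         paste(vapply(grp, function(g)
           paste0("{", paste(g, collapse = ","), "}"), ""),
           collapse = " "))
  }
  A <- t(Q)
  A[I, ] <- 1
  b <- c(rep(0, I - 1L), 1)
  X <- solve(A, b)
  X[X < 0 & X > -1e-14] <- 0
  new("EquilibriumDistribution", X = X, E = 1 - sum(X^2))
})

#' @rdname EquilibriumDistribution-class
#' @export
setMethod("stationaryFreqs", "EquilibriumDistribution", function(x) x@X)

#' @rdname EquilibriumDistribution-class
#' @export
setMethod("asymptoticDivergence", "EquilibriumDistribution",
  function(x) x@E)

setMethod("show", "EquilibriumDistribution", function(object) {
  cat("EquilibriumDistribution\n")
  cat("  X:", paste(format(round(object@X, 6)), collapse = ", "), "\n")
  cat(sprintf("  asymptotic divergence E = %.6f\n", object@E))
  invisible(object)
})
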