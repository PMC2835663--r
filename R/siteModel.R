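#' Construct a site model
#'
#' Builds a [SiteModel-class] from the number of alleles, the mutation-rate
#' matrix and the scaled selection coefficients. Time throughout the package
#' is measured in units of \eqn{1/\mu}, the inverse of a reference mutation
#' rate, so an equal-rates model has every off-diagonal \eqn{\mu_{ij} = 1}
#' and all reported rates are multiples of \eqn{\mu}.
#'
#' @param S numeric vector of scaled selection coefficients
#'   \eqn{S_i = 4 N_e s_i}; its length sets the number of alleles unless
#'   \code{nAlleles} is given. Larger values mean stronger selection against
#'   the allele; the conventional strong-selection ("forbidden allele")
#'   endpoint is 8. Must be finite.
#' @param mu either a single positive number (all off-diagonal rates equal
#'   to it), the string \code{"equal"} (all rates 1), or a full
#'   \eqn{I \times I} matrix in units of the reference rate.
#' @param nAlleles optional allele count; defaults to \code{length(S)}.
#' @param allowZeroRates if TRUE, zero off-diagonal mutation rates are
#'   accepted (the chain may then be reducible and [equilibrium()] will
#'   refuse disconnected models). By default all rates must be > 0:
#'   effectively forbidden transitions should be modeled by large \code{S},
#'   not by zero mutation rate.
#'
#' @return a validated [SiteModel-class] object.
#' @examples
#' neutral4 <- SiteModel(S = c(0, 0, 0, 0))
#' twoAllele <- SiteModel(S = c(0, 2))
#' lethalGC <- SiteModel(S = c(0, 0, 8, 8))   # two permitted, two forbidden
#' @export
SiteModel <- function(S, mu = "equal", nAlleles = length(S),
                      allowZeroRates = FALSE) {
  I <- as.integer(nAlleles)
  if (length(S) == 1L && I > 1L) S <- rep(as.numeric(S), I)
  S <- as.numeric(S)
  if (is.character(mu)) {
    if (!identical(mu, "equal"))
      stop("mu must be a number, a matrix, or the string \"equal\"")
    mu <- matrix(1, I, I)
  } else if (length(mu) == 1L) {
    mu <- matrix(as.numeric(mu), I, I)
  } else {
    mu <- as.matrix(mu)
    storage.mode(mu) <- "double"
  }
  diag(mu) <- 0
  off <- mu[row(mu) != col(mu)]
  if (!allowZeroRates && any(off <= 0))
    stop("all off-diagonal mutation rates must be > 0 ",
         "(model forbidden transitions by large S, or set allowZeroRates = TRUE)")
  new("SiteModel", nAlleles = I, mu = mu, S = S)
}

#' @rdname SiteModel-class
#' @export
setMethod("nAlleles", "SiteModel", function(x) x@nAlleles)

#' @rdname SiteModel-class
#' @export
setMethod("mutationRates", "SiteModel", function(x) x@mu)

#' @rdname SiteModel-class
#' @export
setMethod("selectionCoefficients", "SiteModel", function(x) x@S)

setMethod("show", "SiteModel", function(object) {
  I <- object@nAlleles
  cat(sprintf("SiteModel with %d alleles\n", I))
  cat("  S (scaled selection):", paste(format(object@S), collapse = ", "),
      "\n")
  off <- object@mu[row(object@mu) != col(object@mu)]
  if (all(off == off[1])) {
    cat(sprintf("  mutation rates: all equal to %g (units of reference mu)\n",
                off[1]))
  } else {
    cat("  mutation rates (units of reference mu):\n")
    m <- round(object@mu, 4)
    dimnames(m) <- list(paste0("A", seq_len(I)), paste0("A", seq_len(I)))
    print(m)
  }
  invisible(object)
})

#' Read or write a site model as a YAML config file
#'
#' The config schema has three keys: \code{n_alleles} (integer),
#' \code{mu} (a scalar, the string \code{"equal"}, or a list of rows of the
#' full matrix) and \code{S} (vector of scaled selection coefficients).
#'
#' @param path file path of the YAML config.
#' @return \code{readSiteModel} returns a [SiteModel-class];
#'   \code{writeSiteModel} invisibly returns \code{path}.
#' @examples
#' f <- tempfile(fileext = ".yaml")
#' writeSiteModel(SiteModel(S = c(0, 1, 2, 4)), f)
#' readSiteModel(f)
#' @export
readSiteModel <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$S)) stop("config is missing key 'S'")
  I <- if (!is.null(cfg$n_alleles)) as.integer(cfg$n_alleles)
       else length(cfg$S)
  mu <- cfg$mu
  if (is.null(mu)) mu <- "equal"
  if (is.list(mu)) mu <- do.call(rbind, lapply(mu, as.numeric))
  SiteModel(S = as.numeric(cfg$S), mu = mu, nAlleles = I)
}

#' @rdname readSiteModel
#' @param model a [SiteModel-class] to serialize.
#' @export
writeSiteModel <- function(model, path) {
  stopifnot(is(model, "SiteModel"))
  off <- model@mu[row(model@mu) != col(model@mu)]
  mu <- if (all(off == 1)) "equal"
        else lapply(seq_len(model@nAlleles),
                    function(i) as.numeric(model@mu[i, ]))
  yaml::write_yaml(list(n_alleles = as.integer(model@nAlleles),
                        mu = mu, S = as.numeric(model@S)), path,
                   precision = 15L)
  invisible(path)
}
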