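# Numerical experiments over selection regimes and mutation matrices:
# grids of scaled selection coefficients (with S1 = 0 for the reference
# allele), ensembles of random mutation matrices, and the search for the
# slowest attainable effective rate.

.sweepRow <- function(S, mu) {
  s <- trajectorySummary(SiteModel(S = S, mu = mu), nGrid = 2L)
  c(E = s@E, tHalf = s@tHalf, rEff = s@rEff, decel = s@decel)
}

#' Sweep divergence summaries over a grid of selection regimes
#'
#' For every combination \eqn{(S_2, S_3, S_4)} of the supplied grids (the
#' reference allele keeps \eqn{S_1 = 0}), computes the divergence-curve
#' summaries via [trajectorySummary()]. The default grids
#' \{0, 1, 2, 4, 8\} span neutrality to effectively forbidden alleles.
#'
#' @param S2grid,S3grid,S4grid numeric grids of scaled selection
#'   coefficients (finite, \eqn{\ge 0}).
#' @param mu mutation rates as in [SiteModel()] (default: all equal).
#' @return a [SweepResult-class] with one row per grid point, sorted
#'   lexicographically by \eqn{(S_2, S_3, S_4)}.
#' @examples
#' sw <- selectionGridSweep(S2grid = c(0, 2), S3grid = c(0, 2),
#'                          S4grid = c(0, 2))
#' sweepTable(sw)
#' @export
selectionGridSweep <- function(S2grid = c(0, 1, 2, 4, 8),
                               S3grid = c(0, 1, 2, 4, 8),
                               S4grid = c(0, 1, 2, 4, 8),
                               mu = "equal") {
  stopifnot(all(is.finite(c(S2grid, S3grid, S4grid))),
            all(c(S2grid, S3grid, S4grid) >= 0))
  pts <- expand.grid(S4 = S4grid, S3 = S3grid, S2 = S2grid)[, 3:1]
  pts <- pts[order(pts$S2, pts$S3, pts$S4), , drop = FALSE]
  rows <- t(apply(pts, 1L, function(s)
    .sweepRow(c(0, s[["S2"]], s[["S3"]], s[["S4"]]), mu)))
  tab <- cbind(pts, as.data.frame(rows))
  rownames(tab) <- NULL
  new("SweepResult", table = tab,
      provenance = list(kind = "selection_grid",
                        S2grid = S2grid, S3grid = S3grid, S4grid = S4grid,
                        mu = if (is.character(mu)) mu else "matrix"))
}

.drawMuMatrix <- function(I, low, high, symmetric) {
  m <- matrix(0, I, I)
  if (symmetric) {
    for (i in seq_len(I - 1L)) for (j in (i + 1L):I) {
      m[i, j] <- stats::runif(1L, low, high)
      m[j, i] <- m[i, j]
    }
  } else {
    for (i in seq_len(I)) for (j in seq_len(I)) {
      if (i != j) m[i, j] <- stats::runif(1L, low, high)
    }
  }
  m
}

#' Average half-approach periods over random mutation matrices
#'
#' For each selection mode, draws \code{nMatrices} mutation matrices with
#' off-diagonal entries uniform on \code{[low, high]} — either symmetric
#' (upper triangle drawn and mirrored) or arbitrary (all off-diagonals
#' drawn independently) — computes the half-approach period of each, and
#' reports per-mode averages. Matrices are used exactly as drawn (their
#' mean rate is \eqn{(low+high)/2 = 1} by default, the reference rate);
#' set \code{normalize = TRUE} to rescale each draw's mean off-diagonal
#' rate to 1 for sensitivity analysis. Because averaging the period and
#' averaging the rate answer slightly different questions, both the mean
#' of \eqn{t_{1/2}} (with \eqn{\ln 2 /} that mean) and the mean of
#' \eqn{r_{\mathrm{eff}}} are reported.
#'
#' @param selectionModes list of numeric vectors of scaled selection
#'   coefficients (each a full \eqn{S} vector including the leading 0).
#' @param nMatrices draws per mode.
#' @param low,high bounds of the uniform distribution, \eqn{0 < low < high}.
#' @param symmetric draw symmetric matrices?
#' @param seed integer RNG seed.
#' @param normalize rescale each matrix's mean off-diagonal rate to 1.
#' @return a [SweepResult-class]; one row per mode with columns
#'   \code{meanTHalf}, \code{sdTHalf}, \code{rOfMeanTHalf},
#'   \code{meanREff}.
#' @examples
#' randomMuSweep(list(c(0, 0, 0, 0)), nMatrices = 10, seed = 1)
#' @export
randomMuSweep <- function(selectionModes, nMatrices = 1000L, low = 0.5,
                          high = 1.5, symmetric = TRUE, seed = 1L,
                          normalize = FALSE) {
  stopifnot(is.list(selectionModes), nMatrices >= 1, low > 0, high > low)
  set.seed(as.integer(seed))
  rows <- lapply(selectionModes, function(S) {
    I <- length(S)
    th <- vapply(seq_len(nMatrices), function(k) {
      m <- .drawMuMatrix(I, low, high, symmetric)
      if (normalize) m <- m / mean(m[row(m) != col(m)])
      .sweepRow(S, m)[["tHalf"]]
    }, numeric(1))
    data.frame(mode = paste(S, collapse = ","),
               meanTHalf = mean(th), sdTHalf = stats::sd(th),
               rOfMeanTHalf = log(2) / mean(th),
               meanREff = mean(log(2) / th))
  })
  new("SweepResult", table = do.call(rbind, rows),
      provenance = list(kind = "random_mu", nMatrices = nMatrices,
                        low = low, high = high, symmetric = symmetric,
                        seed = as.integer(seed), normalize = normalize))
}

#' Search for the slowest effective relaxation rate
#'
#' Minimizes \eqn{r_{\mathrm{eff}} = \ln 2 / t_{0,1/2}} over scaled
#' selection coefficients \eqn{(S_2, S_3, S_4)} in a box
#' \eqn{[0, S_{max}]^3}: a coarse grid scan followed by bound-constrained
#' local refinement (L-BFGS-B) from the grid minimizer. With equal
#' mutation rates the minimum sits at the boundary regime of two equally
#' fit alleles and two effectively forbidden ones, with
#' \eqn{r_{\mathrm{eff}}} just above \eqn{4\mu}.
#'
#' @param SMax box upper bound (the conventional strong-selection endpoint
#'   is 8; larger values tighten the approach to the \eqn{4\mu} limit).
#' @param mu mutation rates as in [SiteModel()].
#' @param grid coarse scan grid within \eqn{[0, S_{max}]}.
#' @param refine run the local refinement step?
#' @return list with the minimizing coefficients \code{S} (length 4,
#'   leading 0), the minimal \code{rEff} (units \eqn{\mu}) and the coarse
#'   grid minimum \code{rEffGrid}.
#' @examples
#' minRateSearch(SMax = 8)$rEff    # just above 4
#' @export
minRateSearch <- function(SMax = 8, mu = "equal",
                          grid = c(0, 1, 2, 4, 8), refine = TRUE) {
  grid <- grid[grid <= SMax]
  objective <- function(s) log(2) /
    halfApproachTime(SiteModel(S = c(0, s), mu = mu))
  pts <- as.matrix(expand.grid(S2 = grid, S3 = grid, S4 = grid))
  vals <- apply(pts, 1L, objective)
  best <- which.min(vals)
  sBest <- pts[best, ]
  vBest <- vals[best]
  if (refine && length(grid) > 1L) {
    opt <- stats::optim(sBest, objective, method = "L-BFGS-B",
                        lower = rep(0, 3), upper = rep(SMax, 3),
                        control = list(factr = 1e4))
    if (opt$value < vBest) {
      sBest <- opt$par
      vBest <- opt$value
    }
  }
  list(S = c(0, unname(sBest)), rEff = vBest, rEffGrid = vals[best])
}

#' @rdname SweepResult-class
#' @export
setMethod("sweepTable", "SweepResult", function(x) x@table)

#' @rdname SweepResult-class
#' @export
setMethod("provenance", "SweepResult", function(x) x@provenance)

setMethod("show", "SweepResult", function(object) {
  cat(sprintf("SweepResult (%s): %d rows\n",
              object@provenance$kind %||% "sweep", nrow(object@table)))
  print(utils::head(object@table, 10L), row.names = FALSE)
  if (nrow(object@table) > 10L)
    cat(sprintf("  ... %d more rows\n", nrow(object@table) - 10L))
  invisible(object)
})

`%||%` <- function(a, b) if (is.null(a)) b else a
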