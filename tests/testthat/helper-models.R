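# Shared fixtures: random site models and an independent ODE oracle for
# the divergence of two independent lineages.

# A random 4-allele model with S_i in [0, Smax] and off-diagonal mutation
# rates uniform in [muLow, muHigh] (asymmetric unless symmetric = TRUE).
randomSiteModel <- function(Smax = 8, muLow = 0.5, muHigh = 1.5,
                            I = 4L, symmetric = FALSE) {
  S <- c(0, runif(I - 1L, 0, Smax))
  m <- matrix(runif(I * I, muLow, muHigh), I, I)
  if (symmetric) m[lower.tri(m)] <- t(m)[lower.tri(m)]
  diag(m) <- 0
  SiteModel(S = S, mu = m)
}

# Independent oracle: integrate the ordered-pair master equation with
# deSolve directly from first principles (both lineages evolve by the
# model's generator; ancestor drawn from equilibrium). Only the generator
# and stationary distribution are taken from the package; the dynamics are
# built here.
oraclePairDivergence <- function(model, times) {
  Q <- generator(rateMatrix(model))
  X <- stationaryFreqs(equilibrium(model))
  I <- nrow(Q)
  rhs <- function(t, y, p) {
    pm <- matrix(y, I, I)
    list(as.vector(t(Q) %*% pm + pm %*% Q))
  }
  sol <- deSolve::ode(as.vector(diag(X)), times, rhs, NULL,
                      rtol = 1e-11, atol = 1e-13)
  apply(sol[, -1, drop = FALSE], 1, function(v)
    1 - sum(diag(matrix(v, I, I))))
}

# Write a small FASTA file for I/O tests.
writeFasta <- function(records, path = tempfile(fileext = ".fa")) {
  lines <- unlist(lapply(names(records), function(nm)
    c(paste0(">", nm), records[[nm]])))
  writeLines(lines, path)
  path
}
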