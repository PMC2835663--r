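# Monte Carlo realization of the origin-fixation process: each site is an
# independent continuous-time Markov chain on the alleles, run along two
# lineages from a common equilibrium ancestor. Direct jump-chain
# simulation (exponential waiting times, embedded jump probabilities
# f_ij / -Q_ii); rates are O(mu) and sites are independent, so this is
# exact and fast at the scales used here.

# Advance a vector of allele states from time 0 to `tEnd`, vectorized over
# sites: repeatedly draw waiting times for all still-active sites and
# resolve jumps grouped by current allele.
.advanceLineage <- function(alleles, tEnd, f, outRate) {
  tcur <- numeric(length(alleles))
  active <- rep(TRUE, length(alleles))
  while (any(active)) {
    idx <- which(active)
    a <- alleles[idx]
    wait <- stats::rexp(length(idx), rate = outRate[a])
    tnew <- tcur[idx] + wait
    jump <- tnew <= tEnd
    tcur[idx] <- tnew
    active[idx[!jump]] <- FALSE
    jidx <- idx[jump]
    if (length(jidx)) {
      ja <- alleles[jidx]
      for (al in unique(ja)) {
        sel <- jidx[ja == al]
        alleles[sel] <- sample.int(ncol(f), length(sel), replace = TRUE,
                                   prob = f[al, ] / outRate[al])
      }
    }
  }
  alleles
}

#' Simulate many independent sites along two lineages
#'
#' Draws the ancestral allele of each site from the equilibrium
#' distribution, evolves two independent lineages by the jump chain of the
#' replacement generator, and records the mismatch fraction
#' \eqn{\hat D(t)} at each observation time. Results are bit-for-bit
#' reproducible for a given seed.
#'
#' @param model a [SiteModel-class].
#' @param nSites number of independent sites (\eqn{\ge 1}).
#' @param times increasing observation grid (\eqn{1/\mu} units,
#'   \eqn{\ge 0}).
#' @param seed integer RNG seed.
#' @param keepSequences if TRUE, retain the pair of allele-index sequences
#'   at every observation time (needed by [writeAlignment()]).
#' @return a [SimulationRun-class].
#' @examples
#' run <- simulateSites(SiteModel(S = c(0, 0, 0, 0)), nSites = 1000,
#'                      times = c(0, 0.0866, 0.5), seed = 1)
#' run   # D_hat near 0, 3/8, 3/4
#' @export
simulateSites <- function(model, nSites, times, seed,
                          keepSequences = FALSE) {
  stopifnot(is(model, "SiteModel"))
  if (!is.numeric(nSites) || length(nSites) != 1L || nSites < 1)
    stop("nSites must be a positive count")
  if (length(times) < 1L || any(times < 0) || is.unsorted(times, strictly = TRUE))
    stop("times must be a strictly increasing grid of non-negative times")
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("seed must be a single finite integer")
  nSites <- as.integer(nSites)
  set.seed(as.integer(seed))
  f <- replacementRates(rateMatrix(model))
  outRate <- rowSums(f)
  X <- stationaryFreqs(equilibrium(model))
  anc <- sample.int(nAlleles(model), nSites, replace = TRUE, prob = X)
  lin1 <- anc
  lin2 <- anc
  DHat <- numeric(length(times))
  seqs <- vector("list", length(times))
  tPrev <- 0
  for (k in seq_along(times)) {
    dt <- times[k] - tPrev
    if (dt > 0) {
      lin1 <- .advanceLineage(lin1, dt, f, outRate)
      lin2 <- .advanceLineage(lin2, dt, f, outRate)
    }
    tPrev <- times[k]
    DHat[k] <- mean(lin1 != lin2)
    if (keepSequences) seqs[[k]] <- rbind(lin1, lin2)
  }
  new("SimulationRun", nSites = nSites, times = as.numeric(times),
      DHat = DHat, SE = sqrt(DHat * (1 - DHat) / nSites),
      seed = as.integer(seed),
      sequences = if (keepSequences) seqs else list())
}

setMethod("show", "SimulationRun", function(object) {
  cat(sprintf("SimulationRun: %d sites, seed %d%s\n", object@nSites,
              object@seed,
              if (length(object@sequences)) ", sequences retained" else ""))
  print(data.frame(time = object@times, D_hat = object@DHat,
                   SE = signif(object@SE, 3)), row.names = FALSE)
  invisible(object)
})

#' Write a simulated sequence pair as aligned FASTA
#'
#' Maps allele indices 1-4 to the nucleotides A, T, G, C and writes the
#' two lineages at one observation time as a standard 2-record aligned
#' FASTA file (60-column wrapping). Headers record the selection
#' coefficients, observation time and seed, so the file round-trips
#' through [readFastaPair()] and [observedDivergence()] to exactly the
#' run's stored mismatch fraction.
#'
#' @param run a [SimulationRun-class] created with
#'   \code{keepSequences = TRUE}.
#' @param timeIndex index into the run's observation grid.
#' @param path output file path.
#' @param model the [SiteModel-class] used for the run (only its
#'   coefficients are echoed into the headers; optional).
#' @return invisibly, \code{path}.
#' @export
writeAlignment <- function(run, timeIndex, path, model = NULL) {
  stopifnot(is(run, "SimulationRun"))
  if (!length(run@sequences))
    stop("run has no retained sequences; rerun simulateSites with keepSequences = TRUE")
  if (timeIndex < 1L || timeIndex > length(run@times))
    stop("timeIndex out of range")
  mat <- run@sequences[[timeIndex]]
  if (max(mat) > 4L)
    stop("FASTA output supports at most 4 alleles (A, T, G, C)")
  letters4 <- c("A", "T", "G", "C")
  tag <- sprintf("t=%g seed=%d%s", run@times[timeIndex], run@seed,
                 if (!is.null(model))
                   paste0(" S=", paste(selectionCoefficients(model),
                                       collapse = ","))
                 else "")
  dna <- Biostrings::DNAStringSet(c(
    lineage1 = paste(letters4[mat[1L, ]], collapse = ""),
    lineage2 = paste(letters4[mat[2L, ]], collapse = "")))
  names(dna) <- paste(names(dna), tag)
  Biostrings::writeXStringSet(dna, filepath = path, width = 60L)
  invisible(path)
}
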