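#' Read an aligned pair of sequences from FASTA
#'
#' Reads a FASTA file that must contain exactly two records of equal
#' length, case-folds them to upper case, maps U to T, and computes the
#' per-site comparability mask (both characters in A/C/G/T; gaps, N and
#' other ambiguity codes are excluded pairwise).
#'
#' @param path path to the FASTA file.
#' @return an [AlignedPair-class].
#' @examples
#' f <- tempfile(fileext = ".fa")
#' writeLines(c(">a", "ACGT", ">b", "ACGA"), f)
#' readFastaPair(f)
#' @export
readFastaPair <- function(path) {
  recs <- Biostrings::readBStringSet(path)
  if (length(recs) == 0L) stop("empty FASTA file: ", path)
  if (length(recs) != 2L)
    stop("expected exactly 2 sequences, found ", length(recs))
  s <- toupper(as.character(recs))
  s <- gsub("U", "T", s, fixed = TRUE)
  if (nchar(s[1]) != nchar(s[2]))
    stop("unaligned pair: sequence lengths ", nchar(s[1]), " and ",
         nchar(s[2]), " differ")
  s1 <- strsplit(s[1], "", fixed = TRUE)[[1]]
  s2 <- strsplit(s[2], "", fixed = TRUE)[[1]]
  bases <- c("A", "C", "G", "T")
  new("AlignedPair", seq1 = s1, seq2 = s2,
      comparable = s1 %in% bases & s2 %in% bases)
}

setMethod("show", "AlignedPair", function(object) {
  cat(sprintf("AlignedPair: length %d, %d comparable sites\n",
              length(object@seq1), sum(object@comparable)))
  invisible(object)
})

#' Observed divergence of an aligned pair
#'
#' The fraction of comparable homologous sites occupied by different
#' nucleotides, plus the Jukes-Cantor corrected number of substitutions
#' per site. Errors if no site is comparable, and propagates the
#' saturation error of [jukesCantor()] when \eqn{D \ge 3/4}.
#'
#' @param pair an [AlignedPair-class].
#' @return list with \code{D}, \code{nCompared} and \code{K}.
#' @examples
#' f <- tempfile(fileext = ".fa")
#' writeLines(c(">a", "ACGT", ">b", "ACGA"), f)
#' observedDivergence(readFastaPair(f))   # D = 0.25, K ~ 0.304
#' @export
observedDivergence <- function(pair) {
  stopifnot(is(pair, "AlignedPair"))
  n <- sum(pair@comparable)
  if (n == 0L) stop("no comparable sites (all gapped or ambiguous)")
  D <- sum(pair@seq1[pair@comparable] != pair@seq2[pair@comparable]) / n
  list(D = D, nCompared = n, K = jukesCantor(D))
}
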