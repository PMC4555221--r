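## Synthetic-data generator: random coding sequences and simulated
## screens with exactly the statistical structure the analysis assumes,
## so every stage is testable end-to-end without external data.

#' Generate a random coding sequence
#'
#' Interior codons are sampled base-by-base with P(G) = P(C) = gc/2 and
#' P(A) = P(T) = (1-gc)/2, rejecting stop codons, so the sequence is a
#' valid CDS by construction and matches the GC target in expectation
#' (the fixed ATG initiator and the stop codon dilute it slightly).
#'
#' @param nCodons total codon count including initiator and terminator
#'   (>= 3).
#' @param gc target GC fraction of interior codons, in (0, 1).
#' @param seed optional integer seed for reproducibility.
#' @param id sequence identifier.
#' @return a [CodingSequence-class] with no excluded codon.
#' @examples
#' randomCDS(10, seed = 1)
#' @export
randomCDS <- function(nCodons, gc = 0.5, seed = NULL,
                      id = sprintf("synthetic_%d", nCodons)) {
  stopifnot(nCodons >= 3, gc > 0, gc < 1)
  if (!is.null(seed)) set.seed(seed)
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  nInterior <- nCodons - 2L
  interior <- character(nInterior)
  i <- 1L
  while (i <= nInterior) {
    codon <- paste(sample(names(p), 3L, replace = TRUE, prob = p),
                   collapse = "")
    if (Biostrings::GENETIC_CODE[[codon]] != "*") {
      interior[i] <- codon
      i <- i + 1L
    }
  }
  stop <- sample(c("TAA", "TAG", "TGA"), 1L)
  codingSequence(paste(c("ATG", interior, stop), collapse = ""), id = id)
}

#' Simulate a mutant screen over the accessible mutation space
#'
#' Enumerates the accessible mutation classes of a CDS under a spectrum
#' and draws each class's recovery count from Poisson(lambda * weight),
#' where a class is a distinct protein change (residue, ref_aa, alt_aa)
#' and its weight is its number of distinct nucleotide routes (a Trp PTC
#' has two under EMS, a Gln PTC one).  This is the generative twin of the
#' model fitted by [fitRate()] / [screenModel()].
#'
#' @param cds a [CodingSequence-class].
#' @param spectrum a [MutagenSpectrum-class] (default EMS).
#' @param lambda nonnegative per-route mean recovery rate.
#' @param seed optional integer seed.
#' @param classes which consequence classes form the target space:
#'   `"nonsense"` (default; the PTC saturation argument) or
#'   `"nonsynonymous"` (missense + nonsense).
#' @param routeWeights logical; weight each class by its route count
#'   (default `TRUE`).  With `FALSE` every class has weight 1.
#' @return data.frame with columns `class`, `residue`, `ref_aa`,
#'   `alt_aa`, `weight`, `count`.
#' @examples
#' sim <- simulateScreen(egfpCDS(), lambda = 3, seed = 1)
#' sum(sim$count == 0)   # classes the simulated screen missed
#' @export
simulateScreen <- function(cds, spectrum = emsSpectrum(), lambda,
                           seed = NULL,
                           classes = c("nonsense", "nonsynonymous"),
                           routeWeights = TRUE) {
  stopifnot(lambda >= 0)
  classes <- match.arg(classes)
  if (!is.null(seed)) set.seed(seed)
  scan <- enumerateAccessibleMutations(cds, spectrum)
  keep <- switch(classes,
    nonsense = scan$consequence == "nonsense",
    nonsynonymous = scan$consequence %in% c("missense", "nonsense"))
  scan <- scan[keep & !is.na(scan$residue), , drop = FALSE]
  if (nrow(scan) == 0L)
    return(data.frame(class = character(0), residue = integer(0),
                      ref_aa = character(0), alt_aa = character(0),
                      weight = numeric(0), count = integer(0)))
  key <- sprintf("%s%d%s", scan$ref_aa, scan$residue, scan$alt_aa)
  agg <- aggregate(list(weight = key), by = list(class = key), FUN = length)
  meta <- scan[!duplicated(key), c("residue", "ref_aa", "alt_aa")]
  meta$class <- key[!duplicated(key)]
  out <- merge(meta, agg, by = "class", sort = FALSE)
  out <- out[order(out$residue, out$alt_aa), , drop = FALSE]
  if (!routeWeights) out$weight <- 1
  out$count <- rpois(nrow(out), lambda * out$weight)
  rownames(out) <- NULL
  out[, c("class", "residue", "ref_aa", "alt_aa", "weight", "count")]
}
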