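## Coding-sequence representation and the dual coordinate system.
##
## Physical coordinates are 1-based over the stored sequence.  Reported
## coordinates renumber residues after dropping the excluded insertion
## codon, so that e.g. the single Trp of the EGFP fixture is residue 57
## and its codon occupies reported nucleotides 169-171, matching the
## G170A/G171A arithmetic of the screen literature.

#' Construct a CodingSequence
#'
#' @param bases a [Biostrings::DNAString], or a character string of bases.
#' @param id sequence identifier.
#' @param excludedCodon optional 1-based codon index of an engineered
#'   insertion codon excluded from reported numbering (labelled "1a").
#'   `NA` (default) means every codon is numbered.
#'
#' @return a validated [CodingSequence-class] object.
#' @examples
#' cds <- codingSequence("ATGGGATAA", id = "toy")
#' nResidues(cds)   # 2: Met1, Gly2 (terminator not counted)
#' @export
codingSequence <- function(bases, id = "cds", excludedCodon = NA) {
  if (is.character(bases)) {
    ## validate the raw characters before DNAString() can coerce case or
    ## admit IUPAC ambiguity codes
    bad <- regexpr("[^ACGT]", bases)
    if (bad > 0L)
      stop(sprintf("invalid base '%s' at position %d: only upper-case A/C/G/T are allowed (no lower case, no IUPAC ambiguity codes)",
                   substr(bases, bad, bad), bad))
    bases <- Biostrings::DNAString(bases)
  }
  new("CodingSequence", id = as.character(id), bases = bases,
      excludedCodon = as.integer(excludedCodon))
}

#' Load a coding sequence from a FASTA file
#'
#' Reads a single-record FASTA file (line wrapping is tolerated) and
#' validates it as a CDS.  Lower-case and IUPAC ambiguity bases are
#' rejected, not coerced: an exact consequence classification is undefined
#' for ambiguous bases.
#'
#' @param path path to a FASTA file containing exactly one DNA record.
#' @inheritParams codingSequence
#' @return a [CodingSequence-class].
#' @examples
#' fa <- egfpFastaPath()
#' cds <- loadCDS(fa, excludedCodon = 2)
#' nResidues(cds)   # 238
#' @export
loadCDS <- function(path, excludedCodon = NA) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  ## read with Biostrings, but keep the raw characters: readDNAStringSet
  ## would silently accept IUPAC codes that we must reject.
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^>", lines)
  if (length(hdr) != 1L)
    stop("expected exactly one FASTA record, found ", length(hdr))
  id <- sub("^>\\s*", "", lines[hdr])
  id <- sub("\\s.*$", "", id)
  seq <- paste(lines[-seq_len(hdr)], collapse = "")
  seq <- gsub("[[:space:]]", "", seq)
  codingSequence(seq, id = id, excludedCodon = excludedCodon)
}

#' @rdname cdsId
#' @export
setMethod("cdsId", "CodingSequence", function(x) x@id)
#' @rdname cdsBases
#' @export
setMethod("cdsBases", "CodingSequence", function(x) x@bases)
#' @rdname excludedCodon
#' @export
setMethod("excludedCodon", "CodingSequence", function(x) x@excludedCodon)
#' @rdname nCodons
#' @export
setMethod("nCodons", "CodingSequence", function(x) length(x@bases) %/% 3L)
#' @rdname nResidues
#' @export
setMethod("nResidues", "CodingSequence",
  function(x) nCodons(x) - 1L - !is.na(x@excludedCodon))

setMethod("show", "CodingSequence", function(object) {
  e <- excludedCodon(object)
  cat("CodingSequence '", cdsId(object), "': ", length(object@bases),
      " bp, ", nResidues(object), " reported residues",
      if (!is.na(e)) sprintf(" (codon %d excluded as '1a')", e) else "",
      "\n", sep = "")
})

## -- internal codon bookkeeping ---------------------------------------------

.codonStrings <- function(cds) {
  s <- as.character(cdsBases(cds))
  substring(s, seq(1L, nchar(s), 3L), seq(3L, nchar(s), 3L))
}

## Sequential rank of each codon after dropping the excluded one (NA for
## the excluded codon itself).  The terminator keeps its rank so that its
## bases retain contiguous reported nucleotide positions.
.codonRanks <- function(cds) {
  n <- nCodons(cds)
  e <- excludedCodon(cds)
  r <- seq_len(n)
  if (!is.na(e)) {
    r[r > e] <- r[r > e] - 1L
    r[e] <- NA_integer_
  }
  r
}

## Human-readable residue label per codon: "1", "1a", ..., "ter".
.codonLabels <- function(cds) {
  r <- .codonRanks(cds)
  lab <- as.character(r)
  e <- excludedCodon(cds)
  if (!is.na(e)) lab[e] <- "1a"
  lab[length(lab)] <- "ter"
  lab
}

## Reported residue number per codon (NA for "1a" and the terminator).
.codonResidues <- function(cds) {
  r <- .codonRanks(cds)
  r[length(r)] <- NA_integer_
  r
}

#' Reported nucleotide position of a base
#'
#' Base `b` (1, 2 or 3) of the codon at physical index `codonIndex` maps to
#' reported nucleotide position `3 * (r - 1) + b`, where `r` is the codon's
#' reported rank after dropping the excluded insertion codon.  Querying a
#' base of the excluded codon is an error: its bases carry no reported
#' number.
#'
#' @param cds a [CodingSequence-class].
#' @param codonIndex physical 1-based codon index.
#' @param baseInCodon base within the codon, 1..3.
#' @return integer reported nucleotide position (1-based).
#' @examples
#' cds <- loadCDS(egfpFastaPath(), excludedCodon = 2)
#' reportedPosition(cds, 58, 2)  # codon of residue 57, base 2 -> 170
#' @export
reportedPosition <- function(cds, codonIndex, baseInCodon) {
  stopifnot(is(cds, "CodingSequence"))
  n <- nCodons(cds)
  if (any(codonIndex < 1L | codonIndex > n))
    stop("codon index out of range 1..", n)
  if (any(!baseInCodon %in% 1:3))
    stop("baseInCodon must be 1, 2 or 3")
  r <- .codonRanks(cds)[codonIndex]
  if (anyNA(r))
    stop("unnumbered insertion: codon ", excludedCodon(cds),
         " is excluded from reported numbering")
  3L * (r - 1L) + as.integer(baseInCodon)
}

#' Physical base offset of a reported nucleotide position
#'
#' Inverse of [reportedPosition()]: maps a reported, 1-based nucleotide
#' position back to the physical 1-based offset within the stored
#' sequence (which still contains the excluded codon's bases).
#'
#' @inheritParams reportedPosition
#' @param ntPosition reported nucleotide position (1-based).
#' @return integer physical offset (1-based).
#' @export
physicalPosition <- function(cds, ntPosition) {
  stopifnot(is(cds, "CodingSequence"))
  p <- as.integer(ntPosition)
  if (any(p < 1L | p > 3L * (nCodons(cds) - !is.na(excludedCodon(cds)))))
    stop("reported nucleotide position out of range")
  r <- (p - 1L) %/% 3L + 1L          # reported codon rank
  b <- (p - 1L) %% 3L + 1L
  e <- excludedCodon(cds)
  i <- if (is.na(e)) r else ifelse(r >= e, r + 1L, r)
  (i - 1L) * 3L + b
}

#' Translate a coding sequence
#'
#' `translateCDS()` returns one amino acid per codon (terminator excluded),
#' named by reported residue label; the excluded insertion codon appears
#' under the label `"1a"`.  `reportedProtein()` drops the `"1a"` residue and
#' returns a plain character vector indexed by reported residue number --
#' `reportedProtein(cds)[57]` is the residue the screen literature calls 57.
#'
#' Translation is a direct lookup in the standard genetic code
#' ([Biostrings::GENETIC_CODE]); alternative initiator codons are not
#' remapped (an interior CTG is Leu, never Met).
#'
#' @param cds a [CodingSequence-class].
#' @return `translateCDS()`: named character vector of one-letter residues;
#'   `reportedProtein()`: unnamed character vector of length
#'   `nResidues(cds)`.
#' @examples
#' cds <- loadCDS(egfpFastaPath(), excludedCodon = 2)
#' translateCDS(cds)[["1a"]]   # "V"
#' reportedProtein(cds)[57]    # "W"
#' @export
translateCDS <- function(cds) {
  stopifnot(is(cds, "CodingSequence"))
  codons <- .codonStrings(cds)
  aa <- unname(Biostrings::GENETIC_CODE[codons])
  lab <- .codonLabels(cds)
  keep <- seq_len(length(aa) - 1L)    # drop terminator
  structure(aa[keep], names = lab[keep])
}

#' @rdname translateCDS
#' @export
reportedProtein <- function(cds) {
  aa <- translateCDS(cds)
  unname(aa[names(aa) != "1a"])
}
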