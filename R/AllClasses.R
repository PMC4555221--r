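## Central S4 classes.  Validity is strict: the scan is exact arithmetic on
## codons, so malformed sequences are rejected up front rather than coerced.

#' CodingSequence: a validated protein-coding DNA sequence
#'
#' A single open reading frame over \{A,C,G,T\}: starts with ATG, length a
#' multiple of three, exactly one in-frame stop codon at the end.  An
#' optional `excludedCodon` marks an engineered insertion codon (for the
#' EGFP fixture, the GTG/Val codon after the initiator) that is translated
#' and scanned but labelled "1a" and excluded from reported residue and
#' nucleotide numbering, so that coordinates match the wild-type protein.
#'
#' @slot id single character, sequence identifier.
#' @slot bases a [Biostrings::DNAString] holding the CDS.
#' @slot excludedCodon integer(1), 1-based codon index of the excluded
#'   insertion codon, or `NA` when there is none.  May not be the
#'   initiator or the terminator codon.
#'
#' @seealso [loadCDS()], [codingSequence()], [translateCDS()],
#'   [reportedPosition()]
#' @export
setClass("CodingSequence",
  slots = c(id = "character", bases = "DNAString", excludedCodon = "integer"))

setValidity("CodingSequence", function(object) {
  s <- as.character(object@bases)
  n <- nchar(s)
  if (length(object@id) != 1L || is.na(object@id) || !nzchar(object@id))
    return("'id' must be a single non-empty string")
  if (grepl("[^ACGT]", s))
    return(sprintf("invalid base at position %d: only A/C/G/T are allowed (no lower case, no IUPAC ambiguity codes)",
                   regexpr("[^ACGT]", s)))
  if (n %% 3L != 0L)
    return(sprintf("sequence length %d is not a multiple of 3", n))
  if (n < 9L)
    return("a CDS needs at least 3 codons (start, one residue, stop)")
  codons <- substring(s, seq(1L, n, 3L), seq(3L, n, 3L))
  if (codons[1L] != "ATG")
    return(sprintf("missing ATG initiator: codon 1 is %s", codons[1L]))
  aa <- unname(Biostrings::GENETIC_CODE[codons])
  k <- length(codons)
  if (aa[k] != "*")
    return(sprintf("missing terminator: final codon %d is %s", k, codons[k]))
  internal <- which(aa[-k] == "*")
  if (length(internal))
    return(sprintf("internal stop codon %s at codon index %d",
                   codons[internal[1L]], internal[1L]))
  e <- object@excludedCodon
  if (length(e) != 1L)
    return("'excludedCodon' must be a single integer (or NA)")
  if (!is.na(e) && (e <= 1L || e >= k))
    return(sprintf("excludedCodon %d must be an internal codon (not initiator or terminator)", e))
  TRUE
})

#' MutagenSpectrum: the single-base substitutions a mutagen can induce
#'
#' A named set of ordered base substitutions applied to the sense (coding)
#' strand.  The default EMS spectrum is \{C>T, G>A\}: EMS alkylates guanine
#' and produces almost exclusively G:C to A:T transitions, which appear on
#' the coding strand as C>T or G>A depending on which strand carried the
#' alkylated base.  Including both directions therefore captures the
#' chemistry on either strand without a separate strand flag.
#'
#' @slot name single character, spectrum name.
#' @slot ref,alt parallel character vectors of reference and alternate
#'   bases; `ref[i] != alt[i]` for every pair.  May be empty (a "null"
#'   spectrum scans to an empty result).
#'
#' @seealso [emsSpectrum()], [mutagenSpectrum()], [readSpectrumConfig()]
#' @export
setClass("MutagenSpectrum",
  slots = c(name = "character", ref = "character", alt = "character"))

setValidity("MutagenSpectrum", function(object) {
  if (length(object@name) != 1L || !nzchar(object@name))
    return("'name' must be a single non-empty string")
  if (length(object@ref) != length(object@alt))
    return("'ref' and 'alt' must have equal length")
  bad <- !(object@ref %in% c("A", "C", "G", "T")) |
         !(object@alt %in% c("A", "C", "G", "T"))
  if (any(bad))
    return("substitution bases must be in {A,C,G,T}")
  if (any(object@ref == object@alt))
    return("a substitution must change the base (ref != alt)")
  if (anyDuplicated(paste(object@ref, object@alt)))
    return("duplicate substitutions in spectrum")
  TRUE
})

#' ScreenModel: per-class Poisson recovery model for a mutant screen
#'
#' Each accessible mutation class (for instance, each residue at which the
#' mutagen can induce a premature termination codon) is assumed to be
#' recovered a Poisson(lambda * weight) number of times over the course of
#' the screen.  Class weights default to 1; a natural refinement weights a
#' class by its number of distinct nucleotide routes (2 for a tryptophan
#' PTC, 1 for a glutamine PTC under EMS).
#'
#' @slot classes character vector of class identifiers.
#' @slot multiplicities integer vector, times each class was recovered.
#' @slot weights numeric vector of per-class rate multipliers.
#' @slot lambda numeric(1), fitted or supplied mean recovery rate.
#' @slot includeZeros logical(1), whether `lambda` was fitted from the
#'   full multiplicity vector (`TRUE`) or by zero-truncated maximum
#'   likelihood from the positive counts only (`FALSE`).
#'
#' @seealso [screenModel()], [fitRate()], [saturationSummary()]
#' @export
setClass("ScreenModel",
  slots = c(classes = "character", multiplicities = "integer",
            weights = "numeric", lambda = "numeric", includeZeros = "logical"))

setValidity("ScreenModel", function(object) {
  n <- length(object@classes)
  if (length(object@multiplicities) != n || length(object@weights) != n)
    return("'classes', 'multiplicities' and 'weights' must have equal length")
  if (any(object@multiplicities < 0L))
    return("multiplicities must be nonnegative")
  if (any(object@weights <= 0))
    return("weights must be positive")
  if (length(object@lambda) != 1L || is.na(object@lambda) || object@lambda < 0)
    return("'lambda' must be a single nonnegative number")
  TRUE
})
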