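#' @describeIn CodingSequence-class sequence identifier
#' @param x,object a `CodingSequence`, `MutagenSpectrum` or `ScreenModel`
#' @export
setGeneric("cdsId", function(x) standardGeneric("cdsId"))

#' @describeIn CodingSequence-class the bases as a [Biostrings::DNAString]
#' @export
setGeneric("cdsBases", function(x) standardGeneric("cdsBases"))

#' @describeIn CodingSequence-class 1-based index of the excluded insertion
#'   codon, or `NA`
#' @export
setGeneric("excludedCodon", function(x) standardGeneric("excludedCodon"))

#' @describeIn CodingSequence-class number of codons (including initiator,
#'   any excluded codon, and terminator)
#' @export
setGeneric("nCodons", function(x) standardGeneric("nCodons"))

#' @describeIn CodingSequence-class number of reported residues (excluding
#'   the "1a" insertion codon and the terminator)
#' @export
setGeneric("nResidues", function(x) standardGeneric("nResidues"))

#' @describeIn MutagenSpectrum-class spectrum name
#' @export
setGeneric("spectrumName", function(x) standardGeneric("spectrumName"))

#' @describeIn MutagenSpectrum-class substitutions as "X>Y" strings
#' @export
setGeneric("substitutions", function(x) standardGeneric("substitutions"))

#' @describeIn ScreenModel-class fitted mean recovery rate
#' @export
setGeneric("recoveryRate", function(x) standardGeneric("recoveryRate"))

#' @describeIn ScreenModel-class named integer vector of per-class
#'   recovery multiplicities
#' @export
setGeneric("multiplicities", function(x) standardGeneric("multiplicities"))

#' @describeIn ScreenModel-class named numeric vector of per-class weights
#' @export
setGeneric("classWeights", function(x) standardGeneric("classWeights"))
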