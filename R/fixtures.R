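## Packaged fixtures for the EGFP loss-of-function screen.
##
## The coding sequence is a reconstruction (hence the _synthetic suffix):
## the canonical EGFP ORF with the engineered GTG (Val) codon after the
## initiator, in which three leucine codons were recoded synonymously
## (CTC -> CTG at reported residues 60, 178 and 231) so that, as in the
## reporter line the screen literature describes, every Tyr/Phe/Leu/Ile
## codon admits only silent changes under the EMS spectrum.  The encoded
## protein is unchanged and matches every published residue identity.

#' Paths to the packaged EGFP screen fixtures
#'
#' @return `egfpFastaPath()`: single-record FASTA with the reconstructed
#'   EGFP CDS (load with `excludedCodon = 2`, the engineered Val "1a"
#'   codon). `egfpCDS()`: that sequence loaded as a
#'   [CodingSequence-class]. `egfpCatalogPath()`: the 28-entry mutant
#'   catalog TSV. `egfpConservedPath()`: the 21 highly conserved residues
#'   present in this protein. `egfpAnnotationPath()`: minimal secondary
#'   structure annotation (internal helix 56-72, second beta-strand
#'   containing Gly31/33/35, the three lid glycines).
#' @examples
#' egfpCDS()
#' @export
egfpFastaPath <- function()
  system.file("extdata", "egfp_cds_synthetic.fa", package = "emsScan",
              mustWork = TRUE)

#' @rdname egfpFastaPath
#' @export
egfpCDS <- function() loadCDS(egfpFastaPath(), excludedCodon = 2)

#' @rdname egfpFastaPath
#' @export
egfpCatalogPath <- function()
  system.file("extdata", "egfp_catalog.tsv", package = "emsScan",
              mustWork = TRUE)

#' @rdname egfpFastaPath
#' @export
egfpConservedPath <- function()
  system.file("extdata", "egfp_conserved_residues.tsv", package = "emsScan",
              mustWork = TRUE)

#' @rdname egfpFastaPath
#' @export
egfpAnnotationPath <- function()
  system.file("extdata", "egfp_structure_elements.tsv", package = "emsScan",
              mustWork = TRUE)
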