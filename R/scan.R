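## The mutagen scan: exhaustive enumeration of spectrum-permitted single
## nucleotide substitutions and their protein-level consequences.  This is
## the computational counterpart of the per-codon accessibility tables used
## to argue which residues a chemical screen can and cannot probe.

.CONSEQUENCES <- c("synonymous", "missense", "nonsense",
                   "stop_loss", "stop_retained", "start_loss")

#' Classify the protein-level consequence of a codon change
#'
#' Codons must differ at exactly one base.  Labels follow variant-effect
#' conventions: `nonsense` (new in-frame stop), `stop_loss` (terminator
#' becomes coding), `stop_retained` (terminator changes to another stop
#' codon), `start_loss` (initiator ATG destroyed; outranks missense, so an
#' ATG>ATA change at the initiator is `start_loss`, not Met>Ile missense),
#' `synonymous`, `missense`.
#'
#' @param refCodon,altCodon codon strings (vectorised).
#' @param isInitiator,isTerminator logical flags marking the initiator and
#'   terminator codon (recycled).
#' @return character vector of consequence labels.
#' @examples
#' classifyConsequence("CAG", "TAG")  # nonsense
#' classifyConsequence("GAG", "AAG")  # missense (E>K)
#' @export
classifyConsequence <- function(refCodon, altCodon,
                                isInitiator = FALSE, isTerminator = FALSE) {
  n <- max(length(refCodon), length(altCodon))
  refCodon <- rep_len(toupper(refCodon), n)
  altCodon <- rep_len(toupper(altCodon), n)
  isInitiator <- rep_len(isInitiator, n)
  isTerminator <- rep_len(isTerminator, n)
  diffs <- mapply(function(a, b)
    sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]]), refCodon, altCodon)
  if (any(diffs != 1L))
    stop("codons must differ at exactly one base (got ",
         refCodon[diffs != 1L][1L], " -> ", altCodon[diffs != 1L][1L], ")")
  refAA <- unname(Biostrings::GENETIC_CODE[refCodon])
  altAA <- unname(Biostrings::GENETIC_CODE[altCodon])
  out <- ifelse(isInitiator & refCodon == "ATG", "start_loss",
         ifelse(isTerminator & refAA == "*" & altAA == "*", "stop_retained",
         ifelse(isTerminator & refAA == "*", "stop_loss",
         ifelse(altAA == "*", "nonsense",
         ifelse(refAA == altAA, "synonymous", "missense")))))
  out
}

#' Enumerate all spectrum-accessible single-nucleotide changes
#'
#' Walks every base of the CDS and emits one record per (position, allowed
#' substitution) whose reference base matches, with the codon context and
#' the protein-level consequence.  Output order is deterministic: physical
#' position, then alphabetical alternate base.
#'
#' Bases of the excluded insertion codon are scanned but carry
#' `nt_position = NA` and `residue_label = "1a"`; terminator-codon records
#' carry `residue = NA` with label `"ter"`.  Summaries over "reported
#' residues" therefore simply drop rows with `is.na(residue)`.
#'
#' @param cds a [CodingSequence-class].
#' @param spectrum a [MutagenSpectrum-class], or a name understood by the
#'   package (`"EMS"`, `"none"`).
#' @return a data.frame with columns `nt_position`, `ref`, `alt`,
#'   `residue`, `residue_label`, `ref_codon`, `alt_codon`, `ref_aa`,
#'   `alt_aa`, `consequence`, `physical_pos`.
#' @examples
#' cds <- loadCDS(egfpFastaPath(), excludedCodon = 2)
#' scan <- enumerateAccessibleMutations(cds, emsSpectrum())
#' subset(scan, residue == 57)   # the two Trp57 PTC routes, nt 170/171
#' @export
enumerateAccessibleMutations <- function(cds, spectrum = emsSpectrum()) {
  stopifnot(is(cds, "CodingSequence"))
  spectrum <- .resolveSpectrum(spectrum)
  s <- as.character(cdsBases(cds))
  bases <- strsplit(s, "")[[1]]
  L <- length(bases)

  pos <- integer(0); ref <- character(0); alt <- character(0)
  for (i in seq_along(spectrum@ref)) {
    hit <- which(bases == spectrum@ref[i])
    pos <- c(pos, hit)
    ref <- c(ref, rep(spectrum@ref[i], length(hit)))
    alt <- c(alt, rep(spectrum@alt[i], length(hit)))
  }
  o <- order(pos, alt)
  pos <- pos[o]; ref <- ref[o]; alt <- alt[o]

  codonIdx <- (pos - 1L) %/% 3L + 1L
  baseIn <- (pos - 1L) %% 3L + 1L
  codons <- .codonStrings(cds)
  refCodon <- codons[codonIdx]
  altCodon <- refCodon
  substr(altCodon, baseIn, baseIn) <- alt
  labels <- .codonLabels(cds)
  residues <- .codonResidues(cds)
  ranks <- .codonRanks(cds)
  nt <- ifelse(is.na(ranks[codonIdx]), NA_integer_,
               3L * (ranks[codonIdx] - 1L) + baseIn)

  cons <- if (length(pos))
    classifyConsequence(refCodon, altCodon,
                        isInitiator = codonIdx == 1L,
                        isTerminator = codonIdx == nCodons(cds))
  else character(0)

  data.frame(
    nt_position  = as.integer(nt),
    ref          = ref,
    alt          = alt,
    residue      = residues[codonIdx],
    residue_label = labels[codonIdx],
    ref_codon    = refCodon,
    alt_codon    = altCodon,
    ref_aa       = unname(Biostrings::GENETIC_CODE[refCodon]),
    alt_aa       = unname(Biostrings::GENETIC_CODE[altCodon]),
    consequence  = cons,
    physical_pos = as.integer(pos),
    stringsAsFactors = FALSE)
}

#' Residues at which the mutagen can induce a premature termination codon
#'
#' @param changes scan output from [enumerateAccessibleMutations()].
#' @return data.frame with columns `residue` and `ref_aa`, one row per
#'   numbered residue with at least one nonsense-accessible change
#'   (terminator and insertion codon excluded), sorted by residue.
#' @examples
#' cds <- loadCDS(egfpFastaPath(), excludedCodon = 2)
#' ptc <- ptcSusceptibleResidues(enumerateAccessibleMutations(cds))
#' table(ptc$ref_aa)   # 8 Gln, 1 Trp
#' @export
ptcSusceptibleResidues <- function(changes) {
  hit <- changes[changes$consequence == "nonsense" & !is.na(changes$residue),
                 c("residue", "ref_aa")]
  hit <- unique(hit)
  hit[order(hit$residue), , drop = FALSE]
}

#' Per-residue accessibility profile
#'
#' Aggregates the scan per reported residue: the set of accessible
#' alternative amino acids and four mutually consistent flags --
#' `ptc_accessible` (a nonsense change exists), `missense_accessible`,
#' `nonsyn_accessible` (missense, nonsense or start-loss),
#' `only_silent_accessible` (at least one change, all synonymous: the
#' residue is blind to the mutagen at the protein level), and
#' `untouchable` (no in-spectrum change at all).
#'
#' @param changes scan output from [enumerateAccessibleMutations()].
#' @param cds the scanned [CodingSequence-class].
#' @return data.frame with one row per reported residue (1..`nResidues`).
#' @examples
#' cds <- loadCDS(egfpFastaPath(), excludedCodon = 2)
#' prof <- accessibilityProfile(enumerateAccessibleMutations(cds), cds)
#' prof[66, ]   # Tyr66: only_silent_accessible
#' @export
accessibilityProfile <- function(changes, cds) {
  stopifnot(is(cds, "CodingSequence"))
  aa <- reportedProtein(cds)
  n <- nResidues(cds)
  rows <- changes[!is.na(changes$residue), , drop = FALSE]
  byRes <- split(rows, factor(rows$residue, levels = seq_len(n)))
  alts <- vapply(seq_len(n), function(r) {
    d <- byRes[[r]]
    a <- sort(unique(d$alt_aa[d$alt_aa != aa[r]]))
    paste(a, collapse = ",")
  }, character(1))
  nChanges <- vapply(byRes, nrow, integer(1))
  hasCons <- function(lab) vapply(byRes, function(d)
    any(d$consequence %in% lab), logical(1))
  ptc <- hasCons("nonsense")
  mis <- hasCons("missense")
  nonsyn <- hasCons(c("missense", "nonsense", "start_loss"))
  data.frame(
    residue = seq_len(n),
    ref_aa = aa,
    alternatives = alts,
    n_changes = unname(nChanges),
    ptc_accessible = unname(ptc),
    missense_accessible = unname(mis),
    nonsyn_accessible = unname(nonsyn),
    only_silent_accessible = unname(nChanges > 0L & !nonsyn &
      vapply(byRes, function(d) all(d$consequence == "synonymous"), logical(1))),
    untouchable = unname(nChanges == 0L),
    stringsAsFactors = FALSE)
}

#' Write scan output
#'
#' `writeScanTSV()` writes the tab-separated scan table.  `writeScanVCF()`
#' writes a minimal VCF-style file (CHROM = CDS id, POS = reported
#' nucleotide position, INFO carries the consequence); rows without a
#' reported position (insertion-codon bases) are omitted from the VCF.
#'
#' @param changes scan output from [enumerateAccessibleMutations()].
#' @param path output file path.
#' @param cdsId sequence identifier used as the VCF CHROM field.
#' @return the path, invisibly.
#' @export
writeScanTSV <- function(changes, path) {
  cols <- c("nt_position", "ref", "alt", "residue", "residue_label",
            "ref_codon", "alt_codon", "ref_aa", "alt_aa", "consequence")
  write.table(changes[, cols], path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname writeScanTSV
#' @export
writeScanVCF <- function(changes, path, cdsId = "CDS") {
  keep <- changes[!is.na(changes$nt_position), , drop = FALSE]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##INFO=<ID=CSQ,Number=1,Type=String,Description=\"Protein-level consequence\">",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"), con)
  if (nrow(keep))
    writeLines(sprintf("%s\t%d\t.\t%s\t%s\t.\t.\tCSQ=%s",
                       cdsId, keep$nt_position, keep$ref, keep$alt,
                       keep$consequence), con)
  invisible(path)
}
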