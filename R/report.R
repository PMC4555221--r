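## High-level entry points tying the stages together; these back the
## command-line wrapper in inst/scripts/ems-scan.R.

#' Run the accessibility scan on a FASTA file
#'
#' @param fasta path to a single-record FASTA CDS.
#' @param spectrum a [MutagenSpectrum-class] or name (`"EMS"`, `"none"`).
#' @param excludedCodon optional 1-based insertion codon index (for the
#'   packaged EGFP fixture, 2).
#' @param out optional TSV output path.
#' @param vcf optional VCF-style output path.
#' @return the scan data.frame, invisibly.
#' @examples
#' scan <- runScan(egfpFastaPath(), excludedCodon = 2)
#' @export
runScan <- function(fasta, spectrum = "EMS", excludedCodon = NA,
                    out = NULL, vcf = NULL) {
  cds <- loadCDS(fasta, excludedCodon = excludedCodon)
  changes <- enumerateAccessibleMutations(cds, .resolveSpectrum(spectrum))
  if (!is.null(out)) writeScanTSV(changes, out)
  if (!is.null(vcf)) writeScanVCF(changes, vcf, cdsId = cdsId(cds))
  invisible(changes)
}

#' Full screen report: coverage, structural burden, saturation
#'
#' Runs the scan, reconciles the catalog, tabulates structural burden and
#' fits the PTC-class Poisson recovery model, then writes a plain-text
#' summary.  Output is deterministic given identical inputs.
#'
#' @param fasta path to a single-record FASTA CDS.
#' @param catalog path to the observed-mutation catalog TSV.
#' @param annotation optional structure-annotation TSV (defaults to the
#'   packaged EGFP annotation).
#' @param conserved optional conserved-residue TSV (defaults to the
#'   packaged 21-residue list).
#' @param numbering convention the catalog uses, `"wild_type"` (default)
#'   or `"val2_inclusive"` (converted to wild-type before analysis).
#' @param spectrum a [MutagenSpectrum-class] or name.
#' @param excludedCodon optional insertion codon index (default 2, the
#'   packaged fixture's).
#' @param out optional output path for the text report; `NULL` prints to
#'   the console.
#' @return a list with components `scan`, `coverage`, `burden`,
#'   `saturation` and `lines` (the report text), invisibly.
#' @examples
#' rep <- runReport(egfpFastaPath(), egfpCatalogPath())
#' @export
runReport <- function(fasta, catalog,
                      annotation = egfpAnnotationPath(),
                      conserved = egfpConservedPath(),
                      numbering = c("wild_type", "val2_inclusive"),
                      spectrum = "EMS", excludedCodon = 2, out = NULL) {
  numbering <- match.arg(numbering)
  cds <- loadCDS(fasta, excludedCodon = excludedCodon)
  spectrum <- .resolveSpectrum(spectrum)
  entries <- parseCatalog(catalog)
  if (numbering == "val2_inclusive") {
    attr(entries, "numbering") <- "val2_inclusive"
    entries <- renumberCatalog(entries, "wild_type")
  }
  consTab <- loadConservedResidues(conserved, cds)
  cov <- coverageReport(entries, consTab, cds, spectrum)
  burden <- elementBurden(entries, loadAnnotation(annotation, cds))

  ## PTC saturation: classes = PTC-susceptible residues, weights = route
  ## counts, multiplicities = recovered PTC entries per residue
  scan <- enumerateAccessibleMutations(cds, spectrum)
  ptc <- scan[scan$consequence == "nonsense" & !is.na(scan$residue), ]
  classId <- sprintf("%s%d*", ptc$ref_aa, ptc$residue)
  weights <- table(classId)
  obs <- table(sprintf("%s%d*", entries$ref_aa, entries$residue)[
    entries$category == "PTC"])
  mult <- structure(integer(length(weights)), names = names(weights))
  common <- intersect(names(obs), names(mult))
  mult[common] <- as.integer(obs[common])
  model <- screenModel(mult, weights = as.numeric(weights),
                       includeZeros = TRUE)
  sat <- saturationSummary(model)

  lines <- c(
    sprintf("== EMS accessibility scan: %s ==", cdsId(cds)),
    sprintf("reported residues: %d", nResidues(cds)),
    sprintf("accessible changes: %d (%s)", nrow(scan),
            paste(sprintf("%s %d", names(table(scan$consequence)),
                          table(scan$consequence)), collapse = ", ")),
    sprintf("PTC-susceptible residues: %d (%s)",
            nrow(ptcSusceptibleResidues(scan)),
            paste(sort(unique(sprintf("%s%d",
              ptcSusceptibleResidues(scan)$ref_aa,
              ptcSusceptibleResidues(scan)$residue))), collapse = ",")),
    "",
    "== catalog coverage ==",
    sprintf("entries: %d (%s)", cov$n_entries,
            paste(sprintf("%s %d", names(cov$by_category), cov$by_category),
                  collapse = ", ")),
    sprintf("this-study entries: %d", cov$n_this_study),
    sprintf("unique protein changes: %d; unique nucleotide changes: %d",
            cov$n_unique_protein_changes, cov$n_unique_nt_changes),
    sprintf("conserved hit: %d/%d", cov$conserved_hit, cov$conserved_total),
    sprintf("conserved not hit: %s",
            paste(cov$conserved_not_hit_residues, collapse = ",")),
    sprintf("distinct Gln residues with PTC: %d", cov$n_gln_ptc_residues),
    sprintf("nonconserved substituted residues: %d (%s)",
            cov$n_nonconserved_substituted,
            paste(cov$nonconserved_substituted_residues, collapse = ",")),
    sprintf("unrecovered conserved, mutable: %s",
            paste(cov$unrecovered_conserved_mutable, collapse = ",")),
    sprintf("unrecovered conserved, silent-only: %s",
            paste(cov$unrecovered_conserved_silent_only, collapse = ",")),
    sprintf("spectrum-inconsistent entries: %d",
            length(cov$spectrum_inconsistent)),
    "",
    "== structural burden ==",
    sprintf("%s [%s %d-%d]: residues %s", burden$elements$name,
            burden$elements$kind, burden$elements$start,
            burden$elements$end, burden$elements$residues),
    sprintf("unassigned residues: %s",
            paste(burden$unassigned, collapse = ",")),
    "",
    "== PTC saturation (Poisson recovery model; package formalization) ==",
    sprintf("classes: %d, fitted lambda: %.4f", sat$n_classes, sat$lambda),
    sprintf("expected unseen classes: %.3f", sat$expected_unseen),
    sprintf("observed unseen classes: %d (%s)", sat$observed_unseen,
            paste(sat$observed_unseen_classes, collapse = ",")),
    sprintf("P(all classes seen): %.3f", sat$p_all_seen))

  if (is.null(out)) cat(lines, sep = "\n") else writeLines(lines, out)
  invisible(list(scan = scan, coverage = cov, burden = burden,
                 saturation = sat, lines = lines))
}
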