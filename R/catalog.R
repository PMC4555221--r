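## Observed-mutation catalog: parsing, spectrum reconciliation, coverage.

.FLUOR_LEVELS <- c("no", "negligible", "weak", "weak_to_moderate",
                   "moderate", "wt")
.PROTEIN_LEVELS <- c("no", "very_weak", "weak", "wt", "sterile", "na")
.CATEGORIES <- c("PTC", "chromophore", "chromophore_maturation",
                 "stability_lid", "stability_unknown")

.AA1 <- "ACDEFGHIKLMNPQRSTVWY"

.parseProteinChange <- function(token) {
  pat <- sprintf("^([%s])([0-9]+)([%s*])$", .AA1, .AA1)
  m <- regmatches(token, regexec(pat, token))
  bad <- vapply(m, length, integer(1)) != 4L
  if (any(bad))
    stop("malformed protein-change token: ",
         paste(token[bad], collapse = ", "))
  data.frame(ref_aa = vapply(m, `[`, "", 2L),
             residue = as.integer(vapply(m, `[`, "", 3L)),
             alt_aa = vapply(m, `[`, "", 4L),
             stringsAsFactors = FALSE)
}

.parseNtChange <- function(token) {
  out <- data.frame(nt_position = rep(NA_integer_, length(token)),
                    nt_ref = NA_character_, nt_alt = NA_character_,
                    stringsAsFactors = FALSE)
  has <- !is.na(token) & nzchar(token)
  if (any(has)) {
    m <- regmatches(token[has], regexec("^([ACGT])([0-9]+)([ACGT])$", token[has]))
    bad <- vapply(m, length, integer(1)) != 4L
    if (any(bad))
      stop("malformed nucleotide-change token: ",
           paste(token[has][bad], collapse = ", "))
    out$nt_ref[has] <- vapply(m, `[`, "", 2L)
    out$nt_position[has] <- as.integer(vapply(m, `[`, "", 3L))
    out$nt_alt[has] <- vapply(m, `[`, "", 4L)
  }
  out
}

## "label:1,2;other_label" -> named list of integer batch vectors
.parseSources <- function(sources) {
  lapply(strsplit(sources, ";", fixed = TRUE), function(parts) {
    parts <- trimws(parts)
    labs <- sub(":.*$", "", parts)
    batches <- lapply(parts, function(p) {
      if (!grepl(":", p, fixed = TRUE)) return(integer(0))
      as.integer(strsplit(sub("^[^:]*:", "", p), ",", fixed = TRUE)[[1]])
    })
    names(batches) <- labs
    batches
  })
}

#' Parse an observed-mutation catalog
#'
#' Reads a TSV with columns `protein_change` (e.g. `"G67S"`, `"W57*"`),
#' `nt_change` (optional, `"G170A"` syntax), `fluorescence`,
#' `protein_level`, `conserved` (`yes`/`no`/`na`), `category`, `sources`
#' (semicolon-separated `label:batch,batch` groups) and optional `notes`.
#' Phenotype vocabularies are closed; unknown values are rejected.
#' Duplicate (protein_change, nt_change) rows raise a warning and are
#' flagged in a `duplicate` column.
#'
#' Residue numbers are taken to be in wild-type numbering (the engineered
#' insertion codon does not count); see [renumberCatalog()] to convert.
#'
#' @param path catalog TSV path.
#' @return data.frame of validated entries, one row per catalog entry,
#'   with parsed columns `ref_aa`, `residue`, `alt_aa`, `nt_position`,
#'   `nt_ref`, `nt_alt`, a list-column `source_list`, and attribute
#'   `numbering = "wild_type"`.
#' @examples
#' cat28 <- parseCatalog(egfpCatalogPath())
#' nrow(cat28)            # 28
#' table(cat28$category)
#' @export
parseCatalog <- function(path) {
  raw <- read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
  need <- c("protein_change", "nt_change", "fluorescence", "protein_level",
            "conserved", "category", "sources")
  miss <- setdiff(need, names(raw))
  if (length(miss))
    stop("catalog is missing column(s): ", paste(miss, collapse = ", "))
  if (nrow(raw) == 0L) {
    out <- cbind(raw, .parseProteinChange(character(0)))
    attr(out, "numbering") <- "wild_type"
    return(out)
  }
  pc <- .parseProteinChange(raw$protein_change)
  nt <- .parseNtChange(raw$nt_change)
  for (col in c("fluorescence", "protein_level", "conserved", "category")) {
    raw[[col]] <- trimws(raw[[col]])
  }
  checkVocab <- function(values, allowed, what) {
    bad <- !values %in% allowed
    if (any(bad))
      stop("unknown ", what, " value(s): ",
           paste(unique(values[bad]), collapse = ", "))
  }
  checkVocab(raw$fluorescence, c(.FLUOR_LEVELS, "na"), "fluorescence")
  checkVocab(raw$protein_level, .PROTEIN_LEVELS, "protein_level")
  checkVocab(raw$conserved, c("yes", "no", "na"), "conserved")
  checkVocab(raw$category, .CATEGORIES, "category")
  isPTC <- pc$alt_aa == "*"
  if (any(isPTC != (raw$category == "PTC")))
    stop("category must be PTC exactly for stop-gain entries: ",
         paste(raw$protein_change[isPTC != (raw$category == "PTC")],
               collapse = ", "))
  key <- paste(raw$protein_change, raw$nt_change)
  dup <- duplicated(key) | duplicated(key, fromLast = TRUE)
  if (any(dup))
    warning("duplicate catalog entries: ",
            paste(unique(key[dup]), collapse = "; "))
  out <- data.frame(protein_change = raw$protein_change, pc,
                    nt_change = raw$nt_change, nt,
                    fluorescence = raw$fluorescence,
                    protein_level = raw$protein_level,
                    conserved = raw$conserved,
                    category = raw$category,
                    sources = raw$sources,
                    duplicate = dup,
                    stringsAsFactors = FALSE)
  out$source_list <- .parseSources(raw$sources)
  if ("notes" %in% names(raw)) out$notes <- raw$notes
  attr(out, "numbering") <- "wild_type"
  out
}

#' Check that an entry's nucleotide change produces its protein change
#'
#' @keywords internal
.checkNtConsistency <- function(entries, cds) {
  has <- which(!is.na(entries$nt_position))
  for (i in has) {
    p <- physicalPosition(cds, entries$nt_position[i])
    s <- as.character(cdsBases(cds))
    if (substr(s, p, p) != entries$nt_ref[i])
      stop(entries$protein_change[i], ": reference base at reported position ",
           entries$nt_position[i], " is ", substr(s, p, p), ", not ",
           entries$nt_ref[i])
    ci <- (p - 1L) %/% 3L + 1L
    b <- (p - 1L) %% 3L + 1L
    codon <- .codonStrings(cds)[ci]
    substr(codon, b, b) <- entries$nt_alt[i]
    altAA <- unname(Biostrings::GENETIC_CODE[codon])
    res <- .codonResidues(cds)[ci]
    if (is.na(res) || res != entries$residue[i] ||
        altAA != entries$alt_aa[i])
      stop(entries$protein_change[i], ": nucleotide change ",
           entries$nt_change[i], " does not produce this protein change")
  }
  invisible(TRUE)
}

#' Reconcile catalog entries with the spectrum-accessible mutation space
#'
#' For each catalog entry, finds every accessible nucleotide route that
#' produces its protein change (same residue, same reference and alternate
#' amino acid).  An entry with zero routes is spectrum-inconsistent --
#' that is reported as data, not as an error.  Entries carrying an
#' explicit nucleotide change are additionally checked against the CDS.
#'
#' @param entries catalog data.frame from [parseCatalog()].
#' @param cds the reference [CodingSequence-class].
#' @param spectrum a [MutagenSpectrum-class] (default EMS).
#' @return `entries` with added columns `n_routes` (count of explaining
#'   nucleotide changes) and `routes` (semicolon-separated `"G170A"`-style
#'   tokens).
#' @examples
#' cds <- egfpCDS()
#' v <- validateAgainstSpectrum(parseCatalog(egfpCatalogPath()), cds)
#' v[v$protein_change == "W57*", c("protein_change", "n_routes", "routes")]
#' @export
validateAgainstSpectrum <- function(entries, cds, spectrum = emsSpectrum()) {
  stopifnot(is(cds, "CodingSequence"))
  .checkNtConsistency(entries, cds)
  scan <- enumerateAccessibleMutations(cds, spectrum)
  scan <- scan[!is.na(scan$residue), , drop = FALSE]
  aa <- reportedProtein(cds)
  bad <- which(entries$ref_aa != aa[entries$residue])
  if (length(bad))
    stop("catalog reference residue mismatch vs CDS: ",
         paste(entries$protein_change[bad], collapse = ", "))
  routes <- character(nrow(entries))
  nRoutes <- integer(nrow(entries))
  for (i in seq_len(nrow(entries))) {
    hit <- scan[scan$residue == entries$residue[i] &
                scan$ref_aa == entries$ref_aa[i] &
                scan$alt_aa == entries$alt_aa[i], , drop = FALSE]
    nRoutes[i] <- nrow(hit)
    routes[i] <- paste(sprintf("%s%d%s", hit$ref, hit$nt_position, hit$alt),
                       collapse = ";")
  }
  entries$n_routes <- nRoutes
  entries$routes <- routes
  entries
}

#' Load a conserved-residue list
#'
#' TSV with columns `residue` (wild-type numbering) and `aa` (one-letter).
#' Letters are checked against the translated CDS when one is supplied.
#'
#' @param path TSV path.
#' @param cds optional [CodingSequence-class] to validate letters against.
#' @return data.frame with columns `residue`, `aa`.
#' @export
loadConservedResidues <- function(path, cds = NULL) {
  d <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("residue", "aa") %in% names(d)))
    stop("conserved-residue table needs columns 'residue' and 'aa'")
  d$residue <- as.integer(d$residue)
  if (!is.null(cds)) {
    aa <- reportedProtein(cds)
    bad <- d$aa != aa[d$residue]
    if (any(bad))
      stop("conserved-residue letter mismatch vs CDS at residue(s) ",
           paste(d$residue[bad], collapse = ", "))
  }
  d[order(d$residue), , drop = FALSE]
}

#' Screen coverage report
#'
#' Computes the arithmetic a saturation-screen write-up reports: entry
#' counts per category and source, conserved residues hit and not hit,
#' distinct residues with a recovered PTC, the nonconserved substituted
#' residues, spectrum-inconsistent entries (should be none), and -- using
#' the accessibility profile -- which of the un-recovered conserved
#' residues the mutagen could in principle still mutate nonsynonymously
#' versus those that admit only silent changes.
#'
#' A residue counts as "hit" if at least one catalog entry (substitution
#' or PTC) affects it.
#'
#' @param entries catalog data.frame from [parseCatalog()].
#' @param conserved data.frame from [loadConservedResidues()].
#' @param cds the reference [CodingSequence-class].
#' @param spectrum a [MutagenSpectrum-class] (default EMS).
#' @return a list of class `"coverageReport"`; see the examples for the
#'   main fields.
#' @examples
#' cds <- egfpCDS()
#' rep <- coverageReport(parseCatalog(egfpCatalogPath()),
#'                       loadConservedResidues(egfpConservedPath(), cds), cds)
#' rep$conserved_hit       # 11
#' rep$n_this_study        # 20
#' @export
coverageReport <- function(entries, conserved, cds, spectrum = emsSpectrum()) {
  stopifnot(is(cds, "CodingSequence"))
  conserved <- loadConservedResiduesCheck(conserved, cds)
  entries <- validateAgainstSpectrum(entries, cds, spectrum)
  scan <- enumerateAccessibleMutations(cds, spectrum)
  prof <- accessibilityProfile(scan, cds)

  hitResidues <- sort(unique(entries$residue))
  consHit <- intersect(conserved$residue, hitResidues)
  consNot <- setdiff(conserved$residue, hitResidues)
  glnPTC <- sort(unique(entries$residue[entries$category == "PTC" &
                                        entries$ref_aa == "Q"]))
  srcLabels <- unlist(lapply(entries$source_list, names))
  perSource <- vapply(unique(srcLabels), function(l)
    sum(vapply(entries$source_list, function(sl) l %in% names(sl),
               logical(1))), integer(1))
  nonconsSub <- sort(unique(entries$residue[entries$category != "PTC" &
                            !entries$residue %in% conserved$residue]))
  mutableNot <- consNot[prof$nonsyn_accessible[consNot]]
  silentNot <- consNot[prof$only_silent_accessible[consNot]]

  out <- list(
    n_entries = nrow(entries),
    by_category = table(factor(entries$category, levels = .CATEGORIES)),
    per_source = perSource,
    n_this_study = unname(perSource["this_study"] %||% 0L),
    n_unique_protein_changes = length(unique(entries$protein_change)),
    ## entries with an explicit nucleotide change are distinguished by it
    ## (the two Trp57 PTC routes count separately); others by protein change
    n_unique_nt_changes = length(unique(ifelse(
      !is.na(entries$nt_position), paste0("c.", entries$nt_change),
      paste0("p.", entries$protein_change)))),
    residues_hit = hitResidues,
    conserved_total = nrow(conserved),
    conserved_hit = length(consHit),
    conserved_hit_residues = consHit,
    conserved_not_hit = length(consNot),
    conserved_not_hit_residues = consNot,
    gln_ptc_residues = glnPTC,
    n_gln_ptc_residues = length(glnPTC),
    nonconserved_substituted_residues = nonconsSub,
    n_nonconserved_substituted = length(nonconsSub),
    unrecovered_conserved_mutable = mutableNot,
    unrecovered_conserved_silent_only = silentNot,
    spectrum_inconsistent = entries$protein_change[entries$n_routes == 0L])
  class(out) <- "coverageReport"
  out
}

`%||%` <- function(a, b) if (is.null(a) || is.na(a)) b else a

## accept either a path or a pre-loaded conserved table
loadConservedResiduesCheck <- function(conserved, cds) {
  if (is.character(conserved)) return(loadConservedResidues(conserved, cds))
  aa <- reportedProtein(cds)
  bad <- conserved$aa != aa[conserved$residue]
  if (any(bad))
    stop("conserved-residue letter mismatch vs CDS at residue(s) ",
         paste(conserved$residue[bad], collapse = ", "))
  conserved
}

#' @export
print.coverageReport <- function(x, ...) {
  cat("Screen coverage report\n")
  cat(sprintf("  entries: %d (%s)\n", x$n_entries,
      paste(sprintf("%s %d", names(x$by_category), x$by_category),
            collapse = ", ")))
  cat(sprintf("  this-study entries: %d\n", x$n_this_study))
  cat(sprintf("  conserved hit: %d/%d (not hit: %s)\n",
      x$conserved_hit, x$conserved_total,
      paste(x$conserved_not_hit_residues, collapse = ",")))
  cat(sprintf("  distinct Gln residues with PTC: %d (%s)\n",
      x$n_gln_ptc_residues, paste(x$gln_ptc_residues, collapse = ",")))
  cat(sprintf("  nonconserved substituted residues: %d (%s)\n",
      x$n_nonconserved_substituted,
      paste(x$nonconserved_substituted_residues, collapse = ",")))
  cat(sprintf("  unrecovered conserved, still mutable: %s\n",
      paste(x$unrecovered_conserved_mutable, collapse = ",")))
  cat(sprintf("  unrecovered conserved, silent-only: %s\n",
      paste(x$unrecovered_conserved_silent_only, collapse = ",")))
  if (length(x$spectrum_inconsistent))
    cat("  ** spectrum-inconsistent entries:",
        paste(x$spectrum_inconsistent, collapse = ", "), "\n")
  else cat("  all entries explainable by the spectrum\n")
  invisible(x)
}

#' Convert a catalog between numbering conventions
#'
#' `wild_type` numbering skips the engineered insertion codon so residue
#' numbers match the wild-type protein; `val2_inclusive` counts it, so
#' every residue after position 1 is one higher (G67S becomes G68S).  The
#' initiator Met1 is unaffected.  Nucleotide positions, when present,
#' shift by 3 accordingly.  Converting to the numbering the catalog is
#' already in is a no-op, so a round trip is the identity.
#'
#' @param entries catalog data.frame from [parseCatalog()].
#' @param to target convention, `"wild_type"` or `"val2_inclusive"`.
#' @return the renumbered catalog with its `numbering` attribute updated.
#' @export
renumberCatalog <- function(entries, to = c("wild_type", "val2_inclusive")) {
  to <- match.arg(to)
  from <- attr(entries, "numbering") %||% "wild_type"
  if (from == to) return(entries)
  shift <- if (to == "val2_inclusive") 1L else -1L
  move <- entries$residue >= if (shift > 0L) 2L else 3L
  entries$residue[move] <- entries$residue[move] + shift
  entries$protein_change <- sprintf("%s%d%s", entries$ref_aa,
                                    entries$residue, entries$alt_aa)
  hasNt <- !is.na(entries$nt_position) & move
  entries$nt_position[hasNt] <- entries$nt_position[hasNt] + 3L * shift
  entries$nt_change[hasNt] <- sprintf("%s%d%s", entries$nt_ref[hasNt],
                                      entries$nt_position[hasNt],
                                      entries$nt_alt[hasNt])
  attr(entries, "numbering") <- to
  entries
}
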