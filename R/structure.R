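## Secondary-structure annotation and the structural distribution of
## catalog mutations.  Spans are configuration, not code: the packaged
## default annotates only elements whose boundaries the screen literature
## states in text (the internal helix, the second beta-strand glycines,
## the three lid glycines); full strand boundaries live in figures only
## and can be supplied as an edited table.

.ELEMENT_KINDS <- c("beta_strand", "alpha_helix", "lid", "loop")

#' Load a secondary-structure element annotation
#'
#' TSV with columns `name`, `kind` (one of `beta_strand`, `alpha_helix`,
#' `lid`, `loop`), `start`, `end` (1-based inclusive reported-residue
#' spans).  Overlapping beta-strand spans raise a warning, not an error.
#'
#' @param path annotation TSV path.
#' @param cds optional [CodingSequence-class]; spans are checked against
#'   the protein length when supplied.
#' @return data.frame of validated elements.
#' @examples
#' ann <- loadAnnotation(egfpAnnotationPath())
#' ann[ann$kind == "alpha_helix", ]   # helix 56-72
#' @export
loadAnnotation <- function(path, cds = NULL) {
  d <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("name", "kind", "start", "end")
  if (!all(need %in% names(d)))
    stop("annotation needs columns: ", paste(need, collapse = ", "))
  d$start <- as.integer(d$start)
  d$end <- as.integer(d$end)
  bad <- !d$kind %in% .ELEMENT_KINDS
  if (any(bad))
    stop("unknown element kind(s): ", paste(unique(d$kind[bad]), collapse = ", "))
  if (any(d$start < 1L | d$end < d$start))
    stop("invalid span(s) in annotation")
  if (!is.null(cds) && any(d$end > nResidues(cds)))
    stop("annotation span exceeds protein length ", nResidues(cds))
  strands <- d[d$kind == "beta_strand", , drop = FALSE]
  if (nrow(strands) > 1L) {
    o <- order(strands$start)
    if (any(strands$start[o][-1L] <= strands$end[o][-nrow(strands)]))
      warning("overlapping beta_strand spans in annotation")
  }
  d
}

#' Structural burden of a mutation catalog
#'
#' Assigns each catalog residue to every element whose span contains it
#' (overlapping membership is allowed: a lid residue may also sit on a
#' strand or loop) and tabulates entry counts by category per element.
#' Assignment is a pure function of (residue, spans); element order does
#' not change the result beyond row order.
#'
#' @param entries catalog data.frame from [parseCatalog()].
#' @param elements annotation data.frame from [loadAnnotation()].
#' @return a list with `elements`: one row per annotation element with
#'   its catalog residues (comma-separated), entry count, and per-category
#'   counts; and `unassigned`: catalog residues inside no element.
#' @examples
#' burden <- elementBurden(parseCatalog(egfpCatalogPath()),
#'                         loadAnnotation(egfpAnnotationPath()))
#' burden$elements[, c("name", "residues")]
#' @export
elementBurden <- function(entries, elements) {
  residues <- sort(unique(entries$residue))
  perElem <- lapply(seq_len(nrow(elements)), function(i) {
    inside <- residues[residues >= elements$start[i] &
                       residues <= elements$end[i]]
    rows <- entries[entries$residue %in% inside, , drop = FALSE]
    cbind(elements[i, c("name", "kind", "start", "end")],
          data.frame(
            residues = paste(inside, collapse = ","),
            n_residues = length(inside),
            n_entries = nrow(rows),
            t(as.matrix(table(factor(rows$category, levels = .CATEGORIES)))),
            stringsAsFactors = FALSE, check.names = FALSE))
  })
  elemTab <- if (length(perElem)) do.call(rbind, perElem) else
    cbind(elements, residues = character(0), n_residues = integer(0),
          n_entries = integer(0))
  rownames(elemTab) <- NULL
  covered <- logical(length(residues))
  for (i in seq_len(nrow(elements)))
    covered <- covered | (residues >= elements$start[i] &
                          residues <= elements$end[i])
  list(elements = elemTab, unassigned = residues[!covered])
}
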