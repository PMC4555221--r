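## Independent brute-force oracle: tries every one of the 3L single-base
## variants of a CDS, keeps those whose (ref, alt) pair the spectrum
## permits, and classifies each consequence directly from the standard
## genetic code.  Deliberately naive and separate from the package's
## vectorised scanner.

.oracle_code <- as.list(Biostrings::GENETIC_CODE)

bruteForceScan <- function(seq, subs, excluded = NA) {
  ## seq: plain character CDS; subs: data.frame(ref, alt)
  bases <- strsplit(seq, "")[[1]]
  L <- length(bases)
  nCod <- L / 3
  out <- list()
  for (pos in seq_len(L)) {
    for (alt in setdiff(c("A", "C", "G", "T"), bases[pos])) {
      ok <- any(subs$ref == bases[pos] & subs$alt == alt)
      if (!ok) next
      ci <- (pos - 1) %/% 3 + 1
      b <- (pos - 1) %% 3 + 1
      refCodon <- paste(bases[(ci - 1) * 3 + 1:3], collapse = "")
      altBases <- bases[(ci - 1) * 3 + 1:3]
      altBases[b] <- alt
      altCodon <- paste(altBases, collapse = "")
      refAA <- .oracle_code[[refCodon]]
      altAA <- .oracle_code[[altCodon]]
      cons <- if (ci == 1 && refCodon == "ATG") "start_loss"
        else if (ci == nCod && refAA == "*" && altAA == "*") "stop_retained"
        else if (ci == nCod && refAA == "*") "stop_loss"
        else if (altAA == "*") "nonsense"
        else if (refAA == altAA) "synonymous"
        else "missense"
      ## reported numbering: codons after the excluded one shift down one
      rank <- if (!is.na(excluded) && ci > excluded) ci - 1
              else if (!is.na(excluded) && ci == excluded) NA
              else ci
      out[[length(out) + 1]] <- data.frame(
        physical_pos = pos, ref = bases[pos], alt = alt,
        nt_position = if (is.na(rank)) NA_integer_
                      else as.integer(3 * (rank - 1) + b),
        ref_codon = refCodon, alt_codon = altCodon,
        ref_aa = refAA, alt_aa = altAA, consequence = cons,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(physical_pos = integer(0), ref = character(0),
                      alt = character(0), nt_position = integer(0),
                      ref_codon = character(0), alt_codon = character(0),
                      ref_aa = character(0), alt_aa = character(0),
                      consequence = character(0)))
  d <- do.call(rbind, out)
  d[order(d$physical_pos, d$alt), , drop = FALSE]
}

emsSubs <- data.frame(ref = c("C", "G"), alt = c("T", "A"),
                      stringsAsFactors = FALSE)

## naive per-codon translation oracle
naiveTranslate <- function(seq) {
  codons <- substring(seq, seq(1, nchar(seq), 3), seq(3, nchar(seq), 3))
  unname(unlist(.oracle_code[codons]))
}
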