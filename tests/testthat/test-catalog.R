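test_that("catalog parsing extracts tokens, batches and vocabularies", {
  entries <- parseCatalog(egfpCatalogPath())
  expect_identical(nrow(entries), 28L)
  w <- entries[entries$protein_change == "W57*" & entries$nt_change == "G170A", ]
  expect_identical(w$ref_aa, "W")
  expect_identical(w$residue, 57L)
  expect_identical(w$alt_aa, "*")
  expect_identical(w$nt_position, 170L)
  expect_identical(w$nt_ref, "G")
  expect_identical(w$nt_alt, "A")
  expect_identical(w$source_list[[1]][["this_study"]], 16L)
  g35 <- entries[entries$protein_change == "G35S", ]
  expect_identical(g35$source_list[[1]][["this_study"]], c(23L, 27L, 28L))
  expect_false(any(entries$duplicate))
  expect_identical(attr(entries, "numbering"), "wild_type")
})

test_that("catalog parsing rejects malformed and off-vocabulary rows", {
  writeRows <- function(rows) {
    tmp <- tempfile(fileext = ".tsv")
    writeLines(c(paste("protein_change", "nt_change", "fluorescence",
                       "protein_level", "conserved", "category", "sources",
                       sep = "\t"), rows), tmp)
    tmp
  }
  expect_error(parseCatalog(writeRows(
    "G67X\t\tno\tweak\tyes\tchromophore\tthis_study:1")),
    "malformed protein-change")
  expect_error(parseCatalog(writeRows(
    "G67S\t\tglowing\tweak\tyes\tchromophore\tthis_study:1")),
    "unknown fluorescence")
  expect_error(parseCatalog(writeRows(
    "G67S\t\tno\tweak\tyes\tsparkle\tthis_study:1")),
    "unknown category")
  expect_error(parseCatalog(writeRows(
    "G67S\t\tno\tweak\tyes\tPTC\tthis_study:1")),
    "category must be PTC exactly for stop-gain")
  expect_warning(parseCatalog(writeRows(c(
    "G67S\t\tno\tweak\tyes\tchromophore\tthis_study:1",
    "G67S\t\tno\tweak\tyes\tchromophore\tthis_study:2"))),
    "duplicate catalog entries")
  ## empty catalog with header parses to zero entries
  empty <- parseCatalog(writeRows(character(0)))
  expect_identical(nrow(empty), 0L)
})

test_that("every fixture catalog entry matches the translated protein", {
  cds <- egfpCDS()
  entries <- parseCatalog(egfpCatalogPath())
  aa <- reportedProtein(cds)
  expect_identical(entries$ref_aa, aa[entries$residue])
})

test_that("spectrum reconciliation explains all entries; W57* twice, Y66C never", {
  cds <- egfpCDS()
  entries <- parseCatalog(egfpCatalogPath())
  v <- validateAgainstSpectrum(entries, cds)
  expect_true(all(v$n_routes >= 1L))
  expect_identical(unique(v$n_routes[v$protein_change == "W57*"]), 2L)
  expect_identical(sort(strsplit(v$routes[v$protein_change == "W57*"][1], ";")[[1]]),
                   c("G170A", "G171A"))
  ## a fabricated Tyr66 substitution has no EMS route
  fake <- entries[1, ]
  fake$protein_change <- "Y66C"; fake$ref_aa <- "Y"; fake$residue <- 66L
  fake$alt_aa <- "C"; fake$category <- "chromophore"
  fake$nt_change <- ""; fake$nt_position <- NA_integer_
  fake$nt_ref <- NA_character_; fake$nt_alt <- NA_character_
  vf <- validateAgainstSpectrum(fake, cds)
  expect_identical(vf$n_routes, 0L)
  ## an entry is explainable iff its protein change appears in the scan
  scan <- enumerateAccessibleMutations(cds)
  inScan <- vapply(seq_len(nrow(v)), function(i)
    any(!is.na(scan$residue) & scan$residue == v$residue[i] &
        scan$alt_aa == v$alt_aa[i]), logical(1))
  expect_identical(v$n_routes >= 1L, inScan)
})

test_that("nucleotide-change consistency against the CDS is enforced", {
  cds <- egfpCDS()
  entries <- parseCatalog(egfpCatalogPath())
  bad <- entries[entries$nt_change == "G170A", ]
  bad$nt_position <- 169L; bad$nt_change <- "G169A"
  expect_error(validateAgainstSpectrum(bad, cds), "reference base")
  bad2 <- entries[entries$nt_change == "G170A", ]
  bad2$residue <- 58L; bad2$protein_change <- "N58*"; bad2$ref_aa <- "N"
  expect_error(validateAgainstSpectrum(bad2, cds), "mismatch|does not produce")
})

test_that("coverage report reproduces the screen's printed arithmetic", {
  cds <- egfpCDS()
  entries <- parseCatalog(egfpCatalogPath())
  conserved <- loadConservedResidues(egfpConservedPath(), cds)
  expect_identical(nrow(conserved), 21L)
  cov <- coverageReport(entries, conserved, cds)
  expect_identical(unname(as.integer(cov$by_category)),
                   c(8L, 3L, 5L, 4L, 8L))
  expect_identical(cov$n_entries, 28L)
  expect_identical(cov$n_this_study, 20L)
  expect_identical(cov$conserved_hit, 11L)
  expect_identical(cov$conserved_not_hit, 10L)
  expect_identical(cov$n_gln_ptc_residues, 6L)
  expect_setequal(cov$gln_ptc_residues, c(69L, 94L, 157L, 177L, 183L, 184L))
  expect_setequal(cov$nonconserved_substituted_residues,
                  c(65L, 62L, 205L, 56L, 70L, 110L, 112L))
  expect_length(cov$spectrum_inconsistent, 0L)
  ## both "unique mutant" readings are exposed
  expect_identical(cov$n_unique_protein_changes, 27L)
  expect_identical(cov$n_unique_nt_changes, 28L)
  ## totals are internally consistent
  expect_identical(sum(cov$by_category), cov$n_entries)
  expect_identical(cov$conserved_hit + cov$conserved_not_hit,
                   cov$conserved_total)
})

test_that("unrecovered conserved residues split 5 mutable / 5 silent-only", {
  cds <- egfpCDS()
  cov <- coverageReport(parseCatalog(egfpCatalogPath()),
                        loadConservedResidues(egfpConservedPath(), cds), cds)
  expect_setequal(cov$unrecovered_conserved_mutable,
                  c(55L, 102L, 104L, 134L, 196L))
  expect_setequal(cov$unrecovered_conserved_silent_only,
                  c(27L, 53L, 66L, 130L, 136L))
})

test_that("conserved-list letters are validated against the CDS", {
  cds <- egfpCDS()
  tmp <- tempfile(fileext = ".tsv")
  writeLines(c("residue\taa", "57\tQ"), tmp)
  expect_error(loadConservedResidues(tmp, cds), "mismatch.*57")
})

test_that("renumbering shifts residues after Met1 and round-trips", {
  entries <- parseCatalog(egfpCatalogPath())
  v2 <- renumberCatalog(entries, "val2_inclusive")
  expect_identical(v2$protein_change[entries$protein_change == "G67S"], "G68S")
  expect_identical(v2$nt_change[entries$nt_change == "G170A"], "G173A")
  expect_identical(attr(v2, "numbering"), "val2_inclusive")
  ## renumbering to the current convention is a no-op
  expect_identical(renumberCatalog(entries, "wild_type"), entries)
  back <- renumberCatalog(v2, "wild_type")
  attrBack <- attr(back, "numbering")
  expect_identical(attrBack, "wild_type")
  expect_identical(back$protein_change, entries$protein_change)
  expect_identical(back$nt_change, entries$nt_change)
  expect_identical(back$residue, entries$residue)
})
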