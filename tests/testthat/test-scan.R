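test_that("consequence classification covers all categories", {
  expect_identical(classifyConsequence("CAG", "TAG"), "nonsense")
  expect_identical(classifyConsequence("TAC", "TAT"), "synonymous")
  expect_identical(classifyConsequence("GAG", "AAG"), "missense")   # E>K
  expect_identical(classifyConsequence("ATG", "ATA", isInitiator = TRUE),
                   "start_loss")
  expect_identical(classifyConsequence("ATG", "ATA"), "missense")
  expect_identical(classifyConsequence("TGA", "TCA", isTerminator = TRUE),
                   "stop_loss")
  expect_identical(classifyConsequence("TGA", "TAA", isTerminator = TRUE),
                   "stop_retained")
  expect_error(classifyConsequence("CAG", "TAA"), "exactly one base")
  expect_error(classifyConsequence("CAG", "CAG"), "exactly one base")
})

test_that("EMS scan of the fixture finds the two Trp57 PTC routes", {
  scan <- enumerateAccessibleMutations(egfpCDS(), emsSpectrum())
  w57 <- scan[!is.na(scan$residue) & scan$residue == 57, ]
  nons <- w57[w57$consequence == "nonsense", ]
  expect_identical(nrow(nons), 2L)
  expect_setequal(nons$nt_position, c(170L, 171L))
  expect_identical(unique(nons$ref), "G")
  expect_identical(unique(nons$alt), "A")
  expect_setequal(nons$alt_codon, c("TAG", "TGA"))
})

test_that("fixture PTC accessibility is confined to Gln and Trp codons", {
  scan <- enumerateAccessibleMutations(egfpCDS())
  ptc <- ptcSusceptibleResidues(scan)
  expect_setequal(unique(ptc$ref_aa), c("Q", "W"))
  expect_identical(nrow(ptc), 9L)   # eight Gln + the single Trp
  expect_setequal(ptc$residue[ptc$ref_aa == "Q"],
                  c(69L, 80L, 94L, 157L, 177L, 183L, 184L, 204L))
})

test_that("every Tyr/Phe/Leu/Ile codon of the fixture is silent-only under EMS", {
  cds <- egfpCDS()
  prof <- accessibilityProfile(enumerateAccessibleMutations(cds), cds)
  yfli <- prof[prof$ref_aa %in% c("Y", "F", "L", "I"), ]
  expect_gt(nrow(yfli), 0L)
  expect_false(any(yfli$nonsyn_accessible))
  expect_true(all(yfli$only_silent_accessible | yfli$untouchable))
  ## Tyr66 specifically: the chromogenic tyrosine cannot be substituted
  expect_true(prof$only_silent_accessible[66])
})

test_that("accessibility profile reports the catalog's missense routes", {
  cds <- egfpCDS()
  prof <- accessibilityProfile(enumerateAccessibleMutations(cds), cds)
  alts <- strsplit(prof$alternatives, ",")
  expect_true(all(c("C", "H") %in% alts[[96]]))   # R96C, R96H
  expect_true(all(c("S", "D") %in% alts[[67]]))   # G67S, G67D
  ## flags are mutually consistent
  expect_false(any(prof$only_silent_accessible & prof$nonsyn_accessible))
  expect_false(any(prof$untouchable & prof$n_changes > 0L))
  expect_true(all(prof$ptc_accessible | prof$missense_accessible |
                  prof$only_silent_accessible | prof$untouchable |
                  ## start-loss-only residues (Met1) are nonsyn but neither
                  ## missense nor PTC accessible
                  prof$nonsyn_accessible))
})

test_that("an empty spectrum scans to an empty result", {
  scan <- enumerateAccessibleMutations(egfpCDS(), mutagenSpectrum("none"))
  expect_identical(nrow(scan), 0L)
  expect_true(all(c("nt_position", "consequence") %in% names(scan)))
})

test_that("scanner equals the brute-force oracle on random synthetic CDSs", {
  for (seed in 1:8) {
    cds <- randomCDS(sample(5:100, 1), gc = runif(1, 0.25, 0.75), seed = seed)
    scan <- enumerateAccessibleMutations(cds, emsSpectrum())
    oracle <- bruteForceScan(as.character(cdsBases(cds)), emsSubs)
    expect_identical(nrow(scan), nrow(oracle))
    for (col in c("physical_pos", "ref", "alt", "nt_position", "ref_codon",
                  "alt_codon", "ref_aa", "alt_aa", "consequence"))
      expect_identical(scan[[col]], oracle[[col]], label = col)
  }
})

test_that("oracle equivalence holds with an excluded insertion codon", {
  set.seed(42)
  cds0 <- randomCDS(30, seed = 7)
  ## splice an insertion codon after the initiator, as in the EGFP line
  s <- as.character(cdsBases(cds0))
  s2 <- paste0(substr(s, 1, 3), "GTG", substr(s, 4, nchar(s)))
  cds <- codingSequence(s2, excludedCodon = 2)
  scan <- enumerateAccessibleMutations(cds)
  oracle <- bruteForceScan(s2, emsSubs, excluded = 2)
  expect_identical(scan$nt_position, oracle$nt_position)
  expect_identical(scan$consequence, oracle$consequence)
  expect_true(all(scan$residue_label[is.na(scan$nt_position)] == "1a"))
})

test_that("enumeration count equals an independent single-pass base tally", {
  cds <- egfpCDS()
  s <- as.character(cdsBases(cds))
  scan <- enumerateAccessibleMutations(cds)
  tally <- sum(strsplit(s, "")[[1]] %in% c("C", "G"))
  expect_identical(nrow(scan), tally)
})

test_that("enlarging the spectrum never removes an accessible change", {
  cds <- randomCDS(40, seed = 11)
  small <- enumerateAccessibleMutations(cds, mutagenSpectrum("ct", "C>T"))
  big <- enumerateAccessibleMutations(cds, emsSpectrum())
  keySmall <- paste(small$physical_pos, small$alt)
  keyBig <- paste(big$physical_pos, big$alt)
  expect_true(all(keySmall %in% keyBig))
  expect_gte(nrow(big), nrow(small))
})

test_that("EMS accessible sites are symmetric under reverse complement", {
  ## a C>T site on the sense strand is a G>A site on the antisense strand;
  ## since the EMS spectrum contains both, the accessible site set must map
  ## onto itself under reverse complement (strand-convention sanity check)
  cds <- randomCDS(25, seed = 3)
  s <- as.character(cdsBases(cds))
  scan <- enumerateAccessibleMutations(cds)
  rc <- as.character(Biostrings::reverseComplement(cdsBases(cds)))
  rcBases <- strsplit(rc, "")[[1]]
  rcSites <- sort(which(rcBases %in% c("C", "G")))
  expect_identical(sort(nchar(s) + 1L - scan$physical_pos[!duplicated(scan$physical_pos)]),
                   rcSites)
})

test_that("scan output order is deterministic and TSV/VCF round out the surface", {
  cds <- egfpCDS()
  a <- enumerateAccessibleMutations(cds)
  b <- enumerateAccessibleMutations(cds)
  expect_identical(a, b)
  expect_true(!is.unsorted(a$physical_pos))
  tsv <- tempfile(fileext = ".tsv"); vcf <- tempfile(fileext = ".vcf")
  writeScanTSV(a, tsv)
  back <- read.delim(tsv)
  expect_identical(nrow(back), nrow(a))
  writeScanVCF(a, vcf, cdsId = cdsId(cds))
  lines <- readLines(vcf)
  expect_identical(lines[1], "##fileformat=VCFv4.2")
  body <- lines[!startsWith(lines, "#")]
  expect_identical(length(body), sum(!is.na(a$nt_position)))
})
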