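---
title: "In silico EMS saturation scanning: model, conventions and design notes"
author: "emsScan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{In silico EMS saturation scanning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(emsScan)
```

## The problem

A forward-genetic screen with a chemical mutagen can only ever recover the
mutations the mutagen's chemistry can produce. EMS (ethyl
methanesulfonate) alkylates guanine and induces almost exclusively G:C to
A:T transitions, which appear on the coding strand as C>T or G>A. For a
given coding sequence this makes the reachable mutation space small,
discrete and exactly enumerable, and three questions become computable
rather than rhetorical:

1. **Accessibility.** Which residues can acquire a premature termination
   codon (PTC)? Which can be substituted at all? Which codons admit only
   silent changes, so the screen is structurally blind to them?
2. **Reconciliation.** Is every mutant in an observed catalog explainable
   by the spectrum, and how much of the accessible (and conserved-residue)
   space did the screen cover?
3. **Saturation.** Given the recovery multiplicities, how many accessible
   classes do we expect the screen to have missed?

The packaged worked example is an Arabidopsis GFP loss-of-function screen:
an EGFP reporter, a 28-entry mutant catalog, and a 21-residue list of the
most conserved positions in GFP-like proteins.

## Coordinate conventions

The EGFP reporter carries an engineered GTG (Val) codon directly after the
initiator ATG, inserted to optimise translation initiation. The screen
literature numbers residues as in wild-type GFP, treating this valine as
residue "1a" and skipping it in all coordinates. `CodingSequence` supports
this with an `excludedCodon` slot: the codon is stored, translated and
scanned, but its bases carry no reported nucleotide number and it never
counts toward residue totals. With this convention the protein is 238
reported residues, and the two G>A changes that convert the single
tryptophan (Trp57, codon TGG) into a stop codon sit at reported
nucleotides `3*(57-1)+2 = 170` and `171`:

```{r}
cds <- egfpCDS()
cds
reportedPosition(cds, codonIndex = 58, baseInCodon = 2:3)
```

Reported positions are 1-based and contiguous after removing the excluded
codon; physical coordinates are 0-based internally and 1-based at the R
surface. `renumberCatalog()` converts a catalog to and from the
alternative convention in which the valine is residue 2 and every later
residue is one higher.

The fixture itself (`egfpFastaPath()`) is a *reconstruction*, labelled
`_synthetic` in its filename: the canonical EGFP ORF with the extra Val
codon, in which three leucine codons (reported residues 60, 178, 231) are
recoded synonymously CTC→CTG. The recoding changes no amino acid; it makes
the sequence satisfy the documented property of the reporter line that
every Tyr/Phe/Leu/Ile codon admits only silent EMS changes (a CTC codon
would admit a Leu→Phe missense). All 35 residue identities the catalog and
conserved list touch, the glycine count (22), the glutamine set
{69, 80, 94, 157, 177, 183, 184, 204} and the single Trp57 match the
published protein.

## The scan and its consequence labels

`enumerateAccessibleMutations()` emits one record per (position, permitted
substitution) pair, deterministically ordered (position, then alternate
base), so outputs diff cleanly. Consequences follow variant-effect
conventions: `synonymous`, `missense`, `nonsense`, `stop_loss`,
`stop_retained` (terminator to another stop codon -- a case the five-label
scheme of most write-ups silently omits but an exhaustive scanner must
name), and `start_loss`. At the initiator, `start_loss` outranks missense
so each change carries exactly one label.

Two structural facts about the standard genetic code under the EMS
spectrum drive the biology here, and both fall out of the scan rather
than being hard-coded: stop codons are reachable by a single C>T or G>A
change only from Gln codons (CAA>TAA, CAG>TAG) and Trp (TGG>TAG/TGA) --
and from CGA (Arg), a codon this CDS does not use; and every codon for
Tyr, Phe and Ile, and the Leu codons this CDS uses, can change only
synonymously:

```{r}
scan <- enumerateAccessibleMutations(cds, emsSpectrum())
table(ptcSusceptibleResidues(scan)$ref_aa)
prof <- accessibilityProfile(scan, cds)
subset(prof, residue %in% c(57, 66, 96))[ , c("residue", "ref_aa",
  "alternatives", "ptc_accessible", "only_silent_accessible")]
```

## Catalog reconciliation and coverage

`parseCatalog()` reads the observed-mutation table with closed phenotype
vocabularies (fluorescence: no/negligible/weak/weak_to_moderate/moderate/
wt; protein level: no/very_weak/weak/wt/sterile/na), so reports are
machine-checkable. `validateAgainstSpectrum()` lists, for every entry,
each nucleotide route that produces its protein change; an entry with no
route is reported as data, not an error, because an inconsistent entry is
a finding about the catalog. `coverageReport()` then reproduces the
screen's arithmetic: 28 entries in five categories (8 PTC, 3 chromophore,
5 chromophore maturation, 4 lid-residue stability, 8 stability-unknown),
20 entries from the primary screen, six of eight glutamines hit by PTCs,
11 of 21 conserved residues hit (counting the Trp57 PTC as a hit -- the
arithmetic does not reconcile otherwise), and of the 10 conserved
residues never recovered, exactly 5 (Val55, Asp102, Gly104, Gly134,
Pro196) that EMS could in principle still substitute. Both readings of
"unique mutant" are exposed (27 distinct protein changes; 28 distinct
mutational events, since the Trp57 PTC arose via two different nucleotide
changes).

## The saturation model

The screen literature argues saturation qualitatively; the Poisson
recovery model here is this package's own formalization and is labelled
as such in every report. Each accessible class $i$ (say, each
PTC-susceptible residue) is recovered $X_i \sim \mathrm{Poisson}(\lambda
w_i)$ times independently; then $P(\text{class } i \text{ missed}) =
e^{-\lambda w_i}$, the expected number of unseen classes is $\sum_i
e^{-\lambda w_i}$ and $P(\text{all seen}) = \prod_i (1 - e^{-\lambda
w_i})$. Weights default to 1; the natural refinement sets $w_i$ to the
number of nucleotide routes to the class (2 for the Trp PTC, 1 for each
Gln PTC), which is also what `simulateScreen()` uses generatively.

`fitRate()` is the maximum-likelihood estimator in both observation
regimes. When the class list is complete (`includeZeros = TRUE`) the MLE
is the weighted mean $\sum x_i / \sum w_i$. When unseen classes are
invisible, the zero-truncated MLE solves $\lambda/(1-e^{-\lambda}) =
\bar{x}_{>0}$; the root is found with `stats::uniroot()` on the bracket
$[10^{-8}, 50]$ to $|f| < 10^{-10}$ ($\lambda$ is far below 50 in any
realistic screen), and a mean positive count at the truncated
distribution's lower limit of 1 returns the boundary $\hat\lambda = 0$.

For the nine PTC classes (Trp57 twice, six Gln once each, Gln80 and
Gln204 never), the complete-enumeration fit gives $\hat\lambda = 8/9$ and
an expected $9 e^{-8/9} \approx 3.7$ unseen classes -- the two observed
misses are, if anything, fewer than the homogeneous model expects, so
"approached saturation" is a fair reading, though the fitted rate is too
low to claim completeness ($P(\text{all seen}) \approx 0.009$):

```{r}
m <- screenModel(c(W57 = 2, Q69 = 1, Q80 = 0, Q94 = 1, Q157 = 1,
                   Q177 = 1, Q183 = 1, Q184 = 1, Q204 = 0))
saturationSummary(m)
```

A caution on these worked numbers: with nine classes the likelihood is
shallow, and zero-truncated fits from so few positives are noisy. The
estimator's accuracy guarantees (median relative error below 10%) are
established at 500 classes in the test suite; the nine-class example is a
consistency illustration, not a precise estimate.

## What the synthetic generator does and does not emulate

`randomCDS()` samples interior codons base-by-base at a target GC content
with stop-codon rejection, giving a valid CDS by construction; it does
not model codon-usage bias, neighbouring-base mutability or transcribed
strand asymmetry. `simulateScreen()` draws class counts directly from the
Poisson model the estimator assumes. Passing the end-to-end recovery
tests therefore shows the pipeline is self-consistent -- scan, class
definition, simulation and fitting agree -- not that real screens obey a
homogeneous Poisson law: real recoveries are overdispersed by batch
structure, sib selection and phenotype-dependent ascertainment. The
structural annotation likewise ships only text-attested elements (helix
56--72, the second beta-strand glycines 31/33/35, the three lid
glycines); full strand boundaries exist only graphically in the
literature, so inventing them as defaults seemed worse than leaving the
table editable.

## Numerical and design choices

* Validation is strict and names the offending coordinate (non-triplet
  length, missing start, internal stop at codon *k*, lower-case or
  ambiguous base at position *p*); nothing is coerced.
* Translation is a direct `GENETIC_CODE` lookup. This is deliberate:
  codon-wise use of `Biostrings::translate()` would render interior
  CTG/TTG as initiator Met.
* The scan treats the spectrum as sense-strand substitutions; the default
  EMS set {C>T, G>A} is closed under strand complementation, which the
  test suite checks as a site-symmetry property under reverse complement.
* Problem sizes in the tests -- 20 random CDSs up to 100 codons for
  oracle equivalence, 500 classes and 400 replicates for rate-recovery
  medians, 1000 Monte-Carlo screens for the closed-form checks -- were
  chosen to pin the estimator's documented accuracy while keeping the
  default suite quick to run.
* Seeds are explicit arguments everywhere randomness occurs
  (`randomCDS()`, `simulateScreen()`), so simulated studies are exactly
  reproducible.

## Known limitations

Single CDS only (no gene models, no genomic strand scanning); single-hit
substitutions only (no double hits, indels or context-dependent hotspot
models); phenotype labels are categorical and never quantified; the
saturation model is homogeneous per class unless route weights are
supplied, and says nothing about *why* a class was missed (chance versus
an undetectable phenotype -- for Gln80 and Gln204 the model deliberately
leaves that open).
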