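# emsScan

In silico EMS mutagenesis scanning and screen-saturation analysis for
protein-coding sequences.

## What it is for

Chemical mutagens reach only part of a gene's mutation space. EMS (ethyl
methanesulfonate) induces almost exclusively G:C→A:T transitions — on the
coding strand, C>T or G>A — so for any coding sequence the set of
reachable amino-acid changes is small and exactly enumerable. `emsScan` is
for people running or interpreting forward-genetic screens of a single
reporter or target gene. It:

* enumerates every spectrum-permitted single-nucleotide change and
  classifies its protein-level consequence (synonymous, missense,
  nonsense, start-loss, stop-loss, stop-retained);
* derives per-residue accessibility profiles: which residues can acquire a
  premature termination codon (under EMS, only Gln and Trp codons — and
  CGA Arg codons where a sequence uses them), and which are "mutagen
  blind" because every reachable change is silent (Tyr, Phe, Ile, and most
  Leu codons);
* reconciles an observed mutant catalog against that accessible space and
  computes coverage of a conserved-residue list;
* maps catalog residues onto secondary-structure elements;
* fits a per-class Poisson recovery model: each accessible mutation class
  is recovered X<sub>i</sub> ~ Poisson(λw<sub>i</sub>) times, so
  P(class missed) = e<sup>−λw<sub>i</sub></sup>, expected unseen classes =
  Σ e<sup>−λw<sub>i</sub></sup>, P(all seen) = Π(1 −
  e<sup>−λw<sub>i</sub></sup>); λ is estimated by maximum likelihood (the
  weighted mean when the class list is complete, the zero-truncated
  Poisson MLE when unseen classes are invisible).

The packaged worked example is an Arabidopsis EGFP loss-of-function
screen: a reconstructed EGFP coding sequence (with the engineered Val
"1a" codon excluded from reported numbering, so coordinates match
wild-type GFP), its 28-entry mutant catalog, and the 21 highly conserved
GFP residues.

## Worked example

```r
library(emsScan)

cds <- egfpCDS()
#> CodingSequence 'EGFP_CDS_synthetic': 720 bp, 238 reported residues
#>   (codon 2 excluded as '1a')

scan <- enumerateAccessibleMutations(cds, emsSpectrum())
ptc <- ptcSusceptibleResidues(scan)
table(ptc$ref_aa)
#> Q W
#> 8 1
```

Nine residues can acquire a PTC: the eight glutamines and the single
tryptophan (Trp57, reachable by two routes, G170A and G171A). Coverage of
the observed catalog:

```r
cov <- coverageReport(parseCatalog(egfpCatalogPath()),
                      loadConservedResidues(egfpConservedPath(), cds), cds)
cov
#> Screen coverage report
#>   entries: 28 (PTC 8, chromophore 3, chromophore_maturation 5,
#>            stability_lid 4, stability_unknown 8)
#>   this-study entries: 20
#>   conserved hit: 11/21 (not hit: 27,53,55,66,102,104,130,134,136,196)
#>   distinct Gln residues with PTC: 6 (69,94,157,177,183,184)
#>   nonconserved substituted residues: 7 (56,62,65,70,110,112,205)
#>   unrecovered conserved, still mutable: 55,102,104,134,196
#>   unrecovered conserved, silent-only: 27,53,66,130,136
#>   all entries explainable by the spectrum
```

Every catalog entry has at least one explaining EMS route; 11 of the 21
conserved residues were hit, and of the 10 that were not, five (Tyr66,
Phe27, Phe130, Leu53, Ile136) cannot be substituted by EMS at all, while
five (Val55, Asp102, Gly104, Gly134, Pro196) could have been but were not
recovered. Saturation of the nine PTC classes:

```r
m <- screenModel(c(W57 = 2, Q69 = 1, Q80 = 0, Q94 = 1, Q157 = 1,
                   Q177 = 1, Q183 = 1, Q184 = 1, Q204 = 0))
saturationSummary(m)
#> Saturation summary (per-class Poisson recovery model)
#>   classes: 9, fitted lambda: 0.8889
#>   expected unseen classes: 3.7
#>   observed unseen classes: 2 (Q80, Q204)
#>   P(all classes seen): 0.00852
```

Observing two unseen Gln classes is well within what the fitted model
expects — consistent with a screen that approached, but cannot claim,
saturation.

A command-line wrapper over the same functions lives at
`inst/scripts/ems-scan.R` (`scan` and `report` subcommands).

## Vignette

`vignettes/ems-saturation-scanning.Rmd` documents the model, the "1a"
coordinate convention, the consequence taxonomy, the reconstruction of
the packaged EGFP fixture, what the synthetic generator does and does not
emulate, and known limitations.
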