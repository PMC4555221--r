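Package: emsScan
Title: In Silico EMS Mutagenesis Scanning and Screen Saturation Analysis
        for Coding Sequences
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
        role = c("aut", "cre"))
Description: Tools for analysing forward-genetic point-mutation screens of a
        single protein-coding sequence. The package enumerates every single
        nucleotide substitution permitted by a chemical mutagen spectrum
        (by default the EMS G:C to A:T transition spectrum, seen on the
        coding strand as C>T and G>A), classifies each change's protein
        level consequence, derives per-residue accessibility profiles
        (which residues admit premature termination codons, which admit
        only silent changes and are therefore blind to the mutagen),
        reconciles an observed loss-of-function mutant catalog against the
        accessible mutation space, maps mutated residues onto secondary
        structure elements, and quantifies screen coverage and saturation
        with a per-class Poisson recovery model. A reconstructed EGFP
        coding sequence and the companion mutant catalog of an Arabidopsis
        GFP loss-of-function screen are included as fixtures, together
        with a synthetic-data generator for coding sequences and simulated
        screens.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports: methods, stats, utils, Biostrings, yaml
Suggests: testthat (>= 3.0.0), jsonlite, optparse, knitr, rmarkdown
biocViews: Genetics, Sequencing, FunctionalPrediction, VariantAnnotation
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
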