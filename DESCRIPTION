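Package: emuflux
Title: Quantitative Metabolic Modeling with EMU-Based 13C Flux Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Constraint-based and isotope-assisted modeling of microbial
    metabolism. Provides reaction networks with carbon atom transitions,
    elementary metabolite unit (EMU) decomposition and forward simulation of
    isotope labeling, 13C metabolic flux analysis with profile-likelihood
    confidence intervals, two-scale 13C MFA for genome-scale stoichiometries,
    flux balance and flux variability analysis, external labeling variability
    analysis, MoMA and ROOM knockout phenotype prediction, mass distribution
    vector handling with natural isotope abundance correction, carbon use
    efficiency for community flux models, and principal component analysis of
    proteomics with production-level overlay.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils, pracma, quadprog, minpack.lm, xml2
Suggests: testthat (>= 3.0.0), withr, jsonlite, optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'utils.R'
    'core.R'
    'atom-transitions.R'
    'reaction-network.R'
    'lp.R'
    'fba.R'
    'labeling-io.R'
    'emu-engine.R'
    'c13-fit.R'
    'emuflux-package.R'
    'predictions.R'
    'fixtures.R'
    'isotopomer-oracle.R'
    'labeling-correction.R'
    'pcap.R'
    'sbml-io.R'
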