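Package: ChaperKin
Title: Chaperone-Driven Trimer Dissociation Kinetics and HX-MS
    Subpopulation Deconvolution
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Quantitative models for Hsp70/Hsc70-mediated disassembly of
    DNA-bound transcription-factor trimers. Implements ligand-depletion
    equilibrium binding (quadratic mass-action solution), delayed
    single-exponential dissociation kinetics, a binomial trimer-composition
    model with a shared-rate global kinetic fit and information-criterion
    model comparison, two-Gaussian deconvolution of bimodal (EX1-type)
    hydrogen-exchange isotope envelopes with back-exchange correction,
    sliding-window Hsp70 binding-site scanning of protein sequences, and
    two-state thermal transition fitting. Seeded synthetic-data generators
    emulate every input so the full pipeline is testable without raw data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    minpack.lm,
    jsonlite,
    yaml,
    withr,
    Biostrings
Suggests:
    testthat (>= 3.0.0)
biocViews: Software, Proteomics, MassSpectrometry, TimeCourse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
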