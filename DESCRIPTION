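Package: ncptools
Title: Mass Spectrometry Toolkit for Nostocyclopeptide Structure Elucidation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Topology-aware mass and fragment-ion prediction for
    nostocyclopeptides and related nonribosomal peptides. Computes neutral
    masses and [M+H]+ values for linear peptide acids, linear peptide
    aldehydes and head-to-tail cyclic imines, enumerates b/y/internal,
    ring-opened, residue-loss, neutral-loss and immonium/diagnostic ions,
    annotates unit-resolution CID peak lists, ranks candidate structures
    against observed spectra, predicts NRPS adenylation-domain substrates
    from nine-residue binding-pocket signatures, and simulates realistic
    unit-resolution product-ion spectra for benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
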