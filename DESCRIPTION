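Package: homsms
Title: Tandem Mass Spectrometry Annotation and Structure Inference for
    Highly Oxygenated Organic Molecules
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for interpreting online tandem mass spectra of highly
    oxygenated organic molecules (HOM) measured as nitrate (NO3-) adducts
    by chemical-ionization Orbitrap instruments. Provides exact-mass
    elemental formula arithmetic and constrained formula enumeration
    within a ppm tolerance, MGF and CSV peak-list input/output with
    intensity normalization and relative-intensity filtering, precursor
    and product ion annotation with neutral-loss derivation, cosine
    spectral similarity and complete-linkage hierarchical clustering, a
    rule-based fragmentation-feasibility engine that eliminates candidate
    peroxy-radical isomers and infers ROOR accretion-product (dimer)
    precursor pairs, and a forward simulator of NO3- adduct MS/MS spectra
    for end-to-end testing without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
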