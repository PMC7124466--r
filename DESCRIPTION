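Package: xlmspipe
Title: Identification Pipeline for Isotope-Coded, Cleavable Crosslinking
    Mass Spectrometry
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for identifying chemically crosslinked peptides from
    mass-spectrometry data acquired with an affinity-enrichable,
    isotopically coded (light/heavy, delta 8.0502 Da), CID-cleavable
    amine-reactive crosslinker. Detects co-eluting light/heavy MS1
    feature multiplets in deconvoluted feature tables, emits targeted
    acquisition inclusion lists, builds shuffled-decoy search databases,
    generates or ingests crosslink peptide-spectrum matches, annotates
    them with crosslinker cleavage-product and MS1 multiplet evidence,
    rescores them with a semi-supervised target-decoy linear
    discriminant and q-values, aggregates accepted links to
    protein-protein interactions, and validates links against
    C-alpha/C-alpha distances in structural models. A synthetic-data
    generator provides ground-truthed inputs for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    graphics,
    utils,
    jsonlite,
    yaml,
    xml2,
    Biostrings,
    bio3d
Suggests:
    testthat (>= 3.0.0),
    mzR,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
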