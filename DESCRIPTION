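Package: nabind
Title: Sequence-Based Prediction of DNA- and RNA-Binding Residues
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Predicts DNA- and RNA-binding residues in protein sequences with
    a radial-basis-function support vector machine. Residues are encoded in
    sliding windows from three biochemical features (hydrophobicity index,
    side-chain pKa, molecular mass), position-specific scoring matrix (PSSM)
    profiles, and per-position conservation descriptors (mean and standard
    deviation of each biochemical feature over aligned homologues). Includes
    structure-derived labelling of binding residues from protein-nucleic acid
    complexes (3.5 Angstrom contact rule), fivefold cross-validation with
    sensitivity, specificity, strength, Matthews correlation and ROC/AUC
    evaluation, operating-point selection from a requested sensitivity or
    specificity, confidence-scored per-residue reports, and deterministic
    synthetic-data generators for toy complexes, homologue alignments and
    labelled datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    e1071,
    bio3d,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    pROC
Config/testthat/edition: 3
RoxygenNote: 7.3.3
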