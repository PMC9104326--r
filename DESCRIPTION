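Package: disbench
Title: Benchmarking Residue-Wise Disorder Prediction from Predicted Protein Structures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Derives residue-wise intrinsic-disorder predictions from predicted
    protein structures carrying per-residue pLDDT confidence scores in the
    B-factor field, and benchmarks them against reference disorder annotations.
    Implements the transformed-confidence predictor tpLD (1 - pLDDT/100), the
    thresholded binary predictor pLDn with MCC-based threshold selection, and a
    naive secondary-structure rule (DSSPp) built on a from-scratch
    Kabsch-Sander secondary-structure assignment. Provides DisProt-style and
    DisProt-PDB-style reference construction with conflict resolution and
    masking, classifier metrics (ROC/AUC, precision-recall/Fmax, MCC,
    per-protein RMSD), bootstrap summaries, secondary-structure-codon analysis
    of confidence profiles, and a synthetic cohort generator so the whole
    pipeline runs without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    graphics,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
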