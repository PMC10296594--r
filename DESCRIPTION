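Package: catrace
Title: Secondary Structure Assignment from Protein C-Alpha Traces
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Assigns three-state protein secondary structure (helix, sheet,
    loop) from C-alpha coordinates alone.  Computes a 39-dimensional
    geometric descriptor per residue (pseudo-angles, pseudo-torsions, axis
    and neighborhood distances), trains one linear subspace per structure
    class from sliding windows of descriptors, and classifies residues
    either by orthogonal-projection distance to each class subspace or by
    the Grassmannian chordal distance between a residue-local subspace and
    the class subspaces, followed by rule-based post-processing.  Also
    provides a stacked ensemble classifier over the same descriptors, a
    synthetic C-alpha trace generator (ideal helices, paired beta strands,
    random coils) for fully offline testing, PDB input/output restricted to
    ATOM/HELIX/SHEET records, and evaluation utilities with broom-style
    tidiers and ggplot2 plots.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    caret,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    nnet,
    ranger,
    readr,
    rlang,
    stats,
    tibble,
    xgboost
Suggests:
    optparse,
    pracma,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
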