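Package: glyoxalaseR
Title: Glyoxalase I Gene-Family Curation and Biochemical Analysis for Durum Wheat
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Curation and biochemical analysis toolkit for the glyoxalase I (GLYI)
    gene family of durum wheat (Triticum durum). Implements the gene/transcript/protein
    catalog model with molecular-weight and isoelectric-point computation, PF00903
    domain-length filtering, reference-anchored conserved-site checking via global
    affine-gap alignment with Ni2+/Zn2+ cofactor-dependency and activity classification,
    domain-architecture grouping and subcellular-localization consensus. The biochemical
    layer covers the methylglyoxal/glutathione hemithioacetal equilibrium (forward solve
    and assay design), Michaelis-Menten and competitive-inhibition kinetics with Dixon
    Ki estimation and linearization diagnostics, metal-activation dose-response,
    relative qPCR quantification by the 2^(-delta delta Ct) method with Duncan multiple
    range grouping, and linear-calibration quantification for methylglyoxal and
    glutathione assays. Seeded synthetic-data generators allow end-to-end testing of
    every stage without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    minpack.lm,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
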