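Package: ensdyn
Title: Validation and Collective-Motion Analysis of NMR Conformational Ensembles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for multi-model protein conformational
    ensembles against solution NMR observables. Preprocesses NOE distance
    restraints (removal of stereospecificity, integer-Angstrom binning)
    and evaluates them per ensemble with r^-6 averaging; back-calculates
    backbone amide S2 order parameters and their plain and
    outlier-corrected correlation with experiment; performs pooled
    principal component analysis of collective motions with per-residue
    square fluctuations and Calpha distance-versus-mode correlation maps;
    differences hydrogen-bond occupancies between ligation states;
    assigns simplified three-state secondary structure per conformer; and
    selects excited-state ("invisible state") candidate conformers by
    matching predicted 15N chemical-shift differences to CPMG-derived
    |delta omega| profiles. A synthetic-data generator with planted
    ground truth makes every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
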