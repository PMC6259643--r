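Package: qsarpipe
Title: QSAR Modelling of CXCR2 Antagonist Potency with GA-PLS Descriptor Selection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A quantitative structure-activity relationship (QSAR) pipeline for
    modelling half-maximal inhibitory concentrations (pIC50) of small-molecule
    receptor antagonists. Computes hydrogen-depleted molecular graphs from
    SMILES, topological 2D autocorrelation descriptors (Broto-Moreau, Moran,
    Geary), Burden-eigenvalue (BCUT) descriptors and constitutional counts;
    splits data with the Kennard-Stone maximin algorithm; fits stepwise
    multiple linear regression and NIPALS partial least squares models, with
    genetic-algorithm descriptor-subset selection wrapped around PLS; validates
    models with cross-validation, external Q2, Tropsha criteria and
    Y-randomization; delimits a leverage-based applicability domain (Williams
    plot); and screens substituent-enumerated candidate molecules through the
    fitted model with applicability-domain filtering. Includes generators for
    synthetic molecules and descriptor/activity data with planted signal.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ChemmineR,
    ChemmineOB,
    igraph,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
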