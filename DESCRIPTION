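Package: regiots
Title: Automated Transition-State Search for Radical C-H Functionalization Regioselectivity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts the regioselectivity of sulfinate-mediated radical C-H
    functionalization of nitrogen heteroarenes by automated transition-state
    searching. From an input SMILES the package enumerates candidate aromatic
    C-H reaction sites, builds per-site pseudo-transition-state geometries for
    radical addition (with steric-clash resolution by dihedral rotation and a
    forming C-C bond-length correction), drives a pluggable quantum-chemistry
    backend through a rescue state machine to validated first-order saddle
    points, and converts per-site activation energies into Boltzmann-weighted
    regioisomeric ratios and a ranked site prediction. A batch orchestrator
    with result caching and a dataset-curation pipeline (drug-likeness
    filters, Morgan-fingerprint Tanimoto clustering, diversity sampling) are
    included, together with a deterministic mock engine and fixture
    generators so the full workflow is testable without any quantum-chemistry
    installation. Molecule perception and seeded 3D embedding are delegated
    to RDKit through a bundled Python worker.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    ChemmineR,
    ChemmineOB,
    bio3d,
    optparse
SystemRequirements: Python (>= 3.8) with the rdkit package, available as
    'python' on the PATH (used for SMILES parsing, 3D embedding and
    fingerprints).
Config/testthat/edition: 3
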