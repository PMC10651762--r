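Package: ChemLibDesign
Title: Transformation-Rule Driven Design of Multi-Target Focused Compound Libraries
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Ligand-based design engine for multi-target focused compound
    libraries. Parses and validates medicinal-chemistry transformation rules
    encoded in SMIRKS notation, iteratively enumerates virtual libraries from
    seed compounds under molecular-weight and polar-surface-area gates,
    standardizes and deduplicates compound collections, scores drug-likeness
    (QED) and synthetic accessibility, applies a structural-alert filter
    cascade with per-stage attrition reporting, and characterizes library
    diversity in several chemical spaces (property PCA and t-SNE, ECFP4
    Tanimoto tree maps, and principal-moments-of-inertia shape profiles).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    ChemmineOB,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
SystemRequirements: OpenBabel (obabel on PATH, for 3D conformer generation)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'ChemLibDesign-package.R'
    'alerts.R'
    'chem-elements.R'
    'chem-graph.R'
    'chem-ob.R'
    'chem-smarts.R'
    'chem-smiles.R'
    'chem-smirks.R'
    'chemspace.R'
    'curation.R'
    'descriptors.R'
    'enumeration.R'
    'filtering.R'
    'fingerprint.R'
    'fixtures.R'
    'methods.R'
    'molprops.R'
    'pipeline.R'
    'rule-engine.R'
    'sascore.R'
    'shape.R'
    'utils.R'
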