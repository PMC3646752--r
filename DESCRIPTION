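Package: secflux
Title: Genome-Scale Model of the Yeast Protein Secretory Machinery
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Reconstruction and simulation toolkit for the Saccharomyces
    cerevisiae protein secretory machinery. Represents proteomes as Protein
    Specific Information Matrices (PSIM) of seven secretory features,
    enumerates the combinatorial catalog of theoretical secretory classes,
    ships a curated machinery network (components, subsystems, compartments
    and template/complex-formation/biosynthesis/exchange reactions), and
    instantiates protein-specific post-translational modification and
    transport reaction lists. Steady-state calculators estimate metabolic
    precursor demand, protein synthesis cost in ATP and NADPH equivalents,
    and the specific activity of each machinery component. A seeded
    synthetic-proteome generator makes every stage testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports: methods, stats, utils, tools, yaml, jsonlite, Biostrings
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
biocViews: SystemsBiology, NetworkInference, Proteomics, Pathways
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'utils.R'
    'psim.R'
    'classes.R'
    'model.R'
    'reactions.R'
    'demand.R'
    'activity.R'
    'synthetic.R'
    'cli.R'
    'secflux-package.R'
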