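Package: resbind
Title: Multitask Residue-Level Protein Binding-Site Prediction with
    Equivariant Graph Neural Networks
Version: 0.1.0
Authors@R:
    person("resbind", "developers", email = "resbind@example.org",
           role = c("aut", "cre"))
Description: Labels residue-level binding sites for five partner categories
    (protein, DNA/RNA, ligand, ion, lipid) from heavy-atom contacts in
    mmCIF/PDB structures, builds residue graphs with sequence- and
    structure-derived node and edge features, and trains a four-layer
    equivariant graph neural network with per-task sigmoid heads to
    predict binding probabilities per residue.  Includes a deterministic
    synthetic-complex generator so that every stage (labeling,
    featurization, training, evaluation) is testable offline, plus a
    command-line interface tying the stages together.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
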