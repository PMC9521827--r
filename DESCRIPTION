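Package: gemdraft
Title: Template-Based Draft Reconstruction of Genome-Scale Metabolic Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds draft genome-scale metabolic models for a query organism
    by transferring reactions from template models. Homologous genes are
    identified by reciprocal best-hit bidirectional similarity searches,
    gene-protein-reaction (GPR) Boolean rules are decomposed into isozyme
    clauses and re-written onto the query genome, and redundant reaction
    variants (reversibility re-writes and protonation-state copies) are
    collapsed. Includes COG-profile based template selection, SBML
    Level 3 FBC and COBRA JSON input/output, draft-versus-reference
    benchmarking with precision/recall/F1, multi-model overlap summaries,
    and a deterministic synthetic-fixture generator with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    xml2,
    vegan,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
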