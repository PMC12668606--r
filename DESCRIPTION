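Package: binderscreen
Title: Backbone Filtering, Confidence Scoring and Campaign Orchestration
    for De Novo Protein Binder Design
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the compute side of de novo protein binder design
    campaigns: parsing and writing binder-target complexes in PDB format,
    rigid-body superposition and template grafting, steric-clash and
    secondary-structure topology filters for candidate backbones,
    AlphaFold-style confidence metrics on predicted complexes (binder pLDDT,
    interchain PAE and the pLDDT-weighted interface PAE score CUTRE),
    threshold-based hit calling with append-only score bookkeeping, and a
    batch-based campaign engine with pluggable generative stages.  Synthetic
    stage mocks (ideal backbones, controllable PAE/pLDDT blocks) make the
    whole pipeline testable without GPU inference.  Hit extraction covers
    PDB/FASTA export, codon-usage reverse translation with cloning flanks,
    and ungapped BLOSUM62 similarity.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
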