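Package: cyclescan
Title: Nutrient-Cycle Profile-HMM Annotation of Metagenomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds clustered profile hidden Markov model (HMM) databases from
    KEGG-orthology-keyed protein sets, organizes the profiles into nutrient-cycle
    subsets with key-gene flags, and annotates binned or unbinned metagenome
    assemblies gene-centrically. Annotation runs a two-phase HMM search (key-gene
    subsets first, then the full metabolic database), triages hits through tiered
    e-value and model-versus-query size filters including a relaxed small-protein
    path, resolves one best hit per open reading frame by bit score, and
    aggregates results into per-cycle overviews with bins-harboring counts and
    coverage-weighted abundance. Includes a deterministic synthetic-data
    generator (protein families with conserved motifs, toy multi-bin communities
    with planted genes, coverage tables) so the whole pipeline can be exercised
    with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    yaml,
    methods,
    withr,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
SystemRequirements: HMMER3 (hmmbuild, hmmsearch), Prodigal, MAFFT
Config/testthat/edition: 3
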