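Package: oligotiler
Title: Thermodynamically Constrained Antisense Oligo Tiling for
    RNaseH-Mediated RNA Depletion
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Designs antisense DNA oligo pools for RNaseH-mediated depletion
    of abundant RNAs (typically rRNA) ahead of RNA-seq library construction.
    Oligos are placed along a target RNA by greedy left-to-right tiling that
    maximizes the untiled gap between consecutive oligos up to a user bound,
    subject to length and RNA-DNA hybrid melting-temperature constraints
    computed with nearest-neighbor thermodynamics, followed by a gap-balancing
    refinement pass. For divergent RNA variants (e.g. maternal and somatic
    rRNAs), compact shared pools are built either by exact oligo reuse across
    unaligned targets or by tiling an IUPAC-wildcard consensus of an
    alignment, classifying oligos as common, wildcard or target-unique.
    Includes FASTA/TSV/BED input-output, design summaries with cost baselines,
    digestion-fragment prediction, a reaction-molarity helper and
    deterministic synthetic-fixture generators.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
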