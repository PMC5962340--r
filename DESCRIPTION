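Package: charkit
Title: RNA-DNA Contact Mapping from Chimeric Proximity-Ligation Reads
Version: 0.1.0
Authors@R:
    person("Char", "Kit", email = "maintainer@charkit.dev", role = c("aut", "cre"))
Description: Tools for chromatin-associated RNA sequencing (ChAR-seq) style
    RNA-DNA proximity ligation data. Splits single-end chimeric reads at a
    bridge oligonucleotide using its polarity to distinguish the RNA and DNA
    sides, annotates RNA sides against ranked transcriptome categories with a
    sense-first policy, joins both sides into RNA-DNA contacts, builds
    DpnII-site-normalized coverage tracks with z-score transforms and
    metaprofiles, and computes chromosome enrichment, signal-to-noise,
    resolution, spike-in false-positive and TAD-boundary statistics. Includes
    a deterministic synthetic-data generator (toy genome, annotations,
    chimeric FASTQ reads and a ground-truth table) so the whole pipeline is
    testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    Biostrings,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
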