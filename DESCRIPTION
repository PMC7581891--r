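Package: droughtmem
Title: Drought Stress Memory Transcript Analysis for 3'-Anchored Microarrays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for screening drought stress memory genes with a
    3'-anchored oligonucleotide microarray over two drought/recovery cycles.
    Designs 60-nt stop-codon-anchored tiling probes and unique-exon probes
    from a genome annotation, screens probes for cross-hybridization,
    background-corrects and quantile-normalizes intensity matrices, computes
    empirical-Bayes moderated differential statistics, classifies transcripts
    into the drought-induced/-repressed (DIT/DRT) and memory (DIMT/DRMT)
    taxonomy, performs hypergeometric GO enrichment with randomization-based
    false discovery rates, and builds Pearson correlation co-expression
    networks with Newick tree export. A seeded synthetic-data generator
    produces toy genomes, intensity matrices with planted responsive and
    memory transcripts, GO annotations and ortholog alignment tables so the
    full pipeline can be exercised without external downloads.
License: MIT
Encoding: UTF-8
Imports:
    Biostrings,
    rtracklayer,
    GenomicRanges,
    IRanges,
    S4Vectors,
    igraph,
    ape,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    limma,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
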