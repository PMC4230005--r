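Package: adld
Title: Alignment Diagonal Line Diagrams for Protein Sequence Comparison
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Alignment-free similarity and dissimilarity analysis of protein
    sequences through Alignment Diagonal Line Diagrams (ADLDs). Each amino
    acid is assigned a single numeric score derived from a principal component
    analysis of nine physicochemical properties; protein sequences become
    numerical sequences, pairs of which are compared on a banded dot plot
    whose maximal diagonal runs (similar fragments) and isolated diagonal
    points (free points) summarise shared structure. A similarity degree per
    pair yields a distance matrix over a sequence collection, which can be
    exported to PHYLIP format or turned into a neighbor-joining tree in
    Newick format. Includes a FASTA reader, a synthetic sequence-pair
    generator for controlled substitution/insertion/deletion experiments,
    and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
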