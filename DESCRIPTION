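Package: ltrkit
Title: Structural Annotation, Classification and Insertion-Age Dating of
    LTR Retrotransposons
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale toolkit for intact long terminal repeat (LTR)
    retrotransposon analysis in plant-style genomes: structural detection of
    candidates from exact-repeat seeds (target site duplication and TG...CA
    terminal-motif filtering), primer binding site and polypurine tract
    annotation, rule-based classification into autonomous and non-autonomous
    Copia/Gypsy superfamilies and the LARD/TRIM/TR-GAG/BARE-2 structural
    classes, insertion-age estimation from 5'/3' LTR divergence under the
    Kimura two-parameter model (T = K/2r), gene-context and gene-chimera
    calling, greedy centroid clustering into a non-redundant element library,
    nucleotide-level annotation benchmarking, and a synthetic-genome
    simulator with full truth annotations for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    parallel,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr
Suggests:
    ape,
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
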