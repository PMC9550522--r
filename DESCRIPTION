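Package: polyXY
Title: Detection and Classification of Two-Amino-Acid Regions in Protein
    Sequences
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Scans protein sequences with a fixed-length sliding window to
    detect polyXY regions, i.e. low complexity regions composed of exactly
    two amino-acid types, each occurring at least twice within every
    defining window. Detected regions are classified as direpeats (perfect
    'XY' tandem repeats, tolerating one lone residue), joined (a polyX run
    followed by a polyY run, order recorded) or shuffled (the remainder).
    Downstream summaries cover per-dataset totals and category proportions,
    amino-acid usage against proteome background, relative positional
    profiles, direpeat unit distributions, joined-order asymmetry with
    rank-sum testing, and containment of regions within domain or
    intrinsically-disordered annotations against a same-length
    random-placement baseline. A synthetic proteome generator with
    oracle-defined truth tables supports fully offline testing, and a thin
    command-line wrapper exposes scan, summarize, overlap and simulate
    subcommands.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    S4Vectors,
    IRanges,
    Biostrings,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
biocViews: Sequencing, Proteomics, Software
RoxygenNote: 7.3.3
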