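Package: satcen
Title: Satellite DNA Centromere Profiling from ChIP-seq, RNA-seq and Fibre FISH
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies which satellite DNA family carries centromeric
    (CENP-A) function from chromatin immunoprecipitation sequencing.
    Provides a percent-identity read mapper against a panel of repeat
    consensus sequences (with a dimer trick for tandem-junction reads),
    depth- and length-normalised IP/input enrichment ratios, per-position
    base-frequency matrices with consensus calling and information content,
    tandem repeat period estimation and head-to-tail testing, region
    classification by repeat family, stringent ChIP peak filtering with a
    minimal window-based domain caller, RNA-seq counting on equal-length
    windows, slot-blot densitometry ratios, and two-channel chromatin fibre
    profile segmentation with CENP-A binding pattern classification. A
    seeded synthetic-data generator produces every input (toy genome, IP,
    input and RNA read sets, fibre traces, slot-blot values) with known
    ground truth so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
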