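Package: pemerge
Title: Accurate Paired-End Shotgun Read Merging via Overlap and K-mer Extension
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Merges paired-end shotgun sequencing reads into single longer
    reads by gap-free overlap detection with ratio-based offset scoring and a
    cascade of heuristic acceptance gates, followed by Phred-quality-aware
    consensus calling. Supports k-mer-assisted modes that extend read tails
    from a k-mer count table to confirm overlaps (RSEM), rescue
    non-overlapping pairs (REM), and filter merges containing unsupported
    k-mers. Includes a paired-read simulator with a configurable insert-size
    distribution, quality model and adapter read-through, plus a grader that
    scores merged output against known insert sizes (correct and incorrect
    merge rates and signal-to-noise ratio), so merging accuracy can be
    benchmarked end-to-end without external data. Reads and writes
    FASTQ/FASTA (dual-file or interleaved, plain or gzip, Phred+33/64 with
    autodetection) and provides a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
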