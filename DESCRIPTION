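Package: evochannel
Title: Codon Evolution Models Projected into All Six Reading Frames
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models protein-coding sequence evolution with a continuous-time
    Markov codon substitution model (Goldman-Yang M0) and projects the process
    into all six reading frames via the di-codon (Kronecker-sum) construction.
    Provides per-frame selection-pressure estimates (dN/dS), information-
    theoretic noise measures (conditional entropy, mutual information,
    half-information times) over the amino-acid channel, an exhaustive
    enumeration of the genetic code's per-frame coding degrees of freedom,
    a Monte-Carlo sequence simulator for model verification, and projection
    of empirical codon substitution matrices. Includes codon-usage extraction
    from annotated genomes (GenBank/FASTA) and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    Matrix,
    Biostrings,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    seqinr,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
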