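Package: tmdscan
Title: Detection and Comparative Analysis of Single-Span Transmembrane
    Domain Lengths
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for locating the transmembrane domain (TMD) of bitopic
    (single-span) membrane proteins from hydropathy profiles and for
    comparing TMD-length distributions between protein groups. Detection
    uses a sliding-window scan on the Goldman-Engelman-Steitz or
    Kyte-Doolittle scale, flank attachment, and a deterministic
    edge-refinement procedure anchored at the cytosolic end of the span.
    Downstream analyses include redundancy reduction by identity
    clustering, aligned hydropathy and residue-composition profiles, and
    distribution comparisons via Welch t-tests and the symmetric
    Kullback-Leibler divergence of integer length histograms. A
    deterministic synthetic-sequence generator with planted TMDs supports
    end-to-end validation without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
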