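Package: buszr
Title: Lossless Columnar Compression for BUS Single-Cell Files
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Read, write, sort and losslessly compress BUS ("Barcode, UMI,
    Set") files, the fixed 32-byte binary record format for intermediate
    single-cell RNA-seq quantification results. Sorted BUS files are
    compressed block-wise and column-wise (the BUSZ scheme): barcode and
    UMI columns by delta coding plus run-length and Fibonacci universal
    coding, the equivalence-class column by a NewPFD patched
    frame-of-reference codec, counts and flags by run-length/Fibonacci
    coding. Includes an optional barcode index for random access without
    full decompression, a deterministic generator of realistic sorted BUS
    data, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    S4Vectors
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
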