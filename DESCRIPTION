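Package: ezlink
Title: In Silico Type IIS DNA Assembly for Iterative Fusion-Protein Cloning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates type IIS restriction digestion, sticky-end ligation and
    the genetically purified iterative assembly of fusion-protein open reading
    frames (iFLinkC-EZ style), including exhaustive enumeration of circular
    ligation products, a multi-cycle build planner with reading-frame and scar
    verification, a BsmBI Golden Gate layer compiling translation units into
    poly-cistronic constructs, CDS domestication by synonymous substitution,
    and a deterministic synthetic-parts generator producing complete plasmid
    fixtures. Reads and writes GenBank and FASTA.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    yaml
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
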