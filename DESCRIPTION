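Package: hgvsr
Title: Parsing, Formatting, Validation and Mapping of HGVS Sequence Variants
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for manipulating sequence variants written in the Human
    Genome Variation Society (HGVS) nomenclature. Provides a typed object
    model for variants on genomic (g./m.), coding (c.), non-coding (n.),
    RNA (r.) and protein (p.) sequences; a grammar-based parser whose rules
    can be invoked individually; canonical formatting; intrinsic and
    extrinsic (reference-backed) validation; and an indel-aware mapper that
    projects variants between genomic, transcript and protein coordinates
    through genome-transcript alignments, including liftover between
    transcripts via a shared genomic reference. Reference data are served
    through a pluggable provider interface with a fixture-backed
    implementation and a deterministic synthetic-locus generator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    jsonlite,
    stats
Suggests:
    seqinr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
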