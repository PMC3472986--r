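Package: tagdge
Title: Tag-Based Digital Gene Expression Profiling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for restriction-tag digital gene expression
    (DGE/SAGE-style) experiments in which transcripts are quantified by
    sequencing 21nt tags anchored at the 3'-most NlaIII (CATG) site and cut
    17bp downstream by MmeI. Provides a synthetic-data generator emulating
    the two-library tag-sequencing protocol, raw-read cleaning to clean-tag
    count tables, a virtual CATG+17 tag library with exact and one-mismatch
    tag-to-gene mapping, transcripts-per-million normalisation, the
    Audic-Claverie exact test with Benjamini-Hochberg false discovery rate
    control for two-library differential expression, hypergeometric GO-term
    and pathway enrichment, saturation (rarefaction) analysis, and
    2^-ddCt qPCR validation with concordance summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Biostrings
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
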