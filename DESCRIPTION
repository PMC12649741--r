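Package: arrowdesign
Title: Allele-Specific CRISPR Guide Design with Intentional Mismatches
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for designing allele-specific CRISPR-Cas9 guide RNAs that
    discriminate single-nucleotide mutant alleles (for example EGFR L858R and
    KRAS G12V) from wild-type sequences by deliberate introduction of one-base
    mismatches (the ARROW strategy). Includes PAM-indexed mismatch enumeration
    and tolerance classification, enumeration of candidate off-target sites
    under mismatch and DNA/RNA-bulge budgets, quantification of editing
    outcomes from amplicon sequencing reads using a PAM-proximal indel window,
    and deterministic simulators for planted genomes and edited read sets.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
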