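Package: pairuniq
Title: Reference-Free Removal of PCR Duplicates from Paired-End Short Reads
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Removes PCR duplicates from paired-end sequencing libraries
    without a reference genome. Read pairs are imported from synchronized
    FASTQ files, sorted with a nucleotide comparator in which a shorter
    sequence that exactly matches the 5' end of a longer one counts as its
    duplicate, and duplicates are identified by a single scan over adjacent
    pairs in the sorted list, keeping the copy whose mates are both at
    least as long as the other's. Includes FASTQ/FASTA writers for paired
    and interleaved output, a seeded simulator of paired libraries with
    known duplicate structure for validation, and a command-line front end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    Biostrings
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
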