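# pairuniq

Reference-free removal of PCR duplicates from paired-end short reads.

PCR amplification during sequencing-library preparation produces multiple
copies of the same template molecule. These duplicate read pairs carry no
independent information and bias downstream analyses — scaffold link counts
in genome assembly, allele ratios in variant discovery, coverage estimates.
The standard removal strategy maps reads to a reference genome and collapses
pairs with identical coordinates, which fails for species without a finished
reference and is confounded by structural variation and repeats. pairuniq
instead removes duplicates *de novo*, from the read sequences alone, so it
works for any organism and is untouched by mapping artefacts. It is intended
for anyone processing paired FASTQ libraries ahead of assembly, scaffolding
or population analyses — in particular mate-pair libraries, whose
circularization protocols leave duplicate levels far above those of
short-insert paired-end libraries.

## Method

The tool runs in three steps, entirely in memory:

1. **Import.** All read pairs named by an input-list file (one FASTQ path
   per line; two adjacent lines are the mate files of one library, with
   reads in the same order) are loaded into an indexed pair store.
2. **Sort.** The pair list is sorted by a stable merge sort under a
   sequence comparator: bases are compared position by position with
   `A < C < G < T` (extended to full byte order for other characters);
   when one sequence is a 5′ prefix of the other, the shorter sorts first
   *and the two count as duplicates* — reads from the same molecule may
   differ in length after per-read quality trimming. Mate 1 decides the
   order; mate 2 is consulted only when the mate-1 sequences are the same.
3. **Scan.** Duplicates are collapsed in a single pass over adjacent pairs
   of the sorted list. Two pairs are duplicate candidates when both mates
   are byte-identical or 5′-prefix-equivalent. Of two candidates, the pair
   whose mates are *both* at least as long survives; when each pair is
   longer in one mate, both are kept. Byte-identical copies resolve to the
   earliest input copy, so the surviving header and qualities are
   deterministic.

Retained pairs are written as two synchronized FASTQ or FASTA files, or as
a single interleaved FASTA file with adjacent records belonging to a pair.
Retained reads are byte-identical to their input records — nothing is ever
rewritten.

With one fixed read length per mate, the survivor set provably equals exact
deduplication on the concatenated `read1+read2` key (the collapser-style
oracle); the test suite verifies this equivalence across seeded libraries,
along with conservation (`pairs in = retained + removed`), idempotence, and
an all-pairs dominance bound on variable-length libraries.

## Worked example

Simulate a paired library of 500 template molecules in which half the
molecules are amplified (expected multiplicity 2) and 20% of copies are
3′-truncated by quality trimming, then deduplicate it:

```r
library(pairuniq)

dir <- tempdir()
spec <- fixture_spec(n_clusters = 500, truncation_prob = 0.2,
                     max_truncation = 5, seed = 42)
generate_library(spec,
                 file.path(dir, "lib_1.fq"), file.path(dir, "lib_2.fq"),
                 file.path(dir, "lib.manifest.tsv"))
writeLines(file.path(dir, c("lib_1.fq", "lib_2.fq")),
           file.path(dir, "input_list.txt"))

res <- dedup_pipeline(file.path(dir, "input_list.txt"),
                      file.path(dir, "unique_1.fq"),
                      file.path(dir, "unique_2.fq"),
                      mode = "fastq-pair")
#> pairuniq: 1016 pairs in, 512 retained, 504 duplicates removed (49.61%)
```

The 500 molecules were emitted as 1016 pairs; deduplication retains 512 —
the 500 clusters plus 12 crossed-length copies (each longer in one mate
than the cluster's other surviving copy, so neither dominates), matching
the generator's independent all-pairs oracle exactly. The duplicate level
(49.61%) is the fraction of pairs removed, reported to two decimals.

The same run from a shell, via the installed script:

```sh
pairuniq -i input_list.txt -t q -o unique_1.fq -p unique_2.fq   # paired FASTQ
pairuniq -i input_list.txt -t p -o unique.fa                    # interleaved FASTA
```

Exit codes: 0 success, 1 runtime error, 2 usage error.

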