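---
title: "De novo deduplication of paired short reads: model, parameters and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{De novo deduplication of paired short reads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pairuniq)
```

## The problem

PCR amplification during library preparation copies template molecules, so
a paired-end or mate-pair sequencing run contains groups of read pairs that
all descend from one molecule. Only one member of each group carries
information; the rest inflate coverage and link counts. Mapping-based
removal (collapsing pairs with identical alignment coordinates) requires a
finished reference genome and inherits every mapping artefact. pairuniq
removes duplicates from the sequences alone: it needs no reference, is
indifferent to repeats and structural variation, and treats every organism
alike. The trade-off is the opposite sensitivity: a single sequencing error
or heterozygous site inside a read makes two copies of the same molecule
look distinct, so sequence-based removal is conservative in the presence
of errors.

## The model

A read pair is duplicate-equivalent to another when **both** mates are the
same under the cross-length equality rule: two reads are the same when they
are byte-identical, or when the shorter exactly matches the 5′ end of the
longer. The length allowance exists because per-read quality trimming
shortens reads from their 3′ end; two copies of one molecule can therefore
differ in length while sharing their 5′ sequence. Equality is exact — `N`
matches only `N`, case is not folded (an optional switch uppercases on
load), and qualities play no role.

Among a group of duplicates, the copy whose mates are both at least as long
as the other's is the better representative (it carries the most sequence),
and the dominated copy is removed. When each of two candidates is longer in
one mate, neither dominates and both are kept. When all four lengths tie,
the sequences are necessarily byte-identical and the copy that appeared
first in the input survives, which makes the surviving header and quality
bytes deterministic.

## The algorithm

1. **Import.** All pairs are held in memory in a flat store (one row per
   pair), matching the intended whole-dataset workflow; there is no
   streaming mode.
2. **Sort.** A stable bottom-up merge sort orders the store: mate 1
   decides; mate 2 is consulted when the mate-1 sequences are
   duplicate-equivalent; among fully equivalent pairs, mate-2 length then
   mate-1 length order the group (shorter first); remaining ties fall back
   to the input ordinal. Base order is `A < C < G < T`, which coincides
   with byte order; the comparator uses full byte order so that any
   character is orderable. The merge sort is written in C++ by hand rather
   than delegated to `std::stable_sort` or radix `order()`: the
   prefix-equality rule makes the comparator *not* a strict weak ordering
   (`AC` is equivalent to both `ACA` and `ACC`, which differ), which
   violates the standard-library contract, and a radix sort on the raw
   strings would let a mate-1 length difference override a mate-2 base
   difference, which is the wrong order for this comparator. A hand-written
   merge sort is deterministic under any comparator.
3. **Scan.** One left-to-right pass holds a current representative. A next
   pair that is not a duplicate candidate of the representative causes the
   representative to be emitted. Among candidates the dominated pair is
   dropped; on crossed lengths both are kept and the later pair becomes
   the representative. Emission goes through a stack: a newly emitted pair
   first retracts trailing retained pairs that it is a candidate of and
   dominates. The retraction exists because a dominating pair always sorts
   at or after the pairs it dominates; after a crossed-length event the
   scan can emit a pair and only later meet a copy that dominates it, and
   without retraction that dominated copy would survive, making a second
   deduplication pass remove reads a first pass kept. With retraction,
   deduplication is idempotent. With one fixed read length per mate,
   crossed lengths cannot occur and the retraction never fires.

The scan compares only adjacent candidates, so with variable lengths two
duplicates separated in sort order by a non-duplicate (mate-1 reads `AC`,
`ACG`, `ACT`, where only the first and third pairs are duplicates) are not
merged. This incompleteness is inherent to single-pass adjacent scanning
under a non-transitive equivalence and is deliberate: it preserves the
linear-time scan. Where the equivalence *is* transitive — all reads of a
mate sharing one length — the scan is provably complete, and the survivor
set equals exact-key deduplication of the concatenated `read1+read2`
string. That equivalence is the package's strongest correctness guarantee
and is tested across seeded libraries; on variable-length input the
guaranteed (and tested) properties are the weaker ones: every removed pair
is duplicate-equivalent to and dominated by a retained pair, counts are
conserved, and the operation is idempotent.

## Parameters that matter

* `mode` (writer): `fastq-pair`, `fasta-pair`, or `fasta-interleaved`.
  FASTQ requires qualities; FASTA output discards them. Interleaved FASTA
  places the two mates of each pair in adjacent records, the layout
  expected by single-sequence downstream tools.
* `normalize_case` (loader, default off): uppercases sequences on load.
  Off by default because byte-wise comparison is the conservative reading
  — soft-masked (lowercase) bases are treated as distinct characters.
* Input lists name files in pairs; `.gz` suffixes are decompressed on the
  fly. FASTQ must be strict 4-line records; wrapped FASTQ is rejected
  rather than guessed at.

## The synthetic generator

`fixture_spec()` / `simulate_pairs()` / `generate_library()` produce
paired libraries with known duplicate structure, used by the test suite
and the acceptance script as ground truth. The generator emulates PCR
amplification directly: `n_clusters` template pairs of i.i.d. uniform
ACGT bases, each emitted at a copy number drawn from
`multiplicity_dist`, shuffled, with constant `'I'` qualities and headers
recording the source cluster.

Defaults are fixed study conditions, chosen once: 75 bp reads for both
mates (a typical trimmed short-read length, and the read length of the
mate-pair data on which collapser-equivalence is the reference behaviour)
and multiplicity mixture `{1: 0.5, 2: 0.25, 4: 0.25}` — half the molecules
unamplified, an expected multiplicity of 2, i.e. a duplicate level near
50%, between the <4% of well-made paired-end libraries and the >80% of the
worst mate-pair libraries. The scalability checks use 35 bp reads, a
realistic lower bound for useful short reads. Two optional corruptions
mirror the two ways real copies diverge: `truncation_prob` shortens a copy
from the 3′ end by 1..`max_truncation` bases (5′ anchored, so the copy
remains a duplicate under the prefix rule — 3′-only because 5′ trimming
would break duplicate identity by construction), and `substitution_prob`
introduces one random substitution (making the copy a non-duplicate under
the exact-match rule, as a sequencing error would). The generator draws
`N` never, uniform base composition, no insert-size or quality model, and
no reference genome — it emulates duplicate *structure*, not sequencing
realism, so passing tests certify the deduplication logic, not robustness
to error-rich real data.

The manifest's expected survivor count comes from the generator's own
all-pairs oracle, independent of the scan: a pair is removed when some
other duplicate-equivalent pair dominates it strictly, or is byte-identical
and earlier. With equal lengths this is exact-key counting (fast path);
otherwise it is an O(n²) computation intended for small instances, and a
lower bound on what the adjacent scan retains.

## Numerical and degenerate-input choices

* Empty sequences are rejected at load: the comparator is undefined for
  them. Empty *files* (zero records) are likewise errors, as are mate
  files of unequal record count — silent truncation is never an option.
* Byte order beyond ACGT places `N` between `G` and `T`; lowercase sorts
  after all uppercase. This is an arbitrary but total and documented
  extension of the stated four-base rule.
* Output is in sorted order, not input order; input ordinals are kept on
  the store for traceability and tie-breaking.
* The survivor of a byte-identical group is the earliest input copy;
  nothing else about a read is ever modified, so outputs are byte-stable
  across platforms and repeat runs.

## Validation scales

The test suite and `scripts/acceptance.R` exercise: collapser-equivalence
on 20 seeded equal-length libraries of ≥1,000 pairs (half with a 10%
substitution rate); the dominance bound and idempotence on 50 seeded
variable-length libraries of ≤200 pairs with a 40% per-mate truncation
rate; exact ground-truth collapse for 1, 100 and 10,000 clusters; and an
in-memory smoke test on roughly one million 35 bp pairs, with runtime
compared across 0.1/0.5/1.0 million-pair subsets to confirm near-linear
growth (no absolute speed is asserted). These sizes were chosen to give
tight statistical coverage while keeping a full validation run around a
minute on one core.

## Known limitations

* Sensitivity to errors: one substitution anywhere in either mate makes a
  copy survive. Real duplicate levels are therefore underestimated at high
  error rates; no fuzzy matching is attempted.
* Reverse-complement duplicates (the same fragment sequenced in the other
  orientation) are not detected, matching the scope of sequence-identity
  deduplication.
* The adjacent scan can keep non-adjacent variable-length duplicates (see
  above); the equal-length guarantee is the exactness statement.
* Whole-dataset memory residency is assumed; there is no external sort.
* FASTA input, interleaved FASTQ input and SAM/BAM are out of scope.
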