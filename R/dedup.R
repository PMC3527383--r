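# The deduplication algorithm proper: the sequence comparator with its
# 5'-prefix equality rule, the stable merge sort of the pair list, and the
# adjacent scan that collapses duplicate runs under length dominance.
# The sort and scan loops run in C++ (src/dedup_core.cpp); the R functions
# here define the same semantics one comparison at a time and are the
# reference for small-scale work and documentation.

#' Order two nucleotide sequences
#'
#' Bases are compared at the same position one by one, under the base
#' order A < C < G < T; the order is decided at the first differing base.
#' If no difference is found within the shorter sequence, the order is
#' decided by length: the shorter sequence sorts before, and the two
#' sequences are duplicate-equivalent (the shorter exactly matches the 5'
#' end of the longer). A, C, G, T in order coincides with byte order, and
#' the comparator extends to full byte order so that any character
#' (N, IUPAC ambiguity codes, lowercase) is orderable; no character
#' matches anything but itself.
#'
#' @param a,b Non-empty sequence strings.
#' @return `"before"`, `"equal"` or `"after"`. `"equal"` means
#'   byte-identical; use [duplicate_equivalent()] for the cross-length
#'   duplicate rule.
#' @examples
#' compare_sequences("A", "C")
#' compare_sequences("ACG", "ACGT")  # prefix: shorter sorts before
#' compare_sequences("ACT", "ACG")
#' @export
compare_sequences <- function(a, b) {
  stopifnot(is.character(a), is.character(b), nzchar(a), nzchar(b))
  ra <- charToRaw(a)
  rb <- charToRaw(b)
  m <- min(length(ra), length(rb))
  diff <- which(ra[seq_len(m)] != rb[seq_len(m)])
  if (length(diff)) {
    i <- diff[1L]
    return(if (ra[i] < rb[i]) "before" else "after")
  }
  if (length(ra) < length(rb)) "before"
  else if (length(ra) > length(rb)) "after"
  else "equal"
}

#' Are two sequences duplicates of one another?
#'
#' Two reads count as the same molecule when they are byte-identical, or
#' when the shorter exactly matches the 5' end of the longer (differing
#' read lengths arise from per-read quality trimming, not from different
#' template molecules).
#'
#' @param a,b Non-empty sequence strings.
#' @return `TRUE` or `FALSE`.
#' @examples
#' duplicate_equivalent("AC", "ACGT")
#' duplicate_equivalent("AC", "AGGT")
#' @export
duplicate_equivalent <- function(a, b) {
  stopifnot(nzchar(a), nzchar(b))
  m <- min(nchar(a), nchar(b))
  substr(a, 1L, m) == substr(b, 1L, m)
}

#' Order two read pairs
#'
#' Read-1 sequences are compared first; read-2 sequences are compared
#' only if the read-1 sequences are the same (duplicate-equivalent).
#' The result is `"equal"` exactly when both mates are
#' duplicate-equivalent — the duplicate-candidate criterion.
#'
#' @param p,q Read pairs: any list-like with elements `seq1` and `seq2`
#'   (e.g. a one-row slice of a [pair_store()]).
#' @return `"before"`, `"equal"` (duplicate candidates) or `"after"`.
#' @examples
#' compare_pairs(list(seq1 = "ACG", seq2 = "TTT"),
#'               list(seq1 = "ACGT", seq2 = "TTTA"))
#' @export
compare_pairs <- function(p, q) {
  if (!duplicate_equivalent(p$seq1, q$seq1)) {
    return(compare_sequences(p$seq1, q$seq1))
  }
  if (!duplicate_equivalent(p$seq2, q$seq2)) {
    return(compare_sequences(p$seq2, q$seq2))
  }
  if (nchar(p$seq2) != nchar(q$seq2)) {
    return(if (nchar(p$seq2) < nchar(q$seq2)) "before" else "after")
  }
  if (nchar(p$seq1) != nchar(q$seq1)) {
    return(if (nchar(p$seq1) < nchar(q$seq1)) "before" else "after")
  }
  "equal"
}

#' Choose the surviving copy among two duplicate candidates
#'
#' Of two duplicate pairs, the one whose mates are both at least as long
#' as the other's survives; if each pair is longer in one mate, both are
#' kept. When all four lengths are equal the duplicates are
#' byte-identical and the pair with the smaller input ordinal survives,
#' so the survivor's header and qualities are deterministic.
#'
#' @param p,q Duplicate-candidate read pairs (elements `seq1`, `seq2` and
#'   optionally `ordinal`).
#' @return `"keep-p-drop-q"`, `"keep-q-drop-p"` or `"keep-both"`.
#' @examples
#' select_representative(list(seq1 = "ACGT", seq2 = "TTTT"),
#'                       list(seq1 = "ACG", seq2 = "TTT"))
#' select_representative(list(seq1 = "ACGT", seq2 = "TTT"),
#'                       list(seq1 = "ACG", seq2 = "TTTT"))
#' @export
select_representative <- function(p, q) {
  if (!duplicate_equivalent(p$seq1, q$seq1) ||
      !duplicate_equivalent(p$seq2, q$seq2)) {
    stop("select_representative() called on pairs that are not duplicate ",
         "candidates")
  }
  p_dom <- nchar(p$seq1) >= nchar(q$seq1) && nchar(p$seq2) >= nchar(q$seq2)
  q_dom <- nchar(q$seq1) >= nchar(p$seq1) && nchar(q$seq2) >= nchar(p$seq2)
  if (p_dom && q_dom) {
    # byte-identical duplicates: earliest input pair survives
    op <- if (is.null(p$ordinal)) 0L else p$ordinal
    oq <- if (is.null(q$ordinal)) 1L else q$ordinal
    return(if (op <= oq) "keep-p-drop-q" else "keep-q-drop-p")
  }
  if (p_dom) return("keep-p-drop-q")
  if (q_dom) return("keep-q-drop-p")
  "keep-both"
}

#' Sort a pair store by read sequences
#'
#' Stable merge sort of the whole pair list under [compare_pairs()]:
#' read 1 decides, read 2 breaks ties among duplicate-equivalent read 1s,
#' length breaks ties among duplicate-equivalent pairs (shorter first),
#' and input ordinal breaks full ties, so byte-identical pairs keep their
#' input order.
#'
#' @param store A [pair_store()].
#' @return The same store, rows permuted into sorted order. Ordinals are
#'   carried along unchanged.
#' @export
sort_pairs <- function(store) {
  store <- validate_pair_store(store)
  perm <- sort_order_cpp(store$seq1, store$seq2, store$ordinal)
  out <- store[perm, , drop = FALSE]
  rownames(out) <- NULL
  out
}

dedup_result <- function(retained, n_input) {
  structure(
    list(
      retained = retained,
      n_input = n_input,
      n_retained = nrow(retained),
      n_removed = n_input - nrow(retained)
    ),
    class = "dedup_result"
  )
}

#' @export
print.dedup_result <- function(x, ...) {
  pct <- if (x$n_input > 0) 100 * x$n_removed / x$n_input else 0
  cat(sprintf(
    "deduplicated read pairs: %d in, %d retained, %d duplicates removed (%.2f%%)\n",
    x$n_input, x$n_retained, x$n_removed, pct))
  invisible(x)
}

#' Identify duplicates in a sorted pair list
#'
#' One left-to-right scan over adjacent pairs of the sorted list. A
#' current representative is held; each next pair that is not a duplicate
#' candidate of it causes the representative to be emitted and replaced.
#' Among candidates, [select_representative()] decides: the dominated
#' copy is dropped, and on crossed lengths both are kept, with the later
#' pair becoming the new representative. Emission is through a stack:
#' a newly emitted pair retracts trailing retained pairs that it is a
#' duplicate candidate of and dominates, which keeps deduplication
#' idempotent when crossed-length duplicates occur (with one fixed read
#' length per mate the retraction never fires). Retained pairs keep
#' their original header, sequence and quality bytes.
#'
#' @param sorted_store A [pair_store()] already sorted by [sort_pairs()].
#' @return A `dedup_result`: list with `retained` (a `pair_store` in
#'   sorted order), `n_input`, `n_retained`, `n_removed`.
#' @examples
#' st <- sort_pairs(pair_store(c("AC", "ACG", "ACGT"),
#'                             c("GG", "GGG", "GGGG")))
#' remove_duplicates(st)
#' @export
remove_duplicates <- function(sorted_store) {
  sorted_store <- validate_pair_store(sorted_store)
  if (nrow(sorted_store) == 0L) {
    return(dedup_result(sorted_store, 0L))
  }
  keep <- scan_retain_cpp(sorted_store$seq1, sorted_store$seq2)
  retained <- sorted_store[keep, , drop = FALSE]
  rownames(retained) <- NULL
  dedup_result(retained, nrow(sorted_store))
}

#' Remove PCR duplicates from paired FASTQ files
#'
#' The full three-step flow: import all read pairs named by the input
#' list into memory, sort them by sequence, collapse duplicates by the
#' adjacent scan, and write the unique pairs in the requested output
#' mode. A one-line summary (pairs in, retained, duplicate percentage)
#' goes to the message stream.
#'
#' @param input_list_path Path to the input-list file (one FASTQ path per
#'   line, adjacent lines are mates; see [parse_input_list()]).
#' @param out1,out2,mode Output destination, as in [write_output()].
#' @param normalize_case Uppercase sequences on load (default `FALSE`).
#' @param verbose Emit the run summary (default `TRUE`).
#' @return Invisibly, the `dedup_result`.
#' @export
dedup_pipeline <- function(input_list_path, out1, out2 = NULL,
                           mode = c("fastq-pair", "fasta-pair",
                                    "fasta-interleaved"),
                           normalize_case = FALSE, verbose = TRUE) {
  mode <- match.arg(mode)
  store <- load_pairs(parse_input_list(input_list_path), normalize_case)
  res <- remove_duplicates(sort_pairs(store))
  write_output(res, out1, out2, mode)
  if (verbose) {
    pct <- if (res$n_input > 0) 100 * res$n_removed / res$n_input else 0
    message(sprintf(
      "pairuniq: %d pairs in, %d retained, %d duplicates removed (%.2f%%)",
      res$n_input, res$n_retained, res$n_removed, pct))
  }
  invisible(res)
}
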