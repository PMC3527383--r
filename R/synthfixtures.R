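# Seeded simulator of paired libraries with known duplicate structure.
# Clusters of identical template pairs emulate PCR amplification; optional
# 3'-truncation of copies emulates per-read quality trimming (5' ends stay
# anchored, so truncated copies remain duplicates under the prefix rule);
# optional single-base substitution emulates a sequencing error, which
# makes a copy a NON-duplicate under the exact-match rule. The manifest's
# expected survivor count comes from an all-pairs oracle that is
# independent of the scan-based deduplicator.

#' Describe a synthetic paired library
#'
#' @param n_clusters Number of template molecules (duplicate clusters).
#' @param read_len_1,read_len_2 Read lengths in bases for mate 1 / mate 2
#'   (minimum 10).
#' @param multiplicity_dist Named numeric vector: names are copy numbers,
#'   values their probabilities (must sum to 1). The default mixture
#'   `c("1" = 0.5, "2" = 0.25, "4" = 0.25)` gives a library in which half
#'   the molecules are sequenced once and the rest are PCR-amplified.
#' @param truncation_prob Probability that an emitted mate is 3'-truncated
#'   by 1..`max_truncation` bases (independently per mate). Truncated
#'   copies are still duplicates of their cluster under the 5'-prefix rule.
#' @param max_truncation Maximum truncation depth in bases.
#' @param substitution_prob Probability that an emitted copy carries one
#'   random substitution in one mate, making it a non-duplicate.
#' @param seed Integer seed; the same spec always yields byte-identical
#'   libraries.
#' @return A `fixture_spec` object.
#' @export
fixture_spec <- function(n_clusters = 1000L,
                         read_len_1 = 75L, read_len_2 = 75L,
                         multiplicity_dist = c("1" = 0.5, "2" = 0.25,
                                               "4" = 0.25),
                         truncation_prob = 0, max_truncation = 5L,
                         substitution_prob = 0, seed = 1L) {
  n_clusters <- as.integer(n_clusters)
  stopifnot(n_clusters >= 1L, read_len_1 >= 10L, read_len_2 >= 10L,
            truncation_prob >= 0, truncation_prob <= 1,
            substitution_prob >= 0, substitution_prob <= 1,
            max_truncation >= 1L)
  mult <- suppressWarnings(as.integer(names(multiplicity_dist)))
  if (anyNA(mult) || any(mult < 1L)) {
    stop("multiplicity_dist names must be positive integer copy numbers")
  }
  if (any(multiplicity_dist < 0) || any(multiplicity_dist > 1) ||
      abs(sum(multiplicity_dist) - 1) > 1e-9) {
    stop("multiplicity_dist probabilities must lie in [0,1] and sum to 1")
  }
  if (truncation_prob > 0 &&
      max_truncation >= min(read_len_1, read_len_2)) {
    stop("read length too small for requested truncation depth")
  }
  structure(
    list(n_clusters = n_clusters,
         read_len_1 = as.integer(read_len_1),
         read_len_2 = as.integer(read_len_2),
         multiplicity_dist = multiplicity_dist,
         truncation_prob = truncation_prob,
         max_truncation = as.integer(max_truncation),
         substitution_prob = substitution_prob,
         seed = as.integer(seed)),
    class = "fixture_spec"
  )
}

# n random sequences of the given length, uniform over ACGT, built from
# one long byte draw to stay fast and memory-light at millions of reads.
random_seqs <- function(n, len) {
  draws <- sample.int(4L, n * len, replace = TRUE)
  big <- rawToChar(as.raw(c(65L, 67L, 71L, 84L))[draws])
  substring(big, seq.int(1L, by = len, length.out = n),
            seq.int(len, by = len, length.out = n))
}

#' Simulate a paired library in memory
#'
#' Draws `n_clusters` template pairs of i.i.d. uniform ACGT bases,
#' replicates each according to the multiplicity distribution, applies
#' truncation and substitution per copy, shuffles all pairs, and returns
#' the store together with per-pair ground truth.
#'
#' @param spec A [fixture_spec()].
#' @return A list: `store` (a [pair_store()] with constant-'I' qualities
#'   and headers encoding the cluster id), `manifest` (data frame with
#'   `pair_id`, `cluster_id`, `is_truncated`, `is_mutated`), and
#'   `expected_survivor_count` from [oracle_survivor_count()].
#' @export
simulate_pairs <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  set.seed(spec$seed)
  k <- spec$n_clusters
  t1 <- random_seqs(k, spec$read_len_1)
  t2 <- random_seqs(k, spec$read_len_2)
  mults <- suppressWarnings(as.integer(names(spec$multiplicity_dist)))
  mult <- mults[sample.int(length(mults), k, replace = TRUE,
                           prob = spec$multiplicity_dist)]
  cluster_id <- rep.int(seq_len(k), mult)
  n <- length(cluster_id)
  s1 <- t1[cluster_id]
  s2 <- t2[cluster_id]

  trunc1 <- stats::runif(n) < spec$truncation_prob
  trunc2 <- stats::runif(n) < spec$truncation_prob
  if (any(trunc1)) {
    d <- sample.int(spec$max_truncation, sum(trunc1), replace = TRUE)
    s1[trunc1] <- substr(s1[trunc1], 1L, spec$read_len_1 - d)
  }
  if (any(trunc2)) {
    d <- sample.int(spec$max_truncation, sum(trunc2), replace = TRUE)
    s2[trunc2] <- substr(s2[trunc2], 1L, spec$read_len_2 - d)
  }

  mutated <- stats::runif(n) < spec$substitution_prob
  for (i in which(mutated)) {
    mate <- sample.int(2L, 1L)
    sq <- if (mate == 1L) s1[i] else s2[i]
    pos <- sample.int(nchar(sq), 1L)
    old <- substr(sq, pos, pos)
    new <- sample(setdiff(c("A", "C", "G", "T"), old), 1L)
    substr(sq, pos, pos) <- new
    if (mate == 1L) s1[i] <- sq else s2[i] <- sq
  }

  perm <- sample.int(n)
  s1 <- s1[perm]
  s2 <- s2[perm]
  cluster_id <- cluster_id[perm]
  is_truncated <- (trunc1 | trunc2)[perm]
  is_mutated <- mutated[perm]

  pair_id <- seq_len(n) - 1L
  store <- pair_store(
    seq1 = s1, seq2 = s2,
    header1 = sprintf("synthpair%07d cluster=%d/1", pair_id, cluster_id),
    header2 = sprintf("synthpair%07d cluster=%d/2", pair_id, cluster_id),
    ordinal = pair_id
  )
  manifest <- data.frame(
    pair_id = pair_id, cluster_id = cluster_id,
    is_truncated = is_truncated, is_mutated = is_mutated
  )
  list(store = store, manifest = manifest,
       expected_survivor_count = oracle_survivor_count(s1, s2))
}

#' All-pairs survivor oracle
#'
#' Counts the pairs that survive deduplication under a brute-force,
#' scan-independent rule: a pair is removed when some other
#' duplicate-equivalent pair dominates it in both mate lengths, either
#' strictly or — for byte-identical duplicates — from an earlier
#' position. Dominance composes along 5'-prefix chains, so the rule is
#' well-defined without reference to any scan order. When all reads of a
#' mate share one length (no truncation), this reduces to counting
#' distinct (read1, read2) sequence pairs and a fast exact-key path is
#' used; otherwise the count is O(n^2) and intended for small instances.
#'
#' @param seq1,seq2 Character vectors of mate sequences, parallel.
#' @return Integer survivor count.
#' @export
oracle_survivor_count <- function(seq1, seq2) {
  n <- length(seq1)
  stopifnot(length(seq2) == n)
  if (n == 0L) return(0L)
  l1 <- nchar(seq1)
  l2 <- nchar(seq2)
  if (length(unique(l1)) == 1L && length(unique(l2)) == 1L) {
    return(length(unique(paste(seq1, seq2, sep = "+"))))
  }
  removed <- logical(n)
  idx <- seq_len(n)
  for (x in idx) {
    m1 <- pmin(l1, l1[x])
    m2 <- pmin(l2, l2[x])
    # substring(), not substr(): the truncation points vary per pair and
    # substr() would recycle them to the length of the scalar sequence
    equiv <- substring(seq1, 1L, m1) == substring(seq1[x], 1L, m1) &
      substring(seq2, 1L, m2) == substring(seq2[x], 1L, m2)
    dom <- l1 >= l1[x] & l2 >= l2[x]
    strict <- dom & (l1 > l1[x] | l2 > l2[x])
    ident <- equiv & l1 == l1[x] & l2 == l2[x]
    kill <- equiv & dom & (strict | (ident & idx < x))
    kill[x] <- FALSE
    removed[x] <- any(kill)
  }
  sum(!removed)
}

#' Generate a synthetic paired library on disk
#'
#' Writes the simulated library as two mate FASTQ files plus a
#' tab-separated manifest recording the ground truth for every emitted
#' pair. The same spec (including seed) always produces byte-identical
#' files.
#'
#' @param spec A [fixture_spec()].
#' @param out1,out2 Paths for the mate-1 / mate-2 FASTQ files.
#' @param manifest_out Path for the manifest (TSV with a
#'   `# expected_survivor_count=` header comment, then columns `pair_id`,
#'   `cluster_id`, `is_truncated`, `is_mutated`).
#' @return A `fixture_manifest` object: list with `pairs` (the manifest
#'   data frame) and `expected_survivor_count`.
#' @export
generate_library <- function(spec, out1, out2, manifest_out) {
  sim <- simulate_pairs(spec)
  st <- sim$store
  write_fastq(st$header1, st$seq1, st$qual1, out1)
  write_fastq(st$header2, st$seq2, st$qual2, out2)
  con <- file(manifest_out, "wt")
  on.exit(close(con))
  writeLines(sprintf("# expected_survivor_count=%d",
                     sim$expected_survivor_count), con)
  utils::write.table(sim$manifest, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  structure(
    list(pairs = sim$manifest,
         expected_survivor_count = sim$expected_survivor_count),
    class = "fixture_manifest"
  )
}
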