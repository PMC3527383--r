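# Independent brute-force oracles. These re-derive the comparator, sort
# and scan semantics one character at a time, sharing no code with the
# package implementation.

ref_seq_cmp <- function(a, b) {
  ia <- utf8ToInt(a)
  ib <- utf8ToInt(b)
  m <- min(length(ia), length(ib))
  i <- 1L
  while (i <= m) {
    if (ia[i] != ib[i]) {
      return(list(ord = if (ia[i] < ib[i]) -1L else 1L, equiv = FALSE))
    }
    i <- i + 1L
  }
  list(ord = sign(length(ia) - length(ib)), equiv = TRUE)
}

ref_pair_cmp <- function(a1, a2, b1, b2) {
  c1 <- ref_seq_cmp(a1, b1)
  if (!c1$equiv) return(list(ord = c1$ord, cand = FALSE))
  c2 <- ref_seq_cmp(a2, b2)
  if (!c2$equiv) return(list(ord = c2$ord, cand = FALSE))
  list(ord = if (c2$ord != 0L) c2$ord else c1$ord, cand = TRUE)
}

# Naive stable insertion sort under the reference comparator with
# ordinal tie-break; returns the permutation of indices.
ref_insertion_sort <- function(s1, s2, ordinal) {
  out <- integer(0)
  for (i in seq_along(s1)) {
    pos <- length(out) + 1L
    for (j in seq_along(out)) {
      k <- out[j]
      cc <- ref_pair_cmp(s1[i], s2[i], s1[k], s2[k])
      less <- if (cc$ord != 0L) cc$ord < 0L else ordinal[i] < ordinal[k]
      if (less) {
        pos <- j
        break
      }
    }
    out <- append(out, i, after = pos - 1L)
  }
  out
}

# Reference single-pass scan over a sorted list; returns retained indices.
# Emission retracts trailing retained pairs that the emitted pair is a
# candidate of and dominates (same semantics as the package scan, derived
# independently from the character-level comparator above).
ref_scan_retain <- function(s1, s2) {
  n <- length(s1)
  if (n == 0L) return(integer(0))
  keep <- integer(0)
  emit <- function(keep, e) {
    while (length(keep)) {
      t <- keep[length(keep)]
      cc <- ref_pair_cmp(s1[t], s2[t], s1[e], s2[e])
      e_dom <- nchar(s1[e]) >= nchar(s1[t]) && nchar(s2[e]) >= nchar(s2[t])
      if (cc$cand && e_dom) keep <- keep[-length(keep)] else break
    }
    c(keep, e)
  }
  rep_i <- 1L
  for (i in seq.int(2L, length.out = n - 1L)) {
    cc <- ref_pair_cmp(s1[rep_i], s2[rep_i], s1[i], s2[i])
    if (!cc$cand) {
      keep <- emit(keep, rep_i)
      rep_i <- i
      next
    }
    rep_dom <- nchar(s1[rep_i]) >= nchar(s1[i]) &&
      nchar(s2[rep_i]) >= nchar(s2[i])
    nxt_dom <- nchar(s1[i]) >= nchar(s1[rep_i]) &&
      nchar(s2[i]) >= nchar(s2[rep_i])
    if (rep_dom) {
      # drop i
    } else if (nxt_dom) {
      rep_i <- i
    } else {
      keep <- emit(keep, rep_i)
      rep_i <- i
    }
  }
  emit(keep, rep_i)
}

# TRUE iff every dropped pair is duplicate-equivalent to, and dominated
# in both mate lengths by, at least one retained pair.
all_dropped_dominated <- function(s1, s2, kept_idx) {
  dropped <- setdiff(seq_along(s1), kept_idx)
  if (length(dropped) == 0L) return(TRUE)
  k1 <- s1[kept_idx]
  k2 <- s2[kept_idx]
  l1 <- nchar(k1)
  l2 <- nchar(k2)
  all(vapply(dropped, function(x) {
    lx1 <- nchar(s1[x])
    lx2 <- nchar(s2[x])
    m1 <- pmin(l1, lx1)
    m2 <- pmin(l2, lx2)
    equiv <- substring(k1, 1L, m1) == substring(s1[x], 1L, m1) &
      substring(k2, 1L, m2) == substring(s2[x], 1L, m2)
    dom <- l1 >= lx1 & l2 >= lx2
    any(equiv & dom)
  }, logical(1)))
}

# Exact-key deduplication of equal-length pairs on the concatenated
# sequence (the collapser-style oracle): sorted unique keys.
collapser_keys <- function(s1, s2) {
  sort(unique(paste(s1, s2, sep = "+")))
}
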