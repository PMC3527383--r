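#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Byte-level view of one read sequence. CHARSXP payloads are stable for the
// lifetime of the protecting CharacterVector, so raw pointers are safe here.
struct SeqView {
  const char* p;
  int len;
};

// Compare two sequences base by base. Writes -1/0/+1 into `ord` (first
// differing byte decides; if one is a 5'-prefix of the other, the shorter
// sorts first). Returns true iff the two are duplicate-equivalent, i.e.
// identical or prefix-related; `ord` is 0 only for byte-identical inputs.
static inline bool seq_cmp(const SeqView& a, const SeqView& b, int& ord) {
  const int m = a.len < b.len ? a.len : b.len;
  for (int i = 0; i < m; ++i) {
    const unsigned char ca = (unsigned char)a.p[i];
    const unsigned char cb = (unsigned char)b.p[i];
    if (ca != cb) {
      ord = ca < cb ? -1 : 1;
      return false;
    }
  }
  ord = (a.len < b.len) ? -1 : (a.len > b.len ? 1 : 0);
  return true;
}

// Order two read pairs: read1 decides unless the read1s are
// duplicate-equivalent, in which case read2 decides; among fully
// duplicate-equivalent pairs the length rule orders read2 first, then
// read1. Sets `candidate` when both mates are duplicate-equivalent
// (the duplicate-candidate criterion). Returns -1/0/+1; 0 only when both
// sequences are byte-identical.
static inline int pair_cmp(const SeqView& a1, const SeqView& a2,
                           const SeqView& b1, const SeqView& b2,
                           bool& candidate) {
  int o1, o2;
  candidate = false;
  if (!seq_cmp(a1, b1, o1)) return o1;
  if (!seq_cmp(a2, b2, o2)) return o2;
  candidate = true;
  if (o2 != 0) return o2;
  return o1;
}

static void make_views(const CharacterVector& s, std::vector<SeqView>& v) {
  const R_xlen_t n = s.size();
  v.resize((size_t)n);
  for (R_xlen_t i = 0; i < n; ++i) {
    SEXP e = STRING_ELT(s, i);
    v[(size_t)i].p = CHAR(e);
    v[(size_t)i].len = LENGTH(e);
  }
}

// Stable bottom-up merge sort of pair indices under the pair comparator,
// with input ordinal as the final tie-break. A hand-written merge sort is
// used deliberately: the prefix-equivalence comparator is not a strict weak
// ordering (prefix ties are not transitive across branching extensions), so
// std::sort/std::stable_sort contracts do not apply; merge sort is
// well-defined and deterministic for any comparator.
// [[Rcpp::export]]
IntegerVector sort_order_cpp(CharacterVector seq1, CharacterVector seq2,
                             IntegerVector ordinal) {
  const size_t n = (size_t)seq1.size();
  if ((size_t)seq2.size() != n || (size_t)ordinal.size() != n)
    stop("seq1, seq2 and ordinal must have equal length");
  std::vector<SeqView> s1, s2;
  make_views(seq1, s1);
  make_views(seq2, s2);
  const int* ord = INTEGER(ordinal);

  std::vector<int> idx(n), buf(n);
  for (size_t i = 0; i < n; ++i) idx[i] = (int)i;

  auto leq = [&](int a, int b) -> bool {
    bool cand;
    const int c = pair_cmp(s1[a], s2[a], s1[b], s2[b], cand);
    if (c != 0) return c < 0;
    return ord[a] <= ord[b];
  };

  for (size_t w = 1; w < n; w *= 2) {
    for (size_t lo = 0; lo + w < n; lo += 2 * w) {
      const size_t mid = lo + w;
      const size_t hi = std::min(lo + 2 * w, n);
      size_t i = lo, j = mid, k = lo;
      while (i < mid && j < hi)
        buf[k++] = leq(idx[i], idx[j]) ? idx[i++] : idx[j++];
      while (i < mid) buf[k++] = idx[i++];
      while (j < hi) buf[k++] = idx[j++];
      std::copy(buf.begin() + lo, buf.begin() + hi, idx.begin() + lo);
    }
  }

  IntegerVector out((R_xlen_t)n);
  for (size_t i = 0; i < n; ++i) out[(R_xlen_t)i] = idx[i] + 1;
  return out;
}

// Single left-to-right scan over a sorted pair list. Holds one current
// representative; a next pair that is not a duplicate candidate of the
// representative causes the representative to be emitted. Among candidates
// the pair whose mates are both at least as long dominates and survives
// (mutual dominance means byte-identical sequences, in which case the
// earlier, i.e. current, representative survives); with crossed lengths
// both are kept and the later pair becomes the representative.
//
// The retained output is a stack: emitting a pair first retracts trailing
// retained pairs that the emitted pair is a duplicate candidate of and
// dominates. A dominating pair always sorts at or after the dominated one,
// so after a crossed-length (keep-both) event a later, fully dominating
// copy would otherwise leave a dominated duplicate stranded in the output,
// and deduplication would not be idempotent. With one fixed read length
// per mate no crossed lengths exist and retraction never fires.
// Returns 1-based indices of retained pairs, in scan (= sorted) order.
// [[Rcpp::export]]
IntegerVector scan_retain_cpp(CharacterVector seq1, CharacterVector seq2) {
  const size_t n = (size_t)seq1.size();
  if ((size_t)seq2.size() != n)
    stop("seq1 and seq2 must have equal length");
  if (n == 0) return IntegerVector(0);
  std::vector<SeqView> s1, s2;
  make_views(seq1, s1);
  make_views(seq2, s2);

  std::vector<int> keep;
  keep.reserve(n);
  auto emit = [&](int e) {
    while (!keep.empty()) {
      const int t = keep.back();
      bool cand;
      pair_cmp(s1[t], s2[t], s1[e], s2[e], cand);
      const bool e_dom = s1[e].len >= s1[t].len && s2[e].len >= s2[t].len;
      if (cand && e_dom)
        keep.pop_back();
      else
        break;
    }
    keep.push_back(e);
  };

  int rep = 0;
  for (size_t i = 1; i < n; ++i) {
    bool cand;
    pair_cmp(s1[rep], s2[rep], s1[(int)i], s2[(int)i], cand);
    if (!cand) {
      emit(rep);
      rep = (int)i;
      continue;
    }
    const bool rep_dom = s1[rep].len >= s1[i].len && s2[rep].len >= s2[i].len;
    const bool nxt_dom = s1[i].len >= s1[rep].len && s2[i].len >= s2[rep].len;
    if (rep_dom) {
      // next pair dropped; representative unchanged
    } else if (nxt_dom) {
      rep = (int)i;  // representative dropped
    } else {
      emit(rep);  // crossed lengths: keep both
      rep = (int)i;
    }
  }
  emit(rep);

  IntegerVector out((R_xlen_t)keep.size());
  for (size_t i = 0; i < keep.size(); ++i) out[(R_xlen_t)i] = keep[i] + 1;
  return out;
}
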