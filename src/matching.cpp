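#include <Rcpp.h>
#include <cstdint>
#include <cstring>
#include <vector>
using namespace Rcpp;

// Hamming distance between two equal-length raw vectors (bitwise).
// [[Rcpp::export]]
int cpp_hamming_raw(RawVector a, RawVector b) {
  if (a.size() != b.size()) stop("descriptors must have equal bit length");
  int d = 0;
  for (R_xlen_t i = 0; i < a.size(); ++i) {
    unsigned char x = static_cast<unsigned char>(a[i]) ^ static_cast<unsigned char>(b[i]);
    d += __builtin_popcount(x);
  }
  return d;
}

static void to_words(const RawMatrix& m, std::vector<uint64_t>& out, int nwords) {
  int n = m.ncol(), B = m.nrow();
  out.assign(static_cast<size_t>(n) * nwords, 0);
  for (int j = 0; j < n; ++j) {
    std::memcpy(&out[static_cast<size_t>(j) * nwords], &m(0, j), B);
  }
}

// Exhaustive mutual nearest-neighbour matching on packed binary descriptors
// (columns = descriptors, byte count a multiple of 8). A pair (i, j) is kept
// only when j is i's nearest target AND i is j's nearest reference (mutual
// cross-check), which makes the result one-to-one. Ties are broken toward
// the lowest index. Indices returned are 1-based.
// [[Rcpp::export]]
List cpp_bf_match(RawMatrix ref, RawMatrix tgt) {
  if (ref.nrow() != tgt.nrow()) stop("descriptor byte lengths differ");
  if (ref.nrow() % 8 != 0) stop("descriptor storage must be padded to 8 bytes");
  int nr = ref.ncol(), nt = tgt.ncol();
  int nwords = ref.nrow() / 8;
  if (nr == 0 || nt == 0) {
    return List::create(_["ref_index"] = IntegerVector(0),
                        _["tgt_index"] = IntegerVector(0),
                        _["distance"] = IntegerVector(0));
  }
  std::vector<uint64_t> R, T;
  to_words(ref, R, nwords);
  to_words(tgt, T, nwords);
  const int BIG = 1 << 30;
  std::vector<int> fwdDist(nr, BIG), fwdIdx(nr, -1);
  std::vector<int> bwdDist(nt, BIG), bwdIdx(nt, -1);
  for (int i = 0; i < nr; ++i) {
    const uint64_t* ri = &R[static_cast<size_t>(i) * nwords];
    for (int j = 0; j < nt; ++j) {
      const uint64_t* tj = &T[static_cast<size_t>(j) * nwords];
      int d = 0;
      for (int k = 0; k < nwords; ++k) d += __builtin_popcountll(ri[k] ^ tj[k]);
      if (d < fwdDist[i]) { fwdDist[i] = d; fwdIdx[i] = j; }
      if (d < bwdDist[j]) { bwdDist[j] = d; bwdIdx[j] = i; }
    }
  }
  std::vector<int> oi, oj, od;
  for (int i = 0; i < nr; ++i) {
    int j = fwdIdx[i];
    if (j >= 0 && bwdIdx[j] == i) {
      oi.push_back(i + 1);
      oj.push_back(j + 1);
      od.push_back(fwdDist[i]);
    }
  }
  return List::create(_["ref_index"] = wrap(oi), _["tgt_index"] = wrap(oj),
                      _["distance"] = wrap(od));
}
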