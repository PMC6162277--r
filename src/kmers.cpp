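// Canonical k-mer engine.
//
// k-mers (k <= 26) are packed 2 bits/base (A=0, C=1, G=2, T=3) into a
// uint64 and stored canonically (lexicographic min of word and reverse
// complement). 2k <= 52 bits, so every code is exactly representable as an
// R double, which is how codes cross the R/C++ boundary. Windows containing
// any non-ACGT symbol are skipped.

#include <Rcpp.h>
#include <unordered_map>
#include <algorithm>
#include <vector>
#include <cstdint>

using namespace Rcpp;

static const uint32_t COUNT_SAT = 0xFFFFFFFFu; // 32-bit saturating counts

static inline int base2bits(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  default: return -1;
  }
}

static inline char bits2base(int b) {
  static const char tab[4] = {'A', 'C', 'G', 'T'};
  return tab[b & 3];
}

static void check_k(int k) {
  if (k < 1 || k > 26)
    stop("k must be in [1, 26] (codes must fit exactly in a double)");
}

// Scan one C string, calling f(pos, canonical_code, fwd_is_canonical) for
// every valid k-window. pos is 0-based.
template <typename F>
static void scan_windows(const char *s, R_xlen_t n, int k, F f) {
  uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  uint64_t fwd = 0, rc = 0;
  int run = 0;
  int shift = 2 * (k - 1);
  for (R_xlen_t i = 0; i < n; ++i) {
    int b = base2bits(s[i]);
    if (b < 0) { run = 0; fwd = 0; rc = 0; continue; }
    fwd = ((fwd << 2) | (uint64_t)b) & mask;
    rc = (rc >> 2) | ((uint64_t)(3 - b) << shift);
    if (++run >= k) {
      bool fwd_min = fwd <= rc;
      f(i - k + 1, fwd_min ? fwd : rc, fwd_min);
    }
  }
}

// [[Rcpp::export(name = ".cpp_count_kmers")]]
List cpp_count_kmers(CharacterVector seqs, int k) {
  check_k(k);
  std::unordered_map<uint64_t, uint32_t> tab;
  bool saturated = false;
  R_xlen_t windows = 0;
  for (R_xlen_t j = 0; j < seqs.size(); ++j) {
    if (seqs[j] == NA_STRING) continue;
    const char *s = CHAR(seqs[j]);
    R_xlen_t n = LENGTH(seqs[j]);
    scan_windows(s, n, k, [&](R_xlen_t, uint64_t code, bool) {
      ++windows;
      uint32_t &c = tab[code];
      if (c == COUNT_SAT) saturated = true; else ++c;
    });
  }
  std::vector<uint64_t> codes;
  codes.reserve(tab.size());
  for (auto &kv : tab) codes.push_back(kv.first);
  std::sort(codes.begin(), codes.end());
  NumericVector code_out(codes.size());
  NumericVector count_out(codes.size());
  for (size_t i = 0; i < codes.size(); ++i) {
    code_out[i] = (double)codes[i];
    count_out[i] = (double)tab[codes[i]];
  }
  return List::create(_["code"] = code_out, _["count"] = count_out,
                      _["n_windows"] = (double)windows,
                      _["saturated"] = saturated);
}

// Per-position canonical codes over one sequence (NA where the window
// contains a non-ACGT symbol); fwd = TRUE when the forward word is the
// canonical orientation.
// [[Rcpp::export(name = ".cpp_window_codes")]]
List cpp_window_codes(std::string seq, int k) {
  check_k(k);
  R_xlen_t n = (R_xlen_t)seq.size();
  R_xlen_t m = n >= k ? n - k + 1 : 0;
  NumericVector code(m, NA_REAL);
  LogicalVector fwd(m, NA_LOGICAL);
  scan_windows(seq.c_str(), n, k, [&](R_xlen_t pos, uint64_t c, bool fm) {
    code[pos] = (double)c;
    fwd[pos] = fm;
  });
  return List::create(_["code"] = code, _["fwd"] = fwd);
}

// TRUE for each read containing >= 1 query k-mer (canonical, so either
// strand). query must be sorted ascending.
// [[Rcpp::export(name = ".cpp_reads_with_kmers")]]
LogicalVector cpp_reads_with_kmers(CharacterVector reads, NumericVector query,
                                   int k) {
  check_k(k);
  std::vector<uint64_t> q(query.size());
  for (R_xlen_t i = 0; i < query.size(); ++i) q[i] = (uint64_t)query[i];
  LogicalVector out(reads.size());
  for (R_xlen_t j = 0; j < reads.size(); ++j) {
    bool hit = false;
    if (reads[j] != NA_STRING && !q.empty()) {
      const char *s = CHAR(reads[j]);
      R_xlen_t n = LENGTH(reads[j]);
      scan_windows(s, n, k, [&](R_xlen_t, uint64_t code, bool) {
        if (!hit && std::binary_search(q.begin(), q.end(), code)) hit = true;
      });
    }
    out[j] = hit;
  }
  return out;
}

// [[Rcpp::export(name = ".cpp_encode_kmers")]]
NumericVector cpp_encode_kmers(CharacterVector words, bool canonical) {
  NumericVector out(words.size(), NA_REAL);
  for (R_xlen_t j = 0; j < words.size(); ++j) {
    if (words[j] == NA_STRING) continue;
    const char *s = CHAR(words[j]);
    int k = LENGTH(words[j]);
    if (k < 1 || k > 26) stop("word length must be in [1, 26]");
    uint64_t fwd = 0, rc = 0;
    bool ok = true;
    for (int i = 0; i < k; ++i) {
      int b = base2bits(s[i]);
      if (b < 0) { ok = false; break; }
      fwd = (fwd << 2) | (uint64_t)b;
      rc |= ((uint64_t)(3 - b)) << (2 * i);
    }
    if (!ok) continue;
    out[j] = (double)(canonical ? std::min(fwd, rc) : fwd);
  }
  return out;
}

// [[Rcpp::export(name = ".cpp_decode_kmers")]]
CharacterVector cpp_decode_kmers(NumericVector codes, int k) {
  check_k(k);
  CharacterVector out(codes.size());
  std::string buf(k, 'A');
  for (R_xlen_t j = 0; j < codes.size(); ++j) {
    if (NumericVector::is_na(codes[j])) { out[j] = NA_STRING; continue; }
    uint64_t c = (uint64_t)codes[j];
    for (int i = k - 1; i >= 0; --i) { buf[i] = bits2base((int)(c & 3)); c >>= 2; }
    out[j] = buf;
  }
  return out;
}
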