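#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <algorithm>
#include <unordered_map>

using namespace Rcpp;

// Exact inverted-repeat search on a circular sequence.
//
// Strategy: a window of S (circular, length L, start i) is an inverted-repeat
// partner of the window starting at j iff it equals the window of
// T = revcomp(S) starting at p = (n - j - L) mod n. Feasibility of a repeat
// length L is monotone (any repeat of length L contains one of length L-1
// with the same disjointness), so we binary-search L and, at each step, match
// double rolling hashes of all n circular windows of S against those of T,
// verifying candidate pairs character-by-character to rule out collisions.

static const uint64_t MOD1 = 1000000007ULL;
static const uint64_t MOD2 = 998244353ULL;
static const uint64_t B1 = 1315423911ULL % MOD1;
static const uint64_t B2 = 2654435761ULL % MOD2;

static inline uint64_t mulmod(uint64_t a, uint64_t b, uint64_t m) {
  return (uint64_t)((unsigned __int128)a * b % m);
}

struct Hasher {
  std::vector<uint64_t> h1, h2, p1, p2;
  void build(const std::string &s) {
    size_t n = s.size();
    h1.assign(n + 1, 0); h2.assign(n + 1, 0);
    p1.assign(n + 1, 1); p2.assign(n + 1, 1);
    for (size_t i = 0; i < n; ++i) {
      uint64_t c = (uint64_t)(unsigned char)s[i];
      h1[i + 1] = (mulmod(h1[i], B1, MOD1) + c) % MOD1;
      h2[i + 1] = (mulmod(h2[i], B2, MOD2) + c) % MOD2;
      p1[i + 1] = mulmod(p1[i], B1, MOD1);
      p2[i + 1] = mulmod(p2[i], B2, MOD2);
    }
  }
  // hash of s[i, i+L)
  inline std::pair<uint64_t, uint64_t> get(size_t i, size_t L) const {
    uint64_t a = (h1[i + L] + MOD1 - mulmod(h1[i], p1[L], MOD1)) % MOD1;
    uint64_t b = (h2[i + L] + MOD2 - mulmod(h2[i], p2[L], MOD2)) % MOD2;
    return std::make_pair(a, b);
  }
};

static inline char comp_base(char c) {
  switch (c) {
    case 'A': return 'T'; case 'C': return 'G';
    case 'G': return 'C'; case 'T': return 'A';
    default:  return 'X'; // ambiguity never matches anything (incl. itself)
  }
}

// circular window equality: S[i..i+L) (mod n) vs T[p..p+L) (mod n),
// both given as doubled strings
static bool verify(const std::string &sd, const std::string &td,
                   size_t i, size_t p, size_t L) {
  for (size_t k = 0; k < L; ++k)
    if (sd[i + k] != td[p + k] || sd[i + k] == 'X') return false;
  return true;
}

// all verified disjoint pairs (i, j) at length L; pairs canonical i < j
static std::vector<std::pair<long, long> > pairs_at(
    const std::string &sd, const std::string &td,
    const Hasher &hs, const Hasher &ht, long n, long L) {
  std::unordered_map<uint64_t, std::vector<long> > tmap;
  for (long p = 0; p < n; ++p) {
    std::pair<uint64_t, uint64_t> hp = ht.get((size_t)p, (size_t)L);
    tmap[hp.first * 0x9e3779b97f4a7c15ULL + hp.second].push_back(p);
  }
  std::vector<std::pair<long, long> > out;
  for (long i = 0; i < n; ++i) {
    std::pair<uint64_t, uint64_t> hi = hs.get((size_t)i, (size_t)L);
    std::unordered_map<uint64_t, std::vector<long> >::const_iterator it =
        tmap.find(hi.first * 0x9e3779b97f4a7c15ULL + hi.second);
    if (it == tmap.end()) continue;
    for (size_t u = 0; u < it->second.size(); ++u) {
      long p = it->second[u];
      long j = ((n - p - L) % n + n) % n;
      if (j <= i) continue; // canonical order; partner also enumerated from j
      // disjointness on the circle with both gaps non-empty
      long g1 = ((j - (i + L)) % n + n) % n;
      long g2 = ((i - (j + L)) % n + n) % n;
      if (g1 + g2 != n - 2 * L || g1 < 1 || g2 < 1) continue;
      if (!verify(sd, td, (size_t)i, (size_t)p, (size_t)L)) continue;
      out.push_back(std::make_pair(i, j));
    }
  }
  std::sort(out.begin(), out.end());
  out.erase(std::unique(out.begin(), out.end()), out.end());
  return out;
}

// [[Rcpp::export(name = ".ir_scan_cpp")]]
IntegerMatrix ir_scan_cpp(std::string seq, int min_ir) {
  long n = (long)seq.size();
  if (n < 2 * min_ir + 2) return IntegerMatrix(0, 3);
  std::string t(seq.rbegin(), seq.rend());
  for (size_t k = 0; k < t.size(); ++k) t[k] = comp_base(t[k]);
  std::string sd = seq + seq, td = t + t;
  Hasher hs, ht;
  hs.build(sd); ht.build(td);

  long lo = min_ir, hi = (n - 2) / 2, best = -1;
  while (lo <= hi) {
    long mid = lo + (hi - lo) / 2;
    if (!pairs_at(sd, td, hs, ht, n, mid).empty()) { best = mid; lo = mid + 1; }
    else hi = mid - 1;
  }
  if (best < 0) return IntegerMatrix(0, 3);
  std::vector<std::pair<long, long> > pr = pairs_at(sd, td, hs, ht, n, best);
  IntegerMatrix out((int)pr.size(), 3);
  for (size_t r = 0; r < pr.size(); ++r) {
    out(r, 0) = (int)pr[r].first;
    out(r, 1) = (int)pr[r].second;
    out(r, 2) = (int)best;
  }
  return out;
}
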