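#include <Rcpp.h>
#include <cstring>
#include <cstdint>
#include <unordered_map>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// A/C/G/T -> 0..3, anything else (N, other IUPAC, separator) -> -1
static inline int base_code(unsigned char c) {
  switch (c) {
    case 'A': return 0; case 'C': return 1;
    case 'G': return 2; case 'T': return 3;
    default: return -1;
  }
}

// match semantics: equal AND unambiguous; separators / N never match
static inline bool chars_match_c(unsigned char a, unsigned char b) {
  return a == b && base_code(a) >= 0;
}

static inline uint64_t mix64(uint64_t h) {
  h ^= h >> 33; h *= 0xff51afd7ed558ccdULL;
  h ^= h >> 33; h *= 0xc4ceb9fe1a85ec53ULL;
  h ^= h >> 33; return h;
}

// multiply-xorshift over the 2-bit codes; false if any symbol is not A/C/G/T
static inline bool kmer_hash(const char* s, int K, uint64_t& out) {
  uint64_t h = 0x9E3779B97F4A7C15ULL;
  for (int t = 0; t < K; ++t) {
    int c = base_code((unsigned char)s[t]);
    if (c < 0) return false;
    h = (h ^ (uint64_t)(unsigned)c) * 0x2545F4914F6CDD1DULL;
  }
  out = mix64(h);
  return true;
}

static inline uint64_t bucket_of(uint64_t h, int bits) {
  if (bits <= 0) return 0;
  return h >> (64 - bits);
}

// [[Rcpp::export]]
double cpp_hash_kmer(std::string kmer, int bucket_bits) {
  uint64_t h;
  if (!kmer_hash(kmer.c_str(), (int)kmer.size(), h))
    stop("k-mer contains a non-ACGT character");
  return (double)bucket_of(h, bucket_bits);
}

// Build the sampled seed index: positions p = 0, k1, 2*k1, ... with a clean
// K-mer, stored sorted by (bucket id, position). Lookup is an equal-range
// binary search over the bucket-id vector.
// [[Rcpp::export]]
List cpp_build_index(std::string rtext, int k1, int K, int bucket_bits) {
  const char* R = rtext.c_str();
  long long n = (long long)rtext.size();
  std::vector<long long> pos;
  std::vector<uint64_t> bkt;
  for (long long p = 0; p + K <= n; p += k1) {
    uint64_t h;
    if (kmer_hash(R + p, K, h)) {
      pos.push_back(p);
      bkt.push_back(bucket_of(h, bucket_bits));
    }
  }
  size_t m = pos.size();
  std::vector<size_t> ord(m);
  for (size_t i = 0; i < m; ++i) ord[i] = i;
  // stable: positions are generated increasing, so in-bucket order is kept
  std::stable_sort(ord.begin(), ord.end(),
                   [&](size_t a, size_t b) { return bkt[a] < bkt[b]; });
  NumericVector ob(m), op(m);
  for (size_t i = 0; i < m; ++i) {
    ob[i] = (double)bkt[ord[i]];
    op[i] = (double)pos[ord[i]];
  }
  return List::create(_["bucket"] = ob, _["pos"] = op);
}

// [[Rcpp::export]]
NumericVector cpp_lookup(NumericVector bucket, NumericVector pos,
                         std::string kmer, int bucket_bits) {
  uint64_t h;
  if (!kmer_hash(kmer.c_str(), (int)kmer.size(), h))
    return NumericVector(0);
  double b = (double)bucket_of(h, bucket_bits);
  const double* lo = std::lower_bound(bucket.begin(), bucket.end(), b);
  const double* hi = std::upper_bound(lo, (const double*)bucket.end(), b);
  R_xlen_t i0 = lo - bucket.begin(), n = hi - lo;
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) out[i] = pos[i0 + i];
  return out;
}

// maximal extension through the verified seed (i0, j0, K)
// [[Rcpp::export]]
NumericVector cpp_extend(std::string rtext, std::string qtext,
                         double i0, double j0, int K) {
  const char* R = rtext.c_str();
  const char* Q = qtext.c_str();
  long long nR = (long long)rtext.size(), nQ = (long long)qtext.size();
  long long li = (long long)i0, lj = (long long)j0;
  while (li > 0 && lj > 0 && chars_match_c(R[li - 1], Q[lj - 1])) { --li; --lj; }
  long long ri = (long long)i0 + K, rj = (long long)j0 + K;
  while (ri < nR && rj < nQ && chars_match_c(R[ri], Q[rj])) { ++ri; ++rj; }
  return NumericVector::create((double)li, (double)lj, (double)(ri - li));
}

// Scan query positions j in [j_lo, j_hi), j = 0 (mod k2), against the index.
// q_rec_starts: absolute starts of query records; the containment cache is
// cleared whenever the scan enters a new record. Emitted triples may contain
// duplicates (one MEM reached from several seeds); dedup is the collator's.
// [[Rcpp::export]]
List cpp_scan(std::string rtext, std::string qtext,
              NumericVector bucket, NumericVector pos,
              int K, int k2, int L, int bucket_bits,
              NumericVector q_rec_starts,
              double j_lo, double j_hi, bool containment) {
  const char* R = rtext.c_str();
  const char* Q = qtext.c_str();
  long long nR = (long long)rtext.size(), nQ = (long long)qtext.size();
  long long jlo = (long long)j_lo, jhi = (long long)j_hi;
  std::vector<double> out;
  std::unordered_map<long long, std::pair<long long, long long>> cache;
  R_xlen_t nrec = q_rec_starts.size(), rec_i = 0;
  long long n_probed = 0, n_cand = 0, n_verified = 0, n_emitted = 0;
  long long j0 = ((jlo + k2 - 1) / k2) * k2;
  for (long long j = j0; j < jhi && j + K <= nQ; j += k2) {
    while (rec_i < nrec && (long long)q_rec_starts[rec_i] <= j) {
      cache.clear();
      ++rec_i;
    }
    uint64_t h;
    if (!kmer_hash(Q + j, K, h)) continue;
    ++n_probed;
    double b = (double)bucket_of(h, bucket_bits);
    const double* lo = std::lower_bound(bucket.begin(), bucket.end(), b);
    const double* hi = std::upper_bound(lo, (const double*)bucket.end(), b);
    for (const double* it = lo; it != hi; ++it) {
      long long i = (long long)pos[it - bucket.begin()];
      ++n_cand;
      long long d = i - j;
      if (containment) {
        auto c = cache.find(d);
        if (c != cache.end() && c->second.first <= j &&
            j + K <= c->second.second)
          continue;  // seed wholly inside a known MEM on this diagonal
      }
      if (std::memcmp(R + i, Q + j, (size_t)K) != 0) continue;  // collision
      ++n_verified;
      long long li = i, lj = j;
      while (li > 0 && lj > 0 && chars_match_c(R[li - 1], Q[lj - 1])) { --li; --lj; }
      long long ri = i + K, rj = j + K;
      while (ri < nR && rj < nQ && chars_match_c(R[ri], Q[rj])) { ++ri; ++rj; }
      long long len = ri - li;
      if (len >= L) {
        out.push_back((double)li);
        out.push_back((double)lj);
        out.push_back((double)len);
        cache[d] = std::make_pair(lj, lj + len);
        ++n_emitted;
      }
    }
  }
  size_t nt = out.size() / 3;
  NumericMatrix m((int)nt, 3);
  for (size_t i = 0; i < nt; ++i) {
    m(i, 0) = out[3 * i];
    m(i, 1) = out[3 * i + 1];
    m(i, 2) = out[3 * i + 2];
  }
  return List::create(_["triples"] = m,
                      _["n_probed"] = (double)n_probed,
                      _["n_candidates"] = (double)n_cand,
                      _["n_verified"] = (double)n_verified,
                      _["n_emitted"] = (double)n_emitted);
}

// Brute-force oracle: walk every diagonal of the (R, Q) grid and report
// maximal runs of matching characters of length >= L. Exact, duplicate-free.
// [[Rcpp::export]]
NumericMatrix cpp_oracle_mems(std::string rtext, std::string qtext, int L) {
  const char* R = rtext.c_str();
  const char* Q = qtext.c_str();
  long long nR = (long long)rtext.size(), nQ = (long long)qtext.size();
  std::vector<double> out;
  for (long long d = -(nQ - 1); d <= nR - 1; ++d) {
    long long i = d > 0 ? d : 0;
    long long j = i - d;
    long long run = 0, ri = i, rj = j;
    while (ri < nR && rj < nQ) {
      if (chars_match_c(R[ri], Q[rj])) {
        ++run;
      } else {
        if (run >= L) {
          out.push_back((double)(ri - run));
          out.push_back((double)(rj - run));
          out.push_back((double)run);
        }
        run = 0;
      }
      ++ri; ++rj;
    }
    if (run >= L) {
      out.push_back((double)(ri - run));
      out.push_back((double)(rj - run));
      out.push_back((double)run);
    }
  }
  size_t nt = out.size() / 3;
  NumericMatrix m((int)nt, 3);
  for (size_t i = 0; i < nt; ++i) {
    m(i, 0) = out[3 * i];
    m(i, 1) = out[3 * i + 1];
    m(i, 2) = out[3 * i + 2];
  }
  return m;
}

// ---- sorting --------------------------------------------------------------

struct Triple {
  uint64_t q, r;
  double len;
};

static inline bool triple_lt(const Triple& a, const Triple& b) {
  if (a.q != b.q) return a.q < b.q;
  return a.r < b.r;
}

// byte `which` (0 = least significant) of the conceptual 80-bit key
// key = q * 2^40 + r, both coordinates 40 bits wide
static inline unsigned key_byte(const Triple& t, int which) {
  if (which < 5) return (unsigned)((t.r >> (8 * which)) & 0xFF);
  return (unsigned)((t.q >> (8 * (which - 5))) & 0xFF);
}

// LSD radix over the 6 most significant bytes of the 80-bit key (bytes 4..9),
// then a comparison sort inside each equal-prefix run (which only has to
// settle the low 32 bits of r).
static void radix_sort_triples(std::vector<Triple>& v) {
  size_t n = v.size();
  std::vector<Triple> tmp(n);
  for (int byte = 4; byte <= 9; ++byte) {
    size_t cnt[257] = {0};
    for (size_t i = 0; i < n; ++i) cnt[key_byte(v[i], byte) + 1]++;
    for (int b = 0; b < 256; ++b) cnt[b + 1] += cnt[b];
    for (size_t i = 0; i < n; ++i) tmp[cnt[key_byte(v[i], byte)]++] = v[i];
    v.swap(tmp);
  }
  // finish equal-prefix runs
  size_t s = 0;
  while (s < n) {
    size_t e = s + 1;
    uint64_t qs = v[s].q, rhi = v[s].r >> 32;
    while (e < n && v[e].q == qs && (v[e].r >> 32) == rhi) ++e;
    if (e - s > 1) std::sort(v.begin() + s, v.begin() + e, triple_lt);
    s = e;
  }
}

// method: 0 = auto (threshold governs), 1 = comparison, 2 = radix
// [[Rcpp::export]]
NumericMatrix cpp_sort_triples(NumericMatrix m, int threshold, int method) {
  int n = m.nrow();
  std::vector<Triple> v((size_t)n);
  for (int i = 0; i < n; ++i) {
    double r = m(i, 0), q = m(i, 1);
    if (r < 0 || q < 0 || r >= 1099511627776.0 || q >= 1099511627776.0)
      stop("coordinate exceeds the 40-bit key width (max 2^40 - 1)");
    v[i].r = (uint64_t)r;
    v[i].q = (uint64_t)q;
    v[i].len = m(i, 2);
  }
  bool radix = (method == 2) || (method == 0 && n > threshold);
  if (radix)
    radix_sort_triples(v);
  else
    std::sort(v.begin(), v.end(), triple_lt);
  NumericMatrix out(n, 3);
  for (int i = 0; i < n; ++i) {
    out(i, 0) = (double)v[i].r;
    out(i, 1) = (double)v[i].q;
    out(i, 2) = v[i].len;
  }
  return out;
}
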