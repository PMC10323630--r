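#include <Rcpp.h>
#include <cstdint>
#include <unordered_map>
#include <algorithm>
#include <vector>
#include <string>

using namespace Rcpp;

// 2-bit encoding; k-mers up to 31 bp fit one 64-bit word.
static inline int base2bit(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  default: return -1;
  }
}

static inline uint64_t revcomp_bits(uint64_t x, int k) {
  uint64_t r = 0;
  for (int i = 0; i < k; ++i) {
    r = (r << 2) | (3 - (x & 3));
    x >>= 2;
  }
  return r;
}

static std::string decode_bits(uint64_t x, int k) {
  static const char alpha[4] = {'A', 'C', 'G', 'T'};
  std::string s(k, 'A');
  for (int i = k - 1; i >= 0; --i) {
    s[i] = alpha[x & 3];
    x >>= 2;
  }
  return s;
}

// Roll over a sequence, calling f(pos, key) for every valid (N-free) window.
template <typename F>
static void each_kmer(const std::string &seq, int k, F f) {
  const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  uint64_t key = 0;
  int valid = 0;  // length of current run of unambiguous bases
  const int n = (int) seq.size();
  for (int i = 0; i < n; ++i) {
    int b = base2bit(seq[i]);
    if (b < 0) { valid = 0; key = 0; continue; }
    key = ((key << 2) | (uint64_t) b) & mask;
    if (++valid >= k) f(i - k + 1, key);
  }
}

// [[Rcpp::export]]
List count_kmers_cpp(CharacterVector seqs, int k, bool canonical, int min_count) {
  if (k < 1 || k > 31) stop("k must be between 1 and 31");
  const int ncol = seqs.size();
  std::unordered_map<uint64_t, int> row_of;
  std::vector<int> counts;  // row-major, nrow x ncol
  row_of.reserve(1 << 20);

  for (int j = 0; j < ncol; ++j) {
    std::string s = as<std::string>(seqs[j]);
    each_kmer(s, k, [&](int, uint64_t key) {
      if (canonical) {
        uint64_t rc = revcomp_bits(key, k);
        if (rc < key) key = rc;
      }
      auto it = row_of.find(key);
      int r;
      if (it == row_of.end()) {
        r = (int) row_of.size();
        row_of.emplace(key, r);
        counts.resize(counts.size() + ncol, 0);
      } else r = it->second;
      counts[(size_t) r * ncol + j] += 1;
    });
  }

  // keep rows whose minimum across chromosomes >= min_count
  std::vector<uint64_t> keys;
  keys.reserve(row_of.size());
  for (auto &kv : row_of) {
    const int r = kv.second;
    int mn = counts[(size_t) r * ncol];
    for (int j = 1; j < ncol; ++j)
      mn = std::min(mn, counts[(size_t) r * ncol + j]);
    if (mn >= min_count) keys.push_back(kv.first);
  }
  std::sort(keys.begin(), keys.end());  // lexicographic (A<C<G<T) row order

  const int nrow = (int) keys.size();
  IntegerMatrix m(nrow, ncol);
  CharacterVector rn(nrow);
  for (int i = 0; i < nrow; ++i) {
    const int r = row_of[keys[i]];
    for (int j = 0; j < ncol; ++j)
      m(i, j) = counts[(size_t) r * ncol + j];
    rn[i] = decode_bits(keys[i], k);
  }
  m.attr("dimnames") = List::create(rn, seqs.attr("names"));
  return List::create(_["counts"] = m);
}

// Start positions (0-based) of windows whose (optionally canonical) k-mer
// belongs to the query set. All query k-mers must share one length.
// [[Rcpp::export]]
IntegerVector kmer_positions_cpp(std::string seq, CharacterVector kmers,
                                 bool canonical) {
  if (kmers.size() == 0) return IntegerVector(0);
  const int k = (int) std::string(kmers[0]).size();
  if (k < 1 || k > 31) stop("k must be between 1 and 31");
  std::unordered_map<uint64_t, char> want;
  for (int i = 0; i < kmers.size(); ++i) {
    std::string s = as<std::string>(kmers[i]);
    if ((int) s.size() != k) stop("all k-mers must have the same length");
    uint64_t key = 0;
    for (char c : s) {
      int b = base2bit(c);
      if (b < 0) stop("k-mer contains a non-ACGT base");
      key = (key << 2) | (uint64_t) b;
    }
    want[key] = 1;
    if (canonical) want[revcomp_bits(key, k)] = 1;
  }
  std::vector<int> hits;
  each_kmer(seq, k, [&](int pos, uint64_t key) {
    if (want.count(key)) hits.push_back(pos);
  });
  return wrap(hits);
}

static bool encode_prefix(const std::string &s, int len, uint64_t &key) {
  key = 0;
  for (int i = 0; i < len; ++i) {
    int b = base2bit(s[i]);
    if (b < 0) return false;
    key = (key << 2) | (uint64_t) b;
  }
  return true;
}

static std::string revcomp_str(const std::string &s) {
  std::string r(s.rbegin(), s.rend());
  for (char &c : r) {
    switch (c) {
    case 'A': case 'a': c = 'T'; break;
    case 'C': case 'c': c = 'G'; break;
    case 'G': case 'g': c = 'C'; break;
    case 'T': case 't': c = 'A'; break;
    default: c = 'N';
    }
  }
  return r;
}

// [[Rcpp::export]]
CharacterVector revcomp_cpp(CharacterVector x) {
  CharacterVector out(x.size());
  for (int i = 0; i < x.size(); ++i)
    out[i] = revcomp_str(as<std::string>(x[i]));
  out.attr("names") = x.attr("names");
  return out;
}

// Exact-match placement of error-free reads with fractional multi-mapping.
// Seeds on the first min(read length, 31) bases, verifies full matches, and
// adds 1/n_hits depth per covered site. Both strands are searched.
// [[Rcpp::export]]
List map_reads_cpp(CharacterVector chrom_seqs, CharacterVector reads) {
  const int nc = chrom_seqs.size();
  std::vector<std::string> chroms(nc);
  for (int j = 0; j < nc; ++j) chroms[j] = as<std::string>(chrom_seqs[j]);

  int min_read = INT32_MAX;
  std::vector<std::string> rd(reads.size());
  for (int i = 0; i < reads.size(); ++i) {
    rd[i] = as<std::string>(reads[i]);
    min_read = std::min(min_read, (int) rd[i].size());
  }
  if (reads.size() == 0) stop("no reads supplied");
  const int slen = std::min(min_read, 31);
  if (slen < 1) stop("reads must be non-empty");

  // (seed key, chrom<<40|pos) pairs over every valid genome position
  std::vector<std::pair<uint64_t, uint64_t>> idx;
  for (int j = 0; j < nc; ++j)
    each_kmer(chroms[j], slen, [&](int pos, uint64_t key) {
      idx.emplace_back(key, ((uint64_t) j << 40) | (uint64_t) pos);
    });
  std::sort(idx.begin(), idx.end());

  List depth(nc);
  std::vector<NumericVector> dep(nc);
  for (int j = 0; j < nc; ++j) dep[j] = NumericVector(chroms[j].size());

  IntegerVector nhits(reads.size());
  int unmapped = 0;

  std::vector<std::pair<int, int>> matches;  // (chrom, pos)
  for (int i = 0; i < (int) rd.size(); ++i) {
    matches.clear();
    const std::string &fwd = rd[i];
    const std::string rev = revcomp_str(fwd);
    for (int strand = 0; strand < 2; ++strand) {
      const std::string &q = strand == 0 ? fwd : rev;
      uint64_t key;
      if (!encode_prefix(q, slen, key)) continue;
      auto lo = std::lower_bound(idx.begin(), idx.end(),
                                 std::make_pair(key, (uint64_t) 0));
      for (auto it = lo; it != idx.end() && it->first == key; ++it) {
        const int j = (int) (it->second >> 40);
        const int pos = (int) (it->second & ((1ULL << 40) - 1));
        if (pos + q.size() > chroms[j].size()) continue;
        if (chroms[j].compare(pos, q.size(), q) == 0)
          matches.emplace_back(j, pos);
      }
      if (rev == fwd) break;  // palindromic read: avoid double-counting
    }
    nhits[i] = (int) matches.size();
    if (matches.empty()) { ++unmapped; continue; }
    const double w = 1.0 / matches.size();
    for (auto &m : matches) {
      NumericVector &d = dep[m.first];
      const int end = m.second + (int) rd[i].size();
      for (int p = m.second; p < end; ++p) d[p] += w;
    }
  }
  for (int j = 0; j < nc; ++j) depth[j] = dep[j];
  depth.attr("names") = chrom_seqs.attr("names");
  return List::create(_["depth"] = depth, _["n_unmapped"] = unmapped,
                      _["n_hits"] = nhits);
}
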