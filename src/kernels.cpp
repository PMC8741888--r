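#include <Rcpp.h>
#include <cstdint>
using namespace Rcpp;

// Unit-cost Levenshtein distance, two-row DP.
static int lev_dist(const std::string& a, const std::string& b) {
  const int n = a.size(), m = b.size();
  if (n == 0) return m;
  if (m == 0) return n;
  std::vector<int> prev(m + 1), cur(m + 1);
  for (int j = 0; j <= m; ++j) prev[j] = j;
  for (int i = 1; i <= n; ++i) {
    cur[0] = i;
    const char ai = a[i - 1];
    for (int j = 1; j <= m; ++j) {
      int sub = prev[j - 1] + (ai == b[j - 1] ? 0 : 1);
      int del = prev[j] + 1;
      int ins = cur[j - 1] + 1;
      cur[j] = sub < del ? (sub < ins ? sub : ins) : (del < ins ? del : ins);
    }
    std::swap(prev, cur);
  }
  return prev[m];
}

// [[Rcpp::export]]
int cpp_levenshtein(std::string a, std::string b) { return lev_dist(a, b); }

// Alignment identity: 1 - (edit distance / shorter length), floored at 0.
// [[Rcpp::export]]
double cpp_identity(std::string a, std::string b) {
  if (a.empty() || b.empty()) stop("identity of an empty sequence is undefined");
  int s = std::min(a.size(), b.size());
  double id = 1.0 - (double) lev_dist(a, b) / (double) s;
  return id > 0.0 ? id : 0.0;
}

static inline int base_code(char c) {
  switch (c) {
    case 'A': return 0; case 'C': return 1; case 'G': return 2; case 'T': return 3;
    default: return -1;
  }
}

// Sorted 2-bit-encoded k-gram multiset of s; ok set to false when s contains
// a non-ACGT base (the caller must then skip the word filter for this string).
static void kgrams(const std::string& s, int k, std::vector<uint32_t>& out, bool& ok) {
  out.clear(); ok = true;
  const int n = s.size();
  if (n < k) return;
  for (int i = 0; i + k <= n; ++i) {
    uint32_t code = 0;
    for (int j = 0; j < k; ++j) {
      int b = base_code(s[i + j]);
      if (b < 0) { ok = false; out.clear(); return; }
      code = (code << 2) | (uint32_t) b;
    }
    out.push_back(code);
  }
  std::sort(out.begin(), out.end());
}

static int multiset_shared(const std::vector<uint32_t>& a, const std::vector<uint32_t>& b) {
  size_t i = 0, j = 0; int g = 0;
  while (i < a.size() && j < b.size()) {
    if (a[i] == b[j]) { ++g; ++i; ++j; }
    else if (a[i] < b[j]) ++i;
    else ++j;
  }
  return g;
}

// Safe prefilter: a pair can be skipped only when a provable lower bound on
// the edit distance already rules the identity threshold out.  Two bounds:
// the length difference, and the q-gram (Ukkonen) bound - one edit destroys
// at most k of the shorter string's (S - k + 1) k-grams, so with G shared
// grams the distance is at least ceil((S - k + 1 - G) / k).
static bool word_filter_rejects(const std::vector<uint32_t>& ga, bool oka, int na,
                                const std::vector<uint32_t>& gb, bool okb, int nb,
                                int k, double threshold) {
  int S = std::min(na, nb), L = std::max(na, nb);
  double dmax = (1.0 - threshold) * (double) S + 1e-9;
  if ((double) (L - S) > dmax) return true;
  if (!oka || !okb) return false;
  if (S < k) return false;
  int G = multiset_shared(ga, gb);
  int need = S - k + 1 - G;
  if (need <= 0) return false;
  double dmin = std::ceil((double) need / (double) k);
  return dmin > dmax;
}

// Greedy incremental clustering: inputs must already be in processing order
// (length descending, ties by input order).  Each signature joins the first
// existing cluster seed (in seed-creation order) with identity >= threshold,
// else founds a new cluster.  Returns 1-based cluster ids per input element.
// [[Rcpp::export]]
IntegerVector cpp_greedy_cluster(CharacterVector sigs, double threshold,
                                 int word_size, bool use_word_filter) {
  const int n = sigs.size();
  IntegerVector cl(n);
  std::vector<std::string> seeds;
  std::vector<std::vector<uint32_t>> seed_grams;
  std::vector<bool> seed_ok;
  for (int i = 0; i < n; ++i) {
    std::string s = as<std::string>(sigs[i]);
    if (s.empty()) stop("empty flank signature cannot be clustered");
    std::vector<uint32_t> g; bool ok = true;
    if (use_word_filter) kgrams(s, word_size, g, ok);
    int assigned = -1;
    for (size_t c = 0; c < seeds.size(); ++c) {
      if (use_word_filter &&
          word_filter_rejects(g, ok, s.size(), seed_grams[c], seed_ok[c],
                              seeds[c].size(), word_size, threshold))
        continue;
      int S = std::min(s.size(), seeds[c].size());
      int d = s == seeds[c] ? 0 : lev_dist(s, seeds[c]);
      double id = 1.0 - (double) d / (double) S;
      if (id >= threshold - 1e-12) { assigned = (int) c; break; }
    }
    if (assigned < 0) {
      seeds.push_back(s);
      if (use_word_filter) { seed_grams.push_back(g); seed_ok.push_back(ok); }
      else { seed_grams.push_back(std::vector<uint32_t>()); seed_ok.push_back(true); }
      assigned = (int) seeds.size() - 1;
    }
    cl[i] = assigned + 1;
  }
  return cl;
}

// Overlap scan for read-pair merging.  s2rc/q2rev are the mate already
// reverse-complemented (qualities reversed).  Considers every overlap length
// L in [min_overlap, min(n1, n2)], scores mismatch density m/L, keeps the
// minimum (ties broken towards the larger overlap), and accepts when the
// best density is <= max_density.  Consensus: agreeing positions keep the
// base with the larger of the two qualities; disagreements take the
// higher-quality base and the absolute quality difference.
// [[Rcpp::export]]
List cpp_merge_pair(std::string s1, std::string q1, std::string s2rc,
                    std::string q2rev, int min_overlap, double max_density) {
  const int n1 = s1.size(), n2 = s2rc.size();
  const int maxL = std::min(n1, n2);
  int bestL = -1, bestM = 0;
  double bestD = R_PosInf;
  for (int L = min_overlap; L <= maxL; ++L) {
    int m = 0;
    const int off = n1 - L;
    for (int i = 0; i < L; ++i) if (s1[off + i] != s2rc[i]) ++m;
    double d = (double) m / (double) L;
    if (d < bestD - 1e-12 || (d < bestD + 1e-12 && L > bestL)) {
      bestD = d; bestL = L; bestM = m;
    }
  }
  if (bestL < 0 || bestD > max_density + 1e-12)
    return List::create(_["merged"] = false);
  const int off = n1 - bestL;
  std::string seq = s1.substr(0, off);
  std::string qual = q1.substr(0, off);
  for (int i = 0; i < bestL; ++i) {
    char b1 = s1[off + i], b2 = s2rc[i];
    char c1 = q1[off + i], c2 = q2rev[i];
    if (b1 == b2) {
      seq.push_back(b1);
      qual.push_back(c1 >= c2 ? c1 : c2);
    } else {
      seq.push_back(c2 > c1 ? b2 : b1);
      int d = c1 >= c2 ? c1 - c2 : c2 - c1;
      qual.push_back((char) (33 + d));
    }
  }
  seq += s2rc.substr(bestL);
  qual += q2rev.substr(bestL);
  return List::create(_["merged"] = true, _["seq"] = seq, _["qual"] = qual,
                      _["overlap"] = bestL, _["mismatches"] = bestM,
                      _["density"] = bestD);
}

// 3' adapter search: substitution-only semi-global match of the adapter
// prefix at every start position p; the matched length is clipped at the
// read end.  Returns the leftmost 0-based position whose error rate is
// within max_error_rate (and whose matched length reaches min_overlap), or
// the read length when no acceptable match exists.
// [[Rcpp::export]]
int cpp_adapter_cut(std::string seq, std::string adapter,
                    double max_error_rate, int min_overlap) {
  const int n = seq.size(), alen = adapter.size();
  for (int p = 0; p < n; ++p) {
    int mlen = std::min(alen, n - p);
    if (mlen < min_overlap) break;
    int mism = 0;
    for (int i = 0; i < mlen; ++i) if (seq[p + i] != adapter[i]) ++mism;
    if ((double) mism <= max_error_rate * (double) mlen + 1e-12) return p;
  }
  return n;
}
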