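#include <Rcpp.h>
#include <unordered_map>
using namespace Rcpp;

// Nucleotide codes: A=0, C=1, G=2, T=3, anything else (N) = 4.

// [[Rcpp::export]]
List cpp_encode_dna(CharacterVector seqs) {
  int n = seqs.size();
  List out(n);
  for (int i = 0; i < n; ++i) {
    const char *s = CHAR(STRING_ELT(seqs, i));
    int len = LENGTH(STRING_ELT(seqs, i));
    IntegerVector v(len);
    for (int j = 0; j < len; ++j) {
      switch (s[j]) {
        case 'A': case 'a': v[j] = 0; break;
        case 'C': case 'c': v[j] = 1; break;
        case 'G': case 'g': v[j] = 2; break;
        case 'T': case 't': v[j] = 3; break;
        default: v[j] = 4;
      }
    }
    out[i] = v;
  }
  return out;
}

// Scan encoded sequences with a 5 x L contribution matrix (rows A,C,G,T,N).
// Raw window score = sum_j w[code[j], j]; normalised to
// (raw - minsum) / (maxsum - minsum). Windows with normalised score >=
// threshold are reported (0-based start).
// [[Rcpp::export]]
List cpp_scan_pwm(List encoded, NumericMatrix w, double minsum, double maxsum,
                  double threshold) {
  int L = w.ncol();
  double span = maxsum - minsum;
  if (span <= 0) span = 1.0;
  std::vector<int> r_seq, r_start;
  std::vector<double> r_score;
  int nseq = encoded.size();
  for (int i = 0; i < nseq; ++i) {
    IntegerVector v = encoded[i];
    int len = v.size();
    if (len < L) continue;
    const int *p = INTEGER(v);
    for (int s = 0; s <= len - L; ++s) {
      double raw = 0.0;
      for (int j = 0; j < L; ++j) raw += w(p[s + j], j);
      double sc = (raw - minsum) / span;
      if (sc >= threshold) {
        r_seq.push_back(i + 1);
        r_start.push_back(s);
        r_score.push_back(sc);
      }
    }
  }
  return List::create(_["seq"] = wrap(r_seq), _["start"] = wrap(r_start),
                      _["score"] = wrap(r_score));
}

// Minimum non-negative edge-to-edge gap per (gene, unordered PWM pair).
// Hits must be grouped by gene (gene codes ascending). Overlapping site
// pairs (negative gap) do not count. Homotypic pairs need two distinct hits.
// [[Rcpp::export]]
List cpp_pair_min_gaps(IntegerVector gene, IntegerVector pwm,
                       IntegerVector start, IntegerVector end,
                       int max_gap) {
  int n = gene.size();
  std::vector<int> o_gene, o_p1, o_p2, o_gap;
  std::unordered_map<long long, int> best;
  int i = 0;
  while (i < n) {
    int g = gene[i];
    int j = i;
    while (j < n && gene[j] == g) ++j;
    best.clear();
    for (int a = i; a < j; ++a) {
      for (int b = a + 1; b < j; ++b) {
        int gap = start[b] - end[a];
        int gap2 = start[a] - end[b];
        if (gap2 > gap) gap = gap2;
        if (gap < 0 || gap > max_gap) continue;
        int p1 = pwm[a], p2 = pwm[b];
        if (p1 > p2) std::swap(p1, p2);
        long long key = (long long)p1 * 1000000LL + p2;
        auto it = best.find(key);
        if (it == best.end() || gap < it->second) best[key] = gap;
      }
    }
    for (auto &kv : best) {
      o_gene.push_back(g);
      o_p1.push_back((int)(kv.first / 1000000LL));
      o_p2.push_back((int)(kv.first % 1000000LL));
      o_gap.push_back(kv.second);
    }
    i = j;
  }
  return List::create(_["gene"] = wrap(o_gene), _["pwm1"] = wrap(o_p1),
                      _["pwm2"] = wrap(o_p2), _["min_gap"] = wrap(o_gap));
}

static inline uint32_t xorshift32(uint32_t &s) {
  s ^= s << 13; s ^= s >> 17; s ^= s << 5;
  return s;
}

// Count sampled permutations of y whose Pearson r with x is >= r_obs - tol.
// Self-contained RNG so results depend only on (x, y, n_perm, seed).
// [[Rcpp::export]]
int cpp_perm_corr_count(NumericVector x, NumericVector y, int n_perm,
                        double r_obs, unsigned int seed) {
  int n = x.size();
  double mx = mean(x), my = mean(y);
  std::vector<double> xs(n), ys(n);
  double sx = 0, sy = 0;
  for (int i = 0; i < n; ++i) {
    xs[i] = x[i] - mx; ys[i] = y[i] - my;
    sx += xs[i] * xs[i]; sy += ys[i] * ys[i];
  }
  double denom = std::sqrt(sx * sy);
  uint32_t st = seed == 0 ? 0x9E3779B9u : seed;
  const double tol = 1e-9;
  int count = 0;
  std::vector<int> idx(n);
  for (int k = 0; k < n_perm; ++k) {
    for (int i = 0; i < n; ++i) idx[i] = i;
    for (int i = n - 1; i > 0; --i) {
      int j = (int)(xorshift32(st) % (uint32_t)(i + 1));
      std::swap(idx[i], idx[j]);
    }
    double dot = 0;
    for (int i = 0; i < n; ++i) dot += xs[i] * ys[idx[i]];
    double r = dot / denom;
    if (r >= r_obs - tol) ++count;
  }
  return count;
}
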