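#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <unordered_set>
#include <string>
using namespace Rcpp;

// Needleman-Wunsch global alignment with linear gap penalty and full
// traceback. Tie preference diagonal > up > left keeps output
// deterministic. A positive band restricts |i - j - (n - m)/2| style
// offsets to a diagonal corridor (safe for near-collinear sequences and
// much faster); band <= 0 runs the full matrix. Statistics reported:
//   columns       total alignment columns
//   matches       columns with equal bases
//   mismatches    columns with unequal bases (both non-gap)
//   identity      matches / columns
//   coverage_x/y  fraction of each sequence lying between the first and
//                 last column where both sequences have a base (i.e. not
//                 in a terminal overhang)
//   p             mismatches / (matches + mismatches), gap columns excluded
struct AlnStats {
  double score;
  int columns, matches, mismatches;
  double coverage_x, coverage_y;
};

static const double NEG_INF = -1e30;

static AlnStats nw_stats(const std::string& x, const std::string& y,
                         double match, double mismatch, double gap,
                         int band = 0) {
  const int n = (int)x.size(), m = (int)y.size();
  // traceback codes: 0 diag, 1 up (gap in y), 2 left (gap in x)
  std::vector<uint8_t> T((size_t)(n + 1) * (m + 1), 0);
  std::vector<double> prev(m + 1), cur(m + 1);

  // the band is widened by the length difference so the corner stays
  // reachable
  int half = band > 0 ? band + std::abs(n - m) : 0;
  auto jlo = [&](int i) {
    return band > 0 ? std::max(1, i - half) : 1;
  };
  auto jhi = [&](int i) {
    return band > 0 ? std::min(m, i + half) : m;
  };

  prev[0] = 0.0;
  for (int j = 1; j <= m; ++j) {
    prev[j] = (band > 0 && j > half) ? NEG_INF : j * gap;
    T[j] = 2;
  }
  for (int i = 1; i <= n; ++i) {
    uint8_t* Ti = &T[(size_t)i * (m + 1)];
    const char xi = x[i - 1];
    int lo = jlo(i), hi = jhi(i);
    cur[0] = (band > 0 && i > half) ? NEG_INF : i * gap;
    Ti[0] = 1;
    for (int j = 1; j < lo; ++j) cur[j] = NEG_INF;
    for (int j = hi + 1; j <= m; ++j) cur[j] = NEG_INF;
    for (int j = lo; j <= hi; ++j) {
      double d = prev[j - 1] + (xi == y[j - 1] ? match : mismatch);
      double u = prev[j] + gap;
      double l = cur[j - 1] + gap;
      double best = d; uint8_t t = 0;
      if (u > best) { best = u; t = 1; }
      if (l > best) { best = l; t = 2; }
      cur[j] = best; Ti[j] = t;
    }
    std::swap(prev, cur);
  }

  AlnStats st;
  st.score = prev[m];
  st.matches = 0; st.mismatches = 0;

  // Traceback from (n, m); collect columns in reverse.
  std::vector<uint8_t> ops;
  ops.reserve(n + m);
  int i = n, j = m;
  while (i > 0 || j > 0) {
    uint8_t t;
    if (i == 0) t = 2;
    else if (j == 0) t = 1;
    else t = T[(size_t)i * (m + 1) + j];
    ops.push_back(t);
    if (t == 0) { --i; --j; }
    else if (t == 1) { --i; }
    else { --j; }
  }
  std::reverse(ops.begin(), ops.end());
  st.columns = (int)ops.size();

  int first_both = -1, last_both = -1;
  {
    int xi2 = 0, yi2 = 0, col = 0;
    for (uint8_t t : ops) {
      if (t == 0) {
        if (x[xi2] == y[yi2]) ++st.matches; else ++st.mismatches;
        if (first_both < 0) first_both = col;
        last_both = col;
        ++xi2; ++yi2;
      } else if (t == 1) ++xi2;
      else ++yi2;
      ++col;
    }
  }

  if (first_both < 0) {
    st.coverage_x = 0.0; st.coverage_y = 0.0;
    return st;
  }
  int x_in = 0, y_in = 0;
  {
    int col = 0;
    for (uint8_t t : ops) {
      bool inside = col >= first_both && col <= last_both;
      if (t == 0) { if (inside) { ++x_in; ++y_in; } }
      else if (t == 1) { if (inside) ++x_in; }
      else { if (inside) ++y_in; }
      ++col;
    }
  }
  st.coverage_x = n > 0 ? (double)x_in / n : 0.0;
  st.coverage_y = m > 0 ? (double)y_in / m : 0.0;
  return st;
}

// [[Rcpp::export(name = ".nw_align_cpp")]]
List nw_align_cpp(std::string x, std::string y, double match,
                  double mismatch, double gap, int band) {
  if (x.empty() || y.empty()) stop("sequences must be non-empty");
  if ((double)x.size() * (double)y.size() > 4e8)
    stop("sequences too long for dense global alignment");
  AlnStats st = nw_stats(x, y, match, mismatch, gap, band);
  int sites = st.matches + st.mismatches;
  return List::create(
    _["score"] = st.score,
    _["columns"] = st.columns,
    _["matches"] = st.matches,
    _["mismatches"] = st.mismatches,
    _["identity"] = st.columns > 0 ? (double)st.matches / st.columns : 0.0,
    _["coverage_x"] = st.coverage_x,
    _["coverage_y"] = st.coverage_y,
    _["p"] = sites > 0 ? (double)st.mismatches / sites : NA_REAL,
    _["sites"] = sites);
}

// All-versus-all alignment edge enumeration with a shared-seed prefilter:
// a pair is aligned only when the two sequences share at least one
// seed_k-mer (analogous to seeded search; random unrelated sequences of a
// few hundred bp almost never share an 11-mer). The alignment runs in a
// diagonal band, adequate for the near-collinear terminal-repeat pairs a
// clustering edge can come from. Edges returned are those passing the
// identity and mutual-coverage thresholds.
// [[Rcpp::export(name = ".align_edges_cpp")]]
DataFrame align_edges_cpp(CharacterVector seqs, double min_identity,
                          double min_coverage, double match, double mismatch,
                          double gap, int seed_k, int band) {
  const int n = seqs.size();
  std::vector<std::string> sq(n);
  for (int i = 0; i < n; ++i) sq[i] = as<std::string>(seqs[i]);

  std::vector<std::unordered_set<uint64_t>> seeds(n);
  if (seed_k > 0 && seed_k <= 31) {
    const uint64_t mask = (1ULL << (2 * seed_k)) - 1;
    for (int i = 0; i < n; ++i) {
      uint64_t code = 0; int valid = 0;
      for (char ch : sq[i]) {
        int c;
        switch (ch) {
        case 'A': c = 0; break; case 'C': c = 1; break;
        case 'G': c = 2; break; case 'T': c = 3; break;
        default: c = -1;
        }
        if (c < 0) { valid = 0; code = 0; continue; }
        code = ((code << 2) | (uint64_t)c) & mask;
        if (++valid >= seed_k) seeds[i].insert(code);
      }
    }
  }

  std::vector<int> ei, ej;
  std::vector<double> ident, covx, covy;
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      if (seed_k > 0) {
        const auto& a = seeds[i].size() <= seeds[j].size() ? seeds[i] : seeds[j];
        const auto& b = seeds[i].size() <= seeds[j].size() ? seeds[j] : seeds[i];
        bool shared = false;
        for (uint64_t s : a) if (b.count(s)) { shared = true; break; }
        if (!shared) continue;
      }
      AlnStats st = nw_stats(sq[i], sq[j], match, mismatch, gap, band);
      double id = st.columns > 0 ? (double)st.matches / st.columns : 0.0;
      if (id >= min_identity && st.coverage_x >= min_coverage &&
          st.coverage_y >= min_coverage) {
        ei.push_back(i + 1); ej.push_back(j + 1);
        ident.push_back(id); covx.push_back(st.coverage_x);
        covy.push_back(st.coverage_y);
      }
    }
    Rcpp::checkUserInterrupt();
  }
  return DataFrame::create(_["i"] = ei, _["j"] = ej, _["identity"] = ident,
                           _["coverage_i"] = covx, _["coverage_j"] = covy);
}
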