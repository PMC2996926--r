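#include <Rcpp.h>
#include <algorithm>
using namespace Rcpp;

// Channel of a composite HICF band value (span <= 0 means single-channel).
static inline int channel_of(int v, int span) {
  return span > 0 ? (v - 1) / span : 0;
}

static inline bool band_match(int a, int b, int tol, int span) {
  if (std::abs(a - b) > tol) return false;
  if (span > 0 && channel_of(a, span) != channel_of(b, span)) return false;
  return true;
}

// Greedy two-pointer matching of two sorted band lists. For the
// |a-b| <= tol threshold criterion on sorted sequences this attains the
// maximum bipartite matching; ties always take the earliest partner.
static int match_count_core(const int* a, int na, const int* b, int nb,
                            int tol, int span) {
  int i = 0, j = 0, m = 0;
  while (i < na && j < nb) {
    if (band_match(a[i], b[j], tol, span)) {
      ++m; ++i; ++j;
    } else if (a[i] < b[j]) {
      ++i;
    } else {
      ++j;
    }
  }
  return m;
}

// [[Rcpp::export]]
int cpp_match_count(IntegerVector a, IntegerVector b, int tol, int span = 0) {
  return match_count_core(a.begin(), a.size(), b.begin(), b.size(), tol, span);
}

// Matched index pairs (1-based) of the greedy maximum matching.
// [[Rcpp::export]]
IntegerMatrix cpp_match_pairs(IntegerVector a, IntegerVector b, int tol,
                              int span = 0) {
  int na = a.size(), nb = b.size();
  std::vector<int> ia, ib;
  int i = 0, j = 0;
  while (i < na && j < nb) {
    if (band_match(a[i], b[j], tol, span)) {
      ia.push_back(i + 1); ib.push_back(j + 1); ++i; ++j;
    } else if (a[i] < b[j]) {
      ++i;
    } else {
      ++j;
    }
  }
  IntegerMatrix out(ia.size(), 2);
  for (size_t k = 0; k < ia.size(); ++k) { out(k, 0) = ia[k]; out(k, 1) = ib[k]; }
  return out;
}

// All-pairs match counts over a list of sorted band vectors; pairs with
// fewer than m_min matches are dropped. Indices are 1-based into the list.
// [[Rcpp::export]]
DataFrame cpp_all_pairs(List bands, int tol, int span, int m_min) {
  int n = bands.size();
  std::vector<IntegerVector> bv(n);
  for (int i = 0; i < n; ++i) bv[i] = as<IntegerVector>(bands[i]);
  std::vector<int> ri, rj, rm;
  for (int i = 0; i < n; ++i) {
    const IntegerVector& a = bv[i];
    int na = a.size();
    if (na == 0) continue;
    for (int j = i + 1; j < n; ++j) {
      const IntegerVector& b = bv[j];
      int nb = b.size();
      if (nb == 0) continue;
      // quick reject: band ranges further apart than the tolerance
      if (a[na - 1] + tol < b[0] || b[nb - 1] + tol < a[0]) continue;
      int m = match_count_core(a.begin(), na, b.begin(), nb, tol, span);
      if (m >= m_min && m > 0) { ri.push_back(i + 1); rj.push_back(j + 1); rm.push_back(m); }
    }
  }
  return DataFrame::create(_["i"] = ri, _["j"] = rj, _["m"] = rm);
}

// Match counts of one sorted query band vector against each vector in a list.
// [[Rcpp::export]]
IntegerVector cpp_match_many(IntegerVector query, List bands, int tol, int span) {
  int n = bands.size();
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) {
    IntegerVector b = bands[i];
    out[i] = match_count_core(query.begin(), query.size(), b.begin(), b.size(),
                              tol, span);
  }
  return out;
}

// Monte-Carlo engine for the Sulston null: two clones of n bands each at
// independent uniform positions on (0, gel). Per trial, counts the bands of
// the first clone having at least one band of the second within the
// tolerance (neighbour reuse allowed — the event the score's binomial model
// describes). Returns the tally of trials by match count (length n + 1,
// entry k+1 = number of trials with exactly k such bands). Uses R's RNG, so
// seed with set.seed() before calling.
// [[Rcpp::export]]
IntegerVector cpp_sulston_mc(int n, double tol, double gel, int trials) {
  IntegerVector tally(n + 1);
  std::vector<double> a(n), b(n);
  for (int t = 0; t < trials; ++t) {
    for (int k = 0; k < n; ++k) a[k] = unif_rand() * gel;
    for (int k = 0; k < n; ++k) b[k] = unif_rand() * gel;
    std::sort(b.begin(), b.end());
    int m = 0;
    for (int k = 0; k < n; ++k) {
      // nearest b neighbour via binary search
      std::vector<double>::iterator it =
        std::lower_bound(b.begin(), b.end(), a[k]);
      double d = R_PosInf;
      if (it != b.end()) d = std::min(d, *it - a[k]);
      if (it != b.begin()) d = std::min(d, a[k] - *(it - 1));
      if (d <= tol) ++m;
    }
    ++tally[m];
  }
  return tally;
}
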