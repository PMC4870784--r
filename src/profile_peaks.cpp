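#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Rule-based 1-D peak calling on a smoothed intensity profile.
// An apex sits at i (0-based) iff the profile strictly increased over the
// two steps into i, strictly decreased over the two steps after i, and
// y[i] exceeds the channel mean. The extent is the maximal strictly
// monotone run around the apex; when consecutive extents share the valley
// point, the later extent is trimmed (left-to-right resolution) so extents
// never overlap.

struct Peak { int apex, start, end; };

// scanning implementation: precomputes step signs, walks candidates once
static std::vector<Peak> scan_peaks(const double *y, int n, double mean) {
  std::vector<Peak> out;
  if (n < 5) return out;
  std::vector<int> sg(n - 1);
  for (int i = 0; i + 1 < n; ++i)
    sg[i] = (y[i + 1] > y[i]) - (y[i + 1] < y[i]);
  int lastEnd = -1;
  for (int i = 2; i + 2 < n; ++i) {
    if (sg[i - 2] == 1 && sg[i - 1] == 1 && sg[i] == -1 && sg[i + 1] == -1 &&
        y[i] > mean) {
      int s = i;
      while (s > 0 && sg[s - 1] == 1) --s;
      int e = i;
      while (e + 1 < n && sg[e] == -1) ++e;
      if (s <= lastEnd) s = lastEnd + 1;
      out.push_back({i, s, e});
      lastEnd = e;
    }
  }
  return out;
}

// naive oracle: re-checks the rule at every index with explicit loops
static std::vector<Peak> naive_peaks(const double *y, int n, double mean) {
  std::vector<Peak> out;
  int lastEnd = -1;
  for (int i = 0; i < n; ++i) {
    if (i < 2 || i > n - 3) continue;
    bool up = y[i - 2] < y[i - 1] && y[i - 1] < y[i];
    bool down = y[i] > y[i + 1] && y[i + 1] > y[i + 2];
    if (!up || !down || !(y[i] > mean)) continue;
    int s = i;
    for (int j = i; j > 0; --j) {
      if (y[j - 1] < y[j]) s = j - 1; else break;
    }
    int e = i;
    for (int j = i; j + 1 < n; ++j) {
      if (y[j + 1] < y[j]) e = j + 1; else break;
    }
    if (s <= lastEnd) s = lastEnd + 1;
    out.push_back({i, s, e});
    lastEnd = e;
  }
  return out;
}

// [[Rcpp::export(name = ".cppFindPeaks")]]
IntegerMatrix cppFindPeaks(NumericVector y, double channelMean) {
  std::vector<Peak> pk = scan_peaks(y.begin(), y.size(), channelMean);
  IntegerMatrix m(pk.size(), 3);
  for (size_t i = 0; i < pk.size(); ++i) {
    m(i, 0) = pk[i].apex + 1;  // 1-based for R
    m(i, 1) = pk[i].start + 1;
    m(i, 2) = pk[i].end + 1;
  }
  colnames(m) = CharacterVector::create("apex", "start", "end");
  return m;
}

// [[Rcpp::export(name = ".cppNaiveFindPeaks")]]
IntegerMatrix cppNaiveFindPeaks(NumericVector y, double channelMean) {
  std::vector<Peak> pk = naive_peaks(y.begin(), y.size(), channelMean);
  IntegerMatrix m(pk.size(), 3);
  for (size_t i = 0; i < pk.size(); ++i) {
    m(i, 0) = pk[i].apex + 1;
    m(i, 1) = pk[i].start + 1;
    m(i, 2) = pk[i].end + 1;
  }
  colnames(m) = CharacterVector::create("apex", "start", "end");
  return m;
}

// Exhaustively enumerate every profile of length 1..maxLen over the values
// {0,..,nLevels-1} and compare the scanning caller with the naive oracle.
// Returns c(total profiles, mismatching profiles).
// [[Rcpp::export(name = ".cppEnumerateAgreement")]]
NumericVector cppEnumerateAgreement(int maxLen, int nLevels) {
  double total = 0, bad = 0;
  std::vector<int> digit(maxLen);
  std::vector<double> y(maxLen);
  for (int L = 1; L <= maxLen; ++L) {
    std::fill(digit.begin(), digit.begin() + L, 0);
    while (true) {
      double s = 0;
      for (int i = 0; i < L; ++i) { y[i] = digit[i]; s += digit[i]; }
      double mean = s / L;
      std::vector<Peak> a = scan_peaks(y.data(), L, mean);
      std::vector<Peak> b = naive_peaks(y.data(), L, mean);
      bool same = a.size() == b.size();
      if (same)
        for (size_t k = 0; k < a.size(); ++k)
          if (a[k].apex != b[k].apex || a[k].start != b[k].start ||
              a[k].end != b[k].end) { same = false; break; }
      if (!same) ++bad;
      ++total;
      int c = 0;  // base-nLevels counter
      while (c < L && ++digit[c] == nLevels) digit[c++] = 0;
      if (c == L) break;
    }
  }
  return NumericVector::create(total, bad);
}
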