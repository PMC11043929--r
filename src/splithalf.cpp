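#include <Rcpp.h>
using namespace Rcpp;

// Random half-split of buf[lo, hi): partial Fisher-Yates using R's RNG,
// then means of the two halves. Odd counts: the extra element goes to a
// random half. Assumes hi - lo >= 2.
static inline void half_means(std::vector<double> &buf, int lo, int hi,
                              double &mean1, double &mean2) {
  int n = hi - lo;
  int m1 = n / 2;
  if ((n % 2) && unif_rand() < 0.5) ++m1;
  for (int j = 0; j < m1; ++j) {
    int k = j + (int)(unif_rand() * (n - j));
    if (k >= n) k = n - 1; // guard against unif_rand() == 1.0
    std::swap(buf[lo + j], buf[lo + k]);
  }
  double s1 = 0.0, stot = 0.0;
  for (int j = 0; j < n; ++j) stot += buf[lo + j];
  for (int j = 0; j < m1; ++j) s1 += buf[lo + j];
  mean1 = s1 / m1;
  mean2 = (stot - s1) / (n - m1);
}

static inline double pearson(const std::vector<double> &x,
                             const std::vector<double> &y) {
  int n = x.size();
  double mx = 0.0, my = 0.0;
  for (int i = 0; i < n; ++i) { mx += x[i]; my += y[i]; }
  mx /= n; my /= n;
  double sxy = 0.0, sxx = 0.0, syy = 0.0;
  for (int i = 0; i < n; ++i) {
    double dx = x[i] - mx, dy = y[i] - my;
    sxy += dx * dy; sxx += dx * dx; syy += dy * dy;
  }
  if (sxx <= 0.0 || syy <= 0.0) return NA_REAL;
  return sxy / std::sqrt(sxx * syy);
}

// Permutation split-half engine. `vals` holds, for each participant, the
// congruent-condition values followed by the incongruent-condition values
// (RTs of correct trials for the RT cost; 0/100 error indicators for the
// error cost). `offsets` (length 2 * n_participants + 1) marks the block
// boundaries. For each of B permutations each block is randomly halved,
// the interference cost (incongruent mean minus congruent mean) is
// computed on each half, and the costs are Pearson-correlated across
// participants. Uses R's RNG, so results are reproducible via set.seed().
// [[Rcpp::export]]
NumericVector split_half_perm_engine(NumericVector vals,
                                     IntegerVector offsets,
                                     int n_participants, int B) {
  std::vector<double> buf(vals.begin(), vals.end());
  std::vector<double> cost1(n_participants), cost2(n_participants);
  NumericVector rs(B);
  for (int b = 0; b < B; ++b) {
    for (int p = 0; p < n_participants; ++p) {
      double c1, c2, i1, i2;
      half_means(buf, offsets[2 * p], offsets[2 * p + 1], c1, c2);
      half_means(buf, offsets[2 * p + 1], offsets[2 * p + 2], i1, i2);
      cost1[p] = i1 - c1;
      cost2[p] = i2 - c2;
    }
    rs[b] = pearson(cost1, cost2);
  }
  return rs;
}
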