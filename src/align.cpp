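#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>

using namespace Rcpp;

// Threshold-scored dynamic-programming alignment of two sorted peak lists.
// dp is (m+1) x (n+1), initialized to zero (leading gaps on one side are
// free); cell update takes the max of diagonal + final_score and either
// neighbour + gap. final_score is 1/(1 + (qi - sj)^2) on the max-normalized
// intensities when |dmz| <= tol (identically 1 when intensities are off)
// and -1 otherwise. Among score-optimal tracebacks the one minimizing the
// summed |dmz| over its diagonal pairs (global city-block) is returned,
// with the residual tie order diagonal > up > left.
// [[Rcpp::export]]
List cpp_osa(NumericVector qmz, NumericVector qint,
             NumericVector smz, NumericVector sint,
             double tol, double gap, bool use_intensities) {
  const int m = qmz.size(), n = smz.size();
  const double EPS = 1e-9;
  std::vector<double> dp((m + 1) * (n + 1), 0.0);
  std::vector<double> cb((m + 1) * (n + 1), 0.0);
  auto at = [n](int i, int j) { return i * (n + 1) + j; };

  for (int i = 1; i <= m; ++i) {
    for (int j = 1; j <= n; ++j) {
      double dmz = std::fabs(qmz[i - 1] - smz[j - 1]);
      double fs;
      if (dmz <= tol) {
        if (use_intensities) {
          double d = std::fabs(qint[i - 1] - sint[j - 1]);
          fs = 1.0 / (1.0 + d * d);
        } else {
          fs = 1.0;
        }
      } else {
        fs = -1.0;
      }
      double diag = dp[at(i - 1, j - 1)] + fs;
      double up = dp[at(i - 1, j)] + gap;
      double left = dp[at(i, j - 1)] + gap;
      double best = std::max(diag, std::max(up, left));
      dp[at(i, j)] = best;
      // min city-block over score-optimal predecessors
      double c = R_PosInf;
      if (diag >= best - EPS) c = std::min(c, cb[at(i - 1, j - 1)] + dmz);
      if (up >= best - EPS) c = std::min(c, cb[at(i - 1, j)]);
      if (left >= best - EPS) c = std::min(c, cb[at(i, j - 1)]);
      cb[at(i, j)] = c;
    }
  }

  // traceback consistent with both dp and cb; stop at the zero boundary
  std::vector<int> qi, sj;
  int i = m, j = n;
  while (i > 0 && j > 0) {
    double dmz = std::fabs(qmz[i - 1] - smz[j - 1]);
    double fs;
    if (dmz <= tol) {
      fs = use_intensities
               ? 1.0 / (1.0 + std::pow(std::fabs(qint[i - 1] - sint[j - 1]), 2))
               : 1.0;
    } else {
      fs = -1.0;
    }
    double here = dp[at(i, j)], chere = cb[at(i, j)];
    if (std::fabs(dp[at(i - 1, j - 1)] + fs - here) <= EPS &&
        std::fabs(cb[at(i - 1, j - 1)] + dmz - chere) <= EPS) {
      qi.push_back(i); sj.push_back(j);
      --i; --j;
    } else if (std::fabs(dp[at(i - 1, j)] + gap - here) <= EPS &&
               std::fabs(cb[at(i - 1, j)] - chere) <= EPS) {
      --i;
    } else {
      --j;
    }
  }
  std::reverse(qi.begin(), qi.end());
  std::reverse(sj.begin(), sj.end());
  IntegerMatrix pairs(qi.size(), 2);
  for (size_t k = 0; k < qi.size(); ++k) {
    pairs(k, 0) = qi[k];
    pairs(k, 1) = sj[k];
  }
  double raw = (m == 0 || n == 0) ? 0.0 : dp[at(m, n)];
  double cityblock = (m == 0 || n == 0) ? 0.0 : cb[at(m, n)];
  return List::create(_["raw_score"] = raw, _["pairs"] = pairs,
                      _["global_cityblock"] = cityblock);
}

// Greedy cosine: candidate peak pairs within tol, taken in order of
// descending intensity product, each peak used once; returns
// (sum qi*sj)^2 / (sum qi^2 * sum sj^2) on max-normalized intensities.
// [[Rcpp::export]]
double cpp_cosine_greedy(NumericVector qmz, NumericVector qint,
                         NumericVector smz, NumericVector sint, double tol) {
  const int m = qmz.size(), n = smz.size();
  if (m == 0 || n == 0) return 0.0;
  double qmax = 0.0, smax = 0.0;
  for (int i = 0; i < m; ++i) qmax = std::max(qmax, qint[i]);
  for (int j = 0; j < n; ++j) smax = std::max(smax, sint[j]);
  if (qmax <= 0.0 || smax <= 0.0) return 0.0;
  std::vector<double> q(m), s(n);
  for (int i = 0; i < m; ++i) q[i] = qint[i] / qmax;
  for (int j = 0; j < n; ++j) s[j] = sint[j] / smax;

  struct Cand { double prod; int i, j; };
  std::vector<Cand> cands;
  int lo = 0;
  for (int i = 0; i < m; ++i) {
    while (lo < n && smz[lo] < qmz[i] - tol) ++lo;
    for (int j = lo; j < n && smz[j] <= qmz[i] + tol; ++j) {
      cands.push_back({q[i] * s[j], i, j});
    }
  }
  std::stable_sort(cands.begin(), cands.end(),
                   [](const Cand& a, const Cand& b) { return a.prod > b.prod; });
  std::vector<char> qu(m, 0), su(n, 0);
  double dot = 0.0;
  for (const Cand& c : cands) {
    if (!qu[c.i] && !su[c.j]) {
      qu[c.i] = su[c.j] = 1;
      dot += c.prod;
    }
  }
  double nq = 0.0, ns = 0.0;
  for (int i = 0; i < m; ++i) nq += q[i] * q[i];
  for (int j = 0; j < n; ++j) ns += s[j] * s[j];
  double sc = (dot * dot) / (nq * ns);
  return std::min(1.0, sc);
}

static void merge_within(const NumericVector& mz, const NumericVector& in,
                         double tol, std::vector<double>& omz,
                         std::vector<double>& oin) {
  // chain-merge adjacent peaks closer than tol; intensity-weighted centroid
  const int n = mz.size();
  int i = 0;
  while (i < n) {
    double msum = mz[i] * in[i], isum = in[i];
    double last = mz[i];
    int j = i + 1;
    while (j < n && mz[j] - last <= tol) {
      msum += mz[j] * in[j];
      isum += in[j];
      last = mz[j];
      ++j;
    }
    omz.push_back(isum > 0 ? msum / isum : last);
    oin.push_back(isum);
    i = j;
  }
}

static double shannon(const std::vector<double>& p) {
  double s = 0.0;
  for (double v : p)
    if (v > 0) s -= v * std::log(v);
  return s;
}

// Spectral-entropy similarity: 1 - (2 S_mix - S_q - S_s) / ln 4 with
// tolerance-merged, sum-normalized spectra and a half-weight mixture.
// [[Rcpp::export]]
double cpp_entropy_similarity(NumericVector qmz, NumericVector qint,
                              NumericVector smz, NumericVector sint,
                              double tol) {
  if (qmz.size() == 0 || smz.size() == 0) return 0.0;
  std::vector<double> qm, qi, sm, si;
  merge_within(qmz, qint, tol, qm, qi);
  merge_within(smz, sint, tol, sm, si);
  double qs = 0.0, ss = 0.0;
  for (double v : qi) qs += v;
  for (double v : si) ss += v;
  if (qs <= 0.0 || ss <= 0.0) return 0.0;
  for (double& v : qi) v /= qs;
  for (double& v : si) v /= ss;
  double Sq = shannon(qi), Ss = shannon(si);

  // half-weight mixture over the union peak list, merged within tol
  std::vector<double> umz, uin;
  size_t a = 0, b = 0;
  std::vector<double> allmz, allin;
  while (a < qm.size() || b < sm.size()) {
    if (b >= sm.size() || (a < qm.size() && qm[a] <= sm[b])) {
      allmz.push_back(qm[a]);
      allin.push_back(qi[a] / 2.0);
      ++a;
    } else {
      allmz.push_back(sm[b]);
      allin.push_back(si[b] / 2.0);
      ++b;
    }
  }
  NumericVector amz(allmz.begin(), allmz.end());
  NumericVector ain(allin.begin(), allin.end());
  std::vector<double> mmz, mix;
  merge_within(amz, ain, tol, mmz, mix);
  double Smix = shannon(mix);
  double sim = 1.0 - (2.0 * Smix - Sq - Ss) / std::log(4.0);
  return std::max(0.0, std::min(1.0, sim));
}

// Batch best-match under greedy cosine: for each query spectrum the index
// (1-based) and score of the best subject. Peak lists are two-column
// matrices (mz, intensity), sorted ascending in mz.
// [[Rcpp::export]]
List cpp_cosine_best_match(List qpeaks, List speaks, double tol) {
  const int nq = qpeaks.size(), ns = speaks.size();
  IntegerVector best(nq, NA_INTEGER);
  NumericVector score(nq, NA_REAL);
  std::vector<NumericMatrix> subj(ns);
  for (int j = 0; j < ns; ++j) subj[j] = as<NumericMatrix>(speaks[j]);
  for (int i = 0; i < nq; ++i) {
    NumericMatrix q = as<NumericMatrix>(qpeaks[i]);
    NumericVector qm = q(_, 0), qi = q(_, 1);
    double bs = -1.0;
    int bj = NA_INTEGER;
    for (int j = 0; j < ns; ++j) {
      double sc = cpp_cosine_greedy(qm, qi, subj[j](_, 0), subj[j](_, 1), tol);
      if (sc > bs) {
        bs = sc;
        bj = j + 1;
      }
    }
    best[i] = bj;
    score[i] = bs;
  }
  return List::create(_["index"] = best, _["score"] = score);
}
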