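#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Dynamic-programming search for an optimal segmentation of one continuous
// variable against a fixed opposite-side factor.
//
// Samples must be supplied in increasing order of the variable being
// segmented.  Two factors describe the opposite side:
//   u    - factor whose *global* margins enter the information terms
//          (the opposite variable's bins), codes in 0..nu-1
//   cfac - co-factor whose margins are evaluated *within* each bin
//          (conditioning strata merged with the segmented variable),
//          codes in 0..nc-1
// A segmentation into bins {B} is scored (in total nats, i.e. N * I) as
//   sum_B sum_{u,c} n_{uc} * [ log n_{uc} + log N - log m_u - log n_c ]
//   - (n_bins - 1) * pen_bin
// where m_u are global margins of u and n_c within-bin margins of cfac.
// With nc == 1 this reduces to the plug-in N*I([V];U) decomposition.
//
// Candidate cut positions are sample indices (1-based, cut falls after the
// index); the DP is exact over the candidate grid.  If the unconstrained
// optimum uses more than max_bins bins, a bin-capped DP is run instead.

static double seg_gain(const std::vector<double>& cum, int ncell, int nu, int nc,
                       int i, int j, const std::vector<double>& logm_u,
                       double logN, const std::vector<double>& logtab) {
  // cum is (ncell) x (K+1) column-major cumulative counts at boundary points
  double g = 0.0;
  const double* ci = &cum[(size_t)i * ncell];
  const double* cj = &cum[(size_t)j * ncell];
  for (int c = 0; c < nc; ++c) {
    double n_c = 0.0;
    for (int u = 0; u < nu; ++u) {
      n_c += cj[c * nu + u] - ci[c * nu + u];
    }
    if (n_c <= 0) continue;
    double log_nc = logtab[(int)(n_c + 0.5)];
    for (int u = 0; u < nu; ++u) {
      double n_uc = cj[c * nu + u] - ci[c * nu + u];
      if (n_uc <= 0) continue;
      g += n_uc * (logtab[(int)(n_uc + 0.5)] + logN - logm_u[u] - log_nc);
    }
  }
  return g;
}

// [[Rcpp::export]]
List dp_segment_cpp(IntegerVector u, IntegerVector cfac, int nu, int nc,
                    IntegerVector cand, double pen_bin, int max_bins) {
  const int n = u.size();
  const int ncell = nu * nc;
  // boundary points: 0, cand..., n
  std::vector<int> P;
  P.reserve(cand.size() + 2);
  P.push_back(0);
  for (int k = 0; k < cand.size(); ++k) P.push_back(cand[k]);
  P.push_back(n);
  const int K = (int)P.size() - 1;  // number of intervals between boundaries

  // cumulative counts at each boundary
  std::vector<double> cum((size_t)ncell * (K + 1), 0.0);
  {
    std::vector<double> run(ncell, 0.0);
    int b = 0;
    for (int k = 0; k <= K; ++k) {
      while (b < P[k]) {
        run[cfac[b] * nu + u[b]] += 1.0;
        ++b;
      }
      std::copy(run.begin(), run.end(), &cum[(size_t)k * ncell]);
    }
  }

  std::vector<double> logtab(n + 1, 0.0);
  for (int i = 1; i <= n; ++i) logtab[i] = std::log((double)i);
  const double logN = logtab[n];
  std::vector<double> logm_u(nu, 0.0);
  for (int uu = 0; uu < nu; ++uu) {
    double m = cum[(size_t)K * ncell + uu];  // c = 0 slice plus others
    m = 0.0;
    for (int c = 0; c < nc; ++c) m += cum[(size_t)K * ncell + c * nu + uu];
    logm_u[uu] = m > 0 ? std::log(m) : 0.0;
  }

  const double NEG = -1e300;

  // precompute gains lazily inside DP loops (each pair touched once)
  // 1-D DP with bin-count tracking
  std::vector<double> W(K + 1, NEG);
  std::vector<int> back(K + 1, -1), nb(K + 1, 0);
  W[0] = 0.0;
  for (int j = 1; j <= K; ++j) {
    for (int i = 0; i < j; ++i) {
      if (W[i] <= NEG / 2) continue;
      double val = W[i] + seg_gain(cum, ncell, nu, nc, i, j, logm_u, logN, logtab) -
                   (i > 0 ? pen_bin : 0.0);
      if (val > W[j] + 1e-12) {
        W[j] = val;
        back[j] = i;
        nb[j] = nb[i] + 1;
      }
    }
  }

  std::vector<int> cuts;
  double best = W[K];
  int used = nb[K];

  if (used > max_bins) {
    // capped DP: Wb[b][j] best value of prefix j with exactly b bins
    std::vector<std::vector<double>> Wb(max_bins + 1,
                                        std::vector<double>(K + 1, NEG));
    std::vector<std::vector<int>> Bk(max_bins + 1, std::vector<int>(K + 1, -1));
    Wb[0][0] = 0.0;
    for (int b = 1; b <= max_bins; ++b) {
      for (int j = b; j <= K; ++j) {
        for (int i = b - 1; i < j; ++i) {
          if (Wb[b - 1][i] <= NEG / 2) continue;
          double val = Wb[b - 1][i] +
                       seg_gain(cum, ncell, nu, nc, i, j, logm_u, logN, logtab) -
                       (b > 1 ? pen_bin : 0.0);
          if (val > Wb[b][j] + 1e-12) {
            Wb[b][j] = val;
            Bk[b][j] = i;
          }
        }
      }
    }
    best = NEG;
    int bbest = 1;
    for (int b = 1; b <= max_bins; ++b) {
      if (Wb[b][K] > best) {
        best = Wb[b][K];
        bbest = b;
      }
    }
    int j = K;
    for (int b = bbest; b >= 1; --b) {
      int i = Bk[b][j];
      if (i > 0) cuts.push_back(P[i]);
      j = i;
    }
    used = bbest;
  } else {
    int j = K;
    while (j > 0) {
      int i = back[j];
      if (i > 0) cuts.push_back(P[i]);
      j = i;
    }
  }
  std::sort(cuts.begin(), cuts.end());
  return List::create(_["cut_idx"] = wrap(cuts), _["value"] = best,
                      _["n_bins"] = used);
}

// Parametric (stochastic) complexity of an L-category multinomial over n
// samples, log scale, natural log, via the linear recurrence
//   C(1, n) = 1
//   C(2, n) = sum_h binom(n, h) (h/n)^h ((n-h)/n)^(n-h)
//   C(L, n) = C(L-1, n) + n / (L - 2) * C(L-2, n),  L >= 3
// computed in log space for numerical stability.

static double logsumexp2(double a, double b) {
  double m = a > b ? a : b;
  return m + std::log1p(std::exp((a < b ? a : b) - m));
}

// [[Rcpp::export]]
double log_param_complexity_cpp(int L, int n) {
  if (L <= 1 || n <= 0) return 0.0;
  // log C(2, n)
  double lc2;
  {
    double acc = R_NegInf;
    for (int h = 0; h <= n; ++h) {
      double t = Rf_lchoose((double)n, (double)h);
      if (h > 0) t += h * std::log((double)h / n);
      if (n - h > 0) t += (n - h) * std::log((double)(n - h) / n);
      acc = (acc == R_NegInf) ? t : logsumexp2(acc, t);
    }
    lc2 = acc;
  }
  if (L == 2) return lc2;
  double lprev = 0.0;  // log C(1, n)
  double lcur = lc2;
  for (int k = 3; k <= L; ++k) {
    double lnext = logsumexp2(lcur, std::log((double)n / (k - 2)) + lprev);
    lprev = lcur;
    lcur = lnext;
  }
  return lcur;
}

// Plug-in joint counting helper: cross-tabulate two 0-based code vectors.
// [[Rcpp::export]]
NumericVector cross_tab_cpp(IntegerVector a, IntegerVector b, int na, int nb) {
  NumericVector out(na * nb);
  const int n = a.size();
  for (int i = 0; i < n; ++i) out[b[i] * na + a[i]] += 1.0;
  return out;
}

// Stratified categorical conditional mutual information: plug-in CMI (nats
// per sample) over conditioning strata, plus per-stratum sample counts.
// [[Rcpp::export]]
List strat_mi_cpp(IntegerVector cx, IntegerVector cy, IntegerVector cs,
                  int rx, int ry, int S) {
  const int n = cx.size();
  std::vector<double> nxyz((size_t)rx * ry * S, 0.0);
  std::vector<double> nxs((size_t)rx * S, 0.0), nys((size_t)ry * S, 0.0),
      ns(S, 0.0);
  for (int i = 0; i < n; ++i) {
    int a = cx[i] - 1, b = cy[i] - 1, s = cs[i] - 1;
    nxyz[(size_t)s * rx * ry + b * rx + a] += 1.0;
    nxs[(size_t)s * rx + a] += 1.0;
    nys[(size_t)s * ry + b] += 1.0;
    ns[s] += 1.0;
  }
  double raw = 0.0;
  for (int s = 0; s < S; ++s) {
    if (ns[s] <= 0) continue;
    double lns = std::log(ns[s]);
    for (int b = 0; b < ry; ++b) {
      for (int a = 0; a < rx; ++a) {
        double v = nxyz[(size_t)s * rx * ry + b * rx + a];
        if (v <= 0) continue;
        raw += v / n * (std::log(v) + lns -
                        std::log(nxs[(size_t)s * rx + a]) -
                        std::log(nys[(size_t)s * ry + b]));
      }
    }
  }
  return List::create(_["raw"] = raw, _["n_s"] = wrap(ns));
}
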