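#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Batch z-normalized kmer matching of one query against one database entry.
//
// Windowed dot products D(i,j) = sum_{u<k} q[i+u]*e[j+u] are computed for
// every (query offset i, entry offset j) with a diagonal recurrence
// D(i,j) = D(i-1,j-1) - q[i-1]e[j-1] + q[i+k-1]e[j+k-1], i.e. O(n*m) for all
// kmers at once. The z-normalized Euclidean distance then follows from the
// window means/sds: dist^2 = 2k * (1 - (D - k*mq*me) / (k*sq*se)).
//
// q and e must have NA replaced by 0 beforehand; windows containing NA (or
// with zero variance) are excluded via the retained/evalid masks, so the
// substituted zeros never reach a reported distance.
//
// [[Rcpp::export(name = ".kmerMatchEntry")]]
List kmerMatchEntry(NumericVector q, NumericVector e, int k,
                    LogicalVector retained, NumericVector qmu,
                    NumericVector qsd, LogicalVector evalid,
                    NumericVector emu, NumericVector esd, double thr) {
  const int n = q.size(), m = e.size();
  const int nq = n - k + 1, ne = m - k + 1;
  std::vector<int> out_qs, out_es;
  std::vector<double> out_d;
  if (nq <= 0 || ne <= 0)
    return List::create(_["query_start"] = IntegerVector(0),
                        _["db_start"] = IntegerVector(0),
                        _["dist"] = NumericVector(0));
  const double thr2 = thr * thr;
  const double kk = static_cast<double>(k);
  const double *qp = REAL(q), *ep = REAL(e);
  const double *qmup = REAL(qmu), *qsdp = REAL(qsd);
  const double *emup = REAL(emu), *esdp = REAL(esd);
  const int *retp = LOGICAL(retained), *evp = LOGICAL(evalid);
  // diagonal offset t = j - i
  for (int t = -(nq - 1); t <= ne - 1; ++t) {
    int i0 = std::max(0, -t);
    int iend = std::min(nq - 1, ne - 1 - t);  // last window start on diagonal
    if (i0 > iend) continue;
    // initial window sum at (i0, i0 + t)
    double D = 0.0;
    for (int u = 0; u < k; ++u) D += qp[i0 + u] * ep[i0 + t + u];
    for (int i = i0; i <= iend; ++i) {
      int j = i + t;
      if (i > i0)
        D += qp[i + k - 1] * ep[j + k - 1] - qp[i - 1] * ep[j - 1];
      if (retp[i] && evp[j]) {
        double denom = kk * qsdp[i] * esdp[j];
        double corr = (D - kk * qmup[i] * emup[j]) / denom;
        double dist2 = 2.0 * kk * (1.0 - corr);
        if (dist2 < 0.0) dist2 = 0.0;
        if (dist2 <= thr2) {
          out_qs.push_back(i);
          out_es.push_back(j);
          out_d.push_back(std::sqrt(dist2));
        }
      }
    }
  }
  return List::create(_["query_start"] = wrap(out_qs),
                      _["db_start"] = wrap(out_es),
                      _["dist"] = wrap(out_d));
}

// Rolling window mean/sd/validity for a reactivity vector (NA allowed).
// Returns mu, sd (population sd, matching z-normalization) and valid flags;
// a window is invalid if it contains NA or has (near-)zero variance.
//
// [[Rcpp::export(name = ".windowStats")]]
List windowStats(NumericVector x, int k) {
  const int n = x.size();
  const int nw = n - k + 1;
  if (nw <= 0)
    return List::create(_["mu"] = NumericVector(0), _["sd"] = NumericVector(0),
                        _["valid"] = LogicalVector(0));
  NumericVector mu(nw), sdv(nw);
  LogicalVector valid(nw);
  double s = 0.0, s2 = 0.0;
  int nna = 0;
  for (int u = 0; u < k; ++u) {
    double v = x[u];
    if (ISNAN(v)) { ++nna; } else { s += v; s2 += v * v; }
  }
  const double kk = static_cast<double>(k);
  for (int i = 0; i < nw; ++i) {
    if (i > 0) {
      double out = x[i - 1], in = x[i + k - 1];
      if (ISNAN(out)) --nna; else { s -= out; s2 -= out * out; }
      if (ISNAN(in)) ++nna; else { s += in; s2 += in * in; }
    }
    if (nna > 0) {
      mu[i] = NA_REAL; sdv[i] = NA_REAL; valid[i] = false;
    } else {
      double m = s / kk;
      double v = s2 / kk - m * m;
      if (v < 1e-12) {
        mu[i] = m; sdv[i] = 0.0; valid[i] = false;
      } else {
        mu[i] = m; sdv[i] = std::sqrt(v); valid[i] = true;
      }
    }
  }
  return List::create(_["mu"] = mu, _["sd"] = sdv, _["valid"] = valid);
}
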