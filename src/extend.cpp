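#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <cstdint>
using namespace Rcpp;

// One-directional extension of an ungapped seed by a banded three-state
// (pair / gap-in-db / gap-in-query) affine-gap semi-global DP over the
// reactivity signal, with drop-off termination.
//
// Inputs are the extension "arms": the profile slices immediately after the
// seed (for upstream extension the caller passes the reversed slices before
// the seed). Scores are relative to the seed boundary (origin cell = 0).
// The DP advances one anti-diagonal s = i + j at a time, restricted to a
// band |i - j| <= max(10, ceil(band_fraction * s)) around the seed diagonal.
// Extension stops when the best score on the anti-diagonal has stayed below
// max_dropoff_rate * (running global best) for more than max_dropoff_bases
// consecutive anti-diagonals, or when no in-band cell remains. The reported
// extension is the traceback from the highest-scoring pair cell (ties:
// earliest anti-diagonal, then smallest query offset).

static const double NEG_INF = -1e30;

struct Diag {
  int ilo = 0, n = 0;
  std::vector<double> M, GD, GQ;
  std::vector<uint8_t> tb;  // bits 0-1: M pred (0 start,1 M,2 GD,3 GQ);
                            // bit 2: GD from ext; bit 3: GQ from ext
};

static inline double colScore(double rq, double rd, int bq, int bd,
                              double match_min, double match_max,
                              double mism_min, double mism_max,
                              double maxr, bool seq, double seq_match,
                              double seq_mismatch) {
  double sc;
  if (ISNAN(rq) || ISNAN(rd)) {
    sc = 0.0;
  } else {
    double d = std::fabs(rq - rd);
    double t = maxr / 2.0;
    if (d <= t) {
      sc = match_max - (d / t) * (match_max - match_min);
    } else {
      sc = mism_max - ((d - t) / (maxr - t)) * (mism_max - mism_min);
      if (sc < mism_min) sc = mism_min;
    }
  }
  if (seq) {
    if (bq == bd && bq < 4) sc += seq_match; else sc += seq_mismatch;
  }
  return sc;
}

// [[Rcpp::export(name = ".extendArm")]]
List extendArm(NumericVector q, NumericVector e, IntegerVector qb,
               IntegerVector eb, double match_min, double match_max,
               double mism_min, double mism_max, double gap_open,
               double gap_ext, double maxr, bool seq_scoring,
               double seq_match, double seq_mismatch, double dropoff_rate,
               int dropoff_bases, double band_fraction) {
  const int n = q.size(), m = e.size();
  double global_best = 0.0;
  int best_s = 0, best_i = 0;
  std::vector<Diag> diags(1);
  diags[0].ilo = 0; diags[0].n = 1;
  diags[0].M.assign(1, 0.0);        // origin acts as the "start" state
  diags[0].GD.assign(1, NEG_INF);
  diags[0].GQ.assign(1, NEG_INF);
  diags[0].tb.assign(1, 0);
  int bad = 0;
  for (int s = 1; s <= n + m; ++s) {
    int w = std::max(10, (int)std::ceil(band_fraction * s));
    int ilo = std::max(std::max(0, s - m), (s - w + 1) / 2);  // ceil((s-w)/2)
    int ihi = std::min(std::min(n, s), (s + w) / 2);          // floor((s+w)/2)
    if (ilo > ihi) break;
    diags.emplace_back();
    Diag &cur = diags[s];
    const Diag &p1 = diags[s - 1];
    cur.ilo = ilo; cur.n = ihi - ilo + 1;
    cur.M.assign(cur.n, NEG_INF);
    cur.GD.assign(cur.n, NEG_INF);
    cur.GQ.assign(cur.n, NEG_INF);
    cur.tb.assign(cur.n, 0);
    double step_best = NEG_INF;
    for (int i = ilo; i <= ihi; ++i) {
      int j = s - i;
      int idx = i - ilo;
      uint8_t tb = 0;
      // M: from (i-1, j-1) on diagonal s-2
      if (i >= 1 && j >= 1 && s >= 2) {
        const Diag &p2 = diags[s - 2];
        int pidx = (i - 1) - p2.ilo;
        if (pidx >= 0 && pidx < p2.n) {
          double bestp = p2.M[pidx];
          uint8_t from = (i - 1 == 0 && j - 1 == 0) ? 0 : 1;
          if (p2.GD[pidx] > bestp) { bestp = p2.GD[pidx]; from = 2; }
          if (p2.GQ[pidx] > bestp) { bestp = p2.GQ[pidx]; from = 3; }
          if (bestp > NEG_INF / 2) {
            double sc = colScore(q[i - 1], e[j - 1], qb[i - 1], eb[j - 1],
                                 match_min, match_max, mism_min, mism_max,
                                 maxr, seq_scoring, seq_match, seq_mismatch);
            cur.M[idx] = bestp + sc;
            tb |= from;
          }
        }
      }
      // GD: gap in db, consumes query base; from (i-1, j) on s-1
      if (i >= 1) {
        int pidx = (i - 1) - p1.ilo;
        if (pidx >= 0 && pidx < p1.n) {
          double open_from = p1.M[pidx];  // origin M doubles as start
          double ext_from = p1.GD[pidx];
          double vopen = open_from > NEG_INF / 2 ? open_from + gap_open
                                                 : NEG_INF;
          double vext = ext_from > NEG_INF / 2 ? ext_from + gap_ext : NEG_INF;
          if (vopen >= vext) { cur.GD[idx] = vopen; }
          else { cur.GD[idx] = vext; tb |= 4; }
        }
      }
      // GQ: gap in query, consumes db base; from (i, j-1) on s-1
      if (j >= 1) {
        int pidx = i - p1.ilo;
        if (pidx >= 0 && pidx < p1.n) {
          double open_from = p1.M[pidx];
          double ext_from = p1.GQ[pidx];
          double vopen = open_from > NEG_INF / 2 ? open_from + gap_open
                                                 : NEG_INF;
          double vext = ext_from > NEG_INF / 2 ? ext_from + gap_ext : NEG_INF;
          if (vopen >= vext) { cur.GQ[idx] = vopen; }
          else { cur.GQ[idx] = vext; tb |= 8; }
        }
      }
      cur.tb[idx] = tb;
      double cellmax = std::max(cur.M[idx], std::max(cur.GD[idx], cur.GQ[idx]));
      if (cellmax > step_best) step_best = cellmax;
      if (cur.M[idx] > global_best) {  // strict: ties keep the earliest cell
        global_best = cur.M[idx];
        best_s = s; best_i = i;
      }
    }
    if (step_best < dropoff_rate * global_best) {
      if (++bad > dropoff_bases) break;
    } else {
      bad = 0;
    }
  }
  // Traceback from the best pair cell.
  std::vector<int> states;  // 1 pair, 2 gap-in-db, 3 gap-in-query (reversed)
  int s = best_s, i = best_i;
  int state = 1;  // M
  while (s > 0) {
    const Diag &d = diags[s];
    int idx = i - d.ilo;
    uint8_t tb = d.tb[idx];
    if (state == 1) {
      states.push_back(1);
      uint8_t from = tb & 3;
      s -= 2; i -= 1;
      if (from == 0) break;          // reached origin
      state = (from == 1) ? 1 : (from == 2 ? 2 : 3);
    } else if (state == 2) {         // GD
      states.push_back(2);
      bool ext = (tb & 4) != 0;
      s -= 1; i -= 1;
      state = ext ? 2 : 1;
      if (s == 0) break;
    } else {                         // GQ
      states.push_back(3);
      bool ext = (tb & 8) != 0;
      s -= 1;
      state = ext ? 3 : 1;
      if (s == 0) break;
    }
  }
  std::reverse(states.begin(), states.end());
  if (global_best <= 0.0) {
    return List::create(_["score"] = 0.0, _["qlen"] = 0, _["elen"] = 0,
                        _["states"] = IntegerVector(0));
  }
  return List::create(_["score"] = global_best, _["qlen"] = best_i,
                      _["elen"] = best_s - best_i,
                      _["states"] = wrap(states));
}

// Score-only arm extension (no traceback): same DP and drop-off rule as
// extendArm, rolling over the last two anti-diagonals only. The arm is
// addressed through (start, dir): element u is x[start + dir*u], so the
// upstream direction needs no reversed copies.
struct ArmResult { double score; int qlen, elen; };

static ArmResult extendArmScoreOnly(
    const double *q, const int *qb, int q0, int qdir, int n,
    const double *e, const int *eb, int e0, int edir, int m,
    double match_min, double match_max, double mism_min, double mism_max,
    double gap_open, double gap_ext, double maxr, bool seq,
    double seq_match, double seq_mismatch, double dropoff_rate,
    int dropoff_bases, double band_fraction) {
  ArmResult res{0.0, 0, 0};
  if (n <= 0 || m <= 0) return res;
  double global_best = 0.0;
  int best_i = 0, best_s = 0;
  // rolling storage indexed by i - ilo per diagonal
  std::vector<double> M1(1, 0.0), GD1(1, NEG_INF), GQ1(1, NEG_INF);
  std::vector<double> M2, GD2, GQ2;
  int ilo1 = 0, n1 = 1, ilo2 = 0, n2 = 0;
  std::vector<double> Mc, GDc, GQc;
  int bad = 0;
  for (int s = 1; s <= n + m; ++s) {
    int w = std::max(10, (int)std::ceil(band_fraction * s));
    int ilo = std::max(std::max(0, s - m), (s - w + 1) / 2);
    int ihi = std::min(std::min(n, s), (s + w) / 2);
    if (ilo > ihi) break;
    int nc = ihi - ilo + 1;
    Mc.assign(nc, NEG_INF); GDc.assign(nc, NEG_INF); GQc.assign(nc, NEG_INF);
    double step_best = NEG_INF;
    for (int i = ilo; i <= ihi; ++i) {
      int j = s - i;
      int idx = i - ilo;
      if (i >= 1 && j >= 1 && s >= 2) {
        int pidx = (i - 1) - ilo2;
        if (pidx >= 0 && pidx < n2) {
          double bestp = std::max(M2[pidx], std::max(GD2[pidx], GQ2[pidx]));
          if (bestp > NEG_INF / 2) {
            double sc = colScore(q[q0 + qdir * (i - 1)],
                                 e[e0 + edir * (j - 1)],
                                 qb[q0 + qdir * (i - 1)],
                                 eb[e0 + edir * (j - 1)],
                                 match_min, match_max, mism_min, mism_max,
                                 maxr, seq, seq_match, seq_mismatch);
            Mc[idx] = bestp + sc;
          }
        }
      }
      if (i >= 1) {
        int pidx = (i - 1) - ilo1;
        if (pidx >= 0 && pidx < n1) {
          double vopen = M1[pidx] > NEG_INF / 2 ? M1[pidx] + gap_open
                                                : NEG_INF;
          double vext = GD1[pidx] > NEG_INF / 2 ? GD1[pidx] + gap_ext
                                                : NEG_INF;
          GDc[idx] = std::max(vopen, vext);
        }
      }
      if (j >= 1) {
        int pidx = i - ilo1;
        if (pidx >= 0 && pidx < n1) {
          double vopen = M1[pidx] > NEG_INF / 2 ? M1[pidx] + gap_open
                                                : NEG_INF;
          double vext = GQ1[pidx] > NEG_INF / 2 ? GQ1[pidx] + gap_ext
                                                : NEG_INF;
          GQc[idx] = std::max(vopen, vext);
        }
      }
      double cellmax = std::max(Mc[idx], std::max(GDc[idx], GQc[idx]));
      if (cellmax > step_best) step_best = cellmax;
      if (Mc[idx] > global_best) {
        global_best = Mc[idx];
        best_s = s; best_i = i;
      }
    }
    if (step_best < dropoff_rate * global_best) {
      if (++bad > dropoff_bases) break;
    } else {
      bad = 0;
    }
    M2.swap(M1); GD2.swap(GD1); GQ2.swap(GQ1);
    ilo2 = ilo1; n2 = n1;
    M1.swap(Mc); GD1.swap(GDc); GQ1.swap(GQc);
    ilo1 = ilo; n1 = nc;
  }
  if (global_best > 0.0) {
    res.score = global_best;
    res.qlen = best_i;
    res.elen = best_s - best_i;
  }
  return res;
}

// Batch score-only extension of many HSGs of one query against one entry.
// HSG coordinates are 0-based half-open; returns per HSG the total score
// (seed + both extensions) and the extended intervals.
//
// [[Rcpp::export(name = ".extendHSGsScore")]]
List extendHSGsScore(NumericVector q, NumericVector e, IntegerVector qb,
                     IntegerVector eb, IntegerVector hqs, IntegerVector hqe,
                     IntegerVector hds, IntegerVector hde, double match_min,
                     double match_max, double mism_min, double mism_max,
                     double gap_open, double gap_ext, double maxr,
                     bool seq_scoring, double seq_match, double seq_mismatch,
                     double dropoff_rate, int dropoff_bases,
                     double band_fraction) {
  const int n = q.size(), m = e.size();
  const int nh = hqs.size();
  const double *qp = REAL(q), *ep = REAL(e);
  const int *qbp = INTEGER(qb), *ebp = INTEGER(eb);
  NumericVector score(nh);
  IntegerVector oqs(nh), oqe(nh), ods(nh), ode(nh);
  for (int h = 0; h < nh; ++h) {
    int qs = hqs[h], qe = hqe[h], ds = hds[h], de = hde[h];
    double seed = 0.0;
    for (int u = 0; u < qe - qs; ++u)
      seed += colScore(qp[qs + u], ep[ds + u], qbp[qs + u], ebp[ds + u],
                       match_min, match_max, mism_min, mism_max, maxr,
                       seq_scoring, seq_match, seq_mismatch);
    ArmResult down = extendArmScoreOnly(
        qp, qbp, qe, 1, n - qe, ep, ebp, de, 1, m - de, match_min,
        match_max, mism_min, mism_max, gap_open, gap_ext, maxr, seq_scoring,
        seq_match, seq_mismatch, dropoff_rate, dropoff_bases, band_fraction);
    ArmResult up = extendArmScoreOnly(
        qp, qbp, qs - 1, -1, qs, ep, ebp, ds - 1, -1, ds, match_min,
        match_max, mism_min, mism_max, gap_open, gap_ext, maxr, seq_scoring,
        seq_match, seq_mismatch, dropoff_rate, dropoff_bases, band_fraction);
    score[h] = seed + down.score + up.score;
    oqs[h] = qs - up.qlen; oqe[h] = qe + down.qlen;
    ods[h] = ds - up.elen; ode[h] = de + down.elen;
  }
  return List::create(_["score"] = score, _["query_start"] = oqs,
                      _["query_end"] = oqe, _["db_start"] = ods,
                      _["db_end"] = ode);
}
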