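// Dynamic-programming kernels: EM scan over sequence windows, seed screening,
// profile-HMM Viterbi/forward in local mode, affine-gap profile alignment.
// All log quantities are natural logs; callers convert to bits.
#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static const double NEG_INF = -std::numeric_limits<double>::infinity();

static inline double lse2(double a, double b) {
  if (a == NEG_INF) return b;
  if (b == NEG_INF) return a;
  double m, d;
  if (a > b) { m = a; d = b - a; } else { m = b; d = a - b; }
  if (d < -40.0) return m;  // below double precision of the sum
  return m + std::log1p(std::exp(d));
}

// One E-step (and count accumulation) of the repeats-allowed mixture model.
// seqs: list of integer vectors with codes 1..21 (21 = X).
// logratio: 21 x w matrix, log(p_motif / p_background), X row must be 0.
// pi: per-window site prior.
// Returns posterior-weighted letter counts, sum of posteriors, window count,
// mixture log likelihood (without the constant background term), and
// optionally the per-window posteriors.
// [[Rcpp::export]]
List cpp_em_scan(List seqs, NumericMatrix logratio, double pi, bool want_post) {
  int w = logratio.ncol();
  double lpi = std::log(pi), l1mpi = std::log1p(-pi);
  NumericMatrix counts(21, w);
  double sumz = 0.0, loglik = 0.0;
  long nwin = 0;
  int nseq = seqs.size();
  List post(want_post ? nseq : 0);
  for (int s = 0; s < nseq; ++s) {
    IntegerVector sq = seqs[s];
    int L = sq.size();
    int nw = L - w + 1;
    NumericVector zs(want_post ? std::max(nw, 0) : 0);
    for (int i = 0; i < nw; ++i) {
      double llr = 0.0;
      for (int j = 0; j < w; ++j) llr += logratio(sq[i + j] - 1, j);
      double a = lpi + llr;
      double l = lse2(a, l1mpi);
      double z = std::exp(a - l);
      loglik += l;
      sumz += z;
      ++nwin;
      for (int j = 0; j < w; ++j) counts(sq[i + j] - 1, j) += z;
      if (want_post) zs[i] = z;
    }
    if (want_post) post[s] = zs;
  }
  return List::create(_["counts"] = counts, _["sumz"] = sumz,
                      _["n_windows"] = (double)nwin, _["loglik"] = loglik,
                      _["posteriors"] = post);
}

// Screen candidate seed PWMs: each seed column puts 0.7 on its letter and
// spreads the remainder uniformly over the other 19 canonical letters
// (rescaled so the 20 canonical letters sum to 1 - bg[X]); each seed model
// is scored by its mixture log likelihood (the E-step objective of the
// first EM step). seeds: w x nseed integer matrix of codes (1..20, no X).
// [[Rcpp::export]]
NumericVector cpp_seed_screen(List seqs, IntegerMatrix seeds, NumericVector logbg,
                              double bgx, double pi0) {
  int w = seeds.nrow(), nseed = seeds.ncol();
  int nseq = seqs.size();
  NumericVector out(nseed);
  double scale = 1.0 - bgx;
  double lp_hit = std::log(0.7 * scale), lp_miss = std::log(0.3 / 19.0 * scale);
  double lpi = std::log(pi0), l1mpi = std::log1p(-pi0);
  // concatenate sequences (windows never straddle the separator)
  std::vector<int> cat;
  std::vector<int> starts, nwins;
  for (int s = 0; s < nseq; ++s) {
    IntegerVector sq = seqs[s];
    starts.push_back((int)cat.size());
    nwins.push_back(std::max((int)sq.size() - w + 1, 0));
    for (int t = 0; t < sq.size(); ++t) cat.push_back(sq[t] - 1);
  }
  std::vector<double> lr(21 * w);
  for (int sd = 0; sd < nseed; ++sd) {
    for (int j = 0; j < w; ++j) {
      int obs = seeds(j, sd) - 1;
      double* col = &lr[21 * j];
      for (int a = 0; a < 20; ++a)
        col[a] = (a == obs ? lp_hit : lp_miss) - logbg[a];
      col[20] = 0.0;
    }
    double loglik = 0.0;
    for (int s = 0; s < nseq; ++s) {
      const int* base = cat.data() + starts[s];
      int nw = nwins[s];
      int i = 0;
      for (; i + 4 <= nw; i += 4) {  // 4 independent accumulator chains
        double a0 = 0, a1 = 0, a2 = 0, a3 = 0;
        for (int j = 0; j < w; ++j) {
          const double* col = &lr[21 * j];
          a0 += col[base[i + j]];
          a1 += col[base[i + 1 + j]];
          a2 += col[base[i + 2 + j]];
          a3 += col[base[i + 3 + j]];
        }
        loglik += lse2(lpi + a0, l1mpi) + lse2(lpi + a1, l1mpi) +
                  lse2(lpi + a2, l1mpi) + lse2(lpi + a3, l1mpi);
      }
      for (; i < nw; ++i) {
        double llr = 0.0;
        for (int j = 0; j < w; ++j) llr += lr[base[i + j] + 21 * j];
        loglik += lse2(lpi + llr, l1mpi);
      }
    }
    out[sd] = loglik;
  }
  return out;
}

// Profile-HMM Viterbi in local mode. mlo: 21 x L match log-odds (X row 0);
// t7: 7 x (L-1) log transition matrix, rows MM MI MD IM II DM DD, column k
// holding node k -> node k+1 transitions; lentry/lexit: log local entry/exit.
// Insert emissions score 0 (background); delete states are silent.
// Returns best log-odds and the 1-based inclusive residue span of the hit.
// [[Rcpp::export]]
List cpp_viterbi(IntegerVector seq, NumericMatrix mlo, NumericMatrix t7,
                 double lentry, double lexit) {
  int n = seq.size(), L = mlo.ncol();
  std::vector<double> Mp(L, NEG_INF), Ip(L, NEG_INF), Dp(L, NEG_INF);
  std::vector<double> Mc(L), Ic(L), Dc(L);
  std::vector<int> SMp(L, 0), SIp(L, 0), SDp(L, 0), SMc(L), SIc(L), SDc(L);
  double best = NEG_INF;
  int bstart = 0, bend = 0;
  for (int i = 1; i <= n; ++i) {
    int a = seq[i - 1] - 1;
    for (int k = 0; k < L; ++k) {
      double e = mlo(a, k);
      double v = lentry;  // fresh local entry at residue i
      int st = i;
      if (k > 0) {
        double c;
        c = Mp[k - 1] + t7(0, k - 1);
        if (c > v) { v = c; st = SMp[k - 1]; }
        c = Ip[k - 1] + t7(3, k - 1);
        if (c > v) { v = c; st = SIp[k - 1]; }
        c = Dp[k - 1] + t7(5, k - 1);
        if (c > v) { v = c; st = SDp[k - 1]; }
      }
      Mc[k] = e + v;
      SMc[k] = st;
      if (k < L - 1) {
        double vi = Mp[k] + t7(1, k);
        int si = SMp[k];
        double c = Ip[k] + t7(4, k);
        if (c > vi) { vi = c; si = SIp[k]; }
        Ic[k] = vi;  // insert emission is background: log-odds 0
        SIc[k] = si;
      } else { Ic[k] = NEG_INF; SIc[k] = 0; }
    }
    for (int k = 0; k < L; ++k) {
      if (k == 0) { Dc[k] = NEG_INF; SDc[k] = 0; continue; }
      double vd = Mc[k - 1] + t7(2, k - 1);
      int sd = SMc[k - 1];
      double c = Dc[k - 1] + t7(6, k - 1);
      if (c > vd) { vd = c; sd = SDc[k - 1]; }
      Dc[k] = vd;
      SDc[k] = sd;
    }
    for (int k = 0; k < L; ++k) {
      double s = Mc[k] + lexit;
      if (s > best ||
          (s == best && (SMc[k] < bstart || (SMc[k] == bstart && i < bend)))) {
        best = s; bstart = SMc[k]; bend = i;
      }
    }
    Mp.swap(Mc); Ip.swap(Ic); Dp.swap(Dc);
    SMp.swap(SMc); SIp.swap(SIc); SDp.swap(SDc);
  }
  return List::create(_["score"] = best, _["start"] = bstart, _["end"] = bend);
}

// Profile-HMM forward (log-sum over all local paths), same model as Viterbi.
// [[Rcpp::export]]
double cpp_forward(IntegerVector seq, NumericMatrix mlo, NumericMatrix t7,
                   double lentry, double lexit) {
  int n = seq.size(), L = mlo.ncol();
  std::vector<double> Mp(L, NEG_INF), Ip(L, NEG_INF), Dp(L, NEG_INF);
  std::vector<double> Mc(L), Ic(L), Dc(L);
  double total = NEG_INF;
  for (int i = 1; i <= n; ++i) {
    int a = seq[i - 1] - 1;
    for (int k = 0; k < L; ++k) {
      double v = lentry;
      if (k > 0) {
        v = lse2(v, Mp[k - 1] + t7(0, k - 1));
        v = lse2(v, Ip[k - 1] + t7(3, k - 1));
        v = lse2(v, Dp[k - 1] + t7(5, k - 1));
      }
      Mc[k] = mlo(a, k) + v;
      Ic[k] = (k < L - 1) ? lse2(Mp[k] + t7(1, k), Ip[k] + t7(4, k)) : NEG_INF;
    }
    for (int k = 0; k < L; ++k) {
      if (k == 0) { Dc[k] = NEG_INF; continue; }
      Dc[k] = lse2(Mc[k - 1] + t7(2, k - 1), Dc[k - 1] + t7(6, k - 1));
    }
    for (int k = 0; k < L; ++k) total = lse2(total, Mc[k] + lexit);
    Mp.swap(Mc); Ip.swap(Ic); Dp.swap(Dc);
  }
  return total;
}

// Global alignment of two profiles with affine gaps on a precomputed
// column-pair score matrix. A length-g gap costs gopen + (g-1)*gext.
// Path codes: 0 = aligned pair, 1 = gap in profile 2, 2 = gap in profile 1.
// [[Rcpp::export]]
IntegerVector cpp_nw_dp(NumericMatrix cs, double gopen, double gext) {
  int n1 = cs.nrow(), n2 = cs.ncol();
  NumericMatrix M(n1 + 1, n2 + 1), X(n1 + 1, n2 + 1), Y(n1 + 1, n2 + 1);
  IntegerMatrix pM(n1 + 1, n2 + 1), pX(n1 + 1, n2 + 1), pY(n1 + 1, n2 + 1);
  for (int i = 0; i <= n1; ++i)
    for (int j = 0; j <= n2; ++j) { M(i, j) = X(i, j) = Y(i, j) = NEG_INF; }
  M(0, 0) = 0.0;
  for (int i = 1; i <= n1; ++i) {
    X(i, 0) = -gopen - (i - 1) * gext;
    pX(i, 0) = (i == 1) ? 0 : 1;
  }
  for (int j = 1; j <= n2; ++j) {
    Y(0, j) = -gopen - (j - 1) * gext;
    pY(0, j) = (j == 1) ? 0 : 2;
  }
  for (int i = 1; i <= n1; ++i) {
    for (int j = 1; j <= n2; ++j) {
      // ties prefer M, then X, then Y (deterministic)
      double m = M(i - 1, j - 1); int pm = 0;
      if (X(i - 1, j - 1) > m) { m = X(i - 1, j - 1); pm = 1; }
      if (Y(i - 1, j - 1) > m) { m = Y(i - 1, j - 1); pm = 2; }
      M(i, j) = cs(i - 1, j - 1) + m;
      pM(i, j) = pm;
      double x = M(i - 1, j) - gopen; int px = 0;
      if (X(i - 1, j) - gext > x) { x = X(i - 1, j) - gext; px = 1; }
      if (Y(i - 1, j) - gopen > x) { x = Y(i - 1, j) - gopen; px = 2; }
      X(i, j) = x; pX(i, j) = px;
      double y = M(i, j - 1) - gopen; int py = 0;
      if (X(i, j - 1) - gopen > y) { y = X(i, j - 1) - gopen; py = 1; }
      if (Y(i, j - 1) - gext > y) { y = Y(i, j - 1) - gext; py = 2; }
      Y(i, j) = y; pY(i, j) = py;
    }
  }
  int state = 0;
  double bestv = M(n1, n2);
  if (X(n1, n2) > bestv) { bestv = X(n1, n2); state = 1; }
  if (Y(n1, n2) > bestv) { bestv = Y(n1, n2); state = 2; }
  std::vector<int> rev;
  int i = n1, j = n2;
  while (i > 0 || j > 0) {
    if (state == 0) {
      rev.push_back(0);
      int p = pM(i, j); --i; --j; state = p;
    } else if (state == 1) {
      rev.push_back(1);
      int p = pX(i, j); --i; state = p;
    } else {
      rev.push_back(2);
      int p = pY(i, j); --j; state = p;
    }
  }
  IntegerVector path(rev.size());
  for (size_t t = 0; t < rev.size(); ++t) path[t] = rev[rev.size() - 1 - t];
  return path;
}
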