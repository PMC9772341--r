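// Forward/Viterbi dynamic-programming kernels for the profile HMM.
// All inputs are log2-scale parameters prepared in R; silent delete
// states are resolved within each sequence position.
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static const double NEG_INF = -std::numeric_limits<double>::infinity();

static inline double l2sum(double a, double b) {
  if (a == NEG_INF) return b;
  if (b == NEG_INF) return a;
  double m = a > b ? a : b;
  return m + std::log2(std::exp2(a - m) + std::exp2(b - m));
}

// codes: 1..20 residue index, 0 = ambiguous (emits with prob 1/20 in
// every state, matching the null so the odds cancel).
// [[Rcpp::export(name = ".phmm_dp_cpp")]]
List phmm_dp_cpp(IntegerVector codes, NumericMatrix lem, NumericMatrix lei,
                 NumericVector lmm, NumericVector lmi, NumericVector lmd,
                 NumericVector lim, NumericVector lii,
                 NumericVector ldm, NumericVector ldd,
                 NumericVector lbg_seq, NumericVector lexit,
                 NumericVector lcont, double lq, double l1q,
                 double lentry, bool viterbi) {
  const int L = codes.size();
  const int M = lem.nrow();
  const double lamb = std::log2(1.0 / 20.0);

  std::vector<double> Mprev(M, NEG_INF), Iprev(std::max(M - 1, 0), NEG_INF),
      Dprev(M, NEG_INF), Mcur(M), Icur(std::max(M - 1, 0)), Dcur(M);
  double Nprev = 0.0, Cval = NEG_INF;

  IntegerMatrix btM, btD, btI;
  IntegerVector btE, btC;
  if (viterbi) {
    btM = IntegerMatrix(L, M);
    btD = IntegerMatrix(L, M);
    btI = IntegerMatrix(L, std::max(M - 1, 0));
    btE = IntegerVector(L);
    btC = IntegerVector(L);
  }

  for (int i = 0; i < L; ++i) {
    const int c = codes[i];
    const double entry = Nprev + l1q + lentry;
    const double Ncur = Nprev + lq + lbg_seq[i];

    for (int k = 0; k < M; ++k) {
      const double em = (c == 0) ? lamb : lem(k, c - 1);
      double best = entry;
      int who = 1;
      if (k > 0) {
        const double fm = Mprev[k - 1] + lcont[k - 1] + lmm[k - 1];
        const double fi = Iprev[k - 1] + lim[k - 1];
        const double fd = Dprev[k - 1] + ldm[k - 1];
        if (viterbi) {
          if (fm > best) { best = fm; who = 2; }
          if (fi > best) { best = fi; who = 3; }
          if (fd > best) { best = fd; who = 4; }
        } else {
          best = l2sum(l2sum(best, fm), l2sum(fi, fd));
        }
      }
      Mcur[k] = em + best;
      if (viterbi) btM(i, k) = who;
    }

    for (int k = 0; k < M - 1; ++k) {
      const double em = (c == 0) ? lamb : lei(k, c - 1);
      const double fm = Mprev[k] + lcont[k] + lmi[k];
      const double fi = Iprev[k] + lii[k];
      if (viterbi) {
        if (fm >= fi) { Icur[k] = em + fm; btI(i, k) = 1; }
        else { Icur[k] = em + fi; btI(i, k) = 2; }
      } else {
        Icur[k] = em + l2sum(fm, fi);
      }
    }

    Dcur[0] = NEG_INF;
    for (int k = 1; k < M; ++k) {
      const double fm = Mcur[k - 1] + lcont[k - 1] + lmd[k - 1];
      const double fd = Dcur[k - 1] + ldd[k - 1];
      if (viterbi) {
        if (fm >= fd) { Dcur[k] = fm; btD(i, k) = 1; }
        else { Dcur[k] = fd; btD(i, k) = 2; }
      } else {
        Dcur[k] = l2sum(fm, fd);
      }
    }

    double ev;
    if (viterbi) {
      ev = NEG_INF;
      int who = 1;
      for (int k = 0; k < M; ++k) {
        const double x = Mcur[k] + lexit[k];
        if (x > ev) { ev = x; who = k + 1; }
      }
      if (M > 1 && Dcur[M - 1] > ev) { ev = Dcur[M - 1]; who = M + 1; }
      btE[i] = who;
    } else {
      ev = NEG_INF;
      for (int k = 0; k < M; ++k) ev = l2sum(ev, Mcur[k] + lexit[k]);
      if (M > 1) ev = l2sum(ev, Dcur[M - 1]);
    }

    const double fromC = Cval + lq + lbg_seq[i];
    if (viterbi) {
      if (ev >= fromC) { Cval = ev; btC[i] = 1; }
      else { Cval = fromC; btC[i] = 2; }
    } else {
      Cval = l2sum(ev, fromC);
    }

    Nprev = Ncur;
    std::swap(Mprev, Mcur);
    std::swap(Iprev, Icur);
    std::swap(Dprev, Dcur);
  }

  const double logp = (L == 0) ? NEG_INF : Cval + l1q;
  if (viterbi) {
    return List::create(_["logp"] = logp, _["btM"] = btM, _["btD"] = btD,
                        _["btI"] = btI, _["btE"] = btE, _["btC"] = btC);
  }
  return List::create(_["logp"] = logp);
}
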