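#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Hypergeometric series used by the steady-state count distributions.
//
// Every series below is rearranged so that all terms are positive before
// summation (Kummer transform for 1F1 with negative argument, Pfaff transform
// for 2F1 with negative argument, and a Kummer-regularized double series for
// the 2F2 case). This keeps double precision sufficient: no alternating-sign
// cancellation ever occurs, so the relative error of each pmf entry is at the
// level of the series truncation tolerance (~1e-16).

static const int    MAX_TERMS = 100000;
static const double REL_TOL   = 1e-17;

// 1F1(a, c, z) for a > 0, c > 0, z >= 0: all-positive Kummer series.
static double hyp1f1_pos(double a, double c, double z) {
  if (z == 0.0 || a == 0.0) return 1.0;
  double term = 1.0, sum = 1.0;
  for (int k = 0; k < MAX_TERMS; ++k) {
    term *= (a + k) * z / ((c + k) * (k + 1.0));
    sum += term;
    if (term < sum * REL_TOL) break;
  }
  return sum;
}

// 2F1(a, b, c, x) for a,b,c > 0 and 0 <= x < 1: all-positive Gauss series.
static double hyp2f1_pos(double a, double b, double c, double x) {
  if (x == 0.0 || a == 0.0 || b == 0.0) return 1.0;
  double term = 1.0, sum = 1.0;
  for (int k = 0; k < MAX_TERMS; ++k) {
    term *= (a + k) * (b + k) * x / ((c + k) * (k + 1.0));
    sum += term;
    if (term < sum * REL_TOL) break;
  }
  return sum;
}

// log of the rising factorial (x)_n = x (x+1) ... (x+n-1), x > 0
static double lpoch(double x, double n) {
  return lgamma(x + n) - lgamma(x);
}

// Telegraph (Beta-Poisson) steady-state pmf for n = 0..nmax.
// P(n) = rho^n/n! (son)_n/(Ns)_n 1F1(son+n, Ns+n, -rho)
//      = e^{-rho} rho^n/n! (son)_n/(Ns)_n 1F1(soff, Ns+n, rho),
// the second form by the Kummer transform 1F1(a,c,-z) = e^{-z} 1F1(c-a,c,z);
// note c - a = soff independently of n.
// [[Rcpp::export]]
NumericVector tele_pmf_cpp(double rho, double son, double soff, int nmax) {
  NumericVector out(nmax + 1);
  if (rho == 0.0) { out[0] = 1.0; return out; }
  double ns = son + soff;
  double lrho = std::log(rho);
  for (int n = 0; n <= nmax; ++n) {
    double lc = -rho + n * lrho - lgamma(n + 1.0) + lpoch(son, n) - lpoch(ns, n);
    out[n] = std::exp(lc) * hyp1f1_pos(soff, ns + n, rho);
  }
  return out;
}

// Telegraph pmf integrated over pcap ~ Beta(a, b) (generalized hypergeometric
// closed form, evaluated as a Kummer-regularized double series):
// P(n) = rho^n/n! (son)_n (a)_n / ((Ns)_n (a+b)_n)
//          2F2(a+n, son+n; a+b+n, Ns+n; -rho)
//      = sum_k t_{n,k} e^{-rho} 1F1(b, a+b+n+k, rho),
// t_{n,k} = rho^{n+k}/(n! k!) (son)_n (soff)_k (a)_{n+k}
//           / ((Ns)_n (Ns+n)_k (a+b)_{n+k}),
// obtained by expanding 1F1(soff, Ns+n, rho p) inside the Beta integral and
// using E[p^m e^{-rho p}] = (a)_m/(a+b)_m e^{-rho} 1F1(b, a+b+m, rho).
// All terms positive.
// [[Rcpp::export]]
NumericVector tele_beta_pmf_cpp(double rho, double son, double soff,
                                double a, double b, int nmax) {
  NumericVector out(nmax + 1);
  if (rho == 0.0) { out[0] = 1.0; return out; }
  double ns = son + soff;
  double lrho = std::log(rho);
  for (int n = 0; n <= nmax; ++n) {
    // k = 0 term (log scale to avoid underflow of the prefactor)
    double lt0 = -rho + n * lrho - lgamma(n + 1.0)
      + lpoch(son, n) - lpoch(ns, n) + lpoch(a, n) - lpoch(a + b, n);
    double t = std::exp(lt0);
    double sum = 0.0;
    for (int k = 0; k < MAX_TERMS; ++k) {
      double f = hyp1f1_pos(b, a + b + n + k, rho);
      sum += t * f;
      if (t * f < sum * REL_TOL && k > 0) break;
      t *= rho * (soff + k) * (a + n + k) /
           ((ns + n + k) * (a + b + n + k) * (k + 1.0));
    }
    out[n] = sum;
  }
  return out;
}

// NB(r, p) pmf integrated over pcap ~ Beta(a, b), q = (1-p)/p:
// P(n) = q^n/n! (r)_n (a)_n/(a+b)_n 2F1(a+n, r+n; a+b+n; -q)
// with the Pfaff transform
// 2F1(a+n, r+n; a+b+n; -q) = p^{r+n} 2F1(b, r+n; a+b+n; 1-p),
// whose series has all-positive terms and argument 1-p in (0,1).
// [[Rcpp::export]]
NumericVector nb_beta_pmf_cpp(double r, double p, double a, double b, int nmax) {
  NumericVector out(nmax + 1);
  double q = (1.0 - p) / p;
  if (q == 0.0) { out[0] = 1.0; return out; }
  double lq = std::log(q), lp = std::log(p);
  for (int n = 0; n <= nmax; ++n) {
    double lc = n * lq - lgamma(n + 1.0) + lpoch(r, n)
      + lpoch(a, n) - lpoch(a + b, n) + (r + n) * lp;
    out[n] = std::exp(lc) * hyp2f1_pos(b, r + n, a + b + n, 1.0 - p);
  }
  return out;
}

// Poisson(lambda) pmf integrated over pcap ~ Beta(a, b):
// P(n) = lambda^n/n! (a)_n/(a+b)_n 1F1(a+n, a+b+n, -lambda)
//      = e^{-lambda} lambda^n/n! (a)_n/(a+b)_n 1F1(b, a+b+n, lambda).
// [[Rcpp::export]]
NumericVector pois_beta_pmf_cpp(double lambda, double a, double b, int nmax) {
  NumericVector out(nmax + 1);
  if (lambda == 0.0) { out[0] = 1.0; return out; }
  double ll = std::log(lambda);
  for (int n = 0; n <= nmax; ++n) {
    double lc = -lambda + n * ll - lgamma(n + 1.0)
      + lpoch(a, n) - lpoch(a + b, n);
    out[n] = std::exp(lc) * hyp1f1_pos(b, a + b + n, lambda);
  }
  return out;
}
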