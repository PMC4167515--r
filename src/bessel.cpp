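#include <Rcpp.h>
#include <cmath>
#include <vector>

// Fast evaluation of log I_nu(x) for a vector of non-negative integer
// orders at a single argument x > 0.  The EM inner loop evaluates the
// Skellam pmf over the whole grid of observed count differences at each
// candidate parameter value, so all orders are produced from one Miller
// backward recurrence (normalised by e^x = I_0 + 2 sum_k I_k) instead of
// one O(nu) Bessel call per order.  Orders >= 150 use the uniform
// large-order (Debye) expansion; very large arguments use the Hankel
// expansion, matching the pure-R reference implementation.

static const int UNIF_CUT = 150;     // orders >= this: uniform expansion
static const double HANKEL_X = 5e4;  // x above this (order < 150): Hankel

static double log_besseli_uniform(double x, double nu) {
  double w = x / nu;
  double s = std::sqrt(1.0 + w * w);
  double eta = s + std::log(w) - std::log1p(s);
  double t = 1.0 / s, t2 = t * t;
  double u1 = (3 * t - 5 * t * t2) / 24.0;
  double u2 = (81 * t2 - 462 * t2 * t2 + 385 * t2 * t2 * t2) / 1152.0;
  double t3 = t * t2, t5 = t3 * t2, t7 = t5 * t2, t9 = t7 * t2;
  double u3 = (30375 * t3 - 369603 * t5 + 765765 * t7 - 425425 * t9) / 414720.0;
  double t4 = t2 * t2;
  double u4 = (4465125 * t4 - 94121676 * t4 * t2 + 349922430 * t4 * t4 -
               446185740 * t4 * t4 * t2 + 185910725 * t4 * t4 * t4) / 39813120.0;
  double corr = 1.0 + u1 / nu + u2 / (nu * nu) + u3 / (nu * nu * nu) +
                u4 / (nu * nu * nu * nu);
  return -0.5 * std::log(2.0 * M_PI * nu) - 0.25 * std::log1p(w * w) +
         nu * eta + std::log(corr);
}

static double log_besseli_hankel(double x, double nu) {
  double mu = 4.0 * nu * nu;
  double s = 1.0, term = 1.0;
  for (int k = 1; k <= 10; ++k) {
    term *= -(mu - (2.0 * k - 1.0) * (2.0 * k - 1.0)) / (k * 8.0 * x);
    s += term;
  }
  return x - 0.5 * std::log(2.0 * M_PI * x) + std::log(s);
}

// two-term ascending series for very small arguments
static double log_besseli_small(double x, double nu) {
  return nu * std::log(x / 2.0) - R::lgammafn(nu + 1.0) +
         std::log1p(x * x / 4.0 / (nu + 1.0));
}

// Miller backward recurrence: fills lg[nu] = log I_nu(x) for nu = 0..K.
static void miller_block(double x, int K, std::vector<double> &lg) {
  const double BIG = 1e250, LBIG = std::log(1e250);
  int M = std::max(K, (int)std::ceil(x));
  M += 2 * (int)std::ceil(std::sqrt(40.0 * (M + 1))) + 20;
  double ip1 = 0.0, cur = 1e-280, off = 0.0, sum = 0.0;
  for (int nu = M; nu >= 0; --nu) {
    if (nu <= K) lg[nu] = std::log(cur) + off;
    sum += (nu == 0) ? cur : 2.0 * cur;
    if (nu > 0) {
      double nxt = ip1 + (2.0 * nu / x) * cur;
      ip1 = cur;
      cur = nxt;
      if (cur > BIG) {
        cur /= BIG; ip1 /= BIG; sum /= BIG;
        off += LBIG;
      }
    }
  }
  double lnorm = std::log(sum) + off;  // log of e^{-x}-unnormalised total
  for (int nu = 0; nu <= K; ++nu) lg[nu] += x - lnorm;
}

static void fill_log_besseli(double x, const int *nu, int n, double *out) {
  int K = -1;
  for (int i = 0; i < n; ++i) {
    if (nu[i] < UNIF_CUT && nu[i] > K) K = nu[i];
  }
  std::vector<double> lg;
  if (K >= 0 && x > 1e-8 && x <= HANKEL_X) {
    lg.resize(K + 1);
    miller_block(x, K, lg);
  }
  for (int i = 0; i < n; ++i) {
    double v = nu[i];
    if (v >= UNIF_CUT)      out[i] = log_besseli_uniform(x, v);
    else if (x <= 1e-8)     out[i] = log_besseli_small(x, v);
    else if (x > HANKEL_X)  out[i] = log_besseli_hankel(x, v);
    else                    out[i] = lg[(int)v];
  }
}

// [[Rcpp::export(name = ".cpp_log_besseli")]]
Rcpp::NumericVector cpp_log_besseli(double x, Rcpp::IntegerVector nu) {
  int n = nu.size();
  Rcpp::NumericVector out(n);
  fill_log_besseli(x, nu.begin(), n, out.begin());
  return out;
}

// responsibility-weighted Skellam log-likelihood at sum s, difference d
static double wloglik_s(double s, double d, const double *z, const int *nu,
                        const double *w, int n, std::vector<double> &buf) {
  double th1 = (s + d) / 2.0, th2 = (s - d) / 2.0;
  double x = std::sqrt(s * s - d * d);
  double lr = 0.5 * (std::log(th1) - std::log(th2));
  fill_log_besseli(x, nu, n, buf.data());
  double q = 0.0;
  for (int i = 0; i < n; ++i) q += w[i] * (-s + z[i] * lr + buf[i]);
  return q;
}

// Golden-section maximisation of the weighted Skellam log-likelihood over
// the mean sum s in [lo, hi] at fixed difference d; returns (s, q(s)).
// One call per component per M-step keeps the EM inner loop out of R.
// [[Rcpp::export(name = ".cpp_skellam_wmle")]]
Rcpp::NumericVector cpp_skellam_wmle(Rcpp::NumericVector z,
                                     Rcpp::IntegerVector nu,
                                     Rcpp::NumericVector w,
                                     double d, double lo, double hi,
                                     double tol) {
  int n = z.size();
  std::vector<double> buf(n);
  const double gr = 0.61803398874989484820;
  double a = lo, b = hi;
  double x1 = b - gr * (b - a), x2 = a + gr * (b - a);
  double f1 = wloglik_s(x1, d, z.begin(), nu.begin(), w.begin(), n, buf);
  double f2 = wloglik_s(x2, d, z.begin(), nu.begin(), w.begin(), n, buf);
  int guard = 0;
  while (b - a > tol * (1.0 + std::fabs(a)) && ++guard < 200) {
    if (f1 < f2) {
      a = x1; x1 = x2; f1 = f2;
      x2 = a + gr * (b - a);
      f2 = wloglik_s(x2, d, z.begin(), nu.begin(), w.begin(), n, buf);
    } else {
      b = x2; x2 = x1; f2 = f1;
      x1 = b - gr * (b - a);
      f1 = wloglik_s(x1, d, z.begin(), nu.begin(), w.begin(), n, buf);
    }
  }
  double s = (f1 > f2) ? x1 : x2;
  double q = (f1 > f2) ? f1 : f2;
  return Rcpp::NumericVector::create(s, q);
}
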