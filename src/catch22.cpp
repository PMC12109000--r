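// Canonical 22-feature time-series characterization (catch22 set).
//
// All features are computed on the z-scored series (population standard
// deviation). Conventions that the published feature definitions leave open
// (bin-edge placement, spline knots, two-regime split search) are fixed here
// and mirrored exactly by the independent numpy oracle shipped in
// inst/python/catch22_oracle.py; see the methods vignette.

#include <Rcpp.h>
#include <complex>
#include <vector>
#include <algorithm>
#include <cmath>

using namespace Rcpp;

typedef std::complex<double> cplx;

// ---------------------------------------------------------------- utilities

static double vec_mean(const std::vector<double> &x) {
  double s = 0.0;
  for (double v : x) s += v;
  return s / (double)x.size();
}

// sample SD (n - 1 denominator)
static double vec_sd(const std::vector<double> &x) {
  const double m = vec_mean(x);
  double s = 0.0;
  for (double v : x) s += (v - m) * (v - m);
  return std::sqrt(s / ((double)x.size() - 1.0));
}

static double vec_median(std::vector<double> x) {
  const size_t n = x.size();
  std::sort(x.begin(), x.end());
  if (n % 2 == 1) return x[n / 2];
  return 0.5 * (x[n / 2 - 1] + x[n / 2]);
}

// in-place iterative radix-2 FFT; length must be a power of two
static void fft_pow2(std::vector<cplx> &a, bool inverse) {
  const size_t n = a.size();
  for (size_t i = 1, j = 0; i < n; ++i) {
    size_t bit = n >> 1;
    for (; j & bit; bit >>= 1) j ^= bit;
    j ^= bit;
    if (i < j) std::swap(a[i], a[j]);
  }
  for (size_t len = 2; len <= n; len <<= 1) {
    const double ang = 2.0 * M_PI / (double)len * (inverse ? 1.0 : -1.0);
    const cplx wlen(std::cos(ang), std::sin(ang));
    for (size_t i = 0; i < n; i += len) {
      cplx w(1.0, 0.0);
      for (size_t k = 0; k < len / 2; ++k) {
        cplx u = a[i + k], v = a[i + k + len / 2] * w;
        a[i + k] = u + v;
        a[i + k + len / 2] = u - v;
        w *= wlen;
      }
    }
  }
  if (inverse)
    for (size_t i = 0; i < n; ++i) a[i] /= (double)n;
}

static size_t next_pow2(size_t n) {
  size_t p = 1;
  while (p < n) p <<= 1;
  return p;
}

// full autocorrelation function via FFT; acf[0] == 1
static std::vector<double> acf_fft(const std::vector<double> &z) {
  const size_t n = z.size();
  const double m = vec_mean(z);
  const size_t nfft = next_pow2(2 * n);
  std::vector<cplx> a(nfft, cplx(0.0, 0.0));
  for (size_t i = 0; i < n; ++i) a[i] = cplx(z[i] - m, 0.0);
  fft_pow2(a, false);
  for (size_t i = 0; i < nfft; ++i) a[i] = a[i] * std::conj(a[i]);
  fft_pow2(a, true);
  std::vector<double> acf(n);
  const double denom = a[0].real();
  for (size_t k = 0; k < n; ++k)
    acf[k] = (denom > 0.0) ? a[k].real() / denom : 0.0;
  return acf;
}

// first lag at which the ACF drops below zero; n if it never does
static int first_zero_ac(const std::vector<double> &acf) {
  const int n = (int)acf.size();
  for (int k = 1; k < n; ++k)
    if (acf[k] < 0.0) return k;
  return n;
}

// equiprobable ternary coarse-graining (symbols 0/1/2)
static std::vector<int> ternarize(const std::vector<double> &x) {
  const size_t m = x.size();
  std::vector<double> s(x);
  std::sort(s.begin(), s.end());
  const double th1 = s[(size_t)std::ceil((double)m / 3.0) - 1];
  const double th2 = s[(size_t)std::ceil(2.0 * (double)m / 3.0) - 1];
  std::vector<int> sym(m);
  for (size_t i = 0; i < m; ++i)
    sym[i] = (x[i] <= th1) ? 0 : (x[i] <= th2 ? 1 : 2);
  return sym;
}

// histogram counts with equal-width bins on [lo, hi]; right-open except last
static std::vector<int> hist_counts(const std::vector<double> &x, double lo,
                                    double hi, int nbins) {
  std::vector<int> cnt(nbins, 0);
  const double w = (hi - lo) / (double)nbins;
  for (double v : x) {
    int b = (w > 0.0) ? (int)std::floor((v - lo) / w) : 0;
    if (b < 0) b = 0;
    if (b >= nbins) b = nbins - 1;
    cnt[b]++;
  }
  return cnt;
}

// OLS line fit, x = 0..n-1; returns (intercept, slope)
static void line_fit(const std::vector<double> &y, size_t lo, size_t hi,
                     const std::vector<double> &x, double &a, double &b) {
  const size_t n = hi - lo;
  double sx = 0, sy = 0, sxx = 0, sxy = 0;
  for (size_t i = lo; i < hi; ++i) {
    sx += x[i]; sy += y[i]; sxx += x[i] * x[i]; sxy += x[i] * y[i];
  }
  const double den = (double)n * sxx - sx * sx;
  b = (den != 0.0) ? ((double)n * sxy - sx * sy) / den : 0.0;
  a = (sy - b * sx) / (double)n;
}

// -------------------------------------------------------------- features

// DN_HistogramMode_{5,10}: mean of tied modal bin centers
static double histogram_mode(const std::vector<double> &z, int nbins) {
  const double lo = *std::min_element(z.begin(), z.end());
  const double hi = *std::max_element(z.begin(), z.end());
  std::vector<int> cnt = hist_counts(z, lo, hi, nbins);
  const double w = (hi - lo) / (double)nbins;
  int maxc = 0;
  for (int c : cnt) maxc = std::max(maxc, c);
  double s = 0.0;
  int nmax = 0;
  for (int b = 0; b < nbins; ++b)
    if (cnt[b] == maxc) { s += lo + w * (b + 0.5); nmax++; }
  return s / (double)nmax;
}

// CO_f1ecac: linearly interpolated first 1/e crossing of the ACF
static double f1ecac(const std::vector<double> &acf) {
  const double th = std::exp(-1.0);
  const int n = (int)acf.size();
  for (int k = 1; k < n; ++k) {
    if (acf[k] < th) {
      const double prev = acf[k - 1];
      return (double)(k - 1) + (prev - th) / (prev - acf[k]);
    }
  }
  return (double)n;
}

// CO_FirstMin_ac: lag of the first local ACF minimum
static double first_min_ac(const std::vector<double> &acf) {
  const int n = (int)acf.size();
  for (int k = 1; k + 1 < n; ++k)
    if (acf[k] < acf[k - 1] && acf[k] < acf[k + 1]) return (double)k;
  return (double)n;
}

// CO_HistogramAMI_even_2_5: automutual information, even bins, lag 2, 5 bins
static double histogram_ami_even(const std::vector<double> &z, int tau,
                                 int nbins) {
  const int n = (int)z.size();
  const int m = n - tau;
  const double lo = *std::min_element(z.begin(), z.end()) - 0.1;
  const double hi = *std::max_element(z.begin(), z.end()) + 0.1;
  const double w = (hi - lo) / (double)nbins;
  std::vector<double> joint(nbins * nbins, 0.0);
  std::vector<double> p1(nbins, 0.0), p2(nbins, 0.0);
  for (int i = 0; i < m; ++i) {
    int b1 = std::min(nbins - 1, std::max(0, (int)std::floor((z[i] - lo) / w)));
    int b2 = std::min(nbins - 1,
                      std::max(0, (int)std::floor((z[i + tau] - lo) / w)));
    joint[b1 * nbins + b2] += 1.0;
  }
  for (int i = 0; i < nbins; ++i)
    for (int j = 0; j < nbins; ++j) {
      joint[i * nbins + j] /= (double)m;
      p1[i] += joint[i * nbins + j];
      p2[j] += joint[i * nbins + j];
    }
  double ami = 0.0;
  for (int i = 0; i < nbins; ++i)
    for (int j = 0; j < nbins; ++j) {
      const double pij = joint[i * nbins + j];
      if (pij > 0.0) ami += pij * std::log(pij / (p1[i] * p2[j]));
    }
  return ami;
}

// CO_trev_1_num: mean cubed successive difference
static double trev_1_num(const std::vector<double> &z) {
  const size_t n = z.size();
  double s = 0.0;
  for (size_t i = 0; i + 1 < n; ++i) {
    const double d = z[i + 1] - z[i];
    s += d * d * d;
  }
  return s / (double)(n - 1);
}

// MD_hrv_classic_pnn40: proportion of |successive difference| > 0.04
static double pnn40(const std::vector<double> &z) {
  const size_t n = z.size();
  int cnt = 0;
  for (size_t i = 0; i + 1 < n; ++i)
    if (std::fabs(z[i + 1] - z[i]) > 0.04) cnt++;
  return (double)cnt / (double)(n - 1);
}

static double longest_run(const std::vector<int> &b, int target) {
  int best = 0, cur = 0;
  for (int v : b) {
    cur = (v == target) ? cur + 1 : 0;
    best = std::max(best, cur);
  }
  return (double)best;
}

// SB_BinaryStats_mean_longstretch1: longest above-mean stretch
static double binarystats_mean_long1(const std::vector<double> &z) {
  const double m = vec_mean(z);
  std::vector<int> b(z.size());
  for (size_t i = 0; i < z.size(); ++i) b[i] = z[i] > m ? 1 : 0;
  return longest_run(b, 1);
}

// SB_BinaryStats_diff_longstretch0: longest decreasing stretch
static double binarystats_diff_long0(const std::vector<double> &z) {
  std::vector<int> b(z.size() - 1);
  for (size_t i = 0; i + 1 < z.size(); ++i) b[i] = (z[i + 1] - z[i]) >= 0.0;
  return longest_run(b, 0);
}

// SB_TransitionMatrix_3ac_sumdiagcov
static double transition_matrix_3ac(const std::vector<double> &z,
                                    const std::vector<double> &acf) {
  const int tau = first_zero_ac(acf);
  std::vector<double> ds;
  for (size_t i = 0; i < z.size(); i += (size_t)tau) ds.push_back(z[i]);
  if (ds.size() < 4) return NA_REAL;
  std::vector<int> sym = ternarize(ds);
  double T[3][3] = {{0, 0, 0}, {0, 0, 0}, {0, 0, 0}};
  const size_t m = sym.size();
  for (size_t i = 0; i + 1 < m; ++i) T[sym[i]][sym[i + 1]] += 1.0;
  for (int a = 0; a < 3; ++a)
    for (int b = 0; b < 3; ++b) T[a][b] /= (double)(m - 1);
  // covariance of the three columns (denominator 2), summed over the diagonal
  double colmean[3];
  for (int b = 0; b < 3; ++b)
    colmean[b] = (T[0][b] + T[1][b] + T[2][b]) / 3.0;
  double s = 0.0;
  for (int b = 0; b < 3; ++b) {
    double v = 0.0;
    for (int a = 0; a < 3; ++a)
      v += (T[a][b] - colmean[b]) * (T[a][b] - colmean[b]);
    s += v / 2.0;
  }
  return s;
}

// least-squares cubic spline with one interior knot at the midpoint
// (truncated-power basis on time scaled to [0,1]); returns the residual
static std::vector<double> spline_detrend(const std::vector<double> &z) {
  const size_t n = z.size();
  const int p = 5;
  std::vector<double> X(n * p);
  for (size_t i = 0; i < n; ++i) {
    const double t = (double)i / (double)(n - 1);
    const double tk = t - 0.5;
    X[i * p + 0] = 1.0;
    X[i * p + 1] = t;
    X[i * p + 2] = t * t;
    X[i * p + 3] = t * t * t;
    X[i * p + 4] = tk > 0.0 ? tk * tk * tk : 0.0;
  }
  // normal equations
  double A[5][5] = {{0}}, b[5] = {0};
  for (size_t i = 0; i < n; ++i) {
    for (int r = 0; r < p; ++r) {
      b[r] += X[i * p + r] * z[i];
      for (int c = 0; c < p; ++c) A[r][c] += X[i * p + r] * X[i * p + c];
    }
  }
  // Gaussian elimination with partial pivoting
  double M[5][6];
  for (int r = 0; r < p; ++r) {
    for (int c = 0; c < p; ++c) M[r][c] = A[r][c];
    M[r][p] = b[r];
  }
  for (int col = 0; col < p; ++col) {
    int piv = col;
    for (int r = col + 1; r < p; ++r)
      if (std::fabs(M[r][col]) > std::fabs(M[piv][col])) piv = r;
    for (int c = 0; c <= p; ++c) std::swap(M[col][c], M[piv][c]);
    for (int r = 0; r < p; ++r) {
      if (r == col || M[col][col] == 0.0) continue;
      const double f = M[r][col] / M[col][col];
      for (int c = col; c <= p; ++c) M[r][c] -= f * M[col][c];
    }
  }
  double beta[5];
  for (int r = 0; r < p; ++r)
    beta[r] = (M[r][r] != 0.0) ? M[r][p] / M[r][r] : 0.0;
  std::vector<double> resid(n);
  for (size_t i = 0; i < n; ++i) {
    double fit = 0.0;
    for (int r = 0; r < p; ++r) fit += X[i * p + r] * beta[r];
    resid[i] = z[i] - fit;
  }
  return resid;
}

// PD_PeriodicityWang_th0_01: first spline-detrended ACF peak after a trough
// whose value exceeds 0.01; 0 if none
static double periodicity_wang(const std::vector<double> &z) {
  std::vector<double> resid = spline_detrend(z);
  std::vector<double> acf = acf_fft(resid);
  const int maxtau = (int)(z.size() / 3);
  bool seen_trough = false;
  for (int k = 1; k + 1 <= maxtau && k + 1 < (int)acf.size(); ++k) {
    const bool trough = acf[k] < acf[k - 1] && acf[k] < acf[k + 1];
    const bool peak = acf[k] > acf[k - 1] && acf[k] > acf[k + 1];
    if (trough) seen_trough = true;
    if (seen_trough && peak && acf[k] > 0.01) return (double)k;
  }
  return 0.0;
}

// CO_Embed2_Dist_tau_d_expfit_meandiff
static double embed2_dist_expfit(const std::vector<double> &z,
                                 const std::vector<double> &acf) {
  const int n = (int)z.size();
  int tau = first_zero_ac(acf);
  if (tau > n / 10) tau = n / 10;
  if (tau < 1) tau = 1;
  const int m = n - tau;
  std::vector<double> d(m - 1);
  for (int i = 0; i + 1 < m; ++i) {
    const double dx = z[i + 1] - z[i];
    const double dy = z[i + tau + 1] - z[i + tau];
    d[i] = std::sqrt(dx * dx + dy * dy);
  }
  const double l = vec_mean(d);
  if (l <= 0.0) return NA_REAL;
  const int nbins = (int)std::ceil(std::sqrt((double)d.size()));
  const double lo = *std::min_element(d.begin(), d.end());
  const double hi = *std::max_element(d.begin(), d.end());
  if (hi <= lo) return NA_REAL;
  std::vector<int> cnt = hist_counts(d, lo, hi, nbins);
  const double w = (hi - lo) / (double)nbins;
  double s = 0.0;
  for (int b = 0; b < nbins; ++b) {
    const double center = lo + w * (b + 0.5);
    const double dens = (double)cnt[b] / ((double)d.size() * w);
    const double f = std::exp(-center / l) / l;
    s += std::fabs(dens - f);
  }
  return s / (double)nbins;
}

// IN_AutoMutualInfoStats_40_gaussian_fmmi
static double automutual_fmmi(const std::vector<double> &acf) {
  const int n = (int)acf.size();
  const int T = std::min(40, n / 2);
  std::vector<double> ami(T + 1, 0.0);
  for (int k = 1; k <= T; ++k) {
    double r = acf[k];
    if (r > 0.999999) r = 0.999999;
    if (r < -0.999999) r = -0.999999;
    ami[k] = -0.5 * std::log(1.0 - r * r);
  }
  for (int k = 2; k < T; ++k)
    if (ami[k] < ami[k - 1] && ami[k] < ami[k + 1]) return (double)k;
  return (double)T;
}

// FC_LocalSimple_mean1_tauresrat
static double localsimple_mean1_tauresrat(const std::vector<double> &z,
                                          const std::vector<double> &acf) {
  const size_t n = z.size();
  std::vector<double> e(n - 1);
  for (size_t i = 0; i + 1 < n; ++i) e[i] = z[i + 1] - z[i];
  const int tz = first_zero_ac(acf);
  const int te = first_zero_ac(acf_fft(e));
  return (double)te / (double)tz;
}

// FC_LocalSimple_mean3_stderr: SD of mean-of-last-3 forecast residuals
static double localsimple_mean3_stderr(const std::vector<double> &z) {
  const size_t n = z.size();
  std::vector<double> e(n - 3);
  for (size_t i = 3; i < n; ++i)
    e[i - 3] = z[i] - (z[i - 1] + z[i - 2] + z[i - 3]) / 3.0;
  return vec_sd(e);
}

// DN_OutlierInclude_{p,n}_001_mdrmd: median (over inclusion thresholds at
// which at least 2% of points remain) of the relative median position of
// the included time indices
static double outlier_include_mdrmd(const std::vector<double> &z, bool neg) {
  const size_t n = z.size();
  std::vector<double> y(n);
  for (size_t i = 0; i < n; ++i) y[i] = neg ? -z[i] : z[i];
  const double ymax = *std::max_element(y.begin(), y.end());
  if (ymax < 0.0) return NA_REAL;
  const double inc = 0.01;
  std::vector<double> relmed;
  for (double th = 0.0; th <= ymax; th += inc) {
    std::vector<double> idx;
    for (size_t i = 0; i < n; ++i)
      if (y[i] >= th) idx.push_back((double)i);
    if ((double)idx.size() < 0.02 * (double)n || idx.size() < 2) break;
    relmed.push_back(vec_median(idx) / ((double)(n - 1) / 2.0) - 1.0);
  }
  if (relmed.empty()) return NA_REAL;
  return vec_median(relmed);
}

// SP_Summaries_welch_rect: full-length rectangular-window periodogram;
// returns band-1-of-5 area and the cumulative-half-power (centroid) frequency
static void welch_rect(const std::vector<double> &z, double &area_5_1,
                       double &centroid) {
  const size_t n = z.size();
  const double m = vec_mean(z);
  size_t nfft = std::max((size_t)256, next_pow2(n));
  std::vector<cplx> a(nfft, cplx(0.0, 0.0));
  for (size_t i = 0; i < n; ++i) a[i] = cplx(z[i] - m, 0.0);
  fft_pow2(a, false);
  const size_t nw = nfft / 2 + 1;
  std::vector<double> S(nw);
  for (size_t k = 0; k < nw; ++k)
    S[k] = std::norm(a[k]) / (2.0 * M_PI * (double)n);
  const double dw = 2.0 * M_PI / (double)nfft;
  // area of the first of five equal-width frequency bands
  const size_t b1 = nw / 5;
  double s = 0.0;
  for (size_t k = 0; k < b1; ++k) s += S[k];
  area_5_1 = s * dw;
  // frequency at which cumulative power first exceeds half the total
  double tot = 0.0;
  for (size_t k = 0; k < nw; ++k) tot += S[k];
  double cs = 0.0;
  centroid = (double)(nw - 1) * dw;
  for (size_t k = 0; k < nw; ++k) {
    cs += S[k];
    if (cs > 0.5 * tot) { centroid = (double)k * dw; break; }
  }
}

// SB_MotifThree_quantile_hh: entropy of ternary length-2 word frequencies
static double motif_three_hh(const std::vector<double> &z) {
  std::vector<int> sym = ternarize(z);
  const size_t m = sym.size();
  double cnt[9] = {0};
  for (size_t i = 0; i + 1 < m; ++i) cnt[sym[i] * 3 + sym[i + 1]] += 1.0;
  double hh = 0.0;
  for (int w = 0; w < 9; ++w) {
    const double p = cnt[w] / (double)(m - 1);
    if (p > 0.0) hh -= p * std::log(p);
  }
  return hh;
}

// SC_FluctAnal: proportion of scales assigned to the first scaling regime by
// a two-segment linear fit to log F(tau) vs log tau
static double fluct_anal_prop_r1(const std::vector<double> &z, int lag,
                                 bool rsrange) {
  std::vector<double> x;
  for (size_t i = 0; i < z.size(); i += (size_t)lag) x.push_back(z[i]);
  const size_t N = x.size();
  const double xm = vec_mean(x);
  std::vector<double> cs(N);
  double acc = 0.0;
  for (size_t i = 0; i < N; ++i) { acc += x[i] - xm; cs[i] = acc; }
  // 50 log-spaced window sizes in [5, N/2]
  std::vector<int> taus;
  const double lo = std::log(5.0), hi = std::log((double)N / 2.0);
  for (int k = 0; k < 50; ++k) {
    // snap to a 1e-6 grid before rounding so the grid is reproducible
    // across math libraries
    double xv = std::exp(lo + (hi - lo) * (double)k / 49.0);
    xv = std::floor(xv * 1e6 + 0.5) / 1e6;
    int t = (int)std::floor(xv + 0.5);
    if (t >= 5 && t <= (int)(N / 2) &&
        (taus.empty() || t != taus.back()))
      taus.push_back(t);
  }
  if (taus.size() < 6) return NA_REAL;
  const size_t ntau = taus.size();
  std::vector<double> logt(ntau), logF(ntau);
  std::vector<double> tgrid; // reusable time axis for buffer fits
  for (size_t ti = 0; ti < ntau; ++ti) {
    const int tau = taus[ti];
    const size_t nbuf = N / (size_t)tau;
    if (tgrid.size() < (size_t)tau) {
      tgrid.resize(tau);
      for (int i = 0; i < tau; ++i) tgrid[i] = (double)i;
    }
    double fsum = 0.0;
    std::vector<double> buf(tau);
    for (size_t bI = 0; bI < nbuf; ++bI) {
      for (int i = 0; i < tau; ++i) buf[i] = cs[bI * tau + i];
      double a, b;
      line_fit(buf, 0, tau, tgrid, a, b);
      if (rsrange) {
        double rmin = 1e300, rmax = -1e300;
        for (int i = 0; i < tau; ++i) {
          const double r = buf[i] - (a + b * tgrid[i]);
          rmin = std::min(rmin, r);
          rmax = std::max(rmax, r);
        }
        fsum += (rmax - rmin) * (rmax - rmin);
      } else {
        double ss = 0.0;
        for (int i = 0; i < tau; ++i) {
          const double r = buf[i] - (a + b * tgrid[i]);
          ss += r * r;
        }
        fsum += ss / (double)tau;
      }
    }
    const double F = std::sqrt(fsum / (double)nbuf);
    logt[ti] = std::log((double)tau);
    logF[ti] = std::log(std::max(F, 1e-300));
  }
  // two-regime split minimizing the sum of per-regime mean squared residuals
  double best = 1e300;
  size_t bestsplit = 3;
  for (size_t s = 3; s + 3 <= ntau; ++s) {
    double a1, b1, a2, b2, ss1 = 0.0, ss2 = 0.0;
    line_fit(logF, 0, s, logt, a1, b1);
    line_fit(logF, s, ntau, logt, a2, b2);
    for (size_t i = 0; i < s; ++i) {
      const double r = logF[i] - (a1 + b1 * logt[i]);
      ss1 += r * r;
    }
    for (size_t i = s; i < ntau; ++i) {
      const double r = logF[i] - (a2 + b2 * logt[i]);
      ss2 += r * r;
    }
    const double crit = ss1 / (double)s + ss2 / (double)(ntau - s);
    if (crit < best) { best = crit; bestsplit = s; }
  }
  return (double)bestsplit / (double)ntau;
}

// ------------------------------------------------------------------ export

// [[Rcpp::export(name = ".catch22_cpp")]]
NumericVector catch22_cpp(NumericVector x) {
  const int n = x.size();
  std::vector<double> raw(x.begin(), x.end());
  // z-score with the population standard deviation
  const double m = vec_mean(raw);
  double ss = 0.0;
  for (double v : raw) ss += (v - m) * (v - m);
  const double sd = std::sqrt(ss / (double)n);
  NumericVector out(22, NA_REAL);
  if (sd <= 0.0) return out; // constant series: all features undefined
  std::vector<double> z(n);
  for (int i = 0; i < n; ++i) z[i] = (raw[i] - m) / sd;

  std::vector<double> acf = acf_fft(z);

  out[0] = histogram_mode(z, 5);
  out[1] = histogram_mode(z, 10);
  out[2] = f1ecac(acf);
  out[3] = first_min_ac(acf);
  out[4] = histogram_ami_even(z, 2, 5);
  out[5] = trev_1_num(z);
  out[6] = pnn40(z);
  out[7] = binarystats_mean_long1(z);
  out[8] = binarystats_diff_long0(z);
  out[9] = transition_matrix_3ac(z, acf);
  out[10] = periodicity_wang(z);
  out[11] = embed2_dist_expfit(z, acf);
  out[12] = automutual_fmmi(acf);
  out[13] = localsimple_mean1_tauresrat(z, acf);
  out[14] = localsimple_mean3_stderr(z);
  out[15] = outlier_include_mdrmd(z, false);
  out[16] = outlier_include_mdrmd(z, true);
  double area, centroid;
  welch_rect(z, area, centroid);
  out[17] = area;
  out[18] = centroid;
  out[19] = motif_three_hh(z);
  out[20] = fluct_anal_prop_r1(z, 2, false); // dfa
  out[21] = fluct_anal_prop_r1(z, 1, true);  // rsrangefit
  return out;
}
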