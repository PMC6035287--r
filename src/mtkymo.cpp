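// Compiled core for the Monte-Carlo taper pipeline: lattice rendering with
// pixel-integrated Gaussian PSF, a variable-projection error-function tip
// fitter, and the render -> fit -> normalize -> average loop that the
// (N, d) residual grid search calls hundreds of thousands of times.
//
// All randomness goes through R's RNG (unif_rand / norm_rand / exp_rand),
// so results are reproducible with set.seed() from R.

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <limits>

using namespace Rcpp;

static const int N_PF = 13;
static const double DIMER = 8.0;

// Gaussian CDF
static inline double phi(double z) { return 0.5 * std::erfc(-z * M_SQRT1_2); }

// [[Rcpp::export]]
NumericVector cpp_render_positions(NumericVector pos, int npx,
                                   double pixel_size, double psf_sigma) {
  NumericVector out(npx);
  const double support = 5.0 * psf_sigma;
  for (int i = 0; i < pos.size(); ++i) {
    const double p = pos[i];
    int k0 = (int)std::floor((p - support) / pixel_size);
    int k1 = (int)std::ceil((p + support) / pixel_size);
    if (k0 < 0) k0 = 0;
    if (k1 > npx) k1 = npx;
    for (int k = k0; k < k1; ++k) {
      const double lo = k * pixel_size, hi = (k + 1) * pixel_size;
      out[k] += phi((hi - p) / psf_sigma) - phi((lo - p) / psf_sigma);
    }
  }
  return out;
}

// ---- variable-projection erf edge fit --------------------------------

struct ErfFit {
  double I_BG, I_AMP, x_c, sigma, rss;
  bool ok;
};

// Solve min over (a0, a1) of || y - a0 - a1 * b ||^2. Returns rss; a0, a1 by ref.
static double linear_solve(const std::vector<double>& b,
                           const double* y, int n,
                           double& a0, double& a1) {
  double sb = 0, sbb = 0, sy = 0, sby = 0, syy = 0;
  for (int i = 0; i < n; ++i) {
    sb += b[i]; sbb += b[i] * b[i];
    sy += y[i]; sby += b[i] * y[i]; syy += y[i] * y[i];
  }
  const double det = n * sbb - sb * sb;
  if (det <= 1e-12 * (n * sbb + 1e-300)) {
    a0 = sy / n; a1 = 0;
    return syy - sy * sy / n;
  }
  a1 = (n * sby - sb * sy) / det;
  a0 = (sy - a1 * sb) / n;
  double rss = 0;
  for (int i = 0; i < n; ++i) {
    const double r = y[i] - a0 - a1 * b[i];
    rss += r * r;
  }
  return rss;
}

// rss of the erf model at (xc, sigma) with profiled linear parameters.
// dir = +1: rising edge basis 0.5*(1+erf); dir = -1: falling (erfc).
static double erf_rss(const double* x, const double* y, int n, int dir,
                      double xc, double sigma, double& a0, double& a1) {
  std::vector<double> b(n);
  const double s = M_SQRT2 * sigma;
  for (int i = 0; i < n; ++i) {
    const double z = (x[i] - xc) / s;
    b[i] = (dir > 0) ? phi(z * M_SQRT2) : 1.0 - phi(z * M_SQRT2);
  }
  return linear_solve(b, y, n, a0, a1);
}

// Nelder-Mead over (xc, log sigma) with box penalty on sigma.
static ErfFit fit_erf_core(const double* x, const double* y, int n, int dir,
                           double xc0, double sigma0,
                           double sigma_lo, double sigma_hi) {
  const double ls_lo = std::log(sigma_lo), ls_hi = std::log(sigma_hi);
  double a0 = 0, a1 = 0;
  auto obj = [&](double xc, double ls) {
    double pen = 0;
    if (ls < ls_lo) { pen = 1e6 * (ls_lo - ls) * (ls_lo - ls); ls = ls_lo; }
    if (ls > ls_hi) { pen = 1e6 * (ls - ls_hi) * (ls - ls_hi); ls = ls_hi; }
    double aa0, aa1;
    const double r = erf_rss(x, y, n, dir, xc, std::exp(ls), aa0, aa1);
    return r * (1.0 + pen);
  };
  // initial simplex
  double px[3] = { xc0, xc0 + 40.0, xc0 };
  double py[3] = { std::log(sigma0), std::log(sigma0), std::log(sigma0) + 0.35 };
  double fv[3];
  for (int i = 0; i < 3; ++i) fv[i] = obj(px[i], py[i]);
  for (int iter = 0; iter < 200; ++iter) {
    // order
    int lo = 0, hi = 0;
    for (int i = 1; i < 3; ++i) {
      if (fv[i] < fv[lo]) lo = i;
      if (fv[i] > fv[hi]) hi = i;
    }
    if (std::fabs(fv[hi] - fv[lo]) <= 1e-10 * (std::fabs(fv[lo]) + 1e-12))
      break;
    const double cx = (px[0] + px[1] + px[2] - px[hi]) / 2.0;
    const double cy = (py[0] + py[1] + py[2] - py[hi]) / 2.0;
    double rx = cx + (cx - px[hi]), ry = cy + (cy - py[hi]);
    double fr = obj(rx, ry);
    if (fr < fv[lo]) {
      const double ex = cx + 2.0 * (cx - px[hi]), ey = cy + 2.0 * (cy - py[hi]);
      const double fe = obj(ex, ey);
      if (fe < fr) { px[hi] = ex; py[hi] = ey; fv[hi] = fe; }
      else { px[hi] = rx; py[hi] = ry; fv[hi] = fr; }
    } else {
      // second worst
      int sw = 3 - lo - hi;
      if (hi == lo) sw = (lo + 1) % 3;
      if (fr < fv[sw]) { px[hi] = rx; py[hi] = ry; fv[hi] = fr; }
      else {
        const double kx = cx + 0.5 * (px[hi] - cx), ky = cy + 0.5 * (py[hi] - cy);
        const double fk = obj(kx, ky);
        if (fk < fv[hi]) { px[hi] = kx; py[hi] = ky; fv[hi] = fk; }
        else { // shrink toward best
          for (int i = 0; i < 3; ++i) {
            if (i == lo) continue;
            px[i] = px[lo] + 0.5 * (px[i] - px[lo]);
            py[i] = py[lo] + 0.5 * (py[i] - py[lo]);
            fv[i] = obj(px[i], py[i]);
          }
        }
      }
    }
  }
  int lo = 0;
  for (int i = 1; i < 3; ++i) if (fv[i] < fv[lo]) lo = i;
  ErfFit f;
  double ls = py[lo];
  if (ls < ls_lo) ls = ls_lo;
  if (ls > ls_hi) ls = ls_hi;
  f.x_c = px[lo];
  f.sigma = std::exp(ls);
  f.rss = erf_rss(x, y, n, dir, f.x_c, f.sigma, a0, a1);
  f.I_BG = a0; f.I_AMP = a1;
  const bool pinned = (f.sigma <= sigma_lo * 1.02) || (f.sigma >= sigma_hi * 0.98);
  f.ok = std::isfinite(f.rss) && f.I_AMP > 0 && !pinned &&
         f.x_c > x[0] - 2.0 * (x[n - 1] - x[0]) &&
         f.x_c < x[n - 1] + 2.0 * (x[n - 1] - x[0]);
  return f;
}

static ErfFit fit_erf_multistart(const double* x, const double* y, int n,
                                 int dir, const std::vector<double>& xc_inits,
                                 double sigma0, double sigma_lo,
                                 double sigma_hi) {
  ErfFit best; best.rss = std::numeric_limits<double>::infinity(); best.ok = false;
  best.I_BG = best.I_AMP = best.x_c = best.sigma = NA_REAL;
  for (double xc0 : xc_inits) {
    ErfFit f = fit_erf_core(x, y, n, dir, xc0, sigma0, sigma_lo, sigma_hi);
    if (std::isfinite(f.rss) && f.rss < best.rss) best = f;
  }
  return best;
}

// [[Rcpp::export]]
List cpp_fit_erf(NumericVector x, NumericVector y, int direction,
                 NumericVector xc_inits, double sigma_init,
                 double sigma_lo, double sigma_hi) {
  std::vector<double> inits(xc_inits.begin(), xc_inits.end());
  ErfFit f = fit_erf_multistart(REAL(x), REAL(y), x.size(), direction, inits,
                                sigma_init, sigma_lo, sigma_hi);
  return List::create(_["I_BG"] = f.I_BG, _["I_AMP"] = f.I_AMP,
                      _["x_c"] = f.x_c, _["sigma"] = f.sigma,
                      _["rss"] = f.rss, _["ok"] = f.ok);
}

// ---- Monte-Carlo averaged model profile ------------------------------

// Render one simulated tip profile and fit it; on success append the
// normalized, tip-aligned profile onto the accumulation grid.
// [[Rcpp::export]]
List cpp_sim_avg_profile(int model_b, int N, double d, NumericVector lengths,
                         double label_frac, double psf_sigma,
                         double pixel_size, double snr, int iterations,
                         NumericVector grid, double window) {
  const int ng = grid.size();
  const int m = lengths.size();
  if (m < 1) stop("mt_lengths must be non-empty");
  if (N < 0 || N > N_PF) stop("N must be in 0..13");

  std::vector<double> tot_sum(ng, 0.0);
  std::vector<int> tot_cnt(ng, 0);
  std::vector<double> tot_sq(ng, 0.0);
  std::vector<double> it_sum(ng), it_cnt(ng);
  int n_flagged = 0;

  const double expected_plateau = label_frac * N_PF * pixel_size / DIMER;
  const double support = 5.0 * psf_sigma;

  for (int iter = 0; iter < iterations; ++iter) {
    std::fill(it_sum.begin(), it_sum.end(), 0.0);
    std::fill(it_cnt.begin(), it_cnt.end(), 0.0);
    int m_used = 0;

    for (int j = 0; j < m; ++j) {
      const double L = lengths[j];   // one profile per experimental length
      const int n_dimers = (int)std::floor(L / DIMER);

      int miss[N_PF];
      double max_miss = 0;
      for (int p = 0; p < N_PF; ++p) {
        if (p < N) {
          double raw = (model_b ? (d > 0 ? exp_rand() * d : 0.0) : d);
          if (raw > L) raw = L;
          miss[p] = (int)std::lround(raw / DIMER);
          if (miss[p] > n_dimers) miss[p] = n_dimers;
        } else miss[p] = 0;
        if (miss[p] * DIMER > max_miss) max_miss = miss[p] * DIMER;
      }

      // pixel windows (pixel k covers [k, k+1) * pixel_size)
      int k0 = (int)std::floor((L - window) / pixel_size);
      int k1 = (int)std::floor((L + window) / pixel_size);
      if (k0 < 0) k0 = 0;
      const int npw = k1 - k0 + 1;
      // plateau pixels: >= 4 sigma behind the most eroded tip
      const double pl_hi = L - max_miss - 4.0 * psf_sigma;
      int pk1 = (int)std::floor(pl_hi / pixel_size) - 1;
      int pk0 = pk1 - 4;
      double x_lo_needed = (L - window);
      if (pk0 >= 0 && pk0 * pixel_size < x_lo_needed)
        x_lo_needed = pk0 * pixel_size;

      // label sites from x_lo_needed - support up
      int ks = (int)std::floor((x_lo_needed - support) / DIMER);
      if (ks < 0) ks = 0;                 // dimer index 0-based: site k -> (k+0.5)*8
      std::vector<int> cnt(n_dimers > ks ? n_dimers - ks : 0, 0);
      for (int p = 0; p < N_PF; ++p) {
        const int kend = n_dimers - miss[p];
        for (int k = ks; k < kend; ++k)
          if (unif_rand() < label_frac) cnt[k - ks]++;
      }

      std::vector<double> yw(npw, 0.0);
      double pl_sum = 0; int pl_n = 0;
      for (size_t ci = 0; ci < cnt.size(); ++ci) {
        if (!cnt[ci]) continue;
        const double pos = ((ks + ci) + 0.5) * DIMER;
        const double w = (double)cnt[ci];
        int a = (int)std::floor((pos - support) / pixel_size);
        int b = (int)std::ceil((pos + support) / pixel_size);
        for (int k = a; k <= b; ++k) {
          const double mlo = phi((k * pixel_size - pos) / psf_sigma);
          const double mhi = phi(((k + 1) * pixel_size - pos) / psf_sigma);
          const double mass = w * (mhi - mlo);
          if (k >= k0 && k <= k1) yw[k - k0] += mass;
        }
      }
      if (pk0 >= 0 && pk1 >= pk0) {
        // accumulate plateau region separately (exact, same kernel)
        std::vector<double> yp(pk1 - pk0 + 1, 0.0);
        for (size_t ci = 0; ci < cnt.size(); ++ci) {
          if (!cnt[ci]) continue;
          const double pos = ((ks + ci) + 0.5) * DIMER;
          const double w = (double)cnt[ci];
          for (int k = pk0; k <= pk1; ++k) {
            if (std::fabs((k + 0.5) * pixel_size - pos) > support + pixel_size)
              continue;
            const double mlo = phi((k * pixel_size - pos) / psf_sigma);
            const double mhi = phi(((k + 1) * pixel_size - pos) / psf_sigma);
            yp[k - pk0] += w * (mhi - mlo);
          }
        }
        for (double v : yp) { pl_sum += v; pl_n++; }
      }
      const double plateau = pl_n > 0 ? pl_sum / pl_n : expected_plateau;
      const double noise_sd = R_FINITE(snr) ? plateau / snr : 0.0;
      if (noise_sd > 0)
        for (int k = 0; k < npw; ++k) yw[k] += norm_rand() * noise_sd;

      // fit falling erf edge
      std::vector<double> xw(npw);
      for (int k = 0; k < npw; ++k) xw[k] = (k0 + k + 0.5) * pixel_size;
      // inits: nominal tip and steepest decline
      double best_drop = 0; double xc_grad = L;
      for (int k = 1; k < npw; ++k) {
        const double dr = yw[k - 1] - yw[k];
        if (dr > best_drop) { best_drop = dr; xc_grad = 0.5 * (xw[k - 1] + xw[k]); }
      }
      std::vector<double> inits; inits.push_back(L); inits.push_back(xc_grad);
      ErfFit f = fit_erf_multistart(xw.data(), yw.data(), npw, -1, inits,
                                    psf_sigma, 0.2 * psf_sigma, 2000.0);
      // reject wild tip positions: a fit far from the steepest decline or
      // at the window border would truncate the common support of the
      // whole averaged ensemble
      if (!f.ok || std::fabs(f.x_c - xc_grad) > 500.0 ||
          f.x_c < xw[1] || f.x_c > xw[npw - 2]) { n_flagged++; continue; }
      m_used++;

      // normalize, align, linear interpolation onto grid
      const double xr0 = xw[0] - f.x_c, xr1 = xw[npw - 1] - f.x_c;
      for (int g = 0; g < ng; ++g) {
        const double gx = grid[g];
        if (gx < xr0 || gx > xr1) continue;
        const double fk = (gx - xr0) / pixel_size;
        int kk = (int)std::floor(fk);
        if (kk >= npw - 1) kk = npw - 2;
        const double t = fk - kk;
        const double yv = (1 - t) * yw[kk] + t * yw[kk + 1];
        it_sum[g] += (yv - f.I_BG) / f.I_AMP;
        it_cnt[g] += 1.0;
      }
    }

    if (m_used == 0)
      stop("all tip fits rejected in one Monte-Carlo iteration");
    for (int g = 0; g < ng; ++g) {
      if (it_cnt[g] == m_used) {   // keep only pixels covered by all profiles
        const double v = it_sum[g] / m_used;
        tot_sum[g] += v; tot_sq[g] += v * v; tot_cnt[g]++;
      }
    }
  }

  NumericVector mean_out(ng, NA_REAL), sem_out(ng, NA_REAL);
  LogicalVector cover(ng);
  for (int g = 0; g < ng; ++g) {
    cover[g] = (tot_cnt[g] == iterations);
    if (cover[g]) {
      const double mu = tot_sum[g] / iterations;
      mean_out[g] = mu;
      if (iterations > 1) {
        double v = (tot_sq[g] - iterations * mu * mu) / (iterations - 1);
        if (v < 0) v = 0;
        sem_out[g] = std::sqrt(v / iterations);
      }
    }
  }
  return List::create(_["grid"] = grid, _["mean"] = mean_out,
                      _["sem"] = sem_out, _["coverage"] = cover,
                      _["n_flagged"] = n_flagged);
}
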