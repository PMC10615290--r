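// Hot loops: RF echo synthesis, delay-and-sum, and 3x3 conv2d via im2col.
// All array shapes follow the R-side conventions documented in R/.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline double gauss_cos_pulse(double t, double f0, double sigma_t) {
  // Gaussian-modulated cosine, unit peak at t = 0; truncated at 4.5 sigma.
  double u = t / sigma_t;
  if (u < -4.5 || u > 4.5) return 0.0;
  return std::exp(-0.5 * u * u) * std::cos(2.0 * M_PI * f0 * t);
}

// traces dim = (n_angles, n_elements, n_samples); inactive elements stay zero.
// tau = (z cos th + x sin th)/c + dist(elem, scatterer)/c
// [[Rcpp::export]]
NumericVector rf_synthesize(NumericVector scat_x, NumericVector scat_z,
                            NumericVector refl, NumericVector elem_x,
                            IntegerVector active, NumericVector angles_rad,
                            double c, double fs, double t0, int n_samples,
                            double f0, double sigma_t, bool directivity) {
  const int n_sc = scat_x.size();
  const int n_el = elem_x.size();
  const int n_an = angles_rad.size();
  NumericVector out(static_cast<R_xlen_t>(n_an) * n_el * n_samples);
  out.attr("dim") = IntegerVector::create(n_an, n_el, n_samples);
  const double half = 4.5 * sigma_t;

  for (int a = 0; a < n_an; ++a) {
    const double th = angles_rad[a];
    const double cth = std::cos(th), sth = std::sin(th);
    for (int e = 0; e < n_el; ++e) {
      if (!active[e]) continue;
      const double ex = elem_x[e];
      for (int s = 0; s < n_sc; ++s) {
        const double dx = scat_x[s] - ex;
        const double dz = scat_z[s];
        const double rx = std::sqrt(dx * dx + dz * dz);
        const double tau = (scat_z[s] * cth + scat_x[s] * sth) / c + rx / c;
        double amp = refl[s];
        if (directivity) amp *= dz / rx;  // cos of angle off element normal
        const int k0 = std::max(0, (int)std::ceil((tau - half - t0) * fs));
        const int k1 = std::min(n_samples - 1,
                                (int)std::floor((tau + half - t0) * fs));
        for (int k = k0; k <= k1; ++k) {
          const double t = t0 + k / fs;
          out[a + (R_xlen_t)n_an * (e + (R_xlen_t)n_el * k)] +=
            amp * gauss_cos_pulse(t - tau, f0, sigma_t);
        }
      }
    }
  }
  return out;
}

// Variant of rf_synthesize using a tabulated pulse (e.g. the anti-alias
// filtered pulse): table holds pulse samples at spacing dt_tab starting
// at t_tab0 relative to the echo center.
// [[Rcpp::export]]
NumericVector rf_synthesize_tab(NumericVector scat_x, NumericVector scat_z,
                                NumericVector refl, NumericVector elem_x,
                                IntegerVector active,
                                NumericVector angles_rad, double c,
                                double fs, double t0, int n_samples,
                                NumericVector table, double dt_tab,
                                double t_tab0, bool directivity) {
  const int n_sc = scat_x.size();
  const int n_el = elem_x.size();
  const int n_an = angles_rad.size();
  const int n_tab = table.size();
  NumericVector out(static_cast<R_xlen_t>(n_an) * n_el * n_samples);
  out.attr("dim") = IntegerVector::create(n_an, n_el, n_samples);
  const double t_tab1 = t_tab0 + (n_tab - 1) * dt_tab;

  for (int a = 0; a < n_an; ++a) {
    const double th = angles_rad[a];
    const double cth = std::cos(th), sth = std::sin(th);
    for (int e = 0; e < n_el; ++e) {
      if (!active[e]) continue;
      const double ex = elem_x[e];
      for (int s = 0; s < n_sc; ++s) {
        const double dx = scat_x[s] - ex;
        const double dz = scat_z[s];
        const double rx = std::sqrt(dx * dx + dz * dz);
        const double tau = (scat_z[s] * cth + scat_x[s] * sth) / c + rx / c;
        double amp = refl[s];
        if (directivity) amp *= dz / rx;
        const int k0 = std::max(0, (int)std::ceil((tau + t_tab0 - t0) * fs));
        const int k1 = std::min(n_samples - 1,
                                (int)std::floor((tau + t_tab1 - t0) * fs));
        for (int k = k0; k <= k1; ++k) {
          const double u = (t0 + k / fs - tau - t_tab0) / dt_tab;
          const int m = (int)u;
          if (m < 0 || m >= n_tab - 1) continue;
          const double fr = u - m;
          out[a + (R_xlen_t)n_an * (e + (R_xlen_t)n_el * k)] +=
            amp * ((1.0 - fr) * table[m] + fr * table[m + 1]);
        }
      }
    }
  }
  return out;
}

// Complex-baseband traces for one angle as (n_samples x n_elements)
// matrix (analytic signal demodulated by f0); returns the complex
// beamformed image (n_rows x n_cols). Sub-sample delays interpolate the
// baseband envelope linearly and restore carrier phase exp(i 2 pi f0 tau)
// at the exact delay, avoiding the sidelobe floor of carrier-domain
// interpolation at ~2.2 samples/cycle. Pixel grid: px lateral (cols),
// pz depth (rows). weights[e] == 0 skips element e.
// [[Rcpp::export]]
arma::cx_mat das_angle(const arma::cx_mat& traces, const arma::vec& elem_x,
                       const arma::vec& weights, double t0, double fs,
                       double angle_rad, const arma::vec& px,
                       const arma::vec& pz, double c, double f0) {
  const int n_rows = pz.n_elem, n_cols = px.n_elem;
  const int n_samp = traces.n_rows;
  arma::cx_mat img(n_rows, n_cols, arma::fill::zeros);
  const double cth = std::cos(angle_rad), sth = std::sin(angle_rad);

  for (arma::uword e = 0; e < elem_x.n_elem; ++e) {
    const double wgt = weights[e];
    if (wgt == 0.0) continue;
    const double ex = elem_x[e];
    for (int j = 0; j < n_cols; ++j) {
      const double x = px[j];
      const double tx_lat = x * sth;
      for (int i = 0; i < n_rows; ++i) {
        const double z = pz[i];
        const double dxe = x - ex;
        const double tau = (z * cth + tx_lat) / c +
          std::sqrt(dxe * dxe + z * z) / c;
        const double fidx = (tau - t0) * fs;
        const int k = (int)std::floor(fidx);
        if (k < 0 || k >= n_samp - 1) continue;  // out of window -> zero
        const double frac = fidx - k;
        const std::complex<double> bb =
          (1.0 - frac) * traces(k, e) + frac * traces(k + 1, e);
        const double ph = 2.0 * M_PI * f0 * tau;
        img(i, j) += wgt * bb * std::complex<double>(std::cos(ph),
                                                     std::sin(ph));
      }
    }
  }
  return img;
}

// 3x3 conv, stride 1, zero padding 1. x dim (H, W, C, N), w dim (3, 3, C, K).
// im2col row order matches column-major flattening of w: dh fastest, then
// dw, then channel.
static void im2col(const double* x, int H, int W, int C, arma::mat& K) {
  const int HW = H * W;
  for (int c = 0; c < C; ++c) {
    const double* xc = x + (R_xlen_t)c * HW;
    for (int dw = -1; dw <= 1; ++dw) {
      for (int dh = -1; dh <= 1; ++dh) {
        const int r = (dh + 1) + 3 * (dw + 1) + 9 * c;
        for (int w_ = 0; w_ < W; ++w_) {
          const int ww = w_ + dw;
          double* dst = K.memptr() + r + (R_xlen_t)K.n_rows * (R_xlen_t)H * w_;
          if (ww < 0 || ww >= W) {
            for (int h = 0; h < H; ++h) dst[(R_xlen_t)K.n_rows * h] = 0.0;
            continue;
          }
          const double* src = xc + (R_xlen_t)H * ww;
          for (int h = 0; h < H; ++h) {
            const int hh = h + dh;
            dst[(R_xlen_t)K.n_rows * h] =
              (hh < 0 || hh >= H) ? 0.0 : src[hh];
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector conv2d_fw(NumericVector x, NumericVector w, NumericVector b) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3], Kout = wd[3];
  const int HW = H * W;
  NumericVector out(static_cast<R_xlen_t>(HW) * Kout * N);
  out.attr("dim") = IntegerVector::create(H, W, Kout, N);
  arma::mat Wm(w.begin(), 9 * C, Kout, false, true);
  arma::mat Km(9 * C, HW);
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + (R_xlen_t)n * HW * C, H, W, C, Km);
    arma::mat on(out.begin() + (R_xlen_t)n * HW * Kout, HW, Kout, false, true);
    on = Km.t() * Wm;
    for (int k = 0; k < Kout; ++k) on.col(k) += b[k];
  }
  return out;
}

// [[Rcpp::export]]
List conv2d_bw(NumericVector x, NumericVector w, NumericVector dout) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3], Kout = wd[3];
  const int HW = H * W;
  NumericVector dx(x.size());
  dx.attr("dim") = xd;
  NumericVector dw(w.size());
  dw.attr("dim") = wd;
  NumericVector db(Kout);
  arma::mat Wm(w.begin(), 9 * C, Kout, false, true);
  arma::mat dWm(dw.begin(), 9 * C, Kout, false, true);
  arma::mat Km(9 * C, HW);
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + (R_xlen_t)n * HW * C, H, W, C, Km);
    arma::mat don(dout.begin() + (R_xlen_t)n * HW * Kout, HW, Kout,
                  false, true);
    dWm += Km * don;
    for (int k = 0; k < Kout; ++k) db[k] += arma::accu(don.col(k));
    arma::mat dK = Wm * don.t();  // (9C x HW)
    // col2im accumulate
    double* dxn = dx.begin() + (R_xlen_t)n * HW * C;
    for (int c = 0; c < C; ++c) {
      double* dxc = dxn + (R_xlen_t)c * HW;
      for (int dw_ = -1; dw_ <= 1; ++dw_) {
        for (int dh = -1; dh <= 1; ++dh) {
          const int r = (dh + 1) + 3 * (dw_ + 1) + 9 * c;
          for (int w_ = 0; w_ < W; ++w_) {
            const int ww = w_ + dw_;
            if (ww < 0 || ww >= W) continue;
            for (int h = 0; h < H; ++h) {
              const int hh = h + dh;
              if (hh < 0 || hh >= H) continue;
              dxc[hh + (R_xlen_t)H * ww] += dK(r, h + (R_xlen_t)H * w_);
            }
          }
        }
      }
    }
  }
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}
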