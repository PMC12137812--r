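// Tomography primitives. The forward projector is pixel-driven with bilinear
// splatting onto the detector axis; the backprojector is its exact adjoint,
// which makes multiplicative EM updates mass-consistent and gives exact
// per-angle mass conservation (the splat weights for every pixel sum to 1).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// [[Rcpp::export]]
arma::mat radon_cpp(const arma::mat& img, const arma::vec& angles_deg,
                    const int n_t, const double pixel_size) {
  const int n = img.n_rows, m = img.n_cols, na = angles_deg.n_elem;
  arma::mat sino(na, n_t, arma::fill::zeros);
  const double cx = (m - 1) / 2.0, cy = (n - 1) / 2.0,
               ct = (n_t - 1) / 2.0;
  for (int a = 0; a < na; ++a) {
    const double th = angles_deg(a) * M_PI / 180.0;
    const double c = std::cos(th), s = std::sin(th);
    for (int i = 0; i < n; ++i) {
      const double y = cy - i;
      for (int j = 0; j < m; ++j) {
        const double v = img(i, j);
        if (v == 0.0) continue;
        const double x = j - cx;
        const double tb = x * c + y * s + ct;
        const int b0 = (int)std::floor(tb);
        const double w1 = tb - b0;
        if (b0 >= 0 && b0 < n_t) sino(a, b0) += v * (1.0 - w1) * pixel_size;
        if (b0 + 1 >= 0 && b0 + 1 < n_t) sino(a, b0 + 1) += v * w1 * pixel_size;
      }
    }
  }
  return sino;
}

// Exact adjoint of radon_cpp (same weights, transposed scatter/gather).
// [[Rcpp::export]]
arma::mat backproject_cpp(const arma::mat& sino, const arma::vec& angles_deg,
                          const int n, const double pixel_size) {
  const int na = angles_deg.n_elem, n_t = sino.n_cols;
  arma::mat img(n, n, arma::fill::zeros);
  const double cx = (n - 1) / 2.0, cy = (n - 1) / 2.0, ct = (n_t - 1) / 2.0;
  for (int a = 0; a < na; ++a) {
    const double th = angles_deg(a) * M_PI / 180.0;
    const double c = std::cos(th), s = std::sin(th);
    for (int i = 0; i < n; ++i) {
      const double y = cy - i;
      for (int j = 0; j < n; ++j) {
        const double x = j - cx;
        const double tb = x * c + y * s + ct;
        const int b0 = (int)std::floor(tb);
        const double w1 = tb - b0;
        double acc = 0.0;
        if (b0 >= 0 && b0 < n_t) acc += sino(a, b0) * (1.0 - w1);
        if (b0 + 1 >= 0 && b0 + 1 < n_t) acc += sino(a, b0 + 1) * w1;
        img(i, j) += acc * pixel_size;
      }
    }
  }
  return img;
}

// Bilinear rotation about the image centre (degrees, counter-clockwise in
// the x-right / y-up convention); zero fill outside.
// [[Rcpp::export]]
arma::mat rotate_bilinear_cpp(const arma::mat& img, const double angle_deg) {
  const int n = img.n_rows, m = img.n_cols;
  arma::mat out(n, m, arma::fill::zeros);
  const double th = angle_deg * M_PI / 180.0;
  const double c = std::cos(th), s = std::sin(th);
  const double cx = (m - 1) / 2.0, cy = (n - 1) / 2.0;
  for (int i = 0; i < n; ++i) {
    const double y = cy - i;
    for (int j = 0; j < m; ++j) {
      const double x = j - cx;
      // inverse map: source coordinates of this output pixel
      const double xs = x * c + y * s, ys = -x * s + y * c;
      const double jj = xs + cx, ii = cy - ys;
      const int j0 = (int)std::floor(jj), i0 = (int)std::floor(ii);
      const double fj = jj - j0, fi = ii - i0;
      double v = 0.0;
      for (int di = 0; di <= 1; ++di)
        for (int dj = 0; dj <= 1; ++dj) {
          const int i1 = i0 + di, j1 = j0 + dj;
          if (i1 < 0 || i1 >= n || j1 < 0 || j1 >= m) continue;
          v += img(i1, j1) * (di ? fi : 1.0 - fi) * (dj ? fj : 1.0 - fj);
        }
      out(i, j) = v;
    }
  }
  return out;
}

// Bilinear resize on cell-centre coordinates with edge clamping; preserves
// constants exactly and the mean to interpolation accuracy.
// [[Rcpp::export]]
arma::mat resize_bilinear_cpp(const arma::mat& img, const int out_h,
                              const int out_w) {
  const int n = img.n_rows, m = img.n_cols;
  arma::mat out(out_h, out_w);
  const double sy = (double)n / out_h, sx = (double)m / out_w;
  for (int i = 0; i < out_h; ++i) {
    double ii = (i + 0.5) * sy - 0.5;
    if (ii < 0) ii = 0; if (ii > n - 1) ii = n - 1;
    const int i0 = (int)std::floor(ii);
    const int i1 = std::min(i0 + 1, n - 1);
    const double fi = ii - i0;
    for (int j = 0; j < out_w; ++j) {
      double jj = (j + 0.5) * sx - 0.5;
      if (jj < 0) jj = 0; if (jj > m - 1) jj = m - 1;
      const int j0 = (int)std::floor(jj);
      const int j1 = std::min(j0 + 1, m - 1);
      const double fj = jj - j0;
      out(i, j) = img(i0, j0) * (1 - fi) * (1 - fj) +
                  img(i1, j0) * fi * (1 - fj) +
                  img(i0, j1) * (1 - fi) * fj +
                  img(i1, j1) * fi * fj;
    }
  }
  return out;
}

// SSIM with the original 11x11 Gaussian window (sigma 1.5), constants
// C1=(0.01 L)^2, C2=(0.03 L)^2, averaged over windows fully inside the image.
// [[Rcpp::export]]
double ssim_cpp(const arma::mat& a, const arma::mat& b,
                const double data_range) {
  const int w = 11, r = w / 2;
  arma::vec g(w);
  for (int i = 0; i < w; ++i) {
    const double d = i - r;
    g(i) = std::exp(-d * d / (2.0 * 1.5 * 1.5));
  }
  g /= arma::accu(g);
  const int n = a.n_rows, m = a.n_cols;
  if (n < w || m < w) Rcpp::stop("images too small for the 11x11 SSIM window");

  auto filt = [&](const arma::mat& x) {
    // separable valid correlation
    arma::mat tmp(n - 2 * r, m, arma::fill::zeros);
    for (int i = 0; i < n - 2 * r; ++i)
      for (int j = 0; j < m; ++j) {
        double acc = 0.0;
        for (int k = 0; k < w; ++k) acc += g(k) * x(i + k, j);
        tmp(i, j) = acc;
      }
    arma::mat out(n - 2 * r, m - 2 * r, arma::fill::zeros);
    for (int i = 0; i < n - 2 * r; ++i)
      for (int j = 0; j < m - 2 * r; ++j) {
        double acc = 0.0;
        for (int k = 0; k < w; ++k) acc += g(k) * tmp(i, j + k);
        out(i, j) = acc;
      }
    return out;
  };

  arma::mat mu1 = filt(a), mu2 = filt(b);
  arma::mat s11 = filt(a % a) - mu1 % mu1;
  arma::mat s22 = filt(b % b) - mu2 % mu2;
  arma::mat s12 = filt(a % b) - mu1 % mu2;
  const double C1 = std::pow(0.01 * data_range, 2),
               C2 = std::pow(0.03 * data_range, 2);
  arma::mat num = (2 * mu1 % mu2 + C1) % (2 * s12 + C2);
  arma::mat den = (mu1 % mu1 + mu2 % mu2 + C1) % (s11 + s22 + C2);
  return arma::mean(arma::vectorise(num / den));
}
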