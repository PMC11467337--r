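// 3D CNN kernels: 3x3x3 and 1x1x1 convolutions (forward/backward), 2x2x2
// max pooling and nearest-neighbour upsampling. Tensors are R arrays with
// dim (nx, ny, nz, C, N), column-major. Convolutions loop over samples with
// a reusable im2col buffer to keep peak memory at one sample's columns.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// fill col (nvox x 27*C) from sample pointer xs (nvox * C)
static void im2col_sample(const double* xs, int nx, int ny, int nz, int C,
                          arma::mat& col) {
  size_t nvox = (size_t)nx * ny * nz;
  for (int c = 0; c < C; ++c) {
    const double* xc = xs + (size_t)c * nvox;
    int o = 0;
    for (int dz = -1; dz <= 1; ++dz)
      for (int dy = -1; dy <= 1; ++dy)
        for (int dx = -1; dx <= 1; ++dx) {
          double* dst = col.colptr((size_t)c * 27 + o);
          for (int k = 0; k < nz; ++k) {
            int kk = k + dz;
            bool zok = kk >= 0 && kk < nz;
            for (int j = 0; j < ny; ++j) {
              int jj = j + dy;
              double* d = dst + (size_t)k * nx * ny + (size_t)j * nx;
              if (!zok || jj < 0 || jj >= ny) {
                std::fill(d, d + nx, 0.0);
                continue;
              }
              const double* s = xc + (size_t)kk * nx * ny +
                                (size_t)jj * nx + dx;
              int i0 = std::max(0, -dx), i1 = std::min(nx, nx - dx);
              for (int i = 0; i < i0; ++i) d[i] = 0.0;
              for (int i = i0; i < i1; ++i) d[i] = s[i];
              for (int i = i1; i < nx; ++i) d[i] = 0.0;
            }
          }
          ++o;
        }
  }
}

// scatter-add dcol (nvox x 27*C) into sample gradient dxs (nvox * C)
static void col2im_sample(const arma::mat& dcol, int nx, int ny, int nz,
                          int C, double* dxs) {
  size_t nvox = (size_t)nx * ny * nz;
  for (int c = 0; c < C; ++c) {
    double* xc = dxs + (size_t)c * nvox;
    int o = 0;
    for (int dz = -1; dz <= 1; ++dz)
      for (int dy = -1; dy <= 1; ++dy)
        for (int dx = -1; dx <= 1; ++dx) {
          const double* src = dcol.colptr((size_t)c * 27 + o);
          for (int k = 0; k < nz; ++k) {
            int kk = k + dz;
            if (kk < 0 || kk >= nz) continue;
            for (int j = 0; j < ny; ++j) {
              int jj = j + dy;
              if (jj < 0 || jj >= ny) continue;
              const double* s = src + (size_t)k * nx * ny + (size_t)j * nx;
              double* d = xc + (size_t)kk * nx * ny + (size_t)jj * nx + dx;
              int i0 = std::max(0, -dx), i1 = std::min(nx, nx - dx);
              for (int i = i0; i < i1; ++i) d[i] += s[i];
            }
          }
          ++o;
        }
  }
}

// [[Rcpp::export(name = ".conv3_fw")]]
NumericVector conv3_fw(NumericVector x, IntegerVector dim5,
                       const arma::mat& W, NumericVector bias) {
  int nx = dim5[0], ny = dim5[1], nz = dim5[2], C = dim5[3], N = dim5[4];
  int Cout = W.n_cols;
  size_t nvox = (size_t)nx * ny * nz;
  NumericVector y(nvox * Cout * N);
  arma::mat col(nvox, 27 * C);
  for (int n = 0; n < N; ++n) {
    im2col_sample(x.begin() + (size_t)n * nvox * C, nx, ny, nz, C, col);
    arma::mat out(y.begin() + (size_t)n * nvox * Cout, nvox, Cout,
                  false, true);
    out = col * W;
    for (int co = 0; co < Cout; ++co) out.col(co) += bias[co];
  }
  y.attr("dim") = IntegerVector::create(nx, ny, nz, Cout, N);
  return y;
}

// [[Rcpp::export(name = ".conv3_bw")]]
List conv3_bw(NumericVector x, IntegerVector dim5, const arma::mat& W,
              NumericVector dy) {
  int nx = dim5[0], ny = dim5[1], nz = dim5[2], C = dim5[3], N = dim5[4];
  int Cout = W.n_cols;
  size_t nvox = (size_t)nx * ny * nz;
  NumericVector dx(nvox * C * N);
  arma::mat dW(27 * C, Cout, arma::fill::zeros);
  arma::vec db(Cout, arma::fill::zeros);
  arma::mat col(nvox, 27 * C);
  for (int n = 0; n < N; ++n) {
    const double* xs = x.begin() + (size_t)n * nvox * C;
    arma::mat dyn(const_cast<double*>(dy.begin()) + (size_t)n * nvox * Cout,
                  nvox, Cout, false, true);
    im2col_sample(xs, nx, ny, nz, C, col);
    dW += col.t() * dyn;
    db += arma::sum(dyn, 0).t();
    arma::mat dcol = dyn * W.t();
    col2im_sample(dcol, nx, ny, nz, C, dx.begin() + (size_t)n * nvox * C);
  }
  dx.attr("dim") = dim5;
  return List::create(_["dx"] = dx, _["dW"] = dW, _["db"] = db);
}

// [[Rcpp::export(name = ".conv1_fw")]]
NumericVector conv1_fw(NumericVector x, IntegerVector dim5,
                       const arma::mat& W, NumericVector bias) {
  int nx = dim5[0], ny = dim5[1], nz = dim5[2], C = dim5[3], N = dim5[4];
  int Cout = W.n_cols;
  size_t nvox = (size_t)nx * ny * nz;
  NumericVector y(nvox * Cout * N);
  for (int n = 0; n < N; ++n) {
    arma::mat xin(const_cast<double*>(x.begin()) + (size_t)n * nvox * C,
                  nvox, C, false, true);
    arma::mat out(y.begin() + (size_t)n * nvox * Cout, nvox, Cout,
                  false, true);
    out = xin * W;
    for (int co = 0; co < Cout; ++co) out.col(co) += bias[co];
  }
  y.attr("dim") = IntegerVector::create(nx, ny, nz, Cout, N);
  return y;
}

// [[Rcpp::export(name = ".conv1_bw")]]
List conv1_bw(NumericVector x, IntegerVector dim5, const arma::mat& W,
              NumericVector dy) {
  int nx = dim5[0], ny = dim5[1], nz = dim5[2], C = dim5[3], N = dim5[4];
  int Cout = W.n_cols;
  size_t nvox = (size_t)nx * ny * nz;
  NumericVector dx(nvox * C * N);
  arma::mat dW(C, Cout, arma::fill::zeros);
  arma::vec db(Cout, arma::fill::zeros);
  for (int n = 0; n < N; ++n) {
    arma::mat xin(const_cast<double*>(x.begin()) + (size_t)n * nvox * C,
                  nvox, C, false, true);
    arma::mat dyn(const_cast<double*>(dy.begin()) + (size_t)n * nvox * Cout,
                  nvox, Cout, false, true);
    arma::mat dxn(dx.begin() + (size_t)n * nvox * C, nvox, C, false, true);
    dW += xin.t() * dyn;
    db += arma::sum(dyn, 0).t();
    dxn = dyn * W.t();
  }
  dx.attr("dim") = dim5;
  return List::create(_["dx"] = dx, _["dW"] = dW, _["db"] = db);
}

// [[Rcpp::export(name = ".maxpool3_fw")]]
List maxpool3_fw(NumericVector x, IntegerVector dim5) {
  int nx = dim5[0], ny = dim5[1], nz = dim5[2], C = dim5[3], N = dim5[4];
  int ox = nx / 2, oy = ny / 2, oz = nz / 2;
  size_t nvox_in = (size_t)nx * ny * nz, nvox_out = (size_t)ox * oy * oz;
  NumericVector y(nvox_out * C * N);
  IntegerVector idx(nvox_out * C * N);  // 1-based linear index into x
  const double* xp = x.begin();
  double* yp = y.begin();
  int* ip = idx.begin();
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      size_t base_in = ((size_t)n * C + c) * nvox_in;
      size_t base_out = ((size_t)n * C + c) * nvox_out;
      for (int k = 0; k < oz; ++k)
        for (int j = 0; j < oy; ++j)
          for (int i = 0; i < ox; ++i) {
            double best = -INFINITY;
            size_t bidx = 0;
            for (int dz = 0; dz < 2; ++dz)
              for (int dy = 0; dy < 2; ++dy)
                for (int dx = 0; dx < 2; ++dx) {
                  size_t s = base_in + (size_t)(2 * k + dz) * nx * ny +
                             (size_t)(2 * j + dy) * nx + (2 * i + dx);
                  if (xp[s] > best) { best = xp[s]; bidx = s; }
                }
            size_t o = base_out + (size_t)k * ox * oy + (size_t)j * ox + i;
            yp[o] = best;
            ip[o] = (int)(bidx + 1);
          }
    }
  y.attr("dim") = IntegerVector::create(ox, oy, oz, C, N);
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export(name = ".maxpool3_bw")]]
NumericVector maxpool3_bw(NumericVector dy, IntegerVector idx, double n_in) {
  NumericVector dx((R_xlen_t)n_in);
  double* dxp = dx.begin();
  const double* dyp = dy.begin();
  const int* ip = idx.begin();
  R_xlen_t n = dy.size();
  for (R_xlen_t s = 0; s < n; ++s) dxp[ip[s] - 1] += dyp[s];
  return dx;
}

// [[Rcpp::export(name = ".upsample3_fw")]]
NumericVector upsample3_fw(NumericVector x, IntegerVector dim5) {
  int nx = dim5[0], ny = dim5[1], nz = dim5[2], C = dim5[3], N = dim5[4];
  int ox = 2 * nx, oy = 2 * ny, oz = 2 * nz;
  size_t nvi = (size_t)nx * ny * nz, nvo = (size_t)ox * oy * oz;
  NumericVector y(nvo * C * N);
  const double* xp = x.begin();
  double* yp = y.begin();
  for (size_t cn = 0; cn < (size_t)C * N; ++cn) {
    const double* xs = xp + cn * nvi;
    double* ys = yp + cn * nvo;
    for (int k = 0; k < oz; ++k)
      for (int j = 0; j < oy; ++j) {
        const double* row = xs + (size_t)(k / 2) * nx * ny +
                            (size_t)(j / 2) * nx;
        double* out = ys + (size_t)k * ox * oy + (size_t)j * ox;
        for (int i = 0; i < ox; ++i) out[i] = row[i / 2];
      }
  }
  y.attr("dim") = IntegerVector::create(ox, oy, oz, C, N);
  return y;
}

// [[Rcpp::export(name = ".upsample3_bw")]]
NumericVector upsample3_bw(NumericVector dy, IntegerVector dim5_in) {
  int nx = dim5_in[0], ny = dim5_in[1], nz = dim5_in[2];
  int C = dim5_in[3], N = dim5_in[4];
  int ox = 2 * nx, oy = 2 * ny, oz = 2 * nz;
  size_t nvi = (size_t)nx * ny * nz, nvo = (size_t)ox * oy * oz;
  NumericVector dx(nvi * C * N);
  const double* dyp = dy.begin();
  double* dxp = dx.begin();
  for (size_t cn = 0; cn < (size_t)C * N; ++cn) {
    const double* ds = dyp + cn * nvo;
    double* xs = dxp + cn * nvi;
    for (int k = 0; k < oz; ++k)
      for (int j = 0; j < oy; ++j) {
        const double* in = ds + (size_t)k * ox * oy + (size_t)j * ox;
        double* row = xs + (size_t)(k / 2) * nx * ny + (size_t)(j / 2) * nx;
        for (int i = 0; i < ox; ++i) row[i / 2] += in[i];
      }
  }
  dx.attr("dim") = dim5_in;
  return dx;
}

// Instance norm forward: per (channel, sample) standardization over voxels,
// affine per channel. Returns y and the per-(c,n) statistics for backward.
// [[Rcpp::export(name = ".inorm_fw")]]
List inorm_fw(NumericVector x, IntegerVector dim5, NumericVector gamma,
              NumericVector beta, double eps) {
  int C = dim5[3], N = dim5[4];
  size_t nvox = (size_t)dim5[0] * dim5[1] * dim5[2];
  NumericVector y(x.size());
  NumericVector mu(C * N), istd(C * N);
  const double* xp = x.begin();
  double* yp = y.begin();
  for (int cn = 0; cn < C * N; ++cn) {
    const double* xs = xp + (size_t)cn * nvox;
    double* ys = yp + (size_t)cn * nvox;
    double m = 0, s2 = 0;
    for (size_t v = 0; v < nvox; ++v) m += xs[v];
    m /= nvox;
    for (size_t v = 0; v < nvox; ++v) { double d = xs[v] - m; s2 += d * d; }
    s2 /= nvox;
    double is = 1.0 / std::sqrt(s2 + eps);
    mu[cn] = m; istd[cn] = is;
    int c = cn % C;
    double g = gamma[c], b = beta[c];
    for (size_t v = 0; v < nvox; ++v) ys[v] = (xs[v] - m) * is * g + b;
  }
  y.attr("dim") = dim5;
  return List::create(_["y"] = y, _["mu"] = mu, _["istd"] = istd);
}

// [[Rcpp::export(name = ".inorm_bw")]]
List inorm_bw(NumericVector x, IntegerVector dim5, NumericVector gamma,
              NumericVector mu, NumericVector istd, NumericVector dy) {
  int C = dim5[3], N = dim5[4];
  size_t nvox = (size_t)dim5[0] * dim5[1] * dim5[2];
  NumericVector dx(x.size());
  NumericVector dgamma(C), dbeta(C);
  const double* xp = x.begin();
  const double* dyp = dy.begin();
  double* dxp = dx.begin();
  for (int cn = 0; cn < C * N; ++cn) {
    const double* xs = xp + (size_t)cn * nvox;
    const double* ds = dyp + (size_t)cn * nvox;
    double* os = dxp + (size_t)cn * nvox;
    int c = cn % C;
    double m = mu[cn], is = istd[cn], g = gamma[c];
    double sum_dy = 0, sum_dy_xhat = 0;
    for (size_t v = 0; v < nvox; ++v) {
      double xh = (xs[v] - m) * is;
      sum_dy += ds[v];
      sum_dy_xhat += ds[v] * xh;
    }
    dbeta[c] += sum_dy;
    dgamma[c] += sum_dy_xhat;
    double mean_dy = sum_dy / nvox, mean_dy_xhat = sum_dy_xhat / nvox;
    for (size_t v = 0; v < nvox; ++v) {
      double xh = (xs[v] - m) * is;
      os[v] = (ds[v] * g - mean_dy * g - xh * mean_dy_xhat * g) * is;
    }
  }
  dx.attr("dim") = dim5;
  return List::create(_["dx"] = dx, _["dgamma"] = dgamma,
                      _["dbeta"] = dbeta);
}

// Leaky ReLU forward/backward (mask recomputed from x in backward)
// [[Rcpp::export(name = ".lrelu_fw")]]
NumericVector lrelu_fw(NumericVector x, double slope) {
  NumericVector y(x.size());
  const double* xp = x.begin();
  double* yp = y.begin();
  for (R_xlen_t i = 0; i < x.size(); ++i)
    yp[i] = xp[i] > 0 ? xp[i] : slope * xp[i];
  y.attr("dim") = x.attr("dim");
  return y;
}

// [[Rcpp::export(name = ".lrelu_bw")]]
NumericVector lrelu_bw(NumericVector x, NumericVector dy, double slope) {
  NumericVector dx(x.size());
  const double* xp = x.begin();
  const double* dyp = dy.begin();
  double* dxp = dx.begin();
  for (R_xlen_t i = 0; i < x.size(); ++i)
    dxp[i] = xp[i] > 0 ? dyp[i] : slope * dyp[i];
  dx.attr("dim") = x.attr("dim");
  return dx;
}
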