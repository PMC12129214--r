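#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// 2D cross-correlation with 'same' zero padding, square odd kernel.
// x: H x W x Cin, w: k x k x Cin x Cout (column-major R array), b: Cout.
// [[Rcpp::export(name = ".conv2d_fwd")]]
arma::cube conv2d_fwd(const arma::cube& x, const NumericVector& w,
                      const NumericVector& b) {
  IntegerVector wd = w.attr("dim");
  const int k = wd[0], cin = wd[2], cout = wd[3];
  const int H = x.n_rows, W = x.n_cols, pad = k / 2;
  if ((int)x.n_slices != cin) stop("input channel count does not match weights");
  arma::cube out(H, W, cout);
  for (int co = 0; co < cout; ++co) out.slice(co).fill(b[co]);
  for (int co = 0; co < cout; ++co) {
    for (int ci = 0; ci < cin; ++ci) {
      const arma::mat& xs = x.slice(ci);
      for (int dx = 0; dx < k; ++dx) {
        for (int dy = 0; dy < k; ++dy) {
          const double wv = w[dy + k * dx + k * k * ci + k * k * cin * co];
          if (wv == 0.0) continue;
          const int oy = dy - pad, ox = dx - pad;
          const int i0 = std::max(0, -oy), i1 = std::min(H, H - oy);
          const int j0 = std::max(0, -ox), j1 = std::min(W, W - ox);
          for (int j = j0; j < j1; ++j) {
            double* op = out.slice(co).colptr(j) + i0;
            const double* xp = xs.colptr(j + ox) + i0 + oy;
            for (int i = i0; i < i1; ++i) *op++ += wv * (*xp++);
          }
        }
      }
    }
  }
  return out;
}

// Backward pass of conv2d_fwd. Returns gradients w.r.t. input, weights, bias.
// [[Rcpp::export(name = ".conv2d_bwd")]]
List conv2d_bwd(const arma::cube& x, const NumericVector& w,
                const arma::cube& g) {
  IntegerVector wd = w.attr("dim");
  const int k = wd[0], cin = wd[2], cout = wd[3];
  const int H = x.n_rows, W = x.n_cols, pad = k / 2;
  if ((int)g.n_slices != cout) stop("gradient channel count does not match weights");
  arma::cube gx(H, W, cin, arma::fill::zeros);
  NumericVector gw(w.size());
  gw.attr("dim") = wd;
  NumericVector gb(cout);
  for (int co = 0; co < cout; ++co) {
    gb[co] = arma::accu(g.slice(co));
    const arma::mat& gs = g.slice(co);
    for (int ci = 0; ci < cin; ++ci) {
      const arma::mat& xs = x.slice(ci);
      arma::mat& gxs = gx.slice(ci);
      for (int dx = 0; dx < k; ++dx) {
        for (int dy = 0; dy < k; ++dy) {
          const int oy = dy - pad, ox = dx - pad;
          const int i0 = std::max(0, -oy), i1 = std::min(H, H - oy);
          const int j0 = std::max(0, -ox), j1 = std::min(W, W - ox);
          double acc = 0.0;
          const double wv = w[dy + k * dx + k * k * ci + k * k * cin * co];
          for (int j = j0; j < j1; ++j) {
            const double* gp = gs.colptr(j) + i0;
            const double* xp = xs.colptr(j + ox) + i0 + oy;
            double* gxp = gxs.colptr(j + ox) + i0 + oy;
            for (int i = i0; i < i1; ++i) {
              acc += (*gp) * (*xp++);
              *gxp++ += wv * (*gp++);
            }
          }
          gw[dy + k * dx + k * k * ci + k * k * cin * co] = acc;
        }
      }
    }
  }
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}
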