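// 1D convolution and max-pooling kernels used by the neural-network core.
// Layout convention: signals are cubes of shape (channels, length, batch);
// convolution weights are (out_channels, in_channels * kernel) matrices with
// column index = channel + tap * in_channels (channel fastest). The whole
// batch is lowered into a single im2col matrix so each pass costs one GEMM.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// gather the full batch into (c*k, lout*nb)
static arma::mat im2col_batch(const arma::cube& x, int k, int stride, int pad,
                              int lout) {
  const int c = x.n_rows, l = x.n_cols, nb = x.n_slices;
  arma::mat p(c * k, (size_t)lout * nb, arma::fill::zeros);
  for (int s = 0; s < nb; ++s) {
    const arma::mat& xs = x.slice(s);
    double* pcol0 = p.colptr((size_t)s * lout);
    for (int t = 0; t < lout; ++t) {
      double* pc = pcol0 + (size_t)t * (c * k);
      for (int j = 0; j < k; ++j) {
        int pos = t * stride + j - pad;
        if (pos < 0 || pos >= l) continue;
        const double* xc = xs.colptr(pos);
        std::copy(xc, xc + c, pc + (size_t)j * c);
      }
    }
  }
  return p;
}

// [[Rcpp::export]]
arma::cube cpp_conv1d_forward(const arma::cube& x, const arma::mat& w,
                              const arma::vec& b, int k, int stride, int pad) {
  const int l = x.n_cols, nb = x.n_slices;
  const int lout = (l + 2 * pad - k) / stride + 1;
  const int cout = w.n_rows;
  arma::mat p = im2col_batch(x, k, stride, pad, lout);
  arma::mat ym = w * p;              // (cout, lout*nb)
  ym.each_col() += b;
  arma::cube y(cout, lout, nb);
  std::copy(ym.memptr(), ym.memptr() + ym.n_elem, y.memptr());
  return y;
}

// [[Rcpp::export]]
List cpp_conv1d_backward(const arma::cube& dy, const arma::cube& x,
                         const arma::mat& w, int k, int stride, int pad) {
  const int c = x.n_rows, l = x.n_cols, nb = x.n_slices;
  const int cout = dy.n_rows, lout = dy.n_cols;
  arma::mat p = im2col_batch(x, k, stride, pad, lout);
  arma::mat dym((double*)dy.memptr(), cout, (size_t)lout * nb, false, true);
  arma::mat dw = dym * p.t();
  arma::vec db = arma::sum(dym, 1);
  arma::mat dp = w.t() * dym;        // (c*k, lout*nb)
  arma::cube dx(c, l, nb, arma::fill::zeros);
  for (int s = 0; s < nb; ++s) {
    arma::mat& dxs = dx.slice(s);
    const double* pcol0 = dp.colptr((size_t)s * lout);
    for (int t = 0; t < lout; ++t) {
      const double* pc = pcol0 + (size_t)t * (c * k);
      for (int j = 0; j < k; ++j) {
        int pos = t * stride + j - pad;
        if (pos < 0 || pos >= l) continue;
        double* xc = dxs.colptr(pos);
        const double* src = pc + (size_t)j * c;
        for (int ci = 0; ci < c; ++ci) xc[ci] += src[ci];
      }
    }
  }
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// [[Rcpp::export]]
List cpp_maxpool_forward(const arma::cube& x, int k, int stride, int pad) {
  const int c = x.n_rows, l = x.n_cols, nb = x.n_slices;
  const int lout = (l + 2 * pad - k) / stride + 1;
  arma::cube y(c, lout, nb);
  arma::ucube amax(c, lout, nb);  // 0-based index into the unpadded input
  const double ninf = -std::numeric_limits<double>::infinity();
  for (int s = 0; s < nb; ++s) {
    for (int t = 0; t < lout; ++t) {
      for (int ci = 0; ci < c; ++ci) {
        double best = ninf;
        int besti = 0;
        for (int j = 0; j < k; ++j) {
          int pos = t * stride + j - pad;
          if (pos < 0 || pos >= l) continue;
          double v = x(ci, pos, s);
          if (v > best) { best = v; besti = pos; }
        }
        y(ci, t, s) = best;
        amax(ci, t, s) = besti;
      }
    }
  }
  return List::create(_["y"] = y, _["argmax"] = amax);
}

// [[Rcpp::export]]
arma::cube cpp_maxpool_backward(const arma::cube& dy, const arma::ucube& amax,
                                int l) {
  const int c = dy.n_rows, lout = dy.n_cols, nb = dy.n_slices;
  arma::cube dx(c, l, nb, arma::fill::zeros);
  for (int s = 0; s < nb; ++s) {
    for (int t = 0; t < lout; ++t) {
      for (int ci = 0; ci < c; ++ci) {
        dx(ci, amax(ci, t, s), s) += dy(ci, t, s);
      }
    }
  }
  return dx;
}
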