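// Fused im2col convolution kernels: gather + BLAS matmul + bias + layout
// permutation in one pass. Index maps are built once in R (1-based) and
// reused across minibatches.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// x: input array (B, C_in, H, W) as a flat vector; idx: (R x K) gather map
// with R = B*H_out*W_out rows ordered b-fastest, then h_out, then w_out;
// Wm: (K x C_out); b: bias. Returns the (B, C_out, H_out, W_out) output and
// the gathered matrix M (cached for the weight gradient).
// [[Rcpp::export(name = ".conv_fwd_cpp")]]
List conv_fwd_cpp(NumericVector x, IntegerMatrix idx, NumericMatrix Wm,
                  NumericVector bias, int B, int Hout, int Wout) {
  const int R = idx.nrow(), K = idx.ncol(), Cout = Wm.ncol();
  arma::mat M(R, K);
  for (int j = 0; j < K; ++j) {
    const int *col = &idx(0, j);
    double *dst = M.colptr(j);
    for (int r = 0; r < R; ++r) dst[r] = x[col[r] - 1];
  }
  const arma::mat W(Wm.begin(), K, Cout, false, true);
  arma::mat Y = M * W;
  for (int co = 0; co < Cout; ++co) Y.col(co) += bias[co];
  NumericVector out(static_cast<R_xlen_t>(R) * Cout);
  out.attr("dim") = IntegerVector::create(B, Cout, Hout, Wout);
  double *op = out.begin();
  for (int wo = 0; wo < Wout; ++wo)
    for (int ho = 0; ho < Hout; ++ho)
      for (int co = 0; co < Cout; ++co) {
        const double *src = Y.colptr(co) + B * (ho + Hout * wo);
        double *dst = op + B * (co + Cout * (ho + Hout * wo));
        std::copy(src, src + B, dst);
      }
  return List::create(_["out"] = out, _["M"] = wrap(M));
}

// dout: (B, C_out, H_out, W_out); M: cached gather matrix; returns the
// input gradient (as the flat (B, C_in, H, W) array), dW (K x C_out), db.
// [[Rcpp::export(name = ".conv_bwd_cpp")]]
List conv_bwd_cpp(NumericVector dout, NumericMatrix Mr, IntegerMatrix idx,
                  NumericMatrix Wm, int n_in, int B, int Hout, int Wout) {
  const int R = idx.nrow(), K = idx.ncol(), Cout = Wm.ncol();
  arma::mat G(R, Cout);
  const double *dp = dout.begin();
  for (int wo = 0; wo < Wout; ++wo)
    for (int ho = 0; ho < Hout; ++ho)
      for (int co = 0; co < Cout; ++co) {
        const double *src = dp + B * (co + Cout * (ho + Hout * wo));
        double *dst = G.colptr(co) + B * (ho + Hout * wo);
        std::copy(src, src + B, dst);
      }
  const arma::mat M(Mr.begin(), R, K, false, true);
  const arma::mat W(Wm.begin(), K, Cout, false, true);
  arma::rowvec db = arma::sum(G, 0);
  arma::mat dW = M.t() * G;
  arma::mat dM = G * W.t();
  NumericVector dx(n_in);
  double *xp = dx.begin();
  for (int j = 0; j < K; ++j) {
    const int *col = &idx(0, j);
    const double *src = dM.colptr(j);
    for (int r = 0; r < R; ++r) xp[col[r] - 1] += src[r];
  }
  return List::create(_["dx"] = dx, _["dW"] = wrap(dW),
                      _["db"] = NumericVector(db.begin(), db.end()));
}
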