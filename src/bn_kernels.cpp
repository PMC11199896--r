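// Fused batch-normalization kernels over (B, C, S) activations
// (channel statistics across batch and spatial positions).

#include <Rcpp.h>
using namespace Rcpp;

// [[Rcpp::export(name = ".bn_fwd_cpp")]]
List bn_fwd_cpp(NumericVector x, int B, int C, int S,
                NumericVector gamma, NumericVector beta,
                NumericVector run_mean, NumericVector run_var,
                bool training, double eps, double momentum) {
  const R_xlen_t n = static_cast<R_xlen_t>(B) * C * S;
  const double nc = static_cast<double>(B) * S;
  NumericVector out(n), xhat(n), mu(C), var(C), inv_sd(C);
  NumericVector new_mean = clone(run_mean), new_var = clone(run_var);
  for (int c = 0; c < C; ++c) {
    double m, v;
    if (training) {
      double acc = 0.0;
      for (int s = 0; s < S; ++s) {
        const double *p = &x[B * (c + static_cast<R_xlen_t>(C) * s)];
        for (int b = 0; b < B; ++b) acc += p[b];
      }
      m = acc / nc;
      double acc2 = 0.0;
      for (int s = 0; s < S; ++s) {
        const double *p = &x[B * (c + static_cast<R_xlen_t>(C) * s)];
        for (int b = 0; b < B; ++b) { double d = p[b] - m; acc2 += d * d; }
      }
      v = acc2 / nc;
      new_mean[c] = (1 - momentum) * run_mean[c] + momentum * m;
      double vu = nc > 1 ? v * nc / (nc - 1) : v;
      new_var[c] = (1 - momentum) * run_var[c] + momentum * vu;
    } else {
      m = run_mean[c];
      v = run_var[c];
    }
    const double is = 1.0 / std::sqrt(v + eps);
    mu[c] = m; var[c] = v; inv_sd[c] = is;
    const double g = gamma[c], bt = beta[c];
    for (int s = 0; s < S; ++s) {
      const R_xlen_t off = B * (c + static_cast<R_xlen_t>(C) * s);
      for (int b = 0; b < B; ++b) {
        const double xh = (x[off + b] - m) * is;
        xhat[off + b] = xh;
        out[off + b] = g * xh + bt;
      }
    }
  }
  return List::create(_["out"] = out, _["xhat"] = xhat, _["inv_sd"] = inv_sd,
                      _["mean"] = new_mean, _["var"] = new_var);
}

// [[Rcpp::export(name = ".bn_bwd_cpp")]]
List bn_bwd_cpp(NumericVector dout, NumericVector xhat, NumericVector inv_sd,
                NumericVector gamma, int B, int C, int S, bool training) {
  const R_xlen_t n = static_cast<R_xlen_t>(B) * C * S;
  const double nc = static_cast<double>(B) * S;
  NumericVector dx(n), dgamma(C), dbeta(C);
  for (int c = 0; c < C; ++c) {
    double sg = 0.0, sb = 0.0;
    for (int s = 0; s < S; ++s) {
      const R_xlen_t off = B * (c + static_cast<R_xlen_t>(C) * s);
      for (int b = 0; b < B; ++b) {
        sg += dout[off + b] * xhat[off + b];
        sb += dout[off + b];
      }
    }
    dgamma[c] = sg;
    dbeta[c] = sb;
    const double g = gamma[c], is = inv_sd[c];
    if (training) {
      const double m1 = g * sb / nc;     // mean of dxhat
      const double m2 = g * sg / nc;     // mean of dxhat * xhat
      for (int s = 0; s < S; ++s) {
        const R_xlen_t off = B * (c + static_cast<R_xlen_t>(C) * s);
        for (int b = 0; b < B; ++b) {
          dx[off + b] = is * (g * dout[off + b] - m1 - xhat[off + b] * m2);
        }
      }
    } else {
      for (int s = 0; s < S; ++s) {
        const R_xlen_t off = B * (c + static_cast<R_xlen_t>(C) * s);
        for (int b = 0; b < B; ++b) dx[off + b] = g * is * dout[off + b];
      }
    }
  }
  return List::create(_["dx"] = dx, _["dgamma"] = dgamma, _["dbeta"] = dbeta);
}
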