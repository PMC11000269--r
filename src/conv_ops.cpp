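#include <Rcpp.h>
using namespace Rcpp;

// In-place helpers for the 1D convolution hot path. All matrices are owned
// by the caller (freshly allocated products), so in-place mutation is safe.

// out = M shifted by `off` rows with the positions in `zeroidx` set to zero
// (the adjoint pass needs the shifted matrix itself, not an accumulation).
// [[Rcpp::export]]
NumericMatrix shift_zero_cpp(NumericMatrix M, int off, IntegerVector zeroidx) {
  R_xlen_t len = M.size();
  NumericMatrix out(M.nrow(), M.ncol());
  double *m = REAL(M), *o = REAL(out);
  if (off >= 0) {
    for (R_xlen_t p = off; p < len; ++p) o[p] = m[p - off];
  } else {
    R_xlen_t k = -off;
    for (R_xlen_t p = 0; p < len - k; ++p) o[p] = m[p + k];
  }
  for (R_xlen_t i = 0; i < zeroidx.size(); ++i) o[zeroidx[i] - 1] = 0.0;
  return out;
}

// Z = Z (+ per-column bias) (clamped at zero if relu)
// [[Rcpp::export]]
void bias_relu_inplace(NumericMatrix Z, Nullable<NumericVector> bias, bool relu) {
  R_xlen_t R = Z.nrow(), C = Z.ncol();
  double *z = REAL(Z);
  if (bias.isNotNull()) {
    NumericVector b(bias);
    for (R_xlen_t j = 0; j < C; ++j) {
      double bj = b[j];
      double *col = z + j * R;
      if (relu) {
        for (R_xlen_t r = 0; r < R; ++r) {
          double v = col[r] + bj;
          col[r] = v > 0 ? v : 0;
        }
      } else {
        for (R_xlen_t r = 0; r < R; ++r) col[r] += bj;
      }
    }
  } else if (relu) {
    for (R_xlen_t p = 0; p < (R_xlen_t)(R * C); ++p) {
      if (z[p] < 0) z[p] = 0;
    }
  }
}

// Z = Z + M (elementwise), optionally clamped at zero (residual join)
// [[Rcpp::export]]
void add_inplace(NumericMatrix Z, NumericMatrix M, bool relu) {
  R_xlen_t len = Z.size();
  double *z = REAL(Z), *m = REAL(M);
  if (relu) {
    for (R_xlen_t p = 0; p < len; ++p) {
      double v = z[p] + m[p];
      z[p] = v > 0 ? v : 0;
    }
  } else {
    for (R_xlen_t p = 0; p < len; ++p) z[p] += m[p];
  }
}

// Fused tap combination for a same-padded length-k convolution. M is the
// R x (k*C) product of the activations with all k tap weight blocks laid
// side by side; rows are grouped into segments of length L. Output:
// out[r, c] = sum_j M[r + o_j, j*C + c] over taps o_j = j - (k-1)/2 that
// stay within r's segment, plus optional per-channel bias and ReLU.
// [[Rcpp::export]]
NumericMatrix conv_combine(NumericMatrix M, int C, int L,
                           Nullable<NumericVector> bias, bool relu) {
  R_xlen_t R = M.nrow();
  int k = M.ncol() / C;
  int half = (k - 1) / 2;
  NumericMatrix out(R, C);
  double *m = REAL(M), *o = REAL(out);
  for (int c = 0; c < C; ++c) {
    double *oc = o + (R_xlen_t)c * R;
    for (int j = 0; j < k; ++j) {
      int off = j - half;
      double *mc = m + ((R_xlen_t)j * C + c) * R;
      if (off == 0) {
        for (R_xlen_t r = 0; r < R; ++r) oc[r] += mc[r];
      } else {
        for (R_xlen_t s = 0; s < R; s += L) {
          if (off < 0) {
            for (int p = -off; p < L; ++p) oc[s + p] += mc[s + p + off];
          } else {
            for (int p = 0; p < L - off; ++p) oc[s + p] += mc[s + p + off];
          }
        }
      }
    }
    double bj = bias.isNotNull() ? NumericVector(bias)[c] : 0.0;
    if (bias.isNotNull() || relu) {
      for (R_xlen_t r = 0; r < R; ++r) {
        double v = oc[r] + bj;
        oc[r] = (relu && v < 0) ? 0 : v;
      }
    }
  }
  return out;
}

// Fused batch-norm apply: returns xhat = (Z - m) * ivar and
// out = xhat * gamma + beta in a single read pass.
// [[Rcpp::export]]
List bn_apply(NumericMatrix Z, NumericVector m, NumericVector ivar,
              NumericVector gamma, NumericVector beta) {
  R_xlen_t R = Z.nrow(), C = Z.ncol();
  NumericMatrix xhat(R, C), out(R, C);
  double *z = REAL(Z), *xh = REAL(xhat), *o = REAL(out);
  for (R_xlen_t c = 0; c < C; ++c) {
    double mc = m[c], ic = ivar[c], gc = gamma[c], bc = beta[c];
    double *zi = z + c * R, *xi = xh + c * R, *oi = o + c * R;
    for (R_xlen_t r = 0; r < R; ++r) {
      double x = (zi[r] - mc) * ic;
      xi[r] = x;
      oi[r] = x * gc + bc;
    }
  }
  return List::create(_["xhat"] = xhat, _["out"] = out);
}

// dX = dY where gate > 0, else 0 (ReLU backward through a stored activation)
// [[Rcpp::export]]
NumericMatrix relu_bwd(NumericMatrix dY, NumericMatrix gate) {
  R_xlen_t len = dY.size();
  NumericMatrix out(dY.nrow(), dY.ncol());
  double *d = REAL(dY), *g = REAL(gate), *o = REAL(out);
  for (R_xlen_t p = 0; p < len; ++p) o[p] = g[p] > 0 ? d[p] : 0.0;
  return out;
}

// out = Z * brd(scale) + brd(shift), per-column affine (batch norm apply)
// [[Rcpp::export]]
NumericMatrix col_affine(NumericMatrix Z, NumericVector scale, NumericVector shift) {
  R_xlen_t R = Z.nrow(), C = Z.ncol();
  NumericMatrix out(R, C);
  double *z = REAL(Z), *o = REAL(out);
  for (R_xlen_t j = 0; j < C; ++j) {
    double s = scale[j], b = shift[j];
    double *zi = z + j * R, *oi = o + j * R;
    for (R_xlen_t r = 0; r < R; ++r) oi[r] = zi[r] * s + b;
  }
  return out;
}
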