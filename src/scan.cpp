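// Selective state-space scan: sequential recurrence and its adjoint.
//
//   h_t = exp(delta_t * A) .* h_{t-1} + (delta_t * B_t) * x_t
//   y_t = C_t . h_t + D .* x_t
//
// delta: per-step, per-inner-channel step size (already positive);
// A: d_inner x d_state (negative, diagonal dynamics); B_t, C_t: per-step
// d_state vectors shared across channels; D: per-channel skip.
// Several independent sequences may be concatenated along the time axis
// (seqlens); the hidden state resets at each boundary.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// [[Rcpp::export]]
List scan_forward_cpp(const arma::mat& x, const arma::mat& delta,
                      const arma::mat& B, const arma::mat& C,
                      const arma::mat& A, const arma::vec& Dskip,
                      const arma::ivec& seqlens, const bool save_h) {
  const arma::uword L = x.n_rows, d = x.n_cols, n = A.n_cols;
  arma::mat y(L, d, arma::fill::zeros);
  arma::cube H, Ab;
  if (save_h) { H.set_size(d, n, L); Ab.set_size(d, n, L); }
  arma::mat h(d, n);
  arma::uword t = 0;
  for (arma::uword seg = 0; seg < seqlens.n_elem; ++seg) {
    h.zeros();
    const arma::uword len = (arma::uword)seqlens[seg];
    for (arma::uword k = 0; k < len; ++k, ++t) {
      for (arma::uword i = 0; i < d; ++i) {
        const double dt = delta(t, i), xi = x(t, i);
        double acc = 0.0;
        for (arma::uword s = 0; s < n; ++s) {
          const double ab = std::exp(dt * A(i, s));
          const double hv = ab * h(i, s) + dt * B(t, s) * xi;
          h(i, s) = hv;
          acc += C(t, s) * hv;
          if (save_h) Ab(i, s, t) = ab;
        }
        y(t, i) = acc + Dskip(i) * xi;
      }
      if (save_h) H.slice(t) = h;
    }
  }
  if (save_h) return List::create(_["y"] = y, _["H"] = H, _["Ab"] = Ab);
  return List::create(_["y"] = y);
}

// [[Rcpp::export]]
List scan_backward_cpp(const arma::mat& x, const arma::mat& delta,
                       const arma::mat& B, const arma::mat& C,
                       const arma::mat& A, const arma::vec& Dskip,
                       const arma::ivec& seqlens, const arma::cube& H,
                       const arma::cube& Ab, const arma::mat& dy) {
  const arma::uword L = x.n_rows, d = x.n_cols, n = A.n_cols;
  arma::mat dx(L, d, arma::fill::zeros), ddelta(L, d, arma::fill::zeros);
  arma::mat dB(L, n, arma::fill::zeros), dC(L, n, arma::fill::zeros);
  arma::mat dA(d, n, arma::fill::zeros);
  arma::vec dD(d, arma::fill::zeros);
  arma::mat dh(d, n);

  // segment start index for each segment
  arma::uvec starts(seqlens.n_elem);
  arma::uword acc0 = 0;
  for (arma::uword seg = 0; seg < seqlens.n_elem; ++seg) {
    starts[seg] = acc0;
    acc0 += (arma::uword)seqlens[seg];
  }

  for (arma::uword seg = seqlens.n_elem; seg-- > 0;) {
    const arma::uword s0 = starts[seg];
    const arma::uword len = (arma::uword)seqlens[seg];
    dh.zeros();
    for (arma::uword k = len; k-- > 0;) {
      const arma::uword t = s0 + k;
      for (arma::uword i = 0; i < d; ++i) {
        const double dt = delta(t, i), xi = x(t, i), g = dy(t, i);
        double ddel = 0.0, dxi = g * Dskip(i);
        dD(i) += g * xi;
        for (arma::uword s = 0; s < n; ++s) {
          double dhv = dh(i, s) + g * C(t, s);
          dC(t, s) += g * H(i, s, t);
          const double ab = Ab(i, s, t);
          const double hprev = (k == 0) ? 0.0 : H(i, s, t - 1);
          ddel += dhv * (hprev * A(i, s) * ab + B(t, s) * xi);
          dA(i, s) += dhv * hprev * dt * ab;
          dB(t, s) += dhv * dt * xi;
          dxi += dhv * dt * B(t, s);
          dh(i, s) = dhv * ab;
        }
        ddelta(t, i) = ddel;
        dx(t, i) = dxi;
      }
    }
  }
  return List::create(_["dx"] = dx, _["ddelta"] = ddelta, _["dB"] = dB,
                      _["dC"] = dC, _["dA"] = dA, _["dD"] = dD);
}
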