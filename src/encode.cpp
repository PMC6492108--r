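// Off-resonance EPI encoding operator and its adjoint.
//
// Convention: centered unitary DFT (DC at 0-based index floor(n/2), negative
// exponent forward). Sample time is constant along the readout within one
// phase-encode line, so the off-resonance phase accrual is a per-line image
// modulation and each k-space line is one row of the modulated image's 2-D
// DFT. Dense DFT matrices are used; grid sides are at most a few hundred.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace arma;

static cx_mat dft_matrix(uword n) {
  cx_mat F(n, n);
  const double c = std::floor(n / 2.0);
  const double s = 1.0 / std::sqrt(static_cast<double>(n));
  for (uword k = 0; k < n; ++k) {
    for (uword m = 0; m < n; ++m) {
      double a = -2.0 * M_PI * (static_cast<double>(k) - c) *
                 (static_cast<double>(m) - c) / static_cast<double>(n);
      F(k, m) = cx_double(std::cos(a) * s, std::sin(a) * s);
    }
  }
  return F;
}

// x: M x N image; coils: M x N x J; field: M x N effective off-resonance (Hz,
// B0 + global offset); times: length-M per-line sample time (s); mask: length-M
// 0/1 acquired-line indicator. Returns M x N x J multicoil k-space.
// [[Rcpp::export]]
arma::cx_cube forward_encode_cpp(const arma::cx_mat& x, const arma::cx_cube& coils,
                                 const arma::mat& field, const arma::vec& times,
                                 const arma::uvec& mask) {
  const uword M = x.n_rows, N = x.n_cols, J = coils.n_slices;
  const cx_mat W = dft_matrix(M);
  const cx_mat V = dft_matrix(N);  // symmetric, so right-multiplication is V itself
  cx_cube Y(M, N, J, fill::zeros);
  for (uword k = 0; k < M; ++k) {
    if (mask(k) == 0) continue;
    mat a = (-2.0 * M_PI * times(k)) * field;
    cx_mat ph(cos(a), sin(a));
    for (uword j = 0; j < J; ++j) {
      cx_rowvec row = W.row(k) * (coils.slice(j) % x % ph);
      Y.slice(j).row(k) = row * V;
    }
  }
  return Y;
}

// Adjoint of forward_encode_cpp: sum over coils of conj(C_j) times the
// conjugate-phase backtransform of each coil's k-space. Unacquired lines
// contribute nothing.
// [[Rcpp::export]]
arma::cx_mat adjoint_encode_cpp(const arma::cx_cube& y, const arma::cx_cube& coils,
                                const arma::mat& field, const arma::vec& times,
                                const arma::uvec& mask) {
  const uword M = y.n_rows, N = y.n_cols, J = y.n_slices;
  const cx_mat W = dft_matrix(M);
  const cx_mat Vc = conj(dft_matrix(N));
  cx_cube acc(M, N, J, fill::zeros);
  for (uword k = 0; k < M; ++k) {
    if (mask(k) == 0) continue;
    mat a = (2.0 * M_PI * times(k)) * field;
    cx_mat ph(cos(a), sin(a));
    cx_vec wk = W.row(k).t();  // Hermitian transpose: conj(W(k, .)) as column
    for (uword j = 0; j < J; ++j) {
      cx_rowvec g = y.slice(j).row(k) * Vc;
      acc.slice(j) += (wk * g) % ph;
    }
  }
  cx_mat out(M, N, fill::zeros);
  for (uword j = 0; j < J; ++j) out += conj(coils.slice(j)) % acc.slice(j);
  return out;
}
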