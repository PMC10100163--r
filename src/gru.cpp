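// Batched GRU layer: forward over a padded sequence, backprop through time,
// and a single-step cell for greedy decoding.
//
// Shapes: X (B x I x T) inputs, h0 (B x H), W (I x 3H), U (H x 3H),
// b (1 x 3H). Gate order along columns: update z, reset r, candidate n.
//   z_t = sigmoid(x W_z + h_{t-1} U_z + b_z)
//   r_t = sigmoid(x W_r + h_{t-1} U_r + b_r)
//   n_t = tanh(x W_n + r_t * (h_{t-1} U_n) + b_n)
//   h_t = (1 - z_t) * n_t + z_t * h_{t-1}

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static inline mat sigm(const mat& x) { return 1.0 / (1.0 + exp(-x)); }

// [[Rcpp::export]]
Rcpp::List cpp_gru_forward(const arma::cube& X, const arma::mat& h0,
                           const arma::mat& W, const arma::mat& U,
                           const arma::rowvec& b) {
  const uword B = X.n_rows, T = X.n_slices, H = h0.n_cols;
  cube Hs(B, H, T), Z(B, H, T), R(B, H, T), N(B, H, T), HUn(B, H, T);
  mat h = h0;
  const mat Uz = U.cols(0, H - 1), Ur = U.cols(H, 2 * H - 1),
            Un = U.cols(2 * H, 3 * H - 1);
  const rowvec bz = b.cols(0, H - 1), br = b.cols(H, 2 * H - 1),
               bn = b.cols(2 * H, 3 * H - 1);
  for (uword t = 0; t < T; ++t) {
    mat A = X.slice(t) * W;                       // B x 3H
    mat hUn = h * Un;
    mat z = sigm(A.cols(0, H - 1) + h * Uz + repmat(bz, B, 1));
    mat r = sigm(A.cols(H, 2 * H - 1) + h * Ur + repmat(br, B, 1));
    mat n = tanh(A.cols(2 * H, 3 * H - 1) + r % hUn + repmat(bn, B, 1));
    mat hn = (1.0 - z) % n + z % h;
    Z.slice(t) = z; R.slice(t) = r; N.slice(t) = n; HUn.slice(t) = hUn;
    Hs.slice(t) = hn;
    h = hn;
  }
  return Rcpp::List::create(Rcpp::Named("H") = Hs, Rcpp::Named("Z") = Z,
                            Rcpp::Named("R") = R, Rcpp::Named("N") = N,
                            Rcpp::Named("HUn") = HUn);
}

// dHout: gradient w.r.t. every emitted h_t (B x H x T).
// [[Rcpp::export]]
Rcpp::List cpp_gru_backward(const arma::cube& X, const arma::mat& h0,
                            const arma::mat& W, const arma::mat& U,
                            const arma::cube& Hs, const arma::cube& Z,
                            const arma::cube& R, const arma::cube& N,
                            const arma::cube& HUn, const arma::cube& dHout) {
  const uword B = X.n_rows, I = X.n_cols, T = X.n_slices, H = h0.n_cols;
  const mat Uz = U.cols(0, H - 1), Ur = U.cols(H, 2 * H - 1),
            Un = U.cols(2 * H, 3 * H - 1);
  cube dX(B, I, T, fill::zeros);
  mat dW(I, 3 * H, fill::zeros), dU(H, 3 * H, fill::zeros);
  rowvec db(3 * H, fill::zeros);
  mat carry(B, H, fill::zeros);
  for (uword t = T; t-- > 0;) {
    mat dh = dHout.slice(t) + carry;
    const mat& z = Z.slice(t); const mat& r = R.slice(t);
    const mat& n = N.slice(t); const mat& hUn = HUn.slice(t);
    mat h_prev = (t == 0) ? h0 : Hs.slice(t - 1);
    mat dz = dh % (h_prev - n);
    mat dn_pre = (dh % (1.0 - z)) % (1.0 - n % n);
    mat dr = dn_pre % hUn;
    mat d_hUn = dn_pre % r;
    mat dz_pre = dz % z % (1.0 - z);
    mat dr_pre = dr % r % (1.0 - r);
    mat G = join_rows(dz_pre, dr_pre, dn_pre);   // B x 3H
    dW += X.slice(t).t() * G;
    db += sum(G, 0);
    dU.cols(0, H - 1)         += h_prev.t() * dz_pre;
    dU.cols(H, 2 * H - 1)     += h_prev.t() * dr_pre;
    dU.cols(2 * H, 3 * H - 1) += h_prev.t() * d_hUn;
    dX.slice(t) = G * W.t();
    carry = dh % z + dz_pre * Uz.t() + dr_pre * Ur.t() + d_hUn * Un.t();
  }
  return Rcpp::List::create(Rcpp::Named("dX") = dX, Rcpp::Named("dW") = dW,
                            Rcpp::Named("dU") = dU, Rcpp::Named("db") = db,
                            Rcpp::Named("dh0") = carry);
}

// One step for greedy decoding: x (B x I), h_prev (B x H) -> h (B x H).
// [[Rcpp::export]]
arma::mat cpp_gru_cell(const arma::mat& x, const arma::mat& h_prev,
                       const arma::mat& W, const arma::mat& U,
                       const arma::rowvec& b) {
  const uword B = x.n_rows, H = h_prev.n_cols;
  mat A = x * W;
  mat z = sigm(A.cols(0, H - 1) + h_prev * U.cols(0, H - 1) +
               repmat(b.cols(0, H - 1), B, 1));
  mat r = sigm(A.cols(H, 2 * H - 1) + h_prev * U.cols(H, 2 * H - 1) +
               repmat(b.cols(H, 2 * H - 1), B, 1));
  mat n = tanh(A.cols(2 * H, 3 * H - 1) +
               r % (h_prev * U.cols(2 * H, 3 * H - 1)) +
               repmat(b.cols(2 * H, 3 * H - 1), B, 1));
  return (1.0 - z) % n + z % h_prev;
}
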