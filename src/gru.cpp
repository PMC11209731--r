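// Recurrent core of the Bi-GRU sequence encoder. The embedding lookup,
// the input-side gate products and the output projection are batched on
// the R side; only the timestep recursion lives here.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// xW: (B*L) x 3H input-side pre-activations (r | z | n blocks), step t in
// rows (t-1)B+1..tB. mask: B x L. Recurrent weights Ur, Uz, Un: H x H.
// Returns the final hidden state plus the per-step quantities the
// backward pass needs (as B x (L*H) matrices, step t in columns
// (t-1)H+1..tH).
// [[Rcpp::export(name = ".gru_fwd_cpp")]]
List gru_fwd_cpp(const arma::mat& xW, const arma::vec& bias,
                 const arma::mat& mask, const arma::mat& Ur,
                 const arma::mat& Uz, const arma::mat& Un) {
  const int H = Ur.n_rows;
  const int B = mask.n_rows;
  const int L = mask.n_cols;
  arma::mat h(B, H, arma::fill::zeros);
  arma::mat R(B, L * H), Z(B, L * H), N(B, L * H), Hprev(B, L * H);
  const arma::rowvec br = bias.subvec(0, H - 1).t();
  const arma::rowvec bz = bias.subvec(H, 2 * H - 1).t();
  const arma::rowvec bn = bias.subvec(2 * H, 3 * H - 1).t();
  for (int t = 0; t < L; ++t) {
    arma::mat xr = xW.submat(t * B, 0, t * B + B - 1, H - 1);
    arma::mat xz = xW.submat(t * B, H, t * B + B - 1, 2 * H - 1);
    arma::mat xn = xW.submat(t * B, 2 * H, t * B + B - 1, 3 * H - 1);
    xr.each_row() += br;
    xz.each_row() += bz;
    xn.each_row() += bn;
    arma::mat r = 1.0 / (1.0 + arma::exp(-(xr + h * Ur)));
    arma::mat z = 1.0 / (1.0 + arma::exp(-(xz + h * Uz)));
    arma::mat n = arma::tanh(xn + (r % h) * Un);
    Hprev.cols(t * H, t * H + H - 1) = h;
    R.cols(t * H, t * H + H - 1) = r;
    Z.cols(t * H, t * H + H - 1) = z;
    N.cols(t * H, t * H + H - 1) = n;
    arma::vec m = mask.col(t);
    arma::mat h_new = (1.0 - z) % n + z % h;
    h = h_new.each_col() % m + h.each_col() % (1.0 - m);
  }
  return List::create(_["h"] = h, _["R"] = R, _["Z"] = Z, _["N"] = N,
                      _["Hprev"] = Hprev);
}

// Backward pass through the recursion. dh: B x H gradient at the final
// hidden state. Returns recurrent-weight gradients and DA, the (B*L) x 3H
// matrix of gate pre-activation gradients (dar | daz | dan) from which the
// R side recovers input-weight, bias and embedding gradients in one
// product each.
// [[Rcpp::export(name = ".gru_bwd_cpp")]]
List gru_bwd_cpp(const arma::mat& mask, const arma::mat& Ur,
                 const arma::mat& Uz, const arma::mat& Un,
                 const arma::mat& R, const arma::mat& Z, const arma::mat& N,
                 const arma::mat& Hprev, arma::mat dh) {
  const int H = Ur.n_rows;
  const int B = mask.n_rows;
  const int L = mask.n_cols;
  arma::mat gUr(H, H, arma::fill::zeros), gUz(H, H, arma::fill::zeros),
      gUn(H, H, arma::fill::zeros);
  arma::mat DA(B * L, 3 * H);
  for (int t = L - 1; t >= 0; --t) {
    arma::mat r = R.cols(t * H, t * H + H - 1);
    arma::mat z = Z.cols(t * H, t * H + H - 1);
    arma::mat n = N.cols(t * H, t * H + H - 1);
    arma::mat hp = Hprev.cols(t * H, t * H + H - 1);
    arma::vec m = mask.col(t);
    arma::mat dh_c = dh.each_col() % m;
    arma::mat dh_prev = dh.each_col() % (1.0 - m) + dh_c % z;
    arma::mat dz = dh_c % (hp - n);
    arma::mat dan = (dh_c % (1.0 - z)) % (1.0 - n % n);
    gUn += (r % hp).t() * dan;
    arma::mat drh = dan * Un.t();
    arma::mat dr = drh % hp;
    dh_prev += drh % r;
    arma::mat dar = dr % r % (1.0 - r);
    arma::mat daz = dz % z % (1.0 - z);
    gUr += hp.t() * dar;
    gUz += hp.t() * daz;
    dh_prev += dar * Ur.t() + daz * Uz.t();
    DA.submat(t * B, 0, t * B + B - 1, H - 1) = dar;
    DA.submat(t * B, H, t * B + B - 1, 2 * H - 1) = daz;
    DA.submat(t * B, 2 * H, t * B + B - 1, 3 * H - 1) = dan;
    dh = dh_prev;
  }
  return List::create(_["gUr"] = gUr, _["gUz"] = gUz, _["gUn"] = gUn,
                      _["DA"] = DA);
}
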