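// Hot inner loops of the neural-network code: batched multi-head
// scaled dot-product attention and same-padded 1-D convolution over
// stacked sequence blocks. A batch of B sequences of length L is a
// (B*L) x C matrix of contiguous row blocks.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Multi-head attention over B blocks: per (block, head), softmax of
// Q K^T / sqrt(dk) times V. Returns the concatenated head outputs and
// the attention weights (one L x L slice per block*head) for backprop.
// [[Rcpp::export(name = ".mhaForwardCpp")]]
Rcpp::List mhaForward(const arma::mat& Q, const arma::mat& K, const arma::mat& V,
                      const int B, const int L, const int nh) {
  const int dk = Q.n_cols / nh;
  const double scale = 1.0 / std::sqrt((double) dk);
  mat O(Q.n_rows, Q.n_cols);
  cube A(L, L, (size_t) B * nh);
  for (int b = 0; b < B; ++b) {
    const int r0 = b * L, r1 = r0 + L - 1;
    for (int h = 0; h < nh; ++h) {
      const int c0 = h * dk, c1 = c0 + dk - 1;
      mat S = Q.submat(r0, c0, r1, c1) * K.submat(r0, c0, r1, c1).t() * scale;
      S.each_col() -= max(S, 1);
      S = exp(S);
      S.each_col() /= sum(S, 1);
      A.slice((size_t) b * nh + h) = S;
      O.submat(r0, c0, r1, c1) = S * V.submat(r0, c0, r1, c1);
    }
  }
  return Rcpp::List::create(Rcpp::Named("O") = O, Rcpp::Named("A") = A);
}

// [[Rcpp::export(name = ".mhaBackwardCpp")]]
Rcpp::List mhaBackward(const arma::mat& dO, const arma::mat& Q, const arma::mat& K,
                       const arma::mat& V, const arma::cube& A,
                       const int B, const int L, const int nh) {
  const int dk = Q.n_cols / nh;
  const double scale = 1.0 / std::sqrt((double) dk);
  mat dQ(size(Q), fill::zeros), dK(size(K), fill::zeros),
      dV(size(V), fill::zeros);
  for (int b = 0; b < B; ++b) {
    const int r0 = b * L, r1 = r0 + L - 1;
    for (int h = 0; h < nh; ++h) {
      const int c0 = h * dk, c1 = c0 + dk - 1;
      const mat& Ah = A.slice((size_t) b * nh + h);
      mat dOh = dO.submat(r0, c0, r1, c1);
      dV.submat(r0, c0, r1, c1) = Ah.t() * dOh;
      mat dA = dOh * V.submat(r0, c0, r1, c1).t();
      // softmax backward: dS = A % (dA - rowSums(A % dA))
      mat dS = Ah % (dA - repmat(sum(Ah % dA, 1), 1, L));
      dQ.submat(r0, c0, r1, c1) = dS * K.submat(r0, c0, r1, c1) * scale;
      dK.submat(r0, c0, r1, c1) = dS.t() * Q.submat(r0, c0, r1, c1) * scale;
    }
  }
  return Rcpp::List::create(Rcpp::Named("dQ") = dQ,
                            Rcpp::Named("dK") = dK,
                            Rcpp::Named("dV") = dV);
}

// Same-padded 1-D convolution: W holds K stacked Cin x Cout taps
// (rows (k*Cin)..(k*Cin+Cin-1) are tap k, shifts -(K-1)/2 .. +(K-1)/2).
// [[Rcpp::export(name = ".conv1dForwardCpp")]]
arma::mat conv1dForward(const arma::mat& X, const arma::mat& W, const arma::vec& b,
                  const int B, const int L) {
  const int cin = X.n_cols;
  const int K = W.n_rows / cin;
  const int r = (K - 1) / 2;
  mat out(X.n_rows, W.n_cols);
  out.each_row() = b.t();
  for (int k = 0; k < K; ++k) {
    const int s = k - r;
    const mat Wk = W.rows(k * cin, k * cin + cin - 1);
    const int lo = std::max(0, -s), hi = std::min(L, L - s); // rows lo..hi-1
    if (hi <= lo) continue;
    for (int blk = 0; blk < B; ++blk) {
      const int base = blk * L;
      out.rows(base + lo, base + hi - 1) +=
        X.rows(base + lo + s, base + hi - 1 + s) * Wk;
    }
  }
  return out;
}

// [[Rcpp::export(name = ".conv1dBackwardCpp")]]
Rcpp::List conv1dBackward(const arma::mat& dOut, const arma::mat& X, const arma::mat& W,
                          const int B, const int L) {
  const int cin = X.n_cols;
  const int K = W.n_rows / cin;
  const int r = (K - 1) / 2;
  mat dW(size(W), fill::zeros);
  mat dX(size(X), fill::zeros);
  for (int k = 0; k < K; ++k) {
    const int s = k - r;
    const mat Wk = W.rows(k * cin, k * cin + cin - 1);
    const int lo = std::max(0, -s), hi = std::min(L, L - s);
    if (hi <= lo) continue;
    mat dWk(cin, W.n_cols, fill::zeros);
    for (int blk = 0; blk < B; ++blk) {
      const int base = blk * L;
      const mat dOb = dOut.rows(base + lo, base + hi - 1);
      dWk += X.rows(base + lo + s, base + hi - 1 + s).t() * dOb;
      dX.rows(base + lo + s, base + hi - 1 + s) += dOb * Wk.t();
    }
    dW.rows(k * cin, k * cin + cin - 1) = dWk;
  }
  return Rcpp::List::create(Rcpp::Named("dW") = dW,
                            Rcpp::Named("db") = sum(dOut, 0).t(),
                            Rcpp::Named("dX") = dX);
}
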