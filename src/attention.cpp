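// Multi-head scaled dot-product attention kernels (forward + backward).
//
// Layout convention: activations are row-block matrices, (B * L) x d_model,
// rows (b*L)..(b*L + L - 1) holding sample b. Heads split d_model into H
// contiguous column groups of width dk = d_model / H.
//
// Three attention flavours share one code path:
//   * dense:        u <= 0 or u >= Lq, causal = false
//   * causal dense: causal = true (requires Lq == Lk)
//   * ProbSparse:   0 < u < Lq, causal = false. Only the u queries with the
//     largest max-minus-mean score gap receive softmax weights; the remaining
//     queries fall back to the time-mean of V (uniform weights). The top-u
//     selection is treated as non-differentiable, so those fallback rows pass
//     no gradient to Q or K.
//
// The backward pass recomputes the softmax weights from Q and K (plus the
// forward top-u selection) rather than caching them: the probability cubes
// are large, and recomputation is cheaper than shipping them to R and back.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

static inline void softmax_row_inplace(rowvec& s) {
  double m = s.max();
  s = exp(s - m);
  s /= accu(s);
}

// Recompute the attention weight matrix for one (sample, head) slice.
static void attn_weights(const mat& Qb, const mat& Kb, double scale,
                         bool causal, bool sparse, int u,
                         const umat& sel, int slice, bool store_sel,
                         umat& sel_out, mat& P) {
  const int Lq = Qb.n_rows, Lk = Kb.n_rows;
  mat S = Qb * Kb.t() * scale;
  P.zeros(Lq, Lk);
  if (sparse) {
    uvec chosen;
    if (store_sel) {
      vec M = max(S, 1) - mean(S, 1);
      uvec ord = sort_index(M, "descend");
      chosen = ord.head(u);
      sel_out.col(slice) = chosen;
    } else {
      chosen = sel.col(slice);
    }
    P.fill(1.0 / Lk);            // fallback: uniform = time-mean of V
    for (int r = 0; r < u; ++r) {
      rowvec srow = S.row(chosen(r));
      softmax_row_inplace(srow);
      P.row(chosen(r)) = srow;
    }
  } else if (causal) {
    for (int i = 0; i < Lq; ++i) {
      rowvec srow = S.row(i).head(i + 1);
      softmax_row_inplace(srow);
      P.row(i).head(i + 1) = srow;
    }
  } else {
    for (int i = 0; i < Lq; ++i) {
      rowvec srow = S.row(i);
      softmax_row_inplace(srow);
      P.row(i) = srow;
    }
  }
}

// [[Rcpp::export(name = ".mha_forward")]]
Rcpp::List mha_forward(const arma::mat& Q, const arma::mat& K, const arma::mat& V,
                       int B, int H, bool causal, int u) {
  const int d_model = Q.n_cols;
  if (d_model % H != 0) Rcpp::stop("d_model must be divisible by n_heads");
  const int dk = d_model / H;
  const int Lq = Q.n_rows / B;
  const int Lk = K.n_rows / B;
  if (causal && Lq != Lk) Rcpp::stop("causal attention requires Lq == Lk");
  const double scale = 1.0 / std::sqrt((double)dk);
  const bool sparse = (!causal) && u > 0 && u < Lq;

  mat out(B * Lq, d_model, fill::zeros);
  umat sel;
  if (sparse) sel.set_size(u, B * H);
  mat P;
  const umat dummy;

  for (int b = 0; b < B; ++b) {
    for (int h = 0; h < H; ++h) {
      const int slice = b * H + h;
      mat Qb = Q.submat(b * Lq, h * dk, (b + 1) * Lq - 1, (h + 1) * dk - 1);
      mat Kb = K.submat(b * Lk, h * dk, (b + 1) * Lk - 1, (h + 1) * dk - 1);
      mat Vb = V.submat(b * Lk, h * dk, (b + 1) * Lk - 1, (h + 1) * dk - 1);
      attn_weights(Qb, Kb, scale, causal, sparse, u, dummy, slice, sparse, sel, P);
      out.submat(b * Lq, h * dk, (b + 1) * Lq - 1, (h + 1) * dk - 1) = P * Vb;
    }
  }
  return Rcpp::List::create(Rcpp::Named("out") = out,
                            Rcpp::Named("sel") = sel);
}

// [[Rcpp::export(name = ".mha_backward")]]
Rcpp::List mha_backward(const arma::mat& dOut,
                        const arma::mat& Q, const arma::mat& K, const arma::mat& V,
                        int B, int H, bool causal, int u,
                        const arma::umat& sel) {
  const int d_model = Q.n_cols;
  const int dk = d_model / H;
  const int Lq = Q.n_rows / B;
  const int Lk = K.n_rows / B;
  const double scale = 1.0 / std::sqrt((double)dk);
  const bool sparse = (!causal) && u > 0 && u < Lq;

  mat dQ(size(Q), fill::zeros), dK(size(K), fill::zeros), dV(size(V), fill::zeros);
  mat P;
  umat sel_dummy;

  for (int b = 0; b < B; ++b) {
    for (int h = 0; h < H; ++h) {
      const int slice = b * H + h;
      mat Qb = Q.submat(b * Lq, h * dk, (b + 1) * Lq - 1, (h + 1) * dk - 1);
      mat Kb = K.submat(b * Lk, h * dk, (b + 1) * Lk - 1, (h + 1) * dk - 1);
      mat Vb = V.submat(b * Lk, h * dk, (b + 1) * Lk - 1, (h + 1) * dk - 1);
      mat dOb = dOut.submat(b * Lq, h * dk, (b + 1) * Lq - 1, (h + 1) * dk - 1);

      attn_weights(Qb, Kb, scale, causal, sparse, u, sel, slice, false, sel_dummy, P);

      dV.submat(b * Lk, h * dk, (b + 1) * Lk - 1, (h + 1) * dk - 1) += P.t() * dOb;

      mat dP = dOb * Vb.t();
      // softmax backward; rows where P is not a softmax are zeroed below
      mat dS = P % (dP - repmat(sum(dP % P, 1), 1, Lk));
      if (sparse) {
        // fallback rows carry constant uniform weights: no grad through Q, K
        uvec keep(Lq, fill::zeros);
        for (int r = 0; r < u; ++r) keep(sel(r, slice)) = 1;
        for (int i = 0; i < Lq; ++i) if (!keep(i)) dS.row(i).zeros();
      }
      dS *= scale;
      dQ.submat(b * Lq, h * dk, (b + 1) * Lq - 1, (h + 1) * dk - 1) += dS * Kb;
      dK.submat(b * Lk, h * dk, (b + 1) * Lk - 1, (h + 1) * dk - 1) += dS.t() * Qb;
    }
  }
  return Rcpp::List::create(Rcpp::Named("dQ") = dQ,
                            Rcpp::Named("dK") = dK,
                            Rcpp::Named("dV") = dV);
}
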