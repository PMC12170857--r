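// Per-edge kernels for graph-attention message passing.
// Edges are directed (ei -> ej), 1-based indices from R, self-loops included.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// ELU and its derivative in one pass
// [[Rcpp::export]]
Rcpp::List cpp_elu_both(const arma::mat& x) {
  arma::mat out(x.n_rows, x.n_cols), grad(x.n_rows, x.n_cols);
  const double* xp = x.memptr();
  double* op = out.memptr();
  double* gp = grad.memptr();
  arma::uword nn = x.n_elem;
  for (arma::uword i = 0; i < nn; ++i) {
    double v = xp[i];
    if (v > 0) { op[i] = v; gp[i] = 1.0; }
    else { double e = std::exp(v); op[i] = e - 1.0; gp[i] = e; }
  }
  return Rcpp::List::create(Rcpp::Named("out") = out,
                            Rcpp::Named("grad") = grad);
}

// per-edge attention softmax: logits are LeakyReLU(s1[ei] + s2[ej]),
// normalized over each source neighbourhood
// [[Rcpp::export]]
Rcpp::List cpp_edge_softmax(const arma::vec& s1, const arma::vec& s2,
                            const arma::uvec& ei, const arma::uvec& ej,
                            double slope, int n) {
  arma::uword ne = ei.n_elem;
  arma::vec raw(ne), alpha(ne);
  arma::vec mx(n); mx.fill(-arma::datum::inf);
  for (arma::uword e = 0; e < ne; ++e) {
    double v = s1[ei[e] - 1] + s2[ej[e] - 1];
    if (v < 0) v *= slope;
    raw[e] = v;
    if (v > mx[ei[e] - 1]) mx[ei[e] - 1] = v;
  }
  arma::vec den(n, arma::fill::zeros);
  for (arma::uword e = 0; e < ne; ++e) {
    alpha[e] = std::exp(raw[e] - mx[ei[e] - 1]);
    den[ei[e] - 1] += alpha[e];
  }
  for (arma::uword e = 0; e < ne; ++e) alpha[e] /= den[ei[e] - 1];
  return Rcpp::List::create(Rcpp::Named("alpha") = alpha,
                            Rcpp::Named("raw") = raw);
}

// backward of the edge softmax + LeakyReLU: given dL/dalpha, return the
// gradients of the per-node scores s1 (source) and s2 (destination)
// [[Rcpp::export]]
Rcpp::List cpp_edge_softmax_bwd(const arma::vec& dalpha,
                                const arma::vec& alpha,
                                const arma::vec& raw,
                                const arma::uvec& ei, const arma::uvec& ej,
                                double slope, int n) {
  arma::uword ne = ei.n_elem;
  arma::vec srow(n, arma::fill::zeros);
  for (arma::uword e = 0; e < ne; ++e)
    srow[ei[e] - 1] += alpha[e] * dalpha[e];
  arma::vec ds1(n, arma::fill::zeros), ds2(n, arma::fill::zeros);
  for (arma::uword e = 0; e < ne; ++e) {
    double d = alpha[e] * (dalpha[e] - srow[ei[e] - 1]);
    if (raw[e] < 0) d *= slope;   // raw < 0 iff pre-activation < 0
    ds1[ei[e] - 1] += d;
    ds2[ej[e] - 1] += d;
  }
  return Rcpp::List::create(Rcpp::Named("ds1") = ds1,
                            Rcpp::Named("ds2") = ds2);
}

// full-matrix adjacency cross-entropy (binary a, logits z z^T) and its
// latent gradient: loss = [sum softplus(s) - sum_{a=1} s] / n^2,
// dz = 2 (sigmoid(S) - A) z / n^2
// [[Rcpp::export]]
Rcpp::List cpp_adj_loss(const arma::mat& z, const arma::mat& A) {
  arma::uword n = z.n_rows;
  arma::mat S = z * z.t();
  double loss = 0.0;
  arma::mat G(n, n);
  const double* ap = A.memptr();
  const double* sp = S.memptr();
  double* gp = G.memptr();
  for (arma::uword i = 0; i < n * n; ++i) {
    double s = sp[i];
    double sig = 1.0 / (1.0 + std::exp(-s));
    loss += (s > 0 ? s : 0.0) + std::log1p(std::exp(-std::abs(s)));
    if (ap[i] > 0) loss -= s;
    gp[i] = sig - ap[i];
  }
  double n2 = static_cast<double>(n) * n;
  arma::mat dz = (2.0 / n2) * (G * z);
  return Rcpp::List::create(Rcpp::Named("loss") = loss / n2,
                            Rcpp::Named("dz") = dz);
}

// [[Rcpp::export]]
arma::vec cpp_seg_max(const arma::vec& x, const arma::uvec& g, int ng) {
  arma::vec out(ng);
  out.fill(-arma::datum::inf);
  for (arma::uword e = 0; e < x.n_elem; ++e) {
    arma::uword k = g[e] - 1;
    if (x[e] > out[k]) out[k] = x[e];
  }
  return out;
}

// [[Rcpp::export]]
arma::vec cpp_seg_sum(const arma::vec& x, const arma::uvec& g, int ng) {
  arma::vec out(ng, arma::fill::zeros);
  for (arma::uword e = 0; e < x.n_elem; ++e) out[g[e] - 1] += x[e];
  return out;
}

// dot(A.row(ei[e]), B.row(ej[e])) for every edge; transposed internally so
// each row dot runs over a contiguous column
// [[Rcpp::export]]
arma::vec cpp_edge_dot(const arma::mat& A, const arma::mat& B,
                       const arma::uvec& ei, const arma::uvec& ej) {
  arma::mat At = A.t(), Bt = B.t();
  arma::uword ne = ei.n_elem, d = At.n_rows;
  arma::vec out(ne, arma::fill::zeros);
  for (arma::uword e = 0; e < ne; ++e) {
    const double* a = At.colptr(ei[e] - 1);
    const double* b = Bt.colptr(ej[e] - 1);
    double s = 0.0;
    for (arma::uword c = 0; c < d; ++c) s += a[c] * b[c];
    out[e] = s;
  }
  return out;
}

// out.row(ei[e]) += w[e] * H.row(ej[e]); out has n rows
// [[Rcpp::export]]
arma::mat cpp_edge_aggregate(const arma::mat& H, const arma::vec& w,
                             const arma::uvec& ei, const arma::uvec& ej,
                             int n) {
  arma::mat Ht = H.t();
  arma::uword ne = ei.n_elem, d = Ht.n_rows;
  arma::mat outt(d, n, arma::fill::zeros);
  for (arma::uword e = 0; e < ne; ++e) {
    double* o = outt.colptr(ei[e] - 1);
    const double* hp = Ht.colptr(ej[e] - 1);
    double we = w[e];
    for (arma::uword c = 0; c < d; ++c) o[c] += we * hp[c];
  }
  return outt.t();
}

// ---- stacked-head GAT layer kernels -------------------------------------
// All Q heads processed in one call: Wall is d_in x (Q*d_out) with head q
// in columns [q*d_out, (q+1)*d_out); asrc/adst are d_out x Q.

// [[Rcpp::export]]
Rcpp::List cpp_gat_fwd(const arma::mat& h, const arma::mat& Wall,
                       const arma::mat& asrc, const arma::mat& adst,
                       const arma::uvec& ei, const arma::uvec& ej,
                       double slope, bool elu, int n) {
  arma::uword Q = asrc.n_cols, dout = asrc.n_rows, ne = ei.n_elem;
  arma::mat Hall = h * Wall;            // n x Q*dout
  arma::mat Ht = Hall.t();              // Q*dout x n (contiguous per node)
  arma::mat alpha(ne, Q), raw(ne, Q);
  arma::mat acc(dout, n, arma::fill::zeros);
  arma::vec mx(n), den(n);
  for (arma::uword q = 0; q < Q; ++q) {
    arma::uword off = q * dout;
    arma::vec s1(n), s2(n);
    for (arma::uword i = 0; i < (arma::uword)n; ++i) {
      const double* hp = Ht.colptr(i) + off;
      double v1 = 0, v2 = 0;
      const double* a1 = asrc.colptr(q);
      const double* a2 = adst.colptr(q);
      for (arma::uword c = 0; c < dout; ++c) { v1 += a1[c] * hp[c]; v2 += a2[c] * hp[c]; }
      s1[i] = v1; s2[i] = v2;
    }
    mx.fill(-arma::datum::inf);
    double* rq = raw.colptr(q);
    double* aq = alpha.colptr(q);
    for (arma::uword e = 0; e < ne; ++e) {
      double v = s1[ei[e] - 1] + s2[ej[e] - 1];
      if (v < 0) v *= slope;
      rq[e] = v;
      if (v > mx[ei[e] - 1]) mx[ei[e] - 1] = v;
    }
    den.zeros();
    for (arma::uword e = 0; e < ne; ++e) {
      aq[e] = std::exp(rq[e] - mx[ei[e] - 1]);
      den[ei[e] - 1] += aq[e];
    }
    for (arma::uword e = 0; e < ne; ++e) {
      aq[e] /= den[ei[e] - 1];
      double* o = acc.colptr(ei[e] - 1);
      const double* hp = Ht.colptr(ej[e] - 1) + off;
      double w = aq[e];
      for (arma::uword c = 0; c < dout; ++c) o[c] += w * hp[c];
    }
  }
  acc /= (double)Q;
  arma::mat out = acc.t();              // n x dout (pre-activation)
  arma::mat grad;
  if (elu) {
    grad.set_size(n, dout);
    double* op = out.memptr(); double* gp = grad.memptr();
    for (arma::uword i = 0; i < out.n_elem; ++i) {
      if (op[i] > 0) gp[i] = 1.0;
      else { double e = std::exp(op[i]); op[i] = e - 1.0; gp[i] = e; }
    }
  }
  return Rcpp::List::create(Rcpp::Named("out") = out,
                            Rcpp::Named("Hall") = Hall,
                            Rcpp::Named("alpha") = alpha,
                            Rcpp::Named("raw") = raw,
                            Rcpp::Named("grad") = grad);
}

// backward companion: dpre is n x dout, already divided by nothing (the
// activation chain and 1/Q are applied inside)
// [[Rcpp::export]]
Rcpp::List cpp_gat_bwd(const arma::mat& dout_in, const arma::mat& actgrad,
                       bool elu, const arma::mat& h, const arma::mat& Hall,
                       const arma::mat& alpha, const arma::mat& raw,
                       const arma::mat& Wall, const arma::mat& asrc,
                       const arma::mat& adst, const arma::uvec& ei,
                       const arma::uvec& ej, double slope, bool need_dh,
                       int n) {
  arma::uword Q = asrc.n_cols, dout = asrc.n_rows, ne = ei.n_elem;
  arma::mat dpre = dout_in;
  if (elu) dpre %= actgrad;
  dpre /= (double)Q;
  arma::mat dpre_t = dpre.t();          // dout x n
  arma::mat Ht = Hall.t();              // Q*dout x n
  arma::mat dHall_t(Q * dout, n, arma::fill::zeros);
  arma::mat dasrc(dout, Q, arma::fill::zeros), dadst(dout, Q, arma::fill::zeros);
  arma::vec ds1(n), ds2(n), srow(n);
  for (arma::uword q = 0; q < Q; ++q) {
    arma::uword off = q * dout;
    const double* aq = alpha.colptr(q);
    const double* rq = raw.colptr(q);
    // dalpha_e = dpre.row(ei) . Hq.row(ej); accumulate softmax backward
    srow.zeros();
    arma::vec dal(ne);
    for (arma::uword e = 0; e < ne; ++e) {
      const double* dp = dpre_t.colptr(ei[e] - 1);
      const double* hp = Ht.colptr(ej[e] - 1) + off;
      double s = 0;
      for (arma::uword c = 0; c < dout; ++c) s += dp[c] * hp[c];
      dal[e] = s;
      srow[ei[e] - 1] += aq[e] * s;
      // scatter: dHq.row(ej) += alpha_e * dpre.row(ei)
      double* dh = dHall_t.colptr(ej[e] - 1) + off;
      double w = aq[e];
      for (arma::uword c = 0; c < dout; ++c) dh[c] += w * dp[c];
    }
    ds1.zeros(); ds2.zeros();
    for (arma::uword e = 0; e < ne; ++e) {
      double d = aq[e] * (dal[e] - srow[ei[e] - 1]);
      if (rq[e] < 0) d *= slope;
      ds1[ei[e] - 1] += d;
      ds2[ej[e] - 1] += d;
    }
    // da = Hq^T ds ; dHq += ds1 a_src^T + ds2 a_dst^T
    const double* a1 = asrc.colptr(q);
    const double* a2 = adst.colptr(q);
    for (arma::uword i = 0; i < (arma::uword)n; ++i) {
      const double* hp = Ht.colptr(i) + off;
      double* dh = dHall_t.colptr(i) + off;
      double w1 = ds1[i], w2 = ds2[i];
      for (arma::uword c = 0; c < dout; ++c) {
        dasrc(c, q) += hp[c] * w1;
        dadst(c, q) += hp[c] * w2;
        dh[c] += w1 * a1[c] + w2 * a2[c];
      }
    }
  }
  arma::mat dHall = dHall_t.t();
  arma::mat dWall = h.t() * dHall;      // d_in x Q*dout
  arma::mat dh_out;
  if (need_dh) dh_out = dHall * Wall.t();
  return Rcpp::List::create(Rcpp::Named("dWall") = dWall,
                            Rcpp::Named("dasrc") = dasrc,
                            Rcpp::Named("dadst") = dadst,
                            Rcpp::Named("dh") = dh_out);
}

// Fused expression decoder: h = W z^T + b, per-slice batch normalization,
// weighted squared-error loss against X (gene-major), and all gradients.
// slice_of is 1-based; w_col is the per-spot loss weight.
// [[Rcpp::export]]
Rcpp::List cpp_decode_loss(const arma::mat& z, const arma::mat& Wd,
                           const arma::vec& b, const arma::mat& gamma,
                           const arma::mat& beta, double eps,
                           const arma::uvec& slice_of, int L,
                           const arma::mat& X, const arma::vec& w_col) {
  arma::uword m = Wd.n_rows, n = z.n_rows;
  arma::mat H = Wd * z.t();             // m x n
  H.each_col() += b;
  // per-slice statistics
  arma::mat mu(m, L, arma::fill::zeros), m2(m, L, arma::fill::zeros);
  arma::vec cnt(L, arma::fill::zeros);
  for (arma::uword j = 0; j < n; ++j) {
    arma::uword s = slice_of[j] - 1;
    cnt[s] += 1.0;
    const double* hj = H.colptr(j);
    double* mp = mu.colptr(s); double* qp = m2.colptr(s);
    for (arma::uword g = 0; g < m; ++g) { mp[g] += hj[g]; qp[g] += hj[g] * hj[g]; }
  }
  arma::mat den(m, L);
  for (int s = 0; s < L; ++s) {
    if (cnt[s] == 0) { den.col(s).ones(); continue; }
    for (arma::uword g = 0; g < m; ++g) {
      double mn = mu(g, s) / cnt[s];
      double v = m2(g, s) / cnt[s] - mn * mn;
      if (v < 0) v = 0;
      mu(g, s) = mn;
      den(g, s) = std::sqrt(v + eps);
    }
  }
  // forward output, residual loss, dY and the start of the BN backward
  double loss = 0.0;
  arma::mat dxhat(m, n), xhat(m, n);
  arma::mat sum_dx(m, L, arma::fill::zeros), sum_dxx(m, L, arma::fill::zeros);
  arma::mat dgamma(L, m, arma::fill::zeros), dbeta(L, m, arma::fill::zeros);
  for (arma::uword j = 0; j < n; ++j) {
    arma::uword s = slice_of[j] - 1;
    const double* hj = H.colptr(j);
    const double* xj = X.colptr(j);
    double* xh = xhat.colptr(j);
    double* dx = dxhat.colptr(j);
    double w = w_col[j];
    for (arma::uword g = 0; g < m; ++g) {
      double xv = (hj[g] - mu(g, s)) / den(g, s);
      xh[g] = xv;
      double out = gamma(s, g) * xv + beta(s, g);
      double r = out - xj[g];
      loss += w * r * r;
      double dy = 2.0 * w * r;
      dgamma(s, g) += dy * xv;
      dbeta(s, g) += dy;
      double dxh = gamma(s, g) * dy;
      dx[g] = dxh;
      sum_dx(g, s) += dxh;
      sum_dxx(g, s) += dxh * xv;
    }
  }
  // complete BN backward: dH = (dxhat - mean(dxhat) - xhat*mean(dxhat*xhat))/den
  arma::mat dH(m, n);
  arma::vec db(m, arma::fill::zeros);
  for (arma::uword j = 0; j < n; ++j) {
    arma::uword s = slice_of[j] - 1;
    const double* dx = dxhat.colptr(j);
    const double* xh = xhat.colptr(j);
    double* dh = dH.colptr(j);
    for (arma::uword g = 0; g < m; ++g) {
      dh[g] = (dx[g] - sum_dx(g, s) / cnt[s] -
               xh[g] * sum_dxx(g, s) / cnt[s]) / den(g, s);
      db[g] += dh[g];
    }
  }
  arma::mat dW = dH * z;                // m x d
  arma::mat dz = dH.t() * Wd;           // n x d
  return Rcpp::List::create(Rcpp::Named("loss") = loss,
                            Rcpp::Named("dz") = dz,
                            Rcpp::Named("dW") = dW,
                            Rcpp::Named("db") = db,
                            Rcpp::Named("dgamma") = dgamma,
                            Rcpp::Named("dbeta") = dbeta);
}
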