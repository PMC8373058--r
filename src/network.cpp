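// Numeric core: two-layer embedding network, N-pair loss gradients, and
// the AdamW training loop. Kept in C++ because the optimizer touches the
// |gene union| x 500 weight matrix elementwise on every iteration.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

// forward pass; H receives the post-ReLU hidden activations (needed for backprop)
static mat net_forward(const mat& X, const mat& W1, const rowvec& b1,
                       const mat& W2, const rowvec& b2, mat& H) {
  H = X * W1;
  H.each_row() += b1;
  H.transform([](double x) { return x > 0.0 ? x : 0.0; });
  mat E = H * W2;
  E.each_row() += b2;
  return E;
}

// [[Rcpp::export]]
arma::mat cpp_embed(const arma::mat& X, const arma::mat& W1,
                    const arma::rowvec& b1, const arma::mat& W2,
                    const arma::rowvec& b2) {
  mat H;
  return net_forward(X, W1, b1, W2, b2, H);
}

// N-pair loss from embeddings F (anchors, N x d) and Fp (positives, N x d):
//   (1/N) sum_i log(1 + sum_{j != i} exp(F_i . Fp_j - F_i . Fp_i))
// computed with a max-shift so large inner products do not overflow.
// P receives d(loss)/d(logits) for backprop (P_ii carries the negative mass).
static double npair_from_embeddings(const mat& F, const mat& Fp, mat& P,
                                    bool want_grad) {
  const uword N = F.n_rows;
  mat L = F * Fp.t();
  vec dL = L.diag();
  mat D = L;
  D.each_col() -= dL;               // D_ij = f_i.f_j+ - f_i.f_i+
  double loss = 0.0;
  if (want_grad) P.zeros(N, N);
  for (uword i = 0; i < N; ++i) {
    double m = 0.0;                 // shift; the implicit "1" term is exp(0)
    for (uword j = 0; j < N; ++j)
      if (j != i && D(i, j) > m) m = D(i, j);
    double s = std::exp(-m);        // the "1" term, shifted
    for (uword j = 0; j < N; ++j)
      if (j != i) s += std::exp(D(i, j) - m);
    loss += m + std::log(s);
    if (want_grad) {
      double rowsum = 0.0;
      for (uword j = 0; j < N; ++j) {
        if (j == i) continue;
        double p = std::exp(D(i, j) - m) / s;
        P(i, j) = p / double(N);
        rowsum += p;
      }
      P(i, i) = -rowsum / double(N);
    }
  }
  return loss / double(N);
}

// [[Rcpp::export]]
double cpp_npair_loss_embeddings(const arma::mat& F, const arma::mat& Fp) {
  mat P;
  return npair_from_embeddings(F, Fp, P, false);
}

struct Grads {
  mat dW1, dW2;
  rowvec db1, db2;
  void zeros(uword G, uword Hn, uword d) {
    dW1.zeros(G, Hn); db1.zeros(Hn); dW2.zeros(Hn, d); db2.zeros(d);
  }
  void add(const Grads& o) {
    dW1 += o.dW1; db1 += o.db1; dW2 += o.dW2; db2 += o.db2;
  }
};

// loss + parameter gradients for one N-pair batch (A = anchors, Pm = positives)
static double npair_net_grad(const mat& A, const mat& Pm, const mat& W1,
                             const rowvec& b1, const mat& W2, const rowvec& b2,
                             Grads& g) {
  const uword N = A.n_rows;
  mat X = join_cols(A, Pm);
  mat H;
  mat E = net_forward(X, W1, b1, W2, b2, H);
  mat F = E.rows(0, N - 1);
  mat Fp = E.rows(N, 2 * N - 1);
  mat P;
  double loss = npair_from_embeddings(F, Fp, P, true);
  // dLoss/dF = P * Fp ; dLoss/dFp = P' * F
  mat dE = join_cols(P * Fp, P.t() * F);
  g.dW2 = H.t() * dE;
  g.db2 = sum(dE, 0);
  mat dH = dE * W2.t();
  { // ReLU gate, fused single pass
    double* p = dH.memptr();
    const double* h = H.memptr();
    const uword n = dH.n_elem;
    for (uword k = 0; k < n; ++k)
      if (h[k] <= 0.0) p[k] = 0.0;
  }
  g.dW1 = X.t() * dH;
  g.db1 = sum(dH, 0);
  return loss;
}

// [[Rcpp::export]]
Rcpp::List cpp_npair_grad(const arma::mat& A, const arma::mat& P,
                          const arma::mat& W1, const arma::rowvec& b1,
                          const arma::mat& W2, const arma::rowvec& b2) {
  Grads g;
  double loss = npair_net_grad(A, P, W1, b1, W2, b2, g);
  return Rcpp::List::create(
      Rcpp::Named("loss") = loss, Rcpp::Named("dW1") = g.dW1,
      Rcpp::Named("db1") = g.db1, Rcpp::Named("dW2") = g.dW2,
      Rcpp::Named("db2") = g.db2);
}

// two distinct uniform draws from 0..n-1, via R's RNG (reproducible from set.seed)
static void draw_pair(int n, int& i, int& j) {
  i = (int)(unif_rand() * n);
  if (i >= n) i = n - 1;
  j = (int)(unif_rand() * (n - 1));
  if (j >= n - 1) j = n - 2;
  if (j >= i) ++j;
}

// single-pass fused AdamW step (avoids armadillo temporaries on the large
// weight matrices, which dominate iteration cost)
static void adamw_update(double* th, double* m, double* v, const double* g,
                         uword n, double lr, double b1, double b2, double eps,
                         double wd, double bc1, double bc2) {
  const double sb2 = std::sqrt(bc2);
  for (uword k = 0; k < n; ++k) {
    const double gk = g[k];
    m[k] = b1 * m[k] + (1.0 - b1) * gk;
    v[k] = b2 * v[k] + (1.0 - b2) * gk * gk;
    const double mhat = m[k] / bc1;
    const double denom = std::sqrt(v[k]) / sb2 + eps;
    th[k] -= lr * (mhat / denom + wd * th[k]);
  }
}

// Multitask training: per iteration, one fresh N-pair batch per task, losses
// summed, one decoupled-weight-decay Adam step on the shared parameters.
// tasks: list of list(x = cells x genes matrix, types = list of 0-based index
// vectors, one per cell type). Uses R's RNG; caller seeds.
// [[Rcpp::export]]
Rcpp::List cpp_train(Rcpp::List tasks, arma::mat W1, arma::rowvec b1,
                     arma::mat W2, arma::rowvec b2, int epochs,
                     int batches_per_epoch, double lr, double l2_rate) {
  const uword G = W1.n_rows, Hn = W1.n_cols, d = W2.n_cols;
  const int m_tasks = tasks.size();
  const double beta1 = 0.9, beta2 = 0.999, eps = 1e-8;

  std::vector<mat> X(m_tasks);
  std::vector<std::vector<std::vector<int> > > idx(m_tasks);
  for (int t = 0; t < m_tasks; ++t) {
    Rcpp::List task = tasks[t];
    X[t] = Rcpp::as<mat>(task["x"]);
    Rcpp::List types = task["types"];
    for (int k = 0; k < types.size(); ++k)
      idx[t].push_back(Rcpp::as<std::vector<int> >(types[k]));
  }

  mat mW1(G, Hn, fill::zeros), vW1(G, Hn, fill::zeros);
  mat mW2(Hn, d, fill::zeros), vW2(Hn, d, fill::zeros);
  rowvec mb1(Hn, fill::zeros), vb1(Hn, fill::zeros);
  rowvec mb2(d, fill::zeros), vb2(d, fill::zeros);

  Rcpp::NumericVector loss_history(epochs);
  Grads acc;
  long step = 0;

  // anchors+positives of every task stacked row-wise, so the expensive
  // input-layer gradient (G x hidden) is one matmul per iteration instead
  // of one per task: dW1 = sum_t X_t' dH_t = Xall' dHall
  int total_rows = 0;
  for (int t = 0; t < m_tasks; ++t) total_rows += 2 * (int)idx[t].size();
  mat Xall(total_rows, G), dHall(total_rows, Hn);

  for (int e = 0; e < epochs; ++e) {
    double epoch_loss = 0.0;
    for (int it = 0; it < batches_per_epoch; ++it) {
      double total = 0.0;
      acc.dW2.zeros(Hn, d);
      acc.db2.zeros(d);
      int r0 = 0;
      for (int t = 0; t < m_tasks; ++t) {
        const int N = (int)idx[t].size();
        for (int k = 0; k < N; ++k) {
          int i, j;
          draw_pair((int)idx[t][k].size(), i, j);
          Xall.row(r0 + k) = X[t].row(idx[t][k][i]);
          Xall.row(r0 + N + k) = X[t].row(idx[t][k][j]);
        }
        mat Xt = Xall.rows(r0, r0 + 2 * N - 1);
        mat H;
        mat E = net_forward(Xt, W1, b1, W2, b2, H);
        mat Fa = E.rows(0, N - 1), Fp = E.rows(N, 2 * N - 1);
        mat Pg;
        total += npair_from_embeddings(Fa, Fp, Pg, true);
        mat dE = join_cols(Pg * Fp, Pg.t() * Fa);
        acc.dW2 += H.t() * dE;
        acc.db2 += sum(dE, 0);
        mat dH = dE * W2.t();
        {
          double* p = dH.memptr();
          const double* h = H.memptr();
          for (uword k = 0; k < dH.n_elem; ++k)
            if (h[k] <= 0.0) p[k] = 0.0;
        }
        dHall.rows(r0, r0 + 2 * N - 1) = dH;
        r0 += 2 * N;
      }
      acc.dW1 = Xall.t() * dHall;
      acc.db1 = sum(dHall, 0);
      ++step;
      double bc1 = 1.0 - std::pow(beta1, (double)step);
      double bc2 = 1.0 - std::pow(beta2, (double)step);
      adamw_update(W1.memptr(), mW1.memptr(), vW1.memptr(), acc.dW1.memptr(),
                   W1.n_elem, lr, beta1, beta2, eps, l2_rate, bc1, bc2);
      adamw_update(W2.memptr(), mW2.memptr(), vW2.memptr(), acc.dW2.memptr(),
                   W2.n_elem, lr, beta1, beta2, eps, l2_rate, bc1, bc2);
      adamw_update(b1.memptr(), mb1.memptr(), vb1.memptr(), acc.db1.memptr(),
                   b1.n_elem, lr, beta1, beta2, eps, l2_rate, bc1, bc2);
      adamw_update(b2.memptr(), mb2.memptr(), vb2.memptr(), acc.db2.memptr(),
                   b2.n_elem, lr, beta1, beta2, eps, l2_rate, bc1, bc2);
      epoch_loss += total;
    }
    loss_history[e] = epoch_loss / (double)batches_per_epoch;
    if (e % 20 == 0) Rcpp::checkUserInterrupt();
  }

  return Rcpp::List::create(
      Rcpp::Named("W1") = W1, Rcpp::Named("b1") = b1, Rcpp::Named("W2") = W2,
      Rcpp::Named("b2") = b2, Rcpp::Named("loss_history") = loss_history);
}
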