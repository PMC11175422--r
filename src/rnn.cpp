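// Leaky-ReLU recurrent network: per-trial BPTT training with Adam and a
// plain forward pass. Kept in C++ because training runs tens of thousands
// of trials of short sequences; everything else in the package stays in R.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static inline mat lrelu(const mat& z, double a) {
  return z % (z > 0) + a * (z % (z <= 0));
}
static inline mat lrelu_grad(const mat& z, double a) {
  mat g(size(z));
  g.fill(a);
  g.elem(find(z > 0)).fill(1.0);
  return g;
}

struct Adam {
  mat m, v;
  Adam(uword r, uword c) : m(r, c, fill::zeros), v(r, c, fill::zeros) {}
  void step(mat& w, const mat& g, double lr, double b1, double b2,
            double eps, long t) {
    m = b1 * m + (1 - b1) * g;
    v = b2 * v + (1 - b2) * (g % g);
    mat mh = m / (1 - std::pow(b1, (double)t));
    mat vh = v / (1 - std::pow(b2, (double)t));
    w -= lr * mh / (sqrt(vh) + eps);
  }
};

// softmax column-wise for a vector logit
static inline vec softmax_vec(const vec& z) {
  vec e = exp(z - z.max());
  return e / accu(e);
}

// [[Rcpp::export]]
Rcpp::List rnn_train_cpp(Rcpp::List weights, const arma::cube& x,
                         const arma::imat& target,
                         const arma::mat& step_weight, double lr,
                         double leak, int passes) {
  mat Win = Rcpp::as<mat>(weights["Win"]);    // H x D
  mat Wrec = Rcpp::as<mat>(weights["Wrec"]);  // H x H
  vec b = Rcpp::as<vec>(weights["b"]);        // H
  mat Wout = Rcpp::as<mat>(weights["Wout"]);  // A x H
  vec bout = Rcpp::as<vec>(weights["bout"]);  // A

  const uword T = x.n_rows, D = x.n_cols, n = x.n_slices;
  const uword H = Win.n_rows, A = Wout.n_rows;
  if (target.n_rows != T || target.n_cols != n)
    Rcpp::stop("target dimensions do not match inputs");
  if (Win.n_cols != D) Rcpp::stop("input dimension mismatch");

  Adam aWin(H, D), aWrec(H, H), ab(H, 1), aWout(A, H), about(A, 1);
  long t_adam = 0;
  const double b1 = 0.9, b2 = 0.999, eps = 1e-8;
  double loss_sum = 0.0;
  long loss_n = 0;

  mat Z(H, T), Hs(H, T);
  for (int pass = 0; pass < passes; ++pass) {
    for (uword i = 0; i < n; ++i) {
      // forward
      vec h = zeros<vec>(H);
      for (uword tt = 0; tt < T; ++tt) {
        vec z = Win * vectorise(x.slice(i).row(tt)) + Wrec * h + b;
        Z.col(tt) = z;
        h = lrelu(z, leak);
        Hs.col(tt) = h;
      }
      // backward
      mat gWin(H, D, fill::zeros), gWrec(H, H, fill::zeros);
      vec gb(H, fill::zeros);
      mat gWout(A, H, fill::zeros);
      vec gbout(A, fill::zeros);
      vec dh_next = zeros<vec>(H);
      for (uword tt = T; tt-- > 0;) {
        vec p = softmax_vec(Wout * Hs.col(tt) + bout);
        uword y = (uword)(target(tt, i) - 1);
        double w = step_weight(tt, i);
        loss_sum += -w * std::log(std::max(p(y), 1e-12));
        ++loss_n;
        vec dlogit = w * p;
        dlogit(y) -= w;
        gWout += dlogit * Hs.col(tt).t();
        gbout += dlogit;
        vec dh = Wout.t() * dlogit + dh_next;
        vec dz = dh % lrelu_grad(Z.col(tt), leak).col(0);
        gWin += dz * x.slice(i).row(tt);
        gb += dz;
        if (tt > 0) gWrec += dz * Hs.col(tt - 1).t();
        dh_next = Wrec.t() * dz;
      }
      ++t_adam;
      aWin.step(Win, gWin, lr, b1, b2, eps, t_adam);
      aWrec.step(Wrec, gWrec, lr, b1, b2, eps, t_adam);
      mat bM(b.memptr(), H, 1, false);
      ab.step(bM, gb, lr, b1, b2, eps, t_adam);
      aWout.step(Wout, gWout, lr, b1, b2, eps, t_adam);
      mat boutM(bout.memptr(), A, 1, false);
      about.step(boutM, gbout, lr, b1, b2, eps, t_adam);
    }
  }
  return Rcpp::List::create(
      Rcpp::Named("Win") = Win, Rcpp::Named("Wrec") = Wrec,
      Rcpp::Named("b") = b, Rcpp::Named("Wout") = Wout,
      Rcpp::Named("bout") = bout,
      Rcpp::Named("mean_loss") = loss_sum / std::max(loss_n, 1L));
}

// [[Rcpp::export]]
Rcpp::List rnn_forward_cpp(Rcpp::List weights, const arma::cube& x,
                           double leak) {
  mat Win = Rcpp::as<mat>(weights["Win"]);
  mat Wrec = Rcpp::as<mat>(weights["Wrec"]);
  vec b = Rcpp::as<vec>(weights["b"]);
  mat Wout = Rcpp::as<mat>(weights["Wout"]);
  vec bout = Rcpp::as<vec>(weights["bout"]);
  const uword T = x.n_rows, n = x.n_slices;
  const uword H = Win.n_rows, A = Wout.n_rows;
  cube hidden(T, H, n), logits(T, A, n);
  for (uword i = 0; i < n; ++i) {
    vec h = zeros<vec>(H);
    for (uword tt = 0; tt < T; ++tt) {
      h = lrelu(Win * vectorise(x.slice(i).row(tt)) + Wrec * h + b, leak);
      hidden.slice(i).row(tt) = h.t();
      logits.slice(i).row(tt) = (Wout * h + bout).t();
    }
  }
  return Rcpp::List::create(Rcpp::Named("hidden") = hidden,
                            Rcpp::Named("logits") = logits);
}
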