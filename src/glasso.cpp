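#include <RcppArmadillo.h>
#include <numeric>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Exact binomial coefficient in 64-bit integer arithmetic.
// Multiplicative scheme C(n, r) = prod_i (n - r + i) / i with gcd reduction;
// every intermediate equals C(n - r + i, i) so nothing exceeds the final
// value, which fits in int64 for all n <= 64.
// [[Rcpp::export]]
double binom_exact_cpp(int n, int r) {
  if (n < 0 || r < 0) stop("n and r must be non-negative");
  if (r > n) stop("r must not exceed n");
  if (n > 64) stop("exact integer evaluation supported for n <= 64 only");
  if (r > n - r) r = n - r;
  long long res = 1;
  for (long long i = 1; i <= r; ++i) {
    long long m = n - r + i;
    long long g = std::gcd(m, i);
    // i/g divides res exactly (the running product is an integer binomial)
    res = (res / (i / g)) * (m / g);
  }
  return static_cast<double>(res);
}

static inline double soft_threshold(double x, double t) {
  if (x > t) return x - t;
  if (x < -t) return x + t;
  return 0.0;
}

// Coordinate descent for the lasso subproblem
//   min_b 0.5 b' W11 b - s12' b + lambda * ||b||_1
static void lasso_cd(const arma::mat& W11, const arma::vec& s12,
                     arma::vec& beta, double lambda, double thr, int maxit) {
  const arma::uword q = s12.n_elem;
  for (int it = 0; it < maxit; ++it) {
    double del = 0.0;
    for (arma::uword k = 0; k < q; ++k) {
      double bk = beta(k);
      double resid = s12(k) - arma::dot(W11.col(k), beta) + W11(k, k) * bk;
      double bnew = soft_threshold(resid, lambda) / W11(k, k);
      if (bnew != bk) {
        double d = std::fabs(bnew - bk);
        if (d > del) del = d;
        beta(k) = bnew;
      }
    }
    if (del < thr) break;
  }
}

// One glasso solve via block coordinate descent over columns of W.
// W and B are warm starts and are updated in place. Returns convergence flag.
static bool glasso_solve(const arma::mat& S, double lambda, arma::mat& W,
                         arma::mat& B, double thr, int maxit) {
  const arma::uword p = S.n_rows;
  arma::uvec all = arma::regspace<arma::uvec>(0, p - 1);
  for (int it = 0; it < maxit; ++it) {
    double maxdel = 0.0;
    for (arma::uword j = 0; j < p; ++j) {
      arma::uvec idx = arma::find(all != j);
      arma::mat W11 = W.submat(idx, idx);
      arma::vec s12 = S.col(j);
      s12.shed_row(j);
      arma::vec beta = B.col(j);
      beta.shed_row(j);
      lasso_cd(W11, s12, beta, lambda, thr * 0.1, maxit);
      arma::vec w12 = W11 * beta;
      arma::uword t = 0;
      for (arma::uword i = 0; i < p; ++i) {
        if (i == j) continue;
        double d = std::fabs(W(i, j) - w12(t));
        if (d > maxdel) maxdel = d;
        W(i, j) = w12(t);
        W(j, i) = w12(t);
        B(i, j) = beta(t);
        ++t;
      }
    }
    if (maxdel < thr) return true;
  }
  return false;
}

// Recover the precision matrix from the estimated covariance W and the
// regression coefficients B; exact zeros of B are carried into Theta.
static arma::mat precision_from_blocks(const arma::mat& W, const arma::mat& B) {
  const arma::uword p = W.n_rows;
  arma::mat Theta(p, p, arma::fill::zeros);
  for (arma::uword j = 0; j < p; ++j) {
    double denom = W(j, j);
    for (arma::uword i = 0; i < p; ++i)
      if (i != j) denom -= W(i, j) * B(i, j);
    double tjj = 1.0 / denom;
    Theta(j, j) = tjj;
    for (arma::uword i = 0; i < p; ++i)
      if (i != j) Theta(i, j) = -B(i, j) * tjj;
  }
  // symmetrize, preserving exact structural zeros
  for (arma::uword j = 1; j < p; ++j) {
    for (arma::uword i = 0; i < j; ++i) {
      if (B(i, j) == 0.0 && B(j, i) == 0.0) {
        Theta(i, j) = 0.0;
        Theta(j, i) = 0.0;
      } else {
        double v = 0.5 * (Theta(i, j) + Theta(j, i));
        Theta(i, j) = v;
        Theta(j, i) = v;
      }
    }
  }
  return Theta;
}

// Graphical lasso along a descending penalty path with warm starts.
// Returns, per penalty: the precision estimate, the number of nonzero
// upper-triangle entries, log det(Theta), trace(S Theta) and a convergence
// flag. The Gaussian log-likelihood and EBIC are assembled by the R caller.
// [[Rcpp::export]]
List glasso_path_cpp(const arma::mat& S, const arma::vec& lambdas,
                     double tol, int maxit, bool penalize_diagonal) {
  const arma::uword p = S.n_rows;
  const arma::uword m = lambdas.n_elem;

  double off_mean = 0.0;
  if (p > 1) {
    double acc = 0.0;
    for (arma::uword j = 1; j < p; ++j)
      for (arma::uword i = 0; i < j; ++i) acc += std::fabs(S(i, j));
    off_mean = acc / (0.5 * p * (p - 1));
  }
  double thr = tol * (off_mean > 0 ? off_mean : 1.0);

  arma::mat W = S;
  arma::mat B(p, p, arma::fill::zeros);

  arma::cube thetas(p, p, m);
  arma::ivec edges(m);
  arma::vec logdets(m);
  arma::vec traces(m);
  LogicalVector converged(m);

  for (arma::uword l = 0; l < m; ++l) {
    if (penalize_diagonal) {
      W.diag() = S.diag() + lambdas(l);
    } else {
      W.diag() = S.diag();
    }
    bool ok = glasso_solve(S, lambdas(l), W, B, thr, maxit);
    arma::mat Theta = precision_from_blocks(W, B);
    thetas.slice(l) = Theta;
    int e = 0;
    for (arma::uword j = 1; j < p; ++j)
      for (arma::uword i = 0; i < j; ++i)
        if (Theta(i, j) != 0.0) ++e;
    edges(l) = e;
    double ld, sign;
    bool pd = arma::log_det(ld, sign, Theta);
    if (!pd || sign <= 0.0) {
      ok = false;
      ld = NA_REAL;
    }
    logdets(l) = ld;
    traces(l) = arma::accu(S % Theta);
    converged(l) = ok;
  }

  return List::create(_["precision"] = thetas, _["edges"] = edges,
                      _["logdet"] = logdets, _["trace_s_theta"] = traces,
                      _["converged"] = converged);
}

// Unpenalized Gaussian ML fit of a precision matrix with a fixed zero
// pattern (iterative proportional regression over columns): refit engine
// for support-based EBIC scoring along the penalty path.
// [[Rcpp::export]]
List constrained_mle_cpp(const arma::mat& S, const arma::imat& support,
                         double tol, int maxit) {
  const arma::uword p = S.n_rows;
  arma::mat W = S;
  arma::mat B(p, p, arma::fill::zeros);
  arma::uvec all = arma::regspace<arma::uvec>(0, p - 1);
  bool converged = false;
  for (int it = 0; it < maxit; ++it) {
    double maxdel = 0.0;
    for (arma::uword j = 0; j < p; ++j) {
      arma::uvec others = arma::find(all != j);
      arma::uvec sel;
      {
        std::vector<arma::uword> tmp;
        for (arma::uword t = 0; t < others.n_elem; ++t)
          if (support(others(t), j) != 0) tmp.push_back(t);
        sel = arma::conv_to<arma::uvec>::from(tmp);
      }
      arma::vec beta(others.n_elem, arma::fill::zeros);
      arma::vec w12(others.n_elem, arma::fill::zeros);
      if (sel.n_elem > 0) {
        arma::mat W11 = W.submat(others, others);
        arma::vec s12 = S.col(j);
        s12.shed_row(j);
        arma::vec bsub;
        bool ok = arma::solve(bsub, W11.submat(sel, sel), s12(sel),
                              arma::solve_opts::no_approx);
        if (!ok) {
          return List::create(_["precision"] = R_NilValue,
                              _["converged"] = false);
        }
        beta(sel) = bsub;
        w12 = W11 * beta;
      }
      for (arma::uword t = 0; t < others.n_elem; ++t) {
        double d = std::fabs(W(others(t), j) - w12(t));
        if (d > maxdel) maxdel = d;
        W(others(t), j) = w12(t);
        W(j, others(t)) = w12(t);
        B(others(t), j) = beta(t);
      }
    }
    if (maxdel < tol) {
      converged = true;
      break;
    }
  }
  arma::mat Theta = precision_from_blocks(W, B);
  // enforce exact zeros off the support
  for (arma::uword j = 1; j < p; ++j) {
    for (arma::uword i = 0; i < j; ++i) {
      if (support(i, j) == 0) {
        Theta(i, j) = 0.0;
        Theta(j, i) = 0.0;
      }
    }
  }
  double ld, sign;
  bool pd = arma::log_det(ld, sign, Theta);
  if (!pd || sign <= 0.0) {
    return List::create(_["precision"] = R_NilValue, _["converged"] = false);
  }
  return List::create(_["precision"] = Theta, _["converged"] = converged,
                      _["logdet"] = ld,
                      _["trace_s_theta"] = arma::accu(S % Theta));
}
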