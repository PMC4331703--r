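#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Variational EM kernels for the allele mixture model.  Rows j of the flat
// matrices index flattened (site, base) pairs, base fastest; columns index
// alleles.  phi must be strictly positive everywhere (the M-step floors it).

// Inner E-step for one sample: alternate
//   w[j, k] \propto phi[j, k] * exp(digamma(r[k]) - digamma(sum(r)))
//   r[k]    = sum_j d[j] * w[j, k] + alpha[k]
// until max |delta r| < tol.
static int e_step_sample(const arma::rowvec& dn, const arma::mat& phi,
                         const arma::rowvec& alpha, double tol, int max_iter,
                         arma::rowvec& r, arma::mat& Wn) {
  int it = 0;
  const arma::uword K = phi.n_cols;
  while (it < max_iter) {
    ++it;
    double psum = R::digamma(arma::accu(r));
    arma::rowvec elog(K);
    for (arma::uword k = 0; k < K; ++k) {
      elog[k] = std::exp(R::digamma(r[k]) - psum);
    }
    Wn = phi;
    Wn.each_row() %= elog;
    arma::vec rs = arma::sum(Wn, 1);
    Wn.each_col() /= rs;
    arma::rowvec rnew = dn * Wn + alpha;
    double delta = arma::abs(rnew - r).max();
    r = rnew;
    if (delta < tol) break;
  }
  return it;
}

// [[Rcpp::export]]
List cpp_e_step(const arma::mat& D,     // N x (M*4) counts
                const arma::mat& phi,   // (M*4) x K emission probabilities
                const arma::mat& r0,    // N x K initial Dirichlet parameters
                const arma::rowvec& alpha,
                double tol,
                int max_iter) {
  const arma::uword N = D.n_rows;
  const arma::uword MB = D.n_cols;
  const arma::uword K = phi.n_cols;

  arma::cube W(MB, K, N);
  arma::mat R_(N, K);
  IntegerVector iters(N);

  for (arma::uword n = 0; n < N; ++n) {
    arma::rowvec dn = D.row(n);
    arma::rowvec r = r0.row(n);
    arma::mat Wn(MB, K);
    iters[n] = e_step_sample(dn, phi, alpha, tol, max_iter, r, Wn);
    W.slice(n) = Wn;
    R_.row(n) = r;
  }
  return List::create(_["w"] = W, _["r"] = R_, _["iterations"] = iters);
}

// M-step: phi[j, k] \propto sum_n d[n, j] * w[n, j, k], normalised over the
// four bases of each site per allele.  (allele, site) cells with zero total
// weighted count fall back to uniform; everything is floored at eps and
// renormalised so logs stay finite.  Returns the number of uniform cells.
static int m_step_flat(const arma::mat& D, const arma::cube& W, double eps,
                       arma::mat& phi) {
  const arma::uword N = D.n_rows;
  const arma::uword MB = D.n_cols;
  const arma::uword M = MB / 4;
  const arma::uword K = phi.n_cols;

  phi.zeros();
  for (arma::uword n = 0; n < N; ++n) {
    phi += W.slice(n).each_col() % D.row(n).t();
  }
  int n_zero = 0;
  for (arma::uword k = 0; k < K; ++k) {
    for (arma::uword x = 0; x < M; ++x) {
      double tot = 0;
      for (arma::uword b = 0; b < 4; ++b) tot += phi(4 * x + b, k);
      if (tot <= 0) {
        ++n_zero;
        for (arma::uword b = 0; b < 4; ++b) phi(4 * x + b, k) = 0.25;
      } else {
        for (arma::uword b = 0; b < 4; ++b) phi(4 * x + b, k) /= tot;
      }
      // floor and renormalise
      double tot2 = 0;
      for (arma::uword b = 0; b < 4; ++b) {
        if (phi(4 * x + b, k) < eps) phi(4 * x + b, k) = eps;
        tot2 += phi(4 * x + b, k);
      }
      for (arma::uword b = 0; b < 4; ++b) phi(4 * x + b, k) /= tot2;
    }
  }
  return n_zero;
}

// [[Rcpp::export]]
List cpp_m_step(const arma::mat& D, const arma::cube& W, double eps) {
  arma::mat phi(D.n_cols, W.n_cols);
  int n_zero = m_step_flat(D, W, eps, phi);
  return List::create(_["phi"] = phi, _["n_uniform_cells"] = n_zero);
}

// Mean-field lower bound E_Q[log P(b, z, theta)] - E_Q[log Q(z, theta)] with
// E[log theta_nk] = digamma(r_nk) - digamma(sum_k r_nk).
static double elbo_flat(const arma::mat& D, const arma::mat& phi,
                        const arma::cube& W, const arma::mat& R_,
                        const arma::rowvec& alpha) {
  const arma::uword N = D.n_rows;
  const arma::uword MB = D.n_cols;
  const arma::uword K = phi.n_cols;

  double asum = arma::accu(alpha);
  double lga = R::lgammafn(asum);
  for (arma::uword k = 0; k < K; ++k) lga -= R::lgammafn(alpha[k]);

  double total = 0;
  for (arma::uword n = 0; n < N; ++n) {
    const arma::rowvec r = R_.row(n);
    double rsum = arma::accu(r);
    double psum = R::digamma(rsum);
    arma::rowvec elog(K);
    for (arma::uword k = 0; k < K; ++k) elog[k] = R::digamma(r[k]) - psum;

    const arma::mat& Wn = W.slice(n);
    for (arma::uword j = 0; j < MB; ++j) {
      double d = D(n, j);
      if (d == 0) continue;
      for (arma::uword k = 0; k < K; ++k) {
        double w = Wn(j, k);
        if (w > 0) {
          total += d * w * (std::log(phi(j, k)) + elog[k] - std::log(w));
        }
      }
    }
    double dir_p = lga;
    double dir_q = R::lgammafn(rsum);
    for (arma::uword k = 0; k < K; ++k) {
      dir_p += (alpha[k] - 1.0) * elog[k];
      dir_q += -R::lgammafn(r[k]) + (r[k] - 1.0) * elog[k];
    }
    total += dir_p - dir_q;
  }
  return total;
}

// [[Rcpp::export]]
double cpp_elbo(const arma::mat& D, const arma::mat& phi, const arma::cube& W,
                const arma::mat& R_, const arma::rowvec& alpha) {
  return elbo_flat(D, phi, W, R_, alpha);
}

// Full VB-EM run from a given initialisation: outer iterations of
// (inner E-step to its fixed point, M-step, ELBO) until the relative ELBO
// change drops below tol or max_iter is reached.  All per-iteration work is
// restricted to (site, base) cells with nonzero counts -- cells with d = 0
// contribute nothing to any update -- giving the O(N M K |alphabet|) cost
// a small constant.  The full responsibility cube is materialised once at
// the end from the last E-step's state.
// [[Rcpp::export]]
List cpp_vbem_run(const arma::mat& D, const arma::mat& phi0,
                  const arma::mat& r0, const arma::rowvec& alpha,
                  int max_iter, double tol,
                  double inner_tol, int inner_max_iter, double eps) {
  const arma::uword N = D.n_rows;
  const arma::uword MB = D.n_cols;
  const arma::uword M = MB / 4;
  const arma::uword K = phi0.n_cols;

  // sparse view of the counts: per sample the observed (site, base) cells
  std::vector<arma::uvec> idx(N);
  std::vector<arma::vec> dval(N);
  for (arma::uword n = 0; n < N; ++n) {
    idx[n] = arma::find(D.row(n).t() > 0);
    dval[n] = D.row(n).t();
    dval[n] = dval[n](idx[n]);
  }

  arma::mat phi = phi0;
  arma::mat phi_e = phi0;     // phi used by the most recent E-step
  arma::mat R_ = r0;
  std::vector<arma::mat> Ws(N);   // responsibilities on observed cells
  std::vector<double> trace;
  bool converged = false;

  double asum = arma::accu(alpha);
  double lga = R::lgammafn(asum);
  for (arma::uword k = 0; k < K; ++k) lga -= R::lgammafn(alpha[k]);

  for (int it = 0; it < max_iter; ++it) {
    // E-step (inner loop per sample, observed cells only)
    phi_e = phi;
    for (arma::uword n = 0; n < N; ++n) {
      const arma::mat phi_sub = phi.rows(idx[n]);
      arma::rowvec r = R_.row(n);
      arma::mat Wn(idx[n].n_elem, K);
      int in_it = 0;
      while (in_it < inner_max_iter) {
        ++in_it;
        double psum = R::digamma(arma::accu(r));
        arma::rowvec elog(K);
        for (arma::uword k = 0; k < K; ++k) {
          elog[k] = std::exp(R::digamma(r[k]) - psum);
        }
        Wn = phi_sub;
        Wn.each_row() %= elog;
        arma::vec rs = arma::sum(Wn, 1);
        Wn.each_col() /= rs;
        arma::rowvec rnew = dval[n].t() * Wn + alpha;
        double delta = arma::abs(rnew - r).max();
        r = rnew;
        if (delta < inner_tol) break;
      }
      Ws[n] = Wn;
      R_.row(n) = r;
    }

    // M-step on observed cells
    phi.zeros();
    for (arma::uword n = 0; n < N; ++n) {
      phi.rows(idx[n]) += Ws[n].each_col() % dval[n];
    }
    for (arma::uword k = 0; k < K; ++k) {
      for (arma::uword x = 0; x < M; ++x) {
        double tot = 0;
        for (arma::uword b = 0; b < 4; ++b) tot += phi(4 * x + b, k);
        if (tot <= 0) {
          for (arma::uword b = 0; b < 4; ++b) phi(4 * x + b, k) = 0.25;
        } else {
          for (arma::uword b = 0; b < 4; ++b) phi(4 * x + b, k) /= tot;
        }
        double tot2 = 0;
        for (arma::uword b = 0; b < 4; ++b) {
          if (phi(4 * x + b, k) < eps) phi(4 * x + b, k) = eps;
          tot2 += phi(4 * x + b, k);
        }
        for (arma::uword b = 0; b < 4; ++b) phi(4 * x + b, k) /= tot2;
      }
    }

    // ELBO at (w, r, updated phi)
    double total = 0;
    for (arma::uword n = 0; n < N; ++n) {
      const arma::rowvec r = R_.row(n);
      double rsum = arma::accu(r);
      double psum = R::digamma(rsum);
      arma::rowvec elog(K);
      for (arma::uword k = 0; k < K; ++k) elog[k] = R::digamma(r[k]) - psum;
      for (arma::uword i = 0; i < idx[n].n_elem; ++i) {
        const arma::uword j = idx[n][i];
        for (arma::uword k = 0; k < K; ++k) {
          double w = Ws[n](i, k);
          if (w > 0) {
            total += dval[n][i] * w *
              (std::log(phi(j, k)) + elog[k] - std::log(w));
          }
        }
      }
      double dir_p = lga;
      double dir_q = R::lgammafn(rsum);
      for (arma::uword k = 0; k < K; ++k) {
        dir_p += (alpha[k] - 1.0) * elog[k];
        dir_q += -R::lgammafn(r[k]) + (r[k] - 1.0) * elog[k];
      }
      total += dir_p - dir_q;
    }
    trace.push_back(total);
    if (it > 0) {
      double prev = trace[it - 1];
      if (std::fabs(total - prev) <= tol * std::max(1.0, std::fabs(prev))) {
        converged = true;
        break;
      }
    }
  }

  // materialise the full responsibility cube from the last E-step state
  arma::cube W(MB, K, N);
  for (arma::uword n = 0; n < N; ++n) {
    const arma::rowvec r = R_.row(n);
    double psum = R::digamma(arma::accu(r));
    arma::rowvec elog(K);
    for (arma::uword k = 0; k < K; ++k) {
      elog[k] = std::exp(R::digamma(r[k]) - psum);
    }
    arma::mat Wn = phi_e;
    Wn.each_row() %= elog;
    arma::vec rs = arma::sum(Wn, 1);
    Wn.each_col() /= rs;
    // keep the exact responsibilities the updates used on observed cells
    for (arma::uword i = 0; i < idx[n].n_elem; ++i) {
      Wn.row(idx[n][i]) = Ws[n].row(i);
    }
    W.slice(n) = Wn;
  }

  return List::create(
    _["phi"] = phi, _["r"] = R_, _["w"] = W,
    _["trace"] = NumericVector(trace.begin(), trace.end()),
    _["converged"] = converged,
    _["n_iterations"] = (int) trace.size()
  );
}
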