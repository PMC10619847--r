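// Compiled kernels for partitioned spatial linear models.
//
// Families are encoded as integers: 0 = exponential, 1 = spherical.
// The nugget is added on the true diagonal of same-set covariance
// matrices only; cross-covariance entries never receive it, so duplicated
// coordinates do not make V singular.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline double cov_val(double d, int family, double tau2, double rho) {
  if (family == 0) {
    return tau2 * std::exp(-d / rho);
  }
  // spherical: compact support at the range
  if (d >= rho) return 0.0;
  double u = d / rho;
  return tau2 * (1.0 - 1.5 * u + 0.5 * u * u * u);
}

static inline double dist2d(const arma::mat& A, arma::uword i,
                            const arma::mat& B, arma::uword j) {
  double dx = A(i, 0) - B(j, 0);
  double dy = A(i, 1) - B(j, 1);
  return std::sqrt(dx * dx + dy * dy);
}

// Covariance matrix between two point sets. If `same` is true the sets are
// identical: only the upper triangle is computed, the matrix is symmetrised
// and eta2 is added on the diagonal.
// [[Rcpp::export]]
arma::mat cov_mat_cpp(const arma::mat& A, const arma::mat& B, int family,
                      double tau2, double eta2, double rho, bool same) {
  arma::uword na = A.n_rows, nb = B.n_rows;
  arma::mat V(na, nb);
  if (same) {
    for (arma::uword i = 0; i < na; ++i) {
      V(i, i) = tau2 + eta2;
      for (arma::uword j = i + 1; j < nb; ++j) {
        double v = cov_val(dist2d(A, i, B, j), family, tau2, rho);
        V(i, j) = v;
        V(j, i) = v;
      }
    }
  } else {
    for (arma::uword j = 0; j < nb; ++j)
      for (arma::uword i = 0; i < na; ++i)
        V(i, j) = cov_val(dist2d(A, i, B, j), family, tau2, rho);
  }
  return V;
}

// Blocked REML objective: sum_i log|V_ii| + r' Vbd^{-1} r + log|T_xx|,
// with r = y - X beta_theta and beta_theta the blocked GLS solution at
// theta. Non-positive-definite blocks return a large penalty so simplex
// optimizers can recover.
// [[Rcpp::export]]
double reml_obj_cpp(const arma::vec& theta, const List& D_list,
                    const List& X_list, const List& y_list, int family) {
  double tau2 = theta[0], eta2 = theta[1], rho = theta[2];
  const double penalty = 1e10;
  if (!std::isfinite(tau2) || !std::isfinite(eta2) || !std::isfinite(rho) ||
      tau2 <= 0.0 || eta2 < 0.0 || rho <= 0.0)
    return penalty;
  int P = D_list.size();
  arma::mat X0 = as<arma::mat>(X_list[0]);
  arma::uword R = X0.n_cols;
  arma::mat Txx(R, R, arma::fill::zeros);
  arma::vec txy(R, arma::fill::zeros);
  double logdetV = 0.0, yy = 0.0;
  for (int b = 0; b < P; ++b) {
    arma::mat D = as<arma::mat>(D_list[b]);
    arma::mat X = as<arma::mat>(X_list[b]);
    arma::vec y = as<arma::vec>(y_list[b]);
    arma::uword ni = D.n_rows;
    arma::mat V(ni, ni);
    for (arma::uword i = 0; i < ni; ++i) {
      V(i, i) = tau2 + eta2;
      for (arma::uword j = i + 1; j < ni; ++j) {
        double v = cov_val(D(i, j), family, tau2, rho);
        V(i, j) = v;
        V(j, i) = v;
      }
    }
    arma::mat U;
    if (!arma::chol(U, V)) return penalty;
    for (arma::uword i = 0; i < ni; ++i) logdetV += 2.0 * std::log(U(i, i));
    arma::mat Z(ni, R + 1);
    Z.cols(0, R - 1) = X;
    Z.col(R) = y;
    arma::mat W = arma::solve(arma::trimatl(U.t()), Z);
    arma::mat M = W.t() * W;  // [X'Vi^-1 X, X'Vi^-1 y; ., y'Vi^-1 y]
    Txx += M.submat(0, 0, R - 1, R - 1);
    txy += M.submat(0, R, R - 1, R);
    yy += M(R, R);
  }
  arma::vec beta;
  if (!arma::solve(beta, Txx, txy, arma::solve_opts::no_approx))
    return penalty;
  double rVr = yy - 2.0 * arma::dot(beta, txy) +
               arma::dot(beta, Txx * beta);
  double ldT, signT;
  if (!arma::log_det(ldT, signT, Txx) || signT <= 0.0) return penalty;
  double obj = logdetV + rVr + ldT;
  if (!std::isfinite(obj)) return penalty;
  return obj;
}

// Same objective over a flat block layout: rows of coords/X/y are grouped
// by block, `starts` holds 0-based block offsets with a terminal n. Avoids
// per-evaluation list conversions inside the optimizer loop.
// [[Rcpp::export]]
double reml_obj_flat_cpp(const arma::vec& theta, const arma::mat& coords,
                         const arma::mat& X, const arma::vec& y,
                         const arma::uvec& starts, int family) {
  double tau2 = theta[0], eta2 = theta[1], rho = theta[2];
  const double penalty = 1e10;
  if (!std::isfinite(tau2) || !std::isfinite(eta2) || !std::isfinite(rho) ||
      tau2 <= 0.0 || eta2 < 0.0 || rho <= 0.0)
    return penalty;
  arma::uword P = starts.n_elem - 1, R = X.n_cols;
  arma::mat Txx(R, R, arma::fill::zeros);
  arma::vec txy(R, arma::fill::zeros);
  double logdetV = 0.0, yy = 0.0;
  arma::uword nmax = 0;
  for (arma::uword b = 0; b < P; ++b)
    nmax = std::max(nmax, starts[b + 1] - starts[b]);
  arma::mat V(nmax, nmax), Z(nmax, R + 1);
  for (arma::uword b = 0; b < P; ++b) {
    arma::uword lo = starts[b], ni = starts[b + 1] - lo;
    for (arma::uword i = 0; i < ni; ++i) {
      V(i, i) = tau2 + eta2;
      for (arma::uword j = i + 1; j < ni; ++j) {
        double v = cov_val(dist2d(coords, lo + i, coords, lo + j), family,
                           tau2, rho);
        V(i, j) = v;
        V(j, i) = v;
      }
    }
    arma::mat Vb = V.submat(0, 0, ni - 1, ni - 1);
    arma::mat U;
    if (!arma::chol(U, Vb)) return penalty;
    for (arma::uword i = 0; i < ni; ++i) logdetV += 2.0 * std::log(U(i, i));
    Z.submat(0, 0, ni - 1, R - 1) = X.rows(lo, lo + ni - 1);
    Z.submat(0, R, ni - 1, R) = y.subvec(lo, lo + ni - 1);
    arma::mat W = arma::solve(arma::trimatl(U.t()),
                              Z.submat(0, 0, ni - 1, R));
    arma::mat M = W.t() * W;
    Txx += M.submat(0, 0, R - 1, R - 1);
    txy += M.submat(0, R, R - 1, R);
    yy += M(R, R);
  }
  arma::vec beta;
  if (!arma::solve(beta, Txx, txy, arma::solve_opts::no_approx))
    return penalty;
  double rVr = yy - 2.0 * arma::dot(beta, txy) +
               arma::dot(beta, Txx * beta);
  double ldT, signT;
  if (!arma::log_det(ldT, signT, Txx) || signT <= 0.0) return penalty;
  double obj = logdetV + rVr + ldT;
  if (!std::isfinite(obj)) return penalty;
  return obj;
}

// Per-block GLS pieces at a fixed theta: T_xx, t_xy, and cached products
// V_ii^{-1} X_i, X_i' V_ii^{-1} X_i, X_i' V_ii^{-1} y_i for each block.
// [[Rcpp::export]]
List blocked_gls_cpp(const arma::vec& theta, const List& coords_list,
                     const List& X_list, const List& y_list, int family) {
  double tau2 = theta[0], eta2 = theta[1], rho = theta[2];
  int P = coords_list.size();
  arma::mat X0 = as<arma::mat>(X_list[0]);
  arma::uword R = X0.n_cols;
  arma::mat Txx(R, R, arma::fill::zeros);
  arma::vec txy(R, arma::fill::zeros);
  List UX(P), Uy(P), A(P), bvec(P);
  for (int b = 0; b < P; ++b) {
    arma::mat C = as<arma::mat>(coords_list[b]);
    arma::mat X = as<arma::mat>(X_list[b]);
    arma::vec y = as<arma::vec>(y_list[b]);
    arma::mat V = cov_mat_cpp(C, C, family, tau2, eta2, rho, true);
    arma::mat Vinv;
    if (!arma::inv_sympd(Vinv, V))
      stop("covariance block %d is numerically singular (tau2=%g, eta2=%g, rho=%g)",
           b + 1, tau2, eta2, rho);
    arma::mat ux = Vinv * X;       // V_ii^{-1} X_i
    arma::vec uy = Vinv * y;       // V_ii^{-1} y_i
    arma::mat Ab = X.t() * ux;
    arma::vec bb = X.t() * uy;
    Txx += Ab;
    txy += bb;
    UX[b] = ux;
    Uy[b] = uy;
    A[b] = Ab;
    bvec[b] = bb;
  }
  return List::create(_["Txx"] = Txx, _["txy"] = txy, _["UX"] = UX,
                      _["Uy"] = Uy, _["A"] = A, _["b"] = bvec);
}

// Cross-partition accumulator W_xx = sum_{i<j} [ M_ij + M_ij' ] with
// M_ij = (V_ii^{-1} X_i)' V_ij (V_jj^{-1} X_j). Cross blocks V_ij are built
// on the fly per pair and discarded.
// [[Rcpp::export]]
arma::mat wxx_cpp(const arma::vec& theta, const List& coords_list,
                  const List& UX_list, int family) {
  double tau2 = theta[0], rho = theta[2];
  int P = coords_list.size();
  arma::mat UX0 = as<arma::mat>(UX_list[0]);
  arma::uword R = UX0.n_cols;
  arma::mat W(R, R, arma::fill::zeros);
  std::vector<arma::mat> C(P), U(P);
  for (int i = 0; i < P; ++i) {
    C[i] = as<arma::mat>(coords_list[i]);
    U[i] = as<arma::mat>(UX_list[i]);
  }
  for (int i = 0; i < P - 1; ++i) {
    for (int j = i + 1; j < P; ++j) {
      arma::mat Vij = cov_mat_cpp(C[i], C[j], family, tau2, 0.0, rho, false);
      arma::mat M = U[i].t() * Vij * U[j];
      W += M + M.t();
    }
  }
  return W;
}

// Exact k nearest neighbours by brute force; ties at equal distance are
// broken by the lower observation index. Returns 1-based index matrix and
// matching distances, both q x m, sorted by distance ascending.
// [[Rcpp::export]]
List knn_cpp(const arma::mat& obs, const arma::mat& pred, int m) {
  arma::uword n = obs.n_rows, q = pred.n_rows;
  arma::umat idx(q, m);
  arma::mat dst(q, m);
  std::vector<std::pair<double, arma::uword> > d(n);
  for (arma::uword j = 0; j < q; ++j) {
    for (arma::uword i = 0; i < n; ++i)
      d[i] = std::make_pair(dist2d(obs, i, pred, j), i);
    std::partial_sort(d.begin(), d.begin() + m, d.end());
    for (int k = 0; k < m; ++k) {
      idx(j, k) = d[k].second + 1;
      dst(j, k) = d[k].first;
    }
  }
  return List::create(_["idx"] = idx, _["dist"] = dst);
}

// Nearest-neighbour universal kriging with a single global coefficient
// vector. For each prediction site j with neighbour set y_j:
//   pred  = x_j' beta + c_j' V_j^{-1} (y_j - X_j beta)
//   var   = sigma2 - c_j' V_j^{-1} c_j + g' Chat g,  g = x_j - X_j' V_j^{-1} c_j
// Optionally accumulates the pieces of the areal-mean weight vector
// a* = Q' (sum_j a_j g_j) + sum_j a_j N_j' V_j^{-1} c_j  (local part here,
// Q part applied in R).
// [[Rcpp::export]]
List nn_predict_cpp(const arma::mat& obs, const arma::mat& X,
                    const arma::vec& y, const arma::mat& pred,
                    const arma::mat& predX, const arma::umat& nn_idx,
                    const arma::vec& beta, const arma::mat& Chat,
                    const arma::vec& theta, int family, double sigma2,
                    bool want_astar, const arma::vec& a) {
  double tau2 = theta[0], eta2 = theta[1], rho = theta[2];
  arma::uword q = pred.n_rows, m = nn_idx.n_cols, R = X.n_cols;
  arma::vec fit(q), pv(q);
  arma::vec astar_local;
  arma::vec gsum(R, arma::fill::zeros);
  if (want_astar) astar_local.zeros(obs.n_rows);
  arma::mat Cj(m, 2), Xj(m, R);
  arma::vec yj(m), cj(m), xj(R);
  for (arma::uword j = 0; j < q; ++j) {
    for (arma::uword k = 0; k < m; ++k) {
      arma::uword o = nn_idx(j, k) - 1;
      Cj.row(k) = obs.row(o);
      Xj.row(k) = X.row(o);
      yj[k] = y[o];
    }
    arma::mat Vj = cov_mat_cpp(Cj, Cj, family, tau2, eta2, rho, true);
    for (arma::uword k = 0; k < m; ++k)
      cj[k] = cov_val(dist2d(Cj, k, pred, j), family, tau2, rho);
    arma::vec u;
    if (!arma::solve(u, Vj, cj, arma::solve_opts::likely_sympd +
                                    arma::solve_opts::no_approx))
      stop("local covariance matrix singular at prediction site %d", (int)(j + 1));
    xj = predX.row(j).t();
    arma::vec g = xj - Xj.t() * u;
    fit[j] = arma::dot(xj, beta) + arma::dot(u, yj - Xj * beta);
    pv[j] = sigma2 - arma::dot(cj, u) + arma::as_scalar(g.t() * Chat * g);
    if (want_astar) {
      gsum += a[j] * g;
      for (arma::uword k = 0; k < m; ++k)
        astar_local[nn_idx(j, k) - 1] += a[j] * u[k];
    }
  }
  return List::create(_["fit"] = fit, _["var"] = pv,
                      _["gsum"] = gsum, _["astar_local"] = astar_local);
}

// Purely local predictor: universal kriging recomputed from scratch in each
// neighbourhood, including a local GLS coefficient estimate. Columns of the
// local design that are identically zero are collapsed before solving.
// [[Rcpp::export]]
List local_predict_cpp(const arma::mat& obs, const arma::mat& X,
                       const arma::vec& y, const arma::mat& pred,
                       const arma::mat& predX, const arma::umat& nn_idx,
                       const arma::vec& theta, int family, double sigma2) {
  double tau2 = theta[0], eta2 = theta[1], rho = theta[2];
  arma::uword q = pred.n_rows, m = nn_idx.n_cols, R = X.n_cols;
  arma::vec fit(q), pv(q);
  arma::mat Cj(m, 2), Xfull(m, R);
  arma::vec yj(m), cj(m);
  for (arma::uword j = 0; j < q; ++j) {
    for (arma::uword k = 0; k < m; ++k) {
      arma::uword o = nn_idx(j, k) - 1;
      Cj.row(k) = obs.row(o);
      Xfull.row(k) = X.row(o);
      yj[k] = y[o];
    }
    // collapse all-zero columns of the local design
    arma::uvec keep = arma::find(arma::sum(arma::abs(Xfull), 0).t() > 0.0);
    if (keep.n_elem == 0)
      stop("local design matrix at site %d has no nonzero columns", (int)(j + 1));
    arma::mat Xj = Xfull.cols(keep);
    arma::vec xj = predX.row(j).t();
    xj = xj.elem(keep);
    arma::mat Vj = cov_mat_cpp(Cj, Cj, family, tau2, eta2, rho, true);
    for (arma::uword k = 0; k < m; ++k)
      cj[k] = cov_val(dist2d(Cj, k, pred, j), family, tau2, rho);
    arma::mat Vinv;
    if (!arma::inv_sympd(Vinv, Vj))
      stop("local covariance matrix singular at prediction site %d", (int)(j + 1));
    arma::mat XtVi = Xj.t() * Vinv;
    arma::mat Aj = XtVi * Xj;
    arma::vec betaj;
    if (!arma::solve(betaj, Aj, XtVi * yj, arma::solve_opts::no_approx))
      stop("local design matrix rank deficient after collapsing at site %d",
           (int)(j + 1));
    arma::vec u = Vinv * cj;
    arma::vec g = xj - Xj.t() * u;
    arma::mat Ainv;
    if (!arma::inv_sympd(Ainv, Aj))
      stop("local information matrix singular at site %d", (int)(j + 1));
    fit[j] = arma::dot(xj, betaj) + arma::dot(u, yj - Xj * betaj);
    pv[j] = sigma2 - arma::dot(cj, u) + arma::as_scalar(g.t() * Ainv * g);
  }
  return List::create(_["fit"] = fit, _["var"] = pv);
}

// Streamed block-prediction variance
//   a*' V_oo a* - 2 a*' V_ou a + a' V_uu a
// generating one covariance row at a time; peak extra storage is one row.
// Diagonals of V_oo and V_uu carry the nugget (target is a new noisy
// observation at each site, matching the point predictor's sigma2).
// [[Rcpp::export]]
double block_var_cpp(const arma::mat& obs, const arma::mat& grid,
                     const arma::vec& astar, const arma::vec& a,
                     const arma::vec& theta, int family) {
  double tau2 = theta[0], eta2 = theta[1], rho = theta[2];
  arma::uword n = obs.n_rows, q = grid.n_rows;
  double t_oo = 0.0, t_ou = 0.0, t_uu = 0.0;
  arma::vec row(std::max(n, q));
  for (arma::uword i = 0; i < n; ++i) {
    for (arma::uword j = 0; j < n; ++j)
      row[j] = (i == j) ? tau2 + eta2
                        : cov_val(dist2d(obs, i, obs, j), family, tau2, rho);
    t_oo += astar[i] * arma::dot(row.head(n), astar);
    for (arma::uword j = 0; j < q; ++j)
      row[j] = cov_val(dist2d(obs, i, grid, j), family, tau2, rho);
    t_ou += astar[i] * arma::dot(row.head(q), a);
  }
  for (arma::uword i = 0; i < q; ++i) {
    for (arma::uword j = 0; j < q; ++j)
      row[j] = (i == j) ? tau2 + eta2
                        : cov_val(dist2d(grid, i, grid, j), family, tau2, rho);
    t_uu += a[i] * arma::dot(row.head(q), a);
  }
  return t_oo - 2.0 * t_ou + t_uu;
}
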