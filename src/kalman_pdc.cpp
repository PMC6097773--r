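// Time-varying MVAR tracking (classical and general linear Kalman filters),
// squared partial directed coherence, and masked mean-squared-error
// reductions, in Armadillo for speed.
//
// State layout shared by both filters and by the R wrappers: the MVAR
// coefficient state is a (m*p x m) matrix X; column i holds the
// coefficients of receiver channel i, rows are grouped lag-major:
// row (k-1)*m + j  ==  A_k[i, j].

#define ARMA_NO_DEBUG
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Classical Kalman filter (single trial). Random-walk state model with
// state-noise covariance uc * tr(P)/dim * I (relative adaptation) and a
// scalar measurement-noise proxy rbar = tr(R)/m from the exponentially
// smoothed residual covariance.
// [[Rcpp::export]]
Rcpp::List ckf_cpp(const arma::mat& y, int p, double uc, double p0) {
  const int m = y.n_rows, N = y.n_cols, mp = m * p;
  if (N <= p) Rcpp::stop("series shorter than model order");
  mat X(mp, m, fill::zeros);
  mat P = p0 * eye(mp, mp);
  mat R = eye(m, m);
  cube A(mp, m, N, fill::zeros);
  cube Rtraj(m, m, N, fill::zeros);
  vec h(mp), Ph(mp), kgain(mp);
  rowvec eps(m);
  const int first = p; // 0-based index of first estimated bin
  for (int n = p; n < N; ++n) {
    for (int k = 1; k <= p; ++k) h.subvec((k - 1) * m, k * m - 1) = y.col(n - k);
    P.diag() += uc * trace(P) / mp;
    eps = y.col(n).t();
    eps -= h.t() * X;
    Ph = P * h;
    double s = dot(h, Ph) + trace(R) / m;
    kgain = Ph / s;
    X += kgain * eps;
    // rank-1 update keeps P symmetric in exact arithmetic
    P -= kgain * Ph.t();
    R *= (1.0 - uc);
    R += uc * (eps.t() * eps);
    A.slice(n) = X;
    Rtraj.slice(n) = R;
  }
  for (int n = 0; n < first; ++n) { // back-fill the presample bins
    A.slice(n) = A.slice(first);
    Rtraj.slice(n) = Rtraj.slice(first);
  }
  return Rcpp::List::create(Rcpp::Named("coeffs") = A,
                            Rcpp::Named("resid") = Rtraj);
}

// General linear Kalman filter (multi-trial): all trials are stacked into
// one measurement block sharing the state; measurement-noise covariance is
// the exponentially smoothed across-trial innovation outer product.
// y: cube (m x N x trials)
// [[Rcpp::export]]
Rcpp::List glkf_cpp(const arma::cube& y, int p, double uc, double p0) {
  const int m = y.n_rows, N = y.n_cols, r = y.n_slices, mp = m * p;
  if (N <= p) Rcpp::stop("series shorter than model order");
  mat X(mp, m, fill::zeros);
  mat P = p0 * eye(mp, mp);
  mat RE = eye(r, r);
  cube A(mp, m, N, fill::zeros);
  cube Rtraj(m, m, N, fill::zeros);
  mat H(r, mp), Yn(r, m);
  const int first = p;
  for (int n = p; n < N; ++n) {
    for (int t = 0; t < r; ++t)
      for (int k = 1; k <= p; ++k)
        for (int j = 0; j < m; ++j) H(t, (k - 1) * m + j) = y(j, n - k, t);
    P.diag() += uc * trace(P) / mp;
    for (int t = 0; t < r; ++t) Yn.row(t) = y.slice(t).col(n).t();
    mat E = Yn - H * X;
    mat PHt = P * H.t();
    mat S = H * PHt + RE;
    mat K = solve(S, PHt.t(), solve_opts::likely_sympd).t(); // P H' S^-1
    X += K * E;
    P -= K * PHt.t();
    P = 0.5 * (P + P.t());
    // across-trial innovation covariance, per measurement element
    RE = (1.0 - uc) * RE + (uc / m) * (E * E.t());
    A.slice(n) = X;
    Rtraj.slice(n) = E.t() * E / r;
  }
  for (int n = 0; n < first; ++n) {
    A.slice(n) = A.slice(first);
    Rtraj.slice(n) = Rtraj.slice(first);
  }
  return Rcpp::List::create(Rcpp::Named("coeffs") = A,
                            Rcpp::Named("resid") = Rtraj);
}

// shared PDC core: B_all is (m*m*N x p) with B(i + m*j + m*m*n, k) =
// A_{k+1}[i, j](n); returns the (m, m, F, N) squared-PDC array
static Rcpp::NumericVector pdc_core(const mat& B_all, int m, int N,
                                    const vec& fnorm) {
  const int p = B_all.n_cols, F = fnorm.n_elem;
  mat phre(p, F), phim(p, F);
  for (int f = 0; f < F; ++f)
    for (int k = 0; k < p; ++k) {
      phre(k, f) = std::cos(-2.0 * M_PI * fnorm(f) * (k + 1));
      phim(k, f) = std::sin(-2.0 * M_PI * fnorm(f) * (k + 1));
    }
  // Abar(i,j,f,n) = delta_ij - [Cre + i Cim](i + m*j + m*m*n, f)
  mat Cre = B_all * phre;
  mat Cim = B_all * phim;
  Rcpp::NumericVector out(static_cast<R_xlen_t>(m) * m * F * N);
  out.attr("dim") = Rcpp::IntegerVector::create(m, m, F, N);
  double* o = REAL(out);
  std::vector<double> row(m);
  for (int n = 0; n < N; ++n) {
    for (int f = 0; f < F; ++f) {
      for (int j = 0; j < m; ++j) {
        const double* cre = Cre.colptr(f) + m * j + m * m * n;
        const double* cim = Cim.colptr(f) + m * j + m * m * n;
        double denom = 0.0;
        for (int i = 0; i < m; ++i) {
          double re = ((i == j) ? 1.0 : 0.0) - cre[i];
          double im = -cim[i];
          row[i] = re * re + im * im;
          denom += row[i];
        }
        if (denom <= 0.0)
          Rcpp::stop("zero PDC denominator at sender %d, frequency index %d, time bin %d",
                     j + 1, f + 1, n + 1);
        double* dst = o + m * (j + static_cast<R_xlen_t>(m) * (f + static_cast<R_xlen_t>(F) * n));
        for (int i = 0; i < m; ++i) dst[i] = row[i] / denom;
      }
    }
  }
  return out;
}

// Squared PDC from a coefficient trajectory in slab layout:
// A: cube (m x m*p x N), slice n = [A_1(n) ... A_p(n)].
// fnorm: frequencies normalized by fs. Returns (m, m, F, N) array.
// [[Rcpp::export]]
Rcpp::NumericVector pdc_cpp(const arma::cube& A, const arma::vec& fnorm) {
  const int m = A.n_rows, p = A.n_cols / m, N = A.n_slices;
  mat B(m * m * N, p);
  for (int n = 0; n < N; ++n) {
    const mat& An = A.slice(n);
    for (int k = 0; k < p; ++k)
      for (int j = 0; j < m; ++j)
        for (int i = 0; i < m; ++i)
          B(i + m * j + m * m * n, k) = An(i, k * m + j);
  }
  return pdc_core(B, m, N, fnorm);
}

// Squared PDC from a trajectory in Kalman state layout (mp x m x N)
// [[Rcpp::export]]
Rcpp::NumericVector pdc_state_cpp(const arma::cube& X, const arma::vec& fnorm) {
  const int mp = X.n_rows, m = X.n_cols, N = X.n_slices, p = mp / m;
  mat B(m * m * N, p);
  for (int n = 0; n < N; ++n) {
    const mat& Xn = X.slice(n);
    for (int k = 0; k < p; ++k)
      for (int j = 0; j < m; ++j)
        for (int i = 0; i < m; ++i)
          B(i + m * j + m * m * n, k) = Xn((k * m) + j, i);
  }
  return pdc_core(B, m, N, fnorm);
}

// mean over time bins, lags and masked (i, j) entries of squared
// differences of two state-layout trajectories (mp x m x N)
// [[Rcpp::export]]
double masked_mse_state_cpp(const arma::cube& X, const arma::cube& T,
                            const arma::umat& mask) {
  const int mp = X.n_rows, m = X.n_cols, N = X.n_slices, p = mp / m;
  if (T.n_rows != X.n_rows || T.n_cols != X.n_cols || T.n_slices != X.n_slices)
    Rcpp::stop("trajectory shape mismatch");
  double acc = 0.0;
  long cnt = 0;
  for (int n = 0; n < N; ++n) {
    const mat& Xn = X.slice(n);
    const mat& Tn = T.slice(n);
    for (int i = 0; i < m; ++i)
      for (int j = 0; j < m; ++j) {
        if (!mask(i, j)) continue;
        for (int k = 0; k < p; ++k) {
          double d = Xn(k * m + j, i) - Tn(k * m + j, i);
          acc += d * d;
          ++cnt;
        }
      }
  }
  if (cnt == 0) Rcpp::stop("empty mask");
  return acc / cnt;
}

// mean over frequencies, time bins and masked (i, j) pairs of squared
// differences of two (m, m, F, N) arrays; the diagonal is excluded
// [[Rcpp::export]]
double masked_mse_pdc_cpp(const Rcpp::NumericVector& a,
                          const Rcpp::NumericVector& b,
                          const arma::umat& mask) {
  Rcpp::IntegerVector d = a.attr("dim");
  const int m = d[0], F = d[2], N = d[3];
  if (a.size() != b.size()) Rcpp::stop("PDC grids differ");
  const double* pa = REAL(a);
  const double* pb = REAL(b);
  double acc = 0.0;
  long cnt = 0;
  for (R_xlen_t fn = 0; fn < static_cast<R_xlen_t>(F) * N; ++fn) {
    const double* qa = pa + fn * m * m;
    const double* qb = pb + fn * m * m;
    for (int j = 0; j < m; ++j)
      for (int i = 0; i < m; ++i) {
        if (i == j || !mask(i, j)) continue;
        double dd = qa[i + m * j] - qb[i + m * j];
        acc += dd * dd;
        ++cnt;
      }
  }
  if (cnt == 0) Rcpp::stop("mask empty after excluding the diagonal");
  return acc / cnt;
}
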