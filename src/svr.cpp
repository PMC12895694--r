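// Epsilon-insensitive support vector regression with an RBF kernel,
// solved by SMO on the 2n-variable box-constrained dual (the classic
// formulation: alpha+ / alpha- pairs, single equality constraint).
// Written here because the decoder is the package's core primitive;
// the solver is deterministic (maximal-violating-pair selection, no
// randomised shrinking), so repeated fits on identical data agree bitwise.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Squared-distance based Gaussian kernel between row sets A (na x p) and B (nb x p).
// [[Rcpp::export]]
arma::mat rbf_kernel_cpp(const arma::mat& A, const arma::mat& B, double gamma) {
  vec an = sum(square(A), 1);
  vec bn = sum(square(B), 1);
  mat D = repmat(an, 1, B.n_rows) + repmat(bn.t(), A.n_rows, 1) - 2.0 * (A * B.t());
  D.transform([gamma](double d) { return std::exp(-gamma * (d > 0.0 ? d : 0.0)); });
  return D;
}

// Core SMO loop. K is the n x n kernel over training points, y the target.
// Variables t in [0, 2n): t < n are alpha+ (sign +1), t >= n alpha- (sign -1).
// Returns beta (= alpha+ - alpha-), intercept b, and iteration count.
static void smo_solve(const mat& K, const vec& y, double C, double epsi,
                      double tol, int max_iter, vec& beta, double& b,
                      int& iters) {
  const int n = K.n_rows;
  const int m = 2 * n;
  vec a(m, fill::zeros);
  vec G(m);           // gradient of the dual objective
  for (int t = 0; t < m; ++t) {
    double s = (t < n) ? 1.0 : -1.0;
    G[t] = epsi - s * y[t % n];
  }
  auto sgn = [n](int t) { return (t < n) ? 1.0 : -1.0; };

  iters = 0;
  while (iters < max_iter) {
    // maximal violating pair over I_up / I_low
    int i = -1, j = -1;
    double up_best = -datum::inf, low_best = datum::inf;
    for (int t = 0; t < m; ++t) {
      double s = sgn(t);
      bool in_up  = (s > 0) ? (a[t] < C) : (a[t] > 0);
      bool in_low = (s > 0) ? (a[t] > 0) : (a[t] < C);
      double v = -s * G[t];
      if (in_up && v > up_best)  { up_best = v;  i = t; }
      if (in_low && v < low_best) { low_best = v; j = t; }
    }
    if (i < 0 || j < 0 || up_best - low_best < tol) break;

    const int ii = i % n, jj = j % n;
    const double si = sgn(i), sj = sgn(j);
    double quad = K(ii, ii) + K(jj, jj) - 2.0 * K(ii, jj);
    if (quad < 1e-12) quad = 1e-12;
    // descent step along d_i = si, d_j = -sj (keeps the equality constraint)
    double step = -(si * G[i] - sj * G[j]) / quad;
    double cap_i = (si > 0) ? (C - a[i]) : a[i];
    double cap_j = (sj > 0) ? a[j] : (C - a[j]);
    step = std::min(step, std::min(cap_i, cap_j));
    if (step <= 0) break;
    a[i] += si * step;
    a[j] -= sj * step;
    for (int t = 0; t < m; ++t)
      G[t] += sgn(t) * step * (K(t % n, ii) - K(t % n, jj));
    ++iters;
  }

  beta.zeros(n);
  for (int t = 0; t < m; ++t) beta[t % n] += sgn(t) * a[t];

  // intercept from KKT conditions: free variables pin s*G = -b exactly,
  // bounded ones bracket it.
  double acc = 0.0; int nfree = 0;
  double lo = -datum::inf, hi = datum::inf;
  for (int t = 0; t < m; ++t) {
    double s = sgn(t), sg = s * G[t];
    if (a[t] > 1e-12 && a[t] < C - 1e-12) { acc += sg; ++nfree; }
    else if ((s > 0 && a[t] >= C - 1e-12) || (s < 0 && a[t] <= 1e-12))
      lo = std::max(lo, sg);
    else
      hi = std::min(hi, sg);
  }
  if (nfree > 0) b = -acc / nfree;
  else {
    if (!std::isfinite(lo)) lo = hi;
    if (!std::isfinite(hi)) hi = lo;
    b = -(lo + hi) / 2.0;
  }
}

// [[Rcpp::export]]
Rcpp::List svr_fit_cpp(const arma::mat& K, const arma::vec& y, double C,
                       double epsilon, double tol, int max_iter) {
  vec beta; double b; int iters;
  smo_solve(K, y, C, epsilon, tol, max_iter, beta, b, iters);
  return Rcpp::List::create(Rcpp::Named("beta") = beta,
                            Rcpp::Named("b") = b,
                            Rcpp::Named("iterations") = iters);
}

static double circ_abs_diff(double t1, double t2) {
  double d = std::atan2(std::sin(t1 - t2), std::cos(t1 - t2));
  return std::fabs(d);
}

// single-precision RBF kernel (returned as double) -- the decode hot path is
// dominated by these matrix products; float32 halves the cost and its ~1e-7
// relative error is far below the SMO convergence tolerance
static mat rbf_kernel_f32(const fmat& A, const fmat& B, double gamma) {
  fvec an = sum(square(A), 1);
  fvec bn = sum(square(B), 1);
  fmat D = repmat(an, 1, B.n_rows) + repmat(bn.t(), A.n_rows, 1) - 2.0f * (A * B.t());
  mat K = conv_to<mat>::from(D);
  K.transform([gamma](double d) { return std::exp(-gamma * (d > 0.0 ? d : 0.0)); });
  return K;
}

// Leave-one-run-out periodic SVR decoding of one participant-condition block.
//
// X: trials x voxels, th1/th2: labels in radians (th2 = NA for single-item),
// run: integer run id per trial. scheme: 0 = single label (th1),
// 1 = joint (each two-item trial enters train and test once per label),
// 2 = separate model for item 1, 3 = separate model for item 2.
// gamma <= 0 requests the variance-scaled default 1/(p * var(scaled train)).
// Returns per-fold mean angular error and the trial-averaged FCA above chance.
// [[Rcpp::export]]
Rcpp::List psvr_decode_cpp(const arma::mat& X, const arma::vec& th1,
                           const arma::vec& th2, const arma::ivec& run,
                           int scheme, double C, double epsilon, double gamma,
                           double tol, int max_iter) {
  ivec runs = unique(run);
  const int nfold = runs.n_elem;
  const uword p = X.n_cols;
  vec fold_err(nfold);

  for (int f = 0; f < nfold; ++f) {
    uvec tr = find(run != runs[f]);
    uvec te = find(run == runs[f]);

    // per-voxel min-max scaling fitted on training trials only
    mat Xtr = X.rows(tr), Xte = X.rows(te);
    rowvec mn = min(Xtr, 0), mx = max(Xtr, 0);
    rowvec rg = mx - mn;
    for (uword v = 0; v < p; ++v) {
      if (rg[v] > 0) {
        Xtr.col(v) = (Xtr.col(v) - mn[v]) / rg[v];
        Xte.col(v) = (Xte.col(v) - mn[v]) / rg[v];
      } else {            // constant training voxel: mapped to 0
        Xtr.col(v).zeros();
        Xte.col(v).zeros();
      }
    }

    double g = gamma;
    if (g <= 0) {
      double v = accu(square(Xtr - accu(Xtr) / Xtr.n_elem)) / Xtr.n_elem;
      g = (v > 0) ? 1.0 / (p * v) : 1.0 / p;
    }

    fmat Xtr_f = conv_to<fmat>::from(Xtr);
    fmat Xte_f = conv_to<fmat>::from(Xte);
    mat K0 = rbf_kernel_f32(Xtr_f, Xtr_f, g);
    mat Kte0 = rbf_kernel_f32(Xte_f, Xtr_f, g);

    // assemble training labels (and duplication map for the joint scheme)
    std::vector<uword> map;  // training row -> row of Xtr
    std::vector<double> lab;
    const uword ntr = tr.n_elem;
    if (scheme == 1) {
      map.reserve(2 * ntr); lab.reserve(2 * ntr);
      for (uword k = 0; k < ntr; ++k) { map.push_back(k); lab.push_back(th1[tr[k]]); }
      for (uword k = 0; k < ntr; ++k) { map.push_back(k); lab.push_back(th2[tr[k]]); }
    } else {
      const vec& src = (scheme == 3) ? th2 : th1;
      for (uword k = 0; k < ntr; ++k) { map.push_back(k); lab.push_back(src[tr[k]]); }
    }
    const uword nlab = lab.size();
    mat K(nlab, nlab);
    for (uword aI = 0; aI < nlab; ++aI)
      for (uword bI = 0; bI < nlab; ++bI)
        K(aI, bI) = K0(map[aI], map[bI]);

    vec yx(nlab), yy(nlab);
    for (uword k = 0; k < nlab; ++k) { yx[k] = std::cos(lab[k]); yy[k] = std::sin(lab[k]); }

    vec bx, by; double bbx, bby; int it1, it2;
    smo_solve(K, yx, C, epsilon, tol, max_iter, bx, bbx, it1);
    smo_solve(K, yy, C, epsilon, tol, max_iter, by, bby, it2);

    // fold duplicated betas back onto unique training rows
    vec ex(ntr, fill::zeros), ey(ntr, fill::zeros);
    for (uword k = 0; k < nlab; ++k) { ex[map[k]] += bx[k]; ey[map[k]] += by[k]; }
    vec fx = Kte0 * ex + bbx;
    vec fy = Kte0 * ey + bby;

    double err = 0.0; int nsc = 0;
    for (uword k = 0; k < te.n_elem; ++k) {
      double th_hat = (fx[k] == 0.0 && fy[k] == 0.0) ? 0.0 : std::atan2(fy[k], fx[k]);
      if (scheme == 1) {
        err += circ_abs_diff(th1[te[k]], th_hat);
        err += circ_abs_diff(th2[te[k]], th_hat);
        nsc += 2;
      } else {
        double lbl = (scheme == 3) ? th2[te[k]] : th1[te[k]];
        err += circ_abs_diff(lbl, th_hat);
        nsc += 1;
      }
    }
    fold_err[f] = err / nsc;
  }

  double mean_dx = mean(fold_err);
  return Rcpp::List::create(
      Rcpp::Named("mean_error") = mean_dx,
      Rcpp::Named("fca_above_chance") = 50.0 - mean_dx / datum::pi * 100.0,
      Rcpp::Named("fold_errors") = fold_err);
}

// ---- cluster utilities (4-connectivity on a matrix grid) -------------------

// Label supra-threshold clusters of a t-map. tail: +1 keep t > thr,
// -1 keep t < -thr, 2 keep |t| > thr (positive and negative cells never join).
// [[Rcpp::export]]
Rcpp::List label_clusters_cpp(const arma::mat& tmap, double thresh, int tail) {
  const int nr = tmap.n_rows, nc = tmap.n_cols;
  imat lab(nr, nc, fill::zeros);
  std::vector<double> masses;
  std::vector<int> qr, qc;
  int next = 0;
  for (int c0 = 0; c0 < nc; ++c0) {
    for (int r0 = 0; r0 < nr; ++r0) {
      double v = tmap(r0, c0);
      bool keep = (tail == 1) ? (v > thresh)
                : (tail == -1) ? (v < -thresh)
                : (std::fabs(v) > thresh);
      if (!keep || lab(r0, c0) != 0) continue;
      ++next;
      double sgn0 = (v > 0) ? 1.0 : -1.0;
      double mass = 0.0;
      qr.clear(); qc.clear();
      qr.push_back(r0); qc.push_back(c0);
      lab(r0, c0) = next;
      while (!qr.empty()) {
        int r = qr.back(), c = qc.back();
        qr.pop_back(); qc.pop_back();
        mass += tmap(r, c);
        const int dr[4] = {-1, 1, 0, 0}, dc[4] = {0, 0, -1, 1};
        for (int k = 0; k < 4; ++k) {
          int r2 = r + dr[k], c2 = c + dc[k];
          if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc) continue;
          if (lab(r2, c2) != 0) continue;
          double v2 = tmap(r2, c2);
          bool keep2 = (tail == 1) ? (v2 > thresh)
                     : (tail == -1) ? (v2 < -thresh)
                     : (std::fabs(v2) > thresh && ((v2 > 0) ? 1.0 : -1.0) == sgn0);
          if (keep2) { lab(r2, c2) = next; qr.push_back(r2); qc.push_back(c2); }
        }
      }
      masses.push_back(mass);
    }
  }
  return Rcpp::List::create(Rcpp::Named("labels") = lab,
                            Rcpp::Named("masses") = masses);
}

// Max absolute summed-t cluster mass for each permuted t-map (rows of T_perm,
// reshaped nr x nc column-major). Used to build the sign-flip null.
// [[Rcpp::export]]
arma::vec perm_max_masses_cpp(const arma::mat& T_perm, int nr, int nc,
                              double thresh, int tail) {
  vec out(T_perm.n_rows, fill::zeros);
  for (uword i = 0; i < T_perm.n_rows; ++i) {
    mat tm = reshape(T_perm.row(i).t(), nr, nc);
    Rcpp::List cl = label_clusters_cpp(tm, thresh, tail);
    std::vector<double> masses = Rcpp::as<std::vector<double>>(cl["masses"]);
    double mx = 0.0;
    for (double m : masses) mx = std::max(mx, std::fabs(m));
    out[i] = mx;
  }
  return out;
}
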