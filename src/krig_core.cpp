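// Numeric kernels for kriging training/prediction and body-fixed frames.
// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

// Per-feature absolute-difference matrices |f_h,i - f_h,j|, stacked as an
// n x n x nfeat cube. Computed once per training set and reused across all
// likelihood evaluations.
// [[Rcpp::export]]
arma::cube kw_absdiff(const arma::mat& F) {
  const arma::uword n = F.n_rows, m = F.n_cols;
  arma::cube D(n, n, m);
  for (arma::uword h = 0; h < m; ++h) {
    for (arma::uword i = 0; i < n; ++i) {
      D(i, i, h) = 0.0;
      for (arma::uword j = i + 1; j < n; ++j) {
        double d = std::fabs(F(i, h) - F(j, h));
        D(i, j, h) = d;
        D(j, i, h) = d;
      }
    }
  }
  return D;
}

static arma::mat kernel_from_absdiff(const arma::cube& D,
                                     const arma::vec& theta,
                                     const arma::vec& p) {
  const arma::uword n = D.n_rows;
  arma::mat S(n, n, arma::fill::zeros);
  for (arma::uword h = 0; h < D.n_slices; ++h) {
    if (std::fabs(p(h) - 2.0) < 1e-14)
      S += theta(h) * arma::square(D.slice(h));
    else if (std::fabs(p(h) - 1.0) < 1e-14)
      S += theta(h) * D.slice(h);
    else
      S += theta(h) * arma::pow(D.slice(h), p(h));
  }
  return arma::exp(-S);
}

// Kernel (correlation) matrix of a training set.
// [[Rcpp::export]]
arma::mat kw_kernel_matrix(const arma::mat& F, const arma::vec& theta,
                           const arma::vec& p) {
  return kernel_from_absdiff(kw_absdiff(F), theta, p);
}

// Concentrated log-likelihood of the kriging model with constant trend:
//   mu = (1'R^-1 y)/(1'R^-1 1),  s2 = (y-mu)'R^-1(y-mu)/n,
//   cll = -(n/2) log s2 - (1/2) log det R.
// Returns a capped large value (1e10) when s2 underflows (constant y), and
// -Inf when R cannot be factorised at the given nugget.
// [[Rcpp::export]]
double kw_cll(const arma::cube& D, const arma::vec& y, const arma::vec& theta,
              const arma::vec& p, double nugget) {
  const arma::uword n = y.n_elem;
  arma::mat R = kernel_from_absdiff(D, theta, p);
  R.diag() += nugget;
  arma::mat L;
  if (!arma::chol(L, R, "lower")) return -arma::datum::inf;
  double logdet = 2.0 * arma::accu(arma::log(L.diag()));
  arma::vec ones(n, arma::fill::ones);
  arma::vec a = arma::solve(arma::trimatl(L), y);
  arma::vec b = arma::solve(arma::trimatl(L), ones);
  double mu = arma::dot(b, a) / arma::dot(b, b);
  arma::vec r = a - mu * b;  // L^-1 (y - mu 1)
  double s2 = arma::dot(r, r) / n;
  if (s2 < 1e-300) return 1e10;
  return -0.5 * n * std::log(s2) - 0.5 * logdet;
}

// Full fit at fixed hyperparameters: trend mean, weights a = R^-1(y - mu 1),
// process variance and the concentrated log-likelihood. The nugget is
// escalated by factors of 10 (up to max_nugget) if the Cholesky
// factorisation fails; the nugget actually used is returned.
// [[Rcpp::export]]
List kw_krig_fit(const arma::cube& D, const arma::vec& y,
                 const arma::vec& theta, const arma::vec& p,
                 double nugget, double max_nugget) {
  const arma::uword n = y.n_elem;
  arma::mat R = kernel_from_absdiff(D, theta, p);
  arma::mat L;
  double nug = nugget;
  bool ok = false;
  while (true) {
    arma::mat Rn = R;
    Rn.diag() += nug;
    if (arma::chol(L, Rn, "lower")) { ok = true; break; }
    if (nug >= max_nugget) break;
    nug = std::min(max_nugget, (nug <= 0 ? 1e-12 : nug * 10.0));
  }
  if (!ok) stop("kernel matrix numerically singular even at nugget %g", nug);
  double logdet = 2.0 * arma::accu(arma::log(L.diag()));
  arma::vec ones(n, arma::fill::ones);
  arma::vec a = arma::solve(arma::trimatl(L), y);
  arma::vec b = arma::solve(arma::trimatl(L), ones);
  double mu = arma::dot(b, a) / arma::dot(b, b);
  arma::vec r = a - mu * b;
  double s2 = arma::dot(r, r) / n;
  arma::vec w = arma::solve(arma::trimatu(L.t()), r);
  double cll = (s2 < 1e-300) ? 1e10 : (-0.5 * n * std::log(s2) - 0.5 * logdet);
  return List::create(_["mu"] = mu, _["weights"] = w, _["sigma2"] = s2,
                      _["cll"] = cll, _["nugget"] = nug,
                      _["escalated"] = (nug > nugget));
}

// Batched prediction for a family of kriging models sharing one training
// feature matrix. theta and p are m x nfeat (one row per model), mu length m,
// W is n x m (kriging weights per model). Returns predicted values (q x m)
// and, if want_grad, the feature-space gradients as a q x nfeat x m cube.
// [[Rcpp::export]]
List kw_predict_batch(const arma::mat& Ftrain, const arma::mat& Fnew,
                      const arma::mat& theta, const arma::mat& p,
                      const arma::vec& mu, const arma::mat& W,
                      bool want_grad) {
  const arma::uword n = Ftrain.n_rows, q = Fnew.n_rows,
    m = mu.n_elem, nf = Ftrain.n_cols;
  arma::mat val(q, m);
  arma::cube grad;
  if (want_grad) grad.set_size(q, nf, m);
  arma::vec k(n), diff(nf);
  for (arma::uword s = 0; s < q; ++s) {
    for (arma::uword j = 0; j < m; ++j) {
      double acc = 0.0;
      arma::vec g(nf, arma::fill::zeros);
      for (arma::uword i = 0; i < n; ++i) {
        double e = 0.0;
        for (arma::uword h = 0; h < nf; ++h) {
          double d = std::fabs(Fnew(s, h) - Ftrain(i, h));
          double ph = p(j, h);
          e += theta(j, h) * (ph == 2.0 ? d * d : std::pow(d, ph));
        }
        double kv = std::exp(-e) * W(i, j);
        acc += kv;
        if (want_grad) {
          for (arma::uword h = 0; h < nf; ++h) {
            double d = Fnew(s, h) - Ftrain(i, h);
            double ph = p(j, h);
            double dd;
            if (ph == 2.0) dd = 2.0 * d;
            else {
              double ad = std::fabs(d);
              dd = (ad < 1e-300) ? 0.0 : ph * std::pow(ad, ph - 1.0) *
                (d > 0 ? 1.0 : -1.0);
            }
            g(h) -= theta(j, h) * dd * kv;
          }
        }
      }
      val(s, j) = mu(j) + acc;
      if (want_grad) for (arma::uword h = 0; h < nf; ++h) grad(s, h, j) = g(h);
    }
  }
  if (want_grad)
    return List::create(_["values"] = val, _["gradients"] = grad);
  return List::create(_["values"] = val);
}

// ---- body-fixed frames -----------------------------------------------------

static arma::mat crossmat(const arma::vec3& v) {
  arma::mat33 M(arma::fill::zeros);
  M(0, 1) = -v(2); M(0, 2) =  v(1);
  M(1, 0) =  v(2); M(1, 2) = -v(0);
  M(2, 0) = -v(1); M(2, 1) =  v(0);
  return M;
}

// Unit vector and its 3 x 9 Jacobian from a raw vector and its Jacobian.
static void unitize(const arma::vec3& u, const arma::mat& Ju,
                    arma::vec3& uhat, arma::mat& Juhat) {
  double nrm = arma::norm(u);
  uhat = u / nrm;
  Juhat = (arma::eye(3, 3) - uhat * uhat.t()) / nrm * Ju;
}

// Local frames and their derivatives for every atom of every molecule.
// coords: nmol x 9 (x,y,z of O, H1, H2). Returns:
//   rot:  9 x (3*nmol)  - each column is a 3x3 rotation, column-major
//   drot: 81 x (3*nmol) - d(rot)/d(coords of own molecule), layout
//          (9 rotation entries) x (9 coordinates), column-major per atom.
// Rotation columns are the local axes in global coordinates (local->global).
// [[Rcpp::export]]
List kw_frames(const arma::mat& coords, bool want_deriv) {
  const arma::uword nmol = coords.n_rows;
  arma::mat rot(9, 3 * nmol);
  arma::mat drot;
  if (want_deriv) drot.set_size(81, 3 * nmol);
  arma::mat JO(3, 9, arma::fill::zeros), JH1(3, 9, arma::fill::zeros),
    JH2(3, 9, arma::fill::zeros);
  for (int k = 0; k < 3; ++k) {
    JO(k, k) = 1.0; JH1(k, 3 + k) = 1.0; JH2(k, 6 + k) = 1.0;
  }
  for (arma::uword mI = 0; mI < nmol; ++mI) {
    arma::vec3 O  = coords.submat(mI, 0, mI, 2).t();
    arma::vec3 H1 = coords.submat(mI, 3, mI, 5).t();
    arma::vec3 H2 = coords.submat(mI, 6, mI, 8).t();
    for (int a = 0; a < 3; ++a) {
      arma::vec3 xhat, zhat, u1h, u2h, wh, nv;
      arma::mat Jx(3, 9), Jz(3, 9), Ju1(3, 9), Ju2(3, 9), Jw(3, 9), Jn(3, 9);
      if (a == 0) {
        unitize(H1 - O, JH1 - JO, u1h, Ju1);
        unitize(H2 - O, JH2 - JO, u2h, Ju2);
        unitize(u1h + u2h, Ju1 + Ju2, xhat, Jx);
        nv = arma::cross(u1h, u2h);
        Jn = -crossmat(u2h) * Ju1 + crossmat(u1h) * Ju2;
        unitize(nv, Jn, zhat, Jz);
      } else {
        const arma::vec3& Ha = (a == 1) ? H1 : H2;
        const arma::vec3& Hb = (a == 1) ? H2 : H1;
        const arma::mat& JHa = (a == 1) ? JH1 : JH2;
        const arma::mat& JHb = (a == 1) ? JH2 : JH1;
        unitize(O - Ha, JO - JHa, xhat, Jx);
        unitize(Hb - Ha, JHb - JHa, wh, Jw);
        nv = arma::cross(xhat, wh);
        Jn = -crossmat(wh) * Jx + crossmat(xhat) * Jw;
        unitize(nv, Jn, zhat, Jz);
      }
      arma::vec3 yhat = arma::cross(zhat, xhat);
      arma::mat Jy = -crossmat(xhat) * Jz + crossmat(zhat) * Jx;
      arma::mat33 R;
      R.col(0) = xhat; R.col(1) = yhat; R.col(2) = zhat;
      arma::uword t = 3 * mI + a;
      rot.col(t) = arma::vectorise(R);
      if (want_deriv) {
        for (int c = 0; c < 9; ++c) {
          arma::mat33 dR;
          dR.col(0) = Jx.col(c); dR.col(1) = Jy.col(c); dR.col(2) = Jz.col(c);
          drot.submat(9 * c, t, 9 * c + 8, t) = arma::vectorise(dR);
        }
      }
    }
  }
  if (want_deriv) return List::create(_["rot"] = rot, _["drot"] = drot);
  return List::create(_["rot"] = rot);
}
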