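// Bulk pair-scan + influence engine.
//
// Fits the covariate-conditioned pairwise regression on both eigentraits,
// reparametrizes the interaction coefficients into directed influence
// coefficients with delta-method variances, recomposes eigentrait main
// effects into knockdown-to-phenotype coefficients, and (optionally)
// replays the whole computation under tandem permutations of the two
// scanned genotype columns to collect null test statistics.
//
// The per-eigentrait fits may use different covariate sets, so the
// cross-eigentrait coefficient covariance uses the general
// seemingly-unrelated-regressions form
//   Cov(b1, b2) = s12 (X1'X1)^-1 X1'X2 (X2'X2)^-1,
// with s12 the cross-eigentrait residual covariance.

#include <RcppArmadillo.h>
using namespace Rcpp;

namespace {

constexpr int STATUS_ESTIMABLE = 0;
constexpr int STATUS_RANK_DEFICIENT = 1;
constexpr int STATUS_SINGULAR = 2;
constexpr int STATUS_POLE = 3;

struct PairFit {
  int status = STATUS_RANK_DEFICIENT;
  arma::vec theta;   // (beta_a1, beta_a2, beta_b1, beta_b2, gamma_1, gamma_2)
  arma::mat Sigma;   // 6 x 6
  arma::vec delta;   // 2
  arma::vec m;       // (m_ab, m_ba)
  arma::vec var_m;   // 2
  arma::vec pheno;     // 2 * NP (gene a then gene b)
  arma::vec pheno_var; // 2 * NP
  double df1 = 0.0, df2 = 0.0;
};

// singular values of a 2x2 matrix, closed form
inline void svd2(const arma::mat22& M, double& smax, double& smin) {
  const double a = M(0, 0), b = M(0, 1), c = M(1, 0), d = M(1, 1);
  const double S1 = a * a + b * b + c * c + d * d;
  const double t1 = a * a + b * b - c * c - d * d;
  const double t2 = 2.0 * (a * c + b * d);
  const double S2 = std::sqrt(t1 * t1 + t2 * t2);
  smax = std::sqrt(std::max(0.0, (S1 + S2) / 2.0));
  smin = std::sqrt(std::max(0.0, (S1 - S2) / 2.0));
}

struct FixedBlocks {
  arma::mat F;    // n x f   (intercept + covariates)
  arma::mat FtF;  // f x f
  arma::mat FtU;  // f x 2
};

// Fit one pair given the (possibly permuted) scanned columns.
void fit_pair(const arma::vec& xa, const arma::vec& xb,
              const FixedBlocks& B1, const FixedBlocks& B2,
              const arma::mat& F1tF2, const arma::mat& UtU, const arma::mat& U,
              const arma::mat& L, double cond_limit, double pole_tol,
              double rcond_tol, PairFit& out) {
  const arma::uword n = U.n_rows;
  const arma::uword f1 = B1.F.n_cols, f2 = B2.F.n_cols;
  const arma::uword p1 = f1 + 3, p2 = f2 + 3;
  out.status = STATUS_RANK_DEFICIENT;

  arma::mat Vm(n, 3);
  Vm.col(0) = xa;
  Vm.col(1) = xb;
  Vm.col(2) = xa % xb;

  arma::mat VtV = Vm.t() * Vm;              // 3 x 3
  arma::mat VtU = Vm.t() * U;               // 3 x 2
  arma::mat VtF1 = Vm.t() * B1.F;           // 3 x f1
  arma::mat VtF2 = Vm.t() * B2.F;           // 3 x f2

  arma::mat X1tX1(p1, p1), X2tX2(p2, p2);
  X1tX1.submat(0, 0, f1 - 1, f1 - 1) = B1.FtF;
  X1tX1.submat(0, f1, f1 - 1, p1 - 1) = VtF1.t();
  X1tX1.submat(f1, 0, p1 - 1, f1 - 1) = VtF1;
  X1tX1.submat(f1, f1, p1 - 1, p1 - 1) = VtV;
  X2tX2.submat(0, 0, f2 - 1, f2 - 1) = B2.FtF;
  X2tX2.submat(0, f2, f2 - 1, p2 - 1) = VtF2.t();
  X2tX2.submat(f2, 0, p2 - 1, f2 - 1) = VtF2;
  X2tX2.submat(f2, f2, p2 - 1, p2 - 1) = VtV;

  arma::mat X1tU = arma::join_cols(B1.FtU, VtU); // p1 x 2
  arma::mat X2tU = arma::join_cols(B2.FtU, VtU); // p2 x 2

  if (arma::rcond(X1tX1) < rcond_tol || arma::rcond(X2tX2) < rcond_tol) return;
  arma::mat A1, A2;
  if (!arma::inv_sympd(A1, X1tX1)) return;
  if (!arma::inv_sympd(A2, X2tX2)) return;

  arma::vec b1 = A1 * X1tU.col(0);
  arma::vec b2 = A2 * X2tU.col(1);
  const double df1 = static_cast<double>(n) - static_cast<double>(p1);
  const double df2 = static_cast<double>(n) - static_cast<double>(p2);
  if (df1 <= 0 || df2 <= 0) return;
  const double rss1 = std::max(0.0, UtU(0, 0) - arma::dot(b1, X1tU.col(0)));
  const double rss2 = std::max(0.0, UtU(1, 1) - arma::dot(b2, X2tU.col(1)));
  const double s1 = rss1 / df1;
  const double s2 = rss2 / df2;

  arma::mat X1tX2(p1, p2);
  X1tX2.submat(0, 0, f1 - 1, f2 - 1) = F1tF2;
  X1tX2.submat(0, f2, f1 - 1, p2 - 1) = VtF1.t();
  X1tX2.submat(f1, 0, p1 - 1, f2 - 1) = VtF2;
  X1tX2.submat(f1, f2, p1 - 1, p2 - 1) = VtV;

  const double e1e2 = UtU(0, 1) - arma::dot(b1, X1tU.col(1)) -
                      arma::dot(b2, X2tU.col(0)) +
                      arma::as_scalar(b1.t() * X1tX2 * b2);
  const double s12 = e1e2 / std::sqrt(df1 * df2);
  arma::mat Cov12 = s12 * A1 * X1tX2 * A2;

  // theta = (beta_a1, beta_a2, beta_b1, beta_b2, gamma_1, gamma_2)
  const arma::uvec q1 = {f1, f1 + 1, f1 + 2}; // xa, xb, xab in design 1
  const arma::uvec q2 = {f2, f2 + 1, f2 + 2};
  arma::vec theta(6);
  theta(0) = b1(q1(0));
  theta(1) = b2(q2(0));
  theta(2) = b1(q1(1));
  theta(3) = b2(q2(1));
  theta(4) = b1(q1(2));
  theta(5) = b2(q2(2));

  const arma::uvec et1 = {0, 2, 4};
  const arma::uvec et2 = {1, 3, 5};
  arma::mat Sigma(6, 6, arma::fill::zeros);
  Sigma.submat(et1, et1) = s1 * A1.submat(q1, q1);
  Sigma.submat(et2, et2) = s2 * A2.submat(q2, q2);
  Sigma.submat(et1, et2) = Cov12.submat(q1, q2);
  Sigma.submat(et2, et1) = Cov12.submat(q1, q2).t();

  out.theta = theta;
  out.Sigma = Sigma;
  out.df1 = df1;
  out.df2 = df2;

  // knockdown-to-phenotype recomposition (independent of M singularity)
  const arma::uword NP = L.n_rows;
  if (NP > 0) {
    out.pheno.set_size(2 * NP);
    out.pheno_var.set_size(2 * NP);
    arma::vec ca = {theta(0), theta(1)};
    arma::vec cb = {theta(2), theta(3)};
    const arma::uvec ia = {0, 1}, ib = {2, 3};
    arma::mat Sa = Sigma.submat(ia, ia);
    arma::mat Sb = Sigma.submat(ib, ib);
    out.pheno.subvec(0, NP - 1) = L * ca;
    out.pheno.subvec(NP, 2 * NP - 1) = L * cb;
    out.pheno_var.subvec(0, NP - 1) = arma::diagvec(L * Sa * L.t());
    out.pheno_var.subvec(NP, 2 * NP - 1) = arma::diagvec(L * Sb * L.t());
    out.pheno_var.transform([](double v) { return std::max(v, 0.0); });
  }

  // activity reparametrization: M rows = eigentraits, cols = (a, b)
  arma::mat22 M;
  M(0, 0) = theta(0);
  M(1, 0) = theta(1);
  M(0, 1) = theta(2);
  M(1, 1) = theta(3);
  double smax, smin;
  svd2(M, smax, smin);
  if (smin <= 0.0 || smax / smin > cond_limit) {
    out.status = STATUS_SINGULAR;
    return;
  }
  const double det = M(0, 0) * M(1, 1) - M(0, 1) * M(1, 0);
  arma::mat22 Minv;
  Minv(0, 0) = M(1, 1) / det;
  Minv(0, 1) = -M(0, 1) / det;
  Minv(1, 0) = -M(1, 0) / det;
  Minv(1, 1) = M(0, 0) / det;
  arma::vec g = {theta(4), theta(5)};
  arma::vec delta = Minv * g;
  out.delta = delta;
  if (std::abs(1.0 + delta(0)) < pole_tol || std::abs(1.0 + delta(1)) < pole_tol) {
    out.status = STATUS_POLE;
    return;
  }
  arma::vec m = {delta(0) / (1.0 + delta(1)), delta(1) / (1.0 + delta(0))};

  // analytic Jacobian of delta wrt theta, then of m wrt delta
  arma::mat Jd(2, 6);
  Jd.col(0) = -delta(0) * Minv.col(0);
  Jd.col(1) = -delta(0) * Minv.col(1);
  Jd.col(2) = -delta(1) * Minv.col(0);
  Jd.col(3) = -delta(1) * Minv.col(1);
  Jd.col(4) = Minv.col(0);
  Jd.col(5) = Minv.col(1);
  arma::mat22 Jm;
  Jm(0, 0) = 1.0 / (1.0 + delta(1));
  Jm(0, 1) = -delta(0) / ((1.0 + delta(1)) * (1.0 + delta(1)));
  Jm(1, 0) = -delta(1) / ((1.0 + delta(0)) * (1.0 + delta(0)));
  Jm(1, 1) = 1.0 / (1.0 + delta(0));
  arma::mat J = Jm * Jd;
  arma::vec var_m = arma::diagvec(J * Sigma * J.t());
  var_m.transform([](double v) { return std::max(v, 0.0); });

  out.m = m;
  out.var_m = var_m;
  out.status = STATUS_ESTIMABLE;
}

}  // namespace

// [[Rcpp::export]]
List pair_engine_cpp(const arma::mat& U, const arma::mat& X, const arma::mat& L,
                     const List& covs, const arma::umat& pairs,
                     const arma::umat& perms, double cond_limit,
                     double pole_tol, double rcond_tol) {
  const arma::uword n = U.n_rows;
  const arma::uword P = pairs.n_rows;
  const arma::uword NP = L.n_rows;
  const arma::uword nperm = perms.n_cols;
  if (U.n_cols != 2) stop("engine requires exactly two eigentraits");
  if (covs.size() < 2) stop("need one covariate set per eigentrait");

  arma::mat UtU = U.t() * U;
  arma::uvec cov1 = as<arma::uvec>(covs[0]); // 1-based gene indices
  arma::uvec cov2 = as<arma::uvec>(covs[1]);

  arma::mat coef(P, 6), se_coef(P, 6), delta(P, 2), m(P, 2), var_m(P, 2);
  arma::mat pheno(P, 2 * NP), pheno_se(P, 2 * NP);
  arma::vec df1(P), df2(P);
  arma::ivec status(P);
  coef.fill(NA_REAL); se_coef.fill(NA_REAL); delta.fill(NA_REAL);
  m.fill(NA_REAL); var_m.fill(NA_REAL);
  pheno.fill(NA_REAL); pheno_se.fill(NA_REAL);
  df1.fill(NA_REAL); df2.fill(NA_REAL);

  arma::mat null_m(nperm, 2 * P), null_pheno(nperm, 2 * P * NP);
  null_m.fill(NA_REAL);
  null_pheno.fill(NA_REAL);
  arma::ivec null_skips(P, arma::fill::zeros);

  PairFit fit;
  for (arma::uword p = 0; p < P; ++p) {
    const arma::uword a = pairs(p, 0) - 1;
    const arma::uword b = pairs(p, 1) - 1;

    // per-eigentrait fixed blocks: intercept + covariates minus the pair
    auto make_blocks = [&](const arma::uvec& cov) {
      FixedBlocks blk;
      std::vector<arma::uword> keep;
      for (arma::uword idx : cov) {
        const arma::uword g0 = idx - 1;
        if (g0 != a && g0 != b) keep.push_back(g0);
      }
      blk.F.set_size(n, 1 + keep.size());
      blk.F.col(0).ones();
      for (size_t c = 0; c < keep.size(); ++c) blk.F.col(c + 1) = X.col(keep[c]);
      blk.FtF = blk.F.t() * blk.F;
      blk.FtU = blk.F.t() * U;
      return blk;
    };
    FixedBlocks B1 = make_blocks(cov1);
    FixedBlocks B2 = make_blocks(cov2);
    arma::mat F1tF2 = B1.F.t() * B2.F;

    const arma::vec xa = X.col(a);
    const arma::vec xb = X.col(b);
    fit_pair(xa, xb, B1, B2, F1tF2, UtU, U, L, cond_limit, pole_tol, rcond_tol, fit);
    status(p) = fit.status;
    if (fit.status != STATUS_RANK_DEFICIENT) {
      coef.row(p) = fit.theta.t();
      se_coef.row(p) = arma::sqrt(arma::clamp(arma::diagvec(fit.Sigma), 0.0, arma::datum::inf)).t();
      df1(p) = fit.df1;
      df2(p) = fit.df2;
      if (NP > 0) {
        pheno.row(p) = fit.pheno.t();
        pheno_se.row(p) = arma::sqrt(fit.pheno_var).t();
      }
      if (fit.status == STATUS_ESTIMABLE || fit.status == STATUS_POLE) {
        delta.row(p) = fit.delta.t();
      }
      if (fit.status == STATUS_ESTIMABLE) {
        m.row(p) = fit.m.t();
        var_m.row(p) = fit.var_m.t();
      }
    }
    if (status(p) != STATUS_ESTIMABLE || nperm == 0) continue;

    // tandem permutation null: one shared row permutation of the two
    // scanned columns per draw; everything else untouched
    for (arma::uword q = 0; q < nperm; ++q) {
      arma::uvec idx = perms.col(q) - 1;
      arma::vec xap = xa.elem(idx);
      arma::vec xbp = xb.elem(idx);
      fit_pair(xap, xbp, B1, B2, F1tF2, UtU, U, L, cond_limit, pole_tol, rcond_tol, fit);
      if (fit.status != STATUS_ESTIMABLE) {
        null_skips(p) += 1;
        continue;
      }
      null_m(q, 2 * p) = std::abs(fit.m(0)) / std::sqrt(fit.var_m(0));
      null_m(q, 2 * p + 1) = std::abs(fit.m(1)) / std::sqrt(fit.var_m(1));
      for (arma::uword c = 0; c < 2 * NP; ++c) {
        null_pheno(q, 2 * NP * p + c) =
            std::abs(fit.pheno(c)) / std::sqrt(fit.pheno_var(c));
      }
    }
  }

  return List::create(
      _["coef"] = coef, _["se_coef"] = se_coef, _["delta"] = delta,
      _["m"] = m, _["var_m"] = var_m, _["pheno"] = pheno,
      _["pheno_se"] = pheno_se, _["df1"] = df1, _["df2"] = df2,
      _["status"] = status, _["null_m"] = null_m,
      _["null_pheno"] = null_pheno, _["null_skips"] = null_skips);
}
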