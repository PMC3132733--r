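// Per-SNP logistic regression scan by iteratively reweighted least squares.
// The permutation null recomputes the full scan for every shuffled phenotype
// vector, so this loop is the hot path of the whole package.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Fit status ~ intercept + dosage + covariates on the rows where dosage is
// observed; return the Wald ingredients for the dosage coefficient.
//
// dosage:  n_subjects x n_snps, minor-allele counts 0/1/2, NA = missing
// status:  length n_subjects, 0 = control, 1 = case (no missing)
// covars:  n_subjects x n_cov (possibly 0 columns), no missing
//
// Returns n_snps x 4: beta, se, n_used, code where code is
//   0 = clean fit, 1 = monomorphic among non-missing subjects,
//   2 = not estimable or separation suspected (flagged, no usable p).
// [[Rcpp::export(name = ".waldScanCpp")]]
arma::mat waldScanCpp(const arma::mat& dosage,
                      const arma::vec& status,
                      const arma::mat& covars,
                      const int max_iter = 30,
                      const double tol = 1e-8,
                      const double beta_bound = 12.0,
                      const double se_bound = 100.0) {
    const arma::uword n = dosage.n_rows;
    const arma::uword m = dosage.n_cols;
    const arma::uword nc = covars.n_cols;
    const arma::uword p = 2 + nc;
    arma::mat out(m, 4);
    out.fill(NA_REAL);

    for (arma::uword j = 0; j < m; ++j) {
        const arma::vec dj = dosage.col(j);
        const arma::uvec keep = arma::find_finite(dj);
        const arma::uword nu = keep.n_elem;
        out(j, 2) = (double)nu;

        if (nu < p + 1) { out(j, 3) = 2.0; continue; }

        const arma::vec d = dj.elem(keep);
        const arma::vec y = status.elem(keep);

        // monomorphic among the subjects actually used
        if (d.max() == d.min()) { out(j, 3) = 1.0; continue; }
        // status constant among used subjects: likelihood has no information
        if (y.max() == y.min()) { out(j, 3) = 2.0; continue; }

        arma::mat X(nu, p);
        X.col(0).ones();
        X.col(1) = d;
        if (nc > 0) X.cols(2, p - 1) = covars.rows(keep);

        arma::vec b(p, arma::fill::zeros);
        b(0) = std::log(arma::mean(y) / (1.0 - arma::mean(y)));
        bool converged = false, singular = false;
        arma::mat A(p, p);

        for (int it = 0; it < max_iter; ++it) {
            arma::vec eta = X * b;
            arma::vec mu = 1.0 / (1.0 + arma::exp(-eta));
            mu.clamp(1e-10, 1.0 - 1e-10);
            arma::vec w = mu % (1.0 - mu);
            arma::vec z = eta + (y - mu) / w;
            const arma::mat Xw = X.each_col() % w;
            A = X.t() * Xw;
            arma::vec bnew;
            if (!arma::solve(bnew, A, X.t() * (w % z),
                             arma::solve_opts::no_approx)) {
                singular = true;
                break;
            }
            const double step = arma::abs(bnew - b).max();
            b = bnew;
            if (step < tol) { converged = true; break; }
        }

        if (singular) { out(j, 3) = 2.0; continue; }

        // information evaluated at the final estimate
        {
            arma::vec eta = X * b;
            arma::vec mu = 1.0 / (1.0 + arma::exp(-eta));
            mu.clamp(1e-10, 1.0 - 1e-10);
            arma::vec w = mu % (1.0 - mu);
            A = X.t() * (X.each_col() % w);
        }
        arma::mat cov;
        if (!arma::inv_sympd(cov, A)) { out(j, 3) = 2.0; continue; }
        const double beta = b(1);
        const double se = std::sqrt(cov(1, 1));
        out(j, 0) = beta;
        out(j, 1) = se;
        out(j, 3) = (!converged || std::abs(beta) > beta_bound ||
                     se > se_bound) ? 2.0 : 0.0;
    }
    return out;
}
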