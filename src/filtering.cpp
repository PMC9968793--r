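// Zero-phase IIR application: forward-backward filtering with reflective
// edge padding (3x filter order). Coefficients come from signal::butter on
// the R side; this is only the (performance-critical) application step.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static vec filt1(const vec& b, const vec& a, const vec& x) {
  const uword n = x.n_elem;
  const uword nb = b.n_elem, na = a.n_elem;
  const uword nz = std::max(nb, na) - 1;
  vec z(nz, fill::zeros);
  vec bb(nz + 1, fill::zeros), aa(nz + 1, fill::zeros);
  bb.head(nb) = b / a(0);
  aa.head(na) = a / a(0);
  vec y(n);
  for (uword i = 0; i < n; ++i) {
    double yi = bb(0) * x(i) + z(0);
    for (uword j = 0; j < nz - 1; ++j)
      z(j) = bb(j + 1) * x(i) + z(j + 1) - aa(j + 1) * yi;
    z(nz - 1) = bb(nz) * x(i) - aa(nz) * yi;
    y(i) = yi;
  }
  return y;
}

// [[Rcpp::export]]
arma::vec filtfilt_cpp(const arma::vec& b, const arma::vec& a, const arma::vec& x) {
  const uword n = x.n_elem;
  const uword nfact = 3 * (std::max(b.n_elem, a.n_elem) - 1);
  if (n <= nfact + 1)
    Rcpp::stop("signal too short for zero-phase filtering");
  vec pre = 2 * x(0) - flipud(x.subvec(1, nfact));
  vec post = 2 * x(n - 1) - flipud(x.subvec(n - 1 - nfact, n - 2));
  vec xp = join_cols(join_cols(pre, x), post);
  vec y = filt1(b, a, xp);
  y = flipud(filt1(b, a, flipud(y)));
  return y.subvec(nfact, nfact + n - 1);
}
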