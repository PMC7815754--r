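#include <Rcpp.h>
using namespace Rcpp;

// abundance-weighted beta mean nearest taxon distance between two
// communities given by present-taxon indices (0-based rows of D) and
// normalized weights; perm, when non-null, remaps taxon i -> perm[i]
// (a tip shuffle of the phylogeny).
static double bmntd_one(const IntegerVector& ia, const NumericVector& wa,
                        const IntegerVector& ib, const NumericVector& wb,
                        const NumericMatrix& D, const int* perm) {
  const int na = ia.size(), nb = ib.size();
  double acc = 0.0;
  for (int u = 0; u < na; ++u) {
    const int i = perm ? perm[ia[u]] : ia[u];
    double m = R_PosInf;
    for (int v = 0; v < nb; ++v) {
      const int j = perm ? perm[ib[v]] : ib[v];
      const double d = D(i, j);
      if (d < m) m = d;
    }
    acc += wa[u] * m;
  }
  for (int v = 0; v < nb; ++v) {
    const int j = perm ? perm[ib[v]] : ib[v];
    double m = R_PosInf;
    for (int u = 0; u < na; ++u) {
      const int i = perm ? perm[ia[u]] : ia[u];
      const double d = D(i, j);
      if (d < m) m = d;
    }
    acc += wb[v] * m;
  }
  return 0.5 * acc;
}

// [[Rcpp::export]]
double cpp_bmntd(IntegerVector ia, NumericVector wa,
                 IntegerVector ib, NumericVector wb,
                 NumericMatrix D) {
  if (ia.size() == 0 || ib.size() == 0)
    stop("empty community in bmntd");
  return bmntd_one(ia, wa, ib, wb, D, nullptr);
}

// null betaMNTD under each row of P (n_null x n_taxa matrix of 0-based
// permutations of the taxon set)
// [[Rcpp::export]]
NumericVector cpp_bmntd_null(IntegerVector ia, NumericVector wa,
                             IntegerVector ib, NumericVector wb,
                             NumericMatrix D, IntegerMatrix P) {
  const int n_null = P.nrow();
  NumericVector out(n_null);
  std::vector<int> perm(P.ncol());
  for (int r = 0; r < n_null; ++r) {
    for (int k = 0; k < P.ncol(); ++k) perm[k] = P(r, k);
    out[r] = bmntd_one(ia, wa, ib, wb, D, perm.data());
  }
  return out;
}

// Bray-Curtis between two count/abundance vectors of equal length
// [[Rcpp::export]]
double cpp_bray(NumericVector x, NumericVector y) {
  double num = 0.0, den = 0.0;
  for (int i = 0; i < x.size(); ++i) {
    num += std::fabs(x[i] - y[i]);
    den += x[i] + y[i];
  }
  if (den <= 0) stop("Bray-Curtis undefined for empty pair");
  return num / den;
}
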