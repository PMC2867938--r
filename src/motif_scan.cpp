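#include <Rcpp.h>
using namespace Rcpp;

// Core scan: mean likelihood ratio over all windows of both strands.
// codes: 1..4 for A,C,G,T; NA for any other base (neutral contribution).
// lrm: 4 x L column-major array of log(p_pwm / p_background).
// The reverse strand is scanned as the reverse complement (base 5 - c);
// the reverse complements of all forward windows enumerate exactly the
// windows of the reverse-complement sequence.
static double scan_one(const int* codes, const int n, const double* lrm,
                       const int L) {
  const int nw = n - L + 1;
  if (nw < 1) Rcpp::stop("sequence shorter than the motif");
  double total = 0.0;
  for (int i = 0; i < nw; ++i) {
    double fwd = 0.0, rev = 0.0;
    const int* w = codes + i;
    for (int j = 0; j < L; ++j) {
      const double* col = lrm + 4 * j;
      const int c = w[j];
      if (c != NA_INTEGER) fwd += col[c - 1];
      const int rc = w[L - 1 - j];
      if (rc != NA_INTEGER) rev += col[4 - rc];
    }
    total += std::exp(fwd) + std::exp(rev);
  }
  return total / (2.0 * nw);
}

// [[Rcpp::export(name = ".seq_score_cpp")]]
double seq_score_cpp(IntegerVector codes, NumericMatrix lrm) {
  return scan_one(INTEGER(codes), codes.size(), REAL(lrm), lrm.ncol());
}

// [[Rcpp::export(name = ".seq_scores_cpp")]]
NumericVector seq_scores_cpp(List codes_list, NumericMatrix lrm) {
  const int m = codes_list.size();
  NumericVector out(m);
  for (int k = 0; k < m; ++k) {
    IntegerVector codes = codes_list[k];
    out[k] = scan_one(INTEGER(codes), codes.size(), REAL(lrm), lrm.ncol());
  }
  return out;
}
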