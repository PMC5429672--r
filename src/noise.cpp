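#include <Rcpp.h>
using namespace Rcpp;

// EMCCD-like camera model in one pass: observed = Pois(gain * conc) + offset
// + N(0, readSd), rounded to integer ADU and clipped at zero. Uses R's RNG
// stream (seed-reproducible from set.seed()).
// [[Rcpp::export(name = ".cameraNoise")]]
NumericVector cameraNoise(NumericVector conc, double gain, double offset,
                          double readSd) {
  R_xlen_t n = conc.size();
  NumericVector out(n);
  RNGScope scope;
  for (R_xlen_t i = 0; i < n; ++i) {
    double lambda = conc[i] * gain;
    double v = (lambda > 0.0 ? R::rpois(lambda) : 0.0) + offset;
    if (readSd > 0.0) v += R::norm_rand() * readSd;
    v = std::round(v);
    out[i] = (v < 0.0) ? 0.0 : v;
  }
  return out;
}
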