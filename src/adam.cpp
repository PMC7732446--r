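#include <Rcpp.h>
using namespace Rcpp;

// In-place Adam parameter update. The moment buffers m, v and the
// parameter array w are modified in place; g is the gradient. c1 and c2
// are the bias-correction factors 1 - beta1^t and 1 - beta2^t. Updating in
// place avoids allocating several parameter-sized temporaries per
// minibatch, which dominates the cost of training wide layers otherwise.
// [[Rcpp::export]]
void adam_step_inplace(NumericVector w, NumericVector m, NumericVector v,
                       NumericVector g, double lr, double beta1,
                       double beta2, double eps, double c1, double c2) {
  R_xlen_t n = w.size();
  if (m.size() != n || v.size() != n || g.size() != n)
    stop("adam_step_inplace: length mismatch");
  double *pw = REAL(w), *pm = REAL(m), *pv = REAL(v), *pg = REAL(g);
  for (R_xlen_t i = 0; i < n; ++i) {
    double gi = pg[i];
    double mi = beta1 * pm[i] + (1.0 - beta1) * gi;
    double vi = beta2 * pv[i] + (1.0 - beta2) * gi * gi;
    pm[i] = mi;
    pv[i] = vi;
    pw[i] -= lr * (mi / c1) / (std::sqrt(vi / c2) + eps);
  }
}
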