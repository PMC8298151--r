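#include <Rcpp.h>
using namespace Rcpp;

// Close-returns recurrence histogram for RPDE: for each reference point in
// the delay embedding (subsampled by `stride`), advance until the trajectory
// first leaves the ball of given radius around the reference, then until it
// first re-enters; the elapsed time is one recurrence period. Periods longer
// than t_max (or never completing) are discarded.
// [[Rcpp::export]]
IntegerVector rpde_histogram(NumericVector x, int embed_dim, int delay,
                             double radius, int t_max, int stride) {
  const int n = x.size();
  const int n_embed = n - (embed_dim - 1) * delay;
  IntegerVector hist(t_max);
  if (n_embed <= 1) return hist;
  const double r2 = radius * radius;
  for (int i = 0; i < n_embed - 1; i += stride) {
    const int j_end = std::min(n_embed, i + t_max + 1);
    bool left = false;
    for (int j = i + 1; j < j_end; ++j) {
      double d2 = 0.0;
      for (int k = 0; k < embed_dim; ++k) {
        const double d = x[j + k * delay] - x[i + k * delay];
        d2 += d * d;
        if (d2 > r2) break;
      }
      const bool inside = d2 <= r2;
      if (!left) {
        if (!inside) left = true;
      } else if (inside) {
        hist[j - i - 1]++;          // recurrence period T = j - i
        break;
      }
    }
  }
  return hist;
}
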