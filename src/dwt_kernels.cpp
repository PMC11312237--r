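#include <Rcpp.h>
using namespace Rcpp;

static std::vector<double> conv_down_vec(const std::vector<double>& x,
                                         const NumericVector& filt) {
  const int n = x.size(), L = filt.size();
  const int p = L - 1;
  std::vector<double> ext(n + 2 * p);
  for (int i = 0; i < p; ++i) ext[i] = x[p - 1 - i];
  for (int i = 0; i < n; ++i) ext[p + i] = x[i];
  for (int i = 0; i < p; ++i) ext[p + n + i] = x[n - 1 - i];
  const int O = (n + L - 1) / 2;
  std::vector<double> out(O);
  for (int i = 0; i < O; ++i) {
    double acc = 0.0;
    const int base = 2 * i;
    for (int j = 0; j < L; ++j) acc += filt[j] * ext[base + L - j];
    out[i] = acc;
  }
  return out;
}

// single-branch synthesis step, trimmed to `target` samples
static std::vector<double> conv_up_vec(const std::vector<double>& v,
                                       const NumericVector& filt, int target) {
  const int O = v.size(), L = filt.size();
  const int n_out = 2 * O - L + 2;
  std::vector<double> r(n_out, 0.0);
  for (int m = 0; m < O; ++m) {
    if (v[m] == 0.0) continue;
    const int t0 = 2 * m + 2 - L;
    int jlo = t0 < 0 ? -t0 : 0;
    int jhi = std::min(L - 1, n_out - 1 - t0);
    for (int j = jlo; j <= jhi; ++j) r[t0 + j] += v[m] * filt[j];
  }
  if ((int)r.size() > target) r.resize(target);
  return r;
}

// Full per-band pipeline: `level`-deep analysis of x, then reconstruction
// of one full-length signal per coefficient set with all others zeroed.
// Row k of the result: k = 0 -> cA_level, k = 1 -> cD_level, ...,
// k = level -> cD1.
// [[Rcpp::export]]
NumericMatrix dwt_subbands_cpp(NumericVector x, NumericVector dec_lo,
                               NumericVector dec_hi, NumericVector rec_lo,
                               NumericVector rec_hi, int level) {
  const int n = x.size();
  std::vector< std::vector<double> > details(level);
  std::vector<int> lens(level + 1);  // lens[l-1] = coeff length at level l
  std::vector<double> a(x.begin(), x.end());
  for (int l = 0; l < level; ++l) {
    details[l] = conv_down_vec(a, dec_hi);
    a = conv_down_vec(a, dec_lo);
    lens[l] = details[l].size();
  }
  NumericMatrix out(level + 1, n);
  for (int k = 0; k <= level; ++k) {
    // band k lives at depth `depth`; first synthesis step uses rec_lo for
    // the approximation band, rec_hi for a detail band
    int depth = (k == 0) ? level : level - k + 1;
    std::vector<double> r = (k == 0) ? a : details[depth - 1];
    for (int l = depth; l >= 1; --l) {
      int target = (l > 1) ? lens[l - 2] : n;
      const NumericVector& filt = (l == depth && k != 0) ? rec_hi : rec_lo;
      r = conv_up_vec(r, filt, target);
    }
    for (int i = 0; i < n; ++i) out(k, i) = r[i];
  }
  return out;
}
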