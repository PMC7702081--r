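#include <Rcpp.h>
using namespace Rcpp;

// Multi-time-origin dot-product TCF.
// arr: numeric array [n_entities, n_dim, n_frames] (n_dim = 3 for unit
// vectors, 1 for scalars). origins: 1-based frame indices; every origin must
// satisfy origin + n_lags - 1 <= n_frames. member: optional logical matrix
// [n_origins, n_entities] restricting which entities contribute at each
// origin (origin-membership selection). Returns value per lag (mean over
// contributing origin-entity pairs) and the pair count per lag.
// Accumulation order (origin outer, entity inner, component innermost) is
// fixed so that an R double-loop oracle reproduces the sums bit for bit.
// [[Rcpp::export]]
List cpp_tcf_dot(NumericVector arr, IntegerVector origins, int n_lags,
                 Nullable<LogicalMatrix> member = R_NilValue) {
  IntegerVector dims = arr.attr("dim");
  if (dims.size() != 3) stop("arr must be [n_entities, n_dim, n_frames]");
  const int n = dims[0], nd = dims[1], nf = dims[2];
  const int no = origins.size();
  const double* x = REAL(arr);
  LogicalMatrix mem;
  bool has_mem = member.isNotNull();
  if (has_mem) {
    mem = member.get();
    if (mem.nrow() != no || mem.ncol() != n)
      stop("member must be n_origins x n_entities");
  }
  NumericVector value(n_lags);
  IntegerVector count(n_lags);
  const R_xlen_t frame_stride = (R_xlen_t)n * nd;
  for (int k = 0; k < n_lags; ++k) {
    double acc = 0.0;
    R_xlen_t cnt = 0;
    for (int oi = 0; oi < no; ++oi) {
      const int o = origins[oi] - 1;
      if (o + k >= nf) continue;
      const double* a = x + (R_xlen_t)o * frame_stride;
      const double* b = x + (R_xlen_t)(o + k) * frame_stride;
      for (int e = 0; e < n; ++e) {
        if (has_mem && !mem(oi, e)) continue;
        double dot = 0.0;
        for (int d = 0; d < nd; ++d) dot += a[e + (R_xlen_t)d * n] * b[e + (R_xlen_t)d * n];
        acc += dot;
        ++cnt;
      }
    }
    value[k] = cnt > 0 ? acc / (double)cnt : NA_REAL;
    count[k] = (int)cnt;
  }
  return List::create(_["value"] = value, _["count"] = count);
}

// Continuous-bond survival TCF. h: integer/logical matrix [n_pairs, n_frames]
// of bond indicators. A pair contributes at origin o only if bonded there;
// survival at lag k requires the bond to persist at every frame in [o, o+k].
// Returns S per lag and the bonded-at-origin count per lag.
// [[Rcpp::export]]
List cpp_tcf_survival(IntegerMatrix h, IntegerVector origins, int n_lags) {
  const int np = h.nrow(), nf = h.ncol();
  const int no = origins.size();
  // run[p, f] = number of consecutive bonded frames starting at f
  IntegerMatrix run(np, nf);
  for (int p = 0; p < np; ++p) {
    int acc = 0;
    for (int f = nf - 1; f >= 0; --f) {
      acc = h(p, f) ? acc + 1 : 0;
      run(p, f) = acc;
    }
  }
  NumericVector value(n_lags);
  IntegerVector count(n_lags);
  for (int k = 0; k < n_lags; ++k) {
    R_xlen_t num = 0, den = 0;
    for (int oi = 0; oi < no; ++oi) {
      const int o = origins[oi] - 1;
      if (o + k >= nf) continue;
      for (int p = 0; p < np; ++p) {
        if (!h(p, o)) continue;
        ++den;
        if (run(p, o) > k) ++num;
      }
    }
    value[k] = den > 0 ? (double)num / (double)den : NA_REAL;
    count[k] = (int)den;
  }
  return List::create(_["value"] = value, _["count"] = count);
}
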