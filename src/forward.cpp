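#include <Rcpp.h>
using namespace Rcpp;

// Forward-model kernels operate on a step-function drive: within each run the
// spatial drive is piecewise constant, switching only at stimulus on/off
// boundaries ("intervals": [start, end) frames with an aperture id). A causal
// convolution with an impulse-response kernel h is evaluated by placing the
// cumulative kernel C (C[d] = sum of h over lags 1..d) at every step edge;
// beyond the kernel support the contribution is the constant tail (sum of h).
// This is exact and costs O(edges * support) instead of O(T * support).

static void add_edge(std::vector<double>& r, std::vector<double>& taildiff,
                     int t0, double a, const double* C, int L, double Ctail,
                     int T) {
  if (t0 >= T) return;
  const int lmax = std::min(L, T - t0);
  double* rp = &r[t0];
  for (int l = 0; l < lmax; ++l) rp[l] += a * C[l];
  const int pos = t0 + L;
  if (pos < T) taildiff[pos] += a * Ctail;
}

// convolve the run's step drive with cumulative kernel C; result into r
static void conv_run(std::vector<double>& r, const IntegerVector& s,
                     const IntegerVector& e, const IntegerVector& ap,
                     int first, int n_iv, const double* g, const double* C,
                     int L, double Ctail, int T) {
  std::fill(r.begin(), r.end(), 0.0);
  if (n_iv == 0) return;
  std::vector<double> taildiff(T, 0.0);
  for (int i = first; i < first + n_iv; ++i) {
    const double a = g[ap[i] - 1];
    if (a == 0.0) continue;
    add_edge(r, taildiff, s[i], a, C, L, Ctail, T);
    add_edge(r, taildiff, e[i], -a, C, L, Ctail, T);
  }
  double acc = 0.0;
  for (int t = 0; t < T; ++t) {
    acc += taildiff[t];
    r[t] += acc;
  }
}

// downsample conv(p, hrf) to 1 s bins (mean within bin), one run.
// Gbar = conv(hrf, box(100))/100 precomputed at 10 ms resolution.
static void bold_run(const std::vector<double>& p, const double* Gbar, int LG,
                     int T, int n_sec, double* out) {
  for (int j = 0; j < n_sec; ++j) {
    const int base = j * 100 + 99;
    const int n = std::min(LG, base + 1);
    // 4 independent partial sums break the FP-add dependency chain
    double a0 = 0.0, a1 = 0.0, a2 = 0.0, a3 = 0.0;
    const double* pp = &p[base];
    int d = 0;
    for (; d + 3 < n; d += 4) {
      a0 += Gbar[d] * pp[-d];
      a1 += Gbar[d + 1] * pp[-d - 1];
      a2 += Gbar[d + 2] * pp[-d - 2];
      a3 += Gbar[d + 3] * pp[-d - 3];
    }
    for (; d < n; ++d) a0 += Gbar[d] * pp[-d];
    out[j] = (a0 + a1) + (a2 + a3);
  }
}

static void demean(double* x, int n) {
  double m = 0.0;
  for (int i = 0; i < n; ++i) m += x[i];
  m /= n;
  for (int i = 0; i < n; ++i) x[i] -= m;
}

// run-block bookkeeping shared by the exported entry points -----------------

struct RunIdx {
  std::vector<int> first, count;  // per-run offsets into the interval table
};

static RunIdx index_runs(const IntegerVector& iv_run, int n_runs) {
  RunIdx ri;
  ri.first.assign(n_runs, 0);
  ri.count.assign(n_runs, 0);
  for (int i = 0; i < iv_run.size(); ++i) ri.count[iv_run[i] - 1]++;
  for (int r = 1; r < n_runs; ++r)
    ri.first[r] = ri.first[r - 1] + ri.count[r - 1];
  return ri;  // assumes the interval table is sorted by run (enforced in R)
}

// CST: sustained channel relu(r1)^n and combined transient |r2|^n
// (relu(r2)^n + relu(-r2)^n collapses to |r2|^n pointwise since the on- and
// off-lobes of a biphasic response never overlap in time).
// [[Rcpp::export]]
NumericMatrix cpp_bold_cst(IntegerVector iv_run, IntegerVector iv_s,
                           IntegerVector iv_e, IntegerVector iv_ap,
                           NumericVector g, int n_runs, int T_run,
                           NumericVector C1, double C1tail, NumericVector C2,
                           double C2tail, double nexp, NumericVector Gbar,
                           bool demean_runs) {
  const int n_sec = T_run / 100;
  NumericMatrix out(n_runs * n_sec, 2);
  RunIdx ri = index_runs(iv_run, n_runs);
  std::vector<double> r1(T_run), r2(T_run), p(T_run);
  std::vector<double> bold(n_sec);
  for (int r = 0; r < n_runs; ++r) {
    const int f = ri.first[r], c = ri.count[r];
    conv_run(r1, iv_s, iv_e, iv_ap, f, c, &g[0], &C1[0], C1.size(),
             C1tail, T_run);
    conv_run(r2, iv_s, iv_e, iv_ap, f, c, &g[0], &C2[0], C2.size(),
             C2tail, T_run);
    // sustained
    for (int t = 0; t < T_run; ++t) {
      const double v = r1[t];
      p[t] = (v <= 0.0) ? 0.0 : (nexp == 1.0 ? v : std::pow(v, nexp));
    }
    bold_run(p, &Gbar[0], Gbar.size(), T_run, n_sec, &bold[0]);
    if (demean_runs) demean(&bold[0], n_sec);
    for (int j = 0; j < n_sec; ++j) out(r * n_sec + j, 0) = bold[j];
    // transient (on + off combined)
    for (int t = 0; t < T_run; ++t) {
      const double v = std::fabs(r2[t]);
      p[t] = (v == 0.0) ? 0.0 : (nexp == 1.0 ? v : std::pow(v, nexp));
    }
    bold_run(p, &Gbar[0], Gbar.size(), T_run, n_sec, &bold[0]);
    if (demean_runs) demean(&bold[0], n_sec);
    for (int j = 0; j < n_sec; ++j) out(r * n_sec + j, 1) = bold[j];
  }
  return out;
}

// DN-ST: p = r^n / (sigma^n + (r (*) exp-decay)^n), r = drive (*) gamma(2)
// [[Rcpp::export]]
NumericMatrix cpp_bold_dnst(IntegerVector iv_run, IntegerVector iv_s,
                            IntegerVector iv_e, IntegerVector iv_ap,
                            NumericVector g, int n_runs, int T_run,
                            NumericVector C1, double C1tail, double lambda2,
                            double nexp, double sigma_dn, NumericVector Gbar,
                            bool demean_runs) {
  const int n_sec = T_run / 100;
  NumericMatrix out(n_runs * n_sec, 1);
  RunIdx ri = index_runs(iv_run, n_runs);
  std::vector<double> r(T_run), p(T_run);
  std::vector<double> bold(n_sec);
  const double sn = std::pow(sigma_dn, nexp);
  for (int rr = 0; rr < n_runs; ++rr) {
    const int f = ri.first[rr], c = ri.count[rr];
    conv_run(r, iv_s, iv_e, iv_ap, f, c, &g[0], &C1[0], C1.size(),
             C1tail, T_run);
    double y = 0.0;  // exp-decay low-pass (unit-sum geometric kernel), IIR
    for (int t = 0; t < T_run; ++t) {
      const double v = std::fabs(r[t]);
      y = lambda2 * y + (1.0 - lambda2) * v;
      const double num = (v == 0.0) ? 0.0 : std::pow(v, nexp);
      p[t] = num / (sn + std::pow(y, nexp));
    }
    bold_run(p, &Gbar[0], Gbar.size(), T_run, n_sec, &bold[0]);
    if (demean_runs) demean(&bold[0], n_sec);
    for (int j = 0; j < n_sec; ++j) out(rr * n_sec + j, 0) = bold[j];
  }
  return out;
}

// neural-stage outputs at 10 ms for one set of runs (module-level API; the
// solver uses the fused cpp_bold_* paths instead).
// [[Rcpp::export]]
NumericMatrix cpp_neural_cst(IntegerVector iv_run, IntegerVector iv_s,
                             IntegerVector iv_e, IntegerVector iv_ap,
                             NumericVector g, int n_runs, int T_run,
                             NumericVector C1, double C1tail, NumericVector C2,
                             double C2tail, double nexp) {
  NumericMatrix out(n_runs * T_run, 3);
  RunIdx ri = index_runs(iv_run, n_runs);
  std::vector<double> r1(T_run), r2(T_run);
  for (int r = 0; r < n_runs; ++r) {
    const int f = ri.first[r], c = ri.count[r];
    conv_run(r1, iv_s, iv_e, iv_ap, f, c, &g[0], &C1[0], C1.size(),
             C1tail, T_run);
    conv_run(r2, iv_s, iv_e, iv_ap, f, c, &g[0], &C2[0], C2.size(),
             C2tail, T_run);
    for (int t = 0; t < T_run; ++t) {
      const int row = r * T_run + t;
      double v = r1[t];
      out(row, 0) = (v <= 0.0) ? 0.0 : std::pow(v, nexp);
      v = r2[t];
      out(row, 1) = (v <= 0.0) ? 0.0 : std::pow(v, nexp);
      out(row, 2) = (v >= 0.0) ? 0.0 : std::pow(-v, nexp);
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_neural_dnst(IntegerVector iv_run, IntegerVector iv_s,
                              IntegerVector iv_e, IntegerVector iv_ap,
                              NumericVector g, int n_runs, int T_run,
                              NumericVector C1, double C1tail, double lambda2,
                              double nexp, double sigma_dn) {
  NumericMatrix out(n_runs * T_run, 1);
  RunIdx ri = index_runs(iv_run, n_runs);
  std::vector<double> r(T_run);
  const double sn = std::pow(sigma_dn, nexp);
  for (int rr = 0; rr < n_runs; ++rr) {
    const int f = ri.first[rr], c = ri.count[rr];
    conv_run(r, iv_s, iv_e, iv_ap, f, c, &g[0], &C1[0], C1.size(),
             C1tail, T_run);
    double y = 0.0;
    for (int t = 0; t < T_run; ++t) {
      const double v = std::fabs(r[t]);
      y = lambda2 * y + (1.0 - lambda2) * v;
      const double num = (v == 0.0) ? 0.0 : std::pow(v, nexp);
      out(rr * T_run + t, 0) = num / (sn + std::pow(y, nexp));
    }
  }
  return out;
}

// HRF-convolve an arbitrary neural series (10 ms) and average into 1 s bins,
// run by run (no bleed across run boundaries).
// [[Rcpp::export]]
NumericVector cpp_bold_from_neural(NumericVector p, NumericVector Gbar,
                                   int n_runs, int T_run, bool demean_runs) {
  const int n_sec = T_run / 100;
  NumericVector out(n_runs * n_sec);
  std::vector<double> buf(T_run), bold(n_sec);
  for (int r = 0; r < n_runs; ++r) {
    for (int t = 0; t < T_run; ++t) buf[t] = p[r * T_run + t];
    bold_run(buf, &Gbar[0], Gbar.size(), T_run, n_sec, &bold[0]);
    if (demean_runs) demean(&bold[0], n_sec);
    for (int j = 0; j < n_sec; ++j) out[r * n_sec + j] = bold[j];
  }
  return out;
}

// step drive at 10 ms from the interval table (used by the Spatial model and
// by reference tests).
// [[Rcpp::export]]
NumericVector cpp_drive(IntegerVector iv_run, IntegerVector iv_s,
                        IntegerVector iv_e, IntegerVector iv_ap,
                        NumericVector g, int n_runs, int T_run) {
  NumericVector out(n_runs * T_run);
  RunIdx ri = index_runs(iv_run, n_runs);
  for (int r = 0; r < n_runs; ++r) {
    const int f = ri.first[r], c = ri.count[r];
    std::vector<double> diff(T_run + 1, 0.0);
    for (int i = f; i < f + c; ++i) {
      const double a = g[iv_ap[i] - 1];
      diff[iv_s[i]] += a;
      if (iv_e[i] < T_run) diff[iv_e[i]] -= a;
    }
    double acc = 0.0;
    for (int t = 0; t < T_run; ++t) {
      acc += diff[t];
      // cancellation residue from the running sum: the drive is exactly a
      // sum of current aperture overlaps, so snap near-zero to zero
      out[r * T_run + t] = (std::fabs(acc) < 1e-12) ? 0.0 : acc;
    }
  }
  return out;
}
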