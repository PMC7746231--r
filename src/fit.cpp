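#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Likelihood machinery for the prototype / exemplar choice models.
//
// Parameters are optimized in an unconstrained space theta = (z1..z7, zc):
//   w = softmax(z1..z7, 0)        -- 8 attention weights on the simplex
//   c = 100 * plogis(zc)          -- sensitivity in (0, 100)
// Trials are collapsed to unique stimuli: the likelihood only depends on the
// per-stimulus counts of A and B responses.

static const double SIM_FLOOR = 1e-300;

struct FitData {
  int n_u;                 // unique stimuli
  int k_a, k_b;            // exemplars per category
  const double *mA, *mB;   // n_u x 8 mismatch to prototypes (column-major)
  const double *exA, *exB; // n_u x (8*k) mismatch blocks per exemplar
  std::vector<double> nA, nB; // response counts per unique stimulus
  int kind;                // 0 = prototype, 1 = exemplar
  double eps;
};

static void theta_to_wc(const double *theta, double *w, double *c_out) {
  double z[8];
  for (int i = 0; i < 7; ++i) z[i] = theta[i];
  z[7] = 0.0;
  double zmax = z[0];
  for (int i = 1; i < 8; ++i) if (z[i] > zmax) zmax = z[i];
  double s = 0.0;
  for (int i = 0; i < 8; ++i) { w[i] = std::exp(z[i] - zmax); s += w[i]; }
  for (int i = 0; i < 8; ++i) w[i] /= s;
  *c_out = 100.0 / (1.0 + std::exp(-theta[7]));
}

// summed similarity of unique stimulus u to one category's exemplar block
static inline double exem_sum(const double *ex, int n_u, int k, int u,
                              const double *w, double c) {
  double s = 0.0;
  for (int e = 0; e < k; ++e) {
    const double *blk = ex + (size_t)e * 8 * n_u;
    double d = 0.0;
    for (int i = 0; i < 8; ++i) d += w[i] * blk[(size_t)i * n_u + u];
    s += std::exp(-c * d);
  }
  return s;
}

static double nll_eval(const double *theta, const FitData &fd) {
  double w[8], c;
  theta_to_wc(theta, w, &c);
  double nll = 0.0;
  for (int u = 0; u < fd.n_u; ++u) {
    if (fd.nA[u] == 0.0 && fd.nB[u] == 0.0) continue;
    double sA, sB;
    if (fd.kind == 0) {
      double dA = 0.0, dB = 0.0;
      for (int i = 0; i < 8; ++i) {
        dA += w[i] * fd.mA[(size_t)i * fd.n_u + u];
        dB += w[i] * fd.mB[(size_t)i * fd.n_u + u];
      }
      sA = std::exp(-c * dA);
      sB = std::exp(-c * dB);
    } else {
      sA = exem_sum(fd.exA, fd.n_u, fd.k_a, u, w, c);
      sB = exem_sum(fd.exB, fd.n_u, fd.k_b, u, w, c);
    }
    if (sA < SIM_FLOOR) sA = SIM_FLOOR;
    if (sB < SIM_FLOOR) sB = SIM_FLOOR;
    double p = sA / (sA + sB);
    if (p < fd.eps) p = fd.eps;
    if (p > 1.0 - fd.eps) p = 1.0 - fd.eps;
    nll -= fd.nA[u] * std::log(p) + fd.nB[u] * std::log(1.0 - p);
  }
  return nll;
}

// Nelder-Mead simplex minimization (reflection 1, expansion 2, contraction
// 0.5, shrink 0.5), optim-style relative convergence test on the function
// spread. Returns number of evaluations; sets *converged.
static int nelder_mead(std::vector<double> &x, double &fx, const FitData &fd,
                       int maxit, double reltol, bool *converged) {
  const int n = (int)x.size();
  const double alpha = 1.0, gamma = 2.0, rho = 0.5, sigma = 0.5;
  std::vector<std::vector<double> > pts(n + 1, x);
  std::vector<double> fv(n + 1);
  for (int j = 0; j < n; ++j) {
    double step = std::max(0.25, 0.1 * std::fabs(x[j]));
    pts[j + 1][j] += step;
  }
  int neval = 0;
  for (int j = 0; j <= n; ++j) { fv[j] = nll_eval(pts[j].data(), fd); ++neval; }
  std::vector<int> ord(n + 1);
  std::vector<double> xc(n), xr(n), xe(n), xk(n);
  *converged = false;
  int it = 0;
  while (neval < maxit) {
    for (int j = 0; j <= n; ++j) ord[j] = j;
    std::sort(ord.begin(), ord.end(),
              [&fv](int a, int b) { return fv[a] < fv[b]; });
    int lo = ord[0], hi = ord[n], nh = ord[n - 1];
    if (fv[hi] - fv[lo] <= reltol * (std::fabs(fv[lo]) + reltol)) {
      *converged = true;
      break;
    }
    // centroid of all but worst
    for (int j = 0; j < n; ++j) xc[j] = 0.0;
    for (int j = 0; j <= n; ++j) {
      if (j == hi) continue;
      for (int d = 0; d < n; ++d) xc[d] += pts[j][d];
    }
    for (int d = 0; d < n; ++d) xc[d] /= n;
    for (int d = 0; d < n; ++d) xr[d] = xc[d] + alpha * (xc[d] - pts[hi][d]);
    double fr = nll_eval(xr.data(), fd); ++neval;
    if (fr < fv[lo]) {
      for (int d = 0; d < n; ++d) xe[d] = xc[d] + gamma * (xr[d] - xc[d]);
      double fe = nll_eval(xe.data(), fd); ++neval;
      if (fe < fr) { pts[hi] = xe; fv[hi] = fe; }
      else { pts[hi] = xr; fv[hi] = fr; }
    } else if (fr < fv[nh]) {
      pts[hi] = xr; fv[hi] = fr;
    } else {
      // contraction (outside if reflected better than worst, else inside)
      bool outside = fr < fv[hi];
      const std::vector<double> &ref = outside ? xr : pts[hi];
      double fref = outside ? fr : fv[hi];
      for (int d = 0; d < n; ++d) xk[d] = xc[d] + rho * (ref[d] - xc[d]);
      double fk = nll_eval(xk.data(), fd); ++neval;
      if (fk < fref) { pts[hi] = xk; fv[hi] = fk; }
      else {
        for (int j = 0; j <= n; ++j) {
          if (j == lo) continue;
          for (int d = 0; d < n; ++d)
            pts[j][d] = pts[lo][d] + sigma * (pts[j][d] - pts[lo][d]);
          fv[j] = nll_eval(pts[j].data(), fd); ++neval;
        }
      }
    }
    ++it;
  }
  int best = 0;
  for (int j = 1; j <= n; ++j) if (fv[j] < fv[best]) best = j;
  x = pts[best];
  fx = fv[best];
  return neval;
}

static FitData make_fit_data(const NumericMatrix &mA, const NumericMatrix &mB,
                             const NumericMatrix &exA, const NumericMatrix &exB,
                             const IntegerVector &stim_idx,
                             const LogicalVector &resp_a, int kind, double eps) {
  FitData fd;
  fd.n_u = mA.nrow();
  fd.k_a = exA.ncol() / 8;
  fd.k_b = exB.ncol() / 8;
  fd.mA = mA.begin();
  fd.mB = mB.begin();
  fd.exA = exA.begin();
  fd.exB = exB.begin();
  fd.kind = kind;
  fd.eps = eps;
  fd.nA.assign(fd.n_u, 0.0);
  fd.nB.assign(fd.n_u, 0.0);
  for (int t = 0; t < stim_idx.size(); ++t) {
    int u = stim_idx[t];
    if (resp_a[t]) fd.nA[u] += 1.0; else fd.nB[u] += 1.0;
  }
  return fd;
}

// [[Rcpp::export]]
List cpp_fit_model(NumericMatrix mA, NumericMatrix mB, NumericMatrix exA,
                   NumericMatrix exB, IntegerVector stim_idx,
                   LogicalVector resp_a, int kind, NumericMatrix starts,
                   int maxit, double reltol, double eps) {
  FitData fd = make_fit_data(mA, mB, exA, exB, stim_idx, resp_a, kind, eps);
  const int n_starts = starts.nrow(), npar = starts.ncol();
  NumericVector start_nll(n_starts), init_nll(n_starts);
  LogicalVector conv(n_starts);
  IntegerVector fevals(n_starts);
  std::vector<double> best_x(npar);
  double best_f = R_PosInf;
  for (int s = 0; s < n_starts; ++s) {
    std::vector<double> x(npar);
    for (int j = 0; j < npar; ++j) x[j] = starts(s, j);
    init_nll[s] = nll_eval(x.data(), fd);
    double fx;
    bool cv;
    fevals[s] = nelder_mead(x, fx, fd, maxit, reltol, &cv);
    start_nll[s] = fx;
    conv[s] = cv;
    if (fx < best_f) { best_f = fx; best_x = x; }
  }
  return List::create(_["par"] = NumericVector(best_x.begin(), best_x.end()),
                      _["value"] = best_f, _["start_nll"] = start_nll,
                      _["init_nll"] = init_nll, _["converged"] = conv,
                      _["fevals"] = fevals);
}

// [[Rcpp::export]]
double cpp_nll_theta(NumericVector theta, NumericMatrix mA, NumericMatrix mB,
                     NumericMatrix exA, NumericMatrix exB,
                     IntegerVector stim_idx, LogicalVector resp_a, int kind,
                     double eps) {
  FitData fd = make_fit_data(mA, mB, exA, exB, stim_idx, resp_a, kind, eps);
  return nll_eval(REAL(theta), fd);
}
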