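#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Explicit-Euler Gray-Scott stepper on a periodic cubic grid with
// second-order central (7-point) Laplacians. Saved frames are deep copies
// taken after the step counts listed in save_steps (0 = initial state).
// [[Rcpp::export]]
List cpp_gray_scott(NumericVector u0, NumericVector v0, int n,
                    double Du, double Dv, double f, double k,
                    double dt, double dx, int nsteps,
                    IntegerVector save_steps) {
  const R_xlen_t ncell = (R_xlen_t)n * n * n;
  if (u0.size() != ncell || v0.size() != ncell)
    stop("initial fields must have n^3 entries");
  std::vector<double> u(u0.begin(), u0.end());
  std::vector<double> v(v0.begin(), v0.end());
  std::vector<double> un(ncell), vn(ncell);
  std::vector<int> ip(n), im(n);
  for (int i = 0; i < n; ++i) {
    ip[i] = (i + 1) % n;
    im[i] = (i + n - 1) % n;
  }
  const double idx2 = 1.0 / (dx * dx);

  List out_u(save_steps.size()), out_v(save_steps.size());
  int save_pos = 0;
  auto save_if_due = [&](int step) {
    while (save_pos < save_steps.size() && save_steps[save_pos] == step) {
      out_u[save_pos] = NumericVector(u.begin(), u.end());
      out_v[save_pos] = NumericVector(v.begin(), v.end());
      ++save_pos;
    }
  };
  save_if_due(0);

  const R_xlen_t sy = n, sz = (R_xlen_t)n * n;
  for (int step = 1; step <= nsteps; ++step) {
    for (int kk = 0; kk < n; ++kk) {
      const R_xlen_t zo = (R_xlen_t)kk * sz;
      const R_xlen_t zp = (R_xlen_t)ip[kk] * sz, zm = (R_xlen_t)im[kk] * sz;
      for (int j = 0; j < n; ++j) {
        const R_xlen_t yo = (R_xlen_t)j * sy;
        const R_xlen_t yp = (R_xlen_t)ip[j] * sy, ym = (R_xlen_t)im[j] * sy;
        for (int i = 0; i < n; ++i) {
          const R_xlen_t c = zo + yo + i;
          const double uc = u[c], vc = v[c];
          const double lap_u =
            (u[zo + yo + ip[i]] + u[zo + yo + im[i]] +
             u[zo + yp + i] + u[zo + ym + i] +
             u[zp + yo + i] + u[zm + yo + i] - 6.0 * uc) * idx2;
          const double lap_v =
            (v[zo + yo + ip[i]] + v[zo + yo + im[i]] +
             v[zo + yp + i] + v[zo + ym + i] +
             v[zp + yo + i] + v[zm + yo + i] - 6.0 * vc) * idx2;
          const double uvv = uc * vc * vc;
          un[c] = uc + dt * (Du * lap_u - uvv + f * (1.0 - uc));
          vn[c] = vc + dt * (Dv * lap_v + uvv - (f + k) * vc);
        }
      }
    }
    u.swap(un);
    v.swap(vn);
    if (step % 500 == 0) {
      // blow-up check, cheap single-cell probe plus full scan at checkpoints
      bool bad = false;
      for (R_xlen_t c = 0; c < ncell; ++c)
        if (!std::isfinite(u[c]) || !std::isfinite(v[c])) { bad = true; break; }
      if (bad) stop("Gray-Scott integration became non-finite (unstable configuration)");
    }
    save_if_due(step);
  }
  return List::create(_["u"] = out_u, _["v"] = out_v);
}
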