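#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Event-driven Bloch simulation over a particle ensemble.
//
// ops: one row per primitive operation, columns
//   0 code (1 evolve, 2 rf substep, 3 sample, 4 spoil)
//   1 dt    step duration, seconds (evolve/rf advance time by dt)
//   2-4     Gx, Gy, Gz gradient amplitude, T/m (evolve only)
//   5 angle rf sub-rotation angle, rad (rf only)
//   6-7     zmin, zmax slab bounds, mm (rf only)
//   8 out   1-based sample slot (sample only)
//
// Particles move along pre-tabulated streamlines resampled uniformly in
// time (linear interpolation); sl < 0 marks a static particle at
// static_pos.  Gradient phase uses the particle position at the midpoint of
// each evolve step, which integrates the gradient first moment exactly for
// constant-velocity motion.  A particle whose trajectory time wraps past
// the streamline end is recycled with fresh equilibrium magnetization.

// [[Rcpp::export]]
ComplexVector pca_kernel(NumericMatrix ops,
                         IntegerVector sl,          // 0-based, -1 static
                         NumericVector tau0,        // s
                         NumericMatrix static_pos,  // mm
                         NumericMatrix M_init,
                         double M0, double T1_ms, double T2_ms,
                         NumericMatrix sl_pos,      // concatenated tables, mm
                         IntegerVector sl_offset,   // 0-based row offsets
                         IntegerVector sl_n,
                         NumericVector sl_dt,       // s
                         NumericVector sl_T,        // s
                         double gamma_rad,          // rad / s / T
                         int n_samples) {
  const int np = sl.size();
  const double T1 = T1_ms * 1e-3, T2 = T2_ms * 1e-3;
  std::vector<double> Mx(np), My(np), Mz(np);
  std::vector<double> t_next(np);           // absolute time of next recycle
  for (int p = 0; p < np; ++p) {
    Mx[p] = M_init(p, 0); My[p] = M_init(p, 1); Mz[p] = M_init(p, 2);
    t_next[p] = (sl[p] < 0) ? R_PosInf : sl_T[sl[p]] - tau0[p];
  }
  ComplexVector out(n_samples);
  for (int k = 0; k < n_samples; ++k) { out[k].r = 0.0; out[k].i = 0.0; }

  double t = 0.0;

  const double *PX = REAL(sl_pos);
  const int nrow_pos = sl_pos.nrow();
  const double *SX = REAL(static_pos);
  const int nrow_st = static_pos.nrow();

  auto position = [&](int p, double tt, double &x, double &y, double &z) {
    const int j = sl[p];
    if (j < 0) {
      x = SX[p]; y = SX[p + nrow_st]; z = SX[p + 2 * nrow_st];
      return;
    }
    const double a = tau0[p] + tt;
    double u = a - std::floor(a / sl_T[j]) * sl_T[j];
    double fi = u / sl_dt[j];
    int i0 = (int)fi;
    if (i0 > sl_n[j] - 2) i0 = sl_n[j] - 2;
    const double w = fi - i0;
    const int r0 = sl_offset[j] + i0;
    x = PX[r0] * (1 - w) + PX[r0 + 1] * w;
    y = PX[r0 + nrow_pos] * (1 - w) + PX[r0 + 1 + nrow_pos] * w;
    z = PX[r0 + 2 * nrow_pos] * (1 - w) + PX[r0 + 1 + 2 * nrow_pos] * w;
  };

  const int nops = ops.nrow();
  for (int op = 0; op < nops; ++op) {
    const int code = (int)ops(op, 0);
    const double dt = ops(op, 1);
    if (code == 1) {                      // evolve: relax + gradient phase
      const double e2 = std::exp(-dt / T2);
      const double e1 = std::exp(-dt / T1);
      const double rec = M0 * (1 - e1);
      const double Gx = ops(op, 2), Gy = ops(op, 3), Gz = ops(op, 4);
      const bool grad = (Gx != 0.0 || Gy != 0.0 || Gz != 0.0);
      const double tm = t + dt / 2;
      for (int p = 0; p < np; ++p) {
        double mx = Mx[p], my = My[p];
        // particles with exactly zero transverse magnetization (spoiled or
        // never excited) neither decay nor precess: skip the trigonometry
        if (mx != 0.0 || my != 0.0) {
          mx *= e2; my *= e2;
          if (grad) {
            double x, y, z;
            position(p, tm, x, y, z);
            // positions are mm; 1e-3 converts to meters
            const double th = gamma_rad * (Gx * x + Gy * y + Gz * z) * 1e-3 * dt;
            const double c = std::cos(th), s = std::sin(th);
            const double nx = c * mx - s * my;
            my = s * mx + c * my;
            mx = nx;
          }
          Mx[p] = mx; My[p] = my;
        }
        Mz[p] = Mz[p] * e1 + rec;
      }
      t += dt;
      // recycle particles whose trajectory wrapped during this step
      for (int p = 0; p < np; ++p) {
        if (t >= t_next[p]) {
          Mx[p] = 0.0; My[p] = 0.0; Mz[p] = M0;
          do { t_next[p] += sl_T[sl[p]]; } while (t >= t_next[p]);
        }
      }
    } else if (code == 2) {               // rf substep (no relaxation)
      const double a = ops(op, 5);
      const double zmin = ops(op, 6), zmax = ops(op, 7);
      const double ca = std::cos(a), sa = std::sin(a);
      const double tm = t + dt / 2;
      for (int p = 0; p < np; ++p) {
        double x, y, z;
        position(p, tm, x, y, z);
        if (z < zmin || z > zmax) continue;
        const double ny = ca * My[p] + sa * Mz[p];
        Mz[p] = -sa * My[p] + ca * Mz[p];
        My[p] = ny;
      }
      t += dt;
    } else if (code == 3) {               // sample: sum of transverse M
      const int idx = (int)ops(op, 8) - 1;
      if (idx >= 0 && idx < n_samples) {
        double sr = 0.0, si = 0.0;
        for (int p = 0; p < np; ++p) { sr += Mx[p]; si += My[p]; }
        out[idx].r = sr; out[idx].i = si;
      }
    } else if (code == 4) {               // spoil transverse magnetization
      for (int p = 0; p < np; ++p) { Mx[p] = 0.0; My[p] = 0.0; }
    }
  }
  return out;
}
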