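#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

// 2D linear acoustic propagation in heterogeneous (c, rho) media.
//
// First-order pressure-velocity system on a staggered grid, leapfrog in
// time.  Pressure lives at cell centers (nz x nx); particle velocities live
// on cell faces (vz between rows, vx between columns).  Density at faces is
// the arithmetic average of the two neighboring cells.  Absorbing
// boundaries are an exponentially tapered sponge applied multiplicatively
// to p, vx, vz each step (separable row/column taper).
//
// Field arrays are single precision: the stencil is memory-bandwidth
// bound and the ~1e-7 relative rounding floor sits far below every
// acoustic quantity of interest; coefficients are precomputed in double
// and stored as float.
//
// Sources inject pressure additively (soft source); receivers record the
// mean pressure over the pixels belonging to each element at every step.
//
// [[Rcpp::export]]
NumericMatrix fdtd_run_cpp(NumericMatrix cmap, NumericMatrix rhomap,
                           double dx, double dt, int nsteps,
                           IntegerVector src_idx, IntegerVector src_elem,
                           NumericMatrix src_wave,
                           IntegerVector rec_idx, IntegerVector rec_elem,
                           int n_elements,
                           NumericVector taper_row, NumericVector taper_col) {
  const int nz = cmap.nrow(), nx = cmap.ncol();
  if (rhomap.nrow() != nz || rhomap.ncol() != nx)
    stop("c and rho grids differ in shape");
  if (taper_row.size() != nz || taper_col.size() != nx)
    stop("taper length mismatch");

  std::vector<float> p((size_t)nz * nx, 0.0f);
  std::vector<float> vz((size_t)(nz - 1) * nx, 0.0f);
  std::vector<float> vx((size_t)nz * (nx - 1), 0.0f);

  // precomputed coefficients
  std::vector<float> kdt((size_t)nz * nx);        // rho c^2 dt/dx
  std::vector<float> bz((size_t)(nz - 1) * nx);   // dt/dx / rho at z-faces
  std::vector<float> bx((size_t)nz * (nx - 1));   // dt/dx / rho at x-faces
  const double *cm = cmap.begin(), *rm = rhomap.begin();
  for (int j = 0; j < nx; ++j)
    for (int i = 0; i < nz; ++i) {
      size_t k = (size_t)j * nz + i;
      kdt[k] = (float)(rm[k] * cm[k] * cm[k] * dt / dx);
    }
  for (int j = 0; j < nx; ++j)
    for (int i = 0; i < nz - 1; ++i) {
      double rh = 0.5 * (rm[(size_t)j * nz + i] + rm[(size_t)j * nz + i + 1]);
      bz[(size_t)j * (nz - 1) + i] = (float)(dt / (dx * rh));
    }
  for (int j = 0; j < nx - 1; ++j)
    for (int i = 0; i < nz; ++i) {
      double rh = 0.5 * (rm[(size_t)j * nz + i] + rm[(size_t)(j + 1) * nz + i]);
      bx[(size_t)j * nz + i] = (float)(dt / (dx * rh));
    }

  std::vector<float> tr(nz), tc(nx);
  for (int i = 0; i < nz; ++i) tr[i] = (float)taper_row[i];
  for (int j = 0; j < nx; ++j) tc[j] = (float)taper_col[j];
  // rows/cols inside the taper bands (value < 1); interior skips damping
  int row_lo = 0, row_hi = nz - 1, col_lo = 0, col_hi = nx - 1;
  while (row_lo < nz && tr[row_lo] < 1.0f) ++row_lo;
  while (row_hi >= 0 && tr[row_hi] < 1.0f) --row_hi;
  while (col_lo < nx && tc[col_lo] < 1.0f) ++col_lo;
  while (col_hi >= 0 && tc[col_hi] < 1.0f) --col_hi;

  const int nsrc = src_idx.size(), nrec = rec_idx.size();
  std::vector<int> rec_count(n_elements, 0);
  for (int r = 0; r < nrec; ++r) rec_count[rec_elem[r]]++;

  NumericMatrix rec(nsteps, n_elements);

  for (int t = 0; t < nsteps; ++t) {
    // velocity update: v -= dt/rho grad p
    for (int j = 0; j < nx; ++j) {
      float *__restrict vzc = &vz[(size_t)j * (nz - 1)];
      const float *__restrict pc = &p[(size_t)j * nz];
      const float *__restrict bzc = &bz[(size_t)j * (nz - 1)];
      for (int i = 0; i < nz - 1; ++i)
        vzc[i] -= bzc[i] * (pc[i + 1] - pc[i]);
    }
    for (int j = 0; j < nx - 1; ++j) {
      float *__restrict vxc = &vx[(size_t)j * nz];
      const float *__restrict pc = &p[(size_t)j * nz];
      const float *__restrict pn = &p[(size_t)(j + 1) * nz];
      const float *__restrict bxc = &bx[(size_t)j * nz];
      for (int i = 0; i < nz; ++i)
        vxc[i] -= bxc[i] * (pn[i] - pc[i]);
    }
    // pressure update: p -= rho c^2 dt div v
    for (int j = 0; j < nx; ++j) {
      float *__restrict pc = &p[(size_t)j * nz];
      const float *__restrict kc = &kdt[(size_t)j * nz];
      const float *__restrict vzc = &vz[(size_t)j * (nz - 1)];
      const float *__restrict vxl = (j > 0) ? &vx[(size_t)(j - 1) * nz] : 0;
      const float *__restrict vxr = (j < nx - 1) ? &vx[(size_t)j * nz] : 0;
      if (vxl && vxr) {
        pc[0] -= kc[0] * (vzc[0] + vxr[0] - vxl[0]);
        for (int i = 1; i < nz - 1; ++i)
          pc[i] -= kc[i] * (vzc[i] - vzc[i - 1] + vxr[i] - vxl[i]);
        pc[nz - 1] -= kc[nz - 1] * (-vzc[nz - 2] + vxr[nz - 1] - vxl[nz - 1]);
      } else {
        for (int i = 0; i < nz; ++i) {
          float div = 0.0f;
          if (i < nz - 1) div += vzc[i];
          if (i > 0) div -= vzc[i - 1];
          if (vxr) div += vxr[i];
          if (vxl) div -= vxl[i];
          pc[i] -= kc[i] * div;
        }
      }
    }
    // soft pressure sources
    for (int s = 0; s < nsrc; ++s)
      p[src_idx[s]] += (float)src_wave(t, src_elem[s]);
    // sponge taper
    for (int j = 0; j < nx; ++j) {
      float tcj = tc[j];
      float *__restrict pc = &p[(size_t)j * nz];
      float *__restrict vzc = &vz[(size_t)j * (nz - 1)];
      if (tcj < 1.0f) {
        for (int i = 0; i < nz; ++i) pc[i] *= tcj * tr[i];
        for (int i = 0; i < nz - 1; ++i) vzc[i] *= tcj * tr[i];
      } else {
        for (int i = 0; i < row_lo; ++i) pc[i] *= tr[i];
        for (int i = row_hi + 1; i < nz; ++i) pc[i] *= tr[i];
        for (int i = 0; i < std::min(row_lo, nz - 1); ++i) vzc[i] *= tr[i];
        for (int i = row_hi + 1; i < nz - 1; ++i) vzc[i] *= tr[i];
      }
    }
    for (int j = 0; j < nx - 1; ++j) {
      float tcj = 0.5f * (tc[j] + tc[j + 1]);
      float *__restrict vxc = &vx[(size_t)j * nz];
      if (tcj < 1.0f) {
        for (int i = 0; i < nz; ++i) vxc[i] *= tcj * tr[i];
      } else {
        for (int i = 0; i < row_lo; ++i) vxc[i] *= tr[i];
        for (int i = row_hi + 1; i < nz; ++i) vxc[i] *= tr[i];
      }
    }
    // receivers: mean pressure over each element's pixels
    for (int r = 0; r < nrec; ++r)
      rec(t, rec_elem[r]) += p[rec_idx[r]];
    if ((t & 255) == 255) {
      float probe = p[(size_t)(nx / 2) * nz + nz / 2];
      if (!std::isfinite(probe))
        stop("numerical divergence (non-finite field) at step %d", t + 1);
      Rcpp::checkUserInterrupt();
    }
  }
  for (int e = 0; e < n_elements; ++e)
    if (rec_count[e] > 0)
      for (int t = 0; t < nsteps; ++t) rec(t, e) /= rec_count[e];
  return rec;
}
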