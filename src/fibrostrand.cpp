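#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Assign grid-element centers to the convex polygon containing them.
// Polygons are flattened CCW vertex lists; ties on shared edges go to the
// lowest cell id (polygons must be supplied in increasing cell-id order).
// Returns an nx x ny integer matrix of cell ids (0 = no cell).
// [[Rcpp::export(name = ".raster_assign")]]
IntegerMatrix raster_assign(int nx, int ny, double dx, double dy,
                            NumericVector px, NumericVector py,
                            IntegerVector off, IntegerVector cell_id) {
  const int np = off.size() - 1;
  // bin polygons by bounding box over a coarse grid of bins
  const int bx = std::max(1, nx / 16), by = std::max(1, ny / 2);
  const double wx = nx * dx / bx, wy = ny * dy / by;
  std::vector<std::vector<int>> bins((size_t)bx * by);
  for (int p = 0; p < np; ++p) {
    double x0 = R_PosInf, x1 = R_NegInf, y0 = R_PosInf, y1 = R_NegInf;
    for (int k = off[p]; k < off[p + 1]; ++k) {
      x0 = std::min(x0, px[k]); x1 = std::max(x1, px[k]);
      y0 = std::min(y0, py[k]); y1 = std::max(y1, py[k]);
    }
    int i0 = std::max(0, (int)std::floor(x0 / wx)), i1 = std::min(bx - 1, (int)std::floor(x1 / wx));
    int j0 = std::max(0, (int)std::floor(y0 / wy)), j1 = std::min(by - 1, (int)std::floor(y1 / wy));
    for (int i = i0; i <= i1; ++i)
      for (int j = j0; j <= j1; ++j)
        bins[(size_t)j * bx + i].push_back(p);
  }
  IntegerMatrix out(nx, ny);
  const double eps = 1e-7;
  for (int j = 0; j < ny; ++j) {
    double yc = (j + 0.5) * dy;
    int bj = std::min(by - 1, (int)std::floor(yc / wy));
    for (int i = 0; i < nx; ++i) {
      double xc = (i + 0.5) * dx;
      int bi = std::min(bx - 1, (int)std::floor(xc / wx));
      const std::vector<int> &cand = bins[(size_t)bj * bx + bi];
      int best = 0;
      for (size_t c = 0; c < cand.size(); ++c) {
        int p = cand[c];
        bool inside = true;
        int n = off[p + 1] - off[p];
        for (int e = 0; e < n && inside; ++e) {
          int a = off[p] + e, b = off[p] + (e + 1) % n;
          double cr = (px[b] - px[a]) * (yc - py[a]) - (py[b] - py[a]) * (xc - px[a]);
          if (cr < -eps) inside = false;
        }
        if (inside) { best = cell_id[p]; break; }
      }
      out(i, j) = best;
    }
  }
  return out;
}

static inline void tri_solve_lower(const int *Lp, const int *Li,
                                   const double *Lx, double *x, int n) {
  for (int j = 0; j < n; ++j) {
    double xj = x[j] / Lx[Lp[j]];
    x[j] = xj;
    for (int k = Lp[j] + 1; k < Lp[j + 1]; ++k) x[Li[k]] -= Lx[k] * xj;
  }
}

static inline void tri_solve_upper_t(const int *Lp, const int *Li,
                                     const double *Lx, double *x, int n) {
  // solves L^T x = b using the CSC structure of L (columns of L = rows of L^T)
  for (int j = n - 1; j >= 0; --j) {
    double s = x[j];
    for (int k = Lp[j] + 1; k < Lp[j + 1]; ++k) s -= Lx[k] * x[Li[k]];
    x[j] = s / Lx[Lp[j]];
  }
}

// Integrate the monodomain system over n_steps of size dt.
// Reaction (membrane currents + stimulus, Rush-Larsen gates, Euler Ca2+)
// then Crank-Nicolson diffusion via two triangular solves of the one-time
// Cholesky factor. Rate/current terms are linearly interpolated from
// lookup tables on a uniform V grid. Table columns:
//  0-5 yinf(m,h,j,d,f,x), 6-11 exp(-dt*(a+b)), 12 I_K1, 13 g_K*Xi*(V-E_K),
//  14 I_Kp term, 15 I_MFB.
// model: 0 = CMC membrane, 1 = MFB membrane (passive, no gates).
// [[Rcpp::export(name = ".run_chunk")]]
List run_chunk(int n_steps, double dt, double t0,
               IntegerVector Lp, IntegerVector Li, NumericVector Lx,
               IntegerVector perm0,
               IntegerVector M2p, IntegerVector M2i, NumericVector M2x,
               NumericVector V_in, NumericMatrix gates_in, NumericVector Ca_in,
               IntegerVector model,
               double vmin, double dv, NumericMatrix tab,
               NumericVector cmc_const, // g_na, e_na, g_si
               IntegerVector stim_nodes, double stim_amp,
               NumericVector stim_starts, double stim_dur,
               NumericVector act_in, NumericVector dvdt_in,
               IntegerVector probe_nodes, int probe_stride,
               double act_threshold) {
  const int n = V_in.size();
  NumericVector V = clone(V_in), Ca = clone(Ca_in);
  NumericMatrix gates = clone(gates_in);
  NumericVector act = clone(act_in), dvdt = clone(dvdt_in);
  const double g_na = cmc_const[0], e_na = cmc_const[1], g_si = cmc_const[2];
  const int nbin = tab.nrow();
  std::vector<double> b(n), y(n), vold(n);
  const int npr = probe_nodes.size();
  int nrec = (probe_stride > 0 && npr > 0) ? (n_steps - 1) / probe_stride + 2 : 0;
  NumericMatrix traces(nrec > 0 ? nrec : 0, npr);
  NumericVector trace_t(nrec > 0 ? nrec : 0);
  int rec_row = 0, clamped = 0;
  bool bad = false; double bad_t = NA_REAL; int bad_node = NA_INTEGER;

  std::vector<char> stim_mask(n, 0);
  for (int k = 0; k < stim_nodes.size(); ++k) stim_mask[stim_nodes[k]] = 1;

  for (int step = 0; step < n_steps && !bad; ++step) {
    double t = t0 + step * dt;
    if (nrec > 0 && step % probe_stride == 0 && rec_row < nrec) {
      for (int k = 0; k < npr; ++k) traces(rec_row, k) = V[probe_nodes[k]];
      trace_t[rec_row] = t;
      ++rec_row;
    }
    bool stim_on = false;
    for (int s = 0; s < stim_starts.size(); ++s)
      if (t >= stim_starts[s] - 1e-9 && t < stim_starts[s] + stim_dur - 1e-9) {
        stim_on = true; break;
      }
    // reaction
    for (int i = 0; i < n; ++i) {
      double v = V[i];
      if (!std::isfinite(v)) { bad = true; bad_t = t; bad_node = i + 1; break; }
      vold[i] = v;
      double pos = (v - vmin) / dv;
      if (pos < 0) { pos = 0; ++clamped; }
      if (pos > nbin - 1.000001) { pos = nbin - 1.000001; ++clamped; }
      int i0 = (int)pos;
      double f = pos - i0;
      double i_ion;
      if (model[i] == 0) {
        double m = gates(i, 0), h = gates(i, 1), jg = gates(i, 2),
               d = gates(i, 3), fg = gates(i, 4), x = gates(i, 5);
        double ik1 = tab(i0, 12) + f * (tab(i0 + 1, 12) - tab(i0, 12));
        double gkxi = tab(i0, 13) + f * (tab(i0 + 1, 13) - tab(i0, 13));
        double ikp = tab(i0, 14) + f * (tab(i0 + 1, 14) - tab(i0, 14));
        double esi = 7.7 - 13.0287 * std::log(Ca[i]);
        double i_si = g_si * d * fg * (v - esi);
        double i_na = g_na * m * m * m * h * jg * (v - e_na);
        i_ion = i_na + i_si + x * gkxi + ik1 + ikp;
        // gate updates with rates at the pre-step potential
        for (int g = 0; g < 6; ++g) {
          double yi = tab(i0, g) + f * (tab(i0 + 1, g) - tab(i0, g));
          double re = tab(i0, g + 6) + f * (tab(i0 + 1, g + 6) - tab(i0, g + 6));
          gates(i, g) = yi + (gates(i, g) - yi) * re;
        }
        Ca[i] += dt * (-1e-4 * i_si + 0.07 * (1e-4 - Ca[i]));
      } else {
        i_ion = tab(i0, 15) + f * (tab(i0 + 1, 15) - tab(i0, 15));
      }
      double stim = (stim_on && stim_mask[i]) ? stim_amp : 0.0;
      V[i] = v - dt * (i_ion + stim);
    }
    if (bad) break;
    // diffusion: solve (C + dt/2 Lap) v+ = (C - dt/2 Lap) v*
    for (int i = 0; i < n; ++i) b[i] = 0.0;
    for (int j = 0; j < n; ++j) {
      double vj = V[j];
      for (int k = M2p[j]; k < M2p[j + 1]; ++k) b[M2i[k]] += M2x[k] * vj;
    }
    for (int k = 0; k < n; ++k) y[k] = b[perm0[k]];
    tri_solve_lower(INTEGER(Lp), INTEGER(Li), REAL(Lx), y.data(), n);
    tri_solve_upper_t(INTEGER(Lp), INTEGER(Li), REAL(Lx), y.data(), n);
    for (int k = 0; k < n; ++k) V[perm0[k]] = y[k];
    // measurements
    double tnew = t + dt;
    for (int i = 0; i < n; ++i) {
      double dvi = (V[i] - vold[i]) / dt;
      if (dvi > dvdt[i]) dvdt[i] = dvi;
      if (ISNA(act[i]) && vold[i] < act_threshold && V[i] >= act_threshold) {
        double fr = (act_threshold - vold[i]) / (V[i] - vold[i]);
        act[i] = t + fr * dt;
      }
      if (!std::isfinite(V[i])) { bad = true; bad_t = tnew; bad_node = i + 1; }
    }
  }
  if (nrec > 0 && rec_row < nrec) {
    for (int k = 0; k < npr; ++k) traces(rec_row, k) = V[probe_nodes[k]];
    trace_t[rec_row] = t0 + n_steps * dt;
    ++rec_row;
  }
  if (bad) stop("non-finite membrane potential at t = %f ms (node %d)",
                bad_t, bad_node);
  return List::create(_["v"] = V, _["gates"] = gates, _["ca"] = Ca,
                      _["t"] = t0 + n_steps * dt,
                      _["act_time"] = act, _["dvdt_max"] = dvdt,
                      _["clamped"] = clamped,
                      _["trace_t"] = trace_t, _["traces"] = traces);
}
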