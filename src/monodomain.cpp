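#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Explicit monodomain stepper on a regular nx-by-ny grid (ny = 1 gives a 1D
// cable). Reaction: two-variable phenomenological ionic model with explicit
// APD restitution (fast inward / slow outward currents gated by a single
// recovery variable). Diffusion: 5-point Laplacian with harmonic-mean face
// diffusivities; scar nodes carry zero face diffusivity, which realises the
// no-flux condition at the scar interface exactly.
//
// State: v in [0, 1] (mapped to Vm in R), w in [0, 1].
//   dv/dt = w * v^2 (1 - v) / tau_in - v / tau_out + D lap(v) + I_stim
//   dw/dt = (1 - w) / tau_open   (v <  v_gate)
//         = -w / tau_close       (v >= v_gate)
// w is advanced with its exact per-branch exponential update.
//
// Threshold crossings of v (upward through v_up, downward through v_down)
// are recorded with linear interpolation in time for every node, so full-
// field activation/repolarization markers never require storing traces.

// [[Rcpp::export(name = ".cpp_monodomain")]]
List cpp_monodomain(int nx, int ny, double dx, double dt, int n_steps,
                    NumericVector D,          // per-node diffusivity, mm^2/ms (0 on scar)
                    IntegerVector is_scar,    // per-node 0/1
                    NumericVector tau_in, NumericVector tau_out,
                    NumericVector tau_open, NumericVector tau_close,
                    NumericVector v_gate,
                    IntegerVector stim_nodes,          // 0-based
                    NumericVector stim_onsets,         // ms
                    double stim_duration, double stim_amplitude,
                    IntegerVector record_nodes,        // 0-based
                    int record_every,                  // steps between samples
                    IntegerVector snapshot_steps,      // step indices (0-based)
                    double v_up, double v_down,
                    NumericVector v0,                  // initial v (length 0 => rest)
                    bool reaction_on)
{
  const int N = nx * ny;
  std::vector<double> v(N, 0.0), w(N, 1.0), vnew(N);
  if (v0.size() == N) for (int k = 0; k < N; ++k) v[k] = v0[k];

  // face diffusivities (harmonic mean)
  std::vector<double> Dx((size_t)(nx - 1) * ny, 0.0), Dy((size_t)nx * std::max(ny - 1, 0), 0.0);
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx - 1; ++i) {
      double a = D[j * nx + i], b = D[j * nx + i + 1];
      Dx[(size_t)j * (nx - 1) + i] = (a > 0 && b > 0) ? 2.0 * a * b / (a + b) : 0.0;
    }
  for (int j = 0; j < ny - 1; ++j)
    for (int i = 0; i < nx; ++i) {
      double a = D[j * nx + i], b = D[(j + 1) * nx + i];
      Dy[(size_t)j * nx + i] = (a > 0 && b > 0) ? 2.0 * a * b / (a + b) : 0.0;
    }

  // exact w-update factors
  std::vector<double> eo(N), ec(N);
  for (int k = 0; k < N; ++k) {
    eo[k] = std::exp(-dt / tau_open[k]);
    ec[k] = std::exp(-dt / tau_close[k]);
  }

  const double inv_dx2 = 1.0 / (dx * dx);

  // recording buffers
  const int n_rec = record_nodes.size();
  const int n_samples = (record_every > 0) ? (n_steps / record_every + 1) : 0;
  NumericMatrix traces(n_samples, n_rec);
  NumericVector trace_times(n_samples);
  int sample_idx = 0;

  const int n_snap = snapshot_steps.size();
  NumericMatrix snaps(n_snap > 0 ? N : 0, n_snap);
  NumericVector snap_times(n_snap);
  int snap_ptr = 0;

  // crossing records
  std::vector<int> up_node, dn_node;
  std::vector<double> up_time, dn_time;
  up_node.reserve(4 * N); dn_node.reserve(4 * N);
  up_time.reserve(4 * N); dn_time.reserve(4 * N);

  // sample initial state
  if (record_every > 0) {
    trace_times[0] = 0.0;
    for (int r = 0; r < n_rec; ++r) traces(0, r) = v[record_nodes[r]];
    sample_idx = 1;
  }

  const int n_stim = stim_onsets.size();
  const int n_stim_nodes = stim_nodes.size();

  for (int step = 0; step < n_steps; ++step) {
    const double t = step * dt;

    // stimulus active?
    double stim_now = 0.0;
    for (int s = 0; s < n_stim; ++s)
      if (t >= stim_onsets[s] && t < stim_onsets[s] + stim_duration) { stim_now = stim_amplitude; break; }

    for (int j = 0; j < ny; ++j) {
      const int row = j * nx;
      for (int i = 0; i < nx; ++i) {
        const int k = row + i;
        if (is_scar[k]) { vnew[k] = 0.0; continue; }
        const double vk = v[k];
        // diffusion
        double lap = 0.0;
        if (i > 0)      lap += Dx[(size_t)j * (nx - 1) + i - 1] * (v[k - 1]  - vk);
        if (i < nx - 1) lap += Dx[(size_t)j * (nx - 1) + i]     * (v[k + 1]  - vk);
        if (j > 0)      lap += Dy[(size_t)(j - 1) * nx + i]     * (v[k - nx] - vk);
        if (j < ny - 1) lap += Dy[(size_t)j * nx + i]           * (v[k + nx] - vk);
        double dv = lap * inv_dx2;
        if (reaction_on) {
          dv += w[k] * vk * vk * (1.0 - vk) / tau_in[k] - vk / tau_out[k];
          // recovery variable: exact exponential update
          if (vk < v_gate[k]) w[k] = 1.0 - (1.0 - w[k]) * eo[k];
          else                w[k] *= ec[k];
        }
        vnew[k] = vk + dt * dv;
      }
    }

    if (stim_now > 0.0)
      for (int s = 0; s < n_stim_nodes; ++s) {
        const int k = stim_nodes[s];
        if (!is_scar[k]) vnew[k] += dt * stim_now;
      }

    // crossings (linear interpolation between t and t + dt)
    const double t1 = t + dt;
    for (int k = 0; k < N; ++k) {
      const double a = v[k], b = vnew[k];
      if (a < v_up && b >= v_up) {
        up_node.push_back(k);
        up_time.push_back(t + dt * (v_up - a) / (b - a));
      }
      if (a > v_down && b <= v_down) {
        dn_node.push_back(k);
        dn_time.push_back(t + dt * (v_down - a) / (b - a));
      }
    }

    v.swap(vnew);

    // divergence check
    if ((step & 1023) == 0) {
      for (int k = 0; k < N; ++k)
        if (!std::isfinite(v[k]) || std::fabs(v[k]) > 50.0)
          stop("monodomain solver diverged at t = %f ms", t1);
    }

    // record traces
    if (record_every > 0 && ((step + 1) % record_every == 0) && sample_idx < n_samples) {
      trace_times[sample_idx] = t1;
      for (int r = 0; r < n_rec; ++r) traces(sample_idx, r) = v[record_nodes[r]];
      ++sample_idx;
    }

    // snapshots
    while (snap_ptr < n_snap && snapshot_steps[snap_ptr] == step) {
      snap_times[snap_ptr] = t1;
      for (int k = 0; k < N; ++k) snaps(k, snap_ptr) = v[k];
      ++snap_ptr;
    }

    if ((step & 4095) == 0) Rcpp::checkUserInterrupt();
  }

  NumericVector vfin(N), wfin(N);
  for (int k = 0; k < N; ++k) { vfin[k] = v[k]; wfin[k] = w[k]; }

  return List::create(
    _["trace_times"] = trace_times,
    _["traces"] = traces,
    _["up_node"] = IntegerVector(up_node.begin(), up_node.end()),
    _["up_time"] = NumericVector(up_time.begin(), up_time.end()),
    _["down_node"] = IntegerVector(dn_node.begin(), dn_node.end()),
    _["down_time"] = NumericVector(dn_time.begin(), dn_time.end()),
    _["snapshots"] = snaps,
    _["snapshot_times"] = snap_times,
    _["v_final"] = vfin,
    _["w_final"] = wfin);
}

// Radius-limited downstream-pair aggregation on large electrode sets.
// For every electrode i, scans all j with |x_i - x_j| within R using a
// cell-bucket index, keeps pairs with at_j > at_i and distance <= R, and
// accumulates the statistics each interpolation method needs without
// materializing the pair list. Midpoint assignment for the nearest-
// neighbour method is done against a regular grid (the host mesh).
// [[Rcpp::export(name = ".cpp_rvi_aggregate")]]
List cpp_rvi_aggregate(NumericVector x, NumericVector y, NumericVector z,
                       NumericVector at, NumericVector rt, double R,
                       bool do_nn, double mesh_x0, double mesh_y0,
                       double mesh_dx, int mesh_nx, int mesh_ny)
{
  const int n = x.size();
  const double R2 = R * R;
  const bool has_z = (z.size() == n);

  // bucket grid over electrodes
  double xmin = R_PosInf, xmax = R_NegInf, ymin = R_PosInf, ymax = R_NegInf;
  for (int i = 0; i < n; ++i) {
    if (x[i] < xmin) xmin = x[i];
    if (x[i] > xmax) xmax = x[i];
    if (y[i] < ymin) ymin = y[i];
    if (y[i] > ymax) ymax = y[i];
  }
  const double cell = R > 0 ? R : 1.0;
  const int bx = std::max(1, (int)std::floor((xmax - xmin) / cell) + 1);
  const int by = std::max(1, (int)std::floor((ymax - ymin) / cell) + 1);
  std::vector<std::vector<int>> buckets((size_t)bx * by);
  for (int i = 0; i < n; ++i) {
    int cx = std::min(bx - 1, (int)std::floor((x[i] - xmin) / cell));
    int cy = std::min(by - 1, (int)std::floor((y[i] - ymin) / cell));
    buckets[(size_t)cy * bx + cx].push_back(i);
  }

  NumericVector min_rvi(n, NA_REAL), sum_rvi(n, 0.0);
  IntegerVector n_pairs(n, 0);

  // nearest-neighbour accumulation over mesh nodes
  const int Nmesh = do_nn ? mesh_nx * mesh_ny : 0;
  std::vector<double> nn_sum(Nmesh, 0.0);
  std::vector<int> nn_cnt(Nmesh, 0);

  for (int i = 0; i < n; ++i) {
    if (!R_finite(at[i])) continue;
    const double xi = x[i], yi = y[i], ati = at[i];
    const bool has_rt = R_finite(rt[i]);
    int cx = std::min(bx - 1, (int)std::floor((xi - xmin) / cell));
    int cy = std::min(by - 1, (int)std::floor((yi - ymin) / cell));
    for (int oy = -1; oy <= 1; ++oy) {
      const int gy = cy + oy;
      if (gy < 0 || gy >= by) continue;
      for (int ox = -1; ox <= 1; ++ox) {
        const int gx = cx + ox;
        if (gx < 0 || gx >= bx) continue;
        const std::vector<int> &bk = buckets[(size_t)gy * bx + gx];
        for (size_t q = 0; q < bk.size(); ++q) {
          const int j = bk[q];
          if (j == i || !R_finite(at[j])) continue;
          if (!(at[j] > ati)) continue;                  // strictly downstream
          const double ddx = x[j] - xi, ddy = y[j] - yi;
          double d2 = ddx * ddx + ddy * ddy;
          if (has_z) { const double ddz = z[j] - z[i]; d2 += ddz * ddz; }
          if (d2 > R2) continue;
          if (has_rt) {
            const double rvi = rt[i] - at[j];
            if (n_pairs[i] == 0 || rvi < min_rvi[i]) min_rvi[i] = rvi;
            sum_rvi[i] += rvi;
            n_pairs[i] += 1;
            if (do_nn) {
              const double mx = 0.5 * (xi + x[j]), my = 0.5 * (yi + y[j]);
              // nearest grid node; exact halfway ties go to the lower index
              int ni = (int)std::ceil((mx - mesh_x0) / mesh_dx - 0.5);
              int nj = (int)std::ceil((my - mesh_y0) / mesh_dx - 0.5);
              if (ni >= 0 && ni < mesh_nx && nj >= 0 && nj < mesh_ny) {
                const int k = nj * mesh_nx + ni;
                nn_sum[k] += rvi;
                nn_cnt[k] += 1;
              }
            }
          }
        }
      }
    }
    if ((i & 2047) == 0) Rcpp::checkUserInterrupt();
  }

  List out = List::create(
    _["min_rvi"] = min_rvi,
    _["sum_rvi"] = sum_rvi,
    _["n_pairs"] = n_pairs);
  if (do_nn) {
    out["nn_sum"] = NumericVector(nn_sum.begin(), nn_sum.end());
    out["nn_count"] = IntegerVector(nn_cnt.begin(), nn_cnt.end());
  }
  return out;
}
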