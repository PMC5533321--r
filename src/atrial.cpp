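#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// State encoding (integer): 0 = rest, tau+1 = excited, tau..1 = refractory
// countdown.  Cells are addressed by the R column-major linear index
// i = row + col*L (0-based here).  vlink(r,c) is the vertical connection
// between (r,c) and ((r+1) mod L, c); the vertical direction is cyclic,
// the horizontal one is not.

// One synchronous update from the pre-step state.  Conduction-failure
// uniforms are consumed from R's RNG in ascending linear-index order, one
// draw per defective rest cell that has at least one excited connected
// neighbour this step.
// [[Rcpp::export]]
IntegerMatrix ca_step_core(IntegerMatrix state, LogicalMatrix vlink,
                           LogicalMatrix defective, int tau, double eps) {
  const int L = state.nrow();
  IntegerMatrix out(L, L);
  const int EXC = tau + 1;
  for (int c = 0; c < L; ++c) {
    for (int r = 0; r < L; ++r) {
      int s = state(r, c);
      if (s == EXC) {
        out(r, c) = tau;                       // enters refractory
      } else if (s > 0) {
        out(r, c) = s - 1;                     // countdown; 1 -> 0 (rest)
      } else {
        int up = (r == 0) ? L - 1 : r - 1;
        int dn = (r == L - 1) ? 0 : r + 1;
        bool hit =
          (c > 0     && state(r, c - 1) == EXC) ||
          (c < L - 1 && state(r, c + 1) == EXC) ||
          (vlink(up, c) && state(up, c) == EXC) ||
          (vlink(r,  c) && state(dn, c) == EXC);
        if (hit) {
          if (defective(r, c) && unif_rand() < eps)
            out(r, c) = 0;                     // conduction failure
          else
            out(r, c) = EXC;
        } else {
          out(r, c) = 0;
        }
      }
    }
  }
  return out;
}

// Event-driven full run.  Tracks per-cell last excitation step instead of
// scanning the grid, so cost scales with wavefront size, not L^2.  The
// region-average intensity (excited = 1, refractory counter k -> k/tau,
// rest = 0) is maintained incrementally: a region cell excited at step s
// contributes the fixed ramp 1, 1, (tau-1)/tau, ..., 1/tau, 0 at steps
// s, s+1, ..., s+tau+1, handled with circular difference buffers.
// Candidate excitations are sorted by linear index before the failure
// draws, so the RNG stream is identical to iterating ca_step_core.
//
// pulse_steps: sorted 0-based step indices at which every resting cell of
// column 0 is excited (refractory cells are left alone).
// Records values[t - record_from] for t in [record_from, total_steps).
// [[Rcpp::export]]
NumericVector ca_run_core(LogicalMatrix vlink, LogicalMatrix defective,
                          int tau, double eps, IntegerVector pulse_steps,
                          int total_steps, int record_from,
                          int row0, int row1, int col0, int col1) {
  const int L = vlink.nrow();
  const int NC = L * L;
  const long region_size = (long)(row1 - row0) * (col1 - col0);
  std::vector<int> last_exc(NC, -(tau + 2));   // everything at rest
  std::vector<int> attempted(NC, -1);
  std::vector<int> cur, nxt, cand;
  cur.reserve(4 * L); nxt.reserve(4 * L); cand.reserve(4 * L);

  const int W = tau + 8;                       // circular buffer window
  std::vector<double> dgain(W, 0.0);
  std::vector<int> ddecay(W, 0);
  double S = 0.0;                              // running intensity sum
  long decay_active = 0;

  NumericVector values(total_steps - record_from);
  int pp = 0, npulse = pulse_steps.size();
  const int* pl = (npulse > 0) ? &pulse_steps[0] : NULL;
  const int* vl = vlink.begin();
  const int* df = defective.begin();

  auto in_region = [&](int cell) {
    int r = cell % L, c = cell / L;
    return r >= row0 && r < row1 && c >= col0 && c < col1;
  };
  auto excite = [&](int cell, int when) {
    last_exc[cell] = when;
    if (in_region(cell)) {
      dgain[when % W] += 1.0;
      ddecay[(when + 2) % W] += 1;
      ddecay[(when + tau + 2) % W] -= 1;
    }
  };

  for (int t = 0; t < total_steps; ++t) {
    // (1) pacemaker pulse: column 0, resting cells only
    if (pp < npulse && pl[pp] == t) {
      for (int r = 0; r < L; ++r) {
        int cell = r;                          // col 0
        if (t - last_exc[cell] > tau) {
          excite(cell, t);
          cur.push_back(cell);
        }
      }
      ++pp;
    }
    // (2) advance the incremental intensity to step t and record
    decay_active += ddecay[t % W];
    ddecay[t % W] = 0;
    S += dgain[t % W] - (double)decay_active / tau;
    dgain[t % W] = 0.0;
    if (t >= record_from) values[t - record_from] = S / region_size;
    // (3) propagation decided at t, taking effect at t+1
    cand.clear();
    for (size_t k = 0; k < cur.size(); ++k) {
      int cell = cur[k];
      int r = cell % L, c = cell / L;
      int nb[4];
      int nn = 0;
      if (c > 0)     nb[nn++] = cell - L;
      if (c < L - 1) nb[nn++] = cell + L;
      int up = (r == 0) ? L - 1 : r - 1;
      int dn = (r == L - 1) ? 0 : r + 1;
      if (vl[up + c * L]) nb[nn++] = up + c * L;
      if (vl[cell])       nb[nn++] = dn + c * L;
      for (int j = 0; j < nn; ++j) {
        int n = nb[j];
        if (attempted[n] != t && t - last_exc[n] > tau) {
          attempted[n] = t;
          cand.push_back(n);
        }
      }
    }
    std::sort(cand.begin(), cand.end());
    nxt.clear();
    for (size_t k = 0; k < cand.size(); ++k) {
      int n = cand[k];
      if (df[n] && unif_rand() < eps) continue;
      excite(n, t + 1);
      nxt.push_back(n);
    }
    cur.swap(nxt);
  }
  return values;
}
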