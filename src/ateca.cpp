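#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cstdint>
using namespace Rcpp;

// Neighbourhood index s = 4x + 2y + z for binary (x, y, z).
static inline int nbhd(int x, int y, int z) { return 4 * x + 2 * y + z; }

struct Boundary {
  bool periodic;
  int left, right; // clamped values; ignored when periodic
};

static Boundary make_boundary(bool periodic, int bl, int br) {
  Boundary b;
  b.periodic = periodic;
  b.left = bl;
  b.right = br;
  return b;
}

// ---- synchronous / probabilistically asynchronous steps ----------------

static void sync_step_buf(std::vector<int>& cur, std::vector<int>& nxt,
                          const int* rule, const Boundary& b) {
  const int n = (int)cur.size();
  for (int i = 0; i < n; ++i) {
    int l = b.periodic ? cur[(i - 1 + n) % n] : (i == 0 ? b.left : cur[i - 1]);
    int r = b.periodic ? cur[(i + 1) % n] : (i == n - 1 ? b.right : cur[i + 1]);
    nxt[i] = rule[nbhd(l, cur[i], r)];
  }
  cur.swap(nxt);
}

// Each cell keeps its state with probability p, otherwise applies the rule;
// all rule inputs are read from time t.
static void async_step_buf(std::vector<int>& cur, std::vector<int>& nxt,
                           const int* rule, double p, const Boundary& b) {
  const int n = (int)cur.size();
  for (int i = 0; i < n; ++i) {
    if (unif_rand() < p) {
      nxt[i] = cur[i];
    } else {
      int l = b.periodic ? cur[(i - 1 + n) % n] : (i == 0 ? b.left : cur[i - 1]);
      int r = b.periodic ? cur[(i + 1) % n] : (i == n - 1 ? b.right : cur[i + 1]);
      nxt[i] = rule[nbhd(l, cur[i], r)];
    }
  }
  cur.swap(nxt);
}

// ---- asynchronously tuned step -----------------------------------------

// Draw a uniform random update-order permutation: ord[i] is the rank
// (1..n) at which cell i updates. Uses R's RNG (Fisher-Yates).
static void draw_order_buf(std::vector<int>& ord) {
  const int n = (int)ord.size();
  for (int i = 0; i < n; ++i) ord[i] = i + 1;
  for (int i = n - 1; i > 0; --i) {
    int j = (int)(unif_rand() * (i + 1));
    if (j > i) j = i;
    std::swap(ord[i], ord[j]);
  }
}

// One asynchronously tuned step. `cur` evolves in place while `snap`
// keeps the time-t configuration; cells are processed in ascending rank,
// which makes "neighbour already updated" equivalent to "neighbour has a
// smaller rank". `active` is row-major n x 8. Boundary cells of a clamped
// topology carry rank n+1 (they never update, so they always count as
// updating later than any interior cell, and their value is constant).
// Active-rule tuning writes at most the entry m = 4*c[i-1](t) + 2*c[i](t)
// + c[i+1](t):
//   * active-minimum cells (both neighbours later): no change;
//   * one neighbour earlier: entry m re-initialised from the passive rule
//     (entry m by default; entry 0's value under the literal-a0 variant);
//   * both neighbours earlier (passive-maximum): entry m := c[i](t+1).
static void at_step_buf(std::vector<int>& cur, std::vector<int>& snap,
                        std::vector<int>& active, const int* passive,
                        const std::vector<int>& ord, std::vector<int>& pos,
                        const Boundary& b, bool eq12_literal_a0) {
  const int n = (int)cur.size();
  snap.assign(cur.begin(), cur.end());
  for (int i = 0; i < n; ++i) pos[ord[i] - 1] = i;
  const int reset_val = eq12_literal_a0 ? passive[0] : -1; // -1: use passive[m]
  for (int ri = 0; ri < n; ++ri) {
    const int i = pos[ri];
    const int my = ri + 1;
    int lr, rr, sl, sr, cl, cr;
    if (b.periodic) {
      const int li = (i - 1 + n) % n, rj = (i + 1) % n;
      lr = ord[li]; sl = snap[li]; cl = cur[li];
      rr = ord[rj]; sr = snap[rj]; cr = cur[rj];
    } else {
      if (i == 0) { lr = n + 1; sl = b.left; cl = b.left; }
      else { lr = ord[i - 1]; sl = snap[i - 1]; cl = cur[i - 1]; }
      if (i == n - 1) { rr = n + 1; sr = b.right; cr = b.right; }
      else { rr = ord[i + 1]; sr = snap[i + 1]; cr = cur[i + 1]; }
    }
    const int m = nbhd(sl, snap[i], sr);
    int val;
    if (lr > my && rr > my) {            // active minimum: own active rule
      val = active[i * 8 + m];
    } else if (lr < my && rr > my) {     // left neighbour updated first
      val = passive[nbhd(cl, snap[i], sr)];
      active[i * 8 + m] = (reset_val >= 0) ? reset_val : passive[m];
    } else if (lr > my && rr < my) {     // right neighbour updated first
      val = passive[nbhd(sl, snap[i], cr)];
      active[i * 8 + m] = (reset_val >= 0) ? reset_val : passive[m];
    } else {                             // passive maximum: both updated
      val = passive[nbhd(cl, snap[i], cr)];
      active[i * 8 + m] = val;
    }
    cur[i] = val;
  }
}

// ---- exported single steps ----------------------------------------------

// [[Rcpp::export]]
IntegerVector cpp_sync_step(IntegerVector cells, IntegerVector rule,
                            bool periodic, int bleft, int bright) {
  std::vector<int> cur(cells.begin(), cells.end()), nxt(cells.size());
  Boundary b = make_boundary(periodic, bleft, bright);
  sync_step_buf(cur, nxt, INTEGER(rule), b);
  return IntegerVector(cur.begin(), cur.end());
}

// [[Rcpp::export]]
IntegerVector cpp_async_step(IntegerVector cells, IntegerVector rule,
                             double p, bool periodic, int bleft, int bright) {
  std::vector<int> cur(cells.begin(), cells.end()), nxt(cells.size());
  Boundary b = make_boundary(periodic, bleft, bright);
  async_step_buf(cur, nxt, INTEGER(rule), p, b);
  return IntegerVector(cur.begin(), cur.end());
}

// [[Rcpp::export]]
List cpp_at_step(IntegerVector cells, IntegerMatrix active,
                 IntegerVector passive, IntegerVector order,
                 bool periodic, int bleft, int bright, bool eq12_literal_a0) {
  const int n = cells.size();
  std::vector<int> cur(cells.begin(), cells.end()), snap(n), pos(n);
  std::vector<int> act(n * 8);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < 8; ++k) act[i * 8 + k] = active(i, k);
  std::vector<int> ord(order.begin(), order.end());
  Boundary b = make_boundary(periodic, bleft, bright);
  at_step_buf(cur, snap, act, INTEGER(passive), ord, pos, b, eq12_literal_a0);
  IntegerMatrix act_out(n, 8);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < 8; ++k) act_out(i, k) = act[i * 8 + k];
  return List::create(_["cells"] = IntegerVector(cur.begin(), cur.end()),
                      _["active"] = act_out);
}

// ---- trajectories --------------------------------------------------------

// regime: 0 = sync, 1 = async(p)
// [[Rcpp::export]]
IntegerMatrix cpp_trajectory(IntegerVector init, IntegerVector rule,
                             int regime, double p, int steps,
                             bool periodic, int bleft, int bright) {
  const int n = init.size();
  IntegerMatrix out(steps + 1, n);
  std::vector<int> cur(init.begin(), init.end()), nxt(n);
  Boundary b = make_boundary(periodic, bleft, bright);
  for (int i = 0; i < n; ++i) out(0, i) = cur[i];
  for (int t = 1; t <= steps; ++t) {
    if (regime == 0) sync_step_buf(cur, nxt, INTEGER(rule), b);
    else async_step_buf(cur, nxt, INTEGER(rule), p, b);
    for (int i = 0; i < n; ++i) out(t, i) = cur[i];
  }
  return out;
}

// [[Rcpp::export]]
List cpp_at_trajectory(IntegerVector init, IntegerVector passive, int steps,
                       bool periodic, int bleft, int bright,
                       bool eq12_literal_a0) {
  const int n = init.size();
  IntegerMatrix out(steps + 1, n);
  std::vector<int> cur(init.begin(), init.end()), snap(n), pos(n), ord(n);
  std::vector<int> act(n * 8);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < 8; ++k) act[i * 8 + k] = INTEGER(passive)[k];
  Boundary b = make_boundary(periodic, bleft, bright);
  for (int i = 0; i < n; ++i) out(0, i) = cur[i];
  for (int t = 1; t <= steps; ++t) {
    draw_order_buf(ord);
    at_step_buf(cur, snap, act, INTEGER(passive), ord, pos, b, eq12_literal_a0);
    for (int i = 0; i < n; ++i) out(t, i) = cur[i];
  }
  IntegerMatrix act_out(n, 8);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < 8; ++k) act_out(i, k) = act[i * 8 + k];
  return List::create(_["diagram"] = out, _["active"] = act_out);
}

// ---- computability measure ----------------------------------------------

// One stochastic replicate (or the single deterministic evaluation) of the
// universality/efficiency measure for one rule and one boundary pair.
// All 2^n interior initial states are enumerated; each trajectory is run
// for t_max steps with the boundary clamped. The reachable set is the set
// of configurations occupied at t_max; the first-hitting time of state X
// from init Y is the smallest t >= 1 with state(t) == X, else t_theta.
// tau(X) sums hitting times over all initial states; E is the mean of tau
// over the reachable set. State codes read the interior configuration as a
// binary number with the leftmost cell as the most significant bit.
// regime: 0 = sync, 1 = async(p), 2 = asynchronously tuned.
// [[Rcpp::export]]
List cpp_measure_replicate(IntegerVector passive, int regime, int n,
                           int t_max, int t_theta, double p,
                           bool eq12_literal_a0, int bleft, int bright) {
  if (n < 1 || n > 14) stop("interior width n must be in [1, 14]");
  const int total = 1 << n;
  const int* rule = INTEGER(passive);
  Boundary b = make_boundary(false, bleft, bright);

  std::vector<int> finals(total);
  // first_hit[y * total + x] = smallest t >= 1 with state x, 0 if never
  std::vector<int32_t> first_hit((size_t)total * total, 0);

  std::vector<int> cur(n), nxt(n), snap(n), pos(n), ord(n);
  std::vector<int> act(n * 8);

  for (int y = 0; y < total; ++y) {
    for (int i = 0; i < n; ++i) cur[i] = (y >> (n - 1 - i)) & 1;
    if (regime == 2)
      for (int i = 0; i < n; ++i)
        for (int k = 0; k < 8; ++k) act[i * 8 + k] = rule[k];
    int code = 0;
    for (int t = 1; t <= t_max; ++t) {
      if (regime == 0) sync_step_buf(cur, nxt, rule, b);
      else if (regime == 1) async_step_buf(cur, nxt, rule, p, b);
      else {
        draw_order_buf(ord);
        at_step_buf(cur, snap, act, rule, ord, pos, b, eq12_literal_a0);
      }
      code = 0;
      for (int i = 0; i < n; ++i) code = (code << 1) | cur[i];
      int32_t& fh = first_hit[(size_t)y * total + code];
      if (fh == 0) fh = t;
    }
    finals[y] = code;
  }

  std::vector<int> reach(finals);
  std::sort(reach.begin(), reach.end());
  reach.erase(std::unique(reach.begin(), reach.end()), reach.end());

  const int u = (int)reach.size();
  NumericVector tau(u);
  double esum = 0.0;
  for (int xi = 0; xi < u; ++xi) {
    const int x = reach[xi];
    double s = 0.0;
    for (int y = 0; y < total; ++y) {
      const int32_t fh = first_hit[(size_t)y * total + x];
      s += (fh > 0) ? fh : t_theta;
    }
    tau[xi] = s;
    esum += s;
  }
  return List::create(_["reachable"] = IntegerVector(reach.begin(), reach.end()),
                      _["tau"] = tau,
                      _["U"] = u,
                      _["E"] = esum / u);
}
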