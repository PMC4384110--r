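// Backtracking placement of the 7-strand / 6-loop skeleton onto a sequence.
//
// The candidate space is all assignments with 6-residue strands, per-loop
// lengths in [loop_min, loop_max], total loop length in [tot_min, tot_max]
// and tails within caps. Space constraints are enforced exactly during
// enumeration in every mode. Rule handling differs by mode:
//   mode 0 (decide)    - eager exact filters (per-strand window validity,
//                        per-loop rule checks, monotone running-max cuts) and,
//                        when `prune`, admissible min-feasibility pruning;
//                        stops at the first satisfying assignment.
//   mode 1 (enumerate) - as mode 0 but visits the whole space, counting all
//                        satisfying assignments and storing the first
//                        max_witnesses of them.
//   mode 2 (explain)   - no filters: every candidate assignment is visited
//                        and its number of violated bounds computed; the
//                        first assignment with the fewest violations (in
//                        canonical order) is returned.
// Canonical order everywhere: strand-1 start ascending, then loop lengths
// l1..l6 ascending.
#include <Rcpp.h>
#include <climits>
using namespace Rcpp;

namespace {

struct Ctx {
  // problem
  int L, W, D, R;
  const int *wc;          // W x D column-major (wc[s + W*d])
  const int *valid;       // W x 7 (0/1)
  const int *svio;        // W x 7 per-strand violation counts (explain)
  const int *rule_desc;   // R
  const int *agg_lo;      // R x 3 (interlock, non, all)
  const int *agg_hi;      // R x 3
  const int *face_size;   // D
  const double *cumw;     // L+1
  const int *cumstrong;   // L+1
  double coeff;
  bool check_fav, check_major;
  int strong_cap;         // -1 = disabled
  int loop_min, loop_max, tot_min, tot_max;
  int max_n_tail, max_c_tail;
  int mode, max_wit;
  bool prune;

  // state
  int starts[7];
  long long sum_int[64], sum_non[64];
  int rem_int[8], rem_non[8];   // interlock / non-interlock strands with index > k
  long long n_sat;
  bool found;
  std::vector<int> witnesses;   // flattened, 7 per witness
  long long best_viol;
  int best_starts[7];
  int viol_acc;                 // running violation count (explain)

  bool is_interlock(int k) const {  // 0-based strand index
    return k == 1 || k == 2 || k == 4 || k == 5;
  }

  int window_count(int s, int d) const { return wc[s + (size_t)W * d]; }

  // exact running-max + admissible min-feasibility checks after strand k placed
  bool agg_ok(int k) const {
    int ri = rem_int[k], rn = rem_non[k];
    for (int r = 0; r < R; ++r) {
      int d = rule_desc[r];
      long long ti = sum_int[d], tn = sum_non[d], ta = ti + tn;
      if (ti > agg_hi[r]) return false;
      if (tn > agg_hi[r + R]) return false;
      if (ta > agg_hi[r + 2 * R]) return false;
      if (prune) {
        long long cap = face_size[d];
        if (ti + ri * cap < agg_lo[r]) return false;
        if (tn + rn * cap < agg_lo[r + R]) return false;
        if (ta + (ri + rn) * cap < agg_lo[r + 2 * R]) return false;
      }
    }
    return true;
  }

  int leaf_agg_viol() const {
    int v = 0;
    for (int r = 0; r < R; ++r) {
      int d = rule_desc[r];
      long long ti = sum_int[d], tn = sum_non[d], ta = ti + tn;
      if (ti < agg_lo[r] || ti > agg_hi[r]) ++v;
      if (tn < agg_lo[r + R] || tn > agg_hi[r + R]) ++v;
      if (ta < agg_lo[r + 2 * R] || ta > agg_hi[r + 2 * R]) ++v;
    }
    return v;
  }

  bool leaf_agg_ok() const {
    for (int r = 0; r < R; ++r) {
      int d = rule_desc[r];
      long long ti = sum_int[d], tn = sum_non[d], ta = ti + tn;
      if (ti < agg_lo[r] || ti > agg_hi[r]) return false;
      if (tn < agg_lo[r + R] || tn > agg_hi[r + R]) return false;
      if (ta < agg_lo[r + 2 * R] || ta > agg_hi[r + 2 * R]) return false;
    }
    return true;
  }

  void add_counts(int k, int s, int sign) {
    if (is_interlock(k)) {
      for (int d = 0; d < D; ++d) sum_int[d] += sign * window_count(s, d);
    } else {
      for (int d = 0; d < D; ++d) sum_non[d] += sign * window_count(s, d);
    }
  }

  // loop rule evaluation for fragment [a, a+l)
  int loop_viol(int a, int l) const {
    int v = 0;
    if (check_fav) {
      double fav = cumw[a + l] - cumw[a];
      if (fav < coeff * l - 1e-9) ++v;
    }
    if (check_major) {
      int st = cumstrong[a + l] - cumstrong[a];
      if (2 * st >= l) ++v;
    }
    return v;
  }

  int loop_strong(int a, int l) const { return cumstrong[a + l] - cumstrong[a]; }

  // recurse: strand k placed at starts[k]; loop total so far Tl; strong-in-loops Ts
  void descend(int k, int Tl, int Ts) {
    if (found) return;
    if (k == 6) {  // leaf
      bool sat;
      int v = 0;
      if (mode == 2) {
        v = viol_acc + leaf_agg_viol();
        if (strong_cap >= 0 && Ts > strong_cap) ++v;
        if (v < best_viol) {
          best_viol = v;
          for (int i = 0; i < 7; ++i) best_starts[i] = starts[i];
        }
        return;
      }
      sat = leaf_agg_ok() && !(strong_cap >= 0 && Ts > strong_cap);
      if (sat) {
        ++n_sat;
        if ((int)(witnesses.size() / 7) < max_wit) {
          for (int i = 0; i < 7; ++i) witnesses.push_back(starts[i]);
        }
        if (mode == 0) found = true;
      }
      return;
    }
    // choose loop k (between strand k and k+1) of length l
    int a = starts[k] + 6;       // loop start
    int m2 = 5 - k;              // loops remaining after this one
    for (int l = loop_min; l <= loop_max; ++l) {
      int s_next = a + l;
      if (s_next + 6 + m2 * (6 + loop_min) > L) break;  // no room, larger l worse
      // feasibility interval for the remaining loop total Trem
      long long lo = std::max((long long)m2 * loop_min,
                              (long long)tot_min - Tl - l);
      long long hi = std::min((long long)m2 * loop_max,
                              (long long)tot_max - Tl - l);
      // s6 = s_next + m2*6 + Trem must satisfy s6 + 6 <= L and c_tail cap
      long long hi2 = (long long)L - 6 - s_next - (long long)m2 * 6;
      long long lo2 = (long long)L - 6 - s_next - (long long)m2 * 6 -
                      (max_c_tail == INT_MAX ? (long long)1 << 40 : max_c_tail);
      if (hi > hi2) hi = hi2;
      if (lo < lo2) lo = lo2;
      if (lo > hi) continue;
      int lv = 0, ls = 0;
      if (mode == 2) {
        lv = loop_viol(a, l);
      } else if (check_fav || check_major) {
        if (loop_viol(a, l) > 0) continue;
      }
      ls = loop_strong(a, l);
      if (mode != 2 && strong_cap >= 0 && Ts + ls > strong_cap) continue;
      int kk = k + 1;
      int s = s_next;
      if (mode != 2 && !valid[s + (size_t)W * kk]) continue;
      starts[kk] = s;
      add_counts(kk, s, +1);
      if (mode == 2) {
        int sv = svio[s + (size_t)W * kk];
        viol_acc += lv + sv;
        descend(kk, Tl + l, Ts + ls);
        viol_acc -= lv + sv;
      } else {
        if (agg_ok(kk)) descend(kk, Tl + l, Ts + ls);
      }
      add_counts(kk, s, -1);
      if (found) return;
    }
  }

  void run() {
    n_sat = 0;
    found = false;
    best_viol = LLONG_MAX;
    viol_acc = 0;
    for (int d = 0; d < D; ++d) { sum_int[d] = 0; sum_non[d] = 0; }
    for (int k = 0; k < 8; ++k) { rem_int[k] = 0; rem_non[k] = 0; }
    // rem_int[k] = interlock strands with index > k (0-based)
    for (int k = 0; k < 7; ++k) {
      int ri = 0, rn = 0;
      for (int j = k + 1; j < 7; ++j) {
        if (is_interlock(j)) ++ri; else ++rn;
      }
      rem_int[k] = ri; rem_non[k] = rn;
    }
    int min_rest = 6 * 6 + 6 * loop_min;  // strands 2..7 + minimal loops
    int tot_floor = std::max(6 * loop_min, tot_min);
    int s0_max = (int)std::min((long long)max_n_tail,
                               (long long)L - 42 - tot_floor);
    for (int s0 = 0; s0 <= s0_max; ++s0) {
      if (s0 + 6 + min_rest > L) break;
      if (mode != 2 && !valid[s0 + (size_t)W * 0]) continue;
      starts[0] = s0;
      add_counts(0, s0, +1);
      if (mode == 2) {
        int sv = svio[s0 + (size_t)W * 0];
        viol_acc += sv;
        descend(0, 0, 0);
        viol_acc -= sv;
      } else {
        if (agg_ok(0)) descend(0, 0, 0);
      }
      add_counts(0, s0, -1);
      if (found) break;
    }
  }
};

}  // namespace

// [[Rcpp::export]]
List cpp_search(IntegerMatrix wc, IntegerMatrix valid, IntegerMatrix svio,
                IntegerVector rule_desc, IntegerMatrix agg_lo,
                IntegerMatrix agg_hi, IntegerVector face_size,
                NumericVector cumw, IntegerVector cumstrong, double coeff,
                bool check_fav, bool check_major, int strong_cap,
                int loop_min, int loop_max, int tot_min, int tot_max,
                int max_n_tail, int max_c_tail, int L, int mode,
                int max_wit, bool prune) {
  if (wc.ncol() > 64) stop("too many descriptors (max 64)");
  Ctx c;
  c.L = L;
  c.W = wc.nrow();
  c.D = wc.ncol();
  c.R = rule_desc.size();
  c.wc = wc.begin();
  c.valid = valid.begin();
  c.svio = svio.begin();
  c.rule_desc = rule_desc.begin();
  c.agg_lo = agg_lo.begin();
  c.agg_hi = agg_hi.begin();
  c.face_size = face_size.begin();
  c.cumw = cumw.begin();
  c.cumstrong = cumstrong.begin();
  c.coeff = coeff;
  c.check_fav = check_fav;
  c.check_major = check_major;
  c.strong_cap = strong_cap;
  c.loop_min = loop_min;
  c.loop_max = loop_max;
  c.tot_min = tot_min;
  c.tot_max = tot_max;
  c.max_n_tail = max_n_tail;
  c.max_c_tail = max_c_tail;
  c.mode = mode;
  c.max_wit = max_wit;
  c.prune = prune;
  c.run();

  List out;
  out["n_satisfying"] = (double)c.n_sat;
  if (mode == 2) {
    if (c.best_viol == LLONG_MAX) {
      out["best_starts"] = IntegerVector(0);
      out["best_n_viol"] = NA_REAL;
    } else {
      out["best_starts"] = IntegerVector(c.best_starts, c.best_starts + 7);
      out["best_n_viol"] = (double)c.best_viol;
    }
  } else {
    int nw = c.witnesses.size() / 7;
    IntegerMatrix wit(nw, 7);
    for (int i = 0; i < nw; ++i) {
      for (int j = 0; j < 7; ++j) wit(i, j) = c.witnesses[i * 7 + j];
    }
    out["witnesses"] = wit;
  }
  return out;
}
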