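// Minimum-free-energy secondary structure DP (Zuker-style, no pseudoknots).
//
// Recurrences over a nearest-neighbor model with stacks, tabulated
// hairpin/bulge/internal loop penalties (log-extrapolated past 30 nt) and
// an affine multiloop term.  Lonely pairs allowed, no dangling ends, G:U
// permitted, minimum hairpin loop 3 nt, interior loops capped at
// `max_loop` total unpaired nt.  Positions may be forced unpaired
// (accessibility constraints); a forced position simply never pairs.
// Traceback re-derives each decision in a fixed scan order, so equal-energy
// ties resolve deterministically.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static const double NEG_INF_GUARD = 1e9;

// bases coded 1=A 2=C 3=G 4=U; pair types 1=AU 2=UA 3=CG 4=GC 5=GU 6=UG
static inline int ptype(int a, int b) {
  if (a == 1 && b == 4) return 1;
  if (a == 4 && b == 1) return 2;
  if (a == 2 && b == 3) return 3;
  if (a == 3 && b == 2) return 4;
  if (a == 3 && b == 4) return 5;
  if (a == 4 && b == 3) return 6;
  return 0;
}

struct Model {
  double stack[7][7];        // [ptype_outer][ptype_inner]
  std::vector<double> hairpin, bulge, internal_; // index size-1, length 30
  double ml_a, ml_b, ml_c, lxc;
  int max_loop;

  double hp(int size) const {
    if (size < 3) return NEG_INF_GUARD;
    if (size <= 30) return hairpin[size - 1];
    return hairpin[29] + lxc * std::log(size / 30.0);
  }
  double bul(int size) const {
    if (size <= 30) return bulge[size - 1];
    return bulge[29] + lxc * std::log(size / 30.0);
  }
  double itl(int size) const {
    if (size <= 30) return internal_[size - 1];
    return internal_[29] + lxc * std::log(size / 30.0);
  }
};

class Folder {
public:
  int n;
  std::vector<int> s;          // 0-based base codes
  std::vector<bool> forced;    // forced unpaired
  Model m;
  std::vector<double> V, WM;   // n*n, index i*n+j
  std::vector<double> W;       // suffix MFE, length n+1; W[i] = MFE of i..n-1
  std::vector<int> partner;    // 0-based partner, -1 unpaired

  double &v(int i, int j) { return V[(size_t)i * n + j]; }
  double &wm(int i, int j) { return WM[(size_t)i * n + j]; }

  // interior-loop (stack/bulge/internal) cost between closing pair (i,j)
  // and inner pair (k,l)
  double loop_cost(int i, int j, int k, int l) {
    int s1 = k - i - 1, s2 = j - l - 1;
    if (s1 == 0 && s2 == 0)
      return m.stack[ptype(s[i], s[j])][ptype(s[k], s[l])];
    if (s1 == 0 || s2 == 0) return m.bul(s1 + s2);
    return m.itl(s1 + s2);
  }

  void fill() {
    V.assign((size_t)n * n, NEG_INF_GUARD);
    WM.assign((size_t)n * n, NEG_INF_GUARD);
    for (int span = 4; span < n; ++span) {
      for (int i = 0; i + span < n; ++i) {
        int j = i + span;
        // ---- V(i,j)
        double best = NEG_INF_GUARD;
        if (!forced[i] && !forced[j] && ptype(s[i], s[j]) != 0) {
          best = m.hp(j - i - 1);
          int kmax = std::min(j - 5, i + 1 + m.max_loop);
          for (int k = i + 1; k <= kmax; ++k) {
            int s1 = k - i - 1;
            int lmin = std::max(k + 4, j - 1 - (m.max_loop - s1));
            for (int l = lmin; l <= j - 1; ++l) {
              double inner = v(k, l);
              if (inner >= NEG_INF_GUARD) continue;
              double e = loop_cost(i, j, k, l) + inner;
              if (e < best) best = e;
            }
          }
          // multiloop closed by (i,j): >= 2 inner branches
          for (int k = i + 2; k <= j - 2; ++k) {
            double a = wm(i + 1, k - 1), b = wm(k, j - 1);
            if (a >= NEG_INF_GUARD || b >= NEG_INF_GUARD) continue;
            double e = m.ml_a + m.ml_b + a + b;
            if (e < best) best = e;
          }
        }
        v(i, j) = best;
        // ---- WM(i,j): multiloop segment, >= 1 branch
        double bm = NEG_INF_GUARD;
        if (v(i, j) < NEG_INF_GUARD) bm = v(i, j) + m.ml_b;
        if (i + 1 <= j && wm(i + 1, j) < NEG_INF_GUARD)
          bm = std::min(bm, wm(i + 1, j) + m.ml_c);
        if (i <= j - 1 && wm(i, j - 1) < NEG_INF_GUARD)
          bm = std::min(bm, wm(i, j - 1) + m.ml_c);
        for (int k = i + 1; k <= j; ++k) {
          double a = wm(i, k - 1), b = wm(k, j);
          if (a >= NEG_INF_GUARD || b >= NEG_INF_GUARD) continue;
          bm = std::min(bm, a + b);
        }
        wm(i, j) = bm;
      }
    }
    W.assign(n + 1, 0.0);
    for (int i = n - 1; i >= 0; --i) {
      double best = W[i + 1]; // i unpaired, exterior bases free
      for (int j = i + 4; j < n; ++j) {
        if (v(i, j) >= NEG_INF_GUARD) continue;
        double e = v(i, j) + W[j + 1];
        if (e < best) best = e;
      }
      W[i] = best;
    }
  }

  static bool eq(double a, double b) { return std::fabs(a - b) < 1e-9; }

  void trace_V(int i, int j) {
    partner[i] = j; partner[j] = i;
    double target = v(i, j);
    if (eq(target, m.hp(j - i - 1))) return; // hairpin
    int kmax = std::min(j - 5, i + 1 + m.max_loop);
    for (int k = i + 1; k <= kmax; ++k) {
      int s1 = k - i - 1;
      int lmin = std::max(k + 4, j - 1 - (m.max_loop - s1));
      for (int l = lmin; l <= j - 1; ++l) {
        if (v(k, l) >= NEG_INF_GUARD) continue;
        if (eq(target, loop_cost(i, j, k, l) + v(k, l))) {
          trace_V(k, l);
          return;
        }
      }
    }
    for (int k = i + 2; k <= j - 2; ++k) {
      double a = wm(i + 1, k - 1), b = wm(k, j - 1);
      if (a >= NEG_INF_GUARD || b >= NEG_INF_GUARD) continue;
      if (eq(target, m.ml_a + m.ml_b + a + b)) {
        trace_WM(i + 1, k - 1);
        trace_WM(k, j - 1);
        return;
      }
    }
    stop("traceback failed in V(%d,%d)", i + 1, j + 1);
  }

  void trace_WM(int i, int j) {
    double target = wm(i, j);
    for (int k = i + 1; k <= j; ++k) {
      double a = wm(i, k - 1), b = wm(k, j);
      if (a >= NEG_INF_GUARD || b >= NEG_INF_GUARD) continue;
      if (eq(target, a + b)) { trace_WM(i, k - 1); trace_WM(k, j); return; }
    }
    if (v(i, j) < NEG_INF_GUARD && eq(target, v(i, j) + m.ml_b)) {
      trace_V(i, j);
      return;
    }
    if (i + 1 <= j && wm(i + 1, j) < NEG_INF_GUARD &&
        eq(target, wm(i + 1, j) + m.ml_c)) { trace_WM(i + 1, j); return; }
    if (i <= j - 1 && wm(i, j - 1) < NEG_INF_GUARD &&
        eq(target, wm(i, j - 1) + m.ml_c)) { trace_WM(i, j - 1); return; }
    stop("traceback failed in WM(%d,%d)", i + 1, j + 1);
  }

  void trace() {
    partner.assign(n, -1);
    int i = 0;
    while (i < n) {
      bool found = false;
      // prefer the pairing decision with smallest i, then smallest j
      for (int j = i + 4; j < n; ++j) {
        if (v(i, j) >= NEG_INF_GUARD) continue;
        if (eq(W[i], v(i, j) + W[j + 1])) {
          trace_V(i, j);
          i = j + 1;
          found = true;
          break;
        }
      }
      if (found) continue;
      if (eq(W[i], W[i + 1])) { ++i; continue; }
      stop("traceback failed in exterior at %d", i + 1);
    }
  }
};

// [[Rcpp::export(name = ".c_mfe_fold")]]
List c_mfe_fold(IntegerVector seq_codes, LogicalVector forced_unpaired,
                NumericMatrix stack, NumericVector hairpin,
                NumericVector bulge, NumericVector internal_loop,
                double ml_a, double ml_b, double ml_c,
                double lxc, int max_loop) {
  Folder f;
  f.n = seq_codes.size();
  f.s.assign(seq_codes.begin(), seq_codes.end());
  f.forced.resize(f.n);
  for (int i = 0; i < f.n; ++i) f.forced[i] = forced_unpaired[i];
  for (int a = 0; a < 7; ++a)
    for (int b = 0; b < 7; ++b) f.m.stack[a][b] = 0.0;
  // stack matrix rows/cols ordered AU UA CG GC GU UG -> ptype codes 1..6
  for (int a = 1; a <= 6; ++a)
    for (int b = 1; b <= 6; ++b) f.m.stack[a][b] = stack(a - 1, b - 1);
  f.m.hairpin.assign(hairpin.begin(), hairpin.end());
  f.m.bulge.assign(bulge.begin(), bulge.end());
  f.m.internal_.assign(internal_loop.begin(), internal_loop.end());
  f.m.ml_a = ml_a; f.m.ml_b = ml_b; f.m.ml_c = ml_c;
  f.m.lxc = lxc; f.m.max_loop = max_loop;

  if (f.n < 5) {
    IntegerVector p(f.n, 0);
    return List::create(_["partner"] = p, _["energy"] = 0.0);
  }
  f.fill();
  f.trace();
  IntegerVector p(f.n);
  for (int i = 0; i < f.n; ++i) p[i] = f.partner[i] + 1; // 1-based, 0 = unpaired
  return List::create(_["partner"] = p, _["energy"] = f.W[0]);
}
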