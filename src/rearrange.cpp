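// Signed-permutation rearrangement core.
//
// Inversion (reversal) distance follows the Hannenhalli-Pevzner theory:
// d = b - c + h + f on the breakpoint graph of the permutation extended by
// framing elements, where b counts breakpoints (black edges in non-trivial
// cycles), c non-trivial cycles, h hurdles among unoriented components and
// f indicates a fortress. Linear permutations; circular genomes are
// linearized upstream by pinning an origin.

#include <Rcpp.h>
#include <vector>
#include <queue>
#include <unordered_set>
#include <unordered_map>
#include <cstdint>
#include <algorithm>
#include <functional>

using namespace Rcpp;

namespace {

struct HPStats {
  int d, b, c, h, f;
};

// positions of each unoriented component, flattened and sorted
struct UComp {
  std::vector<int> pos;
};

// Count circular runs of component `id` in the circular sequence `seq`
// (sequence of component ids at the sorted unoriented positions).
static int circular_runs(const std::vector<int>& seq, int id) {
  int m = seq.size();
  int runs = 0;
  for (int i = 0; i < m; i++) {
    int prev = seq[(i + m - 1) % m];
    if (seq[i] == id && prev != id) runs++;
  }
  if (runs == 0) {
    // id fills the whole circle (or absent)
    for (int i = 0; i < m; i++) if (seq[i] == id) return 1;
  }
  return runs;
}

static HPStats hp_stats(const std::vector<int>& s) {
  int n = (int)s.size();
  int m = 2 * n + 2;
  std::vector<int> u(m);
  u[0] = 0;
  u[m - 1] = 2 * n + 1;
  for (int i = 0; i < n; i++) {
    int v = s[i];
    if (v > 0) { u[2 * i + 1] = 2 * v - 1; u[2 * i + 2] = 2 * v; }
    else       { int k = -v; u[2 * i + 1] = 2 * k; u[2 * i + 2] = 2 * k - 1; }
  }
  std::vector<int> pos(m);
  for (int p = 0; p < m; p++) pos[u[p]] = p;

  // alternating-cycle decomposition; black partner of position p is p^1,
  // gray partner is the position of value u[p]^1
  std::vector<int> cyc(m, -1);
  std::vector<int> cyclen;
  int ncyc = 0;
  for (int p0 = 0; p0 < m; p0++) {
    if (cyc[p0] >= 0) continue;
    int id = ncyc++;
    int len = 0;
    int q = p0;
    while (cyc[q] < 0) {
      cyc[q] = id;
      int qb = q ^ 1;
      cyc[qb] = id;
      len++;
      q = pos[u[qb] ^ 1];
    }
    cyclen.push_back(len);
  }

  int b = 0, cprime = 0;
  std::vector<bool> trivial(ncyc, false);
  for (int i = 0; i < ncyc; i++) {
    if (cyclen[i] == 1) trivial[i] = true;
    else { b += cyclen[i]; cprime++; }
  }

  // gray edges: value 2k -- 2k+1, k = 0..n
  int ng = n + 1;
  std::vector<int> glo(ng), ghi(ng), gcyc(ng);
  std::vector<bool> goriented(ng);
  std::vector<bool> cyc_oriented(ncyc, false);
  for (int k = 0; k <= n; k++) {
    int a = pos[2 * k], bb = pos[2 * k + 1];
    if (a > bb) std::swap(a, bb);
    glo[k] = a; ghi[k] = bb;
    gcyc[k] = cyc[a];
    goriented[k] = (((bb - a) % 2) == 0);
    if (goriented[k]) cyc_oriented[cyc[a]] = true;
  }

  // interleaving graph over non-trivial cycles (union-find)
  std::vector<int> uf(ncyc);
  for (int i = 0; i < ncyc; i++) uf[i] = i;
  std::function<int(int)> find = [&](int x) {
    while (uf[x] != x) { uf[x] = uf[uf[x]]; x = uf[x]; }
    return x;
  };
  for (int e = 0; e < ng; e++) {
    if (trivial[gcyc[e]]) continue;
    for (int f2 = e + 1; f2 < ng; f2++) {
      if (trivial[gcyc[f2]]) continue;
      bool x = (glo[e] < glo[f2] && glo[f2] < ghi[e] && ghi[e] < ghi[f2]) ||
               (glo[f2] < glo[e] && glo[e] < ghi[f2] && ghi[f2] < ghi[e]);
      if (x) uf[find(gcyc[e])] = find(gcyc[f2]);
    }
  }

  // component orientation; unoriented components collect their positions
  std::unordered_map<int, bool> comp_oriented;
  for (int i = 0; i < ncyc; i++) {
    if (trivial[i]) continue;
    int r = find(i);
    auto it = comp_oriented.find(r);
    if (it == comp_oriented.end()) comp_oriented[r] = cyc_oriented[i];
    else it->second = it->second || cyc_oriented[i];
  }
  std::unordered_map<int, int> uidx;  // comp root -> dense unoriented index
  std::vector<UComp> ucomps;
  for (auto& kv : comp_oriented) {
    if (!kv.second) {
      uidx[kv.first] = (int)ucomps.size();
      ucomps.push_back(UComp());
    }
  }
  int h = 0, f = 0;
  if (!ucomps.empty()) {
    for (int p = 0; p < m; p++) {
      int ci = cyc[p];
      if (trivial[ci]) continue;
      int r = find(ci);
      auto it = uidx.find(r);
      if (it != uidx.end()) ucomps[it->second].pos.push_back(p);
    }
    // circular sequence of unoriented component ids over sorted positions
    std::vector<std::pair<int, int>> pts;  // (position, comp)
    for (size_t i = 0; i < ucomps.size(); i++)
      for (int p : ucomps[i].pos) pts.push_back({p, (int)i});
    std::sort(pts.begin(), pts.end());
    std::vector<int> seq(pts.size());
    for (size_t i = 0; i < pts.size(); i++) seq[i] = pts[i].second;

    int K = (int)ucomps.size();
    std::vector<bool> is_hurdle(K, false);
    for (int i = 0; i < K; i++) {
      if (circular_runs(seq, i) == 1) { is_hurdle[i] = true; h++; }
    }
    if (h > 0 && (h % 2) == 1) {
      // fortress iff every hurdle is a superhurdle
      bool all_super = true;
      for (int i = 0; i < K && all_super; i++) {
        if (!is_hurdle[i]) continue;
        // delete component i, recount runs of previously-non-hurdle comps
        std::vector<int> seq2;
        for (int v : seq) if (v != i) seq2.push_back(v);
        bool super = false;
        for (int j = 0; j < K; j++) {
          if (j == i || is_hurdle[j]) continue;
          if (circular_runs(seq2, j) == 1) { super = true; break; }
        }
        if (!super) all_super = false;
      }
      if (all_super && h >= 3) f = 1;
    }
  }

  HPStats st;
  st.b = b; st.c = cprime; st.h = h; st.f = f;
  st.d = b - cprime + h + f;
  return st;
}

// rename p relative to q so that q becomes the identity
static std::vector<int> rename_by(const std::vector<int>& p,
                                  const std::vector<int>& q) {
  int n = (int)p.size();
  std::vector<int> posn(n + 1, 0), sgn(n + 1, 0);
  for (int i = 0; i < n; i++) {
    int v = q[i];
    int a = v > 0 ? v : -v;
    posn[a] = i + 1;
    sgn[a] = v > 0 ? 1 : -1;
  }
  std::vector<int> s(n);
  for (int i = 0; i < n; i++) {
    int v = p[i];
    int a = v > 0 ? v : -v;
    int sg = (v > 0 ? 1 : -1) * sgn[a];
    s[i] = sg * posn[a];
  }
  return s;
}

static void do_reversal(std::vector<int>& s, int i, int j) {
  // 1-based inclusive
  int a = i - 1, b = j - 1;
  while (a < b) {
    int t = s[a];
    s[a] = -s[b];
    s[b] = -t;
    a++; b--;
  }
  if (a == b) s[a] = -s[a];
}

static bool is_identity(const std::vector<int>& s) {
  for (int i = 0; i < (int)s.size(); i++) if (s[i] != i + 1) return false;
  return true;
}

static std::vector<int> as_vec(const IntegerVector& x) {
  return std::vector<int>(x.begin(), x.end());
}

// 64-bit encoding for BFS oracle (n <= 8): 5 bits per element
static uint64_t encode_perm(const std::vector<int>& s) {
  uint64_t code = 0;
  for (size_t i = 0; i < s.size(); i++) {
    int v = s[i];
    uint64_t e = (v > 0) ? (uint64_t)v : ((uint64_t)(-v) | 16u);
    code |= e << (5 * i);
  }
  return code;
}

}  // namespace

// [[Rcpp::export]]
IntegerVector cpp_inversion_stats(IntegerVector p, IntegerVector q) {
  std::vector<int> s = rename_by(as_vec(p), as_vec(q));
  HPStats st = hp_stats(s);
  return IntegerVector::create(
      Named("distance") = st.d, Named("breakpoints") = st.b,
      Named("cycles") = st.c, Named("hurdles") = st.h,
      Named("fortress") = st.f);
}

// [[Rcpp::export]]
int cpp_inversion_distance(IntegerVector p, IntegerVector q) {
  std::vector<int> s = rename_by(as_vec(p), as_vec(q));
  return hp_stats(s).d;
}

// [[Rcpp::export]]
NumericMatrix cpp_distance_matrix(IntegerMatrix perms) {
  int k = perms.nrow(), n = perms.ncol();
  NumericMatrix D(k, k);
  std::vector<std::vector<int>> gs(k, std::vector<int>(n));
  for (int i = 0; i < k; i++)
    for (int j = 0; j < n; j++) gs[i][j] = perms(i, j);
  for (int i = 0; i < k; i++) {
    for (int j = i + 1; j < k; j++) {
      std::vector<int> s = rename_by(gs[i], gs[j]);
      double d = hp_stats(s).d;
      D(i, j) = d;
      D(j, i) = d;
    }
  }
  return D;
}

// Greedy parsimonious sorting: at each step apply a reversal that lowers the
// distance by one. Candidates come from oriented gray edges (each defines a
// unique interval); if none is safe, fall back to a lexicographic scan
// (hurdle-merging/cutting steps). Ties: lexicographically smallest (i, j).
// [[Rcpp::export]]
IntegerMatrix cpp_sorting_scenario(IntegerVector p, IntegerVector q) {
  std::vector<int> s = rename_by(as_vec(p), as_vec(q));
  int n = (int)s.size();
  HPStats st = hp_stats(s);
  int d = st.d;
  std::vector<std::pair<int, int>> steps;
  while (d > 0) {
    // recompute gray-edge candidates on current s
    int m = 2 * n + 2;
    std::vector<int> u(m);
    u[0] = 0; u[m - 1] = 2 * n + 1;
    for (int i = 0; i < n; i++) {
      int v = s[i];
      if (v > 0) { u[2 * i + 1] = 2 * v - 1; u[2 * i + 2] = 2 * v; }
      else       { int k2 = -v; u[2 * i + 1] = 2 * k2; u[2 * i + 2] = 2 * k2 - 1; }
    }
    std::vector<int> pos(m);
    for (int p2 = 0; p2 < m; p2++) pos[u[p2]] = p2;
    int best_i = -1, best_j = -1;
    for (int k = 0; k <= n; k++) {
      int a = pos[2 * k], bb = pos[2 * k + 1];
      if (a > bb) std::swap(a, bb);
      if (((bb - a) % 2) != 0) continue;  // unoriented
      if (bb - a < 2) continue;           // adjacency
      int i, j;
      if (a % 2 == 0) { i = a / 2 + 1; j = bb / 2; }
      else            { i = (a + 1) / 2; j = (bb - 1) / 2; }
      if (i < 1 || j > n || i > j) continue;
      do_reversal(s, i, j);
      int d2 = hp_stats(s).d;
      do_reversal(s, i, j);
      if (d2 == d - 1) {
        if (best_i < 0 || i < best_i || (i == best_i && j < best_j)) {
          best_i = i; best_j = j;
        }
      }
    }
    if (best_i < 0) {
      // hurdle case: lexicographic scan for the first improving reversal
      for (int i = 1; i <= n && best_i < 0; i++) {
        for (int j = i; j <= n; j++) {
          do_reversal(s, i, j);
          int d2 = hp_stats(s).d;
          do_reversal(s, i, j);
          if (d2 == d - 1) { best_i = i; best_j = j; break; }
        }
      }
    }
    if (best_i < 0) stop("internal error: no distance-reducing reversal found");
    do_reversal(s, best_i, best_j);
    steps.push_back({best_i, best_j});
    d--;
  }
  IntegerMatrix out((int)steps.size(), 2);
  for (size_t i = 0; i < steps.size(); i++) {
    out(i, 0) = steps[i].first;
    out(i, 1) = steps[i].second;
  }
  return out;
}

// BFS over the reversal graph from p until q (independent oracle; no
// breakpoint-graph theory). Returns -1 when q is not reached within max_d.
// [[Rcpp::export]]
int cpp_brute_force_distance(IntegerVector p, IntegerVector q, int max_d) {
  std::vector<int> s = rename_by(as_vec(p), as_vec(q));
  int n = (int)s.size();
  if (n > 8) stop("brute-force oracle limited to n <= 8");
  if (is_identity(s)) return 0;
  std::unordered_map<uint64_t, int> dist;
  std::queue<uint64_t> fifo;
  std::vector<int> id(n);
  for (int i = 0; i < n; i++) id[i] = i + 1;
  uint64_t start = encode_perm(s), goal = encode_perm(id);
  dist[start] = 0;
  fifo.push(start);
  while (!fifo.empty()) {
    uint64_t code = fifo.front();
    fifo.pop();
    int dcur = dist[code];
    if (dcur >= max_d) continue;
    std::vector<int> cur(n);
    for (int i = 0; i < n; i++) {
      int e = (int)((code >> (5 * i)) & 31u);
      cur[i] = (e & 16) ? -(e & 15) : e;
    }
    for (int i = 1; i <= n; i++) {
      for (int j = i; j <= n; j++) {
        std::vector<int> nxt = cur;
        do_reversal(nxt, i, j);
        uint64_t nc = encode_perm(nxt);
        if (nc == goal) return dcur + 1;
        if (dist.find(nc) == dist.end()) {
          dist[nc] = dcur + 1;
          fifo.push(nc);
        }
      }
    }
  }
  return -1;
}

// Full BFS distance table from the identity for all signed permutations of
// size n (n <= 7). Index = lehmer_rank(|perm|) * 2^n + sign bits (bit i set
// when element at position i is negative). Used by exhaustive oracle tests.
// [[Rcpp::export]]
IntegerVector cpp_bfs_distance_table(int n) {
  if (n < 1 || n > 7) stop("table supported for 1 <= n <= 7");
  long fact = 1;
  for (int i = 2; i <= n; i++) fact *= i;
  long nstates = fact << n;
  std::vector<uint8_t> dist(nstates, 255);

  auto rank_of = [&](const std::vector<int>& s) -> long {
    long r = 0;
    long f = fact;
    std::vector<int> abs_(n);
    for (int i = 0; i < n; i++) abs_[i] = (s[i] > 0 ? s[i] : -s[i]);
    for (int i = 0; i < n; i++) {
      f /= (n - i);
      int smaller = 0;
      for (int j = i + 1; j < n; j++) if (abs_[j] < abs_[i]) smaller++;
      r += (long)smaller * f;
    }
    long bits = 0;
    for (int i = 0; i < n; i++) if (s[i] < 0) bits |= (1L << i);
    return (r << n) | bits;
  };

  std::vector<int> id(n);
  for (int i = 0; i < n; i++) id[i] = i + 1;
  std::queue<std::vector<int>> fifo;
  dist[rank_of(id)] = 0;
  fifo.push(id);
  while (!fifo.empty()) {
    std::vector<int> cur = fifo.front();
    fifo.pop();
    int dcur = dist[rank_of(cur)];
    for (int i = 1; i <= n; i++) {
      for (int j = i; j <= n; j++) {
        std::vector<int> nxt = cur;
        do_reversal(nxt, i, j);
        long r = rank_of(nxt);
        if (dist[r] == 255) {
          dist[r] = (uint8_t)(dcur + 1);
          fifo.push(nxt);
        }
      }
    }
  }
  IntegerVector out(nstates);
  for (long i = 0; i < nstates; i++) out[i] = dist[i];
  return out;
}

// [[Rcpp::export]]
double cpp_perm_table_index(IntegerVector p, IntegerVector q) {
  // index of rename_by(p, q) in the cpp_bfs_distance_table(n) vector (0-based)
  std::vector<int> s = rename_by(as_vec(p), as_vec(q));
  int n = (int)s.size();
  long fact = 1;
  for (int i = 2; i <= n; i++) fact *= i;
  long r = 0, f = fact;
  std::vector<int> abs_(n);
  for (int i = 0; i < n; i++) abs_[i] = (s[i] > 0 ? s[i] : -s[i]);
  for (int i = 0; i < n; i++) {
    f /= (n - i);
    int smaller = 0;
    for (int j = i + 1; j < n; j++) if (abs_[j] < abs_[i]) smaller++;
    r += (long)smaller * f;
  }
  long bits = 0;
  for (int i = 0; i < n; i++) if (s[i] < 0) bits |= (1L << i);
  return (double)((r << n) | bits);
}

// Best single reversal of `g` minimizing the summed inversion distance to the
// rows of `others`; ties broken by smaller interval length then lexicographic.
// Returns (i, j, total_after). Used by the MGR-like greedy heuristic.
// [[Rcpp::export]]
IntegerVector cpp_best_reversal(IntegerVector g, IntegerMatrix others) {
  std::vector<int> cur = as_vec(g);
  int n = (int)cur.size();
  int k = others.nrow();
  std::vector<std::vector<int>> os(k, std::vector<int>(n));
  for (int a = 0; a < k; a++)
    for (int b = 0; b < n; b++) os[a][b] = others(a, b);
  long best_total = -1;
  int best_i = -1, best_j = -1, best_len = n + 1;
  for (int i = 1; i <= n; i++) {
    for (int j = i; j <= n; j++) {
      do_reversal(cur, i, j);
      long tot = 0;
      for (int a = 0; a < k; a++) {
        std::vector<int> s = rename_by(cur, os[a]);
        tot += hp_stats(s).d;
      }
      do_reversal(cur, i, j);
      int len = j - i + 1;
      if (best_total < 0 || tot < best_total ||
          (tot == best_total && (len < best_len ||
            (len == best_len && (i < best_i || (i == best_i && j < best_j)))))) {
        best_total = tot; best_i = i; best_j = j; best_len = len;
      }
    }
  }
  return IntegerVector::create(Named("i") = best_i, Named("j") = best_j,
                               Named("total") = (int)best_total);
}

// [[Rcpp::export]]
IntegerVector cpp_apply_reversals(IntegerVector p, IntegerMatrix steps) {
  std::vector<int> s = as_vec(p);
  for (int r = 0; r < steps.nrow(); r++) do_reversal(s, steps(r, 0), steps(r, 1));
  return IntegerVector(s.begin(), s.end());
}
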