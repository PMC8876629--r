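// Earley chart parser for the pseudoknot grammar family, plus the
// sliding-window scanner used by the grammar detection engine.
//
// Symbol encoding (fixed by the R-side encoder): terminals are codes 0..3
// (A, U, C, G in that order), nonterminals are codes >= 4.  Rule ids are
// 0-based and dense; an augmented rule Start -> S with id = nrules is added
// internally so acceptance is "completed augmented rule, origin 0, in the
// final set".
//
// The window scan exploits that Earley charts are prefix-incremental: the
// chart for a suffix starting at position a contains, in set k, exactly the
// states of the chart for the window [a, a+k-1].  One chart per start
// therefore serves every window end, and all decompositions are read off
// the completed L / D constituents of that single chart.

#include <Rcpp.h>
#include <vector>
#include <array>
#include <cstring>

using namespace Rcpp;

namespace {

const int NT_BASE = 4;   // first nonterminal code
const int MAX_RHS = 8;   // dot positions per rule (rhs length <= 7)

struct Grammar {
  std::vector<int> lhs;                 // per rule (augmented rule appended)
  std::vector<std::vector<int>> rhs;
  int start;                            // code of S
  int nsym;                             // codes 0..nsym-1 are user symbols
  int nrules;                           // user rules (excl. augmented)
  int aug;                              // id of the augmented rule
  std::vector<std::vector<int>> by_lhs; // nonterminal code -> rule ids
};

Grammar make_grammar(const IntegerVector& lhs, const List& rhs,
                     int start, int nsym) {
  Grammar g;
  g.nrules = lhs.size();
  g.lhs.assign(lhs.begin(), lhs.end());
  g.rhs.resize(g.nrules + 1);
  for (int r = 0; r < g.nrules; ++r) {
    IntegerVector v = rhs[r];
    g.rhs[r].assign(v.begin(), v.end());
  }
  g.start = start;
  g.nsym = nsym;
  g.aug = g.nrules;
  g.lhs.push_back(nsym);                // virtual Start symbol, code nsym
  g.rhs[g.aug] = std::vector<int>(1, start);
  g.by_lhs.assign(nsym + 1, std::vector<int>());
  for (int r = 0; r <= g.nrules; ++r) g.by_lhs[g.lhs[r]].push_back(r);
  return g;
}

struct State { int rule, dot, origin; };

// Reusable chart workspace.  Duplicate detection uses generation-stamped
// arrays (cleared by bumping `gen`, not by memset), and each set keeps a
// bucket of state indices per awaited nonterminal so the Completer touches
// only the states that can actually advance.
struct Chart {
  const Grammar* g;
  int cap;                              // max sets = max input length + 1
  int kinds;                            // (nrules + 1) * MAX_RHS
  int nnt;                              // nonterminal count (incl. Start)
  int n;                                // current input length
  std::vector<std::vector<State>> sets;
  std::vector<std::vector<std::vector<int>>> want;  // [set][nt] -> indices
  std::vector<uint16_t> seen;           // [set * kinds + kind] * cap + origin
  uint16_t gen;

  void init(const Grammar& gr, int max_n) {
    g = &gr;
    cap = max_n + 1;
    kinds = (gr.nrules + 1) * MAX_RHS;
    nnt = gr.nsym + 1 - NT_BASE;
    sets.assign(cap, std::vector<State>());
    want.assign(cap, std::vector<std::vector<int>>(nnt));
    seen.assign((size_t)cap * kinds * cap, 0);
    gen = 0;
  }

  void reset(int len) {
    n = len;
    if (++gen == 0) {                   // stamp wrap: hard clear
      std::fill(seen.begin(), seen.end(), 0);
      gen = 1;
    }
    for (int i = 0; i <= n; ++i) {
      sets[i].clear();
      for (int s = 0; s < nnt; ++s) want[i][s].clear();
    }
  }

  bool add(int i, int rule, int dot, int origin) {
    size_t key = ((size_t)i * kinds + rule * MAX_RHS + dot) * cap + origin;
    if (seen[key] == gen) return false;
    seen[key] = gen;
    const std::vector<int>& r = g->rhs[rule];
    if (dot < (int)r.size() && r[dot] >= NT_BASE)
      want[i][r[dot] - NT_BASE].push_back((int)sets[i].size());
    State s = {rule, dot, origin};
    sets[i].push_back(s);
    return true;
  }
};

// Chart closure under Predictor/Scanner/Completer.  Each set is re-scanned
// to a fixpoint so that completions of epsilon-deriving nonterminals (D, K,
// N, ...) inside the current set are not missed: the printed loop "for each
// state in Sets[i]" over a growing set implies exactly this.
void run_earley(const Grammar& g, const int* u, int n, Chart& ch) {
  ch.reset(n);
  ch.add(0, g.aug, 0, 0);
  for (int i = 0; i <= n; ++i) {
    bool changed = true;
    while (changed) {
      changed = false;
      for (size_t k = 0; k < ch.sets[i].size(); ++k) {
        const State st = ch.sets[i][k];
        const std::vector<int>& r = g.rhs[st.rule];
        if (st.dot < (int)r.size()) {
          const int sym = r[st.dot];
          if (sym >= NT_BASE) {                        // Predictor
            const std::vector<int>& prs = g.by_lhs[sym];
            for (size_t p = 0; p < prs.size(); ++p)
              if (ch.add(i, prs[p], 0, i)) changed = true;
          } else if (i < n && u[i] == sym) {           // Scanner
            ch.add(i + 1, st.rule, st.dot + 1, st.origin);
          }
        } else {                                       // Completer
          const int A = g.lhs[st.rule] - NT_BASE;
          // bucket may grow and reallocate while we walk it (origin == i):
          // index through the chart each iteration
          for (size_t m = 0; m < ch.want[st.origin][A].size(); ++m) {
            const State s2 = ch.sets[st.origin][ch.want[st.origin][A][m]];
            if (ch.add(i, s2.rule, s2.dot + 1, s2.origin)) changed = true;
          }
        }
      }
    }
  }
}

}  // namespace

// [[Rcpp::export]]
List cpp_earley_chart(IntegerVector lhs, List rhs, int start, int nsym,
                      IntegerVector input) {
  Grammar g = make_grammar(lhs, rhs, start, nsym);
  std::vector<int> u(input.begin(), input.end());
  const int n = (int)u.size();
  Chart ch;
  ch.init(g, n);
  run_earley(g, u.data(), n, ch);
  List out(n + 1);
  CharacterVector cn = CharacterVector::create("rule", "dot", "origin");
  for (int i = 0; i <= n; ++i) {
    const std::vector<State>& s = ch.sets[i];
    IntegerMatrix m((int)s.size(), 3);
    for (int k = 0; k < (int)s.size(); ++k) {
      m(k, 0) = s[k].rule; m(k, 1) = s[k].dot; m(k, 2) = s[k].origin;
    }
    colnames(m) = cn;
    out[i] = m;
  }
  return out;
}

// Scan all windows [a, b] with a in `starts` (1-based) and b from
// a + min_window - 1 to n.  For each start one suffix chart is built; its
// set k holds exactly the states of the window of length k, so acceptance
// and the (rule, l1, d) decompositions of every window end are read off
// that single chart.  Returns (i1, i2, j1, j2, rule_id) rows, 1-based.
// [[Rcpp::export]]
IntegerMatrix cpp_scan_starts(IntegerVector lhs, List rhs, int start,
                              int nsym, IntegerVector input,
                              IntegerVector starts, int min_window,
                              int max_dd) {
  Grammar g = make_grammar(lhs, rhs, start, nsym);
  std::vector<int> full(input.begin(), input.end());
  const int n = (int)full.size();
  Chart ch;
  ch.init(g, n);

  // S-rule letter tuples (x, y, z, w) in rule-id order, plus L / D codes
  const std::vector<int>& srules = g.by_lhs[g.start];
  const int ns = (int)srules.size();
  std::vector<std::array<int,4>> letters(ns);
  for (int r = 0; r < ns; ++r) {
    const std::vector<int>& rr = g.rhs[srules[r]];
    std::array<int,4> a4 = {{rr[0], rr[2], rr[4], rr[6]}};
    letters[r] = a4;
  }
  const int Lc = g.rhs[srules[0]][1];
  const int Dc = g.rhs[srules[0]][3];

  const int cap = n + 1;
  std::vector<char> Ls((size_t)cap * cap), Ds((size_t)cap * cap), acc(cap);
  std::vector<int> i1v, i2v, j1v, j2v, rv;

  for (int si = 0; si < starts.size(); ++si) {
    const int a = starts[si];                  // 1-based suffix start
    const int m = n - a + 1;                   // suffix length
    if (m < min_window) continue;
    const int* u = full.data() + (a - 1);
    run_earley(g, u, m, ch);

    std::memset(Ls.data(), 0, (size_t)(m + 1) * cap);
    std::memset(Ds.data(), 0, (size_t)(m + 1) * cap);
    std::memset(acc.data(), 0, m + 1);
    for (int k = 0; k <= m; ++k)
      for (size_t s = 0; s < ch.sets[k].size(); ++s) {
        const State& st = ch.sets[k][s];
        if (st.dot != (int)g.rhs[st.rule].size()) continue;
        if (st.rule == g.aug) { if (st.origin == 0) acc[k] = 1; continue; }
        const int A = g.lhs[st.rule];
        if (A == Lc) Ls[(size_t)st.origin * cap + k] = 1;
        else if (A == Dc) Ds[(size_t)st.origin * cap + k] = 1;
      }

    for (int k = min_window; k <= m; ++k) {    // window [a, a + k - 1]
      if (!acc[k]) continue;
      for (int r = 0; r < ns; ++r) {
        if (u[0] != letters[r][0] || u[k - 1] != letters[r][3]) continue;
        for (int l1 = 1; l1 <= k - 5; ++l1) {
          const int py = 1 + l1;               // 0-based position of y
          if (!Ls[(size_t)1 * cap + py]) continue;
          if (u[py] != letters[r][1]) continue;
          for (int d = 0; d <= max_dd; ++d) {
            const int pz = py + 1 + d;         // 0-based position of z
            if (pz > k - 3) break;             // l2 must be nonempty
            if (!Ds[(size_t)(py + 1) * cap + pz]) continue;
            if (u[pz] != letters[r][2]) continue;
            if (!Ls[(size_t)(pz + 1) * cap + (k - 1)]) continue;
            i1v.push_back(a);
            i2v.push_back(a + py);
            j1v.push_back(a + pz);
            j2v.push_back(a + k - 1);
            rv.push_back(r);
          }
        }
      }
    }
  }

  IntegerMatrix out((int)rv.size(), 5);
  for (int k = 0; k < (int)rv.size(); ++k) {
    out(k, 0) = i1v[k]; out(k, 1) = i2v[k]; out(k, 2) = j1v[k];
    out(k, 3) = j2v[k]; out(k, 4) = rv[k];
  }
  colnames(out) = CharacterVector::create("i1", "i2", "j1", "j2", "rule_id");
  return out;
}
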