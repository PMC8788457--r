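#include <Rcpp.h>
using namespace Rcpp;

// Intermolecular duplex minimum free energy by dynamic programming.
// Bases encoded 1=A, 2=C, 3=G, 4=U (0 = unknown, never pairs).
// Pair types 1=AU, 2=UA, 3=CG, 4=GC, 5=GU, 6=UG; 0 = not pairable.

static inline int pair_type(int x, int y) {
  if (x == 1 && y == 4) return 1;
  if (x == 4 && y == 1) return 2;
  if (x == 2 && y == 3) return 3;
  if (x == 3 && y == 2) return 4;
  if (x == 3 && y == 4) return 5;
  if (x == 4 && y == 3) return 6;
  return 0;
}

static inline bool weak_end(int pt) {           // AU/UA/GU/UG closing pair
  return pt == 1 || pt == 2 || pt == 5 || pt == 6;
}

// C[i][j]: minimum energy of a duplex whose 3'-most pair (in a) is (i, j),
// including the initiation term and the terminal penalty at the duplex's
// 5'-most pair, but not the terminal penalty at (i, j) itself.
// Pairs increase in a-position and decrease in b-position (antiparallel,
// no intramolecular structure, no pseudoknots).  Loop sides are capped at
// max_loop unpaired bases.
// [[Rcpp::export(name = ".duplex_dp")]]
List duplex_dp(IntegerVector a, IntegerVector b, NumericMatrix stack,
               double init, double term_au,
               double bulge_open, double bulge_ext,
               double intl_open, double intl_ext, int max_loop) {
  const double INF = 1e30, EPS = 1e-7;
  int n = a.size(), m = b.size();
  std::vector<double> C((size_t)n * m, INF);
  std::vector<int> NP((size_t)n * m, 0), PI((size_t)n * m, -1),
                   PJ((size_t)n * m, -1), PT((size_t)n * m, 0);
  for (int i = 0; i < n; ++i) {
    for (int j = m - 1; j >= 0; --j) {
      int pt = pair_type(a[i], b[j]);
      size_t ij = (size_t)i * m + j;
      PT[ij] = pt;
      if (!pt) continue;
      double best = init + (weak_end(pt) ? term_au : 0.0);
      int bestnp = 1, bpi = -1, bpj = -1;
      int ilo = std::max(0, i - 1 - max_loop);
      int jhi = std::min(m - 1, j + 1 + max_loop);
      for (int i2 = ilo; i2 <= i - 1; ++i2) {
        for (int j2 = j + 1; j2 <= jhi; ++j2) {
          size_t i2j2 = (size_t)i2 * m + j2;
          if (C[i2j2] >= INF / 2) continue;
          int da = i - i2 - 1, db = j2 - j - 1;
          double cost;
          if (da == 0 && db == 0)
            cost = stack(PT[i2j2] - 1, pt - 1);
          else if (da == 0 || db == 0)
            cost = bulge_open + bulge_ext * (da + db);
          else
            cost = intl_open + intl_ext * (da + db);
          double cand = C[i2j2] + cost;
          int np = NP[i2j2] + 1;
          bool better = cand < best - EPS;
          if (!better && std::fabs(cand - best) <= EPS) {
            if (np > bestnp) better = true;
            else if (np == bestnp &&
                     (i2 < bpi || (i2 == bpi && j2 > bpj)))
              better = true;
          }
          if (better) {
            best = cand; bestnp = np; bpi = i2; bpj = j2;
          }
        }
      }
      C[ij] = best; NP[ij] = bestnp; PI[ij] = bpi; PJ[ij] = bpj;
    }
  }
  double bestdg = INF;
  int bestnp = 0, bi = -1, bj = -1;
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < m; ++j) {
      size_t ij = (size_t)i * m + j;
      if (C[ij] >= INF / 2) continue;
      double dg = C[ij] + (weak_end(PT[ij]) ? term_au : 0.0);
      bool better = dg < bestdg - EPS;
      if (!better && std::fabs(dg - bestdg) <= EPS) {
        if (NP[ij] > bestnp) better = true;
        else if (NP[ij] == bestnp && (i < bi || (i == bi && j > bj)))
          better = true;
      }
      if (better) { bestdg = dg; bestnp = NP[ij]; bi = i; bj = j; }
    }
  }
  if (bi < 0)
    return List::create(_["dg"] = R_PosInf,
                        _["a_pos"] = IntegerVector(0),
                        _["b_pos"] = IntegerVector(0));
  std::vector<int> ai, bjv;
  int ci = bi, cj = bj;
  while (ci >= 0) {
    ai.push_back(ci + 1); bjv.push_back(cj + 1);
    size_t ij = (size_t)ci * m + cj;
    int ni = PI[ij], nj = PJ[ij];
    ci = ni; cj = nj;
  }
  std::reverse(ai.begin(), ai.end());
  std::reverse(bjv.begin(), bjv.end());
  return List::create(_["dg"] = bestdg,
                      _["a_pos"] = wrap(ai), _["b_pos"] = wrap(bjv));
}
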