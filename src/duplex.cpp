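#include <Rcpp.h>
using namespace Rcpp;

// Intermolecular RNA-RNA duplex energetics. The sRNA is read 5'->3' and pairs
// antiparallel with the mRNA, so consecutive sRNA positions pair with
// decreasing mRNA positions. Pair codes (sRNA base x mRNA base):
//   1=AU 2=UA 3=GC 4=CG 5=GU 6=UG, 0 = cannot pair.
// stack66(p, q) is the stacking free energy (kcal/mol) of pair q added 3' (on
// the sRNA) of pair p.

static inline int pair_code(int a, int b) {
  if (a == 0 && b == 3) return 1;
  if (a == 3 && b == 0) return 2;
  if (a == 2 && b == 1) return 3;
  if (a == 1 && b == 2) return 4;
  if (a == 2 && b == 3) return 5;
  if (a == 3 && b == 2) return 6;
  return 0;
}

// [[Rcpp::export(name = ".duplex_dp_cpp")]]
List duplex_dp_cpp(IntegerVector s, IntegerVector m, NumericMatrix stack66,
                   double init_energy, double bulge_penalty, int max_span,
                   int max_bulge) {
  int n = s.size(), mm = m.size();
  const double INF = 1e9;
  NumericMatrix H(n, mm);
  IntegerMatrix I0(n, mm), J1(n, mm);  // span anchors: first sRNA pos, last (max) mRNA pos
  IntegerMatrix BI(n, mm), BJ(n, mm);  // backpointers (previous paired cell), -1 = start
  std::fill(H.begin(), H.end(), INF);
  double best = INF;
  int bi = -1, bj = -1;
  for (int i = 0; i < n; ++i) {
    for (int j = mm - 1; j >= 0; --j) {
      int pc = pair_code(s[i], m[j]);
      if (pc == 0) continue;
      double h = 0.0;  // open a new duplex at (i, j)
      int i0 = i, j1 = j, pbi = -1, pbj = -1;
      for (int di = 1; di <= 1 + max_bulge; ++di) {
        for (int dj = 1; dj <= 1 + max_bulge; ++dj) {
          int bulge = (di - 1) + (dj - 1);
          if (bulge > max_bulge) continue;
          int pi = i - di, pj = j + dj;
          if (pi < 0 || pj >= mm) continue;
          if (H(pi, pj) >= INF) continue;
          if (i - I0(pi, pj) + 1 > max_span) continue;
          if (J1(pi, pj) - j + 1 > max_span) continue;
          int ppc = pair_code(s[pi], m[pj]);
          double step = (bulge == 0) ? stack66(ppc - 1, pc - 1)
                                     : bulge_penalty * bulge;
          double cand = H(pi, pj) + step;
          if (cand < h) {
            h = cand;
            i0 = I0(pi, pj);
            j1 = J1(pi, pj);
            pbi = pi;
            pbj = pj;
          }
        }
      }
      H(i, j) = h;
      I0(i, j) = i0;
      J1(i, j) = j1;
      BI(i, j) = pbi;
      BJ(i, j) = pbj;
      if (h < best) {
        best = h;
        bi = i;
        bj = j;
      }
    }
  }
  if (bi < 0) return List::create(_["energy"] = NA_REAL);
  return List::create(
      _["energy"] = best + init_energy,
      _["srna_start"] = I0(bi, bj) + 1, _["srna_end"] = bi + 1,
      _["mrna_start"] = bj + 1, _["mrna_end"] = J1(bi, bj) + 1);
}

// Best duplex anchored on a perfect Watson-Crick complementary run of at
// least seed_len pairs; the duplex is the maximal perfect run containing the
// seed, truncated to the best window of at most max_span pairs.
// [[Rcpp::export(name = ".seed_extend_cpp")]]
List seed_extend_cpp(IntegerVector s, IntegerVector m, NumericMatrix stack66,
                     double init_energy, int seed_len, int max_span) {
  int n = s.size(), mm = m.size();
  IntegerMatrix R(n, mm);
  double best = 0.0;
  int b_si = -1, b_se = -1, b_ms = -1, b_me = -1;
  for (int i = 0; i < n; ++i) {
    for (int j = mm - 1; j >= 0; --j) {
      int pc = pair_code(s[i], m[j]);
      if (pc == 0 || pc > 4) { R(i, j) = 0; continue; }  // WC only
      int prev = (i > 0 && j < mm - 1) ? R(i - 1, j + 1) : 0;
      R(i, j) = prev + 1;
      // maximal run test: cannot extend past (i, j)
      bool maximal = (i == n - 1) || (j == 0);
      if (!maximal) {
        int nxt = pair_code(s[i + 1], m[j - 1]);
        maximal = (nxt == 0 || nxt > 4);
      }
      if (!maximal || R(i, j) < seed_len) continue;
      int L = R(i, j);           // run of L pairs ending at (i, j)
      int i1 = i - L + 1;        // run start on sRNA
      // stack energies along the run (L - 1 stacks)
      std::vector<double> st(L - 1);
      for (int k = 0; k < L - 1; ++k) {
        int p1 = pair_code(s[i1 + k], m[j + L - 1 - k]);
        int p2 = pair_code(s[i1 + k + 1], m[j + L - 2 - k]);
        st[k] = stack66(p1 - 1, p2 - 1);
      }
      int W = std::min(L, max_span);  // window of W pairs
      double sum = 0.0;
      for (int k = 0; k < W - 1; ++k) sum += st[k];
      double wbest = sum;
      int woff = 0;
      for (int off = 1; off + W <= L; ++off) {
        sum += st[off + W - 2] - st[off - 1];
        if (sum < wbest) { wbest = sum; woff = off; }
      }
      if (wbest < best) {
        best = wbest;
        b_si = i1 + woff + 1;
        b_se = i1 + woff + W;
        b_me = j + L - 1 - woff + 1;
        b_ms = b_me - W + 1;
      }
    }
  }
  if (b_si < 0) return List::create(_["energy"] = NA_REAL);
  return List::create(
      _["energy"] = best + init_energy,
      _["srna_start"] = b_si, _["srna_end"] = b_se,
      _["mrna_start"] = b_ms, _["mrna_end"] = b_me);
}
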