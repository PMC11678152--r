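#include <Rcpp.h>
using namespace Rcpp;

// Base codes used throughout the package: A=0, C=1, G=2, U/T=3, other=-1.
// Pair energies follow the simplified base-pair model: GC/CG, AU/UA, GU/UG.

static inline double pair_energy(int a, int b, double e_gc, double e_au,
                                 double e_gu) {
  if (a < 0 || b < 0) return 1.0;  // sentinel > 0: not pairable
  if ((a == 2 && b == 1) || (a == 1 && b == 2)) return e_gc;
  if ((a == 0 && b == 3) || (a == 3 && b == 0)) return e_au;
  if ((a == 2 && b == 3) || (a == 3 && b == 2)) return e_gu;
  return 1.0;
}

// Shared DP over an arbitrary pair-energy matrix E (E(i,j) <= 0 iff i,j may
// pair). Minimum-energy nested structure with >= min_loop unpaired bases in
// hairpin loops. Returns the optimum and the paired positions (1-based).
static List nussinov_dp(const NumericMatrix& E, int min_loop) {
  int n = E.nrow();
  if (n == 0) return List::create(_["mfe"] = 0.0,
                                  _["pairs"] = IntegerMatrix(0, 2));
  NumericMatrix M(n, n);  // zero-initialised
  for (int len = min_loop + 2; len <= n; ++len) {
    for (int i = 0; i + len - 1 < n; ++i) {
      int j = i + len - 1;
      double best = M(i + 1, j);  // i unpaired
      for (int k = i + min_loop + 1; k <= j; ++k) {
        if (E(i, k) > 0) continue;
        double cand = E(i, k);
        if (k - 1 >= i + 1) cand += M(i + 1, k - 1);
        if (k + 1 <= j) cand += M(k + 1, j);
        if (cand < best) best = cand;
      }
      M(i, j) = best;
    }
  }
  // iterative traceback
  std::vector<int> pi, pj;
  std::vector<std::pair<int, int> > stack;
  stack.push_back(std::make_pair(0, n - 1));
  while (!stack.empty()) {
    int i = stack.back().first, j = stack.back().second;
    stack.pop_back();
    if (j - i < min_loop + 1) continue;
    if (M(i, j) == M(i + 1, j)) {
      stack.push_back(std::make_pair(i + 1, j));
      continue;
    }
    for (int k = i + min_loop + 1; k <= j; ++k) {
      if (E(i, k) > 0) continue;
      double cand = E(i, k);
      if (k - 1 >= i + 1) cand += M(i + 1, k - 1);
      if (k + 1 <= j) cand += M(k + 1, j);
      if (cand == M(i, j)) {
        pi.push_back(i + 1);
        pj.push_back(k + 1);
        if (k - 1 >= i + 1) stack.push_back(std::make_pair(i + 1, k - 1));
        if (k + 1 <= j) stack.push_back(std::make_pair(k + 1, j));
        break;
      }
    }
  }
  IntegerMatrix pairs(pi.size(), 2);
  for (size_t r = 0; r < pi.size(); ++r) {
    pairs(r, 0) = pi[r];
    pairs(r, 1) = pj[r];
  }
  return List::create(_["mfe"] = M(0, n - 1), _["pairs"] = pairs);
}

// Stacked-helix variant: a pair contributes energy only when directly
// enclosed by another pair, so a helix of L pairs scores the energies of its
// L-1 inner pairs and isolated pairs score 0. W = optimal over [i..j],
// H = optimal for a helix opened by pair (i, j).
static List nussinov_stack_dp(const NumericMatrix& E, int min_loop) {
  int n = E.nrow();
  if (n == 0) return List::create(_["mfe"] = 0.0,
                                  _["pairs"] = IntegerMatrix(0, 2));
  NumericMatrix W(n, n), H(n, n);
  for (int len = min_loop + 2; len <= n; ++len) {
    for (int i = 0; i + len - 1 < n; ++i) {
      int j = i + len - 1;
      if (E(i, j) <= 0) {
        double h = (j - 1 >= i + 1) ? W(i + 1, j - 1) : 0.0;
        if (j - 1 - (i + 1) > min_loop && E(i + 1, j - 1) <= 0) {
          double ext = E(i + 1, j - 1) + H(i + 1, j - 1);
          if (ext < h) h = ext;
        }
        H(i, j) = h;
      }
      double best = W(i + 1, j);
      for (int k = i + min_loop + 1; k <= j; ++k) {
        if (E(i, k) > 0) continue;
        double cand = H(i, k);
        if (k + 1 <= j) cand += W(k + 1, j);
        if (cand < best) best = cand;
      }
      W(i, j) = best;
    }
  }
  // traceback over both tables
  std::vector<int> pi, pj;
  std::vector<std::pair<std::pair<int, int>, int> > st;  // ((i,j), table 0=W 1=H)
  st.push_back(std::make_pair(std::make_pair(0, n - 1), 0));
  while (!st.empty()) {
    int i = st.back().first.first, j = st.back().first.second;
    int tab = st.back().second;
    st.pop_back();
    if (j - i < min_loop + 1) continue;
    if (tab == 0) {
      if (W(i, j) == W(i + 1, j)) {
        st.push_back(std::make_pair(std::make_pair(i + 1, j), 0));
        continue;
      }
      for (int k = i + min_loop + 1; k <= j; ++k) {
        if (E(i, k) > 0) continue;
        double cand = H(i, k);
        if (k + 1 <= j) cand += W(k + 1, j);
        if (cand == W(i, j)) {
          pi.push_back(i + 1);
          pj.push_back(k + 1);
          st.push_back(std::make_pair(std::make_pair(i, k), 1));
          if (k + 1 <= j)
            st.push_back(std::make_pair(std::make_pair(k + 1, j), 0));
          break;
        }
      }
    } else {
      // helix opened at (i, j): continue stacking or fall back to W inside
      if (j - 1 - (i + 1) > min_loop && E(i + 1, j - 1) <= 0 &&
          H(i, j) == E(i + 1, j - 1) + H(i + 1, j - 1)) {
        pi.push_back(i + 2);
        pj.push_back(j);
        st.push_back(std::make_pair(std::make_pair(i + 1, j - 1), 1));
      } else if (j - 1 >= i + 1) {
        st.push_back(std::make_pair(std::make_pair(i + 1, j - 1), 0));
      }
    }
  }
  IntegerMatrix pairs(pi.size(), 2);
  for (size_t r = 0; r < pi.size(); ++r) {
    pairs(r, 0) = pi[r];
    pairs(r, 1) = pj[r];
  }
  return List::create(_["mfe"] = W(0, n - 1), _["pairs"] = pairs);
}

static NumericMatrix seq_energy_matrix(const IntegerVector& codes,
                                       double e_gc, double e_au, double e_gu,
                                       int min_loop) {
  int n = codes.size();
  NumericMatrix E(n, n);
  std::fill(E.begin(), E.end(), 1.0);
  for (int i = 0; i < n; ++i)
    for (int j = i + min_loop + 1; j < n; ++j)
      E(i, j) = pair_energy(codes[i], codes[j], e_gc, e_au, e_gu);
  return E;
}

// [[Rcpp::export(name = ".fold_stack_cpp")]]
List fold_stack_cpp(IntegerVector codes, double e_gc, double e_au,
                    double e_gu, int min_loop) {
  return nussinov_stack_dp(seq_energy_matrix(codes, e_gc, e_au, e_gu,
                                             min_loop), min_loop);
}

// [[Rcpp::export(name = ".fold_stack_matrix_cpp")]]
List fold_stack_matrix_cpp(NumericMatrix E, int min_loop) {
  return nussinov_stack_dp(E, min_loop);
}

// [[Rcpp::export(name = ".fold_mfe_cpp")]]
List fold_mfe_cpp(IntegerVector codes, double e_gc, double e_au, double e_gu,
                  int min_loop) {
  int n = codes.size();
  NumericMatrix E(n, n);
  std::fill(E.begin(), E.end(), 1.0);
  for (int i = 0; i < n; ++i)
    for (int j = i + min_loop + 1; j < n; ++j)
      E(i, j) = pair_energy(codes[i], codes[j], e_gc, e_au, e_gu);
  return nussinov_dp(E, min_loop);
}

// [[Rcpp::export(name = ".fold_matrix_cpp")]]
List fold_matrix_cpp(NumericMatrix E, int min_loop) {
  return nussinov_dp(E, min_loop);
}

// Consensus pair-energy matrix of an alignment. codes: rows = sequences,
// cols = alignment columns, -1 for gaps. A column pair is pairable when at
// least min_pair_frac of the rows can pair there; its energy is then the
// mean pair energy over all rows (non-pairing rows contribute 0) minus a
// covariance bonus of cov_weight per additional distinct pair type observed
// among the pairing rows (compensatory substitutions support a conserved
// helix).
// [[Rcpp::export(name = ".consensus_energy_cpp")]]
NumericMatrix consensus_energy_cpp(IntegerMatrix codes, double min_pair_frac,
                                   double e_gc, double e_au, double e_gu,
                                   int min_loop, double cov_weight,
                                   double nopair_penalty) {
  int nr = codes.nrow(), n = codes.ncol();
  NumericMatrix E(n, n);
  std::fill(E.begin(), E.end(), 1.0);
  for (int i = 0; i < n; ++i) {
    for (int j = i + min_loop + 1; j < n; ++j) {
      double tot = 0.0;
      int npair = 0;
      int type_count[16] = {0};
      for (int r = 0; r < nr; ++r) {
        int a = codes(r, i), b = codes(r, j);
        double e = pair_energy(a, b, e_gc, e_au, e_gu);
        if (e <= 0) {
          tot += e;
          ++npair;
          ++type_count[a * 4 + b];
        }
      }
      if (npair >= min_pair_frac * nr && npair > 0) {
        // rows that cannot pair penalize the column (alignment
        // inconsistency), RNAalifold-style
        E(i, j) = (tot + nopair_penalty * (nr - npair)) / nr;
        // covariance bonus only for fully consistent columns (every row
        // pairs): compensatory pair types differ from the majority type at
        // BOTH positions (e.g. GC -> CG); single-position wobbles do not
        // count, and inconsistent columns get no bonus
        if (npair == nr) {
          int t0 = 0;
          for (int t = 1; t < 16; ++t)
            if (type_count[t] > type_count[t0]) t0 = t;
          int n_comp = 0;
          for (int t = 0; t < 16; ++t) {
            if (type_count[t] == 0 || t == t0) continue;
            if (t / 4 != t0 / 4 && t % 4 != t0 % 4) ++n_comp;
          }
          E(i, j) -= cov_weight * n_comp;
        }
      }
    }
  }
  return E;
}
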