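// Partition function, base-pair probabilities and stochastic backtracking
// for the bundled stacking + linear-loop-penalty nearest-neighbor model,
// with optional per-position pseudo-energy factors.
//
// Conventions:
//   * positions are 1-based in all tables; matrices are (n+2)x(n+2)
//   * pairfac[i] multiplies Zb(i,j) once per paired endpoint
//     (deigan_paired pseudo-energy mode)
//   * q[i] multiplies every unpaired occurrence of position i
//     (literal_unpaired pseudo-energy mode)
//   * energies in kcal/mol; Boltzmann factors exp(-E/RT)
//
// The decomposition is unambiguous (each structure is generated exactly
// once), which the enumeration-based tests verify to 1e-9.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

struct FoldTables {
  int n;
  double RT;
  std::vector<int> ptype;          // (n+2)^2, 0 = not pairable
  std::vector<double> Zb, M, M1;   // (n+2)^2
  std::vector<double> W, Wr;       // n+2
  std::vector<double> Qpre, Ppre;  // cumulative products of q and cMfac*q
  NumericVector pairfac, q;
  double stackfac[7][7];
  double hinit, hper, iinit, iper, minit, mbr, mper;
  double cMfac;
  double Z;
  int idx(int i, int j) const { return i * (n + 2) + j; }
  bool allowed(int i, int j) const {
    return j - i >= 4 && ptype[idx(i, j)] > 0;
  }
  double qprod(int a, int b) const {  // prod q[a..b], empty if a > b
    if (a > b) return 1.0;
    return Qpre[b] / Qpre[a - 1];
  }
  double mprod(int a, int b) const {  // prod (cMfac*q)[a..b]
    if (a > b) return 1.0;
    return Ppre[b] / Ppre[a - 1];
  }
};

FoldTables build_tables(IntegerVector codes, NumericMatrix stack,
                        NumericVector hairpin, NumericVector internal,
                        NumericVector multi, double RT,
                        NumericVector pairfac, NumericVector q) {
  FoldTables T;
  int n = codes.size();
  T.n = n;
  T.RT = RT;
  T.pairfac = pairfac;
  T.q = q;
  T.hinit = hairpin[0]; T.hper = hairpin[1];
  T.iinit = internal[0]; T.iper = internal[1];
  T.minit = multi[0]; T.mbr = multi[1]; T.mper = multi[2];
  T.cMfac = std::exp(-T.mper / RT);
  for (int a = 1; a <= 6; ++a)
    for (int b = 1; b <= 6; ++b)
      T.stackfac[a][b] = std::exp(-stack(a - 1, b - 1) / RT);

  // pair type codes: CG GC AU UA GU UG -> 1..6 (residues A=1 C=2 G=3 U=4)
  T.ptype.assign((n + 2) * (n + 2), 0);
  auto pt_of = [](int a, int b) {
    int key = a * 10 + b;
    switch (key) {
      case 23: return 1; case 32: return 2; case 14: return 3;
      case 41: return 4; case 34: return 5; case 43: return 6;
      default: return 0;
    }
  };
  for (int i = 1; i <= n; ++i)
    for (int j = i + 1; j <= n; ++j)
      T.ptype[T.idx(i, j)] = pt_of(codes[i - 1], codes[j - 1]);

  T.Qpre.assign(n + 1, 1.0);
  T.Ppre.assign(n + 1, 1.0);
  for (int i = 1; i <= n; ++i) {
    T.Qpre[i] = T.Qpre[i - 1] * q[i - 1];
    T.Ppre[i] = T.Ppre[i - 1] * T.cMfac * q[i - 1];
  }

  T.Zb.assign((n + 2) * (n + 2), 0.0);
  T.M.assign((n + 2) * (n + 2), 0.0);
  T.M1.assign((n + 2) * (n + 2), 0.0);

  for (int span = 4; span <= n - 1; ++span) {
    for (int i = 1; i + span <= n; ++i) {
      int j = i + span;
      // --- Zb(i, j): (i, j) paired ---
      if (T.allowed(i, j)) {
        int u_h = j - i - 1;
        double z = std::exp(-(T.hinit + T.hper * u_h) / RT) * T.qprod(i + 1, j - 1);
        if (T.allowed(i + 1, j - 1)) {
          z += T.stackfac[T.ptype[T.idx(i, j)]][T.ptype[T.idx(i + 1, j - 1)]] *
               T.Zb[T.idx(i + 1, j - 1)];
        }
        for (int k = i + 1; k <= j - 5; ++k) {
          for (int l = k + 4; l <= j - 1; ++l) {
            int u = (k - i - 1) + (j - l - 1);
            if (u < 1 || !T.allowed(k, l)) continue;
            z += std::exp(-(T.iinit + T.iper * u) / RT) *
                 T.qprod(i + 1, k - 1) * T.qprod(l + 1, j - 1) *
                 T.Zb[T.idx(k, l)];
          }
        }
        if (j - i >= 11) {
          double zm = 0.0;
          for (int k = i + 6; k <= j - 5; ++k)
            zm += T.M[T.idx(i + 1, k - 1)] * T.M1[T.idx(k, j - 1)];
          z += std::exp(-(T.minit + T.mbr) / RT) * zm;
        }
        T.Zb[T.idx(i, j)] = z * pairfac[i - 1] * pairfac[j - 1];
      }
      // --- M1(i, j): one branch starting at i, trailing unpaired ---
      {
        double m1 = 0.0;
        for (int l = i + 4; l <= j; ++l)
          if (T.allowed(i, l))
            m1 += T.Zb[T.idx(i, l)] * std::exp(-T.mbr / RT) * T.mprod(l + 1, j);
        T.M1[T.idx(i, j)] = m1;
      }
      // --- M(i, j): >= 1 branch, decomposed by the first branch (k, l) ---
      {
        double m = 0.0;
        for (int k = i; k <= j - 4; ++k) {
          double pre = T.mprod(i, k - 1);
          if (pre == 0.0) continue;
          m += pre * T.M1[T.idx(k, j)];
          for (int l = k + 4; l <= j - 5; ++l) {
            if (!T.allowed(k, l)) continue;
            double rest = T.M[T.idx(l + 1, j)];
            if (rest > 0.0)
              m += pre * T.Zb[T.idx(k, l)] * std::exp(-T.mbr / RT) * rest;
          }
        }
        T.M[T.idx(i, j)] = m;
      }
    }
  }

  // exterior prefix / suffix
  T.W.assign(n + 2, 0.0);
  T.Wr.assign(n + 2, 0.0);
  T.W[0] = 1.0;
  for (int j = 1; j <= n; ++j) {
    double w = T.W[j - 1] * q[j - 1];
    for (int k = 1; k <= j - 4; ++k)
      w += T.W[k - 1] * T.Zb[T.idx(k, j)];
    T.W[j] = w;
  }
  T.Wr[n + 1] = 1.0;
  for (int i = n; i >= 1; --i) {
    double w = q[i - 1] * T.Wr[i + 1];
    for (int l = i + 4; l <= n; ++l)
      w += T.Zb[T.idx(i, l)] * T.Wr[l + 1];
    T.Wr[i] = w;
  }
  T.Z = T.W[n];
  return T;
}

FoldTables tables_from_list(List fold) {
  IntegerVector codes = fold["codes"];
  NumericMatrix stack = fold["stack"];
  FoldTables T = build_tables(codes, stack, fold["hairpin"], fold["internal"],
                              fold["multi"], as<double>(fold["RT"]),
                              fold["pairfac"], fold["q"]);
  return T;
}

}  // namespace

// [[Rcpp::export]]
List cpp_fold(IntegerVector codes, NumericMatrix stack, NumericVector hairpin,
              NumericVector internal, NumericVector multi, double RT,
              NumericVector pairfac, NumericVector q) {
  FoldTables T = build_tables(codes, stack, hairpin, internal, multi, RT,
                              pairfac, q);
  if (!std::isfinite(T.Z) || T.Z <= 0.0)
    stop("partition function overflowed or vanished");
  return List::create(_["codes"] = codes, _["stack"] = stack,
                      _["hairpin"] = hairpin, _["internal"] = internal,
                      _["multi"] = multi, _["RT"] = RT,
                      _["pairfac"] = pairfac, _["q"] = q, _["Z"] = T.Z,
                      _["n"] = T.n);
}

// [[Rcpp::export]]
NumericMatrix cpp_pair_probs(List fold) {
  FoldTables T = tables_from_list(fold);
  int n = T.n;
  NumericMatrix P(n, n);
  if (n < 5) return P;
  double mclose = std::exp(-(T.minit + T.mbr) / T.RT);
  double mbrf = std::exp(-T.mbr / T.RT);
  // X(i,j) = Pb(i,j) / Zb(i,j); processed by decreasing span
  std::vector<double> X((n + 2) * (n + 2), 0.0);
  for (int span = n - 1; span >= 4; --span) {
    for (int k = 1; k + span <= n; ++k) {
      int l = k + span;
      if (!T.allowed(k, l) || T.Zb[T.idx(k, l)] == 0.0) continue;
      double out = T.W[k - 1] * T.Wr[l + 1] / T.Z;
      for (int i = 1; i < k; ++i) {
        for (int j = l + 1; j <= n; ++j) {
          if (!T.allowed(i, j)) continue;
          double x = X[T.idx(i, j)];
          if (x == 0.0) continue;
          double pf = T.pairfac[i - 1] * T.pairfac[j - 1];
          double contrib = 0.0;
          if (i == k - 1 && j == l + 1) {
            contrib += T.stackfac[T.ptype[T.idx(i, j)]][T.ptype[T.idx(k, l)]];
          }
          int u = (k - i - 1) + (j - l - 1);
          if (u >= 1) {
            contrib += std::exp(-(T.iinit + T.iper * u) / T.RT) *
                       T.qprod(i + 1, k - 1) * T.qprod(l + 1, j - 1);
          }
          if (j - i >= 11) {
            double ml = (k - 1 >= i + 1) ? T.M[T.idx(i + 1, k - 1)] : 0.0;
            double mr = (j - 1 >= l + 1) ? T.M[T.idx(l + 1, j - 1)] : 0.0;
            double bracket = ml * T.mprod(l + 1, j - 1) +
                             T.mprod(i + 1, k - 1) * mr + ml * mr;
            contrib += mclose * mbrf * bracket;
          }
          out += x * pf * contrib;
        }
      }
      X[T.idx(k, l)] = out;
      P(k - 1, l - 1) = out * T.Zb[T.idx(k, l)];
    }
  }
  return P;
}

namespace {

struct Task { int mode, i, j; };  // mode: 0=PAIR 1=M 2=M1

void backtrack_one(const FoldTables& T, std::vector<int>& partner) {
  int n = T.n;
  std::fill(partner.begin(), partner.end(), 0);
  std::vector<Task> stack;
  double mbrf = std::exp(-T.mbr / T.RT);
  // exterior
  int j = n;
  while (j >= 1) {
    if (j < 5) { j -= 1; continue; }
    double r = unif_rand() * T.W[j];
    double acc = T.W[j - 1] * T.q[j - 1];
    if (r < acc) { j -= 1; continue; }
    int chosen = -1;
    for (int k = 1; k <= j - 4; ++k) {
      acc += T.W[k - 1] * T.Zb[T.idx(k, j)];
      if (r < acc) { chosen = k; break; }
    }
    if (chosen < 0) {  // numerical slack: take last admissible pair
      for (int k = j - 4; k >= 1; --k)
        if (T.Zb[T.idx(k, j)] > 0.0) { chosen = k; break; }
      if (chosen < 0) { j -= 1; continue; }
    }
    stack.push_back({0, chosen, j});
    j = chosen - 1;
  }
  while (!stack.empty()) {
    Task t = stack.back();
    stack.pop_back();
    int i = t.i; int jj = t.j;
    if (t.mode == 0) {
      partner[i - 1] = jj; partner[jj - 1] = i;
      double tot = T.Zb[T.idx(i, jj)] / (T.pairfac[i - 1] * T.pairfac[jj - 1]);
      double r = unif_rand() * tot;
      int u_h = jj - i - 1;
      double acc = std::exp(-(T.hinit + T.hper * u_h) / T.RT) * T.qprod(i + 1, jj - 1);
      if (r < acc) continue;  // hairpin: nothing inside
      bool done = false;
      if (T.allowed(i + 1, jj - 1)) {
        acc += T.stackfac[T.ptype[T.idx(i, jj)]][T.ptype[T.idx(i + 1, jj - 1)]] *
               T.Zb[T.idx(i + 1, jj - 1)];
        if (r < acc) { stack.push_back({0, i + 1, jj - 1}); continue; }
      }
      for (int k = i + 1; k <= jj - 5 && !done; ++k) {
        for (int l = k + 4; l <= jj - 1; ++l) {
          int u = (k - i - 1) + (jj - l - 1);
          if (u < 1 || !T.allowed(k, l)) continue;
          acc += std::exp(-(T.iinit + T.iper * u) / T.RT) *
                 T.qprod(i + 1, k - 1) * T.qprod(l + 1, jj - 1) *
                 T.Zb[T.idx(k, l)];
          if (r < acc) { stack.push_back({0, k, l}); done = true; break; }
        }
      }
      if (done) continue;
      if (jj - i >= 11) {
        double mclose = std::exp(-(T.minit + T.mbr) / T.RT);
        for (int k = i + 6; k <= jj - 5; ++k) {
          acc += mclose * T.M[T.idx(i + 1, k - 1)] * T.M1[T.idx(k, jj - 1)];
          if (r < acc) {
            stack.push_back({1, i + 1, k - 1});
            stack.push_back({2, k, jj - 1});
            done = true; break;
          }
        }
      }
      if (!done) {
        // numerical slack: fall back to hairpin
        continue;
      }
    } else if (t.mode == 2) {  // M1: one branch starting at i
      double tot = T.M1[T.idx(i, jj)];
      double r = unif_rand() * tot, acc = 0.0;
      int chosen = -1;
      for (int l = i + 4; l <= jj; ++l) {
        if (!T.allowed(i, l)) continue;
        acc += T.Zb[T.idx(i, l)] * mbrf * T.mprod(l + 1, jj);
        if (r < acc) { chosen = l; break; }
      }
      if (chosen < 0)
        for (int l = jj; l >= i + 4; --l)
          if (T.allowed(i, l) && T.Zb[T.idx(i, l)] > 0.0) { chosen = l; break; }
      if (chosen > 0) stack.push_back({0, i, chosen});
    } else {  // M: >= 1 branch, first branch (k, l)
      double tot = T.M[T.idx(i, jj)];
      double r = unif_rand() * tot, acc = 0.0;
      bool done = false;
      for (int k = i; k <= jj - 4 && !done; ++k) {
        double pre = T.mprod(i, k - 1);
        if (pre == 0.0) continue;
        acc += pre * T.M1[T.idx(k, jj)];
        if (r < acc) { stack.push_back({2, k, jj}); done = true; break; }
        for (int l = k + 4; l <= jj - 5; ++l) {
          if (!T.allowed(k, l)) continue;
          double rest = T.M[T.idx(l + 1, jj)];
          if (rest <= 0.0) continue;
          acc += pre * T.Zb[T.idx(k, l)] * mbrf * rest;
          if (r < acc) {
            stack.push_back({0, k, l});
            stack.push_back({1, l + 1, jj});
            done = true; break;
          }
        }
      }
      if (!done) {
        // numerical slack: single branch at first admissible start
        for (int k = i; k <= jj - 4; ++k)
          if (T.M1[T.idx(k, jj)] > 0.0) { stack.push_back({2, k, jj}); break; }
      }
    }
  }
}

}  // namespace

// [[Rcpp::export]]
IntegerMatrix cpp_sample(List fold, int m) {
  FoldTables T = tables_from_list(fold);
  IntegerMatrix out(m, T.n);
  std::vector<int> partner(T.n);
  RNGScope scope;
  for (int s = 0; s < m; ++s) {
    backtrack_one(T, partner);
    for (int i = 0; i < T.n; ++i) out(s, i) = partner[i];
  }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_loop_energies(IntegerMatrix partners, IntegerVector codes,
                                NumericMatrix stack, NumericVector hairpin,
                                NumericVector internal, NumericVector multi) {
  int m = partners.nrow(), n = partners.ncol();
  NumericVector out(m);
  auto pt_of = [](int a, int b) {
    int key = a * 10 + b;
    switch (key) {
      case 23: return 1; case 32: return 2; case 14: return 3;
      case 41: return 4; case 34: return 5; case 43: return 6;
      default: return 0;
    }
  };
  for (int s = 0; s < m; ++s) {
    double e = 0.0;
    for (int i = 1; i <= n; ++i) {
      int j = partners(s, i - 1);
      if (j <= i) continue;
      int t_out = pt_of(codes[i - 1], codes[j - 1]);
      if (t_out == 0) stop("non-pairable residues in sampled pair");
      int kids = 0, unpaired = 0, k = i + 1;
      int first_k = 0, first_l = 0;
      while (k < j) {
        int pk = partners(s, k - 1);
        if (pk > k) {
          if (kids == 0) { first_k = k; first_l = pk; }
          ++kids;
          k = pk + 1;
        } else {
          ++unpaired;
          ++k;
        }
      }
      if (kids == 0) {
        e += hairpin[0] + hairpin[1] * unpaired;
      } else if (kids == 1) {
        if (unpaired == 0) {
          int t_in = pt_of(codes[first_k - 1], codes[first_l - 1]);
          e += stack(t_out - 1, t_in - 1);
        } else {
          e += internal[0] + internal[1] * unpaired;
        }
      } else {
        e += multi[0] + multi[1] * (kids + 1) + multi[2] * unpaired;
      }
    }
    out[s] = e;
  }
  return out;
}
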