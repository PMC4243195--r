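#include <Rcpp.h>
#include <vector>
#include <string>
#include <cmath>
using namespace Rcpp;

// Compact nearest-neighbor RNA energy model ("nn-simple"):
//  - Watson-Crick and G:U pairs; stacking energies from a 6x6 table
//  - hairpin loops:      hairpin_init + hairpin_slope * (L - 3), L >= 3
//  - interior/bulge:     interior_init + interior_slope * u, 1 <= u <= max_loop
//  - multiloops:         ml_init + ml_branch * (branches incl. closing)
//                        + ml_unpaired * u   (linear model)
//  - exterior bases free; duplexes carry no initiation term.
// The same parameter list drives the duplex DP, the Zuker-style fold and
// the McCaskill partition function, so MFE and accessibility are mutually
// consistent.

static const double INF = 1e9;

static inline int bcode(char c) {
  switch (c) {
    case 'A': return 0; case 'C': return 1;
    case 'G': return 2; case 'U': return 3;
    default: return -1;
  }
}

// pair type: CG=0 GC=1 AU=2 UA=3 GU=4 UG=5, -1 if not pairable
static inline int ptype(int x, int y) {
  if (x == 1 && y == 2) return 0;
  if (x == 2 && y == 1) return 1;
  if (x == 0 && y == 3) return 2;
  if (x == 3 && y == 0) return 3;
  if (x == 2 && y == 3) return 4;
  if (x == 3 && y == 2) return 5;
  return -1;
}

struct NNPar {
  NumericMatrix stack;
  double hp_init, hp_slope, int_init, int_slope;
  double ml_init, ml_branch, ml_unpaired, kT;
  int max_loop, min_hairpin;
  explicit NNPar(List p)
      : stack(as<NumericMatrix>(p["stack"])),
        hp_init(as<double>(p["hairpin_init"])),
        hp_slope(as<double>(p["hairpin_slope"])),
        int_init(as<double>(p["interior_init"])),
        int_slope(as<double>(p["interior_slope"])),
        ml_init(as<double>(p["ml_init"])),
        ml_branch(as<double>(p["ml_branch"])),
        ml_unpaired(as<double>(p["ml_unpaired"])),
        kT(as<double>(p["kT"])),
        max_loop(as<int>(p["max_loop"])),
        min_hairpin(as<int>(p["min_hairpin"])) {}
};

static std::vector<int> encode(const std::string& s) {
  std::vector<int> v(s.size());
  for (size_t i = 0; i < s.size(); ++i) v[i] = bcode(s[i]);
  return v;
}

// ---------------------------------------------------------------- duplex ---
// Intermolecular-only MFE of strand a (5'->3') with strand b (5'->3'),
// antiparallel: successive pairs move forward on a and backward on b.
// [[Rcpp::export]]
double cpp_duplex_mfe(std::string sa, std::string sb, List par_) {
  NNPar par(par_);
  std::vector<int> a = encode(sa), b = encode(sb);
  const int n = (int) a.size(), m = (int) b.size();
  // best[i][j]: min energy of a structure whose 3'-most pair on a is (i,j)
  std::vector<double> best(n * m, INF);
  double mfe = 0.0;
  for (int i = 0; i < n; ++i) {
    for (int j = m - 1; j >= 0; --j) {
      int pt = ptype(a[i], b[j]);
      if (pt < 0) continue;
      double e = 0.0;  // structure starting with this pair
      for (int p = i - 1; p >= 0 && (i - p - 1) <= par.max_loop; --p) {
        for (int q = j + 1; q < m; ++q) {
          int u = (i - p - 1) + (q - j - 1);
          if (u > par.max_loop) break;
          double pe = best[p * m + q];
          if (pe >= INF) continue;
          int pt0 = ptype(a[p], b[q]);
          double step = (u == 0) ? par.stack(pt0, pt)
                                 : par.int_init + par.int_slope * u;
          if (pe + step < e) e = pe + step;
        }
      }
      best[i * m + j] = e;
      if (e < mfe) mfe = e;
    }
  }
  return mfe;
}

// ------------------------------------------------------------------ fold ---
// Zuker-style MFE of a single strand with a linear multiloop model.
// mask[i] == TRUE forbids base i from pairing.
// [[Rcpp::export]]
double cpp_fold_mfe(std::string seq, LogicalVector mask, List par_) {
  NNPar par(par_);
  std::vector<int> s = encode(seq);
  const int n = (int) s.size();
  if (n == 0) stop("empty sequence");
  std::vector<double> V(n * n, INF), WM(n * n, INF), WM1(n * n, INF);
  const int mh = par.min_hairpin;

  for (int d = mh + 1; d < n; ++d) {
    for (int i = 0; i + d < n; ++i) {
      int j = i + d;
      // V(i, j)
      double v = INF;
      if (!mask[i] && !mask[j] && ptype(s[i], s[j]) >= 0) {
        int L = j - i - 1;
        v = par.hp_init + par.hp_slope * (L - 3);
        int pt0 = ptype(s[i], s[j]);
        for (int p = i + 1; p <= j - 1 && (p - i - 1) <= par.max_loop; ++p) {
          for (int q = j - 1; q > p; --q) {
            int u = (p - i - 1) + (j - q - 1);
            if (u > par.max_loop) break;
            double in = V[p * n + q];
            if (in >= INF) continue;
            int pt1 = ptype(s[p], s[q]);
            double step = (u == 0) ? par.stack(pt0, pt1)
                                   : par.int_init + par.int_slope * u;
            if (in + step < v) v = in + step;
          }
        }
        for (int k = i + 2; k <= j - 2; ++k) {
          double a = WM[(i + 1) * n + (k - 1)], b = WM1[k * n + (j - 1)];
          if (a < INF && b < INF) {
            double e = par.ml_init + par.ml_branch + a + b;
            if (e < v) v = e;
          }
        }
      }
      V[i * n + j] = v;
      // WM1(i, j): one branch starting exactly at i, tail unpaired
      double w1 = INF;
      for (int l = i + mh + 1; l <= j; ++l) {
        double e = V[i * n + l];
        if (e < INF) {
          e += par.ml_branch + par.ml_unpaired * (j - l);
          if (e < w1) w1 = e;
        }
      }
      WM1[i * n + j] = w1;
      // WM(i, j): >= 1 branch anywhere in [i, j]
      double w = w1;
      if (i + 1 <= j && WM[(i + 1) * n + j] < INF) {
        double e = WM[(i + 1) * n + j] + par.ml_unpaired;
        if (e < w) w = e;
      }
      for (int l = i + mh + 1; l < j; ++l) {
        double e = V[i * n + l];
        double rest = WM[(l + 1) * n + j];
        if (e < INF && rest < INF) {
          e += par.ml_branch + rest;
          if (e < w) w = e;
        }
      }
      WM[i * n + j] = w;
    }
  }
  // shorter spans for WM/WM1 (no V possible but needed as all-unpaired? no:
  // WM requires >= 1 branch, so spans < mh+1 stay INF, handled above)
  std::vector<double> W(n + 1, 0.0);
  for (int j = 0; j < n; ++j) {
    W[j + 1] = W[j];
    for (int i = 0; i <= j - mh - 1; ++i) {
      double v = V[i * n + j];
      if (v < INF && W[i] + v < W[j + 1]) W[j + 1] = W[i] + v;
    }
  }
  return W[n] < 0 ? W[n] : 0.0;
}

// -------------------------------------------------- partition function -----
// McCaskill partition function with a pair-span limit; returns total Q.
// mask[i] == TRUE forbids base i from pairing (it can still sit unpaired in
// any loop), so Q(masked region)/Q(unmasked) is the probability that the
// region is entirely unpaired.
// [[Rcpp::export]]
double cpp_pf(std::string seq, LogicalVector mask, int span, List par_) {
  NNPar par(par_);
  std::vector<int> s = encode(seq);
  const int n = (int) s.size();
  if (n == 0) stop("empty sequence");
  const int mh = par.min_hairpin;
  const double kT = par.kT;
  auto bw = [&](double e) { return std::exp(-e / kT); };

  int sp = span < n ? span : n;
  std::vector<double> QB(n * n, 0.0), QM(n * n, 0.0), QM1(n * n, 0.0);

  for (int d = mh + 1; d <= sp; ++d) {
    for (int i = 0; i + d < n; ++i) {
      int j = i + d;
      double qb = 0.0;
      if (!mask[i] && !mask[j] && ptype(s[i], s[j]) >= 0) {
        int pt0 = ptype(s[i], s[j]);
        qb += bw(par.hp_init + par.hp_slope * (j - i - 1 - 3));
        for (int p = i + 1; p <= j - 1 && (p - i - 1) <= par.max_loop; ++p) {
          for (int q = j - 1; q > p; --q) {
            int u = (p - i - 1) + (j - q - 1);
            if (u > par.max_loop) break;
            double in = QB[p * n + q];
            if (in <= 0.0) continue;
            int pt1 = ptype(s[p], s[q]);
            double step = (u == 0) ? par.stack(pt0, pt1)
                                   : par.int_init + par.int_slope * u;
            qb += bw(step) * in;
          }
        }
        double mlsum = 0.0;
        for (int k = i + 2; k <= j - 2; ++k)
          mlsum += QM[(i + 1) * n + (k - 1)] * QM1[k * n + (j - 1)];
        qb += bw(par.ml_init + par.ml_branch) * mlsum;
      }
      QB[i * n + j] = qb;
    }
    // QM1 and QM on spans up to sp as well (they only live inside pairs)
    for (int i = 0; i + d < n; ++i) {
      int j = i + d;
      double q1 = 0.0;
      for (int l = i + mh + 1; l <= j && (l - i) <= sp; ++l)
        q1 += QB[i * n + l] * bw(par.ml_branch + par.ml_unpaired * (j - l));
      QM1[i * n + j] = q1;
      // QM: i unpaired, or first branch starts at i
      double qm = bw(par.ml_unpaired) * QM[(i + 1) * n + j] + q1;
      for (int l = i + mh + 1; l < j && (l - i) <= sp; ++l)
        qm += QB[i * n + l] * bw(par.ml_branch) * QM[(l + 1) * n + j];
      QM[i * n + j] = qm;
    }
  }
  // QM/QM1 for spans shorter than mh+1 remain 0 (no branch fits); exterior:
  std::vector<double> Q(n + 1, 1.0);
  for (int j = 0; j < n; ++j) {
    double q = Q[j];  // base j unpaired (weight 1)
    for (int i = j - mh - 1; i >= 0 && (j - i) <= sp; --i)
      q += Q[i] * QB[i * n + j];
    Q[j + 1] = q;
  }
  return Q[n];
}
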