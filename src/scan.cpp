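#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Complementarity local alignment of a miRNA (read 3'->5', i.e. reversed)
// against a UTR (5'->3').  Pair scores reward Watson-Crick and G:U wobble
// "matches" between the miRNA base and the UTR base; scores at miRNA seed
// positions are multiplied by seed_scale.  Affine gap penalties.  Multiple
// non-overlapping local maxima are extracted iteratively: best site first,
// its UTR columns are then masked and the DP re-run.

static inline int base_code(char c) {
  switch (c) {
    case 'A': return 0; case 'C': return 1;
    case 'G': return 2; case 'U': return 3;
    default: return -1;
  }
}

// pairing class between a miRNA base and a target (UTR) base:
// 1 G-C, 2 A-U, 3 G-U wobble, 4 mismatch
static inline int pair_class(int m, int u) {
  if ((m == 2 && u == 1) || (m == 1 && u == 2)) return 1;
  if ((m == 0 && u == 3) || (m == 3 && u == 0)) return 2;
  if ((m == 2 && u == 3) || (m == 3 && u == 2)) return 3;
  return 4;
}

// [[Rcpp::export]]
List cpp_scan(std::string mirna, std::string utr, List params) {
  const double s_wc   = as<double>(params["score_wc"]);
  const double s_gu   = as<double>(params["score_gu"]);
  const double s_mm   = as<double>(params["score_mismatch"]);
  double gap_open     = as<double>(params["gap_open"]);
  double gap_extend   = as<double>(params["gap_extend"]);
  const double scale  = as<double>(params["seed_scale"]);
  const int seed_lo   = as<int>(params["seed_lo"]);
  const int seed_hi   = as<int>(params["seed_hi"]);
  const bool scale_gu = as<bool>(params["seed_scale_gu"]);
  const double min_score = as<double>(params["min_score"]);
  const int max_sites = as<int>(params["max_sites"]);

  const double NEG = -1e12;
  if (gap_open < NEG) gap_open = NEG;
  if (gap_extend < NEG) gap_extend = NEG;

  const int m = (int) mirna.size();
  const int n = (int) utr.size();
  std::vector<int> mir(m), utrb(n);
  for (int i = 0; i < m; ++i) mir[i] = base_code(mirna[i]);
  for (int j = 0; j < n; ++j) utrb[j] = base_code(utr[j]);

  // row i (1-based) of the DP corresponds to reversed-miRNA base i,
  // i.e. original miRNA position p = m - i + 1 (p1 = 5' end).
  std::vector<double> pw(m + 1);          // seed weight per row
  std::vector<int> rowbase(m + 1);
  for (int i = 1; i <= m; ++i) {
    int p = m - i + 1;
    rowbase[i] = mir[m - i];
    pw[i] = (p >= seed_lo && p <= seed_hi) ? scale : 1.0;
  }

  std::vector<bool> banned(n + 1, false);
  List out;

  std::vector<double> H((m + 1) * (n + 1), 0.0), E((m + 1) * (n + 1), NEG),
      F((m + 1) * (n + 1), NEG);
  std::vector<unsigned char> TH((m + 1) * (n + 1), 0), TE((m + 1) * (n + 1), 0),
      TF((m + 1) * (n + 1), 0);
  const int W = n + 1;

  for (int iter = 0; iter < max_sites; ++iter) {
    std::fill(H.begin(), H.end(), 0.0);
    std::fill(E.begin(), E.end(), NEG);
    std::fill(F.begin(), F.end(), NEG);
    double best = 0.0; int bi = -1, bj = -1;
    for (int i = 1; i <= m; ++i) {
      for (int j = 1; j <= n; ++j) {
        const int idx = i * W + j;
        // E: gap in miRNA (UTR base j unpaired inside the site)
        double eo = H[idx - 1] + gap_open, ee = E[idx - 1] + gap_extend;
        double ev = (eo >= ee) ? eo : ee;
        TE[idx] = (eo >= ee) ? 0 : 1;
        if (banned[j]) ev = NEG;
        E[idx] = ev;
        // F: gap in UTR (miRNA base opposite a gap)
        double fo = H[idx - W] + gap_open, fe = F[idx - W] + gap_extend;
        double fv = (fo >= fe) ? fo : fe;
        TF[idx] = (fo >= fe) ? 0 : 1;
        F[idx] = fv;
        // H
        int pc = pair_class(rowbase[i], utrb[j - 1]);
        double s = (pc == 1 || pc == 2) ? s_wc : (pc == 3 ? s_gu : s_mm);
        bool wob = (pc == 3);
        double wgt = (wob && !scale_gu) ? 1.0 : pw[i];
        s *= wgt;
        if (banned[j] || rowbase[i] < 0 || utrb[j - 1] < 0) s = NEG;
        double hd = H[idx - W - 1] + s;
        double hv = 0.0; unsigned char th = 0;
        if (hd > hv) { hv = hd; th = 1; }
        if (ev > hv) { hv = ev; th = 2; }
        if (fv > hv) { hv = fv; th = 3; }
        H[idx] = hv; TH[idx] = th;
        if (hv > best) { best = hv; bi = i; bj = j; }
      }
    }
    if (best < min_score || bi < 0) break;

    // traceback
    std::vector<int> mp, up;  // miRNA original position (0 = gap), utr 0-based (-1 = gap)
    int i = bi, j = bj, state = 0;  // 0=H,1=E,2=F
    while (true) {
      const int idx = i * W + j;
      if (state == 0) {
        unsigned char t = TH[idx];
        if (t == 0) break;
        if (t == 1) { mp.push_back(m - i + 1); up.push_back(j - 1); --i; --j; }
        else if (t == 2) state = 1;
        else state = 2;
      } else if (state == 1) {
        mp.push_back(0); up.push_back(j - 1);
        state = TE[idx] == 0 ? 0 : 1; --j;
      } else {
        mp.push_back(m - i + 1); up.push_back(-1);
        state = TF[idx] == 0 ? 0 : 2; --i;
      }
    }
    std::reverse(mp.begin(), mp.end());
    std::reverse(up.begin(), up.end());
    int u0 = n, u1 = -1;
    for (size_t k = 0; k < up.size(); ++k)
      if (up[k] >= 0) { if (up[k] < u0) u0 = up[k]; if (up[k] > u1) u1 = up[k]; }
    if (u1 < 0) break;
    for (int j2 = u0 + 1; j2 <= u1 + 1; ++j2) banned[j2] = true;
    out.push_back(List::create(
        _["score"] = best, _["utr_start"] = u0, _["utr_end"] = u1 + 1,
        _["mir_pos"] = IntegerVector(mp.begin(), mp.end()),
        _["utr_pos"] = IntegerVector(up.begin(), up.end())));
  }
  return out;
}
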