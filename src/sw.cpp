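#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Affine-gap local alignment (Gotoh) between two nucleotide strings.
// Gap of length L costs gap_open + L * gap_ext (BLAST convention: the first
// gap position pays open + ext). Alongside the score, the alignment origin,
// match count and column count are propagated through the recurrence so no
// traceback matrix is kept: memory is O(n), time O(m*n).
//
// Returns [score, a_start, a_end, b_start, b_end, matches, columns],
// 1-based inclusive endpoints, all zero when no positive-scoring alignment
// exists.

// [[Rcpp::export]]
IntegerVector sw_align_cpp(std::string a, std::string b,
                           int match, int mismatch,
                           int gap_open, int gap_ext) {
  const int m = (int) a.size();
  const int n = (int) b.size();
  IntegerVector out(7);
  if (m == 0 || n == 0) return out;

  const int NEG = -1000000000;
  const int go = gap_open + gap_ext, ge = gap_ext;

  // previous-row H and F with metadata (start a, start b, matches, cols)
  std::vector<int> Hs(n + 1, 0), Ha(n + 1, 0), Hb(n + 1, 0),
                   Hm(n + 1, 0), Hc(n + 1, 0);
  std::vector<int> Fs(n + 1, NEG), Fa(n + 1, 0), Fb(n + 1, 0),
                   Fm(n + 1, 0), Fc(n + 1, 0);

  int best = 0, bsa = 0, bsb = 0, bnm = 0, bnc = 0, bi = 0, bj = 0;

  for (int i = 1; i <= m; ++i) {
    const char ai = a[i - 1];
    // cell (i, 0)
    int dS = Hs[0], dA = Ha[0], dB = Hb[0], dM = Hm[0], dC = Hc[0]; // H[i-1][0]
    Hs[0] = 0; Ha[0] = 0; Hb[0] = 0; Hm[0] = 0; Hc[0] = 0;
    int eS = NEG, eA = 0, eB = 0, eM = 0, eC = 0;
    int hS = 0, hA = 0, hB = 0, hM = 0, hC = 0;  // H[i][j-1]
    for (int j = 1; j <= n; ++j) {
      // E: gap in a (consume b[j]); compare open-from-H vs extend
      int eo = hS - go, ee = eS - ge;
      if (eo >= ee) { eS = eo; eA = hA; eB = hB; eM = hM; eC = hC + 1; }
      else          { eS = ee; eC = eC + 1; }
      // F: gap in b (consume a[i]); Hs[j]/Fs[j] still hold row i-1
      int fo = Hs[j] - go, fe = Fs[j] - ge;
      if (fo >= fe) { Fs[j] = fo; Fa[j] = Ha[j]; Fb[j] = Hb[j];
                      Fm[j] = Hm[j]; Fc[j] = Hc[j] + 1; }
      else          { Fs[j] = fe; Fc[j] = Fc[j] + 1; }
      // diagonal
      bool ism = (ai == b[j - 1]);
      int ds = dS + (ism ? match : mismatch);
      int da = dA, db = dB, dm = dM + (ism ? 1 : 0), dc = dC + 1;
      if (dS == 0 && dC == 0) { da = i; db = j; }
      // save H[i-1][j] as next diagonal before overwriting
      dS = Hs[j]; dA = Ha[j]; dB = Hb[j]; dM = Hm[j]; dC = Hc[j];
      // H = max(0, diag, E, F)
      int s = ds, sa = da, sb = db, sm = dm, sc = dc;
      if (eS > s) { s = eS; sa = eA; sb = eB; sm = eM; sc = eC; }
      if (Fs[j] > s) { s = Fs[j]; sa = Fa[j]; sb = Fb[j];
                       sm = Fm[j]; sc = Fc[j]; }
      if (s <= 0) { s = 0; sa = 0; sb = 0; sm = 0; sc = 0; }
      Hs[j] = s; Ha[j] = sa; Hb[j] = sb; Hm[j] = sm; Hc[j] = sc;
      hS = s; hA = sa; hB = sb; hM = sm; hC = sc;
      if (s > best) { best = s; bsa = sa; bsb = sb; bnm = sm; bnc = sc;
                      bi = i; bj = j; }
    }
  }

  out[0] = best;
  out[1] = bsa; out[2] = bi;
  out[3] = bsb; out[4] = bj;
  out[5] = bnm; out[6] = bnc;
  return out;
}

// Ungapped X-drop extension of an exact seed run. The seed occupies
// a[ai..ai+len-1] == b[bi..bi+len-1] (1-based). Extension proceeds outward
// in both directions, stopping when the running score falls more than
// xdrop below the running maximum. Returns [score, a_start, a_end] of the
// best ungapped segment through the seed.
// [[Rcpp::export]]
IntegerVector ungapped_extend_cpp(std::string a, std::string b,
                                  int ai, int bi, int len,
                                  int match, int mismatch, int xdrop) {
  const int m = (int) a.size();
  const int n = (int) b.size();
  int score = match * len;
  int left = 0, right = 0;

  // rightward
  {
    int s = score, bestv = score, bestext = 0;
    int i = ai + len - 1, j = bi + len - 1; // 1-based last seed pos
    int ext = 0;
    while (i + ext < m && j + ext < n) {
      ext++;
      s += (a[i + ext - 1] == b[j + ext - 1]) ? match : mismatch;
      if (s > bestv) { bestv = s; bestext = ext; }
      if (s < bestv - xdrop) break;
    }
    score = bestv; right = bestext;
  }
  // leftward
  {
    int s = score, bestv = score, bestext = 0;
    int ext = 0;
    while (ai - ext > 1 && bi - ext > 1) {
      ext++;
      s += (a[ai - ext - 1] == b[bi - ext - 1]) ? match : mismatch;
      if (s > bestv) { bestv = s; bestext = ext; }
      if (s < bestv - xdrop) break;
    }
    score = bestv; left = bestext;
  }

  IntegerVector out(3);
  out[0] = score;
  out[1] = ai - left;
  out[2] = ai + len - 1 + right;
  return out;
}
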