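#include <Rcpp.h>
#include <vector>
#include <string>
#include <climits>
using namespace Rcpp;

// Affine gap model: a gap of length k costs open + ext * k (every gapped
// column pays ext; the first additionally pays open).

static const int NEG = INT_MIN / 4;

// Banded Smith-Waterman around a fixed diagonal.
//
// Diagonal d = j - i (0-based subject index minus query index); only cells
// with d in [d0 - band, d0 + band] are computed.  Returns the best local
// alignment within the band with 0-based half-open coordinates.
// [[Rcpp::export(name = ".c_banded_sw")]]
List c_banded_sw(std::string q, std::string s, int d0, int band,
                 int match, int mismatch, int gap_open, int gap_ext) {
  int n = q.size(), m = s.size();
  int W = 2 * band + 1;
  // H/E/F: (n+1) rows, W diag-offset columns; k = d - (d0 - band)
  std::vector<int> H((n + 1) * W, NEG), E((n + 1) * W, NEG), F((n + 1) * W, NEG);
  // traceback per state: for H: 0 stop, 1 diag, 2 from F, 3 from E
  //                      for E/F: 0 opened from H, 1 extended
  std::vector<signed char> TH((n + 1) * W, 0), TE((n + 1) * W, 0), TF((n + 1) * W, 0);
  auto idx = [W](int i, int k) { return i * W + k; };

  int best = 0, bi = -1, bk = -1;
  for (int i = 0; i <= n; ++i) {
    for (int k = 0; k < W; ++k) {
      int d = d0 - band + k;
      int j = i + d;
      if (j < 0 || j > m) continue;
      if (i == 0 || j == 0) { H[idx(i, k)] = 0; continue; }
      int e = NEG, f = NEG;
      signed char te = 0, tf = 0;
      if (k - 1 >= 0) { // gap in query: consume subject (move left)
        int hl = H[idx(i, k - 1)], el = E[idx(i, k - 1)];
        if (hl > NEG / 2) { e = hl - gap_open - gap_ext; te = 0; }
        if (el > NEG / 2 && el - gap_ext > e) { e = el - gap_ext; te = 1; }
      }
      if (k + 1 < W) { // gap in subject: consume query (move up)
        int hu = H[idx(i - 1, k + 1)], fu = F[idx(i - 1, k + 1)];
        if (hu > NEG / 2) { f = hu - gap_open - gap_ext; tf = 0; }
        if (fu > NEG / 2 && fu - gap_ext > f) { f = fu - gap_ext; tf = 1; }
      }
      int diag = H[idx(i - 1, k)];
      int sub = (q[i - 1] == s[j - 1]) ? match : mismatch;
      int dsc = (diag > NEG / 2) ? diag + sub : NEG;
      int h = 0; signed char th = 0;
      if (dsc > h) { h = dsc; th = 1; }
      if (f > h) { h = f; th = 2; }
      if (e > h) { h = e; th = 3; }
      H[idx(i, k)] = h; E[idx(i, k)] = e; F[idx(i, k)] = f;
      TH[idx(i, k)] = th; TE[idx(i, k)] = te; TF[idx(i, k)] = tf;
      if (h > best) { best = h; bi = i; bk = k; }
    }
  }
  if (best <= 0)
    return List::create(_["score"] = 0);

  // three-state traceback from the best cell
  int i = bi, k = bk;
  int qe = bi, se = bi + (d0 - band + bk);
  int matches = 0;
  std::string ops;
  int state = 0; // 0 = H, 1 = E, 2 = F
  while (i > 0) {
    int j = i + (d0 - band + k);
    if (j <= 0) break;
    if (state == 0) {
      signed char th = TH[idx(i, k)];
      if (th == 0) break;
      if (th == 1) {
        bool eq = (q[i - 1] == s[j - 1]);
        ops.push_back(eq ? 'M' : 'X');
        if (eq) ++matches;
        --i;
      } else if (th == 2) state = 2;
      else state = 1;
    } else if (state == 1) { // E: gap in query, consumed subject
      ops.push_back('I');
      signed char te = TE[idx(i, k)];
      --k;
      if (te == 0) state = 0;
    } else { // F: gap in subject, consumed query
      ops.push_back('D');
      signed char tf = TF[idx(i, k)];
      --i; ++k;
      if (tf == 0) state = 0;
    }
    if (k < 0 || k >= W) break;
  }
  int j0 = i + (d0 - band + k);
  std::reverse(ops.begin(), ops.end());
  return List::create(
    _["score"] = best,
    _["qs"] = i, _["qe"] = qe, _["ss"] = j0, _["se"] = se,
    _["matches"] = matches, _["alen"] = (int)ops.size(), _["ops"] = ops);
}

// Global (Needleman-Wunsch) alignment with affine gaps; returns the two
// gapped strings plus match/column counts.
// [[Rcpp::export(name = ".c_global_align")]]
List c_global_align(std::string a, std::string b,
                    int match, int mismatch, int gap_open, int gap_ext) {
  int n = a.size(), m = b.size();
  std::vector<int> H((n + 1) * (m + 1), NEG), E((n + 1) * (m + 1), NEG),
      F((n + 1) * (m + 1), NEG);
  std::vector<signed char> TH((n + 1) * (m + 1), 0), TE((n + 1) * (m + 1), 0),
      TF((n + 1) * (m + 1), 0);
  auto idx = [m](int i, int j) { return i * (m + 1) + j; };
  H[0] = 0;
  for (int j = 1; j <= m; ++j) {
    E[idx(0, j)] = -gap_open - gap_ext * j;
    H[idx(0, j)] = E[idx(0, j)];
    TH[idx(0, j)] = 3; TE[idx(0, j)] = (j == 1) ? 0 : 1;
  }
  for (int i = 1; i <= n; ++i) {
    F[idx(i, 0)] = -gap_open - gap_ext * i;
    H[idx(i, 0)] = F[idx(i, 0)];
    TH[idx(i, 0)] = 2; TF[idx(i, 0)] = (i == 1) ? 0 : 1;
    for (int j = 1; j <= m; ++j) {
      int e, f; signed char te, tf;
      int eo = H[idx(i, j - 1)] - gap_open - gap_ext;
      int ee = (E[idx(i, j - 1)] > NEG / 2) ? E[idx(i, j - 1)] - gap_ext : NEG;
      if (ee > eo) { e = ee; te = 1; } else { e = eo; te = 0; }
      int fo = H[idx(i - 1, j)] - gap_open - gap_ext;
      int fe = (F[idx(i - 1, j)] > NEG / 2) ? F[idx(i - 1, j)] - gap_ext : NEG;
      if (fe > fo) { f = fe; tf = 1; } else { f = fo; tf = 0; }
      int sub = (a[i - 1] == b[j - 1]) ? match : mismatch;
      int dsc = H[idx(i - 1, j - 1)] + sub;
      int h = dsc; signed char th = 1;
      if (f > h) { h = f; th = 2; }
      if (e > h) { h = e; th = 3; }
      H[idx(i, j)] = h; E[idx(i, j)] = e; F[idx(i, j)] = f;
      TH[idx(i, j)] = th; TE[idx(i, j)] = te; TF[idx(i, j)] = tf;
    }
  }
  std::string aa, bb;
  int i = n, j = m, matches = 0, state = 0;
  while (i > 0 || j > 0) {
    if (state == 0) {
      signed char th = TH[idx(i, j)];
      if (th == 1) {
        aa.push_back(a[i - 1]); bb.push_back(b[j - 1]);
        if (a[i - 1] == b[j - 1]) ++matches;
        --i; --j;
      } else if (th == 2) state = 2;
      else state = 1;
    } else if (state == 1) {
      aa.push_back('-'); bb.push_back(b[j - 1]);
      if (TE[idx(i, j)] == 0) state = 0;
      --j;
    } else {
      aa.push_back(a[i - 1]); bb.push_back('-');
      if (TF[idx(i, j)] == 0) state = 0;
      --i;
    }
  }
  std::reverse(aa.begin(), aa.end());
  std::reverse(bb.begin(), bb.end());
  return List::create(
    _["score"] = H[idx(n, m)], _["a"] = aa, _["b"] = bb,
    _["matches"] = matches, _["columns"] = (int)aa.size());
}
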