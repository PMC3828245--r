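#include <Rcpp.h>
#include <vector>
#include <string>
#include <algorithm>
using namespace Rcpp;

// Banded global (Needleman-Wunsch) alignment with affine gap penalties.
// Near-identical mitogenome pairs only ever need a narrow band around the
// main diagonal, which keeps the DP linear in sequence length.
//
// Scoring: match +ma, mismatch +mi (negative), a gap of length k costs
// open + k * extend (both positive numbers passed in, subtracted).
// Ambiguity (non-ACGT) sample bases score 0 against anything, so they are
// neither rewarded nor penalised and stay aligned in place.
//
// Traceback preference (deterministic): diagonal, then gap-in-sample
// (reference base deleted), then gap-in-reference (sample base inserted).
// Gap runs are subsequently left-normalised in R.

static inline bool is_acgt(char c) {
  return c == 'A' || c == 'C' || c == 'G' || c == 'T';
}

// [[Rcpp::export(name = ".align_banded")]]
List align_banded(std::string sample, std::string ref,
                  double ma, double mi, double gap_open, double gap_extend,
                  int band) {
  const int n = (int) sample.size();  // rows: sample
  const int m = (int) ref.size();     // cols: reference
  const double NEG = -1e18;

  // Band on j - i: [lo, hi]
  int diff = m - n;
  int lo = std::min(0, diff) - band;
  int hi = std::max(0, diff) + band;
  int W = hi - lo + 1;

  // Three layers: M (diag), X (gap in sample, consumes ref), Y (gap in ref).
  // Stored banded: cell (i, j) lives at column index j - i - lo.
  std::vector<double> M((size_t)(n + 1) * W, NEG), X((size_t)(n + 1) * W, NEG),
      Y((size_t)(n + 1) * W, NEG);
  // traceback: 2 bits per layer: predecessor layer (0=M,1=X,2=Y)
  std::vector<unsigned char> tbM((size_t)(n + 1) * W, 0),
      tbX((size_t)(n + 1) * W, 0), tbY((size_t)(n + 1) * W, 0);

  auto IDX = [&](int i, int j) { return (size_t) i * W + (j - i - lo); };
  auto inband = [&](int i, int j) {
    return j >= 0 && j <= m && (j - i) >= lo && (j - i) <= hi;
  };

  M[IDX(0, 0)] = 0.0;
  for (int j = 1; j <= m; ++j)
    if (inband(0, j)) { X[IDX(0, j)] = -(gap_open + gap_extend * j); tbX[IDX(0, j)] = 1; }
  for (int i = 1; i <= n; ++i)
    if (inband(i, 0)) { Y[IDX(i, 0)] = -(gap_open + gap_extend * i); tbY[IDX(i, 0)] = 2; }

  for (int i = 1; i <= n; ++i) {
    int jlo = std::max(1, i + lo), jhi = std::min(m, i + hi);
    for (int j = jlo; j <= jhi; ++j) {
      size_t id = IDX(i, j);
      // M: from (i-1, j-1)
      if (inband(i - 1, j - 1)) {
        size_t p = IDX(i - 1, j - 1);
        char a = sample[i - 1], b = ref[j - 1];
        double s = !is_acgt(a) ? 0.0 : (a == b ? ma : mi);
        double best = M[p]; unsigned char lay = 0;
        if (X[p] > best) { best = X[p]; lay = 1; }
        if (Y[p] > best) { best = Y[p]; lay = 2; }
        if (best > NEG / 2) { M[id] = best + s; tbM[id] = lay; }
      }
      // X: gap in sample, from (i, j-1)
      if (inband(i, j - 1)) {
        size_t p = IDX(i, j - 1);
        double fromM = (M[p] > NEG / 2) ? M[p] - gap_open - gap_extend : NEG;
        double fromX = (X[p] > NEG / 2) ? X[p] - gap_extend : NEG;
        double fromY = (Y[p] > NEG / 2) ? Y[p] - gap_open - gap_extend : NEG;
        double best = fromM; unsigned char lay = 0;
        if (fromX > best) { best = fromX; lay = 1; }
        if (fromY > best) { best = fromY; lay = 2; }
        if (best > NEG / 2) { X[id] = best; tbX[id] = lay; }
      }
      // Y: gap in reference, from (i-1, j)
      if (inband(i - 1, j)) {
        size_t p = IDX(i - 1, j);
        double fromM = (M[p] > NEG / 2) ? M[p] - gap_open - gap_extend : NEG;
        double fromX = (X[p] > NEG / 2) ? X[p] - gap_open - gap_extend : NEG;
        double fromY = (Y[p] > NEG / 2) ? Y[p] - gap_extend : NEG;
        double best = fromM; unsigned char lay = 0;
        if (fromX > best) { best = fromX; lay = 1; }
        if (fromY > best) { best = fromY; lay = 2; }
        if (best > NEG / 2) { Y[id] = best; tbY[id] = lay; }
      }
    }
  }

  if (!inband(n, m))
    stop("band too narrow for the sequence length difference");
  size_t endid = IDX(n, m);
  double best = M[endid]; int layer = 0;
  if (X[endid] > best) { best = X[endid]; layer = 1; }
  if (Y[endid] > best) { best = Y[endid]; layer = 2; }
  if (best < NEG / 2) stop("alignment failed: band too narrow");

  // Traceback
  std::string ga, gb;
  ga.reserve(n + m); gb.reserve(n + m);
  int i = n, j = m;
  while (i > 0 || j > 0) {
    size_t id = IDX(i, j);
    if (layer == 0) {
      int pl = tbM[id];
      ga.push_back(sample[i - 1]); gb.push_back(ref[j - 1]);
      --i; --j; layer = pl;
    } else if (layer == 1) {
      int pl = tbX[id];
      ga.push_back('-'); gb.push_back(ref[j - 1]);
      --j; layer = pl;
    } else {
      int pl = tbY[id];
      ga.push_back(sample[i - 1]); gb.push_back('-');
      --i; layer = pl;
    }
  }
  std::reverse(ga.begin(), ga.end());
  std::reverse(gb.begin(), gb.end());

  return List::create(_["aligned_sample"] = ga, _["aligned_ref"] = gb,
                      _["score"] = best);
}
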