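#include <Rcpp.h>
#include <cstdint>
#include <climits>
#include <vector>
#include <string>

using namespace Rcpp;

// Global (end-to-end) pairwise alignment with affine gap penalties.
//
// Three-state DP (match/mismatch M, gap-in-query X consuming a reference
// base, gap-in-reference Y consuming a query base). A gap of length L costs
// gap_open + gap_extend * L. Traceback state is packed 2 bits per matrix per
// cell so a 17 kb x 17 kb problem stays under ~300 MB.
//
// Tie-breaking is deterministic: diagonal (match/mismatch) is preferred over
// either gap state and gap-in-query over gap-in-reference; within a gap
// state, extension is preferred over opening, which yields maximal single
// gap runs. Residual placement ambiguity inside repeats is resolved by the
// caller's left-normalization of indel events.

static const int NEG = INT_MIN / 4;

enum Pred : uint8_t { FROM_M = 0, FROM_X = 1, FROM_Y = 2, FROM_NONE = 3 };

// [[Rcpp::export(name = ".nw_affine")]]
List nw_affine(std::string ref, std::string qry,
               int match, int mismatch, int gap_open, int gap_extend) {
  const int n = (int)qry.size();   // rows
  const int m = (int)ref.size();   // cols
  if (n < 1 || m < 1) stop("both sequences must be non-empty");

  const size_t ncell = (size_t)(n + 1) * (size_t)(m + 1);
  // bits 0-1: predecessor of M; 2-3: of X; 4-5: of Y
  std::vector<uint8_t> tb(ncell, (uint8_t)(FROM_NONE | (FROM_NONE << 2) | (FROM_NONE << 4)));

  std::vector<int> Mprev(m + 1), Xprev(m + 1), Yprev(m + 1);
  std::vector<int> Mcur(m + 1), Xcur(m + 1), Ycur(m + 1);

  // row 0
  Mprev[0] = 0; Xprev[0] = NEG; Yprev[0] = NEG;
  for (int j = 1; j <= m; ++j) {
    Mprev[j] = NEG;
    Xprev[j] = -gap_open - gap_extend * j;
    Yprev[j] = NEG;
    tb[j] = (uint8_t)(FROM_NONE | ((j == 1 ? FROM_M : FROM_X) << 2) | (FROM_NONE << 4));
  }

  for (int i = 1; i <= n; ++i) {
    const char qc = qry[i - 1];
    size_t rowoff = (size_t)i * (size_t)(m + 1);

    Mcur[0] = NEG;
    Xcur[0] = NEG;
    Ycur[0] = -gap_open - gap_extend * i;
    tb[rowoff] = (uint8_t)(FROM_NONE | (FROM_NONE << 2) | ((i == 1 ? FROM_M : FROM_Y) << 4));

    // branchless selections (ternaries compile to cmov), so throughput
    // does not depend on how predictable the sequence content is
    for (int j = 1; j <= m; ++j) {
      const int sub = (ref[j - 1] == qc) ? match : mismatch;

      // M: diagonal move; prefer M, then X, then Y on ties
      int best = Mprev[j - 1]; uint8_t pm = FROM_M;
      bool t;
      t = Xprev[j - 1] > best; best = t ? Xprev[j - 1] : best; pm = t ? (uint8_t)FROM_X : pm;
      t = Yprev[j - 1] > best; best = t ? Yprev[j - 1] : best; pm = t ? (uint8_t)FROM_Y : pm;
      const int Mv = (best <= NEG) ? NEG : best + sub;

      // X: gap in query (consumes ref[j-1]); prefer extension
      const int xopn = gap_open + gap_extend;
      int Xv = Xcur[j - 1] - gap_extend; uint8_t px = FROM_X;
      t = Mcur[j - 1] - xopn > Xv; Xv = t ? Mcur[j - 1] - xopn : Xv; px = t ? (uint8_t)FROM_M : px;
      t = Ycur[j - 1] - xopn > Xv; Xv = t ? Ycur[j - 1] - xopn : Xv; px = t ? (uint8_t)FROM_Y : px;
      t = Xv <= NEG; Xv = t ? NEG : Xv; px = t ? (uint8_t)FROM_NONE : px;

      // Y: gap in reference (consumes qry[i-1]); prefer extension
      int Yv = Yprev[j] - gap_extend; uint8_t py = FROM_Y;
      t = Mprev[j] - xopn > Yv; Yv = t ? Mprev[j] - xopn : Yv; py = t ? (uint8_t)FROM_M : py;
      t = Xprev[j] - xopn > Yv; Yv = t ? Xprev[j] - xopn : Yv; py = t ? (uint8_t)FROM_X : py;
      t = Yv <= NEG; Yv = t ? NEG : Yv; py = t ? (uint8_t)FROM_NONE : py;

      Mcur[j] = Mv; Xcur[j] = Xv; Ycur[j] = Yv;
      tb[rowoff + j] = (uint8_t)(pm | (px << 2) | (py << 4));
    }
    std::swap(Mprev, Mcur); std::swap(Xprev, Xcur); std::swap(Yprev, Ycur);
  }

  // final state: prefer M, then X (gap in query), then Y
  int score = Mprev[m]; uint8_t state = FROM_M;
  if (Xprev[m] > score) { score = Xprev[m]; state = FROM_X; }
  if (Yprev[m] > score) { score = Yprev[m]; state = FROM_Y; }

  // traceback
  std::string aref, aqry;
  aref.reserve((size_t)(n + m)); aqry.reserve((size_t)(n + m));
  int i = n, j = m;
  while (i > 0 || j > 0) {
    const uint8_t cell = tb[(size_t)i * (size_t)(m + 1) + j];
    uint8_t pred;
    if (state == FROM_M) {
      pred = cell & 3u;
      aref.push_back(ref[j - 1]); aqry.push_back(qry[i - 1]);
      --i; --j;
    } else if (state == FROM_X) {
      pred = (cell >> 2) & 3u;
      aref.push_back(ref[j - 1]); aqry.push_back('-');
      --j;
    } else {
      pred = (cell >> 4) & 3u;
      aref.push_back('-'); aqry.push_back(qry[i - 1]);
      --i;
    }
    if (pred == FROM_NONE) {
      if (i == 0 && j == 0) break;
      // boundary rows/cols chain within their own gap state
      pred = state;
    }
    state = pred;
  }
  std::reverse(aref.begin(), aref.end());
  std::reverse(aqry.begin(), aqry.end());

  return List::create(_["aligned_ref"] = aref,
                      _["aligned_qry"] = aqry,
                      _["score"] = score);
}
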