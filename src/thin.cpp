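#include <Rcpp.h>
using namespace Rcpp;

// Guo-Hall two-subiteration homotopic thinning of a binary image, followed by
// a cleanup pass that deletes redundant simple pixels sitting in 2x2 foreground
// blocks.  The contract downstream is a 1-pixel-wide, connectivity-preserving
// skeleton (no 2x2 foreground block), not a particular named algorithm.

static inline int px(const IntegerMatrix &I, int r, int c) {
  if (r < 0 || c < 0 || r >= I.nrow() || c >= I.ncol()) return 0;
  return I(r, c) != 0 ? 1 : 0;
}

// One Guo-Hall subiteration; returns number of deleted pixels.
static int gh_subiter(IntegerMatrix &I, int iter) {
  int nr = I.nrow(), nc = I.ncol();
  std::vector<std::pair<int,int>> kill;
  for (int r = 0; r < nr; ++r) {
    for (int c = 0; c < nc; ++c) {
      if (!I(r, c)) continue;
      int p2 = px(I, r - 1, c),     p3 = px(I, r - 1, c + 1);
      int p4 = px(I, r,     c + 1), p5 = px(I, r + 1, c + 1);
      int p6 = px(I, r + 1, c),     p7 = px(I, r + 1, c - 1);
      int p8 = px(I, r,     c - 1), p9 = px(I, r - 1, c - 1);
      int C  = ((!p2) & (p3 | p4)) + ((!p4) & (p5 | p6)) +
               ((!p6) & (p7 | p8)) + ((!p8) & (p9 | p2));
      int N1 = (p9 | p2) + (p3 | p4) + (p5 | p6) + (p7 | p8);
      int N2 = (p2 | p3) + (p4 | p5) + (p6 | p7) + (p8 | p9);
      int N  = N1 < N2 ? N1 : N2;
      int m  = iter == 0 ? ((p6 | p7 | (!p9)) & p8)
                         : ((p2 | p3 | (!p5)) & p4);
      if (C == 1 && N >= 2 && N <= 3 && m == 0)
        kill.push_back(std::make_pair(r, c));
    }
  }
  for (size_t k = 0; k < kill.size(); ++k) I(kill[k].first, kill[k].second) = 0;
  return (int)kill.size();
}

// Number of 0->1 transitions around the 8-neighbourhood (Hilditch crossing
// number); a foreground pixel with exactly one transition can be removed
// without breaking local 8-connectivity.
static int transitions(const IntegerMatrix &I, int r, int c) {
  int n[8] = { px(I, r - 1, c),     px(I, r - 1, c + 1),
               px(I, r,     c + 1), px(I, r + 1, c + 1),
               px(I, r + 1, c),     px(I, r + 1, c - 1),
               px(I, r,     c - 1), px(I, r - 1, c - 1) };
  int a = 0;
  for (int k = 0; k < 8; ++k) a += (n[k] == 0 && n[(k + 1) % 8] == 1);
  return a;
}

static int nneigh(const IntegerMatrix &I, int r, int c) {
  int s = 0;
  for (int dr = -1; dr <= 1; ++dr)
    for (int dc = -1; dc <= 1; ++dc)
      if (dr || dc) s += px(I, r + dr, c + dc);
  return s;
}

// [[Rcpp::export(name = ".thin_cpp")]]
IntegerMatrix thin_cpp(IntegerMatrix mask) {
  IntegerMatrix I = clone(mask);
  for (;;) {
    int d = gh_subiter(I, 0) + gh_subiter(I, 1);
    if (d == 0) break;
  }
  // Remove leftover 2x2 blocks: delete simple, non-endpoint pixels until none.
  int nr = I.nrow(), nc = I.ncol();
  bool changed = true;
  while (changed) {
    changed = false;
    for (int r = 0; r + 1 < nr && !changed; ++r) {
      for (int c = 0; c + 1 < nc && !changed; ++c) {
        if (!(I(r, c) && I(r, c + 1) && I(r + 1, c) && I(r + 1, c + 1)))
          continue;
        int br[4] = { r, r, r + 1, r + 1 };
        int bc[4] = { c, c + 1, c, c + 1 };
        for (int k = 0; k < 4; ++k) {
          int rr = br[k], cc = bc[k];
          if (transitions(I, rr, cc) == 1 && nneigh(I, rr, cc) >= 2) {
            I(rr, cc) = 0;
            changed = true;
            break;
          }
        }
      }
    }
  }
  return I;
}
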