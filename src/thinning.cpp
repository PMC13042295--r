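#include <Rcpp.h>
using namespace Rcpp;

// Zhang-Suen style thinning of a binary image. Input and output are logical
// matrices (row, col), 8-connected foreground. The two sub-iterations delete
// south-east and north-west boundary pixels alternately until a fixpoint.

static inline int at(const LogicalMatrix &m, int r, int c) {
  if (r < 0 || c < 0 || r >= m.nrow() || c >= m.ncol()) return 0;
  return m(r, c) ? 1 : 0;
}

// [[Rcpp::export]]
LogicalMatrix cpp_thin(LogicalMatrix input) {
  LogicalMatrix img = clone(input);
  int nr = img.nrow(), nc = img.ncol();
  bool changed = true;
  std::vector<std::pair<int,int> > kill;
  kill.reserve(256);
  while (changed) {
    changed = false;
    for (int step = 0; step < 2; ++step) {
      kill.clear();
      for (int r = 0; r < nr; ++r) {
        for (int c = 0; c < nc; ++c) {
          if (!img(r, c)) continue;
          // clockwise neighbours starting north
          int p2 = at(img, r - 1, c);
          int p3 = at(img, r - 1, c + 1);
          int p4 = at(img, r,     c + 1);
          int p5 = at(img, r + 1, c + 1);
          int p6 = at(img, r + 1, c);
          int p7 = at(img, r + 1, c - 1);
          int p8 = at(img, r,     c - 1);
          int p9 = at(img, r - 1, c - 1);
          int b = p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9;
          if (b < 2 || b > 6) continue;
          int a = (p2 == 0 && p3 == 1) + (p3 == 0 && p4 == 1) +
                  (p4 == 0 && p5 == 1) + (p5 == 0 && p6 == 1) +
                  (p6 == 0 && p7 == 1) + (p7 == 0 && p8 == 1) +
                  (p8 == 0 && p9 == 1) + (p9 == 0 && p2 == 1);
          if (a != 1) continue;
          if (step == 0) {
            if (p2 * p4 * p6 != 0 || p4 * p6 * p8 != 0) continue;
          } else {
            if (p2 * p4 * p8 != 0 || p2 * p6 * p8 != 0) continue;
          }
          kill.push_back(std::make_pair(r, c));
        }
      }
      if (!kill.empty()) {
        changed = true;
        for (size_t i = 0; i < kill.size(); ++i)
          img(kill[i].first, kill[i].second) = false;
      }
    }
  }
  return img;
}

// Skeleton-tracing degree under reduced 8-adjacency: orthogonal neighbours
// always count; a diagonal neighbour counts only when neither of the two
// shared orthogonal pixels is foreground (this removes the double-counting
// on staircase runs that would otherwise look like junctions).
// Returns an integer matrix with -1 on background.
// [[Rcpp::export]]
IntegerMatrix cpp_neighbor_degree(LogicalMatrix img) {
  int nr = img.nrow(), nc = img.ncol();
  IntegerMatrix deg(nr, nc);
  for (int r = 0; r < nr; ++r)
    for (int c = 0; c < nc; ++c) {
      if (!img(r, c)) { deg(r, c) = -1; continue; }
      int d = 0;
      for (int dr = -1; dr <= 1; ++dr)
        for (int dc = -1; dc <= 1; ++dc) {
          if (dr == 0 && dc == 0) continue;
          if (!at(img, r + dr, c + dc)) continue;
          if (dr != 0 && dc != 0 &&
              (at(img, r + dr, c) || at(img, r, c + dc)))
            continue;
          ++d;
        }
      deg(r, c) = d;
    }
  return deg;
}
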