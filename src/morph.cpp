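#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Local median of an integer-valued image (values must lie in [0, 255]).
// Window is the (2r+1)x(2r+1) square centred on each pixel, clipped to the
// image bounds; the median is the ceil(n/2)-th smallest value (lower median),
// deterministic on integers even when the clipped window has even size.
// Implemented as a per-row sliding 256-bin histogram.
// [[Rcpp::export]]
IntegerMatrix cpp_local_median(const IntegerMatrix& img, int radius) {
  const int H = img.nrow(), W = img.ncol(), R = radius;
  IntegerMatrix out(H, W);
  std::vector<int> hist(256);

  for (int i = 0; i < H; ++i) {
    const int r0 = std::max(0, i - R), r1 = std::min(H - 1, i + R);
    std::fill(hist.begin(), hist.end(), 0);
    int n = 0;
    // initial window: columns [0, min(R, W-1)]
    for (int c = 0; c <= std::min(R, W - 1); ++c)
      for (int r = r0; r <= r1; ++r) { ++hist[img(r, c)]; ++n; }
    for (int j = 0; j < W; ++j) {
      if (j > 0) {
        const int cadd = j + R, cdrop = j - R - 1;
        if (cadd < W)    for (int r = r0; r <= r1; ++r) { ++hist[img(r, cadd)]; ++n; }
        if (cdrop >= 0)  for (int r = r0; r <= r1; ++r) { --hist[img(r, cdrop)]; --n; }
      }
      const int target = (n + 1) / 2;  // ceil(n/2)
      int cum = 0, med = 0;
      for (int v = 0; v < 256; ++v) { cum += hist[v]; if (cum >= target) { med = v; break; } }
      out(i, j) = med;
    }
  }
  return out;
}

static inline int idx(int r, int c, int H) { return r + c * H; }

// ring offsets in cyclic order: N, NE, E, SE, S, SW, W, NW
static const int ring_dr[8] = {-1, -1, 0, 1, 1, 1, 0, -1};
static const int ring_dc[8] = {0, 1, 1, 1, 0, -1, -1, -1};

// Exact simple-point test for 8-connected foreground / 4-connected
// background: deleting p preserves topology iff the foreground in the
// 8-neighbourhood forms exactly one 8-connected component and the
// background forms exactly one cyclic run containing a 4-neighbour.
// (The Rutovitz crossing number misses the mutual diagonal adjacency of
// edge neighbours, e.g. N and W with NW background, and would freeze
// staircase corner pixels.)
static inline bool is_simple(const std::vector<unsigned char>& m,
                             int r, int c, int H) {
  unsigned char p[8];
  int B = 0;
  for (int k = 0; k < 8; ++k) {
    p[k] = m[idx(r + ring_dr[k], c + ring_dc[k], H)];
    B += p[k];
  }
  if (B == 0 || B == 8) return false;

  // foreground 8-components in the ring: union-find over the 8 cells,
  // adjacency = Chebyshev distance <= 1 between offsets
  int parent[8];
  for (int k = 0; k < 8; ++k) parent[k] = k;
  struct UF {
    int* par;
    int find(int x) { while (par[x] != x) x = par[x] = par[par[x]]; return x; }
    void join(int a, int b) { par[find(a)] = find(b); }
  } uf;
  uf.par = parent;
  for (int a = 0; a < 8; ++a) {
    if (!p[a]) continue;
    for (int b = a + 1; b < 8; ++b) {
      if (!p[b]) continue;
      const int dr = ring_dr[a] - ring_dr[b], dc = ring_dc[a] - ring_dc[b];
      if (dr >= -1 && dr <= 1 && dc >= -1 && dc <= 1) uf.join(a, b);
    }
  }
  int fg_comp = 0;
  for (int k = 0; k < 8; ++k) if (p[k] && uf.find(k) == k) ++fg_comp;
  if (fg_comp != 1) return false;

  // background cyclic runs containing a 4-neighbour (even ring positions);
  // consecutive ring cells are mutually 4-adjacent, non-consecutive never are
  int bg_runs4 = 0;
  for (int k = 0; k < 8; ++k) {
    if (p[k]) continue;
    // start of a bg run?
    if (p[(k + 7) % 8]) {
      bool has4 = false;
      for (int j = k; !p[j % 8]; ++j) {
        if ((j % 8) % 2 == 0) has4 = true;
        if (j == k + 8) break;
      }
      if (has4) ++bg_runs4;
    }
  }
  return bg_runs4 == 1;
}

static inline int neighbour_sum(const std::vector<unsigned char>& m,
                                int r, int c, int H) {
  return m[idx(r - 1, c - 1, H)] + m[idx(r - 1, c, H)] + m[idx(r - 1, c + 1, H)]
       + m[idx(r,     c - 1, H)]                       + m[idx(r,     c + 1, H)]
       + m[idx(r + 1, c - 1, H)] + m[idx(r + 1, c, H)] + m[idx(r + 1, c + 1, H)];
}

// Sequential binary thinning to a 1-pixel, 8-connected medial skeleton.
// Four directional sub-passes (N, S, E, W border pixels) per iteration; a
// pixel is deleted immediately when it is simple (crossing number 1) and not
// an end point (2 <= neighbour count <= 6). Sequential deletion of simple
// points preserves both connected-component count and holes; iteration to a
// fixed point makes the operation idempotent.
// [[Rcpp::export]]
LogicalMatrix cpp_thin(const LogicalMatrix& mask) {
  const int H0 = mask.nrow(), W0 = mask.ncol();
  const int H = H0 + 2, W = W0 + 2;  // zero border pad
  std::vector<unsigned char> m(H * W, 0);
  for (int c = 0; c < W0; ++c)
    for (int r = 0; r < H0; ++r)
      m[idx(r + 1, c + 1, H)] = mask(r, c) ? 1 : 0;

  // direction offsets: N, S, E, W neighbour that must be background
  const int dr[4] = {-1, 1, 0, 0};
  const int dc[4] = {0, 0, 1, -1};
  std::vector<int> cand;
  bool changed = true;
  while (changed) {
    changed = false;
    for (int d = 0; d < 4; ++d) {
      // phase 1: collect the current d-border pixels, so one sub-pass can
      // never erode deeper than one layer
      cand.clear();
      for (int c = 1; c <= W0; ++c)
        for (int r = 1; r <= H0; ++r) {
          const int k = idx(r, c, H);
          if (m[k] && !m[idx(r + dr[d], c + dc[d], H)])
            cand.push_back(k);
        }
      // phase 2: delete sequentially, re-checking simplicity on the
      // evolving image so topology is preserved exactly
      for (size_t i = 0; i < cand.size(); ++i) {
        const int k = cand[i];
        const int c = k / H, r = k % H;
        const int B = neighbour_sum(m, r, c, H);
        if (B < 2 || B > 6) continue;      // keep end points and near-interior
        if (!is_simple(m, r, c, H)) continue;
        m[k] = 0;
        changed = true;
      }
    }
  }

  LogicalMatrix out(H0, W0);
  for (int c = 0; c < W0; ++c)
    for (int r = 0; r < H0; ++r)
      out(r, c) = m[idx(r + 1, c + 1, H)] != 0;
  return out;
}

// 8-connected component labelling (stack-based flood fill); labels are
// assigned in column-major scan order starting at 1, 0 = background.
// [[Rcpp::export]]
IntegerMatrix cpp_label8(const LogicalMatrix& mask) {
  const int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix lab(H, W);
  std::vector<std::pair<int,int> > stack;
  int next = 0;
  for (int c = 0; c < W; ++c) {
    for (int r = 0; r < H; ++r) {
      if (!mask(r, c) || lab(r, c)) continue;
      ++next;
      stack.push_back(std::make_pair(r, c));
      lab(r, c) = next;
      while (!stack.empty()) {
        const int pr = stack.back().first, pc = stack.back().second;
        stack.pop_back();
        for (int a = -1; a <= 1; ++a) {
          for (int b = -1; b <= 1; ++b) {
            const int nr = pr + a, nc = pc + b;
            if (nr < 0 || nr >= H || nc < 0 || nc >= W) continue;
            if (mask(nr, nc) && !lab(nr, nc)) {
              lab(nr, nc) = next;
              stack.push_back(std::make_pair(nr, nc));
            }
          }
        }
      }
    }
  }
  return lab;
}

// 4-connected component labelling (used for background/hole analysis, the
// dual connectivity of 8-connected foreground)
// [[Rcpp::export]]
IntegerMatrix cpp_label4(const LogicalMatrix& mask) {
  const int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix lab(H, W);
  std::vector<std::pair<int,int> > stack;
  const int dr[4] = {-1, 1, 0, 0}, dc[4] = {0, 0, -1, 1};
  int next = 0;
  for (int c = 0; c < W; ++c) {
    for (int r = 0; r < H; ++r) {
      if (!mask(r, c) || lab(r, c)) continue;
      ++next;
      stack.push_back(std::make_pair(r, c));
      lab(r, c) = next;
      while (!stack.empty()) {
        const int pr = stack.back().first, pc = stack.back().second;
        stack.pop_back();
        for (int k = 0; k < 4; ++k) {
          const int nr = pr + dr[k], nc = pc + dc[k];
          if (nr < 0 || nr >= H || nc < 0 || nc >= W) continue;
          if (mask(nr, nc) && !lab(nr, nc)) {
            lab(nr, nc) = next;
            stack.push_back(std::make_pair(nr, nc));
          }
        }
      }
    }
  }
  return lab;
}

// count of foreground 8-neighbours at every pixel
// [[Rcpp::export]]
IntegerMatrix cpp_neighbour_count8(const LogicalMatrix& mask) {
  const int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix out(H, W);
  for (int c = 0; c < W; ++c) {
    for (int r = 0; r < H; ++r) {
      int s = 0;
      for (int a = -1; a <= 1; ++a)
        for (int b = -1; b <= 1; ++b) {
          if (!a && !b) continue;
          const int nr = r + a, nc = c + b;
          if (nr >= 0 && nr < H && nc >= 0 && nc < W && mask(nr, nc)) ++s;
        }
      out(r, c) = s;
    }
  }
  return out;
}
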