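#include <Rcpp.h>
#include <deque>
#include <vector>
#include <climits>
#include <cmath>
#include <cstring>
using namespace Rcpp;

// Flat-disc grayscale morphology, median filtering and prominence-thresholded
// regional-minimum detection. Images are integer matrices with values in
// [0, 255]; all neighborhood operators use edge replication so that output
// dimensions equal input dimensions and no artificial dark rims appear.

// ---------------------------------------------------------------------------
// sliding horizontal maximum (window halfwidth w) over one row of length len,
// written into out; clamped windows (callers pad, so clamping == replication)
static void rowSlideMax(const int* row, int len, int w, int* out) {
  std::deque<int> dq; // indices, values decreasing
  int j = 0;
  // prime window [0, w]
  for (; j <= w && j < len; ++j) {
    while (!dq.empty() && row[dq.back()] <= row[j]) dq.pop_back();
    dq.push_back(j);
  }
  for (int i = 0; i < len; ++i) {
    // extend right edge to i + w
    for (; j <= i + w && j < len; ++j) {
      while (!dq.empty() && row[dq.back()] <= row[j]) dq.pop_back();
      dq.push_back(j);
    }
    // drop left of i - w
    while (dq.front() < i - w) dq.pop_front();
    out[i] = row[dq.front()];
  }
}

// in-place flat-disc dilation over a row-major buffer (rows x cols) with
// clipped windows; erosion = negated dilation of the negated buffer
static void rawDilate(std::vector<int>& buf, int rows, int cols, int r) {
  std::vector<int> wOf(r + 1);
  for (int dy = 0; dy <= r; ++dy)
    wOf[dy] = (int)std::floor(std::sqrt((double)r * r - (double)dy * dy));
  std::vector<int> out((size_t)rows * cols, INT_MIN);
  std::vector<int> RM((size_t)rows * cols);
  std::vector<bool> done(r + 1, false);
  for (int dy0 = 0; dy0 <= r; ++dy0) {
    if (done[dy0]) continue;
    int w = wOf[dy0];
    for (int i = 0; i < rows; ++i)
      rowSlideMax(&buf[(size_t)i * cols], cols, w, &RM[(size_t)i * cols]);
    for (int dy = dy0; dy <= r; ++dy) {
      if (wOf[dy] != w || done[dy]) continue;
      done[dy] = true;
      for (int sgn = (dy == 0 ? 1 : -1); sgn <= 1; sgn += 2) {
        int d = sgn * dy;
        for (int y = 0; y < rows; ++y) {
          int ys = y + d;
          if (ys < 0 || ys >= rows) continue;
          const int* src = &RM[(size_t)ys * cols];
          int* dst = &out[(size_t)y * cols];
          for (int x = 0; x < cols; ++x)
            if (src[x] > dst[x]) dst[x] = src[x];
        }
        if (dy == 0) break;
      }
    }
  }
  buf.swap(out);
}

static void rawErode(std::vector<int>& buf, int rows, int cols, int r) {
  for (size_t i = 0; i < buf.size(); ++i) buf[i] = -buf[i];
  rawDilate(buf, rows, cols, r);
  for (size_t i = 0; i < buf.size(); ++i) buf[i] = -buf[i];
}

// flat-disc morphology with edge replication. op: 0 dilate, 1 erode,
// 2 close (dilate then erode), 3 open (erode then dilate). The input is
// padded by 2r so the second pass of a composite operator sees the exact
// extended intermediate surface, not a re-padded crop; windows that reach
// beyond the pad only ever see replicated edge values, so clipping there
// is exact for the conceptually infinite replicated image.
// [[Rcpp::export(name = ".cppMorphDisc")]]
IntegerMatrix cppMorphDisc(IntegerMatrix img, int r, int op) {
  const int n = img.nrow(), m = img.ncol();
  const int pad = 2 * r;
  const int pn = n + 2 * pad, pm = m + 2 * pad;
  std::vector<int> P((size_t)pn * pm);
  for (int i = 0; i < pn; ++i) {
    int ii = std::min(std::max(i - pad, 0), n - 1);
    int* dst = &P[(size_t)i * pm];
    for (int j = 0; j < pm; ++j)
      dst[j] = img(ii, std::min(std::max(j - pad, 0), m - 1));
  }
  switch (op) {
    case 0: rawDilate(P, pn, pm, r); break;
    case 1: rawErode(P, pn, pm, r); break;
    case 2: rawDilate(P, pn, pm, r); rawErode(P, pn, pm, r); break;
    case 3: rawErode(P, pn, pm, r); rawDilate(P, pn, pm, r); break;
    default: stop("unknown morphology op");
  }
  IntegerMatrix out(n, m);
  for (int y = 0; y < n; ++y)
    for (int x = 0; x < m; ++x)
      out(y, x) = P[(size_t)(y + pad) * pm + (x + pad)];
  return out;
}

// ---------------------------------------------------------------------------
// disc median filter; footprint dx^2 + dy^2 <= r^2 (odd cardinality by
// symmetry), borders by edge replication via index clamping.
// [[Rcpp::export(name = ".cppMedianDisc")]]
IntegerMatrix cppMedianDisc(IntegerMatrix img, int r) {
  const int n = img.nrow(), m = img.ncol();
  std::vector<int> offy, offx;
  for (int dy = -r; dy <= r; ++dy)
    for (int dx = -r; dx <= r; ++dx)
      if (dy * dy + dx * dx <= r * r) { offy.push_back(dy); offx.push_back(dx); }
  const int K = (int)offy.size();
  const int rank = K / 2; // 0-based middle (K is odd)
  IntegerMatrix out(n, m);
  std::vector<int> colv(n); // cache one column of img for speed
  // copy to plain buffer (column-major like R)
  std::vector<int> buf((size_t)n * m);
  for (int x = 0; x < m; ++x)
    for (int y = 0; y < n; ++y) buf[(size_t)x * n + y] = img(y, x);
  int cnt[256];
  for (int x = 0; x < m; ++x) {
    for (int y = 0; y < n; ++y) {
      std::memset(cnt, 0, sizeof(cnt));
      for (int k = 0; k < K; ++k) {
        int yy = y + offy[k]; if (yy < 0) yy = 0; else if (yy >= n) yy = n - 1;
        int xx = x + offx[k]; if (xx < 0) xx = 0; else if (xx >= m) xx = m - 1;
        ++cnt[buf[(size_t)xx * n + yy]];
      }
      int acc = 0, med = 0;
      for (int v = 0; v < 256; ++v) { acc += cnt[v]; if (acc > rank) { med = v; break; } }
      out(y, x) = med;
    }
  }
  return out;
}

// ---------------------------------------------------------------------------
// regional minima with prominence thresholding via union-find flooding.
//
// A regional minimum is a connected (8-neighborhood) plateau of equal
// intensity strictly darker than every in-mask neighbor. Its prominence is
// the height of the lowest saddle connecting it to a dominating minimum
// (deeper, or equally deep with lexicographically smaller representative),
// or 255 - depth for a basin that never meets a dominating one (the lifted
// background reference). Plateaus at 255 and all-flat mask components are
// never minima. Each counted basin is reported at its minimum plateau's
// centroid pixel (nearest plateau pixel to the centroid, ties to smallest
// row then column).
// [[Rcpp::export(name = ".cppFindMinima")]]
IntegerMatrix cppFindMinima(IntegerMatrix img, LogicalMatrix mask, int minProm) {
  const int n = img.nrow(), m = img.ncol();
  const size_t N = (size_t)n * m;
  std::vector<int> parent(N, -1);          // -1 = inactive
  std::vector<unsigned char> minVal(N);
  std::vector<int> repR(N), repC(N);
  std::vector<long long> sumR(N), sumC(N);
  std::vector<unsigned long long> bestD2(N);
  std::vector<int> bestR(N), bestC(N);
  std::vector<long long> plateauN(N), compSize(N);
  std::vector<unsigned char> repDone(N, 0), bestInit(N, 0);

  // bucket pixels by intensity
  std::vector<std::vector<int>> bucket(256);
  for (int x = 0; x < m; ++x)
    for (int y = 0; y < n; ++y)
      if (mask(y, x)) bucket[img(y, x)].push_back(x * n + y);

  // union-find
  std::vector<int> stack;
  auto find = [&](int p) {
    int r0 = p;
    while (parent[r0] != r0) r0 = parent[r0];
    while (parent[p] != r0) { int nx = parent[p]; parent[p] = r0; p = nx; }
    return r0;
  };

  struct Hit { int r, c, prom; };
  std::vector<Hit> hits;

  auto lexLess = [&](int r1, int c1, int r2, int c2) {
    return r1 < r2 || (r1 == r2 && c1 < c2);
  };

  for (int v = 0; v < 256; ++v) {
    const std::vector<int>& px = bucket[v];
    if (px.empty()) continue;
    for (size_t k = 0; k < px.size(); ++k) {
      int p = px[k];
      int y = p % n, x = p / n;
      parent[p] = p; minVal[p] = (unsigned char)v;
      sumR[p] = y; sumC[p] = x; plateauN[p] = 1; compSize[p] = 1;
      repDone[p] = 0; bestInit[p] = 0;
      for (int dy = -1; dy <= 1; ++dy) {
        for (int dx = -1; dx <= 1; ++dx) {
          if (!dy && !dx) continue;
          int yy = y + dy, xx = x + dx;
          if (yy < 0 || yy >= n || xx < 0 || xx >= m) continue;
          int q = xx * n + yy;
          if (parent[q] < 0) continue; // inactive (brighter, or masked out)
          int ra = find(p), rb = find(q);
          if (ra == rb) continue;
          int ma = minVal[ra], mb = minVal[rb];
          int win, lose;
          if (ma != mb) { win = (ma < mb) ? ra : rb; lose = (win == ra) ? rb : ra; }
          else if (ma == v) {
            // two plateau fragments at the current level: plain merge
            win = ra; lose = rb;
            sumR[win] += sumR[lose]; sumC[win] += sumC[lose];
            plateauN[win] += plateauN[lose]; compSize[win] += compSize[lose];
            parent[lose] = win;
            continue;
          } else {
            // equal-depth basins: lexicographically smaller representative wins
            win = lexLess(repR[ra], repC[ra], repR[rb], repC[rb]) ? ra : rb;
            lose = (win == ra) ? rb : ra;
          }
          if (minVal[lose] < v) {
            // a genuine basin dies at saddle level v
            int prom = v - minVal[lose];
            if (prom >= minProm)
              hits.push_back({repR[lose], repC[lose], prom});
          }
          // else: current-level plateau fragment absorbed by a deeper basin
          compSize[win] += compSize[lose];
          parent[lose] = win;
        }
      }
    }
    // assign representatives for basins born at this level
    for (size_t k = 0; k < px.size(); ++k) {
      int p = px[k];
      int r0 = find(p);
      if (minVal[r0] != v) continue;
      int y = p % n, x = p / n;
      long long Np = plateauN[r0];
      long long ar = Np * y - sumR[r0], ac = Np * x - sumC[r0];
      unsigned long long ur = (unsigned long long)(ar < 0 ? -ar : ar);
      unsigned long long uc = (unsigned long long)(ac < 0 ? -ac : ac);
      unsigned long long d2 = ur * ur + uc * uc;
      if (!bestInit[r0] || d2 < bestD2[r0] ||
          (d2 == bestD2[r0] && lexLess(y, x, bestR[r0], bestC[r0]))) {
        bestInit[r0] = 1; bestD2[r0] = d2; bestR[r0] = y; bestC[r0] = x;
      }
    }
    for (size_t k = 0; k < px.size(); ++k) {
      int r0 = find(px[k]);
      if (minVal[r0] == v && !repDone[r0]) {
        repR[r0] = bestR[r0]; repC[r0] = bestC[r0]; repDone[r0] = 1;
      }
    }
  }

  // surviving basins: prominence relative to the white (255) background level
  for (int v = 0; v < 255; ++v) {
    for (size_t k = 0; k < bucket[v].size(); ++k) {
      int p = bucket[v][k];
      if (parent[p] != p) continue; // not a root
      if (minVal[p] != v) continue;
      if (compSize[p] == plateauN[p]) continue; // flat component: no minimum
      int prom = 255 - v;
      if (prom >= minProm) hits.push_back({repR[p], repC[p], prom});
    }
  }

  // deterministic ordering by (row, col); 1-based output
  std::sort(hits.begin(), hits.end(), [](const Hit& a, const Hit& b) {
    return a.r < b.r || (a.r == b.r && a.c < b.c);
  });
  IntegerMatrix out((int)hits.size(), 3);
  for (size_t i = 0; i < hits.size(); ++i) {
    out(i, 0) = hits[i].r + 1;
    out(i, 1) = hits[i].c + 1;
    out(i, 2) = hits[i].prom;
  }
  colnames(out) = CharacterVector::create("row", "col", "prominence");
  return out;
}
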