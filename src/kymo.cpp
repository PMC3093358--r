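#include <Rcpp.h>
using namespace Rcpp;

// Draw a worm as a filled tube of varying half-width around a midline
// polyline. `pts` are (x = column, y = row) pixel-center coordinates,
// 1-based; `halfw` is the half-width (pixels) at each vertex. Intensity is
// an anti-aliased coverage value in [0, 1] (1 inside, linear 1-px edge).
// [[Rcpp::export]]
NumericMatrix raster_tube(NumericMatrix pts, NumericVector halfw,
                          int nrow, int ncol) {
  NumericMatrix img(nrow, ncol);
  int K = pts.nrow();
  for (int j = 0; j + 1 < K; ++j) {
    double ax = pts(j, 0), ay = pts(j, 1);
    double bx = pts(j + 1, 0), by = pts(j + 1, 1);
    double ha = halfw[j], hb = halfw[j + 1];
    double pad = std::max(ha, hb) + 1.5;
    int c0 = std::max(0, (int)std::floor(std::min(ax, bx) - pad) - 1);
    int c1 = std::min(ncol - 1, (int)std::ceil(std::max(ax, bx) + pad) - 1);
    int r0 = std::max(0, (int)std::floor(std::min(ay, by) - pad) - 1);
    int r1 = std::min(nrow - 1, (int)std::ceil(std::max(ay, by) + pad) - 1);
    double dx = bx - ax, dy = by - ay, len2 = dx * dx + dy * dy;
    for (int r = r0; r <= r1; ++r) {
      for (int c = c0; c <= c1; ++c) {
        double px = c + 1.0, py = r + 1.0;
        double t = len2 > 0 ? ((px - ax) * dx + (py - ay) * dy) / len2 : 0.0;
        t = std::min(1.0, std::max(0.0, t));
        double qx = ax + t * dx, qy = ay + t * dy;
        double d = std::sqrt((px - qx) * (px - qx) + (py - qy) * (py - qy));
        double h = ha + t * (hb - ha);
        double v = h - d + 0.5;
        if (v > 1.0) v = 1.0;
        if (v > img(r, c)) img(r, c) = v;
      }
    }
  }
  return img;
}

// Zhang-Suen morphological thinning of a binary mask down to an
// 8-connected, one-pixel-wide skeleton.
// [[Rcpp::export]]
LogicalMatrix thin_mask(LogicalMatrix m) {
  int nr = m.nrow(), nc = m.ncol();
  std::vector<int> img(nr * nc, 0);
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r)
      img[r + (size_t)nr * c] = m(r, c) ? 1 : 0;
  auto at = [&](int r, int c) -> int {
    if (r < 0 || r >= nr || c < 0 || c >= nc) return 0;
    return img[r + (size_t)nr * c];
  };
  std::vector<std::pair<int, int> > del;
  bool changed = true;
  while (changed) {
    changed = false;
    for (int pass = 0; pass < 2; ++pass) {
      del.clear();
      for (int c = 0; c < nc; ++c) {
        for (int r = 0; r < nr; ++r) {
          if (!img[r + (size_t)nr * c]) continue;
          int p2 = at(r - 1, c),     p3 = at(r - 1, c + 1);
          int p4 = at(r, c + 1),     p5 = at(r + 1, c + 1);
          int p6 = at(r + 1, c),     p7 = at(r + 1, c - 1);
          int p8 = at(r, c - 1),     p9 = at(r - 1, c - 1);
          int B = p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9;
          if (B < 2 || B > 6) continue;
          int A = (p2 == 0 && p3 == 1) + (p3 == 0 && p4 == 1) +
                  (p4 == 0 && p5 == 1) + (p5 == 0 && p6 == 1) +
                  (p6 == 0 && p7 == 1) + (p7 == 0 && p8 == 1) +
                  (p8 == 0 && p9 == 1) + (p9 == 0 && p2 == 1);
          if (A != 1) continue;
          if (pass == 0) {
            if (p2 * p4 * p6 != 0 || p4 * p6 * p8 != 0) continue;
          } else {
            if (p2 * p4 * p8 != 0 || p2 * p6 * p8 != 0) continue;
          }
          del.push_back(std::make_pair(r, c));
        }
      }
      if (!del.empty()) {
        changed = true;
        for (size_t i = 0; i < del.size(); ++i)
          img[del[i].first + (size_t)nr * del[i].second] = 0;
      }
    }
  }
  LogicalMatrix out(nr, nc);
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r)
      out(r, c) = img[r + (size_t)nr * c] != 0;
  return out;
}

// Minimum Euclidean distance between midline points at least `min_sep`
// indices apart; used by the omega self-contact criterion.
// [[Rcpp::export]]
double min_self_distance(NumericMatrix pts, int min_sep) {
  int K = pts.nrow();
  double best = R_PosInf;
  for (int i = 0; i < K; ++i) {
    for (int j = i + min_sep; j < K; ++j) {
      double dx = pts(i, 0) - pts(j, 0);
      double dy = pts(i, 1) - pts(j, 1);
      double d = dx * dx + dy * dy;
      if (d < best) best = d;
    }
  }
  return std::sqrt(best);
}
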