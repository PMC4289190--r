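// Batch subwindow extraction: crop, bilinear resize to a fixed patch grid,
// and optional per-channel TRGB standardization, flattened channel-planar
// (attr = ch*edge^2 + row*edge + col, 0-based).

#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

// [[Rcpp::export]]
NumericMatrix cpp_extract_patches(NumericVector img, IntegerMatrix specs,
                                  int edge, bool normalize) {
  IntegerVector dims = img.attr("dim");
  if (dims.size() != 3) stop("image must be an H x W x C array");
  const int H = dims[0], W = dims[1], C = dims[2];
  const int plane = edge * edge, nattr = plane * C;
  const int nspec = specs.nrow();
  NumericMatrix out(nspec, nattr);
  const double* px = &img[0];

  std::vector<double> buf(plane);
  for (int s = 0; s < nspec; ++s) {
    const int r0 = specs(s, 0) - 1, c0 = specs(s, 1) - 1, side = specs(s, 2);
    if (r0 < 0 || c0 < 0 || r0 + side > H || c0 + side > W || side < 2)
      stop("subwindow outside image bounds");
    const double scale = (double)side / edge;
    for (int ch = 0; ch < C; ++ch) {
      const double* base = px + (size_t)H * W * ch;
      for (int i = 0; i < edge; ++i) {
        double sy = (i + 0.5) * scale - 0.5;
        if (sy < 0) sy = 0;
        if (sy > side - 1) sy = side - 1;
        const int y0 = (int)std::floor(sy);
        const int y1 = (y0 + 1 < side) ? y0 + 1 : y0;
        const double fy = sy - y0;
        for (int j = 0; j < edge; ++j) {
          double sx = (j + 0.5) * scale - 0.5;
          if (sx < 0) sx = 0;
          if (sx > side - 1) sx = side - 1;
          const int x0 = (int)std::floor(sx);
          const int x1 = (x0 + 1 < side) ? x0 + 1 : x0;
          const double fx = sx - x0;
          const double v00 = base[(r0 + y0) + (size_t)H * (c0 + x0)];
          const double v01 = base[(r0 + y0) + (size_t)H * (c0 + x1)];
          const double v10 = base[(r0 + y1) + (size_t)H * (c0 + x0)];
          const double v11 = base[(r0 + y1) + (size_t)H * (c0 + x1)];
          buf[i * edge + j] = (1 - fy) * ((1 - fx) * v00 + fx * v01) +
                              fy * ((1 - fx) * v10 + fx * v11);
        }
      }
      if (normalize) {
        double m = 0;
        for (int k = 0; k < plane; ++k) m += buf[k];
        m /= plane;
        double v = 0;
        for (int k = 0; k < plane; ++k) {
          const double d = buf[k] - m;
          v += d * d;
        }
        const double sd = std::sqrt(v / plane);  // population sd
        if (sd < 1e-9) {
          for (int k = 0; k < plane; ++k) out(s, ch * plane + k) = 0.0;
        } else {
          for (int k = 0; k < plane; ++k)
            out(s, ch * plane + k) = (buf[k] - m) / sd;
        }
      } else {
        for (int k = 0; k < plane; ++k) out(s, ch * plane + k) = buf[k];
      }
    }
  }
  return out;
}

// 8-connected component labeling (labels 1..k in scan order)
// [[Rcpp::export]]
IntegerMatrix cpp_label8(LogicalMatrix mask) {
  const int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix lab(H, W);
  std::vector<int> queue;
  int next = 0;
  for (int c = 0; c < W; ++c) {
    for (int r = 0; r < H; ++r) {
      if (!mask(r, c) || lab(r, c) != 0) continue;
      ++next;
      queue.clear();
      queue.push_back(r + H * c);
      lab(r, c) = next;
      while (!queue.empty()) {
        const int p = queue.back();
        queue.pop_back();
        const int pr = p % H, pc = p / H;
        for (int dr = -1; dr <= 1; ++dr)
          for (int dc = -1; dc <= 1; ++dc) {
            if (dr == 0 && dc == 0) continue;
            const int rr = pr + dr, cc = pc + dc;
            if (rr < 0 || rr >= H || cc < 0 || cc >= W) continue;
            if (mask(rr, cc) && lab(rr, cc) == 0) {
              lab(rr, cc) = next;
              queue.push_back(rr + H * cc);
            }
          }
      }
    }
  }
  return lab;
}
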