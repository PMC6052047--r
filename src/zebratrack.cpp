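#include <Rcpp.h>
using namespace Rcpp;

// Bilinear sampling of `img` (numeric matrix, row = y, col = x) at source
// coordinates obtained by applying the 2x3 affine [a b tx; c d ty] to each
// output pixel (x, y), 0-based: xs = a*x + b*y + tx, ys = c*x + d*y + ty.
// Out-of-range samples are filled with `fill`.
// [[Rcpp::export]]
NumericMatrix cpp_affine_sample(const NumericMatrix& img, int out_h, int out_w,
                                const NumericVector& affine, double fill) {
  const int H = img.nrow(), W = img.ncol();
  const double a = affine[0], b = affine[1], tx = affine[2];
  const double c = affine[3], d = affine[4], ty = affine[5];
  NumericMatrix out(out_h, out_w);
  for (int x = 0; x < out_w; ++x) {
    for (int y = 0; y < out_h; ++y) {
      const double xs = a * x + b * y + tx;
      const double ys = c * x + d * y + ty;
      if (xs < 0 || ys < 0 || xs > W - 1 || ys > H - 1) {
        out(y, x) = fill;
        continue;
      }
      const int x0 = (int)std::floor(xs), y0 = (int)std::floor(ys);
      const int x1 = std::min(x0 + 1, W - 1), y1 = std::min(y0 + 1, H - 1);
      const double fx = xs - x0, fy = ys - y0;
      out(y, x) = img(y0, x0) * (1 - fx) * (1 - fy) +
                  img(y0, x1) * fx * (1 - fy) +
                  img(y1, x0) * (1 - fx) * fy +
                  img(y1, x1) * fx * fy;
    }
  }
  return out;
}

// 8-connected component labelling of a logical/integer mask. Labels are
// assigned in raster order (column-major, matching R) of each component's
// first-encountered pixel, so the numbering is deterministic.
// [[Rcpp::export]]
IntegerMatrix cpp_label8(const LogicalMatrix& mask) {
  const int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix lab(H, W);
  std::vector<int> stack;
  int next = 0;
  for (int x = 0; x < W; ++x) {
    for (int y = 0; y < H; ++y) {
      if (!mask(y, x) || lab(y, x)) continue;
      ++next;
      stack.push_back(y + x * H);
      lab(y, x) = next;
      while (!stack.empty()) {
        const int idx = stack.back(); stack.pop_back();
        const int cy = idx % H, cx = idx / H;
        for (int dx = -1; dx <= 1; ++dx) {
          for (int dy = -1; dy <= 1; ++dy) {
            const int ny = cy + dy, nx = cx + dx;
            if (ny < 0 || nx < 0 || ny >= H || nx >= W) continue;
            if (mask(ny, nx) && !lab(ny, nx)) {
              lab(ny, nx) = next;
              stack.push_back(ny + nx * H);
            }
          }
        }
      }
    }
  }
  return lab;
}

// Accumulate magnitude-weighted orientation votes into per-cell histograms.
// `bin` holds 1-based bin indices (0 = no vote), `mag` the vote weights.
// Pixels beyond n_cr*cell rows / n_cc*cell cols are ignored (grid remainder).
// Returns an (n_cr * n_cc) x n_bins matrix, cells in column-major grid order.
// [[Rcpp::export]]
NumericMatrix cpp_cell_hist(const NumericMatrix& mag, const IntegerMatrix& bin,
                            int cell, int n_cr, int n_cc, int n_bins) {
  NumericMatrix out(n_cr * n_cc, n_bins);
  const int maxy = n_cr * cell, maxx = n_cc * cell;
  for (int x = 0; x < maxx; ++x) {
    const int cx = x / cell;
    for (int y = 0; y < maxy; ++y) {
      const int b = bin(y, x);
      if (b == 0) continue;
      const int cy = y / cell;
      out(cy + cx * n_cr, b - 1) += mag(y, x);
    }
  }
  return out;
}
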