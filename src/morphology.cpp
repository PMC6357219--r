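#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cfloat>
#include <functional>
using namespace Rcpp;

// Grayscale erosion/dilation with a non-flat spherical-cap ("rolling ball")
// structuring element of radius r pixels, cap height h(q) = sqrt(r^2 - |q|^2).
// Out-of-image offsets are ignored (+Inf / -Inf padding); the centre offset is
// always in-bounds so the opening is <= the input everywhere.
//
// Decomposition: for each |dy| = k the 2-D pass reduces to a 1-D erosion of
// every row with the cap of radius sqrt(r^2 - k^2); +k and -k share the same
// 1-D result, which is then combined across rows. All inner loops run over
// contiguous row memory.

static void erode1d_rows(const std::vector<float>& img, int H, int W,
                         const std::vector<float>& h, int w,
                         std::vector<float>& out, bool dilate) {
  // out(y, x) = min_{|dx|<=w} img(y, x+dx) - h[dx+w]   (erode)
  //           = max_{|dx|<=w} img(y, x+dx) + h[dx+w]   (dilate)
  const float sgn = dilate ? 1.0f : -1.0f;
  for (int y = 0; y < H; ++y) {
    const float* row = &img[(size_t)y * W];
    float* orow = &out[(size_t)y * W];
    // init with centre offset (always valid)
    const float h0 = h[w] * sgn;
    for (int x = 0; x < W; ++x) orow[x] = row[x] + h0;
    for (int d = 1; d <= w; ++d) {
      const float hd = h[w + d] * sgn;
      const float* rp = row + d;   // img(y, x+d) for x in [0, W-1-d]
      const int n = W - d;
      const float* rm = row - d; // img(y, x-d) for x in [d, W-1]
      if (dilate) {
        for (int x = 0; x < n; ++x) orow[x] = std::max(orow[x], rp[x] + hd);
        for (int x = d; x < W; ++x) orow[x] = std::max(orow[x], rm[x] + hd);
      } else {
        for (int x = 0; x < n; ++x) orow[x] = std::min(orow[x], rp[x] + hd);
        for (int x = d; x < W; ++x) orow[x] = std::min(orow[x], rm[x] + hd);
      }
    }
  }
}

static std::vector<float> ball_pass(const std::vector<float>& img, int H, int W,
                                    int r, bool dilate) {
  const double r2 = (double)r * r;
  std::vector<float> out((size_t)H * W, dilate ? -FLT_MAX : FLT_MAX);
  std::vector<float> tmp((size_t)H * W);
  for (int k = 0; k <= r; ++k) {
    const double rem = r2 - (double)k * k;
    if (rem < 0) continue;
    const int w = (int)std::floor(std::sqrt(rem));
    std::vector<float> h(2 * w + 1);
    for (int d = -w; d <= w; ++d)
      h[d + w] = (float)std::sqrt(rem - (double)d * d);
    erode1d_rows(img, H, W, h, w, tmp, dilate);
    // combine rows y-k and y+k into out row y
    for (int y = 0; y < H; ++y) {
      float* orow = &out[(size_t)y * W];
      for (int s = -1; s <= 1; s += 2) {
        const int yy = y + s * k;
        if (yy < 0 || yy >= H) continue;
        const float* trow = &tmp[(size_t)yy * W];
        if (dilate) { for (int x = 0; x < W; ++x) orow[x] = std::max(orow[x], trow[x]); }
        else        { for (int x = 0; x < W; ++x) orow[x] = std::min(orow[x], trow[x]); }
        if (k == 0) break;
      }
    }
  }
  return out;
}

// [[Rcpp::export(name = ".Call_ball_opening")]]
NumericMatrix ball_opening(NumericMatrix img, int radius) {
  const int H = img.nrow(), W = img.ncol();
  std::vector<float> f((size_t)H * W);
  for (int y = 0; y < H; ++y)
    for (int x = 0; x < W; ++x) f[(size_t)y * W + x] = (float)img(y, x);
  std::vector<float> er = ball_pass(f, H, W, radius, false);
  std::vector<float> op = ball_pass(er, H, W, radius, true);
  NumericMatrix out(H, W);
  for (int y = 0; y < H; ++y)
    for (int x = 0; x < W; ++x) out(y, x) = (double)op[(size_t)y * W + x];
  return out;
}

// Separable Gaussian blur, replicate boundary. Used for gradient smoothing and
// structure-tensor integration, where FFT-based 2-D convolution is needlessly
// expensive at sigma ~ 25 px.
// [[Rcpp::export(name = ".Call_gauss_blur")]]
NumericMatrix gauss_blur(NumericMatrix img, double sigma) {
  const int H = img.nrow(), W = img.ncol();
  if (sigma <= 0) return clone(img);
  const int r = std::max(1, (int)std::ceil(3.0 * sigma));
  std::vector<double> k(2 * r + 1);
  double s = 0;
  for (int i = -r; i <= r; ++i) { k[i + r] = std::exp(-0.5 * i * i / (sigma * sigma)); s += k[i + r]; }
  for (double& v : k) v /= s;
  NumericMatrix tmp(H, W), out(H, W);
  // along rows (y direction)
  for (int x = 0; x < W; ++x)
    for (int y = 0; y < H; ++y) {
      double acc = 0;
      for (int i = -r; i <= r; ++i) {
        int yy = y + i; if (yy < 0) yy = 0; else if (yy >= H) yy = H - 1;
        acc += k[i + r] * img(yy, x);
      }
      tmp(y, x) = acc;
    }
  // along columns (x direction)
  for (int y = 0; y < H; ++y)
    for (int x = 0; x < W; ++x) {
      double acc = 0;
      for (int i = -r; i <= r; ++i) {
        int xx = x + i; if (xx < 0) xx = 0; else if (xx >= W) xx = W - 1;
        acc += k[i + r] * tmp(y, xx);
      }
      out(y, x) = acc;
    }
  return out;
}

// Separable correlation with arbitrary row/column kernels (replicate
// boundary); used for derivative-of-Gaussian gradient filters.
// [[Rcpp::export(name = ".Call_sep_conv")]]
NumericMatrix sep_conv(NumericMatrix img, NumericVector krow, NumericVector kcol) {
  const int H = img.nrow(), W = img.ncol();
  const int ry = (krow.size() - 1) / 2, rx = (kcol.size() - 1) / 2;
  NumericMatrix tmp(H, W), out(H, W);
  for (int x = 0; x < W; ++x)
    for (int y = 0; y < H; ++y) {
      double acc = 0;
      for (int i = -ry; i <= ry; ++i) {
        int yy = y + i; if (yy < 0) yy = 0; else if (yy >= H) yy = H - 1;
        acc += krow[i + ry] * img(yy, x);
      }
      tmp(y, x) = acc;
    }
  for (int y = 0; y < H; ++y)
    for (int x = 0; x < W; ++x) {
      double acc = 0;
      for (int i = -rx; i <= rx; ++i) {
        int xx = x + i; if (xx < 0) xx = 0; else if (xx >= W) xx = W - 1;
        acc += kcol[i + rx] * tmp(y, xx);
      }
      out(y, x) = acc;
    }
  return out;
}

// 8-connected component labeling, two-pass union-find.
// [[Rcpp::export(name = ".Call_label8")]]
IntegerMatrix label8(LogicalMatrix mask) {
  const int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix lab(H, W);
  std::vector<int> parent(1, 0); // parent[0] unused
  std::function<int(int)> find = [&](int a) {
    while (parent[a] != a) { parent[a] = parent[parent[a]]; a = parent[a]; }
    return a;
  };
  auto unite = [&](int a, int b) {
    a = find(a); b = find(b);
    if (a != b) parent[std::max(a, b)] = std::min(a, b);
  };
  int next = 0;
  for (int y = 0; y < H; ++y) {
    for (int x = 0; x < W; ++x) {
      if (!mask(y, x)) continue;
      int best = 0;
      // neighbours already visited in raster order: W, NW, N, NE
      const int ny[4] = { y, y - 1, y - 1, y - 1 };
      const int nx[4] = { x - 1, x - 1, x, x + 1 };
      for (int i = 0; i < 4; ++i) {
        if (ny[i] < 0 || nx[i] < 0 || nx[i] >= W) continue;
        int l = lab(ny[i], nx[i]);
        if (l > 0) {
          if (best == 0) best = l;
          else unite(best, l);
        }
      }
      if (best == 0) {
        best = ++next;
        parent.push_back(best);
      }
      lab(y, x) = best;
    }
  }
  // relabel to consecutive ids
  std::vector<int> remap(next + 1, 0);
  int nlab = 0;
  for (int y = 0; y < H; ++y)
    for (int x = 0; x < W; ++x) {
      int l = lab(y, x);
      if (l == 0) continue;
      int r = find(l);
      if (remap[r] == 0) remap[r] = ++nlab;
      lab(y, x) = remap[r];
    }
  return lab;
}
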