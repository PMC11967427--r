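#include <Rcpp.h>
#include <queue>
#include <cmath>
using namespace Rcpp;

// Pixel coordinates are 0-based (x right / columns, y down / rows) throughout;
// R matrices are indexed [y + 1, x + 1].

// 8-connected connected-component labeling of a binary mask.
// [[Rcpp::export(name = ".label8_cpp")]]
IntegerMatrix label8_cpp(const LogicalMatrix& mask) {
  const int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix lab(H, W);
  int next = 0;
  std::queue<std::pair<int, int>> q;
  for (int x0 = 0; x0 < W; ++x0) {
    for (int y0 = 0; y0 < H; ++y0) {
      if (!mask(y0, x0) || lab(y0, x0)) continue;
      ++next;
      lab(y0, x0) = next;
      q.push(std::make_pair(y0, x0));
      while (!q.empty()) {
        const int y = q.front().first, x = q.front().second;
        q.pop();
        for (int dy = -1; dy <= 1; ++dy) {
          for (int dx = -1; dx <= 1; ++dx) {
            const int yy = y + dy, xx = x + dx;
            if (yy < 0 || yy >= H || xx < 0 || xx >= W) continue;
            if (mask(yy, xx) && !lab(yy, xx)) {
              lab(yy, xx) = next;
              q.push(std::make_pair(yy, xx));
            }
          }
        }
      }
    }
  }
  return lab;
}

// Fill holes: background connectivity is 4-connected (the complement of the
// 8-connected foreground), so interiors of diagonal edge rings do not leak.
// [[Rcpp::export(name = ".fill_holes_cpp")]]
LogicalMatrix fill_holes_cpp(const LogicalMatrix& mask) {
  const int H = mask.nrow(), W = mask.ncol();
  LogicalMatrix reach(H, W);
  std::queue<std::pair<int, int>> q;
  for (int x = 0; x < W; ++x) {
    for (int y = 0; y < H; ++y) {
      if ((x == 0 || x == W - 1 || y == 0 || y == H - 1) &&
          !mask(y, x) && !reach(y, x)) {
        reach(y, x) = true;
        q.push(std::make_pair(y, x));
      }
    }
  }
  const int d4y[4] = {-1, 1, 0, 0}, d4x[4] = {0, 0, -1, 1};
  while (!q.empty()) {
    const int y = q.front().first, x = q.front().second;
    q.pop();
    for (int k = 0; k < 4; ++k) {
      const int yy = y + d4y[k], xx = x + d4x[k];
      if (yy < 0 || yy >= H || xx < 0 || xx >= W) continue;
      if (!mask(yy, xx) && !reach(yy, xx)) {
        reach(yy, xx) = true;
        q.push(std::make_pair(yy, xx));
      }
    }
  }
  LogicalMatrix out(H, W);
  for (int x = 0; x < W; ++x)
    for (int y = 0; y < H; ++y)
      out(y, x) = mask(y, x) || !reach(y, x);
  return out;
}

// Moore-neighbour boundary tracing (8-connected, clockwise). Returns an
// ordered closed chain of boundary pixel coordinates (x, y), 0-based.
// [[Rcpp::export(name = ".trace_boundary_cpp")]]
IntegerMatrix trace_boundary_cpp(const LogicalMatrix& mask) {
  const int H = mask.nrow(), W = mask.ncol();
  int sy = -1, sx = -1;
  for (int y = 0; y < H && sy < 0; ++y)
    for (int x = 0; x < W; ++x)
      if (mask(y, x)) { sy = y; sx = x; break; }
  if (sy < 0) return IntegerMatrix(0, 2);
  // clockwise neighbour order starting east, in (x right, y down) coords
  const int dy[8] = {0, 1, 1, 1, 0, -1, -1, -1};
  const int dx[8] = {1, 1, 0, -1, -1, -1, 0, 1};
  std::vector<int> xs, ys;
  int cy = sy, cx = sx;
  // entered scanning row-major from the left, so backtrack direction is west
  int back = 4;
  xs.push_back(cx); ys.push_back(cy);
  int guard = 4 * (H * W + 8);
  int start_dir = -1;
  while (guard-- > 0) {
    int found = -1;
    for (int k = 1; k <= 8; ++k) {
      const int dir = (back + k) % 8;
      const int yy = cy + dy[dir], xx = cx + dx[dir];
      if (yy >= 0 && yy < H && xx >= 0 && xx < W && mask(yy, xx)) {
        found = dir;
        break;
      }
    }
    if (found < 0) break;           // isolated pixel
    if (cy == sy && cx == sx) {
      if (start_dir < 0) start_dir = found;
      else if (found == start_dir && xs.size() > 1) break;  // Jacob's stop
    }
    cy += dy[found];
    cx += dx[found];
    if (cy == sy && cx == sx) {
      // re-check stopping criterion on next loop entry
    }
    xs.push_back(cx); ys.push_back(cy);
    back = (found + 4) % 8;
    if (cy == sy && cx == sx && (int)xs.size() > 2) {
      // completed a loop; peek whether next move repeats the first
      int nxt = -1;
      for (int k = 1; k <= 8; ++k) {
        const int dir = (back + k) % 8;
        const int yy = cy + dy[dir], xx = cx + dx[dir];
        if (yy >= 0 && yy < H && xx >= 0 && xx < W && mask(yy, xx)) {
          nxt = dir;
          break;
        }
      }
      if (nxt == start_dir) break;
    }
  }
  // drop the duplicated closing vertex if present
  int n = xs.size();
  if (n > 1 && xs[n - 1] == xs[0] && ys[n - 1] == ys[0]) --n;
  IntegerMatrix out(n, 2);
  for (int i = 0; i < n; ++i) { out(i, 0) = xs[i]; out(i, 1) = ys[i]; }
  return out;
}

// Count of exposed pixel edges (pixel-edge perimeter), used for tiny shapes
// where a traced chain under-samples the outline.
// [[Rcpp::export(name = ".edge_perimeter_cpp")]]
double edge_perimeter_cpp(const LogicalMatrix& mask) {
  const int H = mask.nrow(), W = mask.ncol();
  int edges = 0;
  for (int x = 0; x < W; ++x) {
    for (int y = 0; y < H; ++y) {
      if (!mask(y, x)) continue;
      if (y == 0 || !mask(y - 1, x)) ++edges;
      if (y == H - 1 || !mask(y + 1, x)) ++edges;
      if (x == 0 || !mask(y, x - 1)) ++edges;
      if (x == W - 1 || !mask(y, x + 1)) ++edges;
    }
  }
  return (double)edges;
}

// Even-odd scanline rasterization of a closed polygon given in continuous
// pixel coordinates; a pixel is set when its centre (x, y) is interior.
// [[Rcpp::export(name = ".rasterize_polygon_cpp")]]
LogicalMatrix rasterize_polygon_cpp(const NumericVector& px,
                                    const NumericVector& py,
                                    int width, int height) {
  const int n = px.size();
  LogicalMatrix out(height, width);
  if (n < 3) return out;
  for (int y = 0; y < height; ++y) {
    const double yc = (double)y;
    std::vector<double> xcross;
    for (int i = 0; i < n; ++i) {
      const int j = (i + 1) % n;
      const double y1 = py[i], y2 = py[j];
      if ((y1 <= yc && y2 > yc) || (y2 <= yc && y1 > yc)) {
        const double t = (yc - y1) / (y2 - y1);
        xcross.push_back(px[i] + t * (px[j] - px[i]));
      }
    }
    std::sort(xcross.begin(), xcross.end());
    for (size_t k = 0; k + 1 < xcross.size(); k += 2) {
      int x0 = (int)std::ceil(xcross[k]);
      int x1 = (int)std::floor(xcross[k + 1]);
      if (x0 < 0) x0 = 0;
      if (x1 > width - 1) x1 = width - 1;
      for (int x = x0; x <= x1; ++x) out(y, x) = true;
    }
  }
  return out;
}

// 5x5 Gaussian smoothing (sigma 1.4, replicate border).
// [[Rcpp::export(name = ".gauss5_cpp")]]
NumericMatrix gauss5_cpp(const NumericMatrix& img) {
  const int H = img.nrow(), W = img.ncol();
  static double k[5][5];
  static bool init = false;
  if (!init) {
    const double s2 = 2.0 * 1.4 * 1.4;
    double sum = 0;
    for (int a = -2; a <= 2; ++a)
      for (int b = -2; b <= 2; ++b) {
        k[a + 2][b + 2] = std::exp(-(a * a + b * b) / s2);
        sum += k[a + 2][b + 2];
      }
    for (int a = 0; a < 5; ++a)
      for (int b = 0; b < 5; ++b) k[a][b] /= sum;
    init = true;
  }
  NumericMatrix out(H, W);
  for (int x = 0; x < W; ++x) {
    for (int y = 0; y < H; ++y) {
      double acc = 0;
      for (int a = -2; a <= 2; ++a) {
        int yy = y + a;
        if (yy < 0) yy = 0;
        if (yy >= H) yy = H - 1;
        for (int b = -2; b <= 2; ++b) {
          int xx = x + b;
          if (xx < 0) xx = 0;
          if (xx >= W) xx = W - 1;
          acc += k[a + 2][b + 2] * img(yy, xx);
        }
      }
      out(y, x) = acc;
    }
  }
  return out;
}

// Sobel first derivatives; returns gx, gy (replicate border).
// [[Rcpp::export(name = ".sobel_cpp")]]
List sobel_cpp(const NumericMatrix& img) {
  const int H = img.nrow(), W = img.ncol();
  NumericMatrix gx(H, W), gy(H, W);
  auto at = [&](int y, int x) {
    if (y < 0) y = 0;
    if (y >= H) y = H - 1;
    if (x < 0) x = 0;
    if (x >= W) x = W - 1;
    return img(y, x);
  };
  for (int x = 0; x < W; ++x) {
    for (int y = 0; y < H; ++y) {
      gx(y, x) = (at(y - 1, x + 1) + 2 * at(y, x + 1) + at(y + 1, x + 1)) -
                 (at(y - 1, x - 1) + 2 * at(y, x - 1) + at(y + 1, x - 1));
      gy(y, x) = (at(y + 1, x - 1) + 2 * at(y + 1, x) + at(y + 1, x + 1)) -
                 (at(y - 1, x - 1) + 2 * at(y - 1, x) + at(y - 1, x + 1));
    }
  }
  return List::create(_["gx"] = gx, _["gy"] = gy);
}

// Non-maximum suppression of the gradient magnitude along the quantized
// gradient direction (4 sectors). Non-maxima are zeroed.
// [[Rcpp::export(name = ".nms_cpp")]]
NumericMatrix nms_cpp(const NumericMatrix& mag, const NumericMatrix& gx,
                      const NumericMatrix& gy) {
  const int H = mag.nrow(), W = mag.ncol();
  NumericMatrix out(H, W);
  auto m = [&](int y, int x) {
    if (y < 0 || y >= H || x < 0 || x >= W) return 0.0;
    return mag(y, x);
  };
  for (int x = 0; x < W; ++x) {
    for (int y = 0; y < H; ++y) {
      const double v = mag(y, x);
      if (v <= 0) continue;
      double ang = std::atan2(gy(y, x), gx(y, x)) * 180.0 / M_PI;
      if (ang < 0) ang += 180.0;
      double n1, n2;
      if (ang < 22.5 || ang >= 157.5) {          // horizontal gradient
        n1 = m(y, x - 1); n2 = m(y, x + 1);
      } else if (ang < 67.5) {                   // diagonal \.
        n1 = m(y - 1, x - 1); n2 = m(y + 1, x + 1);
      } else if (ang < 112.5) {                  // vertical gradient
        n1 = m(y - 1, x); n2 = m(y + 1, x);
      } else {                                   // diagonal /
        n1 = m(y - 1, x + 1); n2 = m(y + 1, x - 1);
      }
      if (v >= n1 && v > n2) out(y, x) = v;
      else if (v >= n2 && v > n1) out(y, x) = v;
      else if (v >= n1 && v >= n2 && n1 == n2 && v == n1) {
        // flat plateau: keep, hysteresis connectivity resolves thickness
        out(y, x) = v;
      }
    }
  }
  return out;
}
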