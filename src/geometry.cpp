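#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <map>
#include <utility>
#include <algorithm>
using namespace Rcpp;

// Brute-force nearest neighbour: for each query row, index (1-based) and
// distance of the closest reference row. Point counts in this package are a
// few thousand, where the O(n*m) scan beats tree construction overhead.
// [[Rcpp::export(name = ".nn_index")]]
List nn_index(NumericMatrix query, NumericMatrix ref) {
  int nq = query.nrow(), nr = ref.nrow();
  IntegerVector idx(nq);
  NumericVector dist(nq);
  for (int i = 0; i < nq; ++i) {
    double qx = query(i, 0), qy = query(i, 1), qz = query(i, 2);
    double best = R_PosInf; int bj = 0;
    for (int j = 0; j < nr; ++j) {
      double dx = ref(j, 0) - qx, dy = ref(j, 1) - qy, dz = ref(j, 2) - qz;
      double d = dx * dx + dy * dy + dz * dz;
      if (d < best) { best = d; bj = j; }
    }
    idx[i] = bj + 1;
    dist[i] = std::sqrt(best);
  }
  return List::create(_["index"] = idx, _["distance"] = dist);
}

static inline void closest_on_triangle(const double *p, const double *a,
                                       const double *b, const double *c,
                                       double *out) {
  // Ericson, Real-Time Collision Detection, 5.1.5
  double ab[3], ac[3], ap[3];
  for (int k = 0; k < 3; ++k) { ab[k] = b[k] - a[k]; ac[k] = c[k] - a[k]; ap[k] = p[k] - a[k]; }
  double d1 = ab[0] * ap[0] + ab[1] * ap[1] + ab[2] * ap[2];
  double d2 = ac[0] * ap[0] + ac[1] * ap[1] + ac[2] * ap[2];
  if (d1 <= 0 && d2 <= 0) { for (int k = 0; k < 3; ++k) out[k] = a[k]; return; }
  double bp[3]; for (int k = 0; k < 3; ++k) bp[k] = p[k] - b[k];
  double d3 = ab[0] * bp[0] + ab[1] * bp[1] + ab[2] * bp[2];
  double d4 = ac[0] * bp[0] + ac[1] * bp[1] + ac[2] * bp[2];
  if (d3 >= 0 && d4 <= d3) { for (int k = 0; k < 3; ++k) out[k] = b[k]; return; }
  double vc = d1 * d4 - d3 * d2;
  if (vc <= 0 && d1 >= 0 && d3 <= 0) {
    double v = d1 / (d1 - d3);
    for (int k = 0; k < 3; ++k) out[k] = a[k] + v * ab[k];
    return;
  }
  double cp[3]; for (int k = 0; k < 3; ++k) cp[k] = p[k] - c[k];
  double d5 = ab[0] * cp[0] + ab[1] * cp[1] + ab[2] * cp[2];
  double d6 = ac[0] * cp[0] + ac[1] * cp[1] + ac[2] * cp[2];
  if (d6 >= 0 && d5 <= d6) { for (int k = 0; k < 3; ++k) out[k] = c[k]; return; }
  double vb = d5 * d2 - d1 * d6;
  if (vb <= 0 && d2 >= 0 && d6 <= 0) {
    double w = d2 / (d2 - d6);
    for (int k = 0; k < 3; ++k) out[k] = a[k] + w * ac[k];
    return;
  }
  double va = d3 * d6 - d5 * d4;
  if (va <= 0 && (d4 - d3) >= 0 && (d5 - d6) >= 0) {
    double w = (d4 - d3) / ((d4 - d3) + (d5 - d6));
    for (int k = 0; k < 3; ++k) out[k] = b[k] + w * (c[k] - b[k]);
    return;
  }
  double denom = 1.0 / (va + vb + vc);
  double v = vb * denom, w = vc * denom;
  for (int k = 0; k < 3; ++k) out[k] = a[k] + ab[k] * v + ac[k] * w;
}

// Closest point on a triangle mesh surface for each query point.
// [[Rcpp::export(name = ".closest_on_mesh")]]
List closest_on_mesh(NumericMatrix points, NumericMatrix verts,
                     IntegerMatrix faces) {
  int np = points.nrow(), nf = faces.nrow();
  NumericMatrix out(np, 3);
  NumericVector dist(np);
  IntegerVector fidx(np);
  for (int i = 0; i < np; ++i) {
    double p[3] = { points(i, 0), points(i, 1), points(i, 2) };
    double best = R_PosInf, bq[3] = {0, 0, 0}; int bf = 0;
    for (int f = 0; f < nf; ++f) {
      int ia = faces(f, 0) - 1, ib = faces(f, 1) - 1, ic = faces(f, 2) - 1;
      double a[3] = { verts(ia, 0), verts(ia, 1), verts(ia, 2) };
      double b[3] = { verts(ib, 0), verts(ib, 1), verts(ib, 2) };
      double c[3] = { verts(ic, 0), verts(ic, 1), verts(ic, 2) };
      double q[3];
      closest_on_triangle(p, a, b, c, q);
      double dx = q[0] - p[0], dy = q[1] - p[1], dz = q[2] - p[2];
      double d = dx * dx + dy * dy + dz * dz;
      if (d < best) { best = d; bf = f; for (int k = 0; k < 3; ++k) bq[k] = q[k]; }
    }
    for (int k = 0; k < 3; ++k) out(i, k) = bq[k];
    dist[i] = std::sqrt(best);
    fidx[i] = bf + 1;
  }
  return List::create(_["point"] = out, _["distance"] = dist, _["face"] = fidx);
}

// Orthographic z-buffer rasterizer. Inputs are per-face-corner 2D image
// coordinates (x right, y down; continuous, pixel (r,c) centre at
// (c-0.5, r-0.5)) and per-corner depth (smaller = nearer). Returns per-pixel
// face index (0 = background) and barycentric weights of the visible face.
// [[Rcpp::export(name = ".rasterize_corners")]]
List rasterize_corners(NumericMatrix corner_xy, NumericVector corner_z,
                       int n_faces, int width, int height) {
  IntegerMatrix face(height, width);
  NumericMatrix b1(height, width), b2(height, width), b3(height, width);
  NumericMatrix zbuf(height, width);
  std::fill(zbuf.begin(), zbuf.end(), R_PosInf);
  for (int f = 0; f < n_faces; ++f) {
    int i0 = 3 * f, i1 = 3 * f + 1, i2 = 3 * f + 2;
    double x0 = corner_xy(i0, 0), y0 = corner_xy(i0, 1);
    double x1 = corner_xy(i1, 0), y1 = corner_xy(i1, 1);
    double x2 = corner_xy(i2, 0), y2 = corner_xy(i2, 1);
    double area = (x1 - x0) * (y2 - y0) - (x2 - x0) * (y1 - y0);
    if (std::fabs(area) < 1e-12) continue;
    int cmin = std::max(0, (int)std::floor(std::min({x0, x1, x2}) - 0.5));
    int cmax = std::min(width - 1, (int)std::ceil(std::max({x0, x1, x2}) - 0.5));
    int rmin = std::max(0, (int)std::floor(std::min({y0, y1, y2}) - 0.5));
    int rmax = std::min(height - 1, (int)std::ceil(std::max({y0, y1, y2}) - 0.5));
    for (int r = rmin; r <= rmax; ++r) {
      double py = r + 0.5;
      for (int c = cmin; c <= cmax; ++c) {
        double px = c + 0.5;
        double w0 = ((x1 - px) * (y2 - py) - (x2 - px) * (y1 - py)) / area;
        double w1 = ((x2 - px) * (y0 - py) - (x0 - px) * (y2 - py)) / area;
        double w2 = 1.0 - w0 - w1;
        if (w0 < -1e-9 || w1 < -1e-9 || w2 < -1e-9) continue;
        double z = w0 * corner_z[i0] + w1 * corner_z[i1] + w2 * corner_z[i2];
        if (z < zbuf(r, c)) {
          zbuf(r, c) = z;
          face(r, c) = f + 1;
          b1(r, c) = w0; b2(r, c) = w1; b3(r, c) = w2;
        }
      }
    }
  }
  return List::create(_["face"] = face, _["b1"] = b1, _["b2"] = b2,
                      _["b3"] = b3, _["depth"] = zbuf);
}

// Gradient-based circular Hough transform on a binary (0/1) image.
// Votes are cast from Sobel edge pixels along the gradient direction
// (toward the bright side) for each candidate radius; the accumulator is
// perimeter-normalized so scores are comparable across radii. Returns
// detections (x, y, r, strength) sorted by decreasing strength after
// non-maximum suppression at min_dist.
// [[Rcpp::export(name = ".hough_circles")]]
NumericMatrix hough_circles(NumericMatrix img, double rmin, double rmax,
                            double sensitivity, double min_dist) {
  int H = img.nrow(), W = img.ncol();
  // Sobel gradients
  std::vector<double> gx(H * W, 0.0), gy(H * W, 0.0);
  for (int r = 1; r < H - 1; ++r)
    for (int c = 1; c < W - 1; ++c) {
      double sx = -img(r - 1, c - 1) + img(r - 1, c + 1)
                  - 2 * img(r, c - 1) + 2 * img(r, c + 1)
                  - img(r + 1, c - 1) + img(r + 1, c + 1);
      double sy = -img(r - 1, c - 1) - 2 * img(r - 1, c) - img(r - 1, c + 1)
                  + img(r + 1, c - 1) + 2 * img(r + 1, c) + img(r + 1, c + 1);
      gx[r * W + c] = sx;
      gy[r * W + c] = sy;
    }
  int nr = std::max(2, (int)std::round(rmax - rmin) + 1);
  std::vector<double> radii(nr);
  for (int i = 0; i < nr; ++i)
    radii[i] = rmin + (rmax - rmin) * i / (double)(nr - 1);
  std::vector<std::vector<double> > acc(nr, std::vector<double>(H * W, 0.0));
  for (int r = 1; r < H - 1; ++r)
    for (int c = 1; c < W - 1; ++c) {
      double sx = gx[r * W + c], sy = gy[r * W + c];
      double mag = std::sqrt(sx * sx + sy * sy);
      if (mag < 1.0) continue;  // binary edges have |g| >= 2
      double ux = sx / mag, uy = sy / mag;
      double px = c + 0.5, py = r + 0.5;
      for (int ri = 0; ri < nr; ++ri) {
        // gradient points from dark to bright: centre of a bright disc lies
        // along +g from the edge
        double cx = px + radii[ri] * ux, cy = py + radii[ri] * uy;
        int c0 = (int)std::floor(cx - 0.5), r0 = (int)std::floor(cy - 0.5);
        double fx = (cx - 0.5) - c0, fy = (cy - 0.5) - r0;
        for (int dr = 0; dr <= 1; ++dr)
          for (int dc = 0; dc <= 1; ++dc) {
            int rr = r0 + dr, cc = c0 + dc;
            if (rr < 0 || rr >= H || cc < 0 || cc >= W) continue;
            double w = (dr ? fy : 1 - fy) * (dc ? fx : 1 - fx);
            acc[ri][rr * W + cc] += w;
          }
      }
    }
  // per-pixel best radius with 3x3 pooled, perimeter-normalised score
  std::vector<double> score(H * W, 0.0), bestr(H * W, 0.0);
  for (int ri = 0; ri < nr; ++ri) {
    double norm = 2 * M_PI * radii[ri] * 2.0;  // ~2 px wide Sobel edge band
    for (int r = 1; r < H - 1; ++r)
      for (int c = 1; c < W - 1; ++c) {
        double s = 0;
        for (int dr = -1; dr <= 1; ++dr)
          for (int dc = -1; dc <= 1; ++dc)
            s += acc[ri][(r + dr) * W + (c + dc)];
        s /= norm;
        if (s > score[r * W + c]) { score[r * W + c] = s; bestr[r * W + c] = radii[ri]; }
      }
  }
  // candidate local maxima above sensitivity
  std::vector<std::pair<double, int> > cand;
  for (int r = 1; r < H - 1; ++r)
    for (int c = 1; c < W - 1; ++c) {
      double s = score[r * W + c];
      if (s < sensitivity) continue;
      bool ismax = true;
      for (int dr = -1; dr <= 1 && ismax; ++dr)
        for (int dc = -1; dc <= 1; ++dc) {
          if (!dr && !dc) continue;
          double sn = score[(r + dr) * W + (c + dc)];
          if (sn > s || (sn == s && (dr < 0 || (dr == 0 && dc < 0)))) { ismax = false; break; }
        }
      if (ismax) cand.push_back(std::make_pair(-s, r * W + c));
    }
  std::sort(cand.begin(), cand.end());
  std::vector<double> ox, oy, orad, ostr;
  for (size_t i = 0; i < cand.size(); ++i) {
    int pix = cand[i].second;
    int r = pix / W, c = pix % W;
    double rad = bestr[pix];
    // sub-pixel centre: centroid of the best-radius accumulator in 3x3
    int ri = 0;
    for (int k = 0; k < nr; ++k) if (radii[k] == rad) { ri = k; break; }
    double sw = 0, swx = 0, swy = 0;
    for (int dr = -1; dr <= 1; ++dr)
      for (int dc = -1; dc <= 1; ++dc) {
        double w = acc[ri][(r + dr) * W + (c + dc)];
        sw += w; swx += w * (c + dc + 0.5); swy += w * (r + dr + 0.5);
      }
    double cx = sw > 0 ? swx / sw : c + 0.5;
    double cy = sw > 0 ? swy / sw : r + 0.5;
    // radius refinement: accumulator-weighted mean over radii at this centre
    double rw = 0, rsum = 0;
    for (int k = 0; k < nr; ++k) {
      double s = 0;
      for (int dr = -1; dr <= 1; ++dr)
        for (int dc = -1; dc <= 1; ++dc)
          s += acc[k][(r + dr) * W + (c + dc)];
      s /= (2 * M_PI * radii[k]);
      rw += s; rsum += s * radii[k];
    }
    if (rw > 0) rad = rsum / rw;
    bool keep = true;
    for (size_t j = 0; j < ox.size(); ++j) {
      double dx = ox[j] - cx, dy = oy[j] - cy;
      // suppress candidates closer than min_dist to, or inside, an
      // already-accepted stronger circle
      if (std::sqrt(dx * dx + dy * dy) < std::max(min_dist, orad[j])) {
        keep = false; break;
      }
    }
    if (keep) {
      ox.push_back(cx); oy.push_back(cy); orad.push_back(rad);
      ostr.push_back(-cand[i].first);
    }
  }
  NumericMatrix out(ox.size(), 4);
  for (size_t i = 0; i < ox.size(); ++i) {
    out(i, 0) = ox[i]; out(i, 1) = oy[i]; out(i, 2) = orad[i]; out(i, 3) = ostr[i];
  }
  colnames(out) = CharacterVector::create("x", "y", "r", "strength");
  return out;
}

// Parity-fill voxelization of a closed mesh. Vertices must already be in
// continuous voxel-index coordinates (voxel (i,j,k) centre at integers,
// 0-based). Rays run along +z through each (x,y) integer column.
// [[Rcpp::export(name = ".voxelize_mesh")]]
LogicalVector voxelize_mesh(NumericMatrix verts, IntegerMatrix faces,
                            int nx, int ny, int nz) {
  LogicalVector out(nx * ny * nz, false);
  std::vector<std::vector<double> > crossings(nx * ny);
  const double eps = 1e-7;
  for (int f = 0; f < faces.nrow(); ++f) {
    int ia = faces(f, 0) - 1, ib = faces(f, 1) - 1, ic = faces(f, 2) - 1;
    double ax = verts(ia, 0) + eps, ay = verts(ia, 1) + 2 * eps, az = verts(ia, 2);
    double bx = verts(ib, 0) + eps, by = verts(ib, 1) + 2 * eps, bz = verts(ib, 2);
    double cx = verts(ic, 0) + eps, cy = verts(ic, 1) + 2 * eps, cz = verts(ic, 2);
    double area = (bx - ax) * (cy - ay) - (cx - ax) * (by - ay);
    if (std::fabs(area) < 1e-14) continue;
    int x0 = std::max(0, (int)std::ceil(std::min({ax, bx, cx})));
    int x1 = std::min(nx - 1, (int)std::floor(std::max({ax, bx, cx})));
    int y0 = std::max(0, (int)std::ceil(std::min({ay, by, cy})));
    int y1 = std::min(ny - 1, (int)std::floor(std::max({ay, by, cy})));
    for (int iy = y0; iy <= y1; ++iy)
      for (int ix = x0; ix <= x1; ++ix) {
        double w0 = ((bx - ix) * (cy - iy) - (cx - ix) * (by - iy)) / area;
        double w1 = ((cx - ix) * (ay - iy) - (ax - ix) * (cy - iy)) / area;
        double w2 = 1.0 - w0 - w1;
        if (w0 < 0 || w1 < 0 || w2 < 0) continue;
        crossings[iy * nx + ix].push_back(w0 * az + w1 * bz + w2 * cz);
      }
  }
  for (int iy = 0; iy < ny; ++iy)
    for (int ix = 0; ix < nx; ++ix) {
      std::vector<double> &z = crossings[iy * nx + ix];
      if (z.size() < 2) continue;
      std::sort(z.begin(), z.end());
      for (size_t k = 0; k + 1 < z.size(); k += 2) {
        int k0 = std::max(0, (int)std::ceil(z[k]));
        int k1 = std::min(nz - 1, (int)std::floor(z[k + 1]));
        for (int kk = k0; kk <= k1; ++kk)
          out[(kk * ny + iy) * nx + ix] = true;
      }
    }
  out.attr("dim") = IntegerVector::create(nx, ny, nz);
  return out;
}

// 3D binary dilation/erosion with a spherical structuring element.
// [[Rcpp::export(name = ".binary_morph3d")]]
LogicalVector binary_morph3d(LogicalVector vol, int radius, bool dilate) {
  IntegerVector dim = vol.attr("dim");
  int nx = dim[0], ny = dim[1], nz = dim[2];
  std::vector<int> off;
  for (int dz = -radius; dz <= radius; ++dz)
    for (int dy = -radius; dy <= radius; ++dy)
      for (int dx = -radius; dx <= radius; ++dx)
        if (dx * dx + dy * dy + dz * dz <= radius * radius) {
          off.push_back(dx); off.push_back(dy); off.push_back(dz);
        }
  int noff = off.size() / 3;
  LogicalVector out(vol.size());
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        bool val = !dilate;
        for (int o = 0; o < noff; ++o) {
          int xx = x + off[3 * o], yy = y + off[3 * o + 1], zz = z + off[3 * o + 2];
          bool v;
          if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
            v = false;
          else
            v = vol[(zz * ny + yy) * nx + xx];
          if (dilate) { if (v) { val = true; break; } }
          else if (!v) { val = false; break; }
        }
        out[(z * ny + y) * nx + x] = val;
      }
  out.attr("dim") = dim;
  return out;
}

// Keep the largest 6-connected foreground component, then fill internal
// holes (background voxels not 6-connected to the array border).
// [[Rcpp::export(name = ".largest_component_fill")]]
LogicalVector largest_component_fill(LogicalVector vol) {
  IntegerVector dim = vol.attr("dim");
  int nx = dim[0], ny = dim[1], nz = dim[2];
  int n = nx * ny * nz;
  std::vector<int> label(n, 0);
  int next = 0, best_label = 0, best_size = 0;
  std::vector<int> stack;
  const int dx[6] = {1, -1, 0, 0, 0, 0};
  const int dy[6] = {0, 0, 1, -1, 0, 0};
  const int dz[6] = {0, 0, 0, 0, 1, -1};
  for (int i = 0; i < n; ++i) {
    if (!vol[i] || label[i]) continue;
    ++next;
    int size = 0;
    stack.push_back(i);
    label[i] = next;
    while (!stack.empty()) {
      int cur = stack.back(); stack.pop_back();
      ++size;
      int x = cur % nx, y = (cur / nx) % ny, z = cur / (nx * ny);
      for (int d = 0; d < 6; ++d) {
        int xx = x + dx[d], yy = y + dy[d], zz = z + dz[d];
        if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz) continue;
        int j = (zz * ny + yy) * nx + xx;
        if (vol[j] && !label[j]) { label[j] = next; stack.push_back(j); }
      }
    }
    if (size > best_size) { best_size = size; best_label = next; }
  }
  // flood outside background from the border
  std::vector<char> outside(n, 0);
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        if (x != 0 && x != nx - 1 && y != 0 && y != ny - 1 && z != 0 && z != nz - 1)
          continue;
        int i = (z * ny + y) * nx + x;
        if (!(vol[i] && label[i] == best_label) && !outside[i]) {
          outside[i] = 1; stack.push_back(i);
        }
      }
  while (!stack.empty()) {
    int cur = stack.back(); stack.pop_back();
    int x = cur % nx, y = (cur / nx) % ny, z = cur / (nx * ny);
    for (int d = 0; d < 6; ++d) {
      int xx = x + dx[d], yy = y + dy[d], zz = z + dz[d];
      if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz) continue;
      int j = (zz * ny + yy) * nx + xx;
      if (!outside[j] && !(vol[j] && label[j] == best_label)) {
        outside[j] = 1; stack.push_back(j);
      }
    }
  }
  LogicalVector out(n);
  for (int i = 0; i < n; ++i) out[i] = !outside[i];
  out.attr("dim") = dim;
  return out;
}

// Separable 3D Gaussian smoothing (sigma in voxels).
// [[Rcpp::export(name = ".gauss_smooth3d")]]
NumericVector gauss_smooth3d(NumericVector vol, double sigma) {
  IntegerVector dim = vol.attr("dim");
  int nx = dim[0], ny = dim[1], nz = dim[2];
  if (sigma <= 0) return clone(vol);
  int rad = std::max(1, (int)std::ceil(3 * sigma));
  std::vector<double> kern(2 * rad + 1);
  double ks = 0;
  for (int i = -rad; i <= rad; ++i) {
    kern[i + rad] = std::exp(-0.5 * i * i / (sigma * sigma));
    ks += kern[i + rad];
  }
  for (size_t i = 0; i < kern.size(); ++i) kern[i] /= ks;
  NumericVector a = clone(vol), b(vol.size());
  // pass along x, y, z in turn
  for (int axis = 0; axis < 3; ++axis) {
    for (int z = 0; z < nz; ++z)
      for (int y = 0; y < ny; ++y)
        for (int x = 0; x < nx; ++x) {
          double s = 0;
          for (int k = -rad; k <= rad; ++k) {
            int xx = x, yy = y, zz = z;
            if (axis == 0) xx = std::min(nx - 1, std::max(0, x + k));
            else if (axis == 1) yy = std::min(ny - 1, std::max(0, y + k));
            else zz = std::min(nz - 1, std::max(0, z + k));
            s += kern[k + rad] * a[(zz * ny + yy) * nx + xx];
          }
          b[(z * ny + y) * nx + x] = s;
        }
    std::swap(a, b);
  }
  a.attr("dim") = dim;
  return a;
}

// Marching tetrahedra isosurface extraction. Each grid cube is split into
// six tetrahedra sharing the main diagonal, with face diagonals consistent
// between neighbouring cubes, so the output surface is watertight. Vertex
// coordinates are continuous 0-based voxel-index coordinates.
// [[Rcpp::export(name = ".marching_tetrahedra")]]
List marching_tetrahedra(NumericVector vol, double level) {
  IntegerVector dim = vol.attr("dim");
  int nx = dim[0], ny = dim[1], nz = dim[2];
  // cube corners: bit0 = x, bit1 = y, bit2 = z
  static const int tets[6][4] = {
    {0, 1, 3, 7}, {0, 3, 2, 7}, {0, 2, 6, 7},
    {0, 6, 4, 7}, {0, 4, 5, 7}, {0, 5, 1, 7}
  };
  std::map<std::pair<long long, long long>, int> edge_vertex;
  std::vector<double> vx, vy, vz;
  std::vector<int> tri;
  long long nxy = (long long)nx * ny;
  int cidx[8];
  long long gid[8];
  double val[8];
  double cx[8], cy[8], cz[8];
  for (int z = 0; z + 1 < nz; ++z)
    for (int y = 0; y + 1 < ny; ++y)
      for (int x = 0; x + 1 < nx; ++x) {
        for (int c = 0; c < 8; ++c) {
          int xx = x + (c & 1), yy = y + ((c >> 1) & 1), zz = z + ((c >> 2) & 1);
          gid[c] = (long long)zz * nxy + (long long)yy * nx + xx;
          val[c] = vol[gid[c]];
          cx[c] = xx; cy[c] = yy; cz[c] = zz;
          cidx[c] = c;
        }
        (void)cidx;
        for (int t = 0; t < 6; ++t) {
          int a = tets[t][0], b = tets[t][1], c = tets[t][2], d = tets[t][3];
          int corners[4] = {a, b, c, d};
          int inside = 0, in_id[4], out_id[4], nin = 0, nout = 0;
          for (int k = 0; k < 4; ++k) {
            if (val[corners[k]] > level) { in_id[nin++] = corners[k]; ++inside; }
            else out_id[nout++] = corners[k];
          }
          if (inside == 0 || inside == 4) continue;
          // edge-interpolated vertex between grid corners p (inside) and q
          // (outside), deduplicated by grid ids
          struct Local {
            static int ev(long long gp, long long gq, double vp, double vq,
                          double pxx, double pyy, double pzz,
                          double qxx, double qyy, double qzz, double lvl,
                          std::map<std::pair<long long, long long>, int> &m,
                          std::vector<double> &vx, std::vector<double> &vy,
                          std::vector<double> &vz) {
              std::pair<long long, long long> key(std::min(gp, gq), std::max(gp, gq));
              std::map<std::pair<long long, long long>, int>::iterator it = m.find(key);
              if (it != m.end()) return it->second;
              double tt = (lvl - vp) / (vq - vp);
              if (tt < 0) tt = 0; if (tt > 1) tt = 1;
              vx.push_back(pxx + tt * (qxx - pxx));
              vy.push_back(pyy + tt * (qyy - pyy));
              vz.push_back(pzz + tt * (qzz - pzz));
              int id = vx.size() - 1;
              m[key] = id;
              return id;
            }
          };
          if (inside == 1 || inside == 3) {
            int apex = (inside == 1) ? in_id[0] : out_id[0];
            int others[3];
            int n = 0;
            for (int k = 0; k < 4; ++k)
              if (corners[k] != apex) others[n++] = corners[k];
            int v0 = Local::ev(gid[apex], gid[others[0]], val[apex], val[others[0]],
                               cx[apex], cy[apex], cz[apex],
                               cx[others[0]], cy[others[0]], cz[others[0]], level,
                               edge_vertex, vx, vy, vz);
            int v1 = Local::ev(gid[apex], gid[others[1]], val[apex], val[others[1]],
                               cx[apex], cy[apex], cz[apex],
                               cx[others[1]], cy[others[1]], cz[others[1]], level,
                               edge_vertex, vx, vy, vz);
            int v2 = Local::ev(gid[apex], gid[others[2]], val[apex], val[others[2]],
                               cx[apex], cy[apex], cz[apex],
                               cx[others[2]], cy[others[2]], cz[others[2]], level,
                               edge_vertex, vx, vy, vz);
            tri.push_back(v0); tri.push_back(v1); tri.push_back(v2);
          } else {
            // two inside, two outside: quad on the four crossing edges
            int p0 = in_id[0], p1 = in_id[1], q0 = out_id[0], q1 = out_id[1];
            int v00 = Local::ev(gid[p0], gid[q0], val[p0], val[q0],
                                cx[p0], cy[p0], cz[p0], cx[q0], cy[q0], cz[q0],
                                level, edge_vertex, vx, vy, vz);
            int v01 = Local::ev(gid[p0], gid[q1], val[p0], val[q1],
                                cx[p0], cy[p0], cz[p0], cx[q1], cy[q1], cz[q1],
                                level, edge_vertex, vx, vy, vz);
            int v11 = Local::ev(gid[p1], gid[q1], val[p1], val[q1],
                                cx[p1], cy[p1], cz[p1], cx[q1], cy[q1], cz[q1],
                                level, edge_vertex, vx, vy, vz);
            int v10 = Local::ev(gid[p1], gid[q0], val[p1], val[q0],
                                cx[p1], cy[p1], cz[p1], cx[q0], cy[q0], cz[q0],
                                level, edge_vertex, vx, vy, vz);
            tri.push_back(v00); tri.push_back(v01); tri.push_back(v11);
            tri.push_back(v00); tri.push_back(v11); tri.push_back(v10);
          }
        }
      }
  int nv = vx.size(), nf = tri.size() / 3;
  NumericMatrix verts(nv, 3);
  for (int i = 0; i < nv; ++i) {
    verts(i, 0) = vx[i]; verts(i, 1) = vy[i]; verts(i, 2) = vz[i];
  }
  IntegerMatrix faces(nf, 3);
  for (int i = 0; i < nf; ++i) {
    faces(i, 0) = tri[3 * i] + 1;
    faces(i, 1) = tri[3 * i + 1] + 1;
    faces(i, 2) = tri[3 * i + 2] + 1;
  }
  return List::create(_["vertices"] = verts, _["faces"] = faces);
}
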