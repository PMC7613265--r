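#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Weighted pair-distance histogram. Bin b covers [b*dr, (b+1)*dr).
// Returns the per-bin sum of w_i*w_j over unordered pairs, the per-bin
// weighted mean distance (for accurate Debye evaluation), and dmax.
// [[Rcpp::export]]
List cpp_pair_hist(NumericMatrix xyz, NumericVector w, double dr) {
  const int n = xyz.nrow();
  if (dr <= 0) stop("dr must be > 0");
  std::vector<double> counts, dsum;
  double dmax = 0.0;
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double dx = xyz(i,0) - xyz(j,0);
      double dy = xyz(i,1) - xyz(j,1);
      double dz = xyz(i,2) - xyz(j,2);
      double d = std::sqrt(dx*dx + dy*dy + dz*dz);
      if (d > dmax) dmax = d;
      int b = (int)(d / dr);
      if ((size_t)b >= counts.size()) { counts.resize(b + 1, 0.0); dsum.resize(b + 1, 0.0); }
      double ww = w[i] * w[j];
      counts[b] += ww;
      dsum[b] += ww * d;
    }
  }
  NumericVector cnt(counts.begin(), counts.end());
  NumericVector dmean(counts.size());
  for (size_t b = 0; b < counts.size(); ++b)
    dmean[b] = counts[b] > 0 ? dsum[b] / counts[b] : (b + 0.5) * dr;
  return List::create(_["counts"] = cnt, _["dmean"] = dmean, _["dmax"] = dmax);
}

// Exact Debye double sum: I(q) = sum_ij w_i w_j sinc(q r_ij), sinc(0) = 1.
// [[Rcpp::export]]
NumericVector cpp_debye_exact(NumericMatrix xyz, NumericVector w, NumericVector q) {
  const int n = xyz.nrow(), nq = q.size();
  NumericVector I(nq);
  double sw2 = 0.0;
  for (int i = 0; i < n; ++i) sw2 += w[i] * w[i];
  for (int k = 0; k < nq; ++k) I[k] = sw2;
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double dx = xyz(i,0) - xyz(j,0);
      double dy = xyz(i,1) - xyz(j,1);
      double dz = xyz(i,2) - xyz(j,2);
      double d = std::sqrt(dx*dx + dy*dy + dz*dz);
      double ww = 2.0 * w[i] * w[j];
      for (int k = 0; k < nq; ++k) {
        double x = q[k] * d;
        I[k] += ww * (x == 0.0 ? 1.0 : std::sin(x) / x);
      }
    }
  }
  return I;
}

// Count bead pairs closer than `threshold`, excluding pairs adjacent along
// a chain (same chain id and consecutive row index). Cell-list accelerated.
// [[Rcpp::export]]
double cpp_clash_count(NumericMatrix xyz, double threshold, IntegerVector chain) {
  const int n = xyz.nrow();
  if (n < 2) return 0.0;
  double xmin[3], xmax[3];
  for (int a = 0; a < 3; ++a) { xmin[a] = xyz(0,a); xmax[a] = xyz(0,a); }
  for (int i = 1; i < n; ++i)
    for (int a = 0; a < 3; ++a) {
      if (xyz(i,a) < xmin[a]) xmin[a] = xyz(i,a);
      if (xyz(i,a) > xmax[a]) xmax[a] = xyz(i,a);
    }
  const double cell = threshold;
  int nc[3];
  for (int a = 0; a < 3; ++a) {
    nc[a] = (int)((xmax[a] - xmin[a]) / cell) + 1;
    if (nc[a] < 1) nc[a] = 1;
  }
  std::vector<std::vector<int> > cells((size_t)nc[0] * nc[1] * nc[2]);
  std::vector<int> ci(n), cj(n), ck(n);
  for (int i = 0; i < n; ++i) {
    ci[i] = std::min((int)((xyz(i,0) - xmin[0]) / cell), nc[0] - 1);
    cj[i] = std::min((int)((xyz(i,1) - xmin[1]) / cell), nc[1] - 1);
    ck[i] = std::min((int)((xyz(i,2) - xmin[2]) / cell), nc[2] - 1);
    cells[ci[i] + (size_t)nc[0] * (cj[i] + (size_t)nc[1] * ck[i])].push_back(i);
  }
  const double t2 = threshold * threshold;
  double count = 0.0;
  for (int i = 0; i < n; ++i) {
    for (int dx = -1; dx <= 1; ++dx) {
      int x = ci[i] + dx; if (x < 0 || x >= nc[0]) continue;
      for (int dy = -1; dy <= 1; ++dy) {
        int y = cj[i] + dy; if (y < 0 || y >= nc[1]) continue;
        for (int dz = -1; dz <= 1; ++dz) {
          int z = ck[i] + dz; if (z < 0 || z >= nc[2]) continue;
          const std::vector<int> &cl = cells[x + (size_t)nc[0] * (y + (size_t)nc[1] * z)];
          for (size_t m = 0; m < cl.size(); ++m) {
            int j = cl[m];
            if (j <= i) continue;
            if (chain[i] == chain[j] && j - i == 1) continue;
            double ddx = xyz(i,0) - xyz(j,0);
            double ddy = xyz(i,1) - xyz(j,1);
            double ddz = xyz(i,2) - xyz(j,2);
            if (ddx*ddx + ddy*ddy + ddz*ddz < t2) count += 1.0;
          }
        }
      }
    }
  }
  return count;
}

static inline bool ev_ok(double px, double py, double pz,
                         const std::vector<double> &lx, const std::vector<double> &ly,
                         const std::vector<double> &lz, int upto,
                         NumericMatrix context, double excl2) {
  // linker beads with index <= upto (non-adjacent predecessors)
  for (int j = 0; j <= upto; ++j) {
    double dx = px - lx[j], dy = py - ly[j], dz = pz - lz[j];
    if (dx*dx + dy*dy + dz*dz < excl2) return false;
  }
  for (int j = 0; j < context.nrow(); ++j) {
    double dx = px - context(j,0), dy = py - context(j,1), dz = pz - context(j,2);
    if (dx*dx + dy*dy + dz*dz < excl2) return false;
  }
  return true;
}

// Self-avoiding random-coil linker: fixed virtual bonds of length `bond`,
// bond angle uniform in [angle_lo, angle_hi] degrees, dihedral uniform in
// [-180, 180). Every bead must be >= `excl` from every non-adjacent linker
// bead and from every context bead. Whole-linker restart on dead ends.
// Uses R's RNG (deterministic under set.seed()).
// [[Rcpp::export]]
NumericMatrix cpp_sample_linker(int n, NumericVector start, NumericVector dir,
                                NumericMatrix context, double bond, double excl,
                                double angle_lo, double angle_hi,
                                int max_restarts, int inner_tries) {
  if (n < 1) stop("n must be >= 1");
  const double excl2 = excl * excl;
  const double deg = M_PI / 180.0;
  std::vector<double> lx(n), ly(n), lz(n);
  int restarts = 0;
  while (true) {
    bool ok = true;
    // virtual previous pair defining the initial frame
    double p2x = start[0] - dir[0], p2y = start[1] - dir[1], p2z = start[2] - dir[2];
    double p1x = start[0], p1y = start[1], p1z = start[2];
    for (int i = 0; i < n; ++i) {
      bool placed = false;
      for (int t = 0; t < inner_tries; ++t) {
        double theta = (angle_lo + R::runif(0.0, 1.0) * (angle_hi - angle_lo)) * deg;
        double phi = (-180.0 + R::runif(0.0, 1.0) * 360.0) * deg;
        // frame: b1 along previous bond
        double b1x = p1x - p2x, b1y = p1y - p2y, b1z = p1z - p2z;
        double nb = std::sqrt(b1x*b1x + b1y*b1y + b1z*b1z);
        b1x /= nb; b1y /= nb; b1z /= nb;
        double rx = 1.0, ry = 0.0, rz = 0.0;
        if (std::fabs(b1x) > 0.9) { rx = 0.0; ry = 1.0; }
        double n1x = b1y*rz - b1z*ry, n1y = b1z*rx - b1x*rz, n1z = b1x*ry - b1y*rx;
        double nn = std::sqrt(n1x*n1x + n1y*n1y + n1z*n1z);
        n1x /= nn; n1y /= nn; n1z /= nn;
        double n2x = b1y*n1z - b1z*n1y, n2y = b1z*n1x - b1x*n1z, n2z = b1x*n1y - b1y*n1x;
        double ca = std::cos(M_PI - theta), sa = std::sin(M_PI - theta);
        double cp = std::cos(phi), sp = std::sin(phi);
        double ux = ca*b1x + sa*(cp*n1x + sp*n2x);
        double uy = ca*b1y + sa*(cp*n1y + sp*n2y);
        double uz = ca*b1z + sa*(cp*n1z + sp*n2z);
        double px = p1x + bond*ux, py = p1y + bond*uy, pz = p1z + bond*uz;
        if (ev_ok(px, py, pz, lx, ly, lz, i - 2, context, excl2)) {
          lx[i] = px; ly[i] = py; lz[i] = pz;
          p2x = p1x; p2y = p1y; p2z = p1z;
          p1x = px; p1y = py; p1z = pz;
          placed = true;
          break;
        }
      }
      if (!placed) { ok = false; break; }
    }
    if (ok) break;
    if (++restarts >= max_restarts)
      stop("linker sampling failed after %d restarts", restarts);
  }
  NumericMatrix out(n, 3);
  for (int i = 0; i < n; ++i) { out(i,0) = lx[i]; out(i,1) = ly[i]; out(i,2) = lz[i]; }
  return out;
}

// Trilinear interpolation of a 3-D array at continuous 0-based voxel
// coordinates. Points outside the grid evaluate to `fill`.
// [[Rcpp::export]]
NumericVector cpp_trilinear(NumericVector vol, IntegerVector dim,
                            NumericMatrix pts, double fill) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int m = pts.nrow();
  NumericVector out(m);
  for (int p = 0; p < m; ++p) {
    double x = pts(p,0), y = pts(p,1), z = pts(p,2);
    if (x < 0 || y < 0 || z < 0 || x > nx - 1 || y > ny - 1 || z > nz - 1) {
      out[p] = fill;
      continue;
    }
    int x0 = (int)x, y0 = (int)y, z0 = (int)z;
    if (x0 == nx - 1) x0--;
    if (y0 == ny - 1) y0--;
    if (z0 == nz - 1) z0--;
    double fx = x - x0, fy = y - y0, fz = z - z0;
    double v = 0.0;
    for (int dx = 0; dx <= 1; ++dx)
      for (int dy = 0; dy <= 1; ++dy)
        for (int dz = 0; dz <= 1; ++dz) {
          double wgt = (dx ? fx : 1 - fx) * (dy ? fy : 1 - fy) * (dz ? fz : 1 - fz);
          v += wgt * vol[(x0 + dx) + (size_t)nx * ((y0 + dy) + (size_t)ny * (z0 + dz))];
        }
    out[p] = v;
  }
  return out;
}

static double delta_of(const std::vector<int> &ch, IntegerVector blobs) {
  const int N = ch.size();
  int npos = 0, nneg = 0;
  for (int i = 0; i < N; ++i) {
    if (ch[i] > 0) ++npos;
    else if (ch[i] < 0) ++nneg;
  }
  double fp = (double)npos / N, fm = (double)nneg / N;
  double sig_seq = (fp + fm) > 0 ? (fp - fm) * (fp - fm) / (fp + fm) : 0.0;
  double dsum = 0.0;
  int used = 0;
  for (int b = 0; b < blobs.size(); ++b) {
    int g = blobs[b];
    if (g > N) continue;
    int nw = N - g + 1;
    int wp = 0, wm = 0;
    for (int i = 0; i < g; ++i) {
      if (ch[i] > 0) ++wp;
      else if (ch[i] < 0) ++wm;
    }
    double acc = 0.0;
    for (int w = 0; ; ++w) {
      double gfp = (double)wp / g, gfm = (double)wm / g;
      double sig = (gfp + gfm) > 0 ? (gfp - gfm) * (gfp - gfm) / (gfp + gfm) : 0.0;
      double d = sig - sig_seq;
      acc += d * d;
      if (w == nw - 1) break;
      if (ch[w] > 0) --wp; else if (ch[w] < 0) --wm;
      if (ch[w + g] > 0) ++wp; else if (ch[w + g] < 0) ++wm;
    }
    dsum += acc / nw;
    ++used;
  }
  if (used == 0) return NA_REAL;
  return dsum / used;
}

// Charge-patterning delta: mean over blob sizes of the mean squared
// deviation of the per-window charge asymmetry from the sequence asymmetry.
// charge: +1 / 0 / -1 per residue.
// [[Rcpp::export]]
double cpp_delta(IntegerVector charge, IntegerVector blobs) {
  std::vector<int> ch(charge.begin(), charge.end());
  return delta_of(ch, blobs);
}

// Maximum delta over deterministic block-segregated rearrangements of the
// composition. Three run families are searched (s in {+1,-1}, sbar = -s):
//   A: [0 n1][s all][0 n2][sbar all][0 n3]        (all neutral splits)
//   B: [s a][0 n1][sbar all][0 n2][s rest]        (one species end-split)
// Family B captures the boundary effect of short sequences, where moving a
// few charges of one species to the far end maximizes the window variance.
// Returns the maximum and an arrangement attaining it.
// [[Rcpp::export]]
List cpp_deltamax(int npos, int nneg, int nneu, IntegerVector blobs) {
  const int N = npos + nneg + nneu;
  double best = -1.0;
  std::vector<int> ch(N), bestarr(N, 0);
  const int signs[2] = { 1, -1 };
  for (int si = 0; si < 2; ++si) {
    int s = signs[si];
    int ns = (s > 0) ? npos : nneg;
    int nb = (s > 0) ? nneg : npos;
    // family A
    for (int n1 = 0; n1 <= nneu; ++n1) {
      for (int n2 = 0; n2 <= nneu - n1; ++n2) {
        int k = 0;
        for (int i = 0; i < n1; ++i) ch[k++] = 0;
        for (int i = 0; i < ns; ++i) ch[k++] = s;
        for (int i = 0; i < n2; ++i) ch[k++] = 0;
        for (int i = 0; i < nb; ++i) ch[k++] = -s;
        for (int i = 0; i < nneu - n1 - n2; ++i) ch[k++] = 0;
        double d = delta_of(ch, blobs);
        if (!ISNA(d) && d > best) { best = d; bestarr = ch; }
      }
    }
    // family B
    for (int a = 0; a <= ns; ++a) {
      for (int n1 = 0; n1 <= nneu; ++n1) {
        int n2 = nneu - n1;
        int k = 0;
        for (int i = 0; i < a; ++i) ch[k++] = s;
        for (int i = 0; i < n1; ++i) ch[k++] = 0;
        for (int i = 0; i < nb; ++i) ch[k++] = -s;
        for (int i = 0; i < n2; ++i) ch[k++] = 0;
        for (int i = 0; i < ns - a; ++i) ch[k++] = s;
        double d = delta_of(ch, blobs);
        if (!ISNA(d) && d > best) { best = d; bestarr = ch; }
      }
    }
  }
  return List::create(_["delta_max"] = best,
                      _["arrangement"] = IntegerVector(bestarr.begin(), bestarr.end()));
}
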