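#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

static const double kDeg2Rad = M_PI / 180.0;

// Bilinear lookup with edge clamping of the +1 neighbour; sx, sy must already
// lie inside [0, w-1] x [0, h-1].  Re-quantizes round-half-to-even (rint with
// the default FP rounding mode).
static inline int bilinear_at(const IntegerMatrix& img, double sx, double sy,
                              int w, int h) {
  int x0 = (int)std::floor(sx), y0 = (int)std::floor(sy);
  double fx = sx - x0, fy = sy - y0;
  int x1 = x0 + 1, y1 = y0 + 1;
  if (x1 > w - 1) x1 = w - 1;  // only reachable when fx == 0
  if (y1 > h - 1) y1 = h - 1;
  double v = (1.0 - fy) * ((1.0 - fx) * img(y0, x0) + fx * img(y0, x1)) +
             fy * ((1.0 - fx) * img(y1, x0) + fx * img(y1, x1));
  int iv = (int)std::rint(v);
  if (iv < 0) iv = 0;
  if (iv > 255) iv = 255;
  return iv;
}

// Rigid resampling of an 8-bit image.  The pose (theta, tx, ty) is the
// forward transform "rotate by theta (degrees, CCW) about the geometric
// center ((w-1)/2, (h-1)/2), then translate by (tx, ty)".  invert = false
// applies the pose (inverse mapping: src = R(-theta)(p - c - t) + c);
// invert = true undoes it (src = R(theta)(p - c) + c + t).  interp: 0 =
// nearest, 1 = bilinear.
// [[Rcpp::export]]
List cpp_rigid_resample(IntegerMatrix img, double theta, int tx, int ty,
                        int interp, bool invert) {
  int h = img.nrow(), w = img.ncol();
  double cx = (w - 1) / 2.0, cy = (h - 1) / 2.0;
  double a = theta * kDeg2Rad, ca = std::cos(a), sa = std::sin(a);
  IntegerMatrix out(h, w);
  LogicalMatrix mask(h, w);
  for (int y = 0; y < h; ++y) {
    for (int x = 0; x < w; ++x) {
      double sx, sy;
      if (!invert) {
        double dx = x - cx - tx, dy = y - cy - ty;
        sx = ca * dx + sa * dy + cx;
        sy = -sa * dx + ca * dy + cy;
      } else {
        double dx = x - cx, dy = y - cy;
        sx = ca * dx - sa * dy + cx + tx;
        sy = sa * dx + ca * dy + cy + ty;
      }
      if (interp == 0) {
        int ix = (int)std::rint(sx), iy = (int)std::rint(sy);
        if (ix >= 0 && ix < w && iy >= 0 && iy < h) {
          out(y, x) = img(iy, ix);
          mask(y, x) = true;
        }
      } else {
        if (sx >= 0.0 && sx <= w - 1.0 && sy >= 0.0 && sy <= h - 1.0) {
          out(y, x) = bilinear_at(img, sx, sy, w, h);
          mask(y, x) = true;
        }
      }
    }
  }
  return List::create(_["image"] = out, _["mask"] = mask);
}

// Exhaustive 2D/2D alignment of one target slice against the floating image.
// Grid scanned in ascending (theta, ty, tx) order; the first strictly larger
// score wins, which realises the smallest-theta/ty/tx tie rule.  A candidate
// pose p is scored by sampling the floating image at forward-transformed
// target coordinates (the invert = true mapping above), so the winning pose
// satisfies rigid_resample(slice, pose) ~ floating.  metric: 0 = NMI
// (entropy ratio from the 256x256 joint histogram), 1 = Pearson cross-
// correlation.  Grid points whose valid-overlap fraction is below
// min_overlap, or whose correlation is degenerate, are skipped.
// [[Rcpp::export]]
List cpp_align_slice(IntegerMatrix target, IntegerMatrix floating,
                     NumericVector thetas, IntegerVector txs,
                     IntegerVector tys, double min_overlap, int metric,
                     int interp) {
  const int h = target.nrow(), w = target.ncol();
  const int npix = w * h;
  const double cx = (w - 1) / 2.0, cy = (h - 1) / 2.0;
  const double log2e = 1.0 / std::log(2.0);

  // column-major copies for cheap linear indexing
  std::vector<int> tv(npix), fv(npix);
  for (int x = 0; x < w; ++x)
    for (int y = 0; y < h; ++y) {
      tv[x * h + y] = target(y, x);
      fv[x * h + y] = floating(y, x);
    }

  std::vector<double> sx0(npix), sy0(npix);
  std::vector<int> bx(npix), by(npix);

  std::vector<int> counts(65536, 0), mt(256, 0), mf(256, 0);
  std::vector<int> touched;
  touched.reserve(npix);

  double best_score = R_NegInf;
  double best_theta = NA_REAL;
  int best_tx = NA_INTEGER, best_ty = NA_INTEGER;
  long evaluations = 0, skipped = 0;
  const int min_valid = (int)std::ceil(min_overlap * npix);

  for (int it = 0; it < thetas.size(); ++it) {
    double a = thetas[it] * kDeg2Rad, ca = std::cos(a), sa = std::sin(a);
    // per-theta source coordinates before the (integer) translation
    for (int x = 0; x < w; ++x) {
      double dx = x - cx;
      for (int y = 0; y < h; ++y) {
        double dy = y - cy;
        int i = x * h + y;
        sx0[i] = ca * dx - sa * dy + cx;
        sy0[i] = sa * dx + ca * dy + cy;
        if (interp == 0) {
          bx[i] = (int)std::rint(sx0[i]);
          by[i] = (int)std::rint(sy0[i]);
        }
      }
    }
    for (int iy = 0; iy < tys.size(); ++iy) {
      int ty = tys[iy];
      for (int ix = 0; ix < txs.size(); ++ix) {
        int tx = txs[ix];
        double score;
        bool ok;
        if (metric == 0) {
          int n = 0;
          touched.clear();
          if (interp == 0) {
            for (int i = 0; i < npix; ++i) {
              int sx = bx[i] + tx, sy = by[i] + ty;
              if (sx >= 0 && sx < w && sy >= 0 && sy < h) {
                int t = tv[i], f = fv[sx * h + sy];
                int idx = t * 256 + f;
                if (counts[idx]++ == 0) touched.push_back(idx);
                ++mt[t];
                ++mf[f];
                ++n;
              }
            }
          } else {
            for (int i = 0; i < npix; ++i) {
              double sx = sx0[i] + tx, sy = sy0[i] + ty;
              if (sx >= 0.0 && sx <= w - 1.0 && sy >= 0.0 && sy <= h - 1.0) {
                int t = tv[i], f = bilinear_at(floating, sx, sy, w, h);
                int idx = t * 256 + f;
                if (counts[idx]++ == 0) touched.push_back(idx);
                ++mt[t];
                ++mf[f];
                ++n;
              }
            }
          }
          ok = n >= min_valid && n >= 1;
          if (ok) {
            double ht = 0.0, hf = 0.0, htf = 0.0, dn = (double)n;
            for (int t = 0; t < 256; ++t)
              if (mt[t]) {
                double p = mt[t] / dn;
                ht -= p * std::log(p) * log2e;
              }
            for (int f = 0; f < 256; ++f)
              if (mf[f]) {
                double p = mf[f] / dn;
                hf -= p * std::log(p) * log2e;
              }
            for (size_t j = 0; j < touched.size(); ++j) {
              double p = counts[touched[j]] / dn;
              htf -= p * std::log(p) * log2e;
            }
            score = (htf == 0.0) ? 2.0 : (ht + hf) / htf;
          } else {
            score = R_NegInf;
          }
          // reset sparse histogram
          for (size_t j = 0; j < touched.size(); ++j) counts[touched[j]] = 0;
          std::fill(mt.begin(), mt.end(), 0);
          std::fill(mf.begin(), mf.end(), 0);
        } else {
          // Pearson cross-correlation over the valid overlap
          double st = 0, sf = 0, stt = 0, sff = 0, stf = 0;
          int n = 0;
          if (interp == 0) {
            for (int i = 0; i < npix; ++i) {
              int sx = bx[i] + tx, sy = by[i] + ty;
              if (sx >= 0 && sx < w && sy >= 0 && sy < h) {
                double t = tv[i], f = fv[sx * h + sy];
                st += t; sf += f; stt += t * t; sff += f * f; stf += t * f;
                ++n;
              }
            }
          } else {
            for (int i = 0; i < npix; ++i) {
              double sx = sx0[i] + tx, sy = sy0[i] + ty;
              if (sx >= 0.0 && sx <= w - 1.0 && sy >= 0.0 && sy <= h - 1.0) {
                double t = tv[i], f = bilinear_at(floating, sx, sy, w, h);
                st += t; sf += f; stt += t * t; sff += f * f; stf += t * f;
                ++n;
              }
            }
          }
          double vt = n * stt - st * st, vf = n * sff - sf * sf;
          ok = n >= min_valid && n >= 2 && vt > 0.0 && vf > 0.0;
          score = ok ? (n * stf - st * sf) / std::sqrt(vt * vf) : R_NegInf;
        }
        if (ok) {
          ++evaluations;
          if (score > best_score) {
            best_score = score;
            best_theta = thetas[it];
            best_tx = tx;
            best_ty = ty;
          }
        } else {
          ++skipped;
        }
      }
    }
  }

  return List::create(
      _["found"] = evaluations > 0, _["theta"] = best_theta,
      _["tx"] = best_tx, _["ty"] = best_ty, _["score"] = best_score,
      _["evaluations"] = (double)evaluations, _["skipped"] = (double)skipped);
}
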