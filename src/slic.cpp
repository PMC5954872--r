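#include <Rcpp.h>
using namespace Rcpp;

// Iterative local k-means over (row, col, gray) with the similarity index
// D = (mu / S) * d_xy + d_g, where d_xy is the Euclidean distance in the
// image plane and d_g the absolute gray-level distance to the center mean.
// Each pixel competes among centers within a (2 * spacing) window; centers
// are updated to the mean position / mean gray of their members.  Labels of
// pixels never reached by any window remain 0 (resolved by the caller's
// connectivity pass).  Fully deterministic: ties keep the first center.
//
// centers: K x 3 matrix (row, col, gray), 0-based coordinates.
// Returns the label image (1..K, 0 = unassigned), final centers and the
// assignment objective (sum of D over assigned pixels) after each pass.
// [[Rcpp::export(name = ".slic_iterate")]]
List slic_iterate(NumericMatrix img, LogicalMatrix mask, NumericMatrix centers,
                  double mu, double S, double spacing, int iters) {
  const int H = img.nrow(), W = img.ncol(), K = centers.nrow();
  IntegerMatrix lab(H, W);
  NumericMatrix dist(H, W);
  NumericVector obj(iters);
  NumericMatrix cen = clone(centers);
  const int win = (int)std::ceil(2.0 * spacing);
  const double w_xy = mu / S;

  for (int it = 0; it < iters; ++it) {
    std::fill(dist.begin(), dist.end(), R_PosInf);
    std::fill(lab.begin(), lab.end(), 0);
    for (int k = 0; k < K; ++k) {
      const double cr = cen(k, 0), cc = cen(k, 1), cg = cen(k, 2);
      const int r0 = std::max(0, (int)std::floor(cr) - win);
      const int r1 = std::min(H - 1, (int)std::ceil(cr) + win);
      const int c0 = std::max(0, (int)std::floor(cc) - win);
      const int c1 = std::min(W - 1, (int)std::ceil(cc) + win);
      for (int c = c0; c <= c1; ++c) {
        for (int r = r0; r <= r1; ++r) {
          if (!mask(r, c)) continue;
          const double dxy = std::sqrt((r - cr) * (r - cr) + (c - cc) * (c - cc));
          const double d = w_xy * dxy + std::fabs(img(r, c) - cg);
          if (d < dist(r, c)) { dist(r, c) = d; lab(r, c) = k + 1; }
        }
      }
    }
    double o = 0.0;
    std::vector<double> sr(K, 0.0), sc(K, 0.0), sg(K, 0.0), n(K, 0.0);
    for (int c = 0; c < W; ++c) {
      for (int r = 0; r < H; ++r) {
        const int k = lab(r, c);
        if (k == 0) continue;
        o += dist(r, c);
        sr[k - 1] += r; sc[k - 1] += c; sg[k - 1] += img(r, c); n[k - 1] += 1.0;
      }
    }
    obj[it] = o;
    for (int k = 0; k < K; ++k) {
      if (n[k] > 0) {
        cen(k, 0) = sr[k] / n[k];
        cen(k, 1) = sc[k] / n[k];
        cen(k, 2) = sg[k] / n[k];
      }
    }
  }
  return List::create(_["labels"] = lab, _["centers"] = cen, _["objective"] = obj);
}
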