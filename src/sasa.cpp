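#include <Rcpp.h>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

// Shrake-Rupley solvent-accessible surface area.
//
// Quadrature points are a deterministic golden-spiral set on the unit
// sphere, scaled per atom to radius (r_i + probe). A point is accessible
// when it lies outside every other atom's probe-expanded sphere. ASA of an
// atom is 4*pi*(r_i+probe)^2 times its accessible point fraction.
//
// coords: n x 3 matrix (Angstrom); radii: length n vdW radii.
// [[Rcpp::export]]
NumericVector sasa_shrake_rupley(NumericMatrix coords, NumericVector radii,
                                 int n_points, double probe) {
  const int n = coords.nrow();
  if (radii.size() != n) stop("radii length must match atom count");
  if (n_points < 32) stop("n_points must be >= 32");

  // golden-spiral unit sphere points
  std::vector<double> px(n_points), py(n_points), pz(n_points);
  const double golden = M_PI * (3.0 - std::sqrt(5.0));
  for (int k = 0; k < n_points; ++k) {
    double z = 1.0 - 2.0 * (k + 0.5) / n_points;
    double r = std::sqrt(std::max(0.0, 1.0 - z * z));
    double th = golden * k;
    px[k] = r * std::cos(th);
    py[k] = r * std::sin(th);
    pz[k] = z;
  }

  NumericVector out(n);
  std::vector<int> nb;
  std::vector<double> nbx, nby, nbz, nbr2, nbd;
  nb.reserve(64);
  for (int i = 0; i < n; ++i) {
    const double ri = radii[i] + probe;
    // neighbour list: atoms whose expanded spheres can occlude atom i,
    // sorted closest-first so buried points are rejected early
    nb.clear();
    nbd.clear();
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      double dx = coords(j, 0) - coords(i, 0);
      double dy = coords(j, 1) - coords(i, 1);
      double dz = coords(j, 2) - coords(i, 2);
      double rj = radii[j] + probe;
      double lim = ri + rj;
      double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < lim * lim) { nb.push_back(j); nbd.push_back(d2); }
    }
    const int nn = (int)nb.size();
    std::vector<int> ord(nn);
    for (int m = 0; m < nn; ++m) ord[m] = m;
    std::sort(ord.begin(), ord.end(),
              [&](int a, int b) { return nbd[a] < nbd[b]; });
    nbx.resize(nn); nby.resize(nn); nbz.resize(nn); nbr2.resize(nn);
    for (int m = 0; m < nn; ++m) {
      int j = nb[ord[m]];
      nbx[m] = coords(j, 0); nby[m] = coords(j, 1); nbz[m] = coords(j, 2);
      double rj = radii[j] + probe;
      nbr2[m] = rj * rj;
    }
    int acc = 0;
    int last = 0;  // neighbour that occluded the previous point (coherence)
    for (int k = 0; k < n_points; ++k) {
      double x = coords(i, 0) + ri * px[k];
      double y = coords(i, 1) + ri * py[k];
      double z = coords(i, 2) + ri * pz[k];
      bool free_pt = true;
      if (nn) {
        double dx = x - nbx[last], dy = y - nby[last], dz = z - nbz[last];
        if (dx * dx + dy * dy + dz * dz < nbr2[last]) free_pt = false;
      }
      if (free_pt) {
        for (int m = 0; m < nn; ++m) {
          if (m == last) continue;
          double dx = x - nbx[m];
          double dy = y - nby[m];
          double dz = z - nbz[m];
          if (dx * dx + dy * dy + dz * dz < nbr2[m]) {
            free_pt = false;
            last = m;
            break;
          }
        }
      }
      if (free_pt) ++acc;
    }
    out[i] = 4.0 * M_PI * ri * ri * (double)acc / n_points;
  }
  return out;
}
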