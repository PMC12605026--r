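#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <unordered_map>
using namespace Rcpp;

// Uniform spatial grid over atom coordinates.  Cell size must be >= the
// largest query cutoff so that scanning the 27 neighbouring cells finds
// every atom within the cutoff.
struct CellGrid {
  double cell;
  double ox, oy, oz;
  int nx, ny, nz;
  std::unordered_map<long long, std::vector<int> > cells;

  CellGrid(const NumericMatrix &xyz, double cell_size) : cell(cell_size) {
    ox = oy = oz = R_PosInf;
    for (int i = 0; i < xyz.nrow(); ++i) {
      ox = std::min(ox, xyz(i, 0));
      oy = std::min(oy, xyz(i, 1));
      oz = std::min(oz, xyz(i, 2));
    }
    for (int i = 0; i < xyz.nrow(); ++i)
      cells[key(ix(xyz(i, 0), ox), ix(xyz(i, 1), oy), ix(xyz(i, 2), oz))]
          .push_back(i);
  }
  int ix(double v, double o) const { return (int)std::floor((v - o) / cell); }
  static long long key(int a, int b, int c) {
    return ((long long)(a + 1048576) << 42) |
           ((long long)(b + 1048576) << 21) | (long long)(c + 1048576);
  }
  template <typename F>
  void neighbours(double x, double y, double z, F f) const {
    int cx = ix(x, ox), cy = ix(y, oy), cz = ix(z, oz);
    for (int a = cx - 1; a <= cx + 1; ++a)
      for (int b = cy - 1; b <= cy + 1; ++b)
        for (int c = cz - 1; c <= cz + 1; ++c) {
          std::unordered_map<long long, std::vector<int> >::const_iterator it =
              cells.find(key(a, b, c));
          if (it == cells.end()) continue;
          for (size_t k = 0; k < it->second.size(); ++k) f(it->second[k]);
        }
  }
};

// Shrake-Rupley per-atom solvent-accessible surface area.
// xyz: atom coordinates (n x 3); radius: van der Waals radius per atom;
// occluder: 1 if the atom occludes others (solvent/ions can be excluded
// from the occluder set while still receiving an area themselves).
// Sample points are a deterministic Fibonacci (golden-spiral) lattice.
// [[Rcpp::export]]
NumericVector cpp_sasa(NumericMatrix xyz, NumericVector radius,
                       LogicalVector occluder, double probe, int n_points) {
  int n = xyz.nrow();
  NumericVector area(n);
  if (n == 0) return area;
  double rmax = 0.0;
  for (int i = 0; i < n; ++i) rmax = std::max(rmax, radius[i]);
  CellGrid grid(xyz, 2.0 * (rmax + probe));

  // golden-spiral lattice on the unit sphere
  std::vector<double> px(n_points), py(n_points), pz(n_points);
  const double ga = M_PI * (3.0 - std::sqrt(5.0));
  for (int k = 0; k < n_points; ++k) {
    double zk = 1.0 - 2.0 * (k + 0.5) / n_points;
    double rk = std::sqrt(std::max(0.0, 1.0 - zk * zk));
    px[k] = std::cos(ga * k) * rk;
    py[k] = std::sin(ga * k) * rk;
    pz[k] = zk;
  }

  std::vector<int> nbr;
  for (int i = 0; i < n; ++i) {
    double ri = radius[i] + probe;
    double xi = xyz(i, 0), yi = xyz(i, 1), zi = xyz(i, 2);
    nbr.clear();
    struct Collect {
      std::vector<int> *out; int self;
      const NumericMatrix *xyz; const NumericVector *radius;
      const LogicalVector *occluder;
      double xi, yi, zi, ri, probe;
      void operator()(int j) {
        if (j == self || !(*occluder)[j]) return;
        double rj = (*radius)[j] + probe;
        double dx = (*xyz)(j, 0) - xi, dy = (*xyz)(j, 1) - yi,
               dz = (*xyz)(j, 2) - zi;
        double lim = ri + rj;
        if (dx * dx + dy * dy + dz * dz < lim * lim) out->push_back(j);
      }
    } collect;
    collect.out = &nbr; collect.self = i; collect.xyz = &xyz;
    collect.radius = &radius; collect.occluder = &occluder;
    collect.xi = xi; collect.yi = yi; collect.zi = zi;
    collect.ri = ri; collect.probe = probe;
    grid.neighbours(xi, yi, zi, collect);

    int exposed = 0;
    for (int k = 0; k < n_points; ++k) {
      double qx = xi + ri * px[k], qy = yi + ri * py[k], qz = zi + ri * pz[k];
      bool free_pt = true;
      for (size_t m = 0; m < nbr.size(); ++m) {
        int j = nbr[m];
        double rj = radius[j] + probe;
        double dx = qx - xyz(j, 0), dy = qy - xyz(j, 1), dz = qz - xyz(j, 2);
        if (dx * dx + dy * dy + dz * dz < rj * rj) { free_pt = false; break; }
      }
      if (free_pt) ++exposed;
    }
    area[i] = 4.0 * M_PI * ri * ri * exposed / n_points;
  }
  return area;
}

// All unordered pairs (i < j) within `cutoff`, 1-based indices.
// [[Rcpp::export]]
DataFrame cpp_close_pairs(NumericMatrix xyz, double cutoff) {
  int n = xyz.nrow();
  std::vector<int> ii, jj;
  std::vector<double> dd;
  if (n > 0) {
    CellGrid grid(xyz, cutoff);
    double c2 = cutoff * cutoff;
    for (int i = 0; i < n; ++i) {
      struct Collect {
        std::vector<int> *ii, *jj; std::vector<double> *dd;
        const NumericMatrix *xyz; int i; double c2;
        void operator()(int j) {
          if (j <= i) return;
          double dx = (*xyz)(j, 0) - (*xyz)(i, 0),
                 dy = (*xyz)(j, 1) - (*xyz)(i, 1),
                 dz = (*xyz)(j, 2) - (*xyz)(i, 2);
          double d2 = dx * dx + dy * dy + dz * dz;
          if (d2 <= c2) {
            ii->push_back(i + 1); jj->push_back(j + 1);
            dd->push_back(std::sqrt(d2));
          }
        }
      } collect;
      collect.ii = &ii; collect.jj = &jj; collect.dd = &dd;
      collect.xyz = &xyz; collect.i = i; collect.c2 = c2;
      grid.neighbours(xyz(i, 0), xyz(i, 1), xyz(i, 2), collect);
    }
  }
  return DataFrame::create(_["i"] = ii, _["j"] = jj, _["dist"] = dd);
}

// All pairs (i in A, j in B) within `cutoff`, 1-based indices.
// [[Rcpp::export]]
DataFrame cpp_cross_pairs(NumericMatrix a, NumericMatrix b, double cutoff) {
  std::vector<int> ii, jj;
  std::vector<double> dd;
  if (a.nrow() > 0 && b.nrow() > 0) {
    CellGrid grid(b, cutoff);
    double c2 = cutoff * cutoff;
    for (int i = 0; i < a.nrow(); ++i) {
      struct Collect {
        std::vector<int> *ii, *jj; std::vector<double> *dd;
        const NumericMatrix *a, *b; int i; double c2;
        void operator()(int j) {
          double dx = (*b)(j, 0) - (*a)(i, 0), dy = (*b)(j, 1) - (*a)(i, 1),
                 dz = (*b)(j, 2) - (*a)(i, 2);
          double d2 = dx * dx + dy * dy + dz * dz;
          if (d2 <= c2) {
            ii->push_back(i + 1); jj->push_back(j + 1);
            dd->push_back(std::sqrt(d2));
          }
        }
      } collect;
      collect.ii = &ii; collect.jj = &jj; collect.dd = &dd;
      collect.a = &a; collect.b = &b; collect.i = i; collect.c2 = c2;
      grid.neighbours(a(i, 0), a(i, 1), a(i, 2), collect);
    }
  }
  return DataFrame::create(_["i"] = ii, _["j"] = jj, _["dist"] = dd);
}
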