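// Density-grid kernels: per-cell monomer counts within a sphere of radius
// r_c around each cell center, and 6-connected component labeling of the
// filled-cell mask.
#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Counts monomers within r_c of each cell center. Cell centers sit at
// origin + delta * (index + 1/2), indices 0..dim-1 (column-major x,y,z).
// [[Rcpp::export]]
NumericVector cpp_cell_counts(NumericMatrix pos, NumericVector origin,
                              double delta, IntegerVector dims, double r_c) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  NumericVector out((R_xlen_t)nx * ny * nz);
  int reach = (int)std::ceil(r_c / delta) + 1;
  double rc2 = r_c * r_c;
  for (int m = 0; m < pos.nrow(); ++m) {
    double px = pos(m, 0), py = pos(m, 1), pz = pos(m, 2);
    int cx = (int)std::floor((px - origin[0]) / delta);
    int cy = (int)std::floor((py - origin[1]) / delta);
    int cz = (int)std::floor((pz - origin[2]) / delta);
    for (int iz = std::max(0, cz - reach); iz <= std::min(nz - 1, cz + reach); ++iz) {
      double dz = origin[2] + delta * (iz + 0.5) - pz;
      for (int iy = std::max(0, cy - reach); iy <= std::min(ny - 1, cy + reach); ++iy) {
        double dy = origin[1] + delta * (iy + 0.5) - py;
        double dyz = dy * dy + dz * dz;
        if (dyz > rc2) continue;
        for (int ix = std::max(0, cx - reach); ix <= std::min(nx - 1, cx + reach); ++ix) {
          double dx = origin[0] + delta * (ix + 0.5) - px;
          if (dx * dx + dyz <= rc2)
            out[(R_xlen_t)ix + nx * ((R_xlen_t)iy + (R_xlen_t)ny * iz)] += 1.0;
        }
      }
    }
  }
  return out;
}

// 6-connected components of a logical mask (column-major 3-D array).
// Labels are positive integers in discovery order; empty cells get 0.
// [[Rcpp::export]]
IntegerVector cpp_label_clusters(LogicalVector mask, IntegerVector dims) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  R_xlen_t ntot = (R_xlen_t)nx * ny * nz;
  IntegerVector lab(ntot, 0);
  std::vector<R_xlen_t> stack;
  int cur = 0;
  for (R_xlen_t s = 0; s < ntot; ++s) {
    if (!mask[s] || lab[s]) continue;
    ++cur;
    stack.push_back(s);
    lab[s] = cur;
    while (!stack.empty()) {
      R_xlen_t c = stack.back(); stack.pop_back();
      int ix = c % nx, iy = (c / nx) % ny, iz = c / ((R_xlen_t)nx * ny);
      const int off[6][3] = {{1,0,0},{-1,0,0},{0,1,0},{0,-1,0},{0,0,1},{0,0,-1}};
      for (int k = 0; k < 6; ++k) {
        int jx = ix + off[k][0], jy = iy + off[k][1], jz = iz + off[k][2];
        if (jx < 0 || jx >= nx || jy < 0 || jy >= ny || jz < 0 || jz >= nz)
          continue;
        R_xlen_t j = (R_xlen_t)jx + nx * ((R_xlen_t)jy + (R_xlen_t)ny * jz);
        if (mask[j] && !lab[j]) { lab[j] = cur; stack.push_back(j); }
      }
    }
  }
  lab.attr("n_clusters") = cur;
  return lab;
}

// Face-neighbour smoothing stencil: out = (2*rho + sum of 6 neighbours)/8,
// zero outside the grid. One pass, no intermediate copies.
// [[Rcpp::export]]
NumericVector cpp_smooth(NumericVector rho, IntegerVector dims) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  NumericVector out((R_xlen_t)nx * ny * nz);
  for (int iz = 0; iz < nz; ++iz) {
    for (int iy = 0; iy < ny; ++iy) {
      R_xlen_t base = nx * ((R_xlen_t)iy + (R_xlen_t)ny * iz);
      for (int ix = 0; ix < nx; ++ix) {
        R_xlen_t c = base + ix;
        double s = 2.0 * rho[c];
        if (ix > 0) s += rho[c - 1];
        if (ix < nx - 1) s += rho[c + 1];
        if (iy > 0) s += rho[c - nx];
        if (iy < ny - 1) s += rho[c + nx];
        if (iz > 0) s += rho[c - (R_xlen_t)nx * ny];
        if (iz < nz - 1) s += rho[c + (R_xlen_t)nx * ny];
        out[c] = s / 8.0;
      }
    }
  }
  return out;
}

// Chord lengths: maximal runs of filled cells along each grid axis,
// pooled over the three axes (grid boundary counts as empty).
// [[Rcpp::export]]
IntegerVector cpp_chords(LogicalVector mask, IntegerVector dims) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  std::vector<int> lens;
  R_xlen_t sxy = (R_xlen_t)nx * ny;
  // x-runs
  for (int iz = 0; iz < nz; ++iz)
    for (int iy = 0; iy < ny; ++iy) {
      R_xlen_t base = nx * ((R_xlen_t)iy + (R_xlen_t)ny * iz);
      int run = 0;
      for (int ix = 0; ix < nx; ++ix) {
        if (mask[base + ix]) ++run;
        else if (run) { lens.push_back(run); run = 0; }
      }
      if (run) lens.push_back(run);
    }
  // y-runs
  for (int iz = 0; iz < nz; ++iz)
    for (int ix = 0; ix < nx; ++ix) {
      R_xlen_t base = ix + sxy * iz;
      int run = 0;
      for (int iy = 0; iy < ny; ++iy) {
        if (mask[base + (R_xlen_t)nx * iy]) ++run;
        else if (run) { lens.push_back(run); run = 0; }
      }
      if (run) lens.push_back(run);
    }
  // z-runs
  for (int iy = 0; iy < ny; ++iy)
    for (int ix = 0; ix < nx; ++ix) {
      R_xlen_t base = ix + (R_xlen_t)nx * iy;
      int run = 0;
      for (int iz = 0; iz < nz; ++iz) {
        if (mask[base + sxy * iz]) ++run;
        else if (run) { lens.push_back(run); run = 0; }
      }
      if (run) lens.push_back(run);
    }
  return wrap(lens);
}
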