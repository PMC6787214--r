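#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Cell of a coordinate in [0,1] on an n-cell grid: half-open cells
// [i/n, (i+1)/n), closed at 1.0.
static inline int cell_of(double v, int n) {
  int c = (int)std::floor(v * n);
  if (c < 0) c = 0;
  if (c >= n) c = n - 1;
  return c;
}

// Mark every grid cell crossed by the polyline through the embedded points.
// Exact traversal: for each segment, collect the parameter values where the
// segment crosses a gridline (plus the endpoints), and evaluate the cell at
// every breakpoint and at the midpoint of every sub-interval. The cell
// index is piecewise constant between crossings, so this enumerates exactly
// the cells the segment passes through under the half-open convention.
// [[Rcpp::export]]
LogicalMatrix raster_line_grid(NumericVector x, NumericVector y, int grid_n) {
  LogicalMatrix grid(grid_n, grid_n);
  int np = x.size();
  if (np == 0) return grid;
  grid(cell_of(y[0], grid_n), cell_of(x[0], grid_n)) = true;
  std::vector<double> ts;
  for (int k = 0; k + 1 < np; ++k) {
    double x0 = x[k], y0 = y[k], x1 = x[k + 1], y1 = y[k + 1];
    ts.clear();
    ts.push_back(0.0);
    ts.push_back(1.0);
    double dxv = x1 - x0, dyv = y1 - y0;
    if (dxv != 0.0) {
      int lo = (int)std::ceil(grid_n * std::min(x0, x1));
      int hi = (int)std::floor(grid_n * std::max(x0, x1));
      for (int g = lo; g <= hi; ++g) {
        double t = ((double)g / grid_n - x0) / dxv;
        if (t > 0.0 && t < 1.0) ts.push_back(t);
      }
    }
    if (dyv != 0.0) {
      int lo = (int)std::ceil(grid_n * std::min(y0, y1));
      int hi = (int)std::floor(grid_n * std::max(y0, y1));
      for (int g = lo; g <= hi; ++g) {
        double t = ((double)g / grid_n - y0) / dyv;
        if (t > 0.0 && t < 1.0) ts.push_back(t);
      }
    }
    std::sort(ts.begin(), ts.end());
    for (size_t i = 0; i < ts.size(); ++i) {
      double t = ts[i];
      grid(cell_of(y0 + t * dyv, grid_n), cell_of(x0 + t * dxv, grid_n)) = true;
      if (i + 1 < ts.size()) {
        double tm = 0.5 * (ts[i] + ts[i + 1]);
        grid(cell_of(y0 + tm * dyv, grid_n),
             cell_of(x0 + tm * dxv, grid_n)) = true;
      }
    }
  }
  return grid;
}
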