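#include <Rcpp.h>
#include <queue>
using namespace Rcpp;

// Nearest map vertex (1-based index) for each query point; brute force.
// [[Rcpp::export]]
IntegerVector cpp_nearest_vertex(NumericVector px, NumericVector py,
                                 NumericVector vx, NumericVector vy) {
  const int np = px.size(), nv = vx.size();
  if (nv == 0) stop("empty vertex set");
  IntegerVector out(np);
  const double *PX = REAL(px), *PY = REAL(py);
  const double *VX = REAL(vx), *VY = REAL(vy);
  int *O = INTEGER(out);
  for (int i = 0; i < np; ++i) {
    const double x = PX[i], y = PY[i];
    double best = R_PosInf;
    int bk = 0;
    for (int k = 0; k < nv; ++k) {
      const double dx = VX[k] - x, dy = VY[k] - y;
      const double d2 = dx * dx + dy * dy;
      if (d2 < best) { best = d2; bk = k; }
    }
    O[i] = bk + 1;
  }
  return out;
}

// Log-intensity of the axon-map activation model, aggregated over each
// pixel's disc-ward axon path. Flat path layout: for pixel i the path
// samples occupy entries ptr[i]..ptr[i+1]-1 (0-based) of ax/ay (microns)
// and ds2 (squared soma distance, microns^2). For each electrode column:
//   L[i] = agg_s -( ((ax-ex)^2+(ay-ey)^2) / (2 rho^2) + ds2 / (2 lam^2) )
// agg = 0 takes the maximum (a fiber fires once any segment is driven
// past threshold); agg = 1 returns the log of the summed intensities.
// Pixels with empty paths get -Inf.
// [[Rcpp::export]]
NumericMatrix cpp_axon_exponent(IntegerVector ptr, NumericVector ax,
                                NumericVector ay, NumericVector ds2,
                                NumericVector ex, NumericVector ey,
                                double rho, double lam, int agg) {
  const int np = ptr.size() - 1, ne = ex.size();
  const double i2r = 1.0 / (2.0 * rho * rho);
  const double i2l = 1.0 / (2.0 * lam * lam);
  NumericMatrix out(np, ne);
  const double *AX = REAL(ax), *AY = REAL(ay), *DS = REAL(ds2);
  const int *P = INTEGER(ptr);
  double *O = REAL(out);
  for (int e = 0; e < ne; ++e) {
    const double exe = ex[e], eye_ = ey[e];
    for (int i = 0; i < np; ++i) {
      double best = R_NegInf, acc = 0.0;
      for (int s = P[i]; s < P[i + 1]; ++s) {
        const double dx = AX[s] - exe, dy = AY[s] - eye_;
        const double v = -((dx * dx + dy * dy) * i2r + DS[s] * i2l);
        if (agg == 0) {
          if (v > best) best = v;
        } else {
          acc += std::exp(v);
        }
      }
      O[e * np + i] = (agg == 0) ? best
                                 : (acc > 0.0 ? std::log(acc) : R_NegInf);
    }
  }
  return out;
}

// Exterior flood fill: returns a logical matrix marking every zero cell of
// `mask` reachable from the image border by 4-connected moves through zero
// cells. The complement (minus the stroke) is the enclosed interior.
// [[Rcpp::export]]
LogicalMatrix cpp_flood_exterior(IntegerMatrix mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  LogicalMatrix ext(nr, nc);
  std::queue<std::pair<int, int> > q;
  for (int i = 0; i < nr; ++i) {
    if (!mask(i, 0))      { ext(i, 0) = true;      q.push(std::make_pair(i, 0)); }
    if (!mask(i, nc - 1) && !ext(i, nc - 1)) { ext(i, nc - 1) = true; q.push(std::make_pair(i, nc - 1)); }
  }
  for (int j = 0; j < nc; ++j) {
    if (!mask(0, j) && !ext(0, j))           { ext(0, j) = true;      q.push(std::make_pair(0, j)); }
    if (!mask(nr - 1, j) && !ext(nr - 1, j)) { ext(nr - 1, j) = true; q.push(std::make_pair(nr - 1, j)); }
  }
  const int di[4] = {1, -1, 0, 0};
  const int dj[4] = {0, 0, 1, -1};
  while (!q.empty()) {
    const int ci = q.front().first, cj = q.front().second;
    q.pop();
    for (int k = 0; k < 4; ++k) {
      const int ni = ci + di[k], nj = cj + dj[k];
      if (ni < 0 || ni >= nr || nj < 0 || nj >= nc) continue;
      if (ext(ni, nj) || mask(ni, nj)) continue;
      ext(ni, nj) = true;
      q.push(std::make_pair(ni, nj));
    }
  }
  return ext;
}
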