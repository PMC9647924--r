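#include <Rcpp.h>
#include <queue>
using namespace Rcpp;

// Matrices are R matrices m[row, col]; exported coordinates are 0-based
// (x = col - 1, y = row - 1), boxes half-open, per the package convention.

// [[Rcpp::export]]
IntegerMatrix cpp_label8(IntegerMatrix mask) {
  int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  int next = 0;
  std::queue<int> q;
  const int dr[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  const int dc[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      if (mask(r, c) != 0 && lab(r, c) == 0) {
        lab(r, c) = ++next;
        q.push(r + c * nr);
        while (!q.empty()) {
          int idx = q.front(); q.pop();
          int cr = idx % nr, cc = idx / nr;
          for (int k = 0; k < 8; ++k) {
            int rr = cr + dr[k], cci = cc + dc[k];
            if (rr >= 0 && rr < nr && cci >= 0 && cci < nc &&
                mask(rr, cci) != 0 && lab(rr, cci) == 0) {
              lab(rr, cci) = next;
              q.push(rr + cci * nr);
            }
          }
        }
      }
    }
  }
  return lab;
}

// Moore-neighbour boundary tracing (8-connected foreground), clockwise,
// Jacob's stopping criterion. Returns k x 2 matrix of (x, y), 0-based.
// [[Rcpp::export]]
IntegerMatrix cpp_trace_boundary(IntegerMatrix lab, int target) {
  int nr = lab.nrow(), nc = lab.ncol();
  int sr = -1, sc = -1;
  // start: topmost row, then leftmost column
  for (int r = 0; r < nr && sr < 0; ++r)
    for (int c = 0; c < nc; ++c)
      if (lab(r, c) == target) { sr = r; sc = c; break; }
  if (sr < 0) return IntegerMatrix(0, 2);
  // clockwise Moore neighbourhood starting at W
  const int dr[8] = {0, -1, -1, -1, 0, 1, 1, 1};
  const int dc[8] = {-1, -1, 0, 1, 1, 1, 0, -1};
  std::vector<int> xs, ys;
  xs.push_back(sc); ys.push_back(sr);
  int cr = sr, cc = sc;
  int search = 0;      // start is topmost-leftmost: W/NW/N/NE are background
  int first_dir = -1;  // direction of the first move away from the start
  int cap = 4 * (nr * nc + 4);
  for (int it = 0; it < cap; ++it) {
    int nd = -1;
    for (int k = 0; k < 8; ++k) {
      int d = (search + k) % 8;
      int rr = cr + dr[d], cci = cc + dc[d];
      if (rr >= 0 && rr < nr && cci >= 0 && cci < nc && lab(rr, cci) == target) {
        nd = d;
        break;
      }
    }
    if (nd < 0) break;  // isolated pixel
    // Jacob's criterion: back at the start, about to repeat the first move
    if (cr == sr && cc == sc && first_dir >= 0 && nd == first_dir) break;
    if (first_dir < 0) first_dir = nd;
    cr += dr[nd]; cc += dc[nd];
    if (!(cr == sr && cc == sc)) { xs.push_back(cc); ys.push_back(cr); }
    search = (nd + 6) % 8;  // back up two positions for the clockwise sweep
  }
  IntegerMatrix out(xs.size(), 2);
  for (size_t i = 0; i < xs.size(); ++i) { out(i, 0) = xs[i]; out(i, 1) = ys[i]; }
  return out;
}

// Max zero-normalized cross-correlation of `tmpl` over every placement fully
// inside `img`. Dimensions where tmpl exceeds img are handled by the caller
// (padding); here tmpl must fit.
// [[Rcpp::export]]
double cpp_zncc_best(NumericMatrix tmpl, NumericMatrix img) {
  int th = tmpl.nrow(), tw = tmpl.ncol();
  int ih = img.nrow(), iw = img.ncol();
  if (th > ih || tw > iw) stop("template larger than image");
  int n = th * tw;
  double tmean = 0.0;
  for (int c = 0; c < tw; ++c)
    for (int r = 0; r < th; ++r) tmean += tmpl(r, c);
  tmean /= n;
  double tss = 0.0;
  std::vector<double> tz(n);
  for (int c = 0; c < tw; ++c)
    for (int r = 0; r < th; ++r) {
      double v = tmpl(r, c) - tmean;
      tz[r + c * th] = v;
      tss += v * v;
    }
  if (tss <= 0) return NA_REAL;  // constant template: undefined, caller maps to 0
  // integral images for window sums / sums of squares
  int pr = ih + 1, pc = iw + 1;
  std::vector<double> S(pr * pc, 0.0), S2(pr * pc, 0.0);
  for (int c = 1; c < pc; ++c)
    for (int r = 1; r < pr; ++r) {
      double v = img(r - 1, c - 1);
      S[r + c * pr]  = v     + S[r - 1 + c * pr] + S[r + (c - 1) * pr] - S[r - 1 + (c - 1) * pr];
      S2[r + c * pr] = v * v + S2[r - 1 + c * pr] + S2[r + (c - 1) * pr] - S2[r - 1 + (c - 1) * pr];
    }
  double best = R_NegInf;
  bool any = false;
  for (int oc = 0; oc + tw <= iw; ++oc) {
    for (int orow = 0; orow + th <= ih; ++orow) {
      int r0 = orow, r1 = orow + th, c0 = oc, c1 = oc + tw;
      double ws  = S[r1 + c1 * pr]  - S[r0 + c1 * pr]  - S[r1 + c0 * pr]  + S[r0 + c0 * pr];
      double ws2 = S2[r1 + c1 * pr] - S2[r0 + c1 * pr] - S2[r1 + c0 * pr] + S2[r0 + c0 * pr];
      double wss = ws2 - ws * ws / n;
      if (wss <= 1e-12) continue;  // constant window
      double cross = 0.0;
      for (int c = 0; c < tw; ++c) {
        int colbase = (c0 + c) * ih;
        int tbase = c * th;
        for (int r = 0; r < th; ++r)
          cross += tz[r + tbase] * img[r0 + r + colbase];
      }
      // sum(tz) == 0, so cross equals the fully centred covariance
      double score = cross / std::sqrt(tss * wss);
      if (score > best) { best = score; any = true; }
    }
  }
  if (!any) return NA_REAL;
  if (best > 1.0) best = 1.0;
  if (best < -1.0) best = -1.0;
  return best;
}
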