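#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

// Connected-component labeling on a 3D logical array.
// Labels are assigned in raster-scan (column-major) order of first encounter,
// starting at 1; background stays 0. connectivity is 6, 18 or 26.
// [[Rcpp::export]]
IntegerVector cc_label_3d(LogicalVector mask, IntegerVector dim, int connectivity) {
  if (dim.size() != 3) stop("dim must have length 3");
  const int d1 = dim[0], d2 = dim[1], d3 = dim[2];
  const R_xlen_t n = (R_xlen_t)d1 * d2 * d3;
  if (mask.size() != n) stop("mask length does not match dim");
  if (connectivity != 6 && connectivity != 18 && connectivity != 26)
    stop("connectivity must be 6, 18 or 26");

  // neighbour offsets: |di|+|dj|+|dk| <= 1 / 2 / 3 for 6 / 18 / 26
  std::vector<int> di, dj, dk;
  int maxman = (connectivity == 6) ? 1 : (connectivity == 18 ? 2 : 3);
  for (int a = -1; a <= 1; ++a)
    for (int b = -1; b <= 1; ++b)
      for (int c = -1; c <= 1; ++c) {
        int man = std::abs(a) + std::abs(b) + std::abs(c);
        if (man >= 1 && man <= maxman) { di.push_back(a); dj.push_back(b); dk.push_back(c); }
      }
  const int nnb = (int)di.size();

  IntegerVector lab(n, 0);
  std::vector<R_xlen_t> stack;
  int next_label = 0;

  for (R_xlen_t idx = 0; idx < n; ++idx) {
    if (!mask[idx] || lab[idx] != 0) continue;
    ++next_label;
    lab[idx] = next_label;
    stack.clear();
    stack.push_back(idx);
    while (!stack.empty()) {
      R_xlen_t cur = stack.back();
      stack.pop_back();
      int k = (int)(cur / ((R_xlen_t)d1 * d2));
      int rem = (int)(cur % ((R_xlen_t)d1 * d2));
      int j = rem / d1;
      int i = rem % d1;
      for (int m = 0; m < nnb; ++m) {
        int ii = i + di[m], jj = j + dj[m], kk = k + dk[m];
        if (ii < 0 || ii >= d1 || jj < 0 || jj >= d2 || kk < 0 || kk >= d3) continue;
        R_xlen_t nb = (R_xlen_t)kk * d1 * d2 + (R_xlen_t)jj * d1 + ii;
        if (mask[nb] && lab[nb] == 0) {
          lab[nb] = next_label;
          stack.push_back(nb);
        }
      }
    }
  }
  lab.attr("n_components") = next_label;
  return lab;
}

static void blur_axis(std::vector<double>& x, int d1, int d2, int d3,
                      int axis, double sigma) {
  if (sigma <= 0) return;
  int radius = (int)std::ceil(3.0 * sigma);
  std::vector<double> kern(2 * radius + 1);
  double s = 0.0;
  for (int t = -radius; t <= radius; ++t) {
    kern[t + radius] = std::exp(-0.5 * t * t / (sigma * sigma));
    s += kern[t + radius];
  }
  for (double& v : kern) v /= s;

  int len = (axis == 0) ? d1 : (axis == 1 ? d2 : d3);
  R_xlen_t stride = (axis == 0) ? 1 : (axis == 1 ? d1 : (R_xlen_t)d1 * d2);
  std::vector<double> line(len), out(len);

  // iterate over all lines along `axis`
  int od1 = (axis == 0) ? d2 : d1;
  int od2 = (axis == 2) ? d2 : d3;
  R_xlen_t s1 = (axis == 0) ? d1 : 1;
  R_xlen_t s2 = (axis == 2) ? d1 : (R_xlen_t)d1 * d2;
  for (int b = 0; b < od2; ++b) {
    for (int a = 0; a < od1; ++a) {
      R_xlen_t base = (R_xlen_t)a * s1 + (R_xlen_t)b * s2;
      for (int t = 0; t < len; ++t) line[t] = x[base + t * stride];
      for (int t = 0; t < len; ++t) {
        double acc = 0.0, wsum = 0.0;
        int lo = std::max(0, t - radius), hi = std::min(len - 1, t + radius);
        for (int u = lo; u <= hi; ++u) {
          double w = kern[u - t + radius];
          acc += w * line[u];
          wsum += w;
        }
        out[t] = acc / wsum;  // renormalised truncation at the border
      }
      for (int t = 0; t < len; ++t) x[base + t * stride] = out[t];
    }
  }
}

// Separable 3D Gaussian blur; sigma_vox gives the per-axis sigma in voxels.
// Border handling renormalises the truncated kernel, so constants are preserved.
// [[Rcpp::export]]
NumericVector gauss_blur_3d(NumericVector x, IntegerVector dim, NumericVector sigma_vox) {
  if (dim.size() != 3 || sigma_vox.size() != 3) stop("dim and sigma_vox must have length 3");
  const int d1 = dim[0], d2 = dim[1], d3 = dim[2];
  if (x.size() != (R_xlen_t)d1 * d2 * d3) stop("x length does not match dim");
  std::vector<double> buf(x.begin(), x.end());
  for (int ax = 0; ax < 3; ++ax) blur_axis(buf, d1, d2, d3, ax, sigma_vox[ax]);
  NumericVector out(buf.begin(), buf.end());
  return out;
}
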