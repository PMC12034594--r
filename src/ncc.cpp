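#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Valid-region normalized cross-correlation of a template against an image.
//
// Scores are written at the anchor pixel (template center, odd dimensions
// required) and lie in [-1, 1]. Anchors where the template does not fully fit
// carry the sentinel value `fill`; windows with (near) zero variance score 0,
// as do degenerate (constant) templates.
//
// Window sums of I and I^2 come from summed-area tables; the cross term is a
// direct loop, which for the small sensor templates used here is faster than
// FFT-based filtering and exact.
// [[Rcpp::export]]
NumericMatrix ncc_valid(const NumericMatrix& image, const NumericMatrix& templ,
                        double fill = -1.0) {
  const int H = image.nrow(), W = image.ncol();
  const int th = templ.nrow(), tw = templ.ncol();
  if (th % 2 == 0 || tw % 2 == 0)
    stop("template dimensions must be odd");
  if (th > H || tw > W)
    stop("template (%dx%d) larger than image (%dx%d)", th, tw, H, W);

  NumericMatrix out(H, W);
  std::fill(out.begin(), out.end(), fill);

  const double n = (double)th * tw;
  double tmean = 0.0;
  for (int k = 0; k < th * tw; ++k) tmean += templ[k];
  tmean /= n;
  std::vector<double> tc(th * tw);
  double ssdT = 0.0;
  for (int k = 0; k < th * tw; ++k) {
    tc[k] = templ[k] - tmean;
    ssdT += tc[k] * tc[k];
  }

  const int hr = th / 2, hc = tw / 2;
  const bool degenerate = ssdT < 1e-12;

  // summed-area tables, (H+1)x(W+1), column-major, S(i,j) = sum over [0,i)x[0,j)
  std::vector<double> S1((H + 1) * (W + 1), 0.0), S2((H + 1) * (W + 1), 0.0);
  for (int j = 0; j < W; ++j) {
    double cs1 = 0.0, cs2 = 0.0;
    for (int i = 0; i < H; ++i) {
      double v = image(i, j);
      cs1 += v; cs2 += v * v;
      S1[(j + 1) * (H + 1) + (i + 1)] = S1[j * (H + 1) + (i + 1)] + cs1;
      S2[(j + 1) * (H + 1) + (i + 1)] = S2[j * (H + 1) + (i + 1)] + cs2;
    }
  }
  auto boxsum = [&](const std::vector<double>& S, int i0, int j0) {
    // sum over rows [i0, i0+th), cols [j0, j0+tw)
    return S[(j0 + tw) * (H + 1) + (i0 + th)] - S[j0 * (H + 1) + (i0 + th)] -
           S[(j0 + tw) * (H + 1) + i0] + S[j0 * (H + 1) + i0];
  };

  for (int j0 = 0; j0 + tw <= W; ++j0) {
    // (direct cross-term path)
    for (int i0 = 0; i0 + th <= H; ++i0) {
      if (degenerate) { out(i0 + hr, j0 + hc) = 0.0; continue; }
      double s1 = boxsum(S1, i0, j0);
      double s2 = boxsum(S2, i0, j0);
      double varI = s2 - s1 * s1 / n;
      if (varI < 1e-12) { out(i0 + hr, j0 + hc) = 0.0; continue; }
      double cross = 0.0;
      const double* tp = tc.data();
      for (int b = 0; b < tw; ++b) {
        const double* col = &image(i0, j0 + b);
        for (int a = 0; a < th; ++a) cross += col[a] * tp[b * th + a];
      }
      double v = cross / std::sqrt(varI * ssdT);
      if (v > 1.0) v = 1.0; else if (v < -1.0) v = -1.0;
      out(i0 + hr, j0 + hc) = v;
    }
  }
  return out;
}

// Same contract as ncc_valid, for rank-1 templates T = base + gain *
// outer(rprof, cprof) (every template this package generates has that form:
// bar patterns are outer products of 1-D edge profiles). NCC is invariant to
// the affine (base, |gain|) part, so the score is computed against the
// centered outer-product pattern and multiplied by sign(gain); the cross
// term factorizes into two 1-D correlations, O(H*W*(th+tw)) instead of
// O(H*W*th*tw).
// [[Rcpp::export]]
NumericMatrix ncc_valid_sep(const NumericMatrix& image,
                            const NumericVector& rprof,
                            const NumericVector& cprof,
                            double sign = 1.0, double fill = -1.0) {
  const int H = image.nrow(), W = image.ncol();
  const int th = rprof.size(), tw = cprof.size();
  if (th % 2 == 0 || tw % 2 == 0)
    stop("template dimensions must be odd");
  if (th > H || tw > W)
    stop("template (%dx%d) larger than image (%dx%d)", th, tw, H, W);

  NumericMatrix out(H, W);
  std::fill(out.begin(), out.end(), fill);

  const double n = (double)th * tw;
  double sr = 0.0, sr2 = 0.0, sc = 0.0, sc2 = 0.0;
  for (int a = 0; a < th; ++a) { sr += rprof[a]; sr2 += rprof[a] * rprof[a]; }
  for (int b = 0; b < tw; ++b) { sc += cprof[b]; sc2 += cprof[b] * cprof[b]; }
  const double pmean = sr * sc / n;                 // mean of outer pattern
  const double ssdP = sr2 * sc2 - sr * sc * pmean;  // sum(P^2) - n*mean^2
  const bool degenerate = ssdP < 1e-12;

  std::vector<double> S1((H + 1) * (W + 1), 0.0), S2((H + 1) * (W + 1), 0.0);
  for (int j = 0; j < W; ++j) {
    double cs1 = 0.0, cs2 = 0.0;
    for (int i = 0; i < H; ++i) {
      double v = image(i, j);
      cs1 += v; cs2 += v * v;
      S1[(j + 1) * (H + 1) + (i + 1)] = S1[j * (H + 1) + (i + 1)] + cs1;
      S2[(j + 1) * (H + 1) + (i + 1)] = S2[j * (H + 1) + (i + 1)] + cs2;
    }
  }
  auto boxsum = [&](const std::vector<double>& S, int i0, int j0) {
    return S[(j0 + tw) * (H + 1) + (i0 + th)] - S[j0 * (H + 1) + (i0 + th)] -
           S[(j0 + tw) * (H + 1) + i0] + S[j0 * (H + 1) + i0];
  };

  // row-direction 1-D correlation: tmp(i, j) = sum_a I(i+a, j) * rprof[a]
  const int Hv = H - th + 1;
  std::vector<double> tmp((size_t)Hv * W, 0.0);
  for (int j = 0; j < W; ++j) {
    const double* col = &image(0, j);
    for (int i = 0; i < Hv; ++i) {
      double acc = 0.0;
      for (int a = 0; a < th; ++a) acc += col[i + a] * rprof[a];
      tmp[(size_t)j * Hv + i] = acc;
    }
  }

  const int hr = th / 2, hc = tw / 2;
  for (int j0 = 0; j0 + tw <= W; ++j0) {
    for (int i0 = 0; i0 < Hv; ++i0) {
      if (degenerate) { out(i0 + hr, j0 + hc) = 0.0; continue; }
      double s1 = boxsum(S1, i0, j0);
      double s2 = boxsum(S2, i0, j0);
      double varI = s2 - s1 * s1 / n;
      if (varI < 1e-12) { out(i0 + hr, j0 + hc) = 0.0; continue; }
      double cross = 0.0;
      for (int b = 0; b < tw; ++b) cross += tmp[(size_t)(j0 + b) * Hv + i0] * cprof[b];
      cross -= pmean * s1;   // center the pattern
      double v = sign * cross / std::sqrt(varI * ssdP);
      if (v > 1.0) v = 1.0; else if (v < -1.0) v = -1.0;
      out(i0 + hr, j0 + hc) = v;
    }
  }
  return out;
}
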