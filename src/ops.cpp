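#include <Rcpp.h>
using namespace Rcpp;

// Low-level numeric kernels for the small CNN backbone. Arrays follow R's
// column-major layout: images/feature maps are H x W x C, convolution
// weights are kh x kw x IC x OC. Indices here are 0-based.

static inline int idx3(int i, int j, int k, int H, int W) {
  return i + H * (j + W * k);
}

// [[Rcpp::export(name = ".conv2d_fwd")]]
NumericVector conv2d_fwd(NumericVector x, NumericVector w, NumericVector b,
                         int stride, int pad) {
  IntegerVector xd = x.attr("dim");
  IntegerVector wd = w.attr("dim");
  const int H = xd[0], W = xd[1], IC = xd[2];
  const int kh = wd[0], kw = wd[1], OC = wd[3];
  if (wd[2] != IC) stop("input channel mismatch between x and w");
  const int Ho = (H + 2 * pad - kh) / stride + 1;
  const int Wo = (W + 2 * pad - kw) / stride + 1;
  NumericVector out(Ho * Wo * OC);
  out.attr("dim") = IntegerVector::create(Ho, Wo, OC);
  for (int oc = 0; oc < OC; ++oc) {
    for (int ox = 0; ox < Wo; ++ox) {
      for (int oy = 0; oy < Ho; ++oy) {
        double acc = b[oc];
        for (int ic = 0; ic < IC; ++ic) {
          for (int kx = 0; kx < kw; ++kx) {
            const int xin = ox * stride + kx - pad;
            if (xin < 0 || xin >= W) continue;
            for (int ky = 0; ky < kh; ++ky) {
              const int yin = oy * stride + ky - pad;
              if (yin < 0 || yin >= H) continue;
              acc += w[ky + kh * (kx + kw * (ic + IC * oc))] *
                     x[idx3(yin, xin, ic, H, W)];
            }
          }
        }
        out[idx3(oy, ox, oc, Ho, Wo)] = acc;
      }
    }
  }
  return out;
}

// Gradients of a conv layer: returns list(gx, gw, gb) given upstream gout.
// [[Rcpp::export(name = ".conv2d_bwd")]]
List conv2d_bwd(NumericVector x, NumericVector w, NumericVector gout,
                int stride, int pad) {
  IntegerVector xd = x.attr("dim");
  IntegerVector wd = w.attr("dim");
  IntegerVector gd = gout.attr("dim");
  const int H = xd[0], W = xd[1], IC = xd[2];
  const int kh = wd[0], kw = wd[1], OC = wd[3];
  const int Ho = gd[0], Wo = gd[1];
  NumericVector gx(H * W * IC), gw(kh * kw * IC * OC), gb(OC);
  gx.attr("dim") = xd;
  gw.attr("dim") = wd;
  for (int oc = 0; oc < OC; ++oc) {
    for (int ox = 0; ox < Wo; ++ox) {
      for (int oy = 0; oy < Ho; ++oy) {
        const double g = gout[idx3(oy, ox, oc, Ho, Wo)];
        if (g == 0.0) continue;
        gb[oc] += g;
        for (int ic = 0; ic < IC; ++ic) {
          for (int kx = 0; kx < kw; ++kx) {
            const int xin = ox * stride + kx - pad;
            if (xin < 0 || xin >= W) continue;
            for (int ky = 0; ky < kh; ++ky) {
              const int yin = oy * stride + ky - pad;
              if (yin < 0 || yin >= H) continue;
              const int wi = ky + kh * (kx + kw * (ic + IC * oc));
              const int xi = idx3(yin, xin, ic, H, W);
              gw[wi] += g * x[xi];
              gx[xi] += g * w[wi];
            }
          }
        }
      }
    }
  }
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// Bilinear resize of an h x w matrix to H x W, half-pixel centers, edges
// clamped. Linear map, so the backward pass is its exact transpose.
// [[Rcpp::export(name = ".bilinear_up")]]
NumericMatrix bilinear_up(NumericMatrix m, int H, int W) {
  const int h = m.nrow(), w = m.ncol();
  NumericMatrix out(H, W);
  const double sy = (double)h / H, sx = (double)w / W;
  for (int X = 0; X < W; ++X) {
    double fx = (X + 0.5) * sx - 0.5;
    if (fx < 0) fx = 0;
    if (fx > w - 1) fx = w - 1;
    const int x0 = (int)fx, x1 = x0 + 1 < w ? x0 + 1 : x0;
    const double wx = fx - x0;
    for (int Y = 0; Y < H; ++Y) {
      double fy = (Y + 0.5) * sy - 0.5;
      if (fy < 0) fy = 0;
      if (fy > h - 1) fy = h - 1;
      const int y0 = (int)fy, y1 = y0 + 1 < h ? y0 + 1 : y0;
      const double wy = fy - y0;
      out(Y, X) = (1 - wy) * ((1 - wx) * m(y0, x0) + wx * m(y0, x1)) +
                  wy * ((1 - wx) * m(y1, x0) + wx * m(y1, x1));
    }
  }
  return out;
}

// [[Rcpp::export(name = ".bilinear_up_bwd")]]
NumericMatrix bilinear_up_bwd(NumericMatrix g, int h, int w) {
  const int H = g.nrow(), W = g.ncol();
  NumericMatrix out(h, w);
  const double sy = (double)h / H, sx = (double)w / W;
  for (int X = 0; X < W; ++X) {
    double fx = (X + 0.5) * sx - 0.5;
    if (fx < 0) fx = 0;
    if (fx > w - 1) fx = w - 1;
    const int x0 = (int)fx, x1 = x0 + 1 < w ? x0 + 1 : x0;
    const double wx = fx - x0;
    for (int Y = 0; Y < H; ++Y) {
      double fy = (Y + 0.5) * sy - 0.5;
      if (fy < 0) fy = 0;
      if (fy > h - 1) fy = h - 1;
      const int y0 = (int)fy, y1 = y0 + 1 < h ? y0 + 1 : y0;
      const double wy = fy - y0;
      const double gv = g(Y, X);
      out(y0, x0) += (1 - wy) * (1 - wx) * gv;
      out(y0, x1) += (1 - wy) * wx * gv;
      out(y1, x0) += wy * (1 - wx) * gv;
      out(y1, x1) += wy * wx * gv;
    }
  }
  return out;
}

// Trilinear interpolation of a 3-D field at continuous 0-based voxel
// coordinates; points outside the grid evaluate to `fill`. Used to sample a
// binary mask as a continuous [0,1] field during annotation transfer.
// [[Rcpp::export(name = ".trilinear_sample")]]
NumericVector trilinear_sample(NumericVector vol, NumericMatrix ijk,
                               double fill) {
  IntegerVector vd = vol.attr("dim");
  const int n0 = vd[0], n1 = vd[1], n2 = vd[2];
  const int n = ijk.nrow();
  NumericVector out(n);
  for (int p = 0; p < n; ++p) {
    const double ci = ijk(p, 0), cj = ijk(p, 1), ck = ijk(p, 2);
    if (ci < 0 || cj < 0 || ck < 0 || ci > n0 - 1 || cj > n1 - 1 ||
        ck > n2 - 1) {
      out[p] = fill;
      continue;
    }
    const int i0 = (int)ci, j0 = (int)cj, k0 = (int)ck;
    const int i1 = i0 + 1 < n0 ? i0 + 1 : i0;
    const int j1 = j0 + 1 < n1 ? j0 + 1 : j0;
    const int k1 = k0 + 1 < n2 ? k0 + 1 : k0;
    const double di = ci - i0, dj = cj - j0, dk = ck - k0;
    double v = 0.0;
    for (int kk = 0; kk <= 1; ++kk) {
      const int k = kk ? k1 : k0;
      const double wk = kk ? dk : 1 - dk;
      if (wk == 0) continue;
      for (int jj = 0; jj <= 1; ++jj) {
        const int j = jj ? j1 : j0;
        const double wj = jj ? dj : 1 - dj;
        if (wj == 0) continue;
        for (int ii = 0; ii <= 1; ++ii) {
          const int i = ii ? i1 : i0;
          const double wi = ii ? di : 1 - di;
          if (wi == 0) continue;
          v += wi * wj * wk * vol[i + n0 * (j + n1 * k)];
        }
      }
    }
    out[p] = v;
  }
  return out;
}
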