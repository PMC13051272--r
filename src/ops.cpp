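#include <Rcpp.h>
using namespace Rcpp;

// Feature maps are H x W x C double arrays, column-major (h fastest).
// im2col row order: kh + k*kw + k*k*c ; column order: ho + Ho*wo.

static inline int out_size(int H, int k, int stride, int pad, int dil) {
  return (H + 2 * pad - dil * (k - 1) - 1) / stride + 1;
}

// [[Rcpp::export]]
NumericMatrix cpp_im2col(NumericVector x, int H, int W, int C,
                         int k, int stride, int pad, int dil) {
  const int Ho = out_size(H, k, stride, pad, dil);
  const int Wo = out_size(W, k, stride, pad, dil);
  NumericMatrix cols(k * k * C, Ho * Wo);
  const double *px = x.begin();
  for (int wo = 0; wo < Wo; ++wo) {
    for (int ho = 0; ho < Ho; ++ho) {
      const int col = ho + Ho * wo;
      double *pc = &cols(0, col);
      const int h0 = ho * stride - pad, w0 = wo * stride - pad;
      for (int c = 0; c < C; ++c) {
        const double *xc = px + (size_t)H * W * c;
        for (int kw = 0; kw < k; ++kw) {
          const int w = w0 + kw * dil;
          for (int kh = 0; kh < k; ++kh) {
            const int h = h0 + kh * dil;
            double v = 0.0;
            if (h >= 0 && h < H && w >= 0 && w < W) v = xc[h + (size_t)H * w];
            pc[kh + k * kw + k * k * c] = v;
          }
        }
      }
    }
  }
  return cols;
}

// [[Rcpp::export]]
NumericVector cpp_col2im(NumericMatrix cols, int H, int W, int C,
                         int k, int stride, int pad, int dil) {
  const int Ho = out_size(H, k, stride, pad, dil);
  const int Wo = out_size(W, k, stride, pad, dil);
  NumericVector x((size_t)H * W * C);
  double *px = x.begin();
  for (int wo = 0; wo < Wo; ++wo) {
    for (int ho = 0; ho < Ho; ++ho) {
      const int col = ho + Ho * wo;
      const double *pc = &cols(0, col);
      const int h0 = ho * stride - pad, w0 = wo * stride - pad;
      for (int c = 0; c < C; ++c) {
        double *xc = px + (size_t)H * W * c;
        for (int kw = 0; kw < k; ++kw) {
          const int w = w0 + kw * dil;
          if (w < 0 || w >= W) continue;
          for (int kh = 0; kh < k; ++kh) {
            const int h = h0 + kh * dil;
            if (h < 0 || h >= H) continue;
            xc[h + (size_t)H * w] += pc[kh + k * kw + k * k * c];
          }
        }
      }
    }
  }
  x.attr("dim") = IntegerVector::create(H, W, C);
  return x;
}

// 2x2 max pooling, stride 2. Returns pooled map and 0-based argmax indices.
// [[Rcpp::export]]
List cpp_maxpool2_fwd(NumericVector x, int H, int W, int C) {
  const int Ho = H / 2, Wo = W / 2;
  NumericVector out((size_t)Ho * Wo * C);
  IntegerVector idx((size_t)Ho * Wo * C);
  const double *px = x.begin();
  for (int c = 0; c < C; ++c) {
    const double *xc = px + (size_t)H * W * c;
    for (int wo = 0; wo < Wo; ++wo) {
      for (int ho = 0; ho < Ho; ++ho) {
        double best = -1e300; int bi = 0;
        for (int dw = 0; dw < 2; ++dw) {
          for (int dh = 0; dh < 2; ++dh) {
            const int h = 2 * ho + dh, w = 2 * wo + dw;
            const int i = h + H * w;
            if (xc[i] > best) { best = xc[i]; bi = i; }
          }
        }
        const size_t o = ho + (size_t)Ho * wo + (size_t)Ho * Wo * c;
        out[o] = best;
        idx[o] = bi + H * W * c;
      }
    }
  }
  out.attr("dim") = IntegerVector::create(Ho, Wo, C);
  return List::create(_["out"] = out, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool2_bwd(NumericVector g, IntegerVector idx,
                               int H, int W, int C) {
  NumericVector dx((size_t)H * W * C);
  for (R_xlen_t i = 0; i < g.size(); ++i) dx[idx[i]] += g[i];
  dx.attr("dim") = IntegerVector::create(H, W, C);
  return dx;
}

// Bilinear x2 upsampling, half-pixel-center convention (align_corners=FALSE).
static inline void up2_coeff(int d, int S, int &i0, int &i1, double &w1) {
  double s = (d + 0.5) / 2.0 - 0.5;
  if (s < 0) s = 0;
  if (s > S - 1) s = S - 1;
  i0 = (int)std::floor(s);
  i1 = i0 + 1 < S ? i0 + 1 : i0;
  w1 = s - i0;
}

// [[Rcpp::export]]
NumericVector cpp_upsample2_fwd(NumericVector x, int H, int W, int C) {
  const int Ho = 2 * H, Wo = 2 * W;
  NumericVector out((size_t)Ho * Wo * C);
  const double *px = x.begin();
  for (int c = 0; c < C; ++c) {
    const double *xc = px + (size_t)H * W * c;
    double *oc = out.begin() + (size_t)Ho * Wo * c;
    for (int wo = 0; wo < Wo; ++wo) {
      int w0, w1; double ww;
      up2_coeff(wo, W, w0, w1, ww);
      for (int ho = 0; ho < Ho; ++ho) {
        int h0, h1; double wh;
        up2_coeff(ho, H, h0, h1, wh);
        oc[ho + (size_t)Ho * wo] =
          (1 - wh) * (1 - ww) * xc[h0 + (size_t)H * w0] +
          wh * (1 - ww) * xc[h1 + (size_t)H * w0] +
          (1 - wh) * ww * xc[h0 + (size_t)H * w1] +
          wh * ww * xc[h1 + (size_t)H * w1];
      }
    }
  }
  out.attr("dim") = IntegerVector::create(Ho, Wo, C);
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_upsample2_bwd(NumericVector g, int H, int W, int C) {
  const int Ho = 2 * H, Wo = 2 * W;
  NumericVector dx((size_t)H * W * C);
  const double *pg = g.begin();
  for (int c = 0; c < C; ++c) {
    double *xc = dx.begin() + (size_t)H * W * c;
    const double *gc = pg + (size_t)Ho * Wo * c;
    for (int wo = 0; wo < Wo; ++wo) {
      int w0, w1; double ww;
      up2_coeff(wo, W, w0, w1, ww);
      for (int ho = 0; ho < Ho; ++ho) {
        int h0, h1; double wh;
        up2_coeff(ho, H, h0, h1, wh);
        const double v = gc[ho + (size_t)Ho * wo];
        xc[h0 + (size_t)H * w0] += (1 - wh) * (1 - ww) * v;
        xc[h1 + (size_t)H * w0] += wh * (1 - ww) * v;
        xc[h0 + (size_t)H * w1] += (1 - wh) * ww * v;
        xc[h1 + (size_t)H * w1] += wh * ww * v;
      }
    }
  }
  dx.attr("dim") = IntegerVector::create(H, W, C);
  return dx;
}

// Criss-cross attention. For position u=(h,w) the H+W-1 context positions
// are the full column w (i = 0..H-1, containing u once), then the row h
// with column w excluded (increasing column order). Softmax over that axis.
static inline void cc_positions(int h, int w, int H, int W, int *ph, int *pw) {
  int n = 0;
  for (int i = 0; i < H; ++i) { ph[n] = i; pw[n] = w; ++n; }
  for (int j = 0; j < W; ++j) {
    if (j == w) continue;
    ph[n] = h; pw[n] = j; ++n;
  }
}

// [[Rcpp::export]]
List cpp_cca_fwd(NumericVector q, NumericVector k, NumericVector v,
                 int H, int W, int Cp, int C) {
  const int P = H + W - 1;
  NumericVector out((size_t)H * W * C);
  NumericVector attn((size_t)P * H * W); // dim (P, H, W)
  std::vector<int> ph(P), pw(P);
  std::vector<double> d(P);
  for (int w = 0; w < W; ++w) {
    for (int h = 0; h < H; ++h) {
      cc_positions(h, w, H, W, ph.data(), pw.data());
      double mx = -1e300;
      for (int i = 0; i < P; ++i) {
        double s = 0.0;
        for (int c = 0; c < Cp; ++c)
          s += q[h + (size_t)H * w + (size_t)H * W * c] *
               k[ph[i] + (size_t)H * pw[i] + (size_t)H * W * c];
        d[i] = s;
        if (s > mx) mx = s;
      }
      double z = 0.0;
      for (int i = 0; i < P; ++i) { d[i] = std::exp(d[i] - mx); z += d[i]; }
      for (int i = 0; i < P; ++i) {
        const double a = d[i] / z;
        attn[i + (size_t)P * (h + (size_t)H * w)] = a;
        for (int c = 0; c < C; ++c)
          out[h + (size_t)H * w + (size_t)H * W * c] +=
            a * v[ph[i] + (size_t)H * pw[i] + (size_t)H * W * c];
      }
    }
  }
  out.attr("dim") = IntegerVector::create(H, W, C);
  attn.attr("dim") = IntegerVector::create(P, H, W);
  return List::create(_["out"] = out, _["attn"] = attn);
}

// [[Rcpp::export]]
List cpp_cca_bwd(NumericVector q, NumericVector k, NumericVector v,
                 NumericVector attn, NumericVector gout,
                 int H, int W, int Cp, int C) {
  const int P = H + W - 1;
  NumericVector dq((size_t)H * W * Cp), dk((size_t)H * W * Cp),
                dv((size_t)H * W * C);
  std::vector<int> ph(P), pw(P);
  std::vector<double> da(P), dd(P);
  for (int w = 0; w < W; ++w) {
    for (int h = 0; h < H; ++h) {
      cc_positions(h, w, H, W, ph.data(), pw.data());
      const size_t ub = (size_t)P * (h + (size_t)H * w);
      // dv and d(attn)
      for (int i = 0; i < P; ++i) {
        const double a = attn[i + ub];
        double s = 0.0;
        for (int c = 0; c < C; ++c) {
          const double g = gout[h + (size_t)H * w + (size_t)H * W * c];
          dv[ph[i] + (size_t)H * pw[i] + (size_t)H * W * c] += a * g;
          s += g * v[ph[i] + (size_t)H * pw[i] + (size_t)H * W * c];
        }
        da[i] = s;
      }
      // softmax backward
      double dot = 0.0;
      for (int i = 0; i < P; ++i) dot += attn[i + ub] * da[i];
      for (int i = 0; i < P; ++i) dd[i] = attn[i + ub] * (da[i] - dot);
      // affinity backward
      for (int i = 0; i < P; ++i) {
        for (int c = 0; c < Cp; ++c) {
          dq[h + (size_t)H * w + (size_t)H * W * c] +=
            dd[i] * k[ph[i] + (size_t)H * pw[i] + (size_t)H * W * c];
          dk[ph[i] + (size_t)H * pw[i] + (size_t)H * W * c] +=
            dd[i] * q[h + (size_t)H * w + (size_t)H * W * c];
        }
      }
    }
  }
  dq.attr("dim") = IntegerVector::create(H, W, Cp);
  dk.attr("dim") = IntegerVector::create(H, W, Cp);
  dv.attr("dim") = IntegerVector::create(H, W, C);
  return List::create(_["dq"] = dq, _["dk"] = dk, _["dv"] = dv);
}
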