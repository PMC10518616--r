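// Numerical kernels for the encoder-decoder network and mask post-processing.
// Tensor layout throughout: R arrays dim c(H, W, C, B), column-major.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline int idx4(int h, int w, int c, int b, int H, int W, int C) {
  return h + H * (w + W * (c + C * b));
}

// Same-padding 2-D cross-correlation. wts dim c(kh, kw, Cin, Cout).
// [[Rcpp::export(name = ".cpp_conv2d_fwd")]]
NumericVector cpp_conv2d_fwd(NumericVector x, NumericVector wts,
                             NumericVector bias, IntegerVector xdim,
                             IntegerVector wdim) {
  const int H = xdim[0], W = xdim[1], Ci = xdim[2], B = xdim[3];
  const int kh = wdim[0], kw = wdim[1], Co = wdim[3];
  const int ph = (kh - 1) / 2, pw = (kw - 1) / 2;
  NumericVector y(H * W * Co * B);
  const double *px = x.begin(), *pw_ = wts.begin(), *pb = bias.begin();
  double *py = y.begin();
  for (int b = 0; b < B; ++b)
    for (int co = 0; co < Co; ++co) {
      const double bv = pb[co];
      for (int w = 0; w < W; ++w)
        for (int h = 0; h < H; ++h) {
          double acc = bv;
          for (int ci = 0; ci < Ci; ++ci)
            for (int dw = 0; dw < kw; ++dw) {
              const int ww = w + dw - pw;
              if (ww < 0 || ww >= W) continue;
              for (int dh = 0; dh < kh; ++dh) {
                const int hh = h + dh - ph;
                if (hh < 0 || hh >= H) continue;
                acc += px[idx4(hh, ww, ci, b, H, W, Ci)] *
                       pw_[dh + kh * (dw + kw * (ci + Ci * co))];
              }
            }
          py[idx4(h, w, co, b, H, W, Co)] = acc;
        }
    }
  y.attr("dim") = IntegerVector::create(H, W, Co, B);
  return y;
}

// Gradients of the same-padding correlation w.r.t. input, weights, bias.
// [[Rcpp::export(name = ".cpp_conv2d_bwd")]]
List cpp_conv2d_bwd(NumericVector x, NumericVector wts, NumericVector gy,
                    IntegerVector xdim, IntegerVector wdim) {
  const int H = xdim[0], W = xdim[1], Ci = xdim[2], B = xdim[3];
  const int kh = wdim[0], kw = wdim[1], Co = wdim[3];
  const int ph = (kh - 1) / 2, pw = (kw - 1) / 2;
  NumericVector gx(x.size()), gw(wts.size()), gb(Co);
  const double *px = x.begin(), *pw_ = wts.begin(), *pg = gy.begin();
  double *pgx = gx.begin(), *pgw = gw.begin(), *pgb = gb.begin();
  for (int b = 0; b < B; ++b)
    for (int co = 0; co < Co; ++co)
      for (int w = 0; w < W; ++w)
        for (int h = 0; h < H; ++h) {
          const double g = pg[idx4(h, w, co, b, H, W, Co)];
          pgb[co] += g;
          for (int ci = 0; ci < Ci; ++ci)
            for (int dw = 0; dw < kw; ++dw) {
              const int ww = w + dw - pw;
              if (ww < 0 || ww >= W) continue;
              for (int dh = 0; dh < kh; ++dh) {
                const int hh = h + dh - ph;
                if (hh < 0 || hh >= H) continue;
                const int wi = dh + kh * (dw + kw * (ci + Ci * co));
                pgx[idx4(hh, ww, ci, b, H, W, Ci)] += g * pw_[wi];
                pgw[wi] += g * px[idx4(hh, ww, ci, b, H, W, Ci)];
              }
            }
        }
  gx.attr("dim") = xdim;
  gw.attr("dim") = wdim;
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// 2x2 stride-2 max pooling; idx stores the window-local argmax in
// row-major window order (0,0)->0, (0,1)->1, (1,0)->2, (1,1)->3,
// ties resolved to the first position in that order.
// [[Rcpp::export(name = ".cpp_maxpool2_fwd")]]
List cpp_maxpool2_fwd(NumericVector x, IntegerVector xdim) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], B = xdim[3];
  const int Ho = H / 2, Wo = W / 2;
  NumericVector y(Ho * Wo * C * B);
  IntegerVector idx(Ho * Wo * C * B);
  const double *px = x.begin();
  double *py = y.begin();
  int *pi = idx.begin();
  const int drow[4] = {0, 0, 1, 1}, dcol[4] = {0, 1, 0, 1};
  for (int b = 0; b < B; ++b)
    for (int c = 0; c < C; ++c)
      for (int w = 0; w < Wo; ++w)
        for (int h = 0; h < Ho; ++h) {
          double best = R_NegInf;
          int bi = 0;
          for (int k = 0; k < 4; ++k) {
            const double v =
                px[idx4(2 * h + drow[k], 2 * w + dcol[k], c, b, H, W, C)];
            if (v > best) { best = v; bi = k; }
          }
          const int o = idx4(h, w, c, b, Ho, Wo, C);
          py[o] = best;
          pi[o] = bi;
        }
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, B);
  idx.attr("dim") = IntegerVector::create(Ho, Wo, C, B);
  return List::create(_["y"] = y, _["idx"] = idx);
}

// Index unpooling: place each pooled value at its recorded argmax, zeros
// elsewhere. Also serves as the max-pool backward pass applied to gradients.
// [[Rcpp::export(name = ".cpp_unpool2")]]
NumericVector cpp_unpool2(NumericVector y, IntegerVector idx,
                          IntegerVector ydim) {
  const int Ho = ydim[0], Wo = ydim[1], C = ydim[2], B = ydim[3];
  const int H = 2 * Ho, W = 2 * Wo;
  NumericVector x(H * W * C * B);
  const double *py = y.begin();
  const int *pi = idx.begin();
  double *px = x.begin();
  const int drow[4] = {0, 0, 1, 1}, dcol[4] = {0, 1, 0, 1};
  for (int b = 0; b < B; ++b)
    for (int c = 0; c < C; ++c)
      for (int w = 0; w < Wo; ++w)
        for (int h = 0; h < Ho; ++h) {
          const int o = idx4(h, w, c, b, Ho, Wo, C);
          const int k = pi[o];
          if (k < 0 || k > 3) stop("pooling index out of range");
          px[idx4(2 * h + drow[k], 2 * w + dcol[k], c, b, H, W, C)] = py[o];
        }
  x.attr("dim") = IntegerVector::create(H, W, C, B);
  return x;
}

// 8-connectivity connected-component labelling of a binary matrix.
// [[Rcpp::export(name = ".cpp_label8")]]
IntegerMatrix cpp_label8(IntegerMatrix mask) {
  const int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix lab(H, W);
  std::vector<int> stack;
  int next = 0;
  for (int c0 = 0; c0 < W; ++c0)
    for (int r0 = 0; r0 < H; ++r0) {
      if (mask(r0, c0) == 0 || lab(r0, c0) != 0) continue;
      ++next;
      stack.push_back(r0 + H * c0);
      lab(r0, c0) = next;
      while (!stack.empty()) {
        const int p = stack.back();
        stack.pop_back();
        const int r = p % H, c = p / H;
        for (int dc = -1; dc <= 1; ++dc)
          for (int dr = -1; dr <= 1; ++dr) {
            const int rr = r + dr, cc = c + dc;
            if (rr < 0 || rr >= H || cc < 0 || cc >= W) continue;
            if (mask(rr, cc) != 0 && lab(rr, cc) == 0) {
              lab(rr, cc) = next;
              stack.push_back(rr + H * cc);
            }
          }
      }
    }
  return lab;
}

// CRC-32 (ISO 3309) and Adler-32, needed when emitting PNG chunks.
// [[Rcpp::export(name = ".cpp_crc32")]]
double cpp_crc32(RawVector data) {
  static uint32_t table[256];
  static bool init = false;
  if (!init) {
    for (uint32_t n = 0; n < 256; ++n) {
      uint32_t c = n;
      for (int k = 0; k < 8; ++k)
        c = (c & 1) ? 0xEDB88320u ^ (c >> 1) : (c >> 1);
      table[n] = c;
    }
    init = true;
  }
  uint32_t c = 0xFFFFFFFFu;
  for (R_xlen_t i = 0; i < data.size(); ++i)
    c = table[(c ^ data[i]) & 0xFFu] ^ (c >> 8);
  return static_cast<double>(c ^ 0xFFFFFFFFu);
}

// [[Rcpp::export(name = ".cpp_adler32")]]
double cpp_adler32(RawVector data) {
  uint32_t a = 1, b = 0;
  for (R_xlen_t i = 0; i < data.size(); ++i) {
    a = (a + data[i]) % 65521u;
    b = (b + a) % 65521u;
  }
  return static_cast<double>((b << 16) | a);
}

// Backward pass of index unpooling: gather the gradient at each recorded
// argmax position back onto the pooled grid.
// [[Rcpp::export(name = ".cpp_pool_gather")]]
NumericVector cpp_pool_gather(NumericVector gy, IntegerVector idx,
                              IntegerVector ydim) {
  const int Ho = ydim[0], Wo = ydim[1], C = ydim[2], B = ydim[3];
  const int H = 2 * Ho, W = 2 * Wo;
  NumericVector g(Ho * Wo * C * B);
  const double *pg = gy.begin();
  const int *pi = idx.begin();
  double *po = g.begin();
  const int drow[4] = {0, 0, 1, 1}, dcol[4] = {0, 1, 0, 1};
  for (int b = 0; b < B; ++b)
    for (int c = 0; c < C; ++c)
      for (int w = 0; w < Wo; ++w)
        for (int h = 0; h < Ho; ++h) {
          const int o = idx4(h, w, c, b, Ho, Wo, C);
          const int k = pi[o];
          po[o] = pg[idx4(2 * h + drow[k], 2 * w + dcol[k], c, b, H, W, C)];
        }
  g.attr("dim") = ydim;
  return g;
}
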