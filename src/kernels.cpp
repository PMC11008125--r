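#include <Rcpp.h>
using namespace Rcpp;

// Activation layout throughout the network: a (H*W*N) x C matrix whose row
// order is sample-major, then image column j, then image row i (i fastest).
// This keeps every layer a plain GEMM plus cheap gathers, with no array
// transposition between layers.

// Gather 3x3 patches (zero padding implicit) so that GEMM with a
// (9*C x Cout) weight matrix performs a same-padded convolution.
// Column order: channel-major blocks of 9, kernel offset dj*3 + di within.
// [[Rcpp::export]]
NumericMatrix im2col_pad(NumericMatrix M, int H, int W, int C, int N) {
  NumericMatrix out((R_xlen_t)H * W * N, 9 * C);   // zero-initialized
  for (int c = 0; c < C; ++c) {
    const double *mc = &M(0, c);
    for (int dj = 0; dj < 3; ++dj) {
      for (int di = 0; di < 3; ++di) {
        const int col = c * 9 + dj * 3 + di;
        double *oc = &out(0, col);
        const int i0 = std::max(0, 1 - di);       // first valid output row
        const int len = std::min(H, H + 1 - di) - i0;
        if (len <= 0) continue;
        for (int n = 0; n < N; ++n) {
          for (int j = 0; j < W; ++j) {
            const int jin = j + dj - 1;
            if (jin < 0 || jin >= W) continue;
            const double *src = mc + ((R_xlen_t)n * W + jin) * H + i0 + di - 1;
            double *dst = oc + ((R_xlen_t)n * W + j) * H + i0;
            std::copy(src, src + len, dst);
          }
        }
      }
    }
  }
  return out;
}

// Transpose-adjoint of im2col_pad: scatter-add patch gradients back onto
// the input gradient.
// [[Rcpp::export]]
NumericMatrix col2im_pad(NumericMatrix dP, int H, int W, int C, int N) {
  NumericMatrix dM((R_xlen_t)H * W * N, C);
  for (int c = 0; c < C; ++c) {
    double *mc = &dM(0, c);
    for (int dj = 0; dj < 3; ++dj) {
      for (int di = 0; di < 3; ++di) {
        const int col = c * 9 + dj * 3 + di;
        const double *oc = &dP(0, col);
        const int i0 = std::max(0, 1 - di);
        const int len = std::min(H, H + 1 - di) - i0;
        if (len <= 0) continue;
        for (int n = 0; n < N; ++n) {
          for (int j = 0; j < W; ++j) {
            const int jin = j + dj - 1;
            if (jin < 0 || jin >= W) continue;
            double *dst = mc + ((R_xlen_t)n * W + jin) * H + i0 + di - 1;
            const double *src = oc + ((R_xlen_t)n * W + j) * H + i0;
            for (int k = 0; k < len; ++k) dst[k] += src[k];
          }
        }
      }
    }
  }
  return dM;
}

// In-place bias add + ReLU on a GEMM output; the post-activation zeros
// encode the ReLU mask for the backward pass.
// [[Rcpp::export]]
void bias_relu_inplace(NumericMatrix Z, NumericVector b) {
  const int C = Z.ncol();
  const R_xlen_t R = Z.nrow();
  for (int c = 0; c < C; ++c) {
    double *z = &Z(0, c);
    const double bc = b[c];
    for (R_xlen_t i = 0; i < R; ++i) {
      const double v = z[i] + bc;
      z[i] = v > 0 ? v : 0;
    }
  }
}

// In-place ReLU backward: zero the gradient where the activation was
// clipped.
// [[Rcpp::export]]
void relu_bwd_inplace(NumericMatrix dZ, NumericMatrix Z) {
  const R_xlen_t n = (R_xlen_t)dZ.nrow() * dZ.ncol();
  double *d = dZ.begin();
  const double *z = Z.begin();
  for (R_xlen_t i = 0; i < n; ++i) if (z[i] <= 0) d[i] = 0;
}

// 2x2 max pooling in the matrix layout. Winner index 1..4 enumerates
// offsets (di, dj) = (0,0), (1,0), (0,1), (1,1); ties take the first,
// deterministically.
// [[Rcpp::export]]
List maxpool_m(NumericMatrix M, int H, int W, int C, int N) {
  const int Ho = H / 2, Wo = W / 2;
  NumericMatrix out((R_xlen_t)Ho * Wo * N, C);
  IntegerMatrix win((R_xlen_t)Ho * Wo * N, C);
  for (int c = 0; c < C; ++c) {
    const double *mc = &M(0, c);
    double *oc = &out(0, c);
    int *wc = &win(0, c);
    for (int n = 0; n < N; ++n) {
      for (int jo = 0; jo < Wo; ++jo) {
        const double *c0 = mc + ((R_xlen_t)n * W + 2 * jo) * H;
        const double *c1 = c0 + H;
        double *orow = oc + ((R_xlen_t)n * Wo + jo) * Ho;
        int *wrow = wc + ((R_xlen_t)n * Wo + jo) * Ho;
        for (int io = 0; io < Ho; ++io) {
          const double v[4] = {c0[2 * io], c0[2 * io + 1],
                               c1[2 * io], c1[2 * io + 1]};
          int best = 0;
          for (int k = 1; k < 4; ++k) if (v[k] > v[best]) best = k;
          orow[io] = v[best];
          wrow[io] = best + 1;
        }
      }
    }
  }
  return List::create(_["A"] = out, _["win"] = win);
}

// Backward of maxpool_m: route each pooled gradient to its winner.
// [[Rcpp::export]]
NumericMatrix maxpool_m_bwd(NumericMatrix dM, IntegerMatrix win,
                            int H, int W, int C, int N) {
  const int Ho = H / 2, Wo = W / 2;
  NumericMatrix dA((R_xlen_t)H * W * N, C);
  for (int c = 0; c < C; ++c) {
    double *ac = &dA(0, c);
    const double *gc = &dM(0, c);
    const int *wc = &win(0, c);
    for (int n = 0; n < N; ++n) {
      for (int jo = 0; jo < Wo; ++jo) {
        double *c0 = ac + ((R_xlen_t)n * W + 2 * jo) * H;
        double *c1 = c0 + H;
        const double *grow = gc + ((R_xlen_t)n * Wo + jo) * Ho;
        const int *wrow = wc + ((R_xlen_t)n * Wo + jo) * Ho;
        for (int io = 0; io < Ho; ++io) {
          const int k = wrow[io] - 1;
          const double v = grow[io];
          if (k == 0) c0[2 * io] += v;
          else if (k == 1) c0[2 * io + 1] += v;
          else if (k == 2) c1[2 * io] += v;
          else c1[2 * io + 1] += v;
        }
      }
    }
  }
  return dA;
}

// CRC-32 (IEEE 802.3, as used by PNG chunk trailers), returned as 4
// big-endian bytes in 0..255.
// [[Rcpp::export]]
IntegerVector crc32_bytes(RawVector data) {
  static uint32_t table[256];
  static bool init = false;
  if (!init) {
    for (uint32_t i = 0; i < 256; ++i) {
      uint32_t c = i;
      for (int k = 0; k < 8; ++k)
        c = (c & 1) ? 0xEDB88320u ^ (c >> 1) : c >> 1;
      table[i] = c;
    }
    init = true;
  }
  uint32_t crc = 0xFFFFFFFFu;
  for (R_xlen_t i = 0; i < data.size(); ++i)
    crc = table[(crc ^ data[i]) & 0xFFu] ^ (crc >> 8);
  crc ^= 0xFFFFFFFFu;
  IntegerVector out(4);
  out[0] = (crc >> 24) & 0xFF;
  out[1] = (crc >> 16) & 0xFF;
  out[2] = (crc >> 8) & 0xFF;
  out[3] = crc & 0xFF;
  return out;
}
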