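#include <Rcpp.h>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

// Patch extraction for convolution. x is an H x W x C array (column-major);
// returns a (Hout*Wout) x (kh*kw*C) matrix whose column order matches the
// column-major flattening of a (kh, kw, C) kernel block, so that
// cols %*% matrix(w, kh*kw*C, Cout) is the convolution output.
// [[Rcpp::export]]
NumericMatrix cpp_im2col(NumericVector x, int kh, int kw, int stride,
                         int pad, int dilation) {
    IntegerVector d = x.attr("dim");
    int H = d[0], W = d[1], C = d[2];
    int eff_kh = (kh - 1) * dilation + 1;
    int eff_kw = (kw - 1) * dilation + 1;
    int Hout = (H + 2 * pad - eff_kh) / stride + 1;
    int Wout = (W + 2 * pad - eff_kw) / stride + 1;
    NumericMatrix out(Hout * Wout, kh * kw * C);
    for (int c = 0; c < C; ++c) {
        for (int j = 0; j < kw; ++j) {
            for (int i = 0; i < kh; ++i) {
                int col = i + kh * j + kh * kw * c;
                double* po = &out(0, col);
                for (int wo = 0; wo < Wout; ++wo) {
                    int wi = wo * stride - pad + j * dilation;
                    if (wi < 0 || wi >= W) continue;
                    const double* px = &x[H * (wi + (R_xlen_t)W * c)];
                    for (int ho = 0; ho < Hout; ++ho) {
                        int hi = ho * stride - pad + i * dilation;
                        if (hi >= 0 && hi < H)
                            po[ho + Hout * wo] = px[hi];
                    }
                }
            }
        }
    }
    return out;
}

// Adjoint of cpp_im2col: scatter-add patch gradients back onto the input grid.
// [[Rcpp::export]]
NumericVector cpp_col2im(NumericMatrix cols, int H, int W, int C, int kh,
                         int kw, int stride, int pad, int dilation) {
    int eff_kh = (kh - 1) * dilation + 1;
    int eff_kw = (kw - 1) * dilation + 1;
    int Hout = (H + 2 * pad - eff_kh) / stride + 1;
    int Wout = (W + 2 * pad - eff_kw) / stride + 1;
    NumericVector x((R_xlen_t)H * W * C);
    for (int c = 0; c < C; ++c) {
        for (int j = 0; j < kw; ++j) {
            for (int i = 0; i < kh; ++i) {
                int col = i + kh * j + kh * kw * c;
                const double* po = &cols(0, col);
                for (int wo = 0; wo < Wout; ++wo) {
                    int wi = wo * stride - pad + j * dilation;
                    if (wi < 0 || wi >= W) continue;
                    double* px = &x[H * (wi + (R_xlen_t)W * c)];
                    for (int ho = 0; ho < Hout; ++ho) {
                        int hi = ho * stride - pad + i * dilation;
                        if (hi >= 0 && hi < H)
                            px[hi] += po[ho + Hout * wo];
                    }
                }
            }
        }
    }
    x.attr("dim") = IntegerVector::create(H, W, C);
    return x;
}

// Bilinear resampling with half-pixel-centre alignment.
// [[Rcpp::export]]
NumericMatrix cpp_resize_bilinear(NumericMatrix x, int oh, int ow) {
    int H = x.nrow(), W = x.ncol();
    NumericMatrix y(oh, ow);
    double sh = (double)H / oh, sw = (double)W / ow;
    for (int j = 0; j < ow; ++j) {
        double fx = (j + 0.5) * sw - 0.5;
        int x0 = (int)std::floor(fx);
        double wx = fx - x0;
        int x0c = std::min(std::max(x0, 0), W - 1);
        int x1c = std::min(std::max(x0 + 1, 0), W - 1);
        for (int i = 0; i < oh; ++i) {
            double fy = (i + 0.5) * sh - 0.5;
            int y0 = (int)std::floor(fy);
            double wy = fy - y0;
            int y0c = std::min(std::max(y0, 0), H - 1);
            int y1c = std::min(std::max(y0 + 1, 0), H - 1);
            y(i, j) = (1 - wy) * (1 - wx) * x(y0c, x0c) +
                      (1 - wy) * wx * x(y0c, x1c) +
                      wy * (1 - wx) * x(y1c, x0c) +
                      wy * wx * x(y1c, x1c);
        }
    }
    return y;
}

// Adjoint of cpp_resize_bilinear: scatter output-grid gradients back to the
// input grid with the same interpolation weights.
// [[Rcpp::export]]
NumericMatrix cpp_resize_bilinear_adjoint(NumericMatrix gy, int H, int W) {
    int oh = gy.nrow(), ow = gy.ncol();
    NumericMatrix gx(H, W);
    double sh = (double)H / oh, sw = (double)W / ow;
    for (int j = 0; j < ow; ++j) {
        double fx = (j + 0.5) * sw - 0.5;
        int x0 = (int)std::floor(fx);
        double wx = fx - x0;
        int x0c = std::min(std::max(x0, 0), W - 1);
        int x1c = std::min(std::max(x0 + 1, 0), W - 1);
        for (int i = 0; i < oh; ++i) {
            double fy = (i + 0.5) * sh - 0.5;
            int y0 = (int)std::floor(fy);
            double wy = fy - y0;
            int y0c = std::min(std::max(y0, 0), H - 1);
            int y1c = std::min(std::max(y0 + 1, 0), H - 1);
            double g = gy(i, j);
            gx(y0c, x0c) += (1 - wy) * (1 - wx) * g;
            gx(y0c, x1c) += (1 - wy) * wx * g;
            gx(y1c, x0c) += wy * (1 - wx) * g;
            gx(y1c, x1c) += wy * wx * g;
        }
    }
    return gx;
}

// Gaussian click kernel exp(-4*d2/R^2) aggregated over clicks at every pixel.
// clicks is an n x 2 matrix of 0-based (row, col); mode 0 = max (guidance),
// mode 1 = sum (weight map).
// [[Rcpp::export]]
NumericMatrix cpp_click_kernel(NumericMatrix clicks, int H, int W,
                               double radius, int mode) {
    NumericMatrix out(H, W);
    int n = clicks.nrow();
    if (n == 0) return out;
    double inv = 4.0 / (radius * radius);
    for (int w = 0; w < W; ++w) {
        for (int h = 0; h < H; ++h) {
            double acc = 0.0;
            for (int k = 0; k < n; ++k) {
                double dr = h - clicks(k, 0);
                double dc = w - clicks(k, 1);
                double v = std::exp(-inv * (dr * dr + dc * dc));
                if (mode == 0) { if (v > acc) acc = v; } else acc += v;
            }
            out(h, w) = acc;
        }
    }
    return out;
}
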