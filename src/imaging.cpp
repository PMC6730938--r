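// Blind Richardson-Lucy deconvolution on small images (the 55x55 maximum
// intensity projections), alternating PSF and image updates from an initial
// small Gaussian kernel. Zero-padded boundaries; direct convolution (the
// kernel is tiny).
#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

const double EPS = 1e-12;

// correlation of `img` with kernel k (centered), same size, zero padding
void correlate(const std::vector<double>& img, int H, int W,
               const std::vector<double>& k, int kh, int kw,
               std::vector<double>& out, bool flip) {
  int ch = kh / 2, cw = kw / 2;
  for (int x = 0; x < H; ++x)
    for (int y = 0; y < W; ++y) {
      double s = 0.0;
      for (int a = 0; a < kh; ++a)
        for (int b = 0; b < kw; ++b) {
          int xi = x + a - ch, yi = y + b - cw;
          if (xi < 0 || xi >= H || yi < 0 || yi >= W) continue;
          double kv = flip ? k[(kh - 1 - a) + kh * (kw - 1 - b)]
                           : k[a + kh * b];
          s += kv * img[xi + H * yi];
        }
      out[x + H * y] = s;
    }
}

} // namespace

// [[Rcpp::export]]
List cpp_rl_blind(NumericMatrix obs, NumericMatrix psf0, int iterations) {
  int H = obs.nrow(), W = obs.ncol();
  int kh = psf0.nrow(), kw = psf0.ncol();
  std::vector<double> g(H * W), f(H * W), h(kh * kw);
  for (int i = 0; i < H * W; ++i) {
    g[i] = obs[i] > 0 ? obs[i] : 0.0;
    f[i] = g[i] > EPS ? g[i] : EPS;
  }
  double hs = 0.0;
  for (int i = 0; i < kh * kw; ++i) { h[i] = psf0[i]; hs += h[i]; }
  for (int i = 0; i < kh * kw; ++i) h[i] /= hs;

  std::vector<double> est(H * W), ratio(H * W), uf(H * W);
  double fsum;

  for (int it = 0; it < iterations; ++it) {
    // PSF update: h <- h * corr(f(-), ratio) / sum(f), renormalized
    correlate(f, H, W, h, kh, kw, est, true);   // f (*) h
    for (int i = 0; i < H * W; ++i)
      ratio[i] = g[i] / (est[i] > EPS ? est[i] : EPS);
    fsum = 0.0;
    for (int i = 0; i < H * W; ++i) fsum += f[i];
    int ch = kh / 2, cw = kw / 2;
    std::vector<double> hn(kh * kw, 0.0);
    for (int a = 0; a < kh; ++a)
      for (int b = 0; b < kw; ++b) {
        double s = 0.0;
        for (int x = 0; x < H; ++x)
          for (int y = 0; y < W; ++y) {
            int xi = x + a - ch, yi = y + b - cw;
            if (xi < 0 || xi >= H || yi < 0 || yi >= W) continue;
            s += f[xi + H * yi] * ratio[x + H * y];
          }
        hn[a + kh * b] = h[a + kh * b] * s / (fsum > EPS ? fsum : EPS);
      }
    double hsum = 0.0;
    for (int i = 0; i < kh * kw; ++i) hsum += hn[i];
    if (hsum > EPS) for (int i = 0; i < kh * kw; ++i) h[i] = hn[i] / hsum;

    // image update: f <- f * corr(ratio, h)
    correlate(f, H, W, h, kh, kw, est, true);
    for (int i = 0; i < H * W; ++i)
      ratio[i] = g[i] / (est[i] > EPS ? est[i] : EPS);
    correlate(ratio, H, W, h, kh, kw, uf, false);
    for (int i = 0; i < H * W; ++i) f[i] *= uf[i];
  }

  NumericMatrix fout(H, W), hout(kh, kw);
  for (int i = 0; i < H * W; ++i) fout[i] = f[i];
  for (int i = 0; i < kh * kw; ++i) hout[i] = h[i];
  return List::create(_["image"] = fout, _["psf"] = hout);
}
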