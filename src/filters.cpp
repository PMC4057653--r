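#include <Rcpp.h>
using namespace Rcpp;

// 2-D median filter for 8-bit imagery, Huang sliding-histogram algorithm on
// an edge-replicated padded buffer. `window` must be odd.
// [[Rcpp::export]]
NumericMatrix median_filter_u8(NumericMatrix img, int window) {
  const int h = img.nrow(), w = img.ncol(), r = window / 2;
  const int H = h + 2 * r, W = w + 2 * r;
  const int n = window * window, target = (n + 1) / 2;

  // padded 8-bit copy, column-major
  std::vector<unsigned char> buf((size_t)H * W);
  const double* ip = REAL(img);
  for (int j = 0; j < W; ++j) {
    int sj = j - r; if (sj < 0) sj = 0; else if (sj >= w) sj = w - 1;
    const double* col = ip + (size_t)sj * h;
    unsigned char* bc = &buf[(size_t)j * H];
    for (int i = 0; i < H; ++i) {
      int si = i - r; if (si < 0) si = 0; else if (si >= h) si = h - 1;
      bc[i] = (unsigned char)(col[si] + 0.5);
    }
  }

  NumericMatrix out(h, w);
  double* op = REAL(out);
  std::vector<int> hist(256);
  const int span = 2 * r + 1;
  for (int j = 0; j < w; ++j) {
    std::fill(hist.begin(), hist.end(), 0);
    for (int dj = 0; dj < span; ++dj) {
      const unsigned char* bc = &buf[(size_t)(j + dj) * H];
      for (int di = 0; di < span; ++di) ++hist[bc[di]];
    }
    int med = 0, below = 0; // below = # samples < med
    while (below + hist[med] < target) { below += hist[med]; ++med; }
    op[(size_t)j * h] = med;

    for (int i = 1; i < h; ++i) {
      for (int dj = 0; dj < span; ++dj) {
        const unsigned char* bc = &buf[(size_t)(j + dj) * H];
        const int rem = bc[i - 1], add = bc[i + 2 * r];
        --hist[rem]; if (rem < med) --below;
        ++hist[add]; if (add < med) ++below;
      }
      if (below >= target) {
        do { --med; below -= hist[med]; } while (below >= target);
      } else {
        while (below + hist[med] < target) { below += hist[med]; ++med; }
      }
      op[(size_t)j * h + i] = med;
    }
  }
  return out;
}

// 256-bin intensity histogram (values rounded to the 8-bit grid).
// [[Rcpp::export]]
IntegerVector intensity_hist(NumericMatrix img) {
  IntegerVector hist(256);
  const double* ip = REAL(img);
  const size_t n = (size_t)img.nrow() * img.ncol();
  for (size_t k = 0; k < n; ++k) {
    int v = (int)(ip[k] + 0.5);
    if (v < 0) v = 0; else if (v > 255) v = 255;
    ++hist[v];
  }
  return hist;
}

// Simulated frame capture: bilinear sub-pixel translation by (dx, dy)
// (edge replication), constant illumination offset, additive Gaussian noise,
// clipping to [0, 255] and rounding to the 8-bit grid. Uses R's RNG.
// [[Rcpp::export]]
NumericMatrix acquire_frame_cpp(NumericMatrix img, double dx, double dy,
                                double offset, double noise_sd) {
  const int h = img.nrow(), w = img.ncol();
  NumericMatrix out(h, w);
  const double* ip = REAL(img);
  double* op = REAL(out);
  const bool noisy = noise_sd > 0;

  // constant row shift: sy = i - dy
  const int s0 = (int)std::floor(-dy);
  const double fy = -dy - s0;
  int ilo = std::max(0, -s0);            // rows with y0 in range
  int ihi = std::min(h, h - 1 - s0);     // rows with y0 + 1 in range

  for (int j = 0; j < w; ++j) {
    double sx = j - dx;
    if (sx < 0) sx = 0; else if (sx > w - 1) sx = w - 1;
    const int x0 = (int)sx, x1 = x0 + 1 < w ? x0 + 1 : w - 1;
    const double fx = sx - x0;
    const double* c0 = ip + (size_t)x0 * h;
    const double* c1 = ip + (size_t)x1 * h;
    const double w00 = (1 - fx) * (1 - fy), w01 = (1 - fx) * fy;
    const double w10 = fx * (1 - fy), w11 = fx * fy;
    double* oc = op + (size_t)j * h;

    auto emit = [&](int i, double val) {
      val += offset;
      if (noisy) val += noise_sd * R::norm_rand();
      if (val < 0) val = 0; else if (val > 255) val = 255;
      oc[i] = std::floor(val + 0.5);
    };
    for (int i = 0; i < ilo; ++i) {
      double sy = i - dy;
      if (sy < 0) sy = 0; else if (sy > h - 1) sy = h - 1;
      const int y0 = (int)sy, y1 = y0 + 1 < h ? y0 + 1 : h - 1;
      const double g = sy - y0;
      emit(i, (1 - fx) * ((1 - g) * c0[y0] + g * c0[y1]) +
              fx * ((1 - g) * c1[y0] + g * c1[y1]));
    }
    for (int i = ilo; i < ihi; ++i) {
      const int y0 = i + s0;
      emit(i, w00 * c0[y0] + w01 * c0[y0 + 1] +
              w10 * c1[y0] + w11 * c1[y0 + 1]);
    }
    for (int i = std::max(ilo, ihi); i < h; ++i) {
      double sy = i - dy;
      if (sy < 0) sy = 0; else if (sy > h - 1) sy = h - 1;
      const int y0 = (int)sy, y1 = y0 + 1 < h ? y0 + 1 : h - 1;
      const double g = sy - y0;
      emit(i, (1 - fx) * ((1 - g) * c0[y0] + g * c0[y1]) +
              fx * ((1 - g) * c1[y0] + g * c1[y1]));
    }
  }
  return out;
}
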