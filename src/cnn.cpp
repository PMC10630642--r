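// VGG19-topology backbone: seeded weight generation, im2col + sgemm
// forward pass in single precision, feature tap at the first fully
// connected layer (post-ReLU). Weights live behind an external pointer
// and are rebuilt from the seed on demand by the R side. Scratch buffers
// are preallocated once per net so repeated forward passes do not churn
// hundreds of MB of fresh pages.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

// splitmix64 + xoshiro256** : tiny, fast, deterministic weight stream.
struct WeightRng {
  uint64_t s[4];
  explicit WeightRng(uint64_t seed) {
    uint64_t x = seed;
    for (int i = 0; i < 4; ++i) {
      x += 0x9e3779b97f4a7c15ULL;
      uint64_t z = x;
      z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
      z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
      s[i] = z ^ (z >> 31);
    }
  }
  static uint64_t rotl(uint64_t x, int k) { return (x << k) | (x >> (64 - k)); }
  uint64_t next() {
    const uint64_t result = rotl(s[1] * 5, 7) * 9;
    const uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return result;
  }
};

struct VGGNet {
  std::vector<int> plan;      // conv depths in order; -1 marks a 2x2 max-pool
  std::vector<fmat> convW;    // (inC*9) x outC
  std::vector<fvec> convB;
  std::vector<fmat> fcW;      // in x out
  std::vector<fvec> fcB;
  int inputSize = 224;
  // reusable forward-pass scratch (uninitialized on purpose)
  fmat bufCols, bufA, bufB;
};

// He-uniform initialization: U(-b, b) with b = sqrt(6 / fan_in), the
// variance-preserving scale for ReLU stacks.
static void fill_he(fmat& w, int fanIn, WeightRng& rng) {
  const float b = std::sqrt(6.f / fanIn);
  const float scale = 2.f * b / 18446744073709551616.0f;  // 2^64
  float* p = w.memptr();
  const uword n = w.n_elem;
  for (uword i = 0; i < n; ++i)
    p[i] = static_cast<float>(rng.next()) * scale - b;
}

// [[Rcpp::export(name = ".cnn_build")]]
SEXP cnn_build(Rcpp::IntegerVector plan, Rcpp::IntegerVector fc,
               int inputSize, double seed) {
  auto* net = new VGGNet();
  net->plan = std::vector<int>(plan.begin(), plan.end());
  net->inputSize = inputSize;
  WeightRng rng(static_cast<uint64_t>(seed));
  int inC = 3;
  size_t maxCols = 0, maxAct = static_cast<size_t>(inputSize) * inputSize * 3;
  int H = inputSize;
  for (int d : net->plan) {
    if (d < 0) { H /= 2; continue; }
    fmat w(inC * 9, d);
    fill_he(w, inC * 9, rng);
    net->convW.push_back(std::move(w));
    net->convB.push_back(fvec(d, fill::zeros));
    maxCols = std::max(maxCols, static_cast<size_t>(H) * H * inC * 9);
    maxAct = std::max(maxAct, static_cast<size_t>(H) * H * d);
    inC = d;
  }
  int pools = 0;
  for (int d : net->plan) if (d < 0) ++pools;
  int side = inputSize >> pools;
  int fin = side * side * inC;
  for (int i = 0; i < fc.size(); ++i) {
    fmat w(fin, fc[i]);
    fill_he(w, fin, rng);
    net->fcW.push_back(std::move(w));
    net->fcB.push_back(fvec(fc[i], fill::zeros));
    fin = fc[i];
  }
  net->bufCols.set_size(maxCols, 1);
  net->bufA.set_size(maxAct, 1);
  net->bufB.set_size(maxAct, 1);
  Rcpp::XPtr<VGGNet> ptr(net, true);
  return ptr;
}

// Replace one weight layer (1-based over conv layers then FC layers).
// [[Rcpp::export(name = ".cnn_set_layer")]]
void cnn_set_layer(SEXP p, int layer, Rcpp::NumericMatrix w,
                   Rcpp::NumericVector b) {
  Rcpp::XPtr<VGGNet> net(p);
  const int nConv = static_cast<int>(net->convW.size());
  fmat* W; fvec* B;
  if (layer >= 1 && layer <= nConv) {
    W = &net->convW[layer - 1]; B = &net->convB[layer - 1];
  } else if (layer > nConv &&
             layer <= nConv + static_cast<int>(net->fcW.size())) {
    W = &net->fcW[layer - nConv - 1]; B = &net->fcB[layer - nConv - 1];
  } else Rcpp::stop("layer index out of range");
  if (static_cast<uword>(w.nrow()) != W->n_rows ||
      static_cast<uword>(w.ncol()) != W->n_cols)
    Rcpp::stop("weight shape mismatch for layer %d: expected %d x %d",
               layer, (int)W->n_rows, (int)W->n_cols);
  if (static_cast<uword>(b.size()) != B->n_elem)
    Rcpp::stop("bias length mismatch for layer %d", layer);
  for (uword i = 0; i < W->n_elem; ++i) (*W)[i] = static_cast<float>(w[i]);
  for (uword i = 0; i < B->n_elem; ++i) (*B)[i] = static_cast<float>(b[i]);
}

// [[Rcpp::export(name = ".cnn_valid")]]
bool cnn_valid(SEXP p) {
  return TYPEOF(p) == EXTPTRSXP && R_ExternalPtrAddr(p) != nullptr;
}

// [[Rcpp::export(name = ".cnn_param_count")]]
double cnn_param_count(SEXP p) {
  Rcpp::XPtr<VGGNet> net(p);
  double n = 0;
  for (auto& w : net->convW) n += w.n_elem;
  for (auto& b : net->convB) n += b.n_elem;
  for (auto& w : net->fcW) n += w.n_elem;
  for (auto& b : net->fcB) n += b.n_elem;
  return n;
}

// [[Rcpp::export(name = ".cnn_checksum")]]
double cnn_checksum(SEXP p) {
  Rcpp::XPtr<VGGNet> net(p);
  double s = 0;
  for (auto& w : net->convW)
    for (uword i = 0; i < w.n_elem; ++i) s += w[i];
  for (auto& w : net->fcW)
    for (uword i = 0; i < w.n_elem; ++i) s += w[i];
  return s;
}

// im2col for a 3x3 pad-1 convolution; src holds C column-major HxW planes.
static void im2col3(const float* src, float* dst, int H, int W, int C) {
  for (int c = 0; c < C; ++c) {
    const float* plane = src + static_cast<size_t>(c) * H * W;
    for (int dr = -1; dr <= 1; ++dr) {
      for (int dc = -1; dc <= 1; ++dc) {
        size_t k = static_cast<size_t>(c) * 9 + (dr + 1) * 3 + (dc + 1);
        float* dk = dst + k * H * W;
        int i0 = std::max(0, -dr), i1 = std::min(H, H - dr);
        for (int j = 0; j < W; ++j) {
          float* d = dk + static_cast<size_t>(j) * H;
          int sj = j + dc;
          if (sj < 0 || sj >= W) { std::memset(d, 0, sizeof(float) * H); continue; }
          const float* s = plane + static_cast<size_t>(sj) * H + dr;
          if (i0 > 0) d[0] = 0.f;
          std::memcpy(d + i0, s + i0, sizeof(float) * (i1 - i0));
          if (i1 < H) d[H - 1] = 0.f;
        }
      }
    }
  }
}

// [[Rcpp::export(name = ".cnn_forward")]]
Rcpp::NumericVector cnn_forward(SEXP p, Rcpp::NumericVector img) {
  Rcpp::XPtr<VGGNet> net(p);
  Rcpp::IntegerVector dims = img.attr("dim");
  if (dims.size() != 3 || dims[0] != net->inputSize ||
      dims[1] != net->inputSize || dims[2] != 3)
    Rcpp::stop("expected a %d x %d x 3 input array", net->inputSize,
               net->inputSize);
  int H = net->inputSize, W = net->inputSize, C = 3;
  float* cur = net->bufA.memptr();
  float* alt = net->bufB.memptr();
  for (R_xlen_t i = 0; i < img.size(); ++i)
    cur[i] = static_cast<float>(img[i]) - 0.5f;  // center the [0,1] input
  size_t li = 0;
  for (int d : net->plan) {
    if (d < 0) {  // 2x2 max-pool, stride 2
      int h2 = H / 2, w2 = W / 2;
      for (int c = 0; c < C; ++c) {
        const float* pl = cur + static_cast<size_t>(c) * H * W;
        float* yo = alt + static_cast<size_t>(c) * h2 * w2;
        for (int j = 0; j < w2; ++j) {
          const float* c0 = pl + static_cast<size_t>(2 * j) * H;
          const float* c1 = c0 + H;
          float* o = yo + static_cast<size_t>(j) * h2;
          for (int i = 0; i < h2; ++i)
            o[i] = std::max(std::max(c0[2 * i], c0[2 * i + 1]),
                            std::max(c1[2 * i], c1[2 * i + 1]));
        }
      }
      std::swap(cur, alt);
      H = h2; W = w2;
      continue;
    }
    im2col3(cur, net->bufCols.memptr(), H, W, C);
    const uword hw = static_cast<uword>(H) * W;
    const fmat cols(net->bufCols.memptr(), hw, static_cast<uword>(C) * 9,
                    false, true);
    fmat out(alt, hw, static_cast<uword>(d), false, true);
    out = cols * net->convW[li];               // sgemm into scratch
    const float* bias = net->convB[li].memptr();
    for (int c = 0; c < d; ++c) {
      float* oc = alt + static_cast<size_t>(c) * hw;
      const float b = bias[c];
      for (uword i = 0; i < hw; ++i) oc[i] = std::max(oc[i] + b, 0.f);
    }
    std::swap(cur, alt);
    C = d;
    ++li;
  }
  // feature tap: FC1 post-ReLU
  const fvec flat(cur, static_cast<uword>(H) * W * C, false, true);
  fvec f = net->fcW[0].t() * flat + net->fcB[0];
  f.transform([](float v) { return v > 0.f ? v : 0.f; });
  return Rcpp::NumericVector(f.begin(), f.end());
}
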