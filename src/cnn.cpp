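// Convolutional network kernels for the inclination regressor.
//
// The network family is fixed: 4 convolutional layers (leaky-ReLU, optional
// max-pooling, optional dropout) followed by 3 fully connected layers, the
// last one linear with 2 units. Convolutions are evaluated as im2col + GEMM
// in single precision; gradients are exact (col2im scatter for the input
// gradient). All stochastic elements (dropout masks) are driven by an
// explicit 64-bit seed so results are reproducible for a fixed seed and
// BLAS build.

#include <RcppArmadillo.h>
#include <random>
#include <cstring>

// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

namespace {

struct ConvLayer {
  int k, stride, pool, in_ch, out_ch;
  double dropout;
};

struct NetSpec {
  int input_px;
  double alpha;  // leaky-ReLU slope
  std::vector<ConvLayer> conv;
  std::vector<int> fc_dims;        // e.g. {64, 32, 2}
  std::vector<double> fc_dropout;  // same length as fc_dims
};

NetSpec parse_spec(const Rcpp::List& spec) {
  NetSpec s;
  s.input_px = Rcpp::as<int>(spec["input_px"]);
  s.alpha = Rcpp::as<double>(spec["alpha"]);
  Rcpp::IntegerVector k = spec["conv_kernel"], ch = spec["conv_channels"],
                      st = spec["conv_stride"], po = spec["conv_pool"];
  Rcpp::NumericVector cd = spec["conv_dropout"];
  int in_ch = 1;
  for (int i = 0; i < k.size(); ++i) {
    ConvLayer L;
    L.k = k[i]; L.stride = st[i]; L.pool = po[i];
    L.in_ch = in_ch; L.out_ch = ch[i]; L.dropout = cd[i];
    s.conv.push_back(L);
    in_ch = ch[i];
  }
  Rcpp::IntegerVector fd = spec["fc_dims"];
  Rcpp::NumericVector fdr = spec["fc_dropout"];
  s.fc_dims.assign(fd.begin(), fd.end());
  s.fc_dropout.assign(fdr.begin(), fdr.end());
  return s;
}

inline int conv_out(int n, int k, int stride) { return (n - k) / stride + 1; }

// im2col for a single-channel-major image stack: img is (px*px*ch) with
// channel-major planes, column layout x-major within plane? We store images
// as column-major px x px matrices (rows = y), channels stacked.
// Patches matrix: (k*k*in_ch) x (out*out), patch columns ordered (ox, oy)
// column-major over output (oy fastest to match arma col-major out plane).
void im2col(const float* img, int px, int in_ch, int k, int stride,
            fmat& cols) {
  int out = conv_out(px, k, stride);
  // cols is (k*k*in_ch) x (out*out); column index = ox*out + oy.
  // Each patch column is k-float contiguous runs from the source plane;
  // memcpy keeps this on the fast path (it dominates the non-GEMM cost).
  for (int ox = 0; ox < out; ++ox) {
    for (int oy = 0; oy < out; ++oy) {
      float* dst = cols.colptr(ox * out + oy);
      int x0 = ox * stride, y0 = oy * stride;
      for (int c = 0; c < in_ch; ++c) {
        const float* plane = img + (size_t)c * px * px + y0;
        if (k == 3) {
          for (int dx = 0; dx < 3; ++dx) {
            const float* sp = plane + (size_t)(x0 + dx) * px;
            dst[0] = sp[0]; dst[1] = sp[1]; dst[2] = sp[2];
            dst += 3;
          }
        } else if (k == 5) {
          for (int dx = 0; dx < 5; ++dx) {
            const float* sp = plane + (size_t)(x0 + dx) * px;
            dst[0] = sp[0]; dst[1] = sp[1]; dst[2] = sp[2];
            dst[3] = sp[3]; dst[4] = sp[4];
            dst += 5;
          }
        } else {
          for (int dx = 0; dx < k; ++dx) {
            std::memcpy(dst, plane + (size_t)(x0 + dx) * px,
                        k * sizeof(float));
            dst += k;
          }
        }
      }
    }
  }
}

// scatter-add transpose of im2col
void col2im_add(const fmat& cols, int px, int in_ch, int k, int stride,
                float* img) {
  int out = conv_out(px, k, stride);
  for (int ox = 0; ox < out; ++ox) {
    for (int oy = 0; oy < out; ++oy) {
      const float* src = cols.colptr(ox * out + oy);
      int x0 = ox * stride, y0 = oy * stride;
      int r = 0;
      for (int c = 0; c < in_ch; ++c) {
        float* plane = img + (size_t)c * px * px + y0;
        if (k == 3) {
          for (int dx = 0; dx < 3; ++dx) {
            float* colp = plane + (size_t)(x0 + dx) * px;
            colp[0] += src[r]; colp[1] += src[r + 1]; colp[2] += src[r + 2];
            r += 3;
          }
        } else if (k == 5) {
          for (int dx = 0; dx < 5; ++dx) {
            float* colp = plane + (size_t)(x0 + dx) * px;
            colp[0] += src[r];     colp[1] += src[r + 1];
            colp[2] += src[r + 2]; colp[3] += src[r + 3];
            colp[4] += src[r + 4];
            r += 5;
          }
        } else {
          for (int dx = 0; dx < k; ++dx) {
            float* colp = plane + (size_t)(x0 + dx) * px;
            for (int dy = 0; dy < k; ++dy) colp[dy] += src[r++];
          }
        }
      }
    }
  }
}

struct LayerCache {
  fvec planes;     // channel-major output planes (conv only)
  fmat bga, bgpre, bgcols;  // backward scratch, reused across samples
  fmat cols;       // im2col patches (conv only)
  fmat pre;        // pre-activation (out_ch x out*out) or fc (units x B)
  fmat act;        // post-activation, post-pool, post-dropout
  umat pool_idx;   // argmax linear index into pre-pool activation
  fmat drop_mask;
};

inline void leaky_fwd(fmat& a, double alpha) {
  a.transform([alpha](float v) { return v > 0.f ? v : (float)(alpha * v); });
}

fmat leaky_bwd(const fmat& pre, const fmat& g, double alpha) {
  fmat out(size(g));
  const float* p = pre.memptr(); const float* gg = g.memptr();
  float* o = out.memptr();
  float a = (float)alpha;
  for (uword i = 0; i < g.n_elem; ++i) o[i] = p[i] > 0.f ? gg[i] : a * gg[i];
  return out;
}

// in place: scales g by the activation derivative read off the sign of the
// (already activated) pre buffer; zeroed dropout units carry zero gradient
// upstream of this, so their sign ambiguity is irrelevant
inline void leaky_bwd_inplace(const fmat& act_sign, fmat& g, double alpha) {
  const float* p = act_sign.memptr();
  float* gg = g.memptr();
  float a = (float)alpha;
  for (uword i = 0; i < g.n_elem; ++i) if (p[i] <= 0.f) gg[i] *= a;
}

struct Params {
  std::vector<fmat> Wc; std::vector<fvec> bc;
  std::vector<fmat> Wf; std::vector<fvec> bf;
};

Params parse_params(const Rcpp::List& par, const NetSpec& s) {
  Params p;
  Rcpp::List Wc = par["conv_w"], bc = par["conv_b"],
             Wf = par["fc_w"], bf = par["fc_b"];
  for (size_t i = 0; i < s.conv.size(); ++i) {
    p.Wc.push_back(conv_to<fmat>::from(Rcpp::as<mat>(Wc[i])));
    p.bc.push_back(conv_to<fvec>::from(Rcpp::as<vec>(bc[i])));
  }
  for (size_t i = 0; i < s.fc_dims.size(); ++i) {
    p.Wf.push_back(conv_to<fmat>::from(Rcpp::as<mat>(Wf[i])));
    p.bf.push_back(conv_to<fvec>::from(Rcpp::as<vec>(bf[i])));
  }
  return p;
}

// Forward for one image; returns flattened features and fills caches.
// img: input_px*input_px floats (single channel).
void conv_forward_one(const Params& P, const NetSpec& s, const float* img,
                      bool training, std::mt19937_64& rng,
                      std::vector<LayerCache>& cache, fvec& flat) {
  int px = s.input_px;
  const float* src = img;
  std::uniform_real_distribution<double> unif(0.0, 1.0);
  for (size_t li = 0; li < s.conv.size(); ++li) {
    const ConvLayer& L = s.conv[li];
    int out = conv_out(px, L.k, L.stride);
    LayerCache& C = cache[li];
    C.cols.set_size(L.k * L.k * L.in_ch, out * out);
    im2col(src, px, L.in_ch, L.k, L.stride, C.cols);
    C.pre = P.Wc[li] * C.cols;            // out_ch x out*out
    C.pre.each_col() += P.bc[li];
    leaky_fwd(C.pre, s.alpha);            // activated in place; backward
                                          // only needs the sign
    int opx = out;
    if (L.pool > 1) {
      int ppx = out / L.pool;
      fmat& a = C.pre;
      fmat pooled(L.out_ch, ppx * ppx);
      C.pool_idx.set_size(L.out_ch, ppx * ppx);
      for (int pxi = 0; pxi < ppx; ++pxi) {
        for (int pyi = 0; pyi < ppx; ++pyi) {
          int pc = pxi * ppx + pyi;
          for (int ch = 0; ch < L.out_ch; ++ch) {
            float best = -1e30f; uword besti = 0;
            for (int dx = 0; dx < L.pool; ++dx) {
              for (int dy = 0; dy < L.pool; ++dy) {
                uword col = (uword)(pxi * L.pool + dx) * out +
                            (pyi * L.pool + dy);
                float v = a(ch, col);
                if (v > best) { best = v; besti = col; }
              }
            }
            pooled(ch, pc) = best;
            C.pool_idx(ch, pc) = besti;
          }
        }
      }
      C.act = std::move(pooled);
      opx = ppx;
    }
    // pooled layers continue from C.act; unpooled ones reuse C.pre
    fmat& outm = (L.pool > 1) ? C.act : C.pre;
    if (training && L.dropout > 0) {
      C.drop_mask.set_size(size(outm));
      float keep = 1.0f - (float)L.dropout;
      for (uword i = 0; i < outm.n_elem; ++i)
        C.drop_mask(i) = unif(rng) < keep ? 1.0f / keep : 0.0f;
      outm %= C.drop_mask;
    }
    // flatten channel-major planes for next layer: plane ch = row ch
    C.planes.set_size((uword)opx * opx * L.out_ch);
    {
      const float* ap = outm.memptr();  // out_ch x opx*opx, column-major
      float* pp = C.planes.memptr();
      int oc = L.out_ch;
      for (int ch = 0; ch < oc; ++ch) {
        float* dst = pp + (size_t)ch * opx * opx;
        const float* sp = ap + ch;
        for (int i2 = 0; i2 < opx * opx; ++i2) dst[i2] = sp[(size_t)i2 * oc];
      }
    }
    src = C.planes.memptr();
    px = opx;
  }
  flat = cache.back().planes;
}

}  // namespace

// Forward pass for a batch. X: (input_px^2) x B double matrix. Returns 2 x B
// predictions. training enables dropout (seeded).
// [[Rcpp::export(rng = false)]]
arma::mat cnn_forward(const Rcpp::List& params, const Rcpp::List& spec,
                      const arma::mat& X, bool training = false,
                      double seed = 0) {
  NetSpec s = parse_spec(spec);
  Params P = parse_params(params, s);
  int B = X.n_cols;
  int nfc = s.fc_dims.size();
  mat out(s.fc_dims.back(), B);
  std::mt19937_64 rng((uint64_t)seed);
  std::uniform_real_distribution<double> unif(0.0, 1.0);
  std::vector<LayerCache> cache(s.conv.size());
  for (int b = 0; b < B; ++b) {
    fvec img = conv_to<fvec>::from(vec(X.col(b)));
    fvec flat;
    conv_forward_one(P, s, img.memptr(), training, rng, cache, flat);
    fvec h = flat;
    for (int f = 0; f < nfc; ++f) {
      fvec z = P.Wf[f] * h + P.bf[f];
      if (f < nfc - 1) {
        for (uword i = 0; i < z.n_elem; ++i)
          if (z(i) < 0) z(i) *= (float)s.alpha;
        if (training && s.fc_dropout[f] > 0) {
          float keep = 1.0f - (float)s.fc_dropout[f];
          for (uword i = 0; i < z.n_elem; ++i)
            z(i) = unif(rng) < keep ? z(i) / keep : 0.0f;
        }
      }
      h = z;
    }
    out.col(b) = conv_to<vec>::from(h);
  }
  return out;
}

// One training step's loss and gradients for a batch (MSE, mean over batch
// and the 2 output units). Returns list(loss, pred, grads).
// [[Rcpp::export(rng = false)]]
Rcpp::List cnn_loss_grad(const Rcpp::List& params, const Rcpp::List& spec,
                         const arma::mat& X, const arma::mat& Y,
                         double seed) {
  NetSpec s = parse_spec(spec);
  Params P = parse_params(params, s);
  int B = X.n_cols;
  int nc = s.conv.size(), nfc = s.fc_dims.size();

  std::vector<fmat> gWc(nc), gWf(nfc);
  std::vector<fvec> gbc(nc), gbf(nfc);
  for (int i = 0; i < nc; ++i) {
    gWc[i].zeros(size(P.Wc[i])); gbc[i].zeros(P.bc[i].n_elem);
  }
  for (int i = 0; i < nfc; ++i) {
    gWf[i].zeros(size(P.Wf[i])); gbf[i].zeros(P.bf[i].n_elem);
  }

  std::mt19937_64 rng((uint64_t)seed);
  std::uniform_real_distribution<double> unif(0.0, 1.0);
  double loss = 0.0;
  mat pred(s.fc_dims.back(), B);
  std::vector<LayerCache> cache(nc);

  // per-layer geometry
  std::vector<int> in_px(nc + 1);
  in_px[0] = s.input_px;
  for (int i = 0; i < nc; ++i) {
    int o = conv_out(in_px[i], s.conv[i].k, s.conv[i].stride);
    in_px[i + 1] = s.conv[i].pool > 1 ? o / s.conv[i].pool : o;
  }

  for (int b = 0; b < B; ++b) {
    fvec img = conv_to<fvec>::from(vec(X.col(b)));
    fvec flat;
    conv_forward_one(P, s, img.memptr(), true, rng, cache, flat);

    // FC forward with caches
    std::vector<fvec> fc_in(nfc), fc_pre(nfc), fc_mask(nfc);
    fvec h = flat;
    for (int f = 0; f < nfc; ++f) {
      fc_in[f] = h;
      fvec z = P.Wf[f] * h + P.bf[f];
      fc_pre[f] = z;
      if (f < nfc - 1) {
        for (uword i = 0; i < z.n_elem; ++i)
          if (z(i) < 0) z(i) *= (float)s.alpha;
        if (s.fc_dropout[f] > 0) {
          float keep = 1.0f - (float)s.fc_dropout[f];
          fc_mask[f].set_size(z.n_elem);
          for (uword i = 0; i < z.n_elem; ++i)
            fc_mask[f](i) = unif(rng) < keep ? 1.0f / keep : 0.0f;
          z %= fc_mask[f];
        }
      }
      h = z;
    }
    vec yh = conv_to<vec>::from(h);
    pred.col(b) = yh;
    vec resid = yh - Y.col(b);
    loss += dot(resid, resid);

    // backward: d loss_b / d yh = 2 resid / (2 * B) (mean over units & batch)
    fvec g = conv_to<fvec>::from(resid) * (float)(2.0 / (2.0 * B));
    for (int f = nfc - 1; f >= 0; --f) {
      if (f < nfc - 1) {
        if (s.fc_dropout[f] > 0) g %= fc_mask[f];
        for (uword i = 0; i < g.n_elem; ++i)
          if (fc_pre[f](i) < 0) g(i) *= (float)s.alpha;
      }
      gWf[f] += g * fc_in[f].t();
      gbf[f] += g;
      if (f > 0 || nc > 0) g = P.Wf[f].t() * g;
    }

    // conv backward
    // g currently: gradient wrt flattened conv output (channel-major planes)
    for (int li = nc - 1; li >= 0; --li) {
      const ConvLayer& L = s.conv[li];
      LayerCache& C = cache[li];
      int opx = in_px[li + 1];  // post-pool size
      int out = conv_out(in_px[li], L.k, L.stride);
      // reshape g into (out_ch x opx*opx)
      fmat ga(L.out_ch, opx * opx);
      for (int ch = 0; ch < L.out_ch; ++ch)
        for (int i = 0; i < opx * opx; ++i)
          ga(ch, i) = g((uword)ch * opx * opx + i);
      if (L.dropout > 0) ga %= C.drop_mask;
      fmat gpre;
      if (L.pool > 1) {
        gpre.zeros(L.out_ch, out * out);
        for (uword pc = 0; pc < (uword)(opx * opx); ++pc)
          for (int ch = 0; ch < L.out_ch; ++ch)
            gpre(ch, C.pool_idx(ch, pc)) += ga(ch, pc);
      } else {
        gpre = std::move(ga);
      }
      gpre = leaky_bwd(C.pre, gpre, s.alpha);
      gWc[li] += gpre * C.cols.t();
      gbc[li] += sum(gpre, 1);
      if (li > 0) {
        fmat gcols = P.Wc[li].t() * gpre;  // (k*k*in_ch) x out*out
        int ipx = in_px[li];
        fvec gimg((uword)ipx * ipx * L.in_ch, fill::zeros);
        col2im_add(gcols, ipx, L.in_ch, L.k, L.stride, gimg.memptr());
        g = gimg;
      }
    }
  }

  loss /= (2.0 * B);
  Rcpp::List Wc(nc), bcL(nc), Wf(nfc), bfL(nfc);
  for (int i = 0; i < nc; ++i) {
    Wc[i] = conv_to<mat>::from(gWc[i]);
    bcL[i] = conv_to<vec>::from(gbc[i]);
  }
  for (int i = 0; i < nfc; ++i) {
    Wf[i] = conv_to<mat>::from(gWf[i]);
    bfL[i] = conv_to<vec>::from(gbf[i]);
  }
  return Rcpp::List::create(
      Rcpp::Named("loss") = loss,
      Rcpp::Named("pred") = pred,
      Rcpp::Named("grads") = Rcpp::List::create(
          Rcpp::Named("conv_w") = Wc, Rcpp::Named("conv_b") = bcL,
          Rcpp::Named("fc_w") = Wf, Rcpp::Named("fc_b") = bfL));
}

namespace {

struct AdamState {
  std::vector<fmat> mWc, vWc, mWf, vWf;
  std::vector<fvec> mbc, vbc, mbf, vbf;
  int t = 0;
};

void adam_step_mat(fmat& w, const fmat& g, fmat& m, fmat& v, float lr,
                   float b1, float b2, float c1, float c2, float eps) {
  m = b1 * m + (1.f - b1) * g;
  v = b2 * v + (1.f - b2) * square(g);
  w -= lr * (m / c1) / (sqrt(v / c2) + eps);
}

void adam_step_vec(fvec& w, const fvec& g, fvec& m, fvec& v, float lr,
                   float b1, float b2, float c1, float c2, float eps) {
  m = b1 * m + (1.f - b1) * g;
  v = b2 * v + (1.f - b2) * square(g);
  w -= lr * (m / c1) / (sqrt(v / c2) + eps);
}

// forward pass only, eval mode, on float data
mat predict_all(const Params& P, const NetSpec& s, const fmat& X) {
  int B = X.n_cols;
  int nfc = s.fc_dims.size();
  mat out(s.fc_dims.back(), B);
  std::mt19937_64 rng(0);
  std::vector<LayerCache> cache(s.conv.size());
  for (int b = 0; b < B; ++b) {
    fvec flat;
    conv_forward_one(P, s, X.colptr(b), false, rng, cache, flat);
    fvec h = flat;
    for (int f = 0; f < nfc; ++f) {
      fvec z = P.Wf[f] * h + P.bf[f];
      if (f < nfc - 1)
        for (uword i = 0; i < z.n_elem; ++i)
          if (z(i) < 0) z(i) *= (float)s.alpha;
      h = z;
    }
    out.col(b) = conv_to<vec>::from(h);
  }
  return out;
}

Rcpp::List params_to_r(const Params& P) {
  int nc = P.Wc.size(), nfc = P.Wf.size();
  Rcpp::List Wc(nc), bc(nc), Wf(nfc), bf(nfc);
  for (int i = 0; i < nc; ++i) {
    Wc[i] = conv_to<mat>::from(P.Wc[i]);
    bc[i] = conv_to<vec>::from(P.bc[i]);
  }
  for (int i = 0; i < nfc; ++i) {
    Wf[i] = conv_to<mat>::from(P.Wf[i]);
    bf[i] = conv_to<vec>::from(P.bf[i]);
  }
  return Rcpp::List::create(Rcpp::Named("conv_w") = Wc,
                            Rcpp::Named("conv_b") = bc,
                            Rcpp::Named("fc_w") = Wf,
                            Rcpp::Named("fc_b") = bf);
}

}  // namespace

// Full training loop: minibatch Adam on MSE with per-epoch validation,
// best-parameter retention and early stopping. X/Y column-per-sample;
// returns trained params (best validation if val given) and the history.
// All randomness (shuffling, dropout) derives from `seed`.
// [[Rcpp::export(rng = false)]]
Rcpp::List cnn_fit(const Rcpp::List& params, const Rcpp::List& spec,
                   const arma::mat& X, const arma::mat& Y,
                   Rcpp::Nullable<Rcpp::NumericMatrix> Xval,
                   Rcpp::Nullable<Rcpp::NumericMatrix> Yval,
                   int epochs, double lr, int batch_size, int patience,
                   double seed, bool verbose) {
  NetSpec s = parse_spec(spec);
  Params P = parse_params(params, s);
  fmat Xf = conv_to<fmat>::from(X);
  fmat Yf = conv_to<fmat>::from(Y);
  fmat Xv, Yv;
  bool has_val = Xval.isNotNull() && Yval.isNotNull();
  if (has_val) {
    Xv = conv_to<fmat>::from(Rcpp::as<mat>(Xval.get()));
    Yv = conv_to<fmat>::from(Rcpp::as<mat>(Yval.get()));
  }
  int n = Xf.n_cols;
  int nc = s.conv.size(), nfc = s.fc_dims.size();

  AdamState A;
  for (int i = 0; i < nc; ++i) {
    A.mWc.push_back(zeros<fmat>(size(P.Wc[i])));
    A.vWc.push_back(zeros<fmat>(size(P.Wc[i])));
    A.mbc.push_back(zeros<fvec>(P.bc[i].n_elem));
    A.vbc.push_back(zeros<fvec>(P.bc[i].n_elem));
  }
  for (int i = 0; i < nfc; ++i) {
    A.mWf.push_back(zeros<fmat>(size(P.Wf[i])));
    A.vWf.push_back(zeros<fmat>(size(P.Wf[i])));
    A.mbf.push_back(zeros<fvec>(P.bf[i].n_elem));
    A.vbf.push_back(zeros<fvec>(P.bf[i].n_elem));
  }
  const float b1 = 0.9f, b2 = 0.999f, eps = 1e-8f;

  std::mt19937_64 rng((uint64_t)seed);
  std::vector<int> order(n);
  for (int i = 0; i < n; ++i) order[i] = i;

  std::vector<double> hist_train, hist_val;
  Params best = P;
  double best_val = datum::inf;
  int bad = 0;

  std::vector<LayerCache> cache(nc);
  std::vector<fmat> gWc(nc), gWf(nfc);
  std::vector<fvec> gbc(nc), gbf(nfc);
  std::vector<int> in_px(nc + 1);
  in_px[0] = s.input_px;
  for (int i = 0; i < nc; ++i) {
    int o = conv_out(in_px[i], s.conv[i].k, s.conv[i].stride);
    in_px[i + 1] = s.conv[i].pool > 1 ? o / s.conv[i].pool : o;
  }

  for (int epoch = 0; epoch < epochs; ++epoch) {
    std::shuffle(order.begin(), order.end(), rng);
    double tot = 0;
    for (int start = 0; start < n; start += batch_size) {
      int B = std::min(batch_size, n - start);
      for (int i = 0; i < nc; ++i) {
        gWc[i].zeros(size(P.Wc[i])); gbc[i].zeros(P.bc[i].n_elem);
      }
      for (int i = 0; i < nfc; ++i) {
        gWf[i].zeros(size(P.Wf[i])); gbf[i].zeros(P.bf[i].n_elem);
      }
      double loss = 0;
      // per-sample accumulation: for this network's layer shapes the
      // per-sample working set stays cache-resident, which beats a
      // batch-wide im2col whose temporaries spill to memory
      for (int bi = 0; bi < B; ++bi) {
        int idx = order[start + bi];
        fvec flat;
        conv_forward_one(P, s, Xf.colptr(idx), true, rng, cache, flat);
        std::vector<fvec> fc_in(nfc), fc_pre(nfc), fc_mask(nfc);
        std::uniform_real_distribution<double> unif(0.0, 1.0);
        fvec h = flat;
        for (int f = 0; f < nfc; ++f) {
          fc_in[f] = h;
          fvec z = P.Wf[f] * h + P.bf[f];
          fc_pre[f] = z;
          if (f < nfc - 1) {
            for (uword i = 0; i < z.n_elem; ++i)
              if (z(i) < 0) z(i) *= (float)s.alpha;
            if (s.fc_dropout[f] > 0) {
              float keep = 1.0f - (float)s.fc_dropout[f];
              fc_mask[f].set_size(z.n_elem);
              for (uword i = 0; i < z.n_elem; ++i)
                fc_mask[f](i) = unif(rng) < keep ? 1.0f / keep : 0.0f;
              z %= fc_mask[f];
            }
          }
          h = z;
        }
        fvec resid = h - Yf.col(idx);
        loss += dot(resid, resid);
        fvec g = resid * (float)(2.0 / (2.0 * B));
        for (int f = nfc - 1; f >= 0; --f) {
          if (f < nfc - 1) {
            if (s.fc_dropout[f] > 0) g %= fc_mask[f];
            for (uword i = 0; i < g.n_elem; ++i)
              if (fc_pre[f](i) < 0) g(i) *= (float)s.alpha;
          }
          gWf[f] += g * fc_in[f].t();
          gbf[f] += g;
          g = P.Wf[f].t() * g;
        }
        for (int li = nc - 1; li >= 0; --li) {
          const ConvLayer& L = s.conv[li];
          LayerCache& C = cache[li];
          int opx = in_px[li + 1];
          int out = conv_out(in_px[li], L.k, L.stride);
          fmat& ga = C.bga;
          ga.set_size(L.out_ch, opx * opx);
          {
            const float* gp = g.memptr();
            float* gap = ga.memptr();
            int oc = L.out_ch;
            for (int ch = 0; ch < oc; ++ch) {
              const float* sp = gp + (size_t)ch * opx * opx;
              float* dp = gap + ch;
              for (int i = 0; i < opx * opx; ++i) dp[(size_t)i * oc] = sp[i];
            }
          }
          if (L.dropout > 0) ga %= C.drop_mask;
          fmat& gpre = (L.pool > 1) ? C.bgpre : ga;
          if (L.pool > 1) {
            gpre.set_size(L.out_ch, out * out);
            gpre.zeros();
            for (uword pc = 0; pc < (uword)(opx * opx); ++pc)
              for (int ch = 0; ch < L.out_ch; ++ch)
                gpre(ch, C.pool_idx(ch, pc)) += ga(ch, pc);
          }
          leaky_bwd_inplace(C.pre, gpre, s.alpha);
          gWc[li] += gpre * C.cols.t();
          gbc[li] += sum(gpre, 1);
          if (li > 0) {
            int ipx = in_px[li];
            C.bgcols = P.Wc[li].t() * gpre;
            g.set_size((uword)ipx * ipx * L.in_ch);
            g.zeros();
            col2im_add(C.bgcols, ipx, L.in_ch, L.k, L.stride, g.memptr());
          }
        }
      }
      tot += loss / 2.0;  // sum over samples of mean-unit squared error
      A.t += 1;
      float c1 = 1.f - std::pow(b1, (float)A.t);
      float c2 = 1.f - std::pow(b2, (float)A.t);
      for (int i = 0; i < nc; ++i) {
        adam_step_mat(P.Wc[i], gWc[i], A.mWc[i], A.vWc[i], (float)lr, b1, b2, c1, c2, eps);
        adam_step_vec(P.bc[i], gbc[i], A.mbc[i], A.vbc[i], (float)lr, b1, b2, c1, c2, eps);
      }
      for (int i = 0; i < nfc; ++i) {
        adam_step_mat(P.Wf[i], gWf[i], A.mWf[i], A.vWf[i], (float)lr, b1, b2, c1, c2, eps);
        adam_step_vec(P.bf[i], gbf[i], A.mbf[i], A.vbf[i], (float)lr, b1, b2, c1, c2, eps);
      }
      Rcpp::checkUserInterrupt();
    }
    double train_loss = tot / n;
    hist_train.push_back(train_loss);
    double val_loss = NA_REAL;
    if (has_val) {
      mat pv = predict_all(P, s, Xv);
      mat dv = pv - conv_to<mat>::from(Yv);
      val_loss = accu(dv % dv) / (2.0 * Xv.n_cols);
      if (val_loss < best_val) {
        best_val = val_loss; best = P; bad = 0;
      } else {
        ++bad;
      }
    }
    hist_val.push_back(val_loss);
    if (verbose)
      Rcpp::Rcout << "epoch " << (epoch + 1) << "  train " << train_loss
                  << "  val " << val_loss << std::endl;
    if (has_val && patience > 0 && bad >= patience) break;
  }

  const Params& final_p = (has_val && best_val < datum::inf) ? best : P;
  return Rcpp::List::create(
      Rcpp::Named("params") = params_to_r(final_p),
      Rcpp::Named("train_loss") = hist_train,
      Rcpp::Named("val_loss") = hist_val,
      Rcpp::Named("best_val") = best_val);
}
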