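// Hand-written CNN core: VGG-16 encoder / U-Net decoder with four task heads,
// float32 storage, im2col + BLAS GEMM convolutions. No framework dependency:
// analytic backward passes are implemented per layer, and per-task Adam
// moment slots realize the independent-optimizer update rule.
#include <RcppArmadillo.h>
#include <map>
#include <set>
#include <string>
#include <vector>
// [[Rcpp::depends(RcppArmadillo)]]

using arma::fmat;
using arma::fvec;
using arma::umat;

static const float PROB_EPS = 1e-7f;

// ---------------------------------------------------------------------------
// Tensor layout: feature maps are fmat (channels x B*h*w); pixel column index
// is b*h*w + r*w + c (row-major pixels, image-major batch).
// ---------------------------------------------------------------------------

// 3x3, pad 1 im2col into a caller-owned buffer K (C*9 x B*h*w); offset
// o = (dy+1)*3 + (dx+1) occupies rows [o*C, (o+1)*C). Border cells that fall
// outside the image are zero; they are zeroed once when the buffer is
// (re)allocated and never written afterwards, so the buffer can be reused
// across iterations at a fixed batch size.
static void im2col3(const fmat& X, int B, int h, int w, fmat& K) {
  const int C = X.n_rows;
  const int hw = h * w;
  if (K.n_rows != (size_t)C * 9 || K.n_cols != (size_t)B * hw)
    K.zeros(C * 9, (size_t)B * hw);
  for (int o = 0; o < 9; ++o) {
    const int dy = o / 3 - 1, dx = o % 3 - 1;
    const int c0 = std::max(0, -dx), c1 = std::min(w, w - dx);  // dest cols
    if (c1 <= c0) continue;
    for (int b = 0; b < B; ++b) {
      for (int r = 0; r < h; ++r) {
        const int rs = r + dy;
        if (rs < 0 || rs >= h) continue;
        const size_t dst0 = (size_t)b * hw + (size_t)r * w + c0;
        const size_t src0 = (size_t)b * hw + (size_t)rs * w + c0 + dx;
        for (int cc = 0; cc < c1 - c0; ++cc) {
          std::memcpy(K.colptr(dst0 + cc) + (size_t)o * C,
                      X.colptr(src0 + cc), sizeof(float) * C);
        }
      }
    }
  }
}

// Transpose of im2col3: scatter-add column gradients back to input layout.
static void col2im3_add(const fmat& Kd, fmat& dX, int B, int h, int w) {
  const int C = dX.n_rows;
  const int hw = h * w;
  for (int o = 0; o < 9; ++o) {
    const int dy = o / 3 - 1, dx = o % 3 - 1;
    const int c0 = std::max(0, -dx), c1 = std::min(w, w - dx);
    if (c1 <= c0) continue;
    for (int b = 0; b < B; ++b) {
      for (int r = 0; r < h; ++r) {
        const int rs = r + dy;
        if (rs < 0 || rs >= h) continue;
        const size_t dst0 = (size_t)b * hw + (size_t)r * w + c0;
        const size_t src0 = (size_t)b * hw + (size_t)rs * w + c0 + dx;
        for (int cc = 0; cc < c1 - c0; ++cc) {
          float* xp = dX.colptr(src0 + cc);
          const float* kp = Kd.colptr(dst0 + cc) + (size_t)o * C;
          for (int ch = 0; ch < C; ++ch) xp[ch] += kp[ch];
        }
      }
    }
  }
}

struct Layer {
  std::string name;
  int k = 3;           // kernel: 3 (conv3), 1 (conv1x1), 0 (fully connected)
  int cin = 0, cout = 0;
  fmat W;              // conv: (cout x cin*k*k); fc: (nout x nin)
  fvec b;
  fmat dW;
  fvec db;
  fmat colbuf;         // persistent im2col buffer, filled by the forward
                       // pass and reused by the immediately following
                       // backward pass of the same mini-batch
  size_t n_par() const { return W.n_elem + b.n_elem; }
};

enum Group { G_ENC = 0, G_DEC, G_HOD, G_HOC, G_HFOV, G_CLS };

struct AdamState {
  int t = 0;
  std::vector<fmat> mW, vW;
  std::vector<fvec> mb, vb;
  std::vector<int> layer_ids;
  bool init = false;
};

struct MtlNet {
  int S = 64;                       // input size (square)
  std::vector<std::vector<int>> enc_widths;
  std::vector<int> dec_widths;
  int cls_hidden = 256;
  bool has_od = false, has_oc = false, has_fovea = false, has_gl = false;
  bool has_decoder = false;

  std::vector<Layer> layers;        // all parameterized layers in fixed order
  std::vector<Group> group_of;      // parallel to layers
  // layer id lookup
  std::vector<int> enc_ids;         // 13 encoder convs
  std::vector<int> enc_block_of;    // block index (0..4) per encoder conv
  std::vector<int> dec_ids;         // 4 decoder convs
  int id_head_od = -1, id_head_oc = -1, id_head_fov = -1;
  int id_fc1 = -1, id_fc2 = -1;

  std::map<std::string, AdamState> slots;

  // ---- forward caches ----
  int B = 0;
  std::vector<fmat> enc_out;        // post-ReLU output of each encoder conv
  std::vector<fmat> skip;           // pre-pool activation of blocks 1..4
  std::vector<umat> pool_idx;       // argmax source column per (ch, out px)
  fmat bottleneck;                  // block-5 output (512 x B*(S/16)^2)
  std::vector<fmat> dec_out;        // post-ReLU decoder outputs
  fmat gap_out;                     // (512 x B)
  fmat fc1_out;                     // post-ReLU (hidden x B)
  fmat z_od, z_oc, z_fov;           // head pre-activations (1 x B*S*S)
  fvec z_cls;                       // pre-sigmoid logits (B)
  std::set<std::string> fwd_tasks;

  int add_layer(const std::string& nm, int k, int cin, int cout, Group g) {
    Layer L;
    L.name = nm; L.k = k; L.cin = cin; L.cout = cout;
    int wcols = (k == 0) ? cin : cin * k * k;
    L.W.zeros(cout, wcols);
    L.b.zeros(cout);
    L.dW.zeros(cout, wcols);
    L.db.zeros(cout);
    layers.push_back(std::move(L));
    group_of.push_back(g);
    return (int)layers.size() - 1;
  }

  bool task_active(const std::string& t) const {
    if (t == "od") return has_od;
    if (t == "oc") return has_oc;
    if (t == "fovea") return has_fovea;
    if (t == "glaucoma") return has_gl;
    return false;
  }

  std::set<int> touched_layers(const std::vector<std::string>& tasks) const {
    std::set<Group> gs;
    for (const auto& t : tasks) {
      gs.insert(G_ENC);
      if (t == "od") { gs.insert(G_DEC); gs.insert(G_HOD); }
      else if (t == "oc") { gs.insert(G_DEC); gs.insert(G_HOC); }
      else if (t == "fovea") { gs.insert(G_DEC); gs.insert(G_HFOV); }
      else if (t == "glaucoma") gs.insert(G_CLS);
    }
    std::set<int> ids;
    for (size_t i = 0; i < layers.size(); ++i)
      if (gs.count(group_of[i])) ids.insert((int)i);
    return ids;
  }
};

static MtlNet* get_net(SEXP ptr) {
  Rcpp::XPtr<MtlNet> p(ptr);
  return p.get();
}

// [[Rcpp::export(name = ".net_create")]]
SEXP net_create(int input_size, Rcpp::List encoder_widths,
                Rcpp::IntegerVector decoder_widths, int classifier_hidden,
                Rcpp::CharacterVector tasks) {
  MtlNet* net = new MtlNet();
  net->S = input_size;
  for (int b = 0; b < encoder_widths.size(); ++b) {
    Rcpp::IntegerVector wv = encoder_widths[b];
    net->enc_widths.push_back(std::vector<int>(wv.begin(), wv.end()));
  }
  net->dec_widths.assign(decoder_widths.begin(), decoder_widths.end());
  net->cls_hidden = classifier_hidden;
  for (int i = 0; i < tasks.size(); ++i) {
    std::string t = Rcpp::as<std::string>(tasks[i]);
    if (t == "od") net->has_od = true;
    else if (t == "oc") net->has_oc = true;
    else if (t == "fovea") net->has_fovea = true;
    else if (t == "glaucoma") net->has_gl = true;
    else Rcpp::stop("unknown task: " + t);
  }
  net->has_decoder = net->has_od || net->has_oc || net->has_fovea;

  // encoder
  int cin = 3;
  for (size_t b = 0; b < net->enc_widths.size(); ++b) {
    for (size_t i = 0; i < net->enc_widths[b].size(); ++i) {
      int cout = net->enc_widths[b][i];
      char nm[32];
      snprintf(nm, sizeof(nm), "conv%d_%d", (int)b + 1, (int)i + 1);
      int id = net->add_layer(nm, 3, cin, cout, G_ENC);
      net->enc_ids.push_back(id);
      net->enc_block_of.push_back((int)b);
      cin = cout;
    }
  }
  const int bott_c = net->enc_widths.back().back();
  // decoder: upsampled previous stage + skip from encoder blocks 4,3,2,1
  if (net->has_decoder) {
    int prev = bott_c;
    for (int s = 0; s < 4; ++s) {
      int skip_c = net->enc_widths[3 - s].back();
      int id = net->add_layer("dec" + std::to_string(s + 1), 3,
                              prev + skip_c, net->dec_widths[s], G_DEC);
      net->dec_ids.push_back(id);
      prev = net->dec_widths[s];
    }
    int last = net->dec_widths[3];
    if (net->has_od) net->id_head_od = net->add_layer("head_od", 1, last, 1, G_HOD);
    if (net->has_oc) net->id_head_oc = net->add_layer("head_oc", 1, last, 1, G_HOC);
    if (net->has_fovea)
      net->id_head_fov = net->add_layer("head_fovea", 1, last, 1, G_HFOV);
  }
  if (net->has_gl) {
    net->id_fc1 = net->add_layer("fc1", 0, bott_c, net->cls_hidden, G_CLS);
    net->id_fc2 = net->add_layer("fc2", 0, net->cls_hidden, 1, G_CLS);
  }
  Rcpp::XPtr<MtlNet> ptr(net, true);
  return ptr;
}

// [[Rcpp::export(name = ".net_count_params")]]
double net_count_params(SEXP ptr) {
  MtlNet* net = get_net(ptr);
  double n = 0;
  for (const auto& L : net->layers) n += (double)L.n_par();
  return n;
}

// [[Rcpp::export(name = ".net_param_shapes")]]
Rcpp::List net_param_shapes(SEXP ptr) {
  MtlNet* net = get_net(ptr);
  Rcpp::List out;
  for (const auto& L : net->layers) {
    out[L.name] = Rcpp::IntegerVector::create(L.cout, (int)L.W.n_cols, L.k);
  }
  return out;
}

// Parameters are exchanged with R as a flat named list "<layer>.weight"
// (matrix cout x cin*k*k, im2col column order) / "<layer>.bias".
// [[Rcpp::export(name = ".net_get_params")]]
Rcpp::List net_get_params(SEXP ptr) {
  MtlNet* net = get_net(ptr);
  Rcpp::List out;
  for (const auto& L : net->layers) {
    arma::mat Wd = arma::conv_to<arma::mat>::from(L.W);
    arma::vec bd = arma::conv_to<arma::vec>::from(L.b);
    out[L.name + ".weight"] = Rcpp::wrap(Wd);
    out[L.name + ".bias"] = Rcpp::wrap(bd);
  }
  return out;
}

// [[Rcpp::export(name = ".net_set_params")]]
void net_set_params(SEXP ptr, Rcpp::List params) {
  MtlNet* net = get_net(ptr);
  for (auto& L : net->layers) {
    std::string wn = L.name + ".weight", bn = L.name + ".bias";
    if (!params.containsElementNamed(wn.c_str()))
      Rcpp::stop("missing parameter: " + wn);
    arma::mat Wd = Rcpp::as<arma::mat>(params[wn]);
    arma::vec bd = Rcpp::as<arma::vec>(params[bn]);
    if (Wd.n_rows != L.W.n_rows || Wd.n_cols != L.W.n_cols)
      Rcpp::stop("shape mismatch for " + wn);
    if (bd.n_elem != L.b.n_elem) Rcpp::stop("shape mismatch for " + bn);
    L.W = arma::conv_to<fmat>::from(Wd);
    L.b = arma::conv_to<fvec>::from(bd);
  }
}

// [[Rcpp::export(name = ".net_get_grads")]]
Rcpp::List net_get_grads(SEXP ptr) {
  MtlNet* net = get_net(ptr);
  Rcpp::List out;
  for (const auto& L : net->layers) {
    out[L.name + ".weight"] =
        Rcpp::wrap(arma::conv_to<arma::mat>::from(L.dW));
    out[L.name + ".bias"] = Rcpp::wrap(arma::conv_to<arma::vec>::from(L.db));
  }
  return out;
}

// ---- layer primitives --------------------------------------------------

static fmat conv3_fwd(Layer& L, const fmat& X, int B, int h, int w,
                      bool relu) {
  im2col3(X, B, h, w, L.colbuf);
  fmat Y = L.W * L.colbuf;
  Y.each_col() += L.b;
  if (relu) Y.transform([](float v) { return v > 0.f ? v : 0.f; });
  return Y;
}

// dY is the gradient at the (post-ReLU, if relu) output; Yout is the cached
// post-activation output used for the ReLU mask. Relies on L.colbuf still
// holding the im2col expansion of this layer's input from the forward pass
// of the same mini-batch (the training loop always pairs forward/backward).
static fmat conv3_bwd(Layer& L, const fmat& Yout, fmat dY, int B, int h,
                      int w, bool relu, bool need_dx = true) {
  if (relu) {
    const float* yp = Yout.memptr();
    float* gp = dY.memptr();
    const size_t n = dY.n_elem;
    for (size_t i = 0; i < n; ++i)
      if (yp[i] <= 0.f) gp[i] = 0.f;
  }
  L.dW += dY * L.colbuf.t();
  L.db += arma::sum(dY, 1);
  if (!need_dx) return fmat();
  fmat dK = L.W.t() * dY;
  fmat dX(L.cin, (size_t)B * h * w, arma::fill::zeros);
  col2im3_add(dK, dX, B, h, w);
  return dX;
}

static void pool2_fwd(const fmat& X, int B, int h, int w, fmat& Y, umat& idx) {
  const int C = X.n_rows, h2 = h / 2, w2 = w / 2;
  Y.set_size(C, (size_t)B * h2 * w2);
  idx.set_size(C, (size_t)B * h2 * w2);
  for (int b = 0; b < B; ++b) {
    for (int r2 = 0; r2 < h2; ++r2) {
      for (int c2 = 0; c2 < w2; ++c2) {
        const size_t jo = (size_t)b * h2 * w2 + (size_t)r2 * w2 + c2;
        size_t cand[4];
        cand[0] = (size_t)b * h * w + (size_t)(2 * r2) * w + 2 * c2;
        cand[1] = cand[0] + 1;
        cand[2] = cand[0] + w;
        cand[3] = cand[2] + 1;
        const float* p0 = X.colptr(cand[0]);
        const float* p1 = X.colptr(cand[1]);
        const float* p2 = X.colptr(cand[2]);
        const float* p3 = X.colptr(cand[3]);
        float* yp = Y.colptr(jo);
        arma::uword* ip = idx.colptr(jo);
        for (int ch = 0; ch < C; ++ch) {
          float best = p0[ch]; size_t bi = cand[0];
          if (p1[ch] > best) { best = p1[ch]; bi = cand[1]; }
          if (p2[ch] > best) { best = p2[ch]; bi = cand[2]; }
          if (p3[ch] > best) { best = p3[ch]; bi = cand[3]; }
          yp[ch] = best; ip[ch] = bi;
        }
      }
    }
  }
}

static fmat pool2_bwd(const fmat& dY, const umat& idx, int B, int h, int w,
                      int C) {
  fmat dX(C, (size_t)B * h * w, arma::fill::zeros);
  for (size_t j = 0; j < dY.n_cols; ++j) {
    const float* gp = dY.colptr(j);
    const arma::uword* ip = idx.colptr(j);
    for (int ch = 0; ch < C; ++ch) dX(ch, ip[ch]) += gp[ch];
  }
  return dX;
}

struct BilinTaps { std::vector<int> i0, i1; std::vector<float> w1; };

// scale-2 bilinear (half-pixel-center convention): src = (i + 0.5)/2 - 0.5
static BilinTaps bilin_taps(int n_out, int n_in) {
  BilinTaps t;
  t.i0.resize(n_out); t.i1.resize(n_out); t.w1.resize(n_out);
  for (int i = 0; i < n_out; ++i) {
    double f = 0.5 * i - 0.25;
    int i0 = (int)std::floor(f);
    double w1 = f - i0;
    if (i0 < 0) { i0 = 0; w1 = 0.0; }
    int i1 = std::min(i0 + 1, n_in - 1);
    t.i0[i] = i0; t.i1[i] = i1; t.w1[i] = (float)w1;
  }
  return t;
}

static fmat up2_fwd(const fmat& X, int B, int h, int w) {
  const int C = X.n_rows, H = 2 * h, W = 2 * w;
  BilinTaps ty = bilin_taps(H, h), tx = bilin_taps(W, w);
  fmat Y(C, (size_t)B * H * W, arma::fill::zeros);
  for (int b = 0; b < B; ++b) {
    const size_t ob = (size_t)b * H * W, ib = (size_t)b * h * w;
    for (int r = 0; r < H; ++r) {
      for (int c = 0; c < W; ++c) {
        float* yp = Y.colptr(ob + (size_t)r * W + c);
        const float wys[2] = {1.f - ty.w1[r], ty.w1[r]};
        const int ys[2] = {ty.i0[r], ty.i1[r]};
        const float wxs[2] = {1.f - tx.w1[c], tx.w1[c]};
        const int xs[2] = {tx.i0[c], tx.i1[c]};
        for (int a = 0; a < 2; ++a) {
          for (int d = 0; d < 2; ++d) {
            const float wt = wys[a] * wxs[d];
            if (wt == 0.f) continue;
            const float* xp = X.colptr(ib + (size_t)ys[a] * w + xs[d]);
            for (int ch = 0; ch < C; ++ch) yp[ch] += wt * xp[ch];
          }
        }
      }
    }
  }
  return Y;
}

static fmat up2_bwd(const fmat& dY, int B, int h, int w) {
  const int C = dY.n_rows, H = 2 * h, W = 2 * w;
  BilinTaps ty = bilin_taps(H, h), tx = bilin_taps(W, w);
  fmat dX(C, (size_t)B * h * w, arma::fill::zeros);
  for (int b = 0; b < B; ++b) {
    const size_t ob = (size_t)b * H * W, ib = (size_t)b * h * w;
    for (int r = 0; r < H; ++r) {
      for (int c = 0; c < W; ++c) {
        const float* gp = dY.colptr(ob + (size_t)r * W + c);
        const float wys[2] = {1.f - ty.w1[r], ty.w1[r]};
        const int ys[2] = {ty.i0[r], ty.i1[r]};
        const float wxs[2] = {1.f - tx.w1[c], tx.w1[c]};
        const int xs[2] = {tx.i0[c], tx.i1[c]};
        for (int a = 0; a < 2; ++a) {
          for (int d = 0; d < 2; ++d) {
            const float wt = wys[a] * wxs[d];
            if (wt == 0.f) continue;
            float* xp = dX.colptr(ib + (size_t)ys[a] * w + xs[d]);
            for (int ch = 0; ch < C; ++ch) xp[ch] += wt * gp[ch];
          }
        }
      }
    }
  }
  return dX;
}

// ---- whole-network forward --------------------------------------------

// images: numeric array (S, S, 3, B) in [0,1]
// [[Rcpp::export(name = ".net_forward")]]
Rcpp::List net_forward(SEXP ptr, Rcpp::NumericVector images,
                       Rcpp::CharacterVector tasks) {
  MtlNet* net = get_net(ptr);
  const int S = net->S;
  Rcpp::IntegerVector dm = images.attr("dim");
  if (dm.size() != 4 || dm[0] != S || dm[1] != S || dm[2] != 3)
    Rcpp::stop("images must be an array (input_size, input_size, 3, B)");
  const int B = dm[3];
  net->B = B;
  net->fwd_tasks.clear();
  bool want_dec = false, want_cls = false;
  for (int i = 0; i < tasks.size(); ++i) {
    std::string t = Rcpp::as<std::string>(tasks[i]);
    if (!net->task_active(t)) Rcpp::stop("task not in model: " + t);
    net->fwd_tasks.insert(t);
    if (t == "glaucoma") want_cls = true; else want_dec = true;
  }

  // pack input to (3 x B*S*S)
  fmat X(3, (size_t)B * S * S);
  const double* src = images.begin();
  for (int b = 0; b < B; ++b)
    for (int ch = 0; ch < 3; ++ch)
      for (int c = 0; c < S; ++c)
        for (int r = 0; r < S; ++r)
          X(ch, (size_t)b * S * S + (size_t)r * S + c) =
              (float)src[r + (size_t)S * (c + (size_t)S * (ch + 3 * b))];

  const int n_enc = (int)net->enc_ids.size();
  net->enc_out.assign(n_enc, fmat());
  net->skip.assign(4, fmat());
  net->pool_idx.assign(4, umat());

  int h = S, w = S;
  fmat cur = std::move(X);
  int li = 0;
  for (int blk = 0; blk < 5; ++blk) {
    const int nconv = (int)net->enc_widths[blk].size();
    for (int i = 0; i < nconv; ++i, ++li) {
      Layer& L = net->layers[net->enc_ids[li]];
      cur = conv3_fwd(L, cur, B, h, w, true);
      net->enc_out[li] = cur;
    }
    if (blk < 4) {
      net->skip[blk] = cur;  // pre-pool activation feeding the skip path
      fmat pooled; umat idx;
      pool2_fwd(cur, B, h, w, pooled, idx);
      net->pool_idx[blk] = idx;
      cur = std::move(pooled);
      h /= 2; w /= 2;
    }
  }
  net->bottleneck = cur;  // at S/16

  Rcpp::List out;
  if (want_dec) {
    net->dec_out.assign(4, fmat());
    fmat d = net->bottleneck;
    int dh = S / 16, dw = S / 16;
    for (int s = 0; s < 4; ++s) {
      fmat up = up2_fwd(d, B, dh, dw);
      dh *= 2; dw *= 2;
      fmat cat = arma::join_cols(up, net->skip[3 - s]);
      Layer& L = net->layers[net->dec_ids[s]];
      d = conv3_fwd(L, cat, B, dh, dw, true);
      net->dec_out[s] = d;
    }
    const fmat& feat = net->dec_out[3];
    auto head_fwd = [&](int id) {
      const Layer& L = net->layers[id];
      fmat z = L.W * feat;
      z.each_col() += L.b;
      return z;
    };
    auto map_out = [&](const fmat& z, bool sigmoid) {
      Rcpp::NumericVector arr((size_t)S * S * B);
      arr.attr("dim") = Rcpp::IntegerVector::create(S, S, B);
      double* dst = arr.begin();
      for (int b = 0; b < B; ++b)
        for (int r = 0; r < S; ++r)
          for (int c = 0; c < S; ++c) {
            float v = z(0, (size_t)b * S * S + (size_t)r * S + c);
            if (sigmoid) v = 1.f / (1.f + std::exp(-v));
            dst[r + (size_t)S * c + (size_t)S * S * b] = v;
          }
      return arr;
    };
    if (net->fwd_tasks.count("od")) {
      net->z_od = head_fwd(net->id_head_od);
      out["od"] = map_out(net->z_od, true);
    }
    if (net->fwd_tasks.count("oc")) {
      net->z_oc = head_fwd(net->id_head_oc);
      out["oc"] = map_out(net->z_oc, true);
    }
    if (net->fwd_tasks.count("fovea")) {
      net->z_fov = head_fwd(net->id_head_fov);
      out["fovea"] = map_out(net->z_fov, false);
    }
  }
  if (want_cls) {
    const int hw16 = (S / 16) * (S / 16);
    net->gap_out.set_size(net->bottleneck.n_rows, B);
    for (int b = 0; b < B; ++b)
      net->gap_out.col(b) = arma::mean(
          net->bottleneck.cols((size_t)b * hw16, (size_t)(b + 1) * hw16 - 1), 1);
    const Layer& F1 = net->layers[net->id_fc1];
    net->fc1_out = F1.W * net->gap_out;
    net->fc1_out.each_col() += F1.b;
    net->fc1_out.transform([](float v) { return v > 0.f ? v : 0.f; });
    const Layer& F2 = net->layers[net->id_fc2];
    fmat z2 = F2.W * net->fc1_out;
    z2.each_col() += F2.b;
    net->z_cls = z2.row(0).t();
    Rcpp::NumericVector pr(B);
    for (int b = 0; b < B; ++b)
      pr[b] = 1.0 / (1.0 + std::exp(-(double)net->z_cls(b)));
    out["glaucoma"] = pr;
  }
  return out;
}

// ---- losses + whole-network backward ----------------------------------

// targets: list keyed by task; od/oc/fovea: array (S,S,B); glaucoma: numeric B
// Returns named per-task loss values. Gradients are accumulated into the
// layer dW/db buffers (zeroed first unless accumulate).
// [[Rcpp::export(name = ".net_backward")]]
Rcpp::NumericVector net_backward(SEXP ptr, Rcpp::CharacterVector tasks,
                                 Rcpp::List targets,
                                 Rcpp::NumericVector loss_weights,
                                 double gamma, bool accumulate) {
  MtlNet* net = get_net(ptr);
  const int S = net->S, B = net->B;
  const size_t N = (size_t)B * S * S;
  if (B == 0) Rcpp::stop("no forward pass cached");

  std::vector<std::string> tvec;
  for (int i = 0; i < tasks.size(); ++i) {
    std::string t = Rcpp::as<std::string>(tasks[i]);
    if (!net->fwd_tasks.count(t))
      Rcpp::stop("backward task '" + t + "' was not part of the last forward");
    tvec.push_back(t);
  }
  std::map<std::string, double> cw;
  Rcpp::CharacterVector lwn = loss_weights.names();
  for (int i = 0; i < loss_weights.size(); ++i)
    cw[Rcpp::as<std::string>(lwn[i])] = loss_weights[i];

  if (!accumulate)
    for (auto& L : net->layers) { L.dW.zeros(); L.db.zeros(); }

  std::vector<std::string> loss_names;
  std::vector<double> loss_vals;
  auto push_loss = [&](const std::string& nm, double v) {
    loss_names.push_back(nm);
    loss_vals.push_back(v);
  };

  auto unpack_map = [&](Rcpp::NumericVector arr) {
    fmat Y(1, N);
    const double* p = arr.begin();
    for (int b = 0; b < B; ++b)
      for (int c = 0; c < S; ++c)
        for (int r = 0; r < S; ++r)
          Y(0, (size_t)b * S * S + (size_t)r * S + c) =
              (float)p[r + (size_t)S * c + (size_t)S * S * b];
    return Y;
  };

  bool any_dec = false;
  fmat dFeat;  // gradient at dec_out[3]
  const fmat* feat = net->has_decoder ? &net->dec_out[3] : nullptr;

  auto head_bwd = [&](int id, const fmat& dz) {
    Layer& L = net->layers[id];
    L.dW += dz * feat->t();
    L.db += arma::sum(dz, 1);
    if (!any_dec) {
      dFeat = L.W.t() * dz;
      any_dec = true;
    } else {
      dFeat += L.W.t() * dz;
    }
  };

  bool any_cls = false;
  fvec dz_cls;

  for (const auto& t : tvec) {
    const double c = cw.count(t) ? cw[t] : 1.0;
    if (t == "od" || t == "oc") {
      fmat Y = unpack_map(targets[t]);
      const fmat& z = (t == "od") ? net->z_od : net->z_oc;
      fmat P = 1.0f / (1.0f + arma::exp(-z));
      // mean-over-pixels BCE, averaged over the batch
      double loss = 0;
      const float* pp = P.memptr(); const float* yy = Y.memptr();
      for (size_t i = 0; i < N; ++i) {
        float p = std::min(std::max(pp[i], PROB_EPS), 1.f - PROB_EPS);
        loss -= yy[i] * std::log((double)p) +
                (1. - yy[i]) * std::log(1. - (double)p);
      }
      loss /= (double)N;
      fmat dz = (P - Y) * (float)(c / (double)N);
      head_bwd((t == "od") ? net->id_head_od : net->id_head_oc, dz);
      push_loss(t, c * loss);
    } else if (t == "fovea") {
      fmat Y = unpack_map(targets[t]);
      // per-image L1 SUM, averaged over the batch
      double loss = arma::accu(arma::conv_to<arma::mat>::from(
                        arma::abs(net->z_fov - Y))) / (double)B;
      fmat dz = arma::sign(net->z_fov - Y) * (float)(c / (double)B);
      head_bwd(net->id_head_fov, dz);
      push_loss(t, c * loss);
    } else if (t == "glaucoma") {
      Rcpp::NumericVector yv = targets[t];
      if (yv.size() != B) Rcpp::stop("glaucoma targets must have length B");
      dz_cls.zeros(B);
      double loss = 0;
      const double g = gamma;
      for (int b = 0; b < B; ++b) {
        double p = 1.0 / (1.0 + std::exp(-(double)net->z_cls(b)));
        double y = yv[b];
        double pt = (y >= 0.5) ? p : 1.0 - p;
        pt = std::min(std::max(pt, (double)PROB_EPS), 1.0 - (double)PROB_EPS);
        loss += -std::pow(1.0 - pt, g) * std::log(pt);
        double dLdpt = g * std::pow(1.0 - pt, g - 1.0) * std::log(pt) -
                       std::pow(1.0 - pt, g) / pt;
        double s = p * (1.0 - p);
        double dptdz = (y >= 0.5) ? s : -s;
        dz_cls(b) += (float)(c * dLdpt * dptdz / (double)B);
      }
      loss /= (double)B;
      push_loss(t, c * loss);
      any_cls = true;
    }
  }

  // decoder backward
  fmat dBott(net->bottleneck.n_rows, net->bottleneck.n_cols,
             arma::fill::zeros);
  std::vector<fmat> dSkip(4);
  if (any_dec) {
    fmat d = dFeat;
    int dh = S, dw = S;
    for (int s = 3; s >= 0; --s) {
      Layer& L = net->layers[net->dec_ids[s]];
      fmat dcat = conv3_bwd(L, net->dec_out[s], d, B, dh, dw, true);
      const int up_c = (s == 0) ? (int)net->bottleneck.n_rows
                                : net->dec_widths[s - 1];
      fmat dup = dcat.rows(0, up_c - 1);
      fmat dsk = dcat.rows(up_c, dcat.n_rows - 1);
      if (dSkip[3 - s].n_elem == 0) dSkip[3 - s] = dsk; else dSkip[3 - s] += dsk;
      dh /= 2; dw /= 2;
      d = up2_bwd(dup, B, dh, dw);
      if (s == 0) dBott += d;
    }
  }
  // classifier backward
  if (any_cls) {
    Layer& F2 = net->layers[net->id_fc2];
    fmat dz2(1, B);
    for (int b = 0; b < B; ++b) dz2(0, b) = dz_cls(b);
    F2.dW += dz2 * net->fc1_out.t();
    F2.db += arma::sum(dz2, 1);
    fmat dh1 = F2.W.t() * dz2;
    dh1 %= arma::conv_to<fmat>::from(net->fc1_out > 0.f);
    Layer& F1 = net->layers[net->id_fc1];
    F1.dW += dh1 * net->gap_out.t();
    F1.db += arma::sum(dh1, 1);
    fmat dgap = F1.W.t() * dh1;
    const int hw16 = (S / 16) * (S / 16);
    for (int b = 0; b < B; ++b) {
      fvec gcol = dgap.col(b) / (float)hw16;
      for (int j = 0; j < hw16; ++j) dBott.col((size_t)b * hw16 + j) += gcol;
    }
  }

  // encoder backward
  if (any_dec || any_cls) {
    fmat d = dBott;
    int h = S / 16, w = S / 16;
    int li = (int)net->enc_ids.size() - 1;
    for (int blk = 4; blk >= 0; --blk) {
      if (blk < 4) {
        h *= 2; w *= 2;
        d = pool2_bwd(d, net->pool_idx[blk], B, h, w,
                      net->layers[net->enc_ids[li]].cout);
        if (dSkip[blk].n_elem > 0) d += dSkip[blk];
      }
      const int nconv = (int)net->enc_widths[blk].size();
      for (int i = nconv - 1; i >= 0; --i, --li) {
        Layer& L = net->layers[net->enc_ids[li]];
        d = conv3_bwd(L, net->enc_out[li], d, B, h, w, true, li > 0);
      }
    }
  }
  Rcpp::NumericVector losses(loss_vals.begin(), loss_vals.end());
  losses.names() = Rcpp::CharacterVector(loss_names.begin(), loss_names.end());
  return losses;
}

// ---- updates -----------------------------------------------------------

// [[Rcpp::export(name = ".net_apply_sgd")]]
void net_apply_sgd(SEXP ptr, Rcpp::CharacterVector tasks, double lr) {
  MtlNet* net = get_net(ptr);
  std::vector<std::string> tv;
  for (int i = 0; i < tasks.size(); ++i)
    tv.push_back(Rcpp::as<std::string>(tasks[i]));
  std::set<int> ids = net->touched_layers(tv);
  const float e = (float)lr;
  for (int id : ids) {
    Layer& L = net->layers[id];
    L.W -= e * L.dW;
    L.b -= e * L.db;
  }
}

// One Adam step on the moment slot `slot` over the layers touched by `tasks`.
// Slot isolation is what turns plain alternation into MTL-IO: each task name
// is its own slot, so its moving averages never see another task's gradients.
// [[Rcpp::export(name = ".net_apply_adam")]]
void net_apply_adam(SEXP ptr, std::string slot, Rcpp::CharacterVector tasks,
                    double lr, double beta1, double beta2, double eps) {
  MtlNet* net = get_net(ptr);
  std::vector<std::string> tv;
  for (int i = 0; i < tasks.size(); ++i)
    tv.push_back(Rcpp::as<std::string>(tasks[i]));
  std::set<int> ids = net->touched_layers(tv);
  AdamState& st = net->slots[slot];
  if (!st.init) {
    st.layer_ids.assign(ids.begin(), ids.end());
    st.mW.resize(st.layer_ids.size());
    st.vW.resize(st.layer_ids.size());
    st.mb.resize(st.layer_ids.size());
    st.vb.resize(st.layer_ids.size());
    for (size_t i = 0; i < st.layer_ids.size(); ++i) {
      const Layer& L = net->layers[st.layer_ids[i]];
      st.mW[i].zeros(L.W.n_rows, L.W.n_cols);
      st.vW[i].zeros(L.W.n_rows, L.W.n_cols);
      st.mb[i].zeros(L.b.n_elem);
      st.vb[i].zeros(L.b.n_elem);
    }
    st.init = true;
  }
  st.t += 1;
  const float b1 = (float)beta1, b2 = (float)beta2;
  const float bc1 = 1.f - std::pow(b1, (float)st.t);
  const float bc2 = 1.f - std::pow(b2, (float)st.t);
  const float e = (float)lr, ep = (float)eps;
  auto fused = [&](float* wv, float* mv, float* vv, const float* gv,
                   size_t n) {
    for (size_t j = 0; j < n; ++j) {
      const float g = gv[j];
      mv[j] = b1 * mv[j] + (1.f - b1) * g;
      vv[j] = b2 * vv[j] + (1.f - b2) * g * g;
      wv[j] -= e * (mv[j] / bc1) / (std::sqrt(vv[j] / bc2) + ep);
    }
  };
  for (size_t i = 0; i < st.layer_ids.size(); ++i) {
    Layer& L = net->layers[st.layer_ids[i]];
    fused(L.W.memptr(), st.mW[i].memptr(), st.vW[i].memptr(),
          L.dW.memptr(), L.W.n_elem);
    fused(L.b.memptr(), st.mb[i].memptr(), st.vb[i].memptr(),
          L.db.memptr(), L.b.n_elem);
  }
}

// [[Rcpp::export(name = ".net_reset_optimizers")]]
void net_reset_optimizers(SEXP ptr) {
  MtlNet* net = get_net(ptr);
  net->slots.clear();
}

// [[Rcpp::export(name = ".net_optimizer_steps")]]
Rcpp::IntegerVector net_optimizer_steps(SEXP ptr) {
  MtlNet* net = get_net(ptr);
  std::vector<int> ts;
  std::vector<std::string> nm;
  for (const auto& kv : net->slots) {
    nm.push_back(kv.first);
    ts.push_back(kv.second.t);
  }
  Rcpp::IntegerVector out(ts.begin(), ts.end());
  out.names() = Rcpp::CharacterVector(nm.begin(), nm.end());
  return out;
}

// ---------------------------------------------------------------------------
// Small image utilities used by post-processing and IO
// ---------------------------------------------------------------------------

// 8-connected component labeling of a binary matrix (iterative flood fill).
// [[Rcpp::export(name = ".label_components")]]
Rcpp::IntegerMatrix label_components(Rcpp::LogicalMatrix mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  Rcpp::IntegerMatrix lab(nr, nc);
  int next = 0;
  std::vector<std::pair<int, int>> stack;
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      if (!mask(r, c) || lab(r, c) != 0) continue;
      ++next;
      stack.clear();
      stack.push_back({r, c});
      lab(r, c) = next;
      while (!stack.empty()) {
        auto rc = stack.back();
        stack.pop_back();
        for (int dr = -1; dr <= 1; ++dr) {
          for (int dc = -1; dc <= 1; ++dc) {
            if (dr == 0 && dc == 0) continue;
            int rr = rc.first + dr, cc = rc.second + dc;
            if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
            if (mask(rr, cc) && lab(rr, cc) == 0) {
              lab(rr, cc) = next;
              stack.push_back({rr, cc});
            }
          }
        }
      }
    }
  }
  return lab;
}

// Bilinear resize of (H, W) or (H, W, C) double arrays (half-pixel centers).
// [[Rcpp::export(name = ".resize_bilinear")]]
Rcpp::NumericVector resize_bilinear(Rcpp::NumericVector img, int out_h,
                                    int out_w) {
  Rcpp::IntegerVector dm = img.attr("dim");
  int H, W, C;
  if (dm.size() == 2) { H = dm[0]; W = dm[1]; C = 1; }
  else if (dm.size() == 3) { H = dm[0]; W = dm[1]; C = dm[2]; }
  else Rcpp::stop("expected a 2-d or 3-d array");
  Rcpp::NumericVector out((size_t)out_h * out_w * C);
  const double sy = (double)H / out_h, sx = (double)W / out_w;
  const double* src = img.begin();
  double* dst = out.begin();
  for (int ch = 0; ch < C; ++ch) {
    const double* sp = src + (size_t)ch * H * W;
    double* dp = dst + (size_t)ch * out_h * out_w;
    for (int j = 0; j < out_w; ++j) {
      double fx = (j + 0.5) * sx - 0.5;
      int x0 = (int)std::floor(fx);
      double wx = fx - x0;
      if (x0 < 0) { x0 = 0; wx = 0; }
      int x1 = std::min(x0 + 1, W - 1);
      for (int i = 0; i < out_h; ++i) {
        double fy = (i + 0.5) * sy - 0.5;
        int y0 = (int)std::floor(fy);
        double wy = fy - y0;
        if (y0 < 0) { y0 = 0; wy = 0; }
        int y1 = std::min(y0 + 1, H - 1);
        double v = (1 - wy) * ((1 - wx) * sp[y0 + (size_t)H * x0] +
                               wx * sp[y0 + (size_t)H * x1]) +
                   wy * ((1 - wx) * sp[y1 + (size_t)H * x0] +
                         wx * sp[y1 + (size_t)H * x1]);
        dp[i + (size_t)out_h * j] = v;
      }
    }
  }
  if (C == 1) out.attr("dim") = Rcpp::IntegerVector::create(out_h, out_w);
  else out.attr("dim") = Rcpp::IntegerVector::create(out_h, out_w, C);
  return out;
}
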