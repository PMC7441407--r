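// Fully convolutional sleep-staging network.
//
// Layout conventions: activations are arma::mat with rows = time positions
// (patch-major: row p*L + t is position t of patch p) and columns =
// channels.  This keeps the long dimension first so every GEMM is tall,
// which is what single-threaded BLAS handles best.  Convolutions are
// im2col + GEMM; all convolutions use "same" zero padding so sequence
// lengths are preserved exactly.

#include <RcppArmadillo.h>
#include <random>
#if defined(__GLIBC__)
#include <malloc.h>
#endif
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;
using Rcpp::List;
using Rcpp::Named;
using Rcpp::stop;

struct Par {
  mat W;   // value
  mat m;   // Adam first moment
  mat v;   // Adam second moment
  mat g;   // gradient accumulator
  bool l1; // subject to the L1 weight penalty (conv/projection weights)
  std::string name;
  Par() : l1(false) {}
  Par(int r, int c, bool l1_, std::string nm)
      : W(r, c, fill::zeros), m(r, c, fill::zeros), v(r, c, fill::zeros),
        g(r, c, fill::zeros), l1(l1_), name(nm) {}
};

// im2col for a batch of N patches of length L stored patch-major in X
// (L*N x C).  Output is (L*N x C*K); kernel tap k occupies columns
// [k*C, (k+1)*C).  Kernel size K is odd; dilation dil; same zero padding.
static mat im2col(const mat &X, int L, int N, int K, int dil) {
  const int C = X.n_cols;
  mat col(X.n_rows, (uword)C * K);
  for (int k = 0; k < K; ++k) {
    const int off = (k - K / 2) * dil;
    const int t0 = std::max(0, -off), t1 = std::min(L, L - off);
    for (int p = 0; p < N; ++p) {
      const uword r0 = (uword)p * L;
      if (t0 > 0)
        col.submat(r0, k * C, r0 + t0 - 1, (k + 1) * C - 1).zeros();
      if (t1 < L)
        col.submat(r0 + t1, k * C, r0 + L - 1, (k + 1) * C - 1).zeros();
      if (t1 > t0)
        col.submat(r0 + t0, k * C, r0 + t1 - 1, (k + 1) * C - 1) =
            X.rows(r0 + t0 + off, r0 + t1 - 1 + off);
    }
  }
  return col;
}

// Adjoint of im2col: accumulate gradient blocks back onto input positions.
static mat col2im(const mat &dcol, int C, int L, int N, int K, int dil) {
  mat dX(dcol.n_rows, C, fill::zeros);
  for (int k = 0; k < K; ++k) {
    const int off = (k - K / 2) * dil;
    const int t0 = std::max(0, -off), t1 = std::min(L, L - off);
    if (t1 <= t0) continue;
    for (int p = 0; p < N; ++p) {
      const uword r0 = (uword)p * L;
      dX.rows(r0 + t0 + off, r0 + t1 - 1 + off) +=
          dcol.submat(r0 + t0, k * C, r0 + t1 - 1, (k + 1) * C - 1);
    }
  }
  return dX;
}

static inline void lrelu_(mat &A, double slope) {
  double *a = A.memptr();
  const uword n = A.n_elem;
  for (uword i = 0; i < n; ++i)
    if (a[i] < 0) a[i] *= slope;
}
// multiply dPre (in place) by the leaky-ReLU derivative, read off the
// post-activation values (valid: leaky ReLU is monotone, sign-preserving)
static inline void lrelu_bwd_(mat &d, const mat &A, double slope) {
  double *dp = d.memptr();
  const double *ap = A.memptr();
  const uword n = d.n_elem;
  for (uword i = 0; i < n; ++i)
    if (ap[i] <= 0) dp[i] *= slope;
}

struct LocalCache {
  mat Xin, col1, A1, col2, A2;
  Mat<unsigned char> amax; // 0/1: which of the two pooled inputs won
};

class Net {
public:
  // architecture
  int patch_len, n_epochs, spe, n_classes;
  ivec local_ch;            // channels of the three local blocks
  int K_loc;                // local kernel size (3)
  int embed_dim;            // embedding width == dilated channel width
  int n_dblocks;            // dilated blocks
  ivec dils;                // dilation plan within a block
  int K_dil;                // dilated kernel size (7)
  double slope, dropout;

  std::vector<Par> pars;
  // parameter indices.  Weight matrices are stored transposed relative to
  // the usual (out x in) convention: W is (C_in*K x C_out) so Y = col * W.
  std::vector<int> iW1, ib1, iW2, ib2, iWr;
  int iWe, ibe;
  std::vector<int> iWd, ibd;
  int iWo, ibo;
  long adam_t;
  std::mt19937_64 rng;

  // caches from the last forward pass (training mode)
  std::vector<LocalCache> lc;
  mat Fmat, E;
  std::vector<mat> dcol, dA;         // dilated per-layer caches
  std::vector<mat> dIn, dMask, dOut; // dilated per-block caches
  mat logits, probs;

  Net(List cfg, unsigned long seed) : adam_t(0), rng(seed) {
    patch_len = cfg["patch_length"];
    n_epochs = cfg["epochs_per_night"];
    spe = cfg["samples_per_epoch"];
    n_classes = cfg["n_classes"];
    Rcpp::IntegerVector lch = cfg["local_channels"];
    local_ch = ivec(lch.size());
    for (int i = 0; i < lch.size(); ++i) local_ch[i] = lch[i];
    K_loc = cfg["local_kernel"];
    embed_dim = cfg["embedding_dim"];
    n_dblocks = cfg["dilated_blocks"];
    Rcpp::IntegerVector dr = cfg["dilation_rates"];
    dils = ivec(dr.size());
    for (int i = 0; i < dr.size(); ++i) dils[i] = dr[i];
    K_dil = cfg["dilated_kernel"];
    slope = cfg["leaky_slope"];
    dropout = cfg["dropout_rate"];
    if (patch_len % (1 << local_ch.n_elem) != 0)
      stop("patch_length must be divisible by 2^(number of local blocks)");
    build();
  }

  int final_len() const { return patch_len >> local_ch.n_elem; }

  void addPar(std::vector<int> &idx, int r, int c, bool l1, std::string nm) {
    idx.push_back((int)pars.size());
    pars.emplace_back(r, c, l1, nm);
  }
  int addPar(int r, int c, bool l1, std::string nm) {
    pars.emplace_back(r, c, l1, nm);
    return (int)pars.size() - 1;
  }

  void build() {
    int cin = 1;
    for (uword b = 0; b < local_ch.n_elem; ++b) {
      int co = local_ch[b];
      char nm[64];
      snprintf(nm, 64, "local%llu.", (unsigned long long)b + 1);
      addPar(iW1, cin * K_loc, co, true, std::string(nm) + "W1");
      addPar(ib1, 1, co, false, std::string(nm) + "b1");
      addPar(iW2, co * K_loc, co, true, std::string(nm) + "W2");
      addPar(ib2, 1, co, false, std::string(nm) + "b2");
      addPar(iWr, cin, co, true, std::string(nm) + "Wres");
      cin = co;
    }
    iWe = addPar(cin * final_len(), embed_dim, false, "embed.W");
    ibe = addPar(1, embed_dim, false, "embed.b");
    for (int b = 0; b < n_dblocks; ++b)
      for (uword l = 0; l < dils.n_elem; ++l) {
        char nm[64];
        snprintf(nm, 64, "dilated%d.%llu.", b + 1, (unsigned long long)l + 1);
        addPar(iWd, embed_dim * K_dil, embed_dim, true, std::string(nm) + "W");
        addPar(ibd, 1, embed_dim, false, std::string(nm) + "b");
      }
    iWo = addPar(embed_dim, n_classes, true, "out.W");
    ibo = addPar(1, n_classes, false, "out.b");
    init_weights();
  }

  void init_weights() {
    // He-style normal initialisation, fan-in = C_in * kernel taps
    for (auto &p : pars) {
      if (p.W.n_rows == 1) { // biases
        p.W.zeros();
        continue;
      }
      double sd = std::sqrt(2.0 / p.W.n_rows);
      std::normal_distribution<double> nd(0.0, sd);
      for (uword i = 0; i < p.W.n_elem; ++i) p.W(i) = nd(rng);
    }
  }

  // patches: (patch_len * n_epochs) x 1, patch-major; the window for epoch i
  // is centred on the centre of epoch i and zero padded at the array bounds
  mat extract_patches(const vec &x) const {
    const int n = (int)x.n_elem;
    if (n != n_epochs * spe)
      stop("input must have length %d (got %d)", n_epochs * spe, n);
    mat X((uword)patch_len * n_epochs, 1, fill::zeros);
    const int half = patch_len / 2;
    for (int p = 0; p < n_epochs; ++p) {
      const int centre = p * spe + spe / 2;
      const int s0 = centre - half;
      for (int t = 0; t < patch_len; ++t) {
        const int src = s0 + t;
        if (src >= 0 && src < n) X((uword)p * patch_len + t, 0) = x[src];
      }
    }
    return X;
  }

  // local feature extractor: patches (P*N x 1) -> embeddings (N x D)
  mat local_forward(const mat &X0in, bool keep) {
    if (keep) lc.assign(local_ch.n_elem, LocalCache());
    mat X = X0in;
    int L = patch_len;
    const int N = (int)(X0in.n_rows / patch_len);
    for (uword b = 0; b < local_ch.n_elem; ++b) {
      LocalCache c;
      c.Xin = X;
      c.col1 = im2col(X, L, N, K_loc, 1);
      mat A1 = c.col1 * pars[iW1[b]].W;
      A1.each_row() += pars[ib1[b]].W.row(0);
      lrelu_(A1, slope);
      c.A1 = A1;
      c.col2 = im2col(A1, L, N, K_loc, 1);
      mat A2 = c.col2 * pars[iW2[b]].W;
      A2.each_row() += pars[ib2[b]].W.row(0);
      lrelu_(A2, slope);
      c.A2 = A2;
      // max pool stride 2 within each patch
      const int L2 = L / 2;
      const uword C = A2.n_cols;
      mat Y((uword)L2 * N, C);
      c.amax.set_size((uword)L2 * N, C);
      for (uword ch = 0; ch < C; ++ch) {
        const double *src = A2.colptr(ch);
        double *dst = Y.colptr(ch);
        unsigned char *am = c.amax.colptr(ch);
        for (int p = 0; p < N; ++p)
          for (int t = 0; t < L2; ++t) {
            const uword i0 = (uword)p * L + 2 * t, o = (uword)p * L2 + t;
            if (src[i0] >= src[i0 + 1]) { dst[o] = src[i0]; am[o] = 0; }
            else { dst[o] = src[i0 + 1]; am[o] = 1; }
          }
      }
      // residual: stride-2 subsample of the block input, 1x1 projection
      uvec idx((uword)L2 * N);
      for (int p = 0; p < N; ++p)
        for (int t = 0; t < L2; ++t)
          idx[(uword)p * L2 + t] = (uword)p * L + 2 * t;
      Y += X.rows(idx) * pars[iWr[b]].W;
      if (keep) lc[b] = c;
      X = Y;
      L = L2;
    }
    // flatten each patch (final_len x C3 block) to a row, then embed
    const int C3 = (int)local_ch[local_ch.n_elem - 1], L3 = final_len();
    mat F(N, (uword)C3 * L3);
    for (int p = 0; p < N; ++p)
      F.row(p) =
          vectorise(X.rows((uword)p * L3, (uword)(p + 1) * L3 - 1)).t();
    mat Emb = F * pars[iWe].W;
    Emb.each_row() += pars[ibe].W.row(0);
    lrelu_(Emb, slope);
    if (keep) { Fmat = F; E = Emb; }
    return Emb;
  }

  // dilated temporal stack + output head: E (n_epochs x D) -> logits
  mat dilated_forward(const mat &Ein, bool training, bool keep) {
    const int N = 1, L = (int)Ein.n_rows;
    mat A = Ein;
    if (keep) {
      dcol.assign(iWd.size(), mat());
      dA.assign(iWd.size(), mat());
      dIn.assign(n_dblocks, mat());
      dMask.assign(n_dblocks, mat());
      dOut.assign(n_dblocks, mat());
    }
    std::uniform_real_distribution<double> unif(0.0, 1.0);
    int li = 0;
    for (int b = 0; b < n_dblocks; ++b) {
      mat In = A;
      if (keep) dIn[b] = In;
      for (uword l = 0; l < dils.n_elem; ++l, ++li) {
        mat col = im2col(A, L, N, K_dil, (int)dils[l]);
        mat Z = col * pars[iWd[li]].W;
        Z.each_row() += pars[ibd[li]].W.row(0);
        lrelu_(Z, slope);
        if (keep) { dcol[li] = col; dA[li] = Z; }
        A = Z;
      }
      if (training && dropout > 0) {
        mat M(A.n_rows, A.n_cols);
        const double keepp = 1.0 - dropout;
        for (uword i = 0; i < M.n_elem; ++i)
          M(i) = unif(rng) < keepp ? 1.0 / keepp : 0.0;
        A %= M;
        if (keep) dMask[b] = M;
      } else if (keep) {
        dMask[b] = mat();
      }
      A += In;
      if (keep) dOut[b] = A;
    }
    mat Zo = A * pars[iWo].W;
    Zo.each_row() += pars[ibo].W.row(0);
    return Zo;
  }

  mat softmax_rows(const mat &Z) const {
    mat P = Z;
    for (uword i = 0; i < P.n_rows; ++i) {
      rowvec r = P.row(i);
      r -= r.max();
      r = exp(r);
      P.row(i) = r / accu(r);
    }
    return P;
  }

  mat forward(const vec &x, bool training, bool keep) {
    mat X = extract_patches(x);
    mat Emb = local_forward(X, keep);
    logits = dilated_forward(Emb, training, keep);
    probs = softmax_rows(logits); // n_epochs x n_classes
    return probs;
  }

  // labels: int vector length n_epochs, values 0..3 or -1 (masked).
  // Returns data loss; fills grad accumulators when accumulate = true.
  double backward_from(const ivec &labels, bool accumulate) {
    if ((int)labels.n_elem != n_epochs)
      stop("labels must have length %d", n_epochs);
    uvec valid = find(labels >= 0);
    if (valid.n_elem == 0) stop("all epochs are masked: loss undefined");
    double loss = 0.0;
    mat dZ(probs.n_rows, probs.n_cols, fill::zeros);
    const double inv = 1.0 / (double)valid.n_elem;
    for (uword k = 0; k < valid.n_elem; ++k) {
      const uword i = valid[k];
      const int y = (int)labels[i];
      loss += -std::log(std::max(probs(i, y), 1e-300));
      dZ.row(i) = probs.row(i) * inv;
      dZ(i, y) -= inv;
    }
    loss *= inv;
    if (!accumulate) return loss;

    const int L = n_epochs;
    // output head
    pars[iWo].g += dOut[n_dblocks - 1].t() * dZ;
    pars[ibo].g += sum(dZ, 0);
    mat dAcur = dZ * pars[iWo].W.t();

    // dilated blocks in reverse
    int li = (int)iWd.size() - 1;
    for (int b = n_dblocks - 1; b >= 0; --b) {
      mat dInb = dAcur; // residual branch
      mat dStack = dAcur;
      if (dMask[b].n_elem > 0) dStack %= dMask[b];
      for (int l = (int)dils.n_elem - 1; l >= 0; --l, --li) {
        lrelu_bwd_(dStack, dA[li], slope);
        pars[iWd[li]].g += dcol[li].t() * dStack;
        pars[ibd[li]].g += sum(dStack, 0);
        mat dc = dStack * pars[iWd[li]].W.t();
        dStack = col2im(dc, embed_dim, L, 1, K_dil, (int)dils[l]);
      }
      dAcur = dStack + dInb;
    }

    // embedding
    lrelu_bwd_(dAcur, E, slope);
    pars[iWe].g += Fmat.t() * dAcur;
    pars[ibe].g += sum(dAcur, 0);
    mat dF = dAcur * pars[iWe].W.t();
    const int C3 = (int)local_ch[local_ch.n_elem - 1], L3 = final_len();
    const int N = n_epochs;
    mat dX((uword)L3 * N, C3);
    for (int p = 0; p < N; ++p)
      dX.rows((uword)p * L3, (uword)(p + 1) * L3 - 1) =
          reshape(dF.row(p).t(), L3, C3);

    // local blocks in reverse
    int Lb = final_len();
    for (int b = (int)local_ch.n_elem - 1; b >= 0; --b) {
      const LocalCache &c = lc[b];
      const int Lin = Lb * 2;
      // residual branch
      uvec idx((uword)Lb * N);
      for (int p = 0; p < N; ++p)
        for (int t = 0; t < Lb; ++t)
          idx[(uword)p * Lb + t] = (uword)p * Lin + 2 * t;
      pars[iWr[b]].g += c.Xin.rows(idx).t() * dX;
      mat dXs = dX * pars[iWr[b]].W.t();
      // pool backward
      mat dA2(c.A2.n_rows, c.A2.n_cols, fill::zeros);
      for (uword ch = 0; ch < dA2.n_cols; ++ch) {
        double *dst = dA2.colptr(ch);
        const double *src = dX.colptr(ch);
        const unsigned char *am = c.amax.colptr(ch);
        for (int p = 0; p < N; ++p)
          for (int t = 0; t < Lb; ++t) {
            const uword o = (uword)p * Lb + t, i0 = (uword)p * Lin + 2 * t;
            dst[i0 + am[o]] += src[o];
          }
      }
      lrelu_bwd_(dA2, c.A2, slope);
      pars[iW2[b]].g += c.col2.t() * dA2;
      pars[ib2[b]].g += sum(dA2, 0);
      mat dc2 = dA2 * pars[iW2[b]].W.t();
      mat dA1 = col2im(dc2, (int)c.A1.n_cols, Lin, N, K_loc, 1);
      lrelu_bwd_(dA1, c.A1, slope);
      pars[iW1[b]].g += c.col1.t() * dA1;
      pars[ib1[b]].g += sum(dA1, 0);
      // gradient w.r.t. block input is only needed above the first block
      if (b > 0) {
        mat dc1 = dA1 * pars[iW1[b]].W.t();
        mat dXin = col2im(dc1, (int)c.Xin.n_cols, Lin, N, K_loc, 1);
        dXin.rows(idx) += dXs;
        dX = dXin;
        Lb = Lin;
      }
    }
    return loss;
  }

  long n_l1_weights() const {
    long n = 0;
    for (const auto &p : pars)
      if (p.l1) n += (long)p.W.n_elem;
    return n;
  }
  double l1_penalty(double lambda) const {
    double s = 0;
    for (const auto &p : pars)
      if (p.l1) s += accu(abs(p.W));
    return lambda * s / (double)n_l1_weights();
  }

  void zero_grad() {
    for (auto &p : pars) p.g.zeros();
  }

  void adam_step(double lr, double b1, double b2, double eps, double lambda) {
    ++adam_t;
    const double c1 = 1.0 - std::pow(b1, (double)adam_t);
    const double c2 = 1.0 - std::pow(b2, (double)adam_t);
    const double lw = lambda / (double)n_l1_weights();
    for (auto &p : pars) {
      mat g = p.g;
      if (p.l1 && lambda > 0) g += lw * sign(p.W);
      p.m = b1 * p.m + (1 - b1) * g;
      p.v = b2 * p.v + (1 - b2) * (g % g);
      p.W -= lr * (p.m / c1) / (sqrt(p.v / c2) + eps);
    }
  }
};

// ------------------------------------------------------------------ R API

// Training allocates and frees many multi-megabyte activation buffers per
// step; keep them on the heap instead of round-tripping through mmap.
// [[Rcpp::export(name = ".cs_tune_allocator")]]
void cs_tune_allocator() {
#if defined(__GLIBC__) && defined(M_MMAP_THRESHOLD)
  mallopt(M_MMAP_THRESHOLD, 256 * 1024 * 1024);
  mallopt(M_TRIM_THRESHOLD, 256 * 1024 * 1024);
#endif
}

// [[Rcpp::export(name = ".net_create")]]
SEXP net_create(List config, int seed) {
  Rcpp::XPtr<Net> p(new Net(config, (unsigned long)seed), true);
  return p;
}

// [[Rcpp::export(name = ".net_forward")]]
Rcpp::NumericMatrix net_forward(SEXP ptr, Rcpp::NumericVector samples) {
  Rcpp::XPtr<Net> net(ptr);
  vec x(samples.begin(), samples.size());
  mat P = net->forward(x, false, false); // n_epochs x n_classes
  return Rcpp::wrap(P);
}

// [[Rcpp::export(name = ".net_extract_patches")]]
Rcpp::NumericMatrix net_extract_patches(SEXP ptr, Rcpp::NumericVector samples) {
  Rcpp::XPtr<Net> net(ptr);
  vec x(samples.begin(), samples.size());
  mat X = net->extract_patches(x); // (P*N) x 1
  mat out(net->n_epochs, net->patch_len);
  for (int p = 0; p < net->n_epochs; ++p)
    out.row(p) = X.submat((uword)p * net->patch_len, 0,
                          (uword)(p + 1) * net->patch_len - 1, 0).t();
  return Rcpp::wrap(out);
}

// [[Rcpp::export(name = ".net_embed")]]
Rcpp::NumericMatrix net_embed(SEXP ptr, Rcpp::NumericMatrix patches) {
  Rcpp::XPtr<Net> net(ptr);
  const int N = patches.nrow(), P = patches.ncol();
  if (P != net->patch_len) stop("patches must have %d columns", net->patch_len);
  mat X((uword)P * N, 1);
  for (int p = 0; p < N; ++p)
    for (int t = 0; t < P; ++t) X((uword)p * P + t, 0) = patches(p, t);
  mat Emb = net->local_forward(X, false); // N x D
  return Rcpp::wrap(Emb);
}

// [[Rcpp::export(name = ".net_loss")]]
double net_loss(SEXP ptr, Rcpp::NumericVector samples,
                Rcpp::IntegerVector labels) {
  Rcpp::XPtr<Net> net(ptr);
  vec x(samples.begin(), samples.size());
  ivec y(labels.size());
  for (int i = 0; i < labels.size(); ++i) y[i] = labels[i];
  net->forward(x, false, false);
  return net->backward_from(y, false);
}

// One optimisation step on a batch; gradients averaged over the batch.
// [[Rcpp::export(name = ".net_train_step")]]
List net_train_step(SEXP ptr, List batch, double lr, double l1_lambda,
                    double beta1, double beta2, double eps) {
  Rcpp::XPtr<Net> net(ptr);
  const int B = batch.size();
  net->zero_grad();
  double loss = 0.0;
  for (int i = 0; i < B; ++i) {
    List s = batch[i];
    Rcpp::NumericVector samples = s["samples"];
    Rcpp::IntegerVector labels = s["labels"];
    vec x(samples.begin(), samples.size());
    ivec y(labels.size());
    for (int j = 0; j < labels.size(); ++j) y[j] = labels[j];
    net->forward(x, true, true);
    loss += net->backward_from(y, true);
  }
  loss /= B;
  for (auto &p : net->pars) p.g /= (double)B;
  const double pen = net->l1_penalty(l1_lambda);
  net->adam_step(lr, beta1, beta2, eps, l1_lambda);
  return List::create(Named("data_loss") = loss, Named("penalty") = pen,
                      Named("total") = loss + pen);
}

// [[Rcpp::export(name = ".net_weights")]]
List net_weights(SEXP ptr) {
  Rcpp::XPtr<Net> net(ptr);
  List out(net->pars.size());
  Rcpp::CharacterVector nm(net->pars.size());
  for (size_t i = 0; i < net->pars.size(); ++i) {
    out[i] = Rcpp::wrap(net->pars[i].W);
    nm[i] = net->pars[i].name;
  }
  out.attr("names") = nm;
  return out;
}

// [[Rcpp::export(name = ".net_set_weights")]]
void net_set_weights(SEXP ptr, List w) {
  Rcpp::XPtr<Net> net(ptr);
  if ((size_t)w.size() != net->pars.size())
    stop("weight list has %d entries, model has %d", w.size(),
         (int)net->pars.size());
  for (size_t i = 0; i < net->pars.size(); ++i) {
    Rcpp::NumericMatrix Wi = w[i];
    if ((uword)Wi.nrow() != net->pars[i].W.n_rows ||
        (uword)Wi.ncol() != net->pars[i].W.n_cols)
      stop("weight '%s' has the wrong shape", net->pars[i].name.c_str());
    net->pars[i].W = mat(Wi.begin(), Wi.nrow(), Wi.ncol());
    net->pars[i].m.zeros();
    net->pars[i].v.zeros();
  }
  net->adam_t = 0;
}

// [[Rcpp::export(name = ".net_param_count")]]
List net_param_count(SEXP ptr) {
  Rcpp::XPtr<Net> net(ptr);
  long local = 0, embed = 0, dilated = 0, out = 0;
  for (size_t i = 0; i < net->pars.size(); ++i) {
    const long n = (long)net->pars[i].W.n_elem;
    const std::string &nm = net->pars[i].name;
    if (nm.rfind("local", 0) == 0) local += n;
    else if (nm.rfind("embed", 0) == 0) embed += n;
    else if (nm.rfind("dilated", 0) == 0) dilated += n;
    else out += n;
  }
  return List::create(Named("local") = (double)local,
                      Named("embedding") = (double)embed,
                      Named("dilated") = (double)dilated,
                      Named("output") = (double)out,
                      Named("total") = (double)(local + embed + dilated + out));
}

// [[Rcpp::export(name = ".net_set_dropout")]]
void net_set_dropout(SEXP ptr, double rate) {
  Rcpp::XPtr<Net> net(ptr);
  if (rate < 0 || rate >= 1) stop("dropout rate must be in [0, 1)");
  net->dropout = rate;
}

// [[Rcpp::export(name = ".net_set_seed")]]
void net_set_seed(SEXP ptr, int seed) {
  Rcpp::XPtr<Net> net(ptr);
  net->rng.seed((unsigned long)seed);
}

// [[Rcpp::export(name = ".net_perturb_check")]]
double net_finite_diff_loss(SEXP ptr, Rcpp::NumericVector samples,
                            Rcpp::IntegerVector labels, int par_index,
                            int elem_index, double delta) {
  // helper for finite-difference gradient checks in the test suite
  Rcpp::XPtr<Net> net(ptr);
  vec x(samples.begin(), samples.size());
  ivec y(labels.size());
  for (int j = 0; j < labels.size(); ++j) y[j] = labels[j];
  double save = net->pars[par_index].W(elem_index);
  net->pars[par_index].W(elem_index) = save + delta;
  net->forward(x, false, false);
  double l = net->backward_from(y, false);
  net->pars[par_index].W(elem_index) = save;
  return l;
}

// [[Rcpp::export(name = ".net_grad")]]
List net_grad(SEXP ptr, Rcpp::NumericVector samples,
              Rcpp::IntegerVector labels) {
  // analytic gradients for the same check (no update, no dropout)
  Rcpp::XPtr<Net> net(ptr);
  vec x(samples.begin(), samples.size());
  ivec y(labels.size());
  for (int j = 0; j < labels.size(); ++j) y[j] = labels[j];
  net->zero_grad();
  net->forward(x, false, true);
  double loss = net->backward_from(y, true);
  List out(net->pars.size());
  Rcpp::CharacterVector nm(net->pars.size());
  for (size_t i = 0; i < net->pars.size(); ++i) {
    out[i] = Rcpp::wrap(net->pars[i].g);
    nm[i] = net->pars[i].name;
  }
  out.attr("names") = nm;
  return List::create(Named("loss") = loss, Named("grad") = out);
}
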