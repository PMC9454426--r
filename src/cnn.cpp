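// 1-D CNN for spectrum classification: [conv -> leaky ReLU -> max-pool] x B
// -> flatten -> fully connected. Training (float32, im2col + GEMM, Adam,
// softmax cross-entropy) plus double-precision forward, input-gradient and
// DeepLift (rescale rule) passes sharing the same layer arithmetic.
//
// Layouts: a batch activation is a (C, L*B) matrix, sample b occupying
// columns [b*L, (b+1)*L). im2col column ordering is (channel fastest,
// kernel tap slower), matching the weight-column ordering. Convolutions
// are "valid" (no padding); pooling drops the remainder.
//
// Because the leaky ReLU is monotone increasing, max-pooling commutes
// with it: the forward pass pools the conv pre-activations directly and
// applies the activation to the pooled values, so the full-length
// activation tensor is never materialized and all elementwise work in
// the backward pass happens at pooled size.

#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

struct ArchDims {
  int kernel, pool, n_classes, n_bins, n_blocks;
  std::vector<int> ch;            // channels per block (ch[0] input = 1)
  std::vector<int> Lin, Lconv, Lpool;
};

static ArchDims make_dims(int n_bins, const std::vector<int>& channels,
                          int kernel, int pool, int n_classes) {
  ArchDims d;
  d.kernel = kernel; d.pool = pool; d.n_classes = n_classes;
  d.n_bins = n_bins; d.n_blocks = (int)channels.size();
  d.ch.push_back(1);
  for (int c : channels) d.ch.push_back(c);
  int L = n_bins;
  for (int l = 0; l < d.n_blocks; ++l) {
    d.Lin.push_back(L);
    int Lc = L - kernel + 1;
    if (Lc < 1)
      Rcpp::stop("conv block %d: input length %d shorter than kernel %d",
                 l + 1, L, kernel);
    int Lp = Lc / pool;
    if (Lp < 1)
      Rcpp::stop("conv block %d: pooling collapses length %d to zero",
                 l + 1, Lc);
    d.Lconv.push_back(Lc);
    d.Lpool.push_back(Lp);
    L = Lp;
  }
  return d;
}

template <typename eT>
struct Net {
  std::vector<Mat<eT>> W;   // conv weights: (C_out, C_in*k)
  std::vector<Col<eT>> b;   // conv biases
  Mat<eT> Wfc;              // (n_classes, C_last * L_last)
  Col<eT> bfc;
};

template <typename eT>
static Net<eT> net_from_list(const Rcpp::List& weights) {
  Net<eT> net;
  Rcpp::List cw = weights["conv_w"], cb = weights["conv_b"];
  for (int l = 0; l < cw.size(); ++l) {
    net.W.push_back(conv_to<Mat<eT>>::from(Rcpp::as<arma::mat>(cw[l])));
    net.b.push_back(conv_to<Col<eT>>::from(Rcpp::as<arma::vec>(cb[l])));
  }
  net.Wfc = conv_to<Mat<eT>>::from(Rcpp::as<arma::mat>(weights["fc_w"]));
  net.bfc = conv_to<Col<eT>>::from(Rcpp::as<arma::vec>(weights["fc_b"]));
  return net;
}

template <typename eT>
static Rcpp::List net_to_list(const Net<eT>& net) {
  Rcpp::List cw(net.W.size()), cb(net.b.size());
  for (size_t l = 0; l < net.W.size(); ++l) {
    cw[l] = Rcpp::wrap(conv_to<arma::mat>::from(net.W[l]));
    cb[l] = Rcpp::wrap(conv_to<arma::vec>::from(net.b[l]));
  }
  return Rcpp::List::create(
      Rcpp::Named("conv_w") = cw, Rcpp::Named("conv_b") = cb,
      Rcpp::Named("fc_w") = Rcpp::wrap(conv_to<arma::mat>::from(net.Wfc)),
      Rcpp::Named("fc_b") = Rcpp::wrap(conv_to<arma::vec>::from(net.bfc)));
}

// ---- layer primitives ----------------------------------------------------

template <typename eT>
static void im2col(const Mat<eT>& A, int C, int Lin, int k, int B,
                   Mat<eT>& Xcol) {
  const int Lout = Lin - k + 1;
  if ((int)Xcol.n_rows != C * k || Xcol.n_cols != (size_t)Lout * B)
    Xcol.set_size(C * k, (size_t)Lout * B);
  const size_t bytes = sizeof(eT) * C * k;
  for (int bb = 0; bb < B; ++bb) {
    const eT* src0 = A.colptr(bb * Lin);
    eT* dst = Xcol.colptr(bb * Lout);
    for (int j = 0; j < Lout; ++j)
      std::memcpy(dst + (size_t)j * C * k, src0 + (size_t)j * C, bytes);
  }
}

template <typename eT>
static void col2im_add(const Mat<eT>& dXcol, int C, int Lin, int k, int B,
                       Mat<eT>& dA) {
  const int Lout = Lin - k + 1;
  dA.zeros(C, Lin * B);
  const int ck = C * k;
  for (int bb = 0; bb < B; ++bb) {
    eT* dst0 = dA.colptr(bb * Lin);
    const eT* src = dXcol.colptr(bb * Lout);
    for (int j = 0; j < Lout; ++j) {
      eT* dst = dst0 + (size_t)j * C;
      const eT* s = src + (size_t)j * ck;
      for (int t = 0; t < ck; ++t) dst[t] += s[t];
    }
  }
}

// pool conv pre-activations: P(c, out) = max over window, amax = source col
template <typename eT>
static void pool_fwd(const Mat<eT>& Z, int C, int Lc, int pool, int B,
                     Mat<eT>& P, Mat<uword>& amax) {
  const int Lp = Lc / pool;
  if ((int)P.n_rows != C || P.n_cols != (size_t)Lp * B) {
    P.set_size(C, (size_t)Lp * B);
    amax.set_size(C, (size_t)Lp * B);
  }
  for (int bb = 0; bb < B; ++bb)
    for (int m = 0; m < Lp; ++m) {
      const size_t out = (size_t)bb * Lp + m;
      const size_t base = (size_t)bb * Lc + (size_t)m * pool;
      eT* pc = P.colptr(out);
      uword* ac = amax.colptr(out);
      const eT* z0 = Z.colptr(base);
      for (int c = 0; c < C; ++c) { pc[c] = z0[c]; ac[c] = base; }
      for (int p = 1; p < pool; ++p) {
        const eT* zp = Z.colptr(base + p);
        for (int c = 0; c < C; ++c)
          if (zp[c] > pc[c]) { pc[c] = zp[c]; ac[c] = base + p; }
      }
    }
}

template <typename eT>
static inline eT leaky(eT z, eT slope) { return z > 0 ? z : slope * z; }

// ---- forward for a batch (training or prediction) ------------------------

template <typename eT>
struct FwdCache {
  std::vector<Mat<eT>> Xcol;   // im2col input of each conv (training)
  std::vector<Mat<eT>> Ppre;   // pooled pre-activations
  std::vector<Mat<uword>> amax;
  std::vector<Mat<eT>> Zfull;  // full conv pre-activations (DeepLift only)
  Mat<eT> F;                   // flattened FC input
  Mat<eT> scores;
};

template <typename eT>
static void forward_batch(const Net<eT>& net, const ArchDims& d,
                          const Mat<eT>& X /* (n_bins, B) */, FwdCache<eT>& c,
                          eT slope, bool keep, bool keep_full) {
  const int B = X.n_cols;
  c.Xcol.assign(d.n_blocks, Mat<eT>());
  c.Ppre.assign(d.n_blocks, Mat<eT>());
  c.amax.assign(d.n_blocks, Mat<uword>());
  c.Zfull.assign(d.n_blocks, Mat<eT>());
  Mat<eT> A(1, (size_t)d.n_bins * B);
  std::memcpy(A.memptr(), X.memptr(), sizeof(eT) * X.n_elem);
  for (int l = 0; l < d.n_blocks; ++l) {
    Mat<eT> Xcol;
    im2col(A, d.ch[l], d.Lin[l], d.kernel, B, Xcol);
    Mat<eT> Z = net.W[l] * Xcol;
    Z.each_col() += net.b[l];
    Mat<eT> P; Mat<uword> amax;
    pool_fwd(Z, d.ch[l + 1], d.Lconv[l], d.pool, B, P, amax);
    if (keep) {
      c.Xcol[l] = std::move(Xcol);
      c.Ppre[l] = P;                     // pre-activation copy (pooled size)
      c.amax[l] = std::move(amax);
    }
    if (keep_full) c.Zfull[l] = std::move(Z);
    // activation applied to the pooled values (monotonicity)
    P.transform([slope](eT z) { return leaky<eT>(z, slope); });
    A = std::move(P);
  }
  const int Llast = d.Lpool[d.n_blocks - 1];
  const int Clast = d.ch[d.n_blocks];
  c.F.set_size((size_t)Clast * Llast, B);
  for (int bb = 0; bb < B; ++bb)
    std::memcpy(c.F.colptr(bb), A.colptr((size_t)bb * Llast),
                sizeof(eT) * Clast * Llast);
  c.scores = net.Wfc * c.F;
  c.scores.each_col() += net.bfc;
}

// ---- Adam ----------------------------------------------------------------

template <typename MatT>
static void adam_update(MatT& w, MatT& m, MatT& v, const MatT& g, float lr,
                        float b1, float b2, float eps, long t) {
  m = b1 * m + (1 - b1) * g;
  v = b2 * v + (1 - b2) * square(g);
  const float c1 = 1.0f / (1.0f - (float)std::pow((double)b1, (double)t));
  const float c2 = 1.0f / (1.0f - (float)std::pow((double)b2, (double)t));
  w -= lr * (c1 * m) / (sqrt(c2 * v) + eps);
}

// ---- exported: weight initialization -------------------------------------

// [[Rcpp::export]]
Rcpp::List cnn_init_cpp(int n_bins, std::vector<int> channels, int kernel,
                        int pool, int n_classes, int seed) {
  ArchDims d = make_dims(n_bins, channels, kernel, pool, n_classes);
  std::mt19937 rng((unsigned)seed);
  std::normal_distribution<double> gauss(0.0, 1.0);
  Net<double> net;
  for (int l = 0; l < d.n_blocks; ++l) {
    const int fan_in = d.ch[l] * d.kernel;
    mat W(d.ch[l + 1], fan_in);
    const double sd = std::sqrt(2.0 / fan_in);
    for (uword i = 0; i < W.n_elem; ++i) W(i) = sd * gauss(rng);
    net.W.push_back(W);
    net.b.push_back(zeros<vec>(d.ch[l + 1]));
  }
  const int nfc = d.ch[d.n_blocks] * d.Lpool[d.n_blocks - 1];
  mat Wfc(d.n_classes, nfc);
  const double sdf = std::sqrt(2.0 / nfc);
  for (uword i = 0; i < Wfc.n_elem; ++i) Wfc(i) = sdf * gauss(rng);
  net.Wfc = Wfc;
  net.bfc = zeros<vec>(d.n_classes);
  Rcpp::List out = net_to_list(net);
  out["flatten_len"] = nfc;
  return out;
}

// ---- exported: training --------------------------------------------------

// All large per-batch buffers are allocated once and reused across
// batches (fresh 100-MB allocations per batch would spend more time in
// page faults than in the GEMMs). The final partial batch runs on
// aliases over the leading columns of the same buffers: every
// per-sample block is a contiguous column range, so the layouts stay
// valid for any batch size up to the allocated one.
struct TrainWS {
  std::vector<fmat> A;      // A[l]: input activations of block l (+ final)
  std::vector<fmat> Xcol, Z, Ppre, dXcol;
  std::vector<Mat<uword>> amax;
  fmat dF;
};

static fmat alias(fmat& buf, int rows, size_t cols) {
  return fmat(buf.memptr(), rows, cols, false, true);
}
static Mat<uword> alias_u(Mat<uword>& buf, int rows, size_t cols) {
  return Mat<uword>(buf.memptr(), rows, cols, false, true);
}

// [[Rcpp::export]]
Rcpp::List cnn_train_cpp(Rcpp::List weights, const arma::mat& X,
                         const arma::ivec& y, std::vector<int> channels,
                         int kernel, int pool, double slope, int epochs,
                         int batch_size, double lr, int seed) {
  const int N = X.n_cols;
  ArchDims d = make_dims(X.n_rows, channels, kernel, pool,
                         Rcpp::as<arma::mat>(weights["fc_w"]).n_rows);
  Net<float> net = net_from_list<float>(weights);
  fmat Xf = conv_to<fmat>::from(X);
  const float sl = (float)slope;
  const int Bmax = std::min(batch_size, N);

  TrainWS ws;
  ws.A.resize(d.n_blocks + 1);
  ws.Xcol.resize(d.n_blocks); ws.Z.resize(d.n_blocks);
  ws.Ppre.resize(d.n_blocks); ws.dXcol.resize(d.n_blocks);
  ws.amax.resize(d.n_blocks);
  for (int l = 0; l < d.n_blocks; ++l) {
    ws.A[l].set_size(d.ch[l], (size_t)d.Lin[l] * Bmax);
    ws.Xcol[l].set_size(d.ch[l] * d.kernel, (size_t)d.Lconv[l] * Bmax);
    ws.Z[l].set_size(d.ch[l + 1], (size_t)d.Lconv[l] * Bmax);
    ws.Ppre[l].set_size(d.ch[l + 1], (size_t)d.Lpool[l] * Bmax);
    ws.amax[l].set_size(d.ch[l + 1], (size_t)d.Lpool[l] * Bmax);
    ws.dXcol[l].set_size(d.ch[l] * d.kernel, (size_t)d.Lconv[l] * Bmax);
  }
  ws.A[d.n_blocks].set_size(d.ch[d.n_blocks],
                            (size_t)d.Lpool[d.n_blocks - 1] * Bmax);
  const int nfc = d.ch[d.n_blocks] * d.Lpool[d.n_blocks - 1];
  ws.dF.set_size(nfc, Bmax);
  std::vector<fmat> dA(d.n_blocks);   // gradient w.r.t. block inputs
  for (int l = 1; l < d.n_blocks; ++l)
    dA[l].set_size(d.ch[l], (size_t)d.Lin[l] * Bmax);
  std::vector<fmat> dZbuf(d.n_blocks);
  for (int l = 0; l < d.n_blocks; ++l)
    dZbuf[l].set_size(d.ch[l + 1], (size_t)d.Lconv[l] * Bmax);

  Net<float> mom, vel;  // Adam state mirrors the parameter structure
  for (size_t l = 0; l < net.W.size(); ++l) {
    mom.W.push_back(zeros<fmat>(size(net.W[l])));
    vel.W.push_back(zeros<fmat>(size(net.W[l])));
    mom.b.push_back(zeros<fvec>(net.b[l].n_elem));
    vel.b.push_back(zeros<fvec>(net.b[l].n_elem));
  }
  mom.Wfc = zeros<fmat>(size(net.Wfc)); vel.Wfc = zeros<fmat>(size(net.Wfc));
  mom.bfc = zeros<fvec>(net.bfc.n_elem); vel.bfc = zeros<fvec>(net.bfc.n_elem);
  const float b1 = 0.9f, b2 = 0.999f, aeps = 1e-8f;
  long t = 0;

  std::mt19937 rng((unsigned)seed);
  std::vector<int> idx(N);
  for (int i = 0; i < N; ++i) idx[i] = i;
  std::vector<double> loss_hist;

  for (int ep = 0; ep < epochs; ++ep) {
    std::shuffle(idx.begin(), idx.end(), rng);
    double ep_loss = 0.0; int ep_n = 0;
    for (int start = 0; start < N; start += batch_size) {
      const int B = std::min(batch_size, N - start);
      ivec yb(B);
      fmat A0 = alias(ws.A[0], 1, (size_t)d.n_bins * B);
      for (int i = 0; i < B; ++i) {
        std::memcpy(A0.memptr() + (size_t)i * d.n_bins,
                    Xf.colptr(idx[start + i]), sizeof(float) * d.n_bins);
        yb(i) = y(idx[start + i]);
      }

      // ---- forward ----
      for (int l = 0; l < d.n_blocks; ++l) {
        fmat Al = alias(ws.A[l], d.ch[l], (size_t)d.Lin[l] * B);
        fmat Xcol = alias(ws.Xcol[l], d.ch[l] * d.kernel,
                          (size_t)d.Lconv[l] * B);
        im2col(Al, d.ch[l], d.Lin[l], d.kernel, B, Xcol);
        fmat Z = alias(ws.Z[l], d.ch[l + 1], (size_t)d.Lconv[l] * B);
        Z = net.W[l] * Xcol;
        Z.each_col() += net.b[l];
        fmat Pp = alias(ws.Ppre[l], d.ch[l + 1], (size_t)d.Lpool[l] * B);
        Mat<uword> am = alias_u(ws.amax[l], d.ch[l + 1],
                                (size_t)d.Lpool[l] * B);
        pool_fwd(Z, d.ch[l + 1], d.Lconv[l], d.pool, B, Pp, am);
        fmat An = alias(ws.A[l + 1], d.ch[l + 1], (size_t)d.Lpool[l] * B);
        const float* pp = Pp.memptr();
        float* an = An.memptr();
        const size_t n = Pp.n_elem;
        for (size_t i = 0; i < n; ++i)
          an[i] = pp[i] > 0 ? pp[i] : sl * pp[i];
      }
      // flatten is a pure reinterpretation: sample blocks are contiguous
      fmat F(ws.A[d.n_blocks].memptr(), nfc, B, false, true);
      fmat scores = net.Wfc * F;
      scores.each_col() += net.bfc;

      // softmax cross-entropy
      fmat P = scores;
      P.each_row() -= max(P, 0);
      P = exp(P);
      P.each_row() /= sum(P, 0);
      double loss = 0.0;
      for (int i = 0; i < B; ++i)
        loss -= std::log((double)std::max(P(yb(i), i), 1e-12f));
      loss /= B;
      if (!std::isfinite(loss))
        Rcpp::stop("training diverged: non-finite loss at epoch %d", ep + 1);
      ep_loss += loss * B; ep_n += B;

      fmat dscores = P;
      for (int i = 0; i < B; ++i) dscores(yb(i), i) -= 1.0f;
      dscores /= (float)B;

      // ---- backward ----
      fmat dWfc = dscores * F.t();
      fvec dbfc = sum(dscores, 1);
      fmat dFa = alias(ws.dF, nfc, B);
      dFa = net.Wfc.t() * dscores;

      // dP starts as a reinterpretation of dF; after each block it is
      // re-bound to that block's input-gradient buffer
      float* dp_mem = ws.dF.memptr();
      int dp_C = d.ch[d.n_blocks];
      size_t dp_L = d.Lpool[d.n_blocks - 1];

      std::vector<fmat> dW(d.n_blocks);
      std::vector<fvec> db(d.n_blocks);
      for (int l = d.n_blocks - 1; l >= 0; --l) {
        const int C = d.ch[l + 1];
        fmat dP(dp_mem, dp_C, dp_L * B, false, true);
        // activation derivative at pooled pre-activations (pooled size)
        {
          float* dp = dP.memptr();
          const float* pp = ws.Ppre[l].memptr();
          const size_t n = dP.n_elem;
          for (size_t i = 0; i < n; ++i)
            if (pp[i] <= 0) dp[i] *= sl;
        }
        // scatter through the pool to full conv length
        fmat dZ = alias(dZbuf[l], C, (size_t)d.Lconv[l] * B);
        dZ.zeros();
        {
          for (uword j = 0; j < dP.n_cols; ++j) {
            const float* dpc = dP.colptr(j);
            const uword* ac = ws.amax[l].colptr(j);
            for (int cc = 0; cc < C; ++cc)
              dZ.colptr(ac[cc])[cc] += dpc[cc];
          }
        }
        fmat Xcol = alias(ws.Xcol[l], d.ch[l] * d.kernel,
                          (size_t)d.Lconv[l] * B);
        dW[l] = dZ * Xcol.t();
        db[l] = sum(dP, 1);
        if (l > 0) {
          fmat dXcol = alias(ws.dXcol[l], d.ch[l] * d.kernel,
                             (size_t)d.Lconv[l] * B);
          dXcol = net.W[l].t() * dZ;
          fmat dAl = alias(dA[l], d.ch[l], (size_t)d.Lin[l] * B);
          col2im_add(dXcol, d.ch[l], d.Lin[l], d.kernel, B, dAl);
          // reinterpret as the pooled-grid gradient of the previous block
          dp_mem = dA[l].memptr();
          dp_C = d.ch[l];
          dp_L = d.Lin[l];
        }
      }

      ++t;
      for (int l = 0; l < d.n_blocks; ++l) {
        adam_update(net.W[l], mom.W[l], vel.W[l], dW[l], (float)lr, b1, b2,
                    aeps, t);
        adam_update(net.b[l], mom.b[l], vel.b[l], db[l], (float)lr, b1, b2,
                    aeps, t);
      }
      adam_update(net.Wfc, mom.Wfc, vel.Wfc, dWfc, (float)lr, b1, b2, aeps, t);
      adam_update(net.bfc, mom.bfc, vel.bfc, dbfc, (float)lr, b1, b2, aeps, t);
    }
    loss_hist.push_back(ep_loss / ep_n);
    Rcpp::checkUserInterrupt();
  }

  Rcpp::List out = net_to_list(net);
  out["loss"] = loss_hist;
  return out;
}

// ---- exported: prediction forward (double) -------------------------------

// [[Rcpp::export]]
arma::mat cnn_forward_cpp(Rcpp::List weights, const arma::mat& X,
                          std::vector<int> channels, int kernel, int pool,
                          double slope) {
  ArchDims d = make_dims(X.n_rows, channels, kernel, pool,
                         Rcpp::as<arma::mat>(weights["fc_w"]).n_rows);
  Net<double> net = net_from_list<double>(weights);
  const int N = X.n_cols, chunk = 64;
  mat scores(d.n_classes, N);
  for (int s = 0; s < N; s += chunk) {
    const int B = std::min(chunk, N - s);
    FwdCache<double> c;
    forward_batch(net, d, mat(X.cols(s, s + B - 1)), c, slope, false, false);
    scores.cols(s, s + B - 1) = c.scores;
  }
  return scores;
}

// ---- exported: DeepLift (rescale rule) and input gradient ----------------
//
// mode = 0: DeepLift multipliers against the reference input. The rescale
//           rule is applied at the (pooled) leaky-ReLU units; each max-pool
//           routes its multiplier to the argmax position of the actual
//           input with the delta-ratio factor, so summation-to-delta holds
//           exactly (up to float error) outside eps-degenerate deltas.
// mode = 1: plain input gradient of the target score (reference ignored).

// [[Rcpp::export]]
Rcpp::List cnn_backprop_input_cpp(Rcpp::List weights, const arma::vec& x,
                                  const arma::vec& ref,
                                  std::vector<int> channels, int kernel,
                                  int pool, double slope, int target,
                                  int mode, double eps) {
  ArchDims d = make_dims(x.n_elem, channels, kernel, pool,
                         Rcpp::as<arma::mat>(weights["fc_w"]).n_rows);
  const bool dl = (mode == 0);
  if (dl && ref.n_elem != x.n_elem)
    Rcpp::stop("reference length %d does not match spectrum length %d",
               (int)ref.n_elem, (int)x.n_elem);
  if (target < 0 || target >= d.n_classes) Rcpp::stop("bad target class");
  Net<double> net = net_from_list<double>(weights);

  FwdCache<double> cx, cr;
  forward_batch(net, d, mat(x), cx, slope, true, true);
  if (dl) forward_batch(net, d, mat(ref), cr, slope, true, true);

  vec mout = zeros<vec>(d.n_classes);
  mout(target) = 1.0;
  vec mF = net.Wfc.t() * mout;

  const int Llast = d.Lpool[d.n_blocks - 1];
  const int Clast = d.ch[d.n_blocks];
  mat mP(Clast, Llast);
  std::memcpy(mP.memptr(), mF.memptr(), sizeof(double) * Clast * Llast);

  for (int l = d.n_blocks - 1; l >= 0; --l) {
    const int C = d.ch[l + 1];
    // leaky ReLU on the pooled pre-activations: rescale rule
    for (uword i = 0; i < mP.n_elem; ++i) {
      const double zx = cx.Ppre[l](i);
      double f;
      if (dl) {
        const double zr = cr.Ppre[l](i);
        const double dz = zx - zr;
        f = (std::abs(dz) > eps)
              ? (leaky(zx, slope) - leaky(zr, slope)) / dz
              : (zx > 0 ? 1.0 : slope);
      } else {
        f = (zx > 0 ? 1.0 : slope);
      }
      mP(i) *= f;
    }
    // pool: route to the argmax position of the actual input
    mat mZ(C, d.Lconv[l], fill::zeros);
    for (uword j = 0; j < mP.n_cols; ++j)
      for (int cc = 0; cc < C; ++cc) {
        const uword a = cx.amax[l](cc, j);
        double f = 1.0;
        if (dl) {
          const double num = cx.Ppre[l](cc, j) - cr.Ppre[l](cc, j);
          const double den = cx.Zfull[l](cc, a) - cr.Zfull[l](cc, a);
          f = (std::abs(den) > eps) ? num / den : 1.0;
        }
        mZ(cc, a) += mP(cc, j) * f;
      }
    // conv: linear, multipliers flow through the weights
    mat mXcol = net.W[l].t() * mZ;
    mat mprev;
    col2im_add(mXcol, d.ch[l], d.Lin[l], d.kernel, 1, mprev);
    mP = std::move(mprev);
  }

  vec multiplier = vectorise(mP);
  vec contrib = dl ? vec(multiplier % (x - ref)) : multiplier;
  const double score_x = cx.scores(target, 0);
  const double score_r = dl ? cr.scores(target, 0) : NA_REAL;
  return Rcpp::List::create(
      Rcpp::Named("contrib") = contrib,
      Rcpp::Named("multiplier") = multiplier,
      Rcpp::Named("score_x") = score_x,
      Rcpp::Named("score_ref") = score_r,
      Rcpp::Named("scores_x") = vec(cx.scores.col(0)));
}
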