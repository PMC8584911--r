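// Training loop of the concrete autoencoder.
//
// Each sample in a minibatch gets its own Gumbel noise in the concrete
// selection layer (the standard concrete/Gumbel-softmax formulation;
// sharing noise across a batch inflates selector-gradient variance and
// stalls hardening).  Arithmetic is single precision, as is conventional
// for neural-network training.  All stochastic draws come from R's RNG
// stream via unif_rand() in a documented column-major order, so a run is an
// exact function of the R-side seed and single steps can be replicated by
// the plain-R reference implementation used in the tests.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

using namespace Rcpp;
using arma::fmat;
using arma::frowvec;
using arma::uvec;

// Column-major uniform draws from R's stream, clamped away from 0 and 1
// in float precision (a double this close to 1 would round to 1.0f and
// make the Gumbel transform infinite).
static void fill_runif(fmat &M) {
  float *p = M.memptr();
  const size_t m = M.n_elem;
  for (size_t i = 0; i < m; ++i) {
    float u = (float)unif_rand();
    if (u < 1e-7f) u = 1e-7f;
    if (u > 0.99999988f) u = 0.99999988f;
    p[i] = u;
  }
}

static void fill_gumbel(fmat &M) {
  fill_runif(M);
  float *p = M.memptr();
  for (size_t i = 0; i < M.n_elem; ++i) p[i] = -std::log(-std::log(p[i]));
}

static void fill_mask(fmat &M, double dropout) {
  float *p = M.memptr();
  for (size_t i = 0; i < M.n_elem; ++i)
    p[i] = (unif_rand() >= dropout) ? 1.0f : 0.0f;
}

// Row-wise softmax with max-shift, in place.
static void row_softmax_inplace(fmat &M) {
  for (size_t j = 0; j < M.n_rows; ++j) {
    float mx = M.row(j).max();
    double s = 0;
    for (size_t i = 0; i < M.n_cols; ++i) {
      float e = std::exp(M(j, i) - mx);
      M(j, i) = e;
      s += e;
    }
    M.row(j) /= (float)s;
  }
}

static double mean_max_prob(const fmat &A) {
  fmat P = A;
  row_softmax_inplace(P);
  return arma::mean(arma::conv_to<arma::vec>::from(arma::max(P, 1)));
}

static void leaky_inplace(fmat &Z, float slope) {
  float *p = Z.memptr();
  for (size_t i = 0; i < Z.n_elem; ++i)
    if (p[i] < 0) p[i] *= slope;
}

struct Adam {
  std::vector<fmat *> params;
  std::vector<fmat> m, v;
  long t = 0;
  void init(const std::vector<fmat *> &ps) {
    params = ps;
    for (fmat *p : ps) {
      m.emplace_back(arma::zeros<fmat>(p->n_rows, p->n_cols));
      v.emplace_back(arma::zeros<fmat>(p->n_rows, p->n_cols));
    }
  }
  void step(const std::vector<fmat *> &grads, float lr) {
    ++t;
    const float b1 = 0.9f, b2 = 0.999f, eps = 1e-8f;
    const float c1 = 1.0f - std::pow(b1, (float)t);
    const float c2 = 1.0f - std::pow(b2, (float)t);
    for (size_t i = 0; i < params.size(); ++i) {
      float *p = params[i]->memptr(), *g = grads[i]->memptr(),
            *mi = m[i].memptr(), *vi = v[i].memptr();
      const size_t ne = params[i]->n_elem;
      for (size_t j = 0; j < ne; ++j) {
        mi[j] = b1 * mi[j] + (1 - b1) * g[j];
        vi[j] = b2 * vi[j] + (1 - b2) * g[j] * g[j];
        p[j] -= lr * (mi[j] / c1) / (std::sqrt(vi[j] / c2) + eps);
      }
    }
  }
};

// Decoder forward; caches pre-activations and layer inputs when training.
struct Decoder {
  int L;
  std::vector<fmat> *W;
  std::vector<frowvec> *b;
  std::vector<fmat> inputs, Zs;
  float slope;

  fmat forward(const fmat &S, const std::vector<fmat> *masks, float dropout,
               bool cache) {
    if (cache) {
      inputs.assign(L, fmat());
      Zs.assign(L, fmat());
    }
    fmat H = S;
    for (int l = 0; l < L; ++l) {
      if (cache) inputs[l] = H;
      fmat Z = H * (*W)[l];
      Z.each_row() += (*b)[l];
      if (l < L - 1) {
        leaky_inplace(Z, slope);
        if (masks) Z = Z % (*masks)[l] / (1.0f - dropout);
        if (cache) Zs[l] = Z;   // post-activation sign == pre-activation sign
        H = std::move(Z);
      } else {
        H = std::move(Z);
      }
    }
    return H;
  }
};

// Per-sample concrete selection: fills S (bsz x k), the per-sample
// *unnormalized* softmax numerators in Wsl (k x n x bsz) and the row sums
// in Rsum (k x bsz); consumers divide by the row sum lazily.  Two fused
// passes per sample: build (A+G)/T tracking row maxima, then exponentiate
// while accumulating the row sums and the selected mixtures.
static void concrete_forward(const fmat &A, const fmat &Xb, float temp,
                             arma::fcube &Wsl, fmat &Rsum, fmat &G, fmat &S) {
  const int bsz = Xb.n_rows, k = A.n_rows, n = A.n_cols;
  const float invT = 1.0f / temp;
  std::vector<float> rmax(k), rsum(k), sacc(k);
  for (int s = 0; s < bsz; ++s) {
    fill_gumbel(G);
    float *W = Wsl.slice_memptr(s);
    const float *a = A.memptr(), *g = G.memptr();
    std::fill(rmax.begin(), rmax.end(),
              -std::numeric_limits<float>::infinity());
    for (int i = 0; i < n; ++i) {
      const int off = i * k;
      for (int j = 0; j < k; ++j) {
        const float m = (a[off + j] + g[off + j]) * invT;
        W[off + j] = m;
        if (m > rmax[j]) rmax[j] = m;
      }
    }
    std::fill(rsum.begin(), rsum.end(), 0.0f);
    std::fill(sacc.begin(), sacc.end(), 0.0f);
    for (int i = 0; i < n; ++i) {
      const int off = i * k;
      const float x = Xb(s, i);
      for (int j = 0; j < k; ++j) {
        const float e = std::exp(W[off + j] - rmax[j]);
        W[off + j] = e;
        rsum[j] += e;
        sacc[j] += e * x;
      }
    }
    for (int j = 0; j < k; ++j) {
      Rsum(j, s) = rsum[j];
      S(s, j) = sacc[j] / rsum[j];
    }
  }
}

// [[Rcpp::export(name = ".cpp_train_cae")]]
List cpp_train_cae(const arma::mat &Xtr_d, const arma::mat &Xva_d,
                   const arma::mat &A0, const List &W0, const List &b0,
                   double slope_d, double dropout, int epochs, double lr,
                   double t_start, double t_end, int batch_size) {
  const fmat Xtr = arma::conv_to<fmat>::from(Xtr_d);
  const fmat Xva = arma::conv_to<fmat>::from(Xva_d);
  const int n = Xtr.n_cols, ntr = Xtr.n_rows, nva = Xva.n_rows;
  const int k = A0.n_rows;
  const int L = W0.size();
  const float slope = (float)slope_d;

  fmat A = arma::conv_to<fmat>::from(A0);
  std::vector<fmat> W(L);
  std::vector<frowvec> b(L);
  for (int l = 0; l < L; ++l) {
    W[l] = arma::conv_to<fmat>::from(as<arma::mat>(W0[l]));
    b[l] = arma::conv_to<frowvec>::from(as<arma::rowvec>(b0[l]));
  }
  std::vector<fmat> bmat(L);       // biases as 1-row mats for the optimizer
  for (int l = 0; l < L; ++l) bmat[l] = fmat(b[l]);

  std::vector<fmat *> pptr;
  pptr.push_back(&A);
  for (int l = 0; l < L; ++l) pptr.push_back(&W[l]);
  for (int l = 0; l < L; ++l) pptr.push_back(&bmat[l]);
  Adam opt;
  opt.init(pptr);

  Decoder dec;
  dec.L = L; dec.W = &W; dec.b = &b; dec.slope = slope;

  NumericVector tr_temp(epochs), tr_mmp(epochs), tr_loss(epochs),
      tr_vloss(epochs);

  arma::fcube Wsl(k, n, batch_size);
  fmat Rsum(k, batch_size);
  std::vector<fmat> masks(L - 1);
  fmat G(k, n), keys(ntr, 1);
  const bool use_drop = dropout > 0;

  for (int e = 1; e <= epochs; ++e) {
    const double dtemp = t_start * std::pow(t_end / t_start,
                                            (double)e / epochs);
    const float temp = (float)dtemp;
    fill_runif(keys);
    uvec ord = arma::sort_index(keys.col(0));
    double eloss = 0;

    for (int s0 = 0; s0 < ntr; s0 += batch_size) {
      const int bend = std::min(s0 + batch_size, ntr) - 1;
      const uvec idx = ord.subvec(s0, bend);
      const fmat Xb = Xtr.rows(idx);
      const int bsz = Xb.n_rows;

      fmat S(bsz, k);
      concrete_forward(A, Xb, temp, Wsl, Rsum, G, S);
      if (use_drop)
        for (int l = 0; l < L - 1; ++l) {
          masks[l].set_size(bsz, W[l].n_cols);
          fill_mask(masks[l], dropout);
        }
      for (int l = 0; l < L; ++l) b[l] = bmat[l].row(0);
      fmat Y = dec.forward(S, use_drop ? &masks : nullptr, (float)dropout,
                           true);
      fmat R = Y - Xb;
      const double loss = arma::accu(arma::conv_to<arma::mat>::from(R % R)) /
                          R.n_elem;
      eloss += loss * bsz;

      // decoder backward
      std::vector<fmat> gW(L), gb(L);
      fmat dZ = (2.0f / (float)R.n_elem) * R;
      fmat dS;
      for (int l = L - 1; l >= 0; --l) {
        gW[l] = dec.inputs[l].t() * dZ;
        gb[l] = arma::sum(dZ, 0);
        fmat dPrev = dZ * W[l].t();
        if (l > 0) {
          // dec.Zs[l-1] holds the dropped-out activation: its sign matches
          // the pre-activation where the unit survived, and it is zero where
          // dropped, so one elementwise pass applies both local derivatives
          const fmat &Zp = dec.Zs[l - 1];
          if (use_drop) dPrev = dPrev % masks[l - 1] / (1.0f - dropout);
          float *dp = dPrev.memptr();
          const float *zp = Zp.memptr();
          for (size_t q = 0; q < dPrev.n_elem; ++q)
            if (zp[q] < 0) dp[q] *= slope;
          dZ = std::move(dPrev);
        } else {
          dS = std::move(dPrev);
        }
      }

      // selection backward: per-sample softmax Jacobian, accumulated.
      // dot(w_j, x) is exactly the forward output s_j, so no recompute;
      // the stored numerators are normalized on the fly.
      fmat dA(k, n, arma::fill::zeros);
      {
        const float invT = 1.0f / temp;
        float *da = dA.memptr();
        std::vector<float> dsj(k), rj(k), inv(k);
        for (int s = 0; s < bsz; ++s) {
          const float *W = Wsl.slice_memptr(s);
          for (int j = 0; j < k; ++j) {
            dsj[j] = dS(s, j);
            rj[j] = dsj[j] * S(s, j);
            inv[j] = invT / Rsum(j, s);
          }
          for (int i = 0; i < n; ++i) {
            const int off = i * k;
            const float x = Xb(s, i);
            for (int j = 0; j < k; ++j)
              da[off + j] += W[off + j] * inv[j] * (dsj[j] * x - rj[j]);
          }
        }
      }

      std::vector<fmat *> gptr;
      gptr.push_back(&dA);
      for (int l = 0; l < L; ++l) gptr.push_back(&gW[l]);
      for (int l = 0; l < L; ++l) gptr.push_back(&gb[l]);
      opt.step(gptr, (float)lr);
    }

    // epoch-end diagnostics: stochastic-selection validation loss at the
    // current temperature (no dropout), mean-max probability of the logits
    for (int l = 0; l < L; ++l) b[l] = bmat[l].row(0);
    fmat Sv(nva, k);
    {
      arma::fcube Wtmp(k, n, nva);
      fmat Rtmp(k, nva);
      concrete_forward(A, Xva, temp, Wtmp, Rtmp, G, Sv);
    }
    fmat Yv = dec.forward(Sv, nullptr, 0.0f, false);
    fmat Rv = Yv - Xva;
    tr_temp[e - 1] = dtemp;
    tr_mmp[e - 1] = mean_max_prob(A);
    tr_loss[e - 1] = eloss / ntr;
    tr_vloss[e - 1] =
        arma::accu(arma::conv_to<arma::mat>::from(Rv % Rv)) / Rv.n_elem;
  }

  // hard argmax selection for extraction and held-out MSE
  uvec picks(k);
  for (int j = 0; j < k; ++j) picks[j] = A.row(j).index_max();
  for (int l = 0; l < L; ++l) b[l] = bmat[l].row(0);
  fmat Sh(nva, k);
  for (int j = 0; j < k; ++j) Sh.col(j) = Xva.col(picks[j]);
  fmat Yh = dec.forward(Sh, nullptr, 0.0f, false);
  fmat Rh = Yh - Xva;
  const double val_mse =
      arma::accu(arma::conv_to<arma::mat>::from(Rh % Rh)) / Rh.n_elem;

  List Wout(L), bout(L);
  for (int l = 0; l < L; ++l) {
    Wout[l] = arma::conv_to<arma::mat>::from(W[l]);
    arma::rowvec bl = arma::conv_to<arma::rowvec>::from(bmat[l].row(0));
    bout[l] = NumericVector(bl.begin(), bl.end());
  }
  IntegerVector picks_r(k);
  for (int j = 0; j < k; ++j) picks_r[j] = (int)picks[j] + 1;
  return List::create(
      _["A"] = arma::conv_to<arma::mat>::from(A), _["W"] = Wout,
      _["b"] = bout, _["picks"] = picks_r, _["val_mse"] = val_mse,
      _["trace"] = DataFrame::create(
          _["epoch"] = seq_len(epochs), _["temperature"] = tr_temp,
          _["mean_max_prob"] = tr_mmp, _["train_loss"] = tr_loss,
          _["val_loss"] = tr_vloss));
}
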