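// Single-precision CNN+RNN freezing-of-gait classifier.
//
// The network mirrors the embedded deployment target: every parameter and
// every intermediate is a 32-bit float.  Two execution paths exist:
//
//   * fog_forward(): plain sequential scalar loops, one window at a time.
//     Each window's score depends only on that window, so streaming
//     (one-sample-at-a-time) and batch prediction are bit-identical.
//   * fog_train_cpp(): mini-batch BPTT with Armadillo float matrices; speed
//     matters here and training does not carry a bit-identity contract.
//
// Layer stack (input vector v of length ch*(ps+1), Eq.-1 ordering: current
// sample's channels first, then one lag back, ... oldest last):
//   feature-wise normalization (frozen moments, learned gamma/beta)
//   -> reshape to (ch channels x T=ps+1 time steps), oldest step first
//   -> 1-D convolution along time, `filters` kernels, same padding, ReLU
//   -> sequence view (T steps x filters)
//   -> simple tanh RNN (h1 units) -> simple tanh RNN (h2 units), last state
//   -> dense + sigmoid scalar score.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#include <random>

using namespace Rcpp;

static const float NORM_EPS = 1e-5f;

// [[Rcpp::export]]
NumericVector as_float32_cpp(NumericVector x) {
  NumericVector out(x.size());
  for (R_xlen_t i = 0; i < x.size(); ++i) out[i] = (double)(float)x[i];
  return out;
}

struct NetDims {
  int ch, ps, T, P, K, F, H1, H2, pad;
};

static NetDims dims_from(int ch, int ps, int filters, int kernel, int h1, int h2) {
  NetDims d;
  d.ch = ch; d.ps = ps; d.T = ps + 1; d.P = ch * (ps + 1);
  d.K = kernel; d.F = filters; d.H1 = h1; d.H2 = h2; d.pad = kernel / 2;
  return d;
}

// Glorot-uniform initialisation, all values float-representable.
// [[Rcpp::export]]
List fog_init_params(int ch, int ps, int filters, int kernel, int h1, int h2,
                     int seed) {
  NetDims d = dims_from(ch, ps, filters, kernel, h1, h2);
  std::mt19937 rng((unsigned)seed);
  auto glorot = [&](int nr, int nc, int fan_in, int fan_out) {
    double lim = std::sqrt(6.0 / (fan_in + fan_out));
    std::uniform_real_distribution<double> unif(-lim, lim);
    NumericMatrix m(nr, nc);
    for (int j = 0; j < nc; ++j)
      for (int i = 0; i < nr; ++i) m(i, j) = (double)(float)unif(rng);
    return m;
  };
  NumericVector mu(d.P, 0.0), var(d.P, 1.0), gamma(d.P, 1.0), beta(d.P, 0.0);
  List out = List::create(
    _["mu"] = mu, _["var"] = var, _["gamma"] = gamma, _["beta"] = beta,
    _["convW"] = glorot(d.K * d.ch, d.F, d.K * d.ch, d.F),
    _["convb"] = NumericVector(d.F, 0.0),
    _["w1x"] = glorot(d.F, d.H1, d.F, d.H1),
    _["w1h"] = glorot(d.H1, d.H1, d.H1, d.H1),
    _["b1"] = NumericVector(d.H1, 0.0),
    _["w2x"] = glorot(d.H1, d.H2, d.H1, d.H2),
    _["w2h"] = glorot(d.H2, d.H2, d.H2, d.H2),
    _["b2"] = NumericVector(d.H2, 0.0),
    _["wout"] = glorot(d.H2, 1, d.H2, 1),
    _["bout"] = NumericVector(1, 0.0));
  return out;
}

static std::vector<float> fvec_from(NumericVector x) {
  std::vector<float> v(x.size());
  for (R_xlen_t i = 0; i < x.size(); ++i) v[i] = (float)x[i];
  return v;
}

static std::vector<float> fvec_from_mat(NumericMatrix x) {
  std::vector<float> v(x.size());
  for (R_xlen_t i = 0; i < x.size(); ++i) v[i] = (float)x[i];
  return v; // column-major, like R
}

// Deterministic scalar forward pass; identical arithmetic for any batch size.
// [[Rcpp::export]]
NumericVector fog_forward(List params, NumericMatrix X, int ch, int ps,
                          int filters, int kernel, int h1, int h2) {
  NetDims d = dims_from(ch, ps, filters, kernel, h1, h2);
  if (X.ncol() != d.P)
    stop("window length %d does not match model input length %d", X.ncol(), d.P);

  std::vector<float> mu = fvec_from(params["mu"]);
  std::vector<float> var = fvec_from(params["var"]);
  std::vector<float> gamma = fvec_from(params["gamma"]);
  std::vector<float> beta = fvec_from(params["beta"]);
  std::vector<float> convW = fvec_from_mat(params["convW"]); // (K*ch) x F
  std::vector<float> convb = fvec_from(params["convb"]);
  std::vector<float> w1x = fvec_from_mat(params["w1x"]); // F x H1
  std::vector<float> w1h = fvec_from_mat(params["w1h"]); // H1 x H1
  std::vector<float> b1 = fvec_from(params["b1"]);
  std::vector<float> w2x = fvec_from_mat(params["w2x"]); // H1 x H2
  std::vector<float> w2h = fvec_from_mat(params["w2h"]); // H2 x H2
  std::vector<float> b2 = fvec_from(params["b2"]);
  std::vector<float> wout = fvec_from(params["wout"]);
  float bout = (float)NumericVector(params["bout"])[0];

  std::vector<float> invsd(d.P);
  for (int p = 0; p < d.P; ++p) invsd[p] = 1.0f / std::sqrt(var[p] + NORM_EPS);

  int n = X.nrow();
  NumericVector scores(n);
  std::vector<float> Xm(d.ch * d.T);      // (c, tt) column-major: c + ch*tt
  std::vector<float> A(d.F * d.T);        // (f, tt): f + F*tt
  std::vector<float> h1prev(d.H1), h1cur(d.H1);
  std::vector<float> H1seq(d.H1 * d.T);   // (j, tt)
  std::vector<float> h2prev(d.H2), h2cur(d.H2);

  for (int r = 0; r < n; ++r) {
    // normalization + reshape: feature p = lag*ch + c sits at time tt = ps-lag
    for (int lag = 0; lag <= d.ps; ++lag) {
      int tt = d.ps - lag;
      for (int c = 0; c < d.ch; ++c) {
        int p = lag * d.ch + c;
        float v = ((float)X(r, p) - mu[p]) * invsd[p];
        Xm[c + d.ch * tt] = gamma[p] * v + beta[p];
      }
    }
    // conv along time, same padding, ReLU
    for (int tt = 0; tt < d.T; ++tt) {
      for (int f = 0; f < d.F; ++f) {
        float acc = convb[f];
        for (int k = 0; k < d.K; ++k) {
          int src = tt + k - d.pad;
          if (src < 0 || src >= d.T) continue;
          const float* wcol = &convW[(size_t)f * (d.K * d.ch)];
          for (int c = 0; c < d.ch; ++c)
            acc += wcol[k * d.ch + c] * Xm[c + d.ch * src];
        }
        A[f + d.F * tt] = acc > 0.0f ? acc : 0.0f;
      }
    }
    // RNN 1
    std::fill(h1prev.begin(), h1prev.end(), 0.0f);
    for (int tt = 0; tt < d.T; ++tt) {
      for (int j = 0; j < d.H1; ++j) {
        float a = b1[j];
        const float* wx = &w1x[(size_t)j * d.F];
        for (int i = 0; i < d.F; ++i) a += A[i + d.F * tt] * wx[i];
        const float* wh = &w1h[(size_t)j * d.H1];
        for (int i = 0; i < d.H1; ++i) a += h1prev[i] * wh[i];
        h1cur[j] = std::tanh(a);
      }
      for (int j = 0; j < d.H1; ++j) {
        h1prev[j] = h1cur[j];
        H1seq[j + d.H1 * tt] = h1cur[j];
      }
    }
    // RNN 2
    std::fill(h2prev.begin(), h2prev.end(), 0.0f);
    for (int tt = 0; tt < d.T; ++tt) {
      for (int j = 0; j < d.H2; ++j) {
        float a = b2[j];
        const float* wx = &w2x[(size_t)j * d.H1];
        for (int i = 0; i < d.H1; ++i) a += H1seq[i + d.H1 * tt] * wx[i];
        const float* wh = &w2h[(size_t)j * d.H2];
        for (int i = 0; i < d.H2; ++i) a += h2prev[i] * wh[i];
        h2cur[j] = std::tanh(a);
      }
      h2prev = h2cur;
    }
    float out = bout;
    for (int j = 0; j < d.H2; ++j) out += wout[j] * h2prev[j];
    scores[r] = (double)(1.0f / (1.0f + std::exp(-out)));
  }
  return scores;
}

// ---------------------------------------------------------------------------
// Training: mini-batch Adam with backpropagation through time (float32).

struct Adam {
  arma::fmat m, v;
  void init(arma::uword nr, arma::uword nc) {
    m.zeros(nr, nc); v.zeros(nr, nc);
  }
  void step(arma::fmat& w, const arma::fmat& g, float lr, int t) {
    const float b1 = 0.9f, b2 = 0.999f, eps = 1e-7f;
    m = b1 * m + (1.0f - b1) * g;
    v = b2 * v + (1.0f - b2) * (g % g);
    float c1 = 1.0f - std::pow(b1, (float)t);
    float c2 = 1.0f - std::pow(b2, (float)t);
    w -= lr * (m / c1) / (arma::sqrt(v / c2) + eps);
  }
};

static arma::fmat fmat_from(SEXP s) {
  NumericMatrix m(s);
  arma::fmat out(m.nrow(), m.ncol());
  for (int j = 0; j < m.ncol(); ++j)
    for (int i = 0; i < m.nrow(); ++i) out(i, j) = (float)m(i, j);
  return out;
}

static arma::frowvec frow_from(SEXP s) {
  NumericVector v(s);
  arma::frowvec out(v.size());
  for (R_xlen_t i = 0; i < v.size(); ++i) out[i] = (float)v[i];
  return out;
}

static NumericMatrix mat_to_R(const arma::fmat& m) {
  NumericMatrix out(m.n_rows, m.n_cols);
  for (arma::uword j = 0; j < m.n_cols; ++j)
    for (arma::uword i = 0; i < m.n_rows; ++i) out(i, j) = (double)m(i, j);
  return out;
}

static NumericVector row_to_R(const arma::frowvec& v) {
  NumericVector out(v.n_elem);
  for (arma::uword i = 0; i < v.n_elem; ++i) out[i] = (double)v[i];
  return out;
}

// [[Rcpp::export]]
List fog_train_cpp(List params, NumericMatrix X, IntegerVector y,
                   int ch, int ps, int filters, int kernel, int h1, int h2,
                   int epochs, int batch, double lr_in,
                   double w0_in, double w1_in, int seed) {
  NetDims d = dims_from(ch, ps, filters, kernel, h1, h2);
  if (X.ncol() != d.P) stop("window length does not match model input length");
  const int n = X.nrow();
  const float lr = (float)lr_in, cw0 = (float)w0_in, cw1 = (float)w1_in;

  arma::fmat Xf(n, d.P);
  for (int j = 0; j < d.P; ++j)
    for (int i = 0; i < n; ++i) Xf(i, j) = (float)X(i, j);
  arma::fvec yf(n);
  for (int i = 0; i < n; ++i) yf[i] = (float)y[i];

  arma::frowvec mu = frow_from(params["mu"]);
  arma::frowvec var = frow_from(params["var"]);
  arma::frowvec invsd = 1.0f / arma::sqrt(var + NORM_EPS);
  arma::frowvec gamma = frow_from(params["gamma"]);
  arma::frowvec beta = frow_from(params["beta"]);
  arma::fmat convW = fmat_from(params["convW"]);
  arma::frowvec convb = frow_from(params["convb"]);
  arma::fmat w1x = fmat_from(params["w1x"]);
  arma::fmat w1h = fmat_from(params["w1h"]);
  arma::frowvec b1 = frow_from(params["b1"]);
  arma::fmat w2x = fmat_from(params["w2x"]);
  arma::fmat w2h = fmat_from(params["w2h"]);
  arma::frowvec b2 = frow_from(params["b2"]);
  arma::fmat wout = fmat_from(params["wout"]); // H2 x 1
  float bout = (float)NumericVector(params["bout"])[0];

  Adam a_gamma; a_gamma.init(1, d.P);
  Adam a_beta;  a_beta.init(1, d.P);
  Adam a_convW; a_convW.init(convW.n_rows, convW.n_cols);
  Adam a_convb; a_convb.init(1, d.F);
  Adam a_w1x; a_w1x.init(d.F, d.H1);
  Adam a_w1h; a_w1h.init(d.H1, d.H1);
  Adam a_b1;  a_b1.init(1, d.H1);
  Adam a_w2x; a_w2x.init(d.H1, d.H2);
  Adam a_w2h; a_w2h.init(d.H2, d.H2);
  Adam a_b2;  a_b2.init(1, d.H2);
  Adam a_wout; a_wout.init(d.H2, 1);
  Adam a_bout; a_bout.init(1, 1);

  std::mt19937 rng((unsigned)seed);
  std::vector<int> order(n);
  for (int i = 0; i < n; ++i) order[i] = i;

  NumericVector loss_hist(epochs);
  int adam_t = 0;

  // im2col index map: column kc = k*ch + c of output step tt reads input
  // feature (ps - (tt + k - pad))*ch + c, or zero outside [0, T).
  for (int ep = 0; ep < epochs; ++ep) {
    std::shuffle(order.begin(), order.end(), rng);
    double ep_loss = 0.0; long ep_n = 0;

    for (int start = 0; start < n; start += batch) {
      int B = std::min(batch, n - start);
      arma::uvec idx(B);
      for (int i = 0; i < B; ++i) idx[i] = (arma::uword)order[start + i];
      arma::fmat Xb = Xf.rows(idx);
      arma::fvec yb = yf.elem(idx);

      // normalization layer
      arma::fmat V = Xb;
      V.each_row() -= mu;
      V.each_row() %= invsd;
      arma::fmat N = V;
      N.each_row() %= gamma;
      N.each_row() += beta;

      // im2col (rows: tt*B + b)
      arma::fmat Col(d.T * B, d.K * d.ch, arma::fill::zeros);
      for (int tt = 0; tt < d.T; ++tt) {
        for (int k = 0; k < d.K; ++k) {
          int src = tt + k - d.pad;
          if (src < 0 || src >= d.T) continue;
          int lag = d.ps - src;
          Col.submat(tt * B, k * d.ch, tt * B + B - 1, k * d.ch + d.ch - 1) =
            N.cols(lag * d.ch, lag * d.ch + d.ch - 1);
        }
      }
      arma::fmat C = Col * convW;
      C.each_row() += convb;
      arma::fmat Arel = arma::clamp(C, 0.0f, std::numeric_limits<float>::max());

      // RNN 1 forward
      std::vector<arma::fmat> H1s(d.T);
      arma::fmat Hprev(B, d.H1, arma::fill::zeros);
      for (int tt = 0; tt < d.T; ++tt) {
        arma::fmat Z = Arel.rows(tt * B, tt * B + B - 1) * w1x + Hprev * w1h;
        Z.each_row() += b1;
        H1s[tt] = arma::tanh(Z);
        Hprev = H1s[tt];
      }
      // RNN 2 forward
      std::vector<arma::fmat> H2s(d.T);
      arma::fmat H2prev(B, d.H2, arma::fill::zeros);
      for (int tt = 0; tt < d.T; ++tt) {
        arma::fmat Z = H1s[tt] * w2x + H2prev * w2h;
        Z.each_row() += b2;
        H2s[tt] = arma::tanh(Z);
        H2prev = H2s[tt];
      }
      arma::fvec logits = H2s[d.T - 1] * wout + bout;
      arma::fvec s = 1.0f / (1.0f + arma::exp(-logits));
      arma::fvec wi = cw0 + (cw1 - cw0) * yb; // per-sample class weight

      arma::fvec sc = arma::clamp(s, 1e-7f, 1.0f - 1e-7f);
      arma::fvec li = -(yb % arma::log(sc) + (1.0f - yb) % arma::log(1.0f - sc));
      ep_loss += (double)arma::accu(wi % li);
      ep_n += B;

      // backward
      arma::fvec ds = (wi % (s - yb)) / (float)B; // dL/dlogit
      arma::fmat dwout = H2s[d.T - 1].t() * ds;
      float dbout = arma::accu(ds);

      arma::fmat dH2 = ds * wout.t(); // grad at last step
      arma::fmat dw2x(d.H1, d.H2, arma::fill::zeros);
      arma::fmat dw2h(d.H2, d.H2, arma::fill::zeros);
      arma::frowvec db2(d.H2, arma::fill::zeros);
      std::vector<arma::fmat> dH1s(d.T);
      for (int tt = d.T - 1; tt >= 0; --tt) {
        arma::fmat dZ = dH2 % (1.0f - H2s[tt] % H2s[tt]);
        dw2x += H1s[tt].t() * dZ;
        if (tt > 0) dw2h += H2s[tt - 1].t() * dZ;
        db2 += arma::sum(dZ, 0);
        dH1s[tt] = dZ * w2x.t();
        dH2 = (tt > 0) ? arma::fmat(dZ * w2h.t()) : arma::fmat();
      }

      arma::fmat dw1x(d.F, d.H1, arma::fill::zeros);
      arma::fmat dw1h(d.H1, d.H1, arma::fill::zeros);
      arma::frowvec db1(d.H1, arma::fill::zeros);
      arma::fmat dA(d.T * B, d.F, arma::fill::zeros);
      arma::fmat dH1(B, d.H1, arma::fill::zeros);
      for (int tt = d.T - 1; tt >= 0; --tt) {
        arma::fmat dZ = (dH1 + dH1s[tt]) % (1.0f - H1s[tt] % H1s[tt]);
        dw1x += Arel.rows(tt * B, tt * B + B - 1).t() * dZ;
        if (tt > 0) dw1h += H1s[tt - 1].t() * dZ;
        db1 += arma::sum(dZ, 0);
        dA.rows(tt * B, tt * B + B - 1) = dZ * w1x.t();
        dH1 = (tt > 0) ? arma::fmat(dZ * w1h.t())
                       : arma::fmat(B, d.H1, arma::fill::zeros);
      }

      arma::fmat dC = dA % arma::conv_to<arma::fmat>::from(C > 0.0f);
      arma::fmat dconvW = Col.t() * dC;
      arma::frowvec dconvb = arma::sum(dC, 0);
      arma::fmat dCol = dC * convW.t();

      arma::fmat dN(B, d.P, arma::fill::zeros);
      for (int tt = 0; tt < d.T; ++tt) {
        for (int k = 0; k < d.K; ++k) {
          int src = tt + k - d.pad;
          if (src < 0 || src >= d.T) continue;
          int lag = d.ps - src;
          dN.cols(lag * d.ch, lag * d.ch + d.ch - 1) +=
            dCol.submat(tt * B, k * d.ch, tt * B + B - 1,
                        k * d.ch + d.ch - 1);
        }
      }
      arma::frowvec dgamma = arma::sum(dN % V, 0);
      arma::frowvec dbeta = arma::sum(dN, 0);

      ++adam_t;
      arma::fmat gm(gamma), bm(beta);
      a_gamma.step(gm, arma::fmat(dgamma), lr, adam_t); gamma = gm.row(0);
      a_beta.step(bm, arma::fmat(dbeta), lr, adam_t); beta = bm.row(0);
      a_convW.step(convW, dconvW, lr, adam_t);
      arma::fmat cb(convb);
      a_convb.step(cb, arma::fmat(dconvb), lr, adam_t); convb = cb.row(0);
      a_w1x.step(w1x, dw1x, lr, adam_t);
      a_w1h.step(w1h, dw1h, lr, adam_t);
      arma::fmat b1m(b1);
      a_b1.step(b1m, arma::fmat(db1), lr, adam_t); b1 = b1m.row(0);
      a_w2x.step(w2x, dw2x, lr, adam_t);
      a_w2h.step(w2h, dw2h, lr, adam_t);
      arma::fmat b2m(b2);
      a_b2.step(b2m, arma::fmat(db2), lr, adam_t); b2 = b2m.row(0);
      a_wout.step(wout, dwout, lr, adam_t);
      arma::fmat boutm(1, 1); boutm(0, 0) = bout;
      arma::fmat dboutm(1, 1); dboutm(0, 0) = dbout;
      a_bout.step(boutm, dboutm, lr, adam_t); bout = boutm(0, 0);
    }
    loss_hist[ep] = ep_loss / (double)ep_n;
  }

  List out_params = List::create(
    _["mu"] = row_to_R(mu), _["var"] = row_to_R(var),
    _["gamma"] = row_to_R(gamma), _["beta"] = row_to_R(beta),
    _["convW"] = mat_to_R(convW), _["convb"] = row_to_R(convb),
    _["w1x"] = mat_to_R(w1x), _["w1h"] = mat_to_R(w1h),
    _["b1"] = row_to_R(b1),
    _["w2x"] = mat_to_R(w2x), _["w2h"] = mat_to_R(w2h),
    _["b2"] = row_to_R(b2),
    _["wout"] = mat_to_R(wout),
    _["bout"] = NumericVector::create((double)bout));
  return List::create(_["params"] = out_params, _["loss"] = loss_hist);
}
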