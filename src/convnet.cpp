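// Multi-kernel 1-D convolutional text classifier:
// embedding lookup -> parallel convolutions (kernel sizes 1..5) -> ReLU ->
// global max-pool -> concat -> FC + batch norm + ReLU (x2) -> sigmoid.
// Trained with Adam on binary cross-entropy; dropout on the pooled
// concatenation and between the fully connected layers. All randomness comes
// from an internal seeded generator so training is bit-reproducible.

#include <RcppArmadillo.h>
#include "rng.h"
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

namespace {

struct Params {
  arma::mat emb;                    // (V+1) x E, row 0 = frozen padding
  std::vector<int> ks;              // kernel sizes
  std::vector<arma::mat> conv_w;    // d x (k*E)
  std::vector<arma::vec> conv_b;    // d
  arma::mat w1; arma::rowvec b1, g1, be1, bn1_mean, bn1_var;
  arma::mat w2; arma::rowvec b2, g2, be2, bn2_mean, bn2_var;
  arma::vec w_out; double b_out;
  int d, P, h1, h2, E;
};

Params from_list(List lst) {
  Params p;
  p.emb = as<arma::mat>(lst["emb"]);
  IntegerVector ks = lst["kernel_sizes"];
  p.ks.assign(ks.begin(), ks.end());
  List cw = lst["conv_w"], cb = lst["conv_b"];
  for (int i = 0; i < cw.size(); ++i) {
    p.conv_w.push_back(as<arma::mat>(cw[i]));
    p.conv_b.push_back(as<arma::vec>(cb[i]));
  }
  p.w1 = as<arma::mat>(lst["w1"]);
  p.b1 = as<arma::rowvec>(lst["b1"]);
  p.g1 = as<arma::rowvec>(lst["g1"]);
  p.be1 = as<arma::rowvec>(lst["be1"]);
  p.bn1_mean = as<arma::rowvec>(lst["bn1_mean"]);
  p.bn1_var = as<arma::rowvec>(lst["bn1_var"]);
  p.w2 = as<arma::mat>(lst["w2"]);
  p.b2 = as<arma::rowvec>(lst["b2"]);
  p.g2 = as<arma::rowvec>(lst["g2"]);
  p.be2 = as<arma::rowvec>(lst["be2"]);
  p.bn2_mean = as<arma::rowvec>(lst["bn2_mean"]);
  p.bn2_var = as<arma::rowvec>(lst["bn2_var"]);
  p.w_out = as<arma::vec>(lst["w_out"]);
  p.b_out = as<double>(lst["b_out"]);
  p.E = p.emb.n_cols;
  p.d = p.conv_w[0].n_rows;
  p.P = p.d * static_cast<int>(p.ks.size());
  p.h1 = p.w1.n_cols;
  p.h2 = p.w2.n_cols;
  return p;
}

List to_list(const Params& p) {
  List cw(p.conv_w.size()), cb(p.conv_b.size());
  for (size_t i = 0; i < p.conv_w.size(); ++i) {
    cw[i] = wrap(p.conv_w[i]);
    cb[i] = wrap(p.conv_b[i]);
  }
  IntegerVector ks(p.ks.begin(), p.ks.end());
  return List::create(
      _["emb"] = wrap(p.emb), _["kernel_sizes"] = ks, _["conv_w"] = cw,
      _["conv_b"] = cb, _["w1"] = wrap(p.w1), _["b1"] = wrap(p.b1),
      _["g1"] = wrap(p.g1), _["be1"] = wrap(p.be1),
      _["bn1_mean"] = wrap(p.bn1_mean), _["bn1_var"] = wrap(p.bn1_var),
      _["w2"] = wrap(p.w2), _["b2"] = wrap(p.b2), _["g2"] = wrap(p.g2),
      _["be2"] = wrap(p.be2), _["bn2_mean"] = wrap(p.bn2_mean),
      _["bn2_var"] = wrap(p.bn2_var), _["w_out"] = wrap(p.w_out),
      _["b_out"] = p.b_out);
}

constexpr double BN_EPS = 1e-5;
constexpr double BN_MOMENTUM = 0.9;

std::vector<int> pad_doc(const IntegerVector& doc, int kmax) {
  std::vector<int> d(doc.begin(), doc.end());
  while (static_cast<int>(d.size()) < kmax) d.push_back(0);
  return d;
}

// Convolution + ReLU + global max-pool for one note. ReLU then max equals
// max then ReLU (both monotone), so we pool the raw activation and clamp.
// argpos[u] stores the window start (0-based) of the max activation.
void conv_pool(const std::vector<int>& doc, const Params& p,
               arma::rowvec& pooled, arma::rowvec& pooled_pre,
               std::vector<int>& argpos) {
  const int T = doc.size();
  arma::mat X(T, p.E);
  for (int t = 0; t < T; ++t) X.row(t) = p.emb.row(doc[t]);
  pooled.set_size(p.P);
  pooled_pre.set_size(p.P);
  argpos.assign(p.P, 0);
  for (size_t c = 0; c < p.ks.size(); ++c) {
    const int k = p.ks[c];
    const int n_win = T - k + 1;
    arma::mat wins(n_win, k * p.E);
    for (int t = 0; t < n_win; ++t)
      for (int j = 0; j < k; ++j)
        wins(t, arma::span(j * p.E, (j + 1) * p.E - 1)) = X.row(t + j);
    arma::mat A = wins * p.conv_w[c].t();           // n_win x d
    A.each_row() += p.conv_b[c].t();
    for (int f = 0; f < p.d; ++f) {
      arma::uword imax;
      const double amax = A.col(f).max(imax);
      const int u = static_cast<int>(c) * p.d + f;
      pooled_pre(u) = amax;
      pooled(u) = amax > 0.0 ? amax : 0.0;
      argpos[u] = static_cast<int>(imax);
    }
  }
}

// Fully connected head at inference (running batch-norm statistics).
double head_logit(const Params& p, const arma::rowvec& pooled) {
  arma::rowvec z1 = pooled * p.w1 + p.b1;
  arma::rowvec x1 = (z1 - p.bn1_mean) / arma::sqrt(p.bn1_var + BN_EPS);
  arma::rowvec a1 = arma::max(x1 % p.g1 + p.be1, arma::zeros<arma::rowvec>(p.h1));
  arma::rowvec z2 = a1 * p.w2 + p.b2;
  arma::rowvec x2 = (z2 - p.bn2_mean) / arma::sqrt(p.bn2_var + BN_EPS);
  arma::rowvec a2 = arma::max(x2 % p.g2 + p.be2, arma::zeros<arma::rowvec>(p.h2));
  return arma::dot(a2, p.w_out) + p.b_out;
}

double sigmoid(double x) { return 1.0 / (1.0 + std::exp(-x)); }

struct Adam {
  arma::mat m, v;
  void init(const arma::mat& shape) {
    m.zeros(shape.n_rows, shape.n_cols);
    v.zeros(shape.n_rows, shape.n_cols);
  }
  void step(arma::mat& p, const arma::mat& g, double lr, double c1, double c2) {
    m = 0.9 * m + 0.1 * g;
    v = 0.999 * v + 0.001 * (g % g);
    p -= lr * (m / c1) / (arma::sqrt(v / c2) + 1e-8);
  }
};

double eval_loss(const Params& p, const List& docs, const NumericVector& y,
                 int kmax) {
  double loss = 0.0;
  const int n = docs.size();
  for (int i = 0; i < n; ++i) {
    std::vector<int> doc = pad_doc(docs[i], kmax);
    arma::rowvec pooled, pre;
    std::vector<int> pos;
    conv_pool(doc, p, pooled, pre, pos);
    const double s = sigmoid(head_logit(p, pooled));
    const double eps = 1e-12;
    loss -= y[i] * std::log(s + eps) + (1.0 - y[i]) * std::log(1.0 - s + eps);
  }
  return loss / std::max(1, n);
}

}  // namespace

// [[Rcpp::export(name = ".cn_init")]]
List cn_init(int vocab_size, int embed_dim, IntegerVector kernel_sizes, int d,
             int h1, int h2, int seed, Nullable<NumericMatrix> emb_init) {
  DetRNG rng(static_cast<uint64_t>(seed) * 0xA24BAED4963EE407ULL + 3ULL);
  Params p;
  p.E = embed_dim;
  p.ks.assign(kernel_sizes.begin(), kernel_sizes.end());
  p.d = d;
  p.P = d * static_cast<int>(p.ks.size());
  p.h1 = h1;
  p.h2 = h2;
  p.emb.set_size(vocab_size + 1, embed_dim);
  if (emb_init.isNotNull()) {
    arma::mat e0 = as<arma::mat>(NumericMatrix(emb_init));
    if (static_cast<int>(e0.n_rows) != vocab_size ||
        static_cast<int>(e0.n_cols) != embed_dim)
      stop("embedding init must be vocab_size x embed_dim");
    p.emb.rows(1, vocab_size) = e0;
  } else {
    for (arma::uword i = 1; i < p.emb.n_rows; ++i)
      for (int j = 0; j < embed_dim; ++j)
        p.emb(i, j) = rng.normal() * 0.1;
  }
  p.emb.row(0).zeros();
  auto he = [&](arma::mat& w, int fan_in) {
    const double sd = std::sqrt(2.0 / fan_in);
    for (arma::uword i = 0; i < w.n_elem; ++i) w(i) = rng.normal() * sd;
  };
  for (int k : p.ks) {
    arma::mat w(d, k * embed_dim);
    he(w, k * embed_dim);
    p.conv_w.push_back(w);
    p.conv_b.push_back(arma::zeros<arma::vec>(d));
  }
  p.w1.set_size(p.P, h1); he(p.w1, p.P);
  p.b1.zeros(h1); p.g1.ones(h1); p.be1.zeros(h1);
  p.bn1_mean.zeros(h1); p.bn1_var.ones(h1);
  p.w2.set_size(h1, h2); he(p.w2, h1);
  p.b2.zeros(h2); p.g2.ones(h2); p.be2.zeros(h2);
  p.bn2_mean.zeros(h2); p.bn2_var.ones(h2);
  p.w_out.set_size(h2);
  for (int i = 0; i < h2; ++i) p.w_out(i) = rng.normal() * std::sqrt(1.0 / h2);
  p.b_out = 0.0;
  return to_list(p);
}

// [[Rcpp::export(name = ".cn_score")]]
NumericVector cn_score(List params, List docs) {
  Params p = from_list(params);
  const int kmax = *std::max_element(p.ks.begin(), p.ks.end());
  const int n = docs.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    std::vector<int> doc = pad_doc(docs[i], kmax);
    arma::rowvec pooled, pre;
    std::vector<int> pos;
    conv_pool(doc, p, pooled, pre, pos);
    out[i] = sigmoid(head_logit(p, pooled));
  }
  return out;
}

// [[Rcpp::export(name = ".cn_train")]]
List cn_train(List params, List docs, NumericVector y, List val_docs,
              NumericVector val_y, int epochs, int batch_size, double lr,
              double dropout, int seed) {
  Params p = from_list(params);
  const int kmax = *std::max_element(p.ks.begin(), p.ks.end());
  const int n = docs.size();
  DetRNG rng(static_cast<uint64_t>(seed) * 0xC2B2AE3D27D4EB4FULL + 11ULL);

  Adam a_emb; a_emb.init(p.emb);
  std::vector<Adam> a_cw(p.ks.size()), a_cb(p.ks.size());
  for (size_t c = 0; c < p.ks.size(); ++c) {
    a_cw[c].init(p.conv_w[c]);
    a_cb[c].init(arma::mat(p.conv_b[c]));
  }
  Adam a_w1, a_b1, a_g1, a_be1, a_w2, a_b2, a_g2, a_be2, a_wo, a_bo;
  a_w1.init(p.w1); a_b1.init(arma::mat(p.b1)); a_g1.init(arma::mat(p.g1));
  a_be1.init(arma::mat(p.be1)); a_w2.init(p.w2); a_b2.init(arma::mat(p.b2));
  a_g2.init(arma::mat(p.g2)); a_be2.init(arma::mat(p.be2));
  a_wo.init(arma::mat(p.w_out)); a_bo.init(arma::mat(1, 1));
  arma::mat bo_mat(1, 1); bo_mat(0, 0) = p.b_out;

  std::vector<int> order(n);
  for (int i = 0; i < n; ++i) order[i] = i;

  NumericVector tr_hist(epochs), val_hist(epochs);
  long tstep = 0;

  for (int ep = 0; ep < epochs; ++ep) {
    for (int i = n - 1; i > 0; --i)
      std::swap(order[i], order[rng.below(i + 1)]);
    double ep_loss = 0.0;
    int n_batches = 0;
    for (int start = 0; start < n; start += batch_size, ++n_batches) {
      const int B = std::min(batch_size, n - start);
      std::vector<std::vector<int>> bdocs(B);
      arma::vec by(B);
      arma::mat pooled(B, p.P);
      arma::mat pre(B, p.P);
      std::vector<std::vector<int>> argpos(B);
      for (int i = 0; i < B; ++i) {
        const int idx = order[start + i];
        bdocs[i] = pad_doc(docs[idx], kmax);
        by(i) = y[idx];
        arma::rowvec pv, pp;
        conv_pool(bdocs[i], p, pv, pp, argpos[i]);
        pooled.row(i) = pv;
        pre.row(i) = pp;
      }
      auto make_mask = [&](int rows, int cols) {
        arma::mat msk(rows, cols);
        if (dropout <= 0.0) { msk.ones(); return msk; }
        const double keep = 1.0 - dropout;
        for (arma::uword j = 0; j < msk.n_elem; ++j)
          msk(j) = rng.unif() < keep ? 1.0 / keep : 0.0;
        return msk;
      };
      arma::mat mask0 = make_mask(B, p.P);
      arma::mat pd = pooled % mask0;

      // FC1 + BN + ReLU + dropout
      arma::mat z1 = pd * p.w1; z1.each_row() += p.b1;
      arma::rowvec mu1 = arma::mean(z1, 0);
      arma::mat zc1 = z1.each_row() - mu1;
      arma::rowvec var1 = arma::mean(arma::square(zc1), 0);
      arma::rowvec inv1 = 1.0 / arma::sqrt(var1 + BN_EPS);
      arma::mat xhat1 = zc1.each_row() % inv1;
      arma::mat y1 = xhat1.each_row() % p.g1; y1.each_row() += p.be1;
      arma::mat relu1 = arma::conv_to<arma::mat>::from(y1 > 0.0);
      arma::mat mask1 = make_mask(B, p.h1);
      arma::mat a1 = (y1 % relu1) % mask1;

      // FC2 + BN + ReLU + dropout
      arma::mat z2 = a1 * p.w2; z2.each_row() += p.b2;
      arma::rowvec mu2 = arma::mean(z2, 0);
      arma::mat zc2 = z2.each_row() - mu2;
      arma::rowvec var2 = arma::mean(arma::square(zc2), 0);
      arma::rowvec inv2 = 1.0 / arma::sqrt(var2 + BN_EPS);
      arma::mat xhat2 = zc2.each_row() % inv2;
      arma::mat y2 = xhat2.each_row() % p.g2; y2.each_row() += p.be2;
      arma::mat relu2 = arma::conv_to<arma::mat>::from(y2 > 0.0);
      arma::mat mask2 = make_mask(B, p.h2);
      arma::mat a2 = (y2 % relu2) % mask2;

      arma::vec logits = a2 * p.w_out + p.b_out;
      arma::vec probs = 1.0 / (1.0 + arma::exp(-logits));
      const double eps = 1e-12;
      ep_loss += arma::as_scalar(
          -arma::mean(by % arma::log(probs + eps) +
                      (1.0 - by) % arma::log(1.0 - probs + eps)));

      // running statistics for inference
      p.bn1_mean = BN_MOMENTUM * p.bn1_mean + (1 - BN_MOMENTUM) * mu1;
      p.bn1_var = BN_MOMENTUM * p.bn1_var + (1 - BN_MOMENTUM) * var1;
      p.bn2_mean = BN_MOMENTUM * p.bn2_mean + (1 - BN_MOMENTUM) * mu2;
      p.bn2_var = BN_MOMENTUM * p.bn2_var + (1 - BN_MOMENTUM) * var2;

      // ---- backward ----
      arma::vec dlogit = (probs - by) / B;
      arma::mat dwo = a2.t() * dlogit;            // h2 x 1
      const double dbo = arma::accu(dlogit);
      arma::mat da2 = dlogit * p.w_out.t();       // B x h2
      da2 %= mask2;
      arma::mat dy2 = da2 % relu2;
      arma::rowvec dg2 = arma::sum(dy2 % xhat2, 0);
      arma::rowvec dbe2v = arma::sum(dy2, 0);
      arma::mat dz2 = dy2 * static_cast<double>(B);
      dz2.each_row() -= dbe2v;
      dz2 -= xhat2.each_row() % dg2;
      dz2.each_row() %= (p.g2 % inv2) / B;
      arma::mat dw2 = a1.t() * dz2;
      arma::rowvec db2v = arma::sum(dz2, 0);
      arma::mat da1 = dz2 * p.w2.t();
      da1 %= mask1;
      arma::mat dy1 = da1 % relu1;
      arma::rowvec dg1 = arma::sum(dy1 % xhat1, 0);
      arma::rowvec dbe1v = arma::sum(dy1, 0);
      arma::mat dz1 = dy1 * static_cast<double>(B);
      dz1.each_row() -= dbe1v;
      dz1 -= xhat1.each_row() % dg1;
      dz1.each_row() %= (p.g1 % inv1) / B;
      arma::mat dw1 = pd.t() * dz1;
      arma::rowvec db1v = arma::sum(dz1, 0);
      arma::mat dpd = dz1 * p.w1.t();
      arma::mat dpooled = dpd % mask0;

      arma::mat demb(p.emb.n_rows, p.E, arma::fill::zeros);
      std::vector<arma::mat> dcw(p.ks.size());
      std::vector<arma::vec> dcb(p.ks.size());
      for (size_t c = 0; c < p.ks.size(); ++c) {
        dcw[c].zeros(p.d, p.ks[c] * p.E);
        dcb[c].zeros(p.d);
      }
      for (int i = 0; i < B; ++i) {
        for (size_t c = 0; c < p.ks.size(); ++c) {
          const int k = p.ks[c];
          for (int f = 0; f < p.d; ++f) {
            const int u = static_cast<int>(c) * p.d + f;
            const double g = dpooled(i, u);
            if (g == 0.0 || pre(i, u) <= 0.0) continue;
            const int t0 = argpos[i][u];
            for (int j = 0; j < k; ++j) {
              const int tok = bdocs[i][t0 + j];
              dcw[c](f, arma::span(j * p.E, (j + 1) * p.E - 1)) +=
                  g * p.emb.row(tok);
              if (tok != 0)
                demb.row(tok) +=
                    g * p.conv_w[c](f, arma::span(j * p.E, (j + 1) * p.E - 1));
            }
            dcb[c](f) += g;
          }
        }
      }
      demb.row(0).zeros();

      ++tstep;
      const double c1 = 1.0 - std::pow(0.9, tstep);
      const double c2 = 1.0 - std::pow(0.999, tstep);
      a_emb.step(p.emb, demb, lr, c1, c2);
      p.emb.row(0).zeros();
      for (size_t c = 0; c < p.ks.size(); ++c) {
        a_cw[c].step(p.conv_w[c], dcw[c], lr, c1, c2);
        arma::mat cb_mat(p.conv_b[c]);
        a_cb[c].step(cb_mat, arma::mat(dcb[c]), lr, c1, c2);
        p.conv_b[c] = cb_mat;
      }
      a_w1.step(p.w1, dw1, lr, c1, c2);
      arma::mat tmp;
      tmp = arma::mat(p.b1); a_b1.step(tmp, arma::mat(db1v), lr, c1, c2); p.b1 = tmp;
      tmp = arma::mat(p.g1); a_g1.step(tmp, arma::mat(dg1), lr, c1, c2); p.g1 = tmp;
      tmp = arma::mat(p.be1); a_be1.step(tmp, arma::mat(dbe1v), lr, c1, c2); p.be1 = tmp;
      a_w2.step(p.w2, dw2, lr, c1, c2);
      tmp = arma::mat(p.b2); a_b2.step(tmp, arma::mat(db2v), lr, c1, c2); p.b2 = tmp;
      tmp = arma::mat(p.g2); a_g2.step(tmp, arma::mat(dg2), lr, c1, c2); p.g2 = tmp;
      tmp = arma::mat(p.be2); a_be2.step(tmp, arma::mat(dbe2v), lr, c1, c2); p.be2 = tmp;
      tmp = arma::mat(p.w_out); a_wo.step(tmp, dwo, lr, c1, c2); p.w_out = tmp.col(0);
      arma::mat dbo_mat(1, 1); dbo_mat(0, 0) = dbo;
      a_bo.step(bo_mat, dbo_mat, lr, c1, c2);
      p.b_out = bo_mat(0, 0);
    }
    tr_hist[ep] = ep_loss / std::max(1, n_batches);
    val_hist[ep] = val_docs.size() > 0 ? eval_loss(p, val_docs, val_y, kmax)
                                       : NA_REAL;
  }

  return List::create(_["params"] = to_list(p), _["train_loss"] = tr_hist,
                      _["val_loss"] = val_hist);
}

// Fully connected head on an explicit pooled vector (inference mode).
// [[Rcpp::export(name = ".cn_head_logit")]]
double cn_head_logit(List params, NumericVector pooled) {
  Params p = from_list(params);
  if (static_cast<int>(pooled.size()) != p.P)
    stop("pooled vector must have length %d", p.P);
  arma::rowvec pv(pooled.begin(), pooled.size());
  return head_logit(p, pv);
}

// Pooled-unit occlusion attribution: contribution of unit u is
// logit(full) - logit(with pooled[u] set to 0), in log-odds units.
// [[Rcpp::export(name = ".cn_attribute")]]
List cn_attribute(List params, IntegerVector doc) {
  Params p = from_list(params);
  const int kmax = *std::max_element(p.ks.begin(), p.ks.end());
  std::vector<int> d = pad_doc(doc, kmax);
  arma::rowvec pooled, pre;
  std::vector<int> argpos;
  conv_pool(d, p, pooled, pre, argpos);
  const double base = head_logit(p, pooled);

  IntegerVector unit_kernel(p.P), unit_start(p.P);
  NumericVector contribution(p.P);
  for (int u = 0; u < p.P; ++u) {
    const int c = u / p.d;
    unit_kernel[u] = p.ks[c];
    unit_start[u] = argpos[u] + 1;  // 1-based for R
    if (pooled(u) == 0.0) {
      contribution[u] = 0.0;
      continue;
    }
    arma::rowvec occ = pooled;
    occ(u) = 0.0;
    contribution[u] = base - head_logit(p, occ);
  }
  return List::create(_["base_logit"] = base, _["score"] = sigmoid(base),
                      _["unit_kernel"] = unit_kernel,
                      _["unit_start"] = unit_start,
                      _["contribution"] = contribution,
                      _["pooled"] = wrap(pooled));
}
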