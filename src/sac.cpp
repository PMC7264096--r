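// [[Rcpp::depends(RcppArmadillo)]]
#include "jaw_core.h"
#include <cmath>

using namespace Rcpp;
using arma::mat;
using arma::vec;
using arma::rowvec;

// Soft Actor-Critic with a tanh-squashed Gaussian policy, twin critics,
// EMA target critics, Adam, and a uniform replay buffer. Networks are
// multi-layer perceptrons with two ReLU hidden layers. All randomness is
// drawn from the R RNG so runs are reproducible under set.seed().

namespace {

constexpr double LOG_SQRT_2PI = 0.9189385332046727;  // log(sqrt(2*pi))
constexpr double LS_MIN = -20.0, LS_MAX = 2.0;       // log-sigma clamp

struct Dense {
  mat W; vec b;
  mat mW, vW; vec mb, vb;  // Adam moments
  void init(int in, int out) {
    const double lim = std::sqrt(6.0 / (in + out));  // Xavier uniform
    W.set_size(out, in);
    for (arma::uword i = 0; i < W.n_elem; ++i)
      W(i) = (2.0 * unif_rand() - 1.0) * lim;
    b.zeros(out);
    mW.zeros(out, in); vW.zeros(out, in); mb.zeros(out); vb.zeros(out);
  }
  mat fwd(const mat& X) const { mat Y = W * X; Y.each_col() += b; return Y; }
};

void adam_step(Dense& d, const mat& gW, const vec& gb, double lr, long t,
               double b1 = 0.9, double b2 = 0.999, double eps = 1e-8) {
  d.mW = b1 * d.mW + (1 - b1) * gW;
  d.vW = b2 * d.vW + (1 - b2) * arma::square(gW);
  d.mb = b1 * d.mb + (1 - b1) * gb;
  d.vb = b2 * d.vb + (1 - b2) * arma::square(gb);
  const double c1 = 1.0 - std::pow(b1, (double) t);
  const double c2 = 1.0 - std::pow(b2, (double) t);
  d.W -= lr * (d.mW / c1) / (arma::sqrt(d.vW / c2) + eps);
  d.b -= lr * (d.mb / c1) / (arma::sqrt(d.vb / c2) + eps);
}

struct Critic {
  Dense l1, l2, l3;
  void init(int in, int h) { l1.init(in, h); l2.init(h, h); l3.init(h, 1); }
};

struct CriticCache { mat X, h1, h2; rowvec q; };

void critic_fwd(const Critic& c, const mat& X, CriticCache& cc) {
  cc.X = X;
  cc.h1 = arma::clamp(c.l1.fwd(X), 0.0, arma::datum::inf);
  cc.h2 = arma::clamp(c.l2.fwd(cc.h1), 0.0, arma::datum::inf);
  cc.q = arma::conv_to<rowvec>::from(c.l3.fwd(cc.h2));
}

rowvec critic_eval(const Critic& c, const mat& X) {
  CriticCache cc; critic_fwd(c, X, cc); return cc.q;
}

struct CriticGrads { mat gW1, gW2, gW3; vec gb1, gb2, gb3; mat dX; };

void critic_bwd(const Critic& c, const CriticCache& cc, const rowvec& dq,
                CriticGrads& g, bool want_dx) {
  mat dqm(1, dq.n_elem);
  dqm.row(0) = dq;
  g.gW3 = dqm * cc.h2.t();
  g.gb3 = arma::sum(dqm, 1);
  mat dh2 = (c.l3.W.t() * dqm) % arma::conv_to<mat>::from(cc.h2 > 0);
  g.gW2 = dh2 * cc.h1.t();
  g.gb2 = arma::sum(dh2, 1);
  mat dh1 = (c.l2.W.t() * dh2) % arma::conv_to<mat>::from(cc.h1 > 0);
  g.gW1 = dh1 * cc.X.t();
  g.gb1 = arma::sum(dh1, 1);
  if (want_dx) g.dX = c.l1.W.t() * dh1;
}

struct Policy {
  Dense l1, l2, mu, ls;
  void init(int in, int h, int out) {
    l1.init(in, h); l2.init(h, h); mu.init(h, out); ls.init(h, out);
  }
};

struct PolicyCache {
  mat X, h1, h2, mu, ls, lsmask, sigma, xi, z, t;
  rowvec logp;
};

inline double softplus(double x) {
  return x > 0 ? x + std::log1p(std::exp(-x)) : std::log1p(std::exp(x));
}

// forward + (optionally) reparameterized sampling; log-density includes the
// tanh change-of-variables correction log|det dt/dz| = sum log(1 - t^2)
void policy_fwd(const Policy& p, const mat& X, bool deterministic,
                bool zero_noise, double bound, PolicyCache& pc) {
  pc.X = X;
  pc.h1 = arma::clamp(p.l1.fwd(X), 0.0, arma::datum::inf);
  pc.h2 = arma::clamp(p.l2.fwd(pc.h1), 0.0, arma::datum::inf);
  pc.mu = p.mu.fwd(pc.h2);
  mat ls_raw = p.ls.fwd(pc.h2);
  pc.lsmask = arma::conv_to<mat>::from(ls_raw > LS_MIN && ls_raw < LS_MAX);
  pc.ls = arma::clamp(ls_raw, LS_MIN, LS_MAX);
  pc.sigma = arma::exp(pc.ls);
  pc.xi.set_size(arma::size(pc.mu));
  if (deterministic || zero_noise) {
    pc.xi.zeros();
  } else {
    for (arma::uword i = 0; i < pc.xi.n_elem; ++i) pc.xi(i) = norm_rand();
  }
  pc.z = pc.mu + pc.sigma % pc.xi;
  pc.t = arma::tanh(pc.z);
  const arma::uword A = pc.mu.n_rows, B = pc.mu.n_cols;
  pc.logp.zeros(B);
  for (arma::uword j = 0; j < B; ++j) {
    double lp = 0.0;
    for (arma::uword i = 0; i < A; ++i) {
      const double z = pc.z(i, j);
      // log(1 - tanh(z)^2) = 2 (log 2 - z - softplus(-2z)), stable
      const double log1mt2 = 2.0 * (std::log(2.0) - z - softplus(-2.0 * z));
      // density over the tanh-squashed action t in [-1,1]; the
      // environment-scale bound is applied outside the networks
      lp += -0.5 * pc.xi(i, j) * pc.xi(i, j) - LOG_SQRT_2PI - pc.ls(i, j)
            - log1mt2;
    }
    pc.logp(j) = lp;
  }
}

struct PolicyGrads { mat gW1, gW2, gWmu, gWls; vec gb1, gb2, gbmu, gbls; };

// backprop given gradients at the mu / log-sigma heads (pre-clamp)
void policy_bwd(const Policy& p, const PolicyCache& pc, const mat& gmu,
                const mat& gls_in, PolicyGrads& g) {
  mat gls = gls_in % pc.lsmask;
  g.gWmu = gmu * pc.h2.t();  g.gbmu = arma::sum(gmu, 1);
  g.gWls = gls * pc.h2.t();  g.gbls = arma::sum(gls, 1);
  mat dh2 = (p.mu.W.t() * gmu + p.ls.W.t() * gls) % arma::conv_to<mat>::from(pc.h2 > 0);
  g.gW2 = dh2 * pc.h1.t();   g.gb2 = arma::sum(dh2, 1);
  mat dh1 = (p.l2.W.t() * dh2) % arma::conv_to<mat>::from(pc.h1 > 0);
  g.gW1 = dh1 * pc.X.t();    g.gb1 = arma::sum(dh1, 1);
}

struct SAC {
  int obs_dim, act_dim, hidden;
  double gamma, alpha, tau, lr_start, lr_floor, lr_decay, bound;
  long n_updates = 0;
  long t_pi = 0, t_q = 0;  // Adam step counters
  Policy pi;
  Critic q1, q2, qt1, qt2;
  mat S, A, S2; vec Rr, Dn;  // replay ring
  int cap = 0, size = 0, pos = 0;

  double lr() const {
    const double v = lr_start * std::pow(lr_decay, (double) n_updates);
    return v > lr_floor ? v : lr_floor;
  }
  mat act(const mat& obs, bool deterministic, rowvec* logp = nullptr) {
    PolicyCache pc;
    policy_fwd(pi, obs, deterministic, false, bound, pc);
    if (logp) *logp = pc.logp;
    return bound * pc.t;
  }
  // soft state value at s' under the target critics (Bellman backup)
  rowvec soft_value(const mat& S2m) {
    PolicyCache pc;
    policy_fwd(pi, S2m, false, false, bound, pc);
    mat X2 = arma::join_cols(S2m, pc.t);  // critics see tanh units
    rowvec qmin = arma::min(critic_eval(qt1, X2), critic_eval(qt2, X2));
    return qmin - alpha * pc.logp;
  }
  double critic_update(const mat& Sm, const mat& Am, const mat& S2m,
                       const vec& r, const vec& done) {
    const double B = (double) Sm.n_cols;
    rowvec v2 = soft_value(S2m);
    rowvec y = r.t() + gamma * (1.0 - done.t()) % v2;
    mat X = arma::join_cols(Sm, Am);
    CriticCache c1, c2;
    critic_fwd(q1, X, c1);
    critic_fwd(q2, X, c2);
    const double loss = arma::accu(arma::square(c1.q - y)) / B +
                        arma::accu(arma::square(c2.q - y)) / B;
    const double lr_now = lr();
    CriticGrads g1, g2;
    critic_bwd(q1, c1, 2.0 * (c1.q - y) / B, g1, false);
    critic_bwd(q2, c2, 2.0 * (c2.q - y) / B, g2, false);
    ++t_q;
    adam_step(q1.l1, g1.gW1, g1.gb1, lr_now, t_q);
    adam_step(q1.l2, g1.gW2, g1.gb2, lr_now, t_q);
    adam_step(q1.l3, g1.gW3, g1.gb3, lr_now, t_q);
    adam_step(q2.l1, g2.gW1, g2.gb1, lr_now, t_q);
    adam_step(q2.l2, g2.gW2, g2.gb2, lr_now, t_q);
    adam_step(q2.l3, g2.gW3, g2.gb3, lr_now, t_q);
    return loss;
  }
  // returns the objective estimate E[min Q - alpha log pi]; entropy_out
  // gets -mean(log pi)
  double actor_update(const mat& Sm, bool zero_noise, bool apply,
                      double* entropy_out = nullptr) {
    const double B = (double) Sm.n_cols;
    PolicyCache pc;
    policy_fwd(pi, Sm, false, zero_noise, bound, pc);
    mat Xa = arma::join_cols(Sm, pc.t);
    CriticCache c1, c2;
    critic_fwd(q1, Xa, c1);
    critic_fwd(q2, Xa, c2);
    rowvec qmin = arma::min(c1.q, c2.q);
    const double objective = arma::mean(qmin - alpha * pc.logp);
    if (entropy_out) *entropy_out = -arma::mean(pc.logp);
    if (!apply) return objective;
    // route d mean(minQ)/da through the per-sample argmin critic
    rowvec pick1 = arma::conv_to<rowvec>::from(c1.q <= c2.q);
    CriticGrads g1, g2;
    critic_bwd(q1, c1, pick1 / B, g1, true);
    critic_bwd(q2, c2, (1.0 - pick1) / B, g2, true);
    mat Qa = g1.dX.rows(obs_dim, obs_dim + act_dim - 1) +
             g2.dX.rows(obs_dim, obs_dim + act_dim - 1);
    // loss = -objective; d loss/dz and direct log-sigma term
    mat one_m_t2 = 1.0 - arma::square(pc.t);
    mat gz = -Qa % one_m_t2 + (alpha / B) * 2.0 * pc.t;
    mat gmu = gz;
    mat gls = gz % (pc.sigma % pc.xi) - alpha / B;
    PolicyGrads pg;
    policy_bwd(pi, pc, gmu, gls, pg);
    const double lr_now = lr();
    ++t_pi;
    adam_step(pi.l1, pg.gW1, pg.gb1, lr_now, t_pi);
    adam_step(pi.l2, pg.gW2, pg.gb2, lr_now, t_pi);
    adam_step(pi.mu, pg.gWmu, pg.gbmu, lr_now, t_pi);
    adam_step(pi.ls, pg.gWls, pg.gbls, lr_now, t_pi);
    return objective;
  }
  void update_targets(double tau_use) {
    auto ema = [&](Dense& tgt, const Dense& src) {
      tgt.W = tau_use * src.W + (1.0 - tau_use) * tgt.W;
      tgt.b = tau_use * src.b + (1.0 - tau_use) * tgt.b;
    };
    ema(qt1.l1, q1.l1); ema(qt1.l2, q1.l2); ema(qt1.l3, q1.l3);
    ema(qt2.l1, q2.l1); ema(qt2.l2, q2.l2); ema(qt2.l3, q2.l3);
  }
  void store(const vec& s, const vec& a, const vec& s2, double r, double d) {
    S.col(pos) = s; A.col(pos) = a / bound; S2.col(pos) = s2;
    Rr(pos) = r; Dn(pos) = d;
    pos = (pos + 1) % cap;
    if (size < cap) ++size;
  }
};

List dense_to_list(const Dense& d) {
  return List::create(_["W"] = d.W, _["b"] = d.b);
}
void dense_from_list(Dense& d, const List& l, bool reset_adam) {
  d.W = as<mat>(l["W"]); d.b = as<vec>(l["b"]);
  if (reset_adam) {
    d.mW.zeros(arma::size(d.W)); d.vW.zeros(arma::size(d.W));
    d.mb.zeros(d.b.n_elem); d.vb.zeros(d.b.n_elem);
  }
}
List critic_to_list(const Critic& c) {
  return List::create(_["l1"] = dense_to_list(c.l1),
                      _["l2"] = dense_to_list(c.l2),
                      _["l3"] = dense_to_list(c.l3));
}
void critic_from_list(Critic& c, const List& l, bool reset_adam) {
  dense_from_list(c.l1, l["l1"], reset_adam);
  dense_from_list(c.l2, l["l2"], reset_adam);
  dense_from_list(c.l3, l["l3"], reset_adam);
}

}  // namespace

// [[Rcpp::export]]
SEXP cpp_sac_new(int obs_dim, int act_dim, int hidden, double gamma,
                 double alpha, double tau, double lr_start, double lr_floor,
                 double lr_decay, double bound, int buffer_capacity) {
  XPtr<SAC> p(new SAC(), true);
  p->obs_dim = obs_dim; p->act_dim = act_dim; p->hidden = hidden;
  p->gamma = gamma; p->alpha = alpha; p->tau = tau;
  p->lr_start = lr_start; p->lr_floor = lr_floor; p->lr_decay = lr_decay;
  p->bound = bound;
  p->pi.init(obs_dim, hidden, act_dim);
  p->q1.init(obs_dim + act_dim, hidden);
  p->q2.init(obs_dim + act_dim, hidden);
  p->qt1 = p->q1; p->qt2 = p->q2;
  p->cap = buffer_capacity;
  p->S.set_size(obs_dim, buffer_capacity);
  p->A.set_size(act_dim, buffer_capacity);
  p->S2.set_size(obs_dim, buffer_capacity);
  p->Rr.set_size(buffer_capacity);
  p->Dn.set_size(buffer_capacity);
  return p;
}

// [[Rcpp::export]]
List cpp_sac_get_weights(SEXP ptr) {
  XPtr<SAC> p(ptr);
  return List::create(
    _["policy"] = List::create(_["l1"] = dense_to_list(p->pi.l1),
                               _["l2"] = dense_to_list(p->pi.l2),
                               _["mu"] = dense_to_list(p->pi.mu),
                               _["ls"] = dense_to_list(p->pi.ls)),
    _["q1"] = critic_to_list(p->q1), _["q2"] = critic_to_list(p->q2),
    _["qt1"] = critic_to_list(p->qt1), _["qt2"] = critic_to_list(p->qt2),
    _["n_updates"] = (double) p->n_updates);
}

// [[Rcpp::export]]
void cpp_sac_set_weights(SEXP ptr, List w, bool reset_adam = true) {
  XPtr<SAC> p(ptr);
  if (w.containsElementNamed("policy")) {
    List pl = w["policy"];
    dense_from_list(p->pi.l1, pl["l1"], reset_adam);
    dense_from_list(p->pi.l2, pl["l2"], reset_adam);
    dense_from_list(p->pi.mu, pl["mu"], reset_adam);
    dense_from_list(p->pi.ls, pl["ls"], reset_adam);
  }
  if (w.containsElementNamed("q1")) critic_from_list(p->q1, w["q1"], reset_adam);
  if (w.containsElementNamed("q2")) critic_from_list(p->q2, w["q2"], reset_adam);
  if (w.containsElementNamed("qt1")) critic_from_list(p->qt1, w["qt1"], reset_adam);
  if (w.containsElementNamed("qt2")) critic_from_list(p->qt2, w["qt2"], reset_adam);
  if (w.containsElementNamed("n_updates"))
    p->n_updates = (long) as<double>(w["n_updates"]);
}

// [[Rcpp::export]]
List cpp_sac_act(SEXP ptr, arma::mat obs, bool deterministic) {
  XPtr<SAC> p(ptr);
  rowvec logp;
  mat a = p->act(obs, deterministic, &logp);
  return List::create(_["action"] = a, _["logp"] = logp);
}

// [[Rcpp::export]]
List cpp_sac_policy_params(SEXP ptr, arma::mat obs) {
  XPtr<SAC> p(ptr);
  PolicyCache pc;
  policy_fwd(p->pi, obs, true, true, p->bound, pc);
  return List::create(_["mu"] = pc.mu, _["sigma"] = pc.sigma);
}

// [[Rcpp::export]]
List cpp_sac_q(SEXP ptr, arma::mat S, arma::mat A, bool target = false) {
  XPtr<SAC> p(ptr);
  mat X = arma::join_cols(S, A / p->bound);
  rowvec a1 = critic_eval(target ? p->qt1 : p->q1, X);
  rowvec a2 = critic_eval(target ? p->qt2 : p->q2, X);
  return List::create(_["q1"] = a1, _["q2"] = a2,
                      _["qmin"] = arma::min(a1, a2));
}

// [[Rcpp::export]]
arma::rowvec cpp_sac_soft_value(SEXP ptr, arma::mat S2) {
  XPtr<SAC> p(ptr);
  return p->soft_value(S2);
}

// [[Rcpp::export]]
double cpp_sac_critic_update(SEXP ptr, arma::mat S, arma::mat A,
                             arma::mat S2, arma::vec r, arma::vec done) {
  XPtr<SAC> p(ptr);
  if (S.n_cols == 0) stop("empty batch");
  double loss = p->critic_update(S, A / p->bound, S2, r, done);
  ++p->n_updates;
  return loss;
}

// [[Rcpp::export]]
double cpp_sac_actor_update(SEXP ptr, arma::mat S, bool zero_noise = false) {
  XPtr<SAC> p(ptr);
  if (S.n_cols == 0) stop("empty batch");
  return p->actor_update(S, zero_noise, true);
}

// [[Rcpp::export]]
void cpp_sac_update_targets(SEXP ptr, double tau = -1.0) {
  XPtr<SAC> p(ptr);
  p->update_targets(tau < 0 ? p->tau : tau);
}

// [[Rcpp::export]]
List cpp_sac_info(SEXP ptr) {
  XPtr<SAC> p(ptr);
  return List::create(_["lr"] = p->lr(), _["n_updates"] = (double) p->n_updates,
                      _["buffer_size"] = p->size,
                      _["buffer_capacity"] = p->cap,
                      _["obs_dim"] = p->obs_dim, _["act_dim"] = p->act_dim,
                      _["hidden"] = p->hidden, _["alpha"] = p->alpha,
                      _["gamma"] = p->gamma, _["tau"] = p->tau,
                      _["bound"] = p->bound);
}

// [[Rcpp::export]]
void cpp_sac_store(SEXP ptr, arma::vec s, arma::vec a, arma::vec s2,
                   double r, double done) {
  XPtr<SAC> p(ptr);
  p->store(s, a, s2, r, done);
}

// [[Rcpp::export]]
List cpp_sac_buffer_batch(SEXP ptr, arma::uvec idx) {
  XPtr<SAC> p(ptr);
  idx -= 1;  // 1-based from R
  arma::mat S = p->S.cols(idx), A = p->bound * p->A.cols(idx);
  arma::mat S2 = p->S2.cols(idx);
  arma::vec r = p->Rr(idx), d = p->Dn(idx);
  return List::create(_["s"] = S, _["a"] = A, _["s_next"] = S2,
                      _["r"] = r, _["done"] = d);
}

// [[Rcpp::export]]
arma::vec cpp_sac_buffer_rewards(SEXP ptr) {
  XPtr<SAC> p(ptr);
  return p->Rr.head(p->size);
}

// --- loss / gradient probes (used by finite-difference tests) ----------

// [[Rcpp::export]]
double cpp_sac_critic_loss_y(SEXP ptr, arma::mat S, arma::mat A,
                             arma::rowvec y) {
  XPtr<SAC> p(ptr);
  mat X = arma::join_cols(S, A / p->bound);
  rowvec d1 = critic_eval(p->q1, X) - y, d2 = critic_eval(p->q2, X) - y;
  const double B = (double) S.n_cols;
  return arma::accu(arma::square(d1)) / B + arma::accu(arma::square(d2)) / B;
}

// [[Rcpp::export]]
arma::vec cpp_sac_critic_grads_y(SEXP ptr, arma::mat S, arma::mat A,
                                 arma::rowvec y) {
  XPtr<SAC> p(ptr);
  mat X = arma::join_cols(S, A / p->bound);
  const double B = (double) S.n_cols;
  CriticCache c1, c2;
  critic_fwd(p->q1, X, c1);
  critic_fwd(p->q2, X, c2);
  CriticGrads g1, g2;
  critic_bwd(p->q1, c1, 2.0 * (c1.q - y) / B, g1, false);
  critic_bwd(p->q2, c2, 2.0 * (c2.q - y) / B, g2, false);
  return arma::join_cols(
    arma::join_cols(arma::vectorise(g1.gW1), g1.gb1,
                    arma::vectorise(g1.gW2), g1.gb2),
    arma::join_cols(arma::vectorise(g1.gW3), g1.gb3),
    arma::join_cols(arma::vectorise(g2.gW1), g2.gb1,
                    arma::vectorise(g2.gW2), g2.gb2),
    arma::join_cols(arma::vectorise(g2.gW3), g2.gb3));
}

// [[Rcpp::export]]
arma::vec cpp_sac_get_flat(SEXP ptr, std::string which) {
  XPtr<SAC> p(ptr);
  auto flat_d = [](const Dense& d) -> arma::vec {
    return arma::join_cols(arma::vectorise(d.W), d.b);
  };
  if (which == "q1" || which == "q2") {
    const Critic& c = which == "q1" ? p->q1 : p->q2;
    return arma::join_cols(flat_d(c.l1), flat_d(c.l2), flat_d(c.l3));
  }
  return arma::join_cols(arma::join_cols(flat_d(p->pi.l1), flat_d(p->pi.l2)),
                         arma::join_cols(flat_d(p->pi.mu), flat_d(p->pi.ls)));
}

// [[Rcpp::export]]
void cpp_sac_set_flat(SEXP ptr, std::string which, arma::vec theta) {
  XPtr<SAC> p(ptr);
  arma::uword off = 0;
  auto unflat_d = [&](Dense& d) {
    for (arma::uword j = 0; j < d.W.n_cols; ++j)
      for (arma::uword i = 0; i < d.W.n_rows; ++i) d.W(i, j) = theta(off++);
    for (arma::uword i = 0; i < d.b.n_elem; ++i) d.b(i) = theta(off++);
  };
  if (which == "q1" || which == "q2") {
    Critic& c = which == "q1" ? p->q1 : p->q2;
    unflat_d(c.l1); unflat_d(c.l2); unflat_d(c.l3);
  } else {
    unflat_d(p->pi.l1); unflat_d(p->pi.l2);
    unflat_d(p->pi.mu); unflat_d(p->pi.ls);
  }
}

// [[Rcpp::export]]
double cpp_sac_actor_loss(SEXP ptr, arma::mat S) {
  XPtr<SAC> p(ptr);
  return -p->actor_update(S, true, false);  // zero-noise, no parameter step
}

// [[Rcpp::export]]
arma::vec cpp_sac_actor_grads(SEXP ptr, arma::mat S) {
  // gradient of the zero-noise actor loss w.r.t. policy parameters,
  // replicating actor_update's backward pass without stepping
  XPtr<SAC> p(ptr);
  const double B = (double) S.n_cols;
  PolicyCache pc;
  policy_fwd(p->pi, S, false, true, p->bound, pc);
  mat Xa = arma::join_cols(S, pc.t);
  CriticCache c1, c2;
  critic_fwd(p->q1, Xa, c1);
  critic_fwd(p->q2, Xa, c2);
  rowvec pick1 = arma::conv_to<rowvec>::from(c1.q <= c2.q);
  CriticGrads g1, g2;
  critic_bwd(p->q1, c1, pick1 / B, g1, true);
  critic_bwd(p->q2, c2, (1.0 - pick1) / B, g2, true);
  mat Qa = g1.dX.rows(p->obs_dim, p->obs_dim + p->act_dim - 1) +
           g2.dX.rows(p->obs_dim, p->obs_dim + p->act_dim - 1);
  mat gz = -Qa % (1.0 - arma::square(pc.t)) +
           (p->alpha / B) * 2.0 * pc.t;
  mat gls = gz % (pc.sigma % pc.xi) - p->alpha / B;
  PolicyGrads pg;
  policy_bwd(p->pi, pc, gz, gls, pg);
  return arma::join_cols(
    arma::join_cols(arma::vectorise(pg.gW1), pg.gb1,
                    arma::vectorise(pg.gW2), pg.gb2),
    arma::join_cols(arma::vectorise(pg.gWmu), pg.gbmu,
                    arma::vectorise(pg.gWls), pg.gbls));
}

// --- training loop ------------------------------------------------------

// [[Rcpp::export]]
List cpp_sac_train(SEXP ptr, List core_list, arma::mat endpoints,
                   arma::vec pos_scale, double vel_scale,
                   List reward_w, List episode_cfg,
                   int total_steps, int batch_size, int warmup,
                   int stats_every, int updates_per_step = 1,
                   int random_steps = 0) {
  XPtr<SAC> p(ptr);
  posselt::JawCore core = posselt::core_from_list(core_list);
  const double w_u = as<double>(reward_w["w_u"]);
  const double w_r = as<double>(reward_w["w_r"]);
  const double w_s = as<double>(reward_w["w_s"]);
  const double eps_d = as<double>(reward_w["epsilon"]);
  const int T = as<int>(episode_cfg["max_steps"]);
  const double success_radius = as<double>(episode_cfg["success_radius"]);
  const int K = as<int>(episode_cfg["substeps"]);
  const double dt = as<double>(episode_cfg["dt"]);
  const int n_mus = (int) core.anchors.n_rows;
  const int half = n_mus / 2;
  const int obs_dim = p->obs_dim;

  arma::vec P(3, arma::fill::zeros), v(3, arma::fill::zeros);
  arma::vec e(n_mus, arma::fill::zeros), tensions(n_mus);
  arma::vec tgt(3);
  int ep_steps = 0;
  double ep_return = 0.0;
  bool need_reset = true;
  double dist = arma::datum::inf;
  int n_episodes = 0;

  auto sample_target = [&]() {
    arma::vec out(3);
    if (unif_rand() < 0.5) {
      arma::vec w(8);
      for (int i = 0; i < 8; ++i) w(i) = unif_rand();
      w /= arma::accu(w);
      out = endpoints.t() * w;
    } else {
      int i = std::min(7, (int) (unif_rand() * 8));
      int j = std::min(7, (int) (unif_rand() * 8));
      double lam = unif_rand();
      out = lam * endpoints.row(i).t() + (1.0 - lam) * endpoints.row(j).t();
    }
    return out;
  };
  auto build_obs = [&]() {
    arma::vec o(obs_dim);
    o.head(n_mus) = e;
    o.subvec(n_mus, n_mus + 2) = P / pos_scale;
    o.subvec(n_mus + 3, n_mus + 5) = v / vel_scale;
    o.subvec(n_mus + 6, n_mus + 8) = tgt / pos_scale;
    return o;
  };

  std::vector<double> ep_rows;    // episode, steps, return, final_dist, success
  std::vector<double> upd_rows;   // env_step, critic_loss, actor_obj, entropy, lr

  for (int step = 1; step <= total_steps; ++step) {
    if (need_reset) {
      P.zeros(); v.zeros(); e.zeros();
      tgt = sample_target();
      ep_steps = 0; ep_return = 0.0;
      need_reset = false;
    }
    arma::vec obs = build_obs();
    mat a;
    if (step <= random_steps) {        // uniform warm-up exploration
      a.set_size(p->act_dim, 1);
      for (int i = 0; i < p->act_dim; ++i)
        a(i, 0) = p->bound * (2.0 * unif_rand() - 1.0);
    } else {
      a = p->act(obs, false);
    }
    e = arma::clamp(e + a.col(0), 0.0, 1.0);
    for (int k = 0; k < K; ++k) posselt::step_core(core, P, v, e, dt, tensions);
    if (!P.is_finite() || !v.is_finite())
      stop("training aborted: non-finite physics state at env step %d", step);
    posselt::net_force_core(core, P, v, e, tensions);
    dist = arma::norm(tgt - P);
    double asym = 0.0;
    for (int i = 0; i < half; ++i) asym += std::fabs(e(i) - e(half + i));
    const double r = -w_u * std::log(dist + eps_d)
                     - w_r * arma::norm(tensions)
                     - w_s * asym;
    ep_return += r;
    ++ep_steps;
    const bool success = dist < success_radius;
    const bool done_env = success || ep_steps >= T;
    arma::vec obs2 = build_obs();
    p->store(obs, a.col(0), obs2, r, success ? 1.0 : 0.0);

    if (p->size >= std::max(batch_size, warmup)) {
      double closs = 0.0, aobj = 0.0, entropy = 0.0;
      for (int u = 0; u < updates_per_step; ++u) {
        arma::uvec idx(batch_size);
        for (int b = 0; b < batch_size; ++b)
          idx(b) = std::min(p->size - 1, (int) (unif_rand() * p->size));
        mat Sb = p->S.cols(idx), Ab = p->A.cols(idx), S2b = p->S2.cols(idx);
        vec rb = p->Rr(idx), db = p->Dn(idx);
        closs = p->critic_update(Sb, Ab, S2b, rb, db);
        aobj = p->actor_update(Sb, false, true, &entropy);
        p->update_targets(p->tau);
        ++p->n_updates;
      }
      if (!std::isfinite(closs) || !std::isfinite(aobj))
        stop("training diverged: non-finite loss at env step %d", step);
      if (stats_every > 0 && step % stats_every == 0) {
        upd_rows.insert(upd_rows.end(),
                        {(double) step, closs, aobj, entropy, p->lr()});
      }
    }
    if (done_env) {
      ++n_episodes;
      ep_rows.insert(ep_rows.end(),
                     {(double) n_episodes, (double) ep_steps, ep_return,
                      dist, success ? 1.0 : 0.0});
      need_reset = true;
    }
    if (step % 2048 == 0) Rcpp::checkUserInterrupt();
  }

  mat ep_mat(ep_rows.size() / 5, 5);
  for (arma::uword i = 0; i < ep_mat.n_rows; ++i)
    for (int j = 0; j < 5; ++j) ep_mat(i, j) = ep_rows[i * 5 + j];
  mat upd_mat(upd_rows.size() / 5, 5);
  for (arma::uword i = 0; i < upd_mat.n_rows; ++i)
    for (int j = 0; j < 5; ++j) upd_mat(i, j) = upd_rows[i * 5 + j];
  return List::create(_["episodes"] = ep_mat, _["updates"] = upd_mat,
                      _["n_updates"] = (double) p->n_updates);
}

// [[Rcpp::export]]
bool cpp_ptr_valid(SEXP ptr) {
  return TYPEOF(ptr) == EXTPTRSXP && R_ExternalPtrAddr(ptr) != nullptr;
}
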