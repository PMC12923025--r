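// Training kernel for the NRI engine: full forward + backward pass for one
// trajectory segment (encoder GNN, Gumbel-softmax edge sample, decoder
// rollout) with hand-derived gradients. Mirrors the pure-R reference
// semantics exactly; a finite-difference test in the suite checks the
// gradients end to end.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

using namespace Rcpp;
using arma::mat;
using arma::uvec;
using arma::vec;

namespace {

struct Lin {
  mat W;
  vec b;
};

struct Mlp {
  Lin l1, l2;
};

Mlp read_mlp(const List& l) {
  Mlp m;
  List l1 = l["l1"], l2 = l["l2"];
  m.l1.W = as<mat>(l1["W"]);
  m.l1.b = as<vec>(l1["b"]);
  m.l2.W = as<mat>(l2["W"]);
  m.l2.b = as<vec>(l2["b"]);
  return m;
}

List mlp_grad_list(const Mlp& g) {
  return List::create(
      _["l1"] = List::create(_["W"] = g.l1.W, _["b"] = g.l1.b),
      _["l2"] = List::create(_["W"] = g.l2.W, _["b"] = g.l2.b));
}

inline void elu_inplace(mat& x) {
  x.for_each([](double& v) { if (v < 0) v = std::expm1(v); });
}

// derivative factor applied to upstream grad, given post-activation values
inline void elu_bwd_inplace(mat& d, const mat& post) {
  const arma::uword n = d.n_elem;
  for (arma::uword i = 0; i < n; ++i) {
    if (post[i] < 0) d[i] *= (post[i] + 1.0);
  }
}

// caches hold only layer outputs; the layer input is passed back to the
// backward call by the owner, avoiding a second copy of large gathers
struct MlpCache {
  mat h1, out;  // post-activation
  bool act_out;
};

const mat& mlp_fwd(const Mlp& p, const mat& x, bool act_out, MlpCache& c) {
  c.h1 = x * p.l1.W;
  c.h1.each_row() += p.l1.b.t();
  elu_inplace(c.h1);
  c.out = c.h1 * p.l2.W;
  c.out.each_row() += p.l2.b.t();
  if (act_out) elu_inplace(c.out);
  c.act_out = act_out;
  return c.out;
}

mat mlp_bwd(const Mlp& p, const MlpCache& c, const mat& x, mat dout,
            Mlp& grad) {
  if (c.act_out) elu_bwd_inplace(dout, c.out);
  grad.l2.W += c.h1.t() * dout;
  grad.l2.b += arma::sum(dout, 0).t();
  mat dh1 = dout * p.l2.W.t();
  elu_bwd_inplace(dh1, c.h1);
  grad.l1.W += x.t() * dh1;
  grad.l1.b += arma::sum(dh1, 0).t();
  return dh1 * p.l1.W.t();
}

Mlp zero_like(const Mlp& p) {
  Mlp g;
  g.l1.W = arma::zeros<mat>(p.l1.W.n_rows, p.l1.W.n_cols);
  g.l1.b = arma::zeros<vec>(p.l1.b.n_elem);
  g.l2.W = arma::zeros<mat>(p.l2.W.n_rows, p.l2.W.n_cols);
  g.l2.b = arma::zeros<vec>(p.l2.b.n_elem);
  return g;
}

mat gather2(const mat& x, const uvec& a, const uvec& b) {
  return arma::join_rows(x.rows(a), x.rows(b));
}

void scatter_add(mat& target, const mat& src, const uvec& idx) {
  for (arma::uword r = 0; r < src.n_rows; ++r) {
    target.row(idx[r]) += src.row(r);
  }
}

mat softmax_rows(mat x) {
  x.each_col() -= arma::max(x, 1);
  x = arma::exp(x);
  x.each_col() /= arma::sum(x, 1);
  return x;
}

}  // namespace

// [[Rcpp::export]]
List nri_segment_grad_cpp(List params, const arma::mat& X,
                          const arma::mat& S0, List targets,
                          const arma::uvec& send0, const arma::uvec& recv0,
                          const arma::uvec& send_b0, const arma::uvec& recv_b0,
                          const arma::uvec& pair_rep0,
                          const arma::mat& gumbel, const arma::mat& z_clamp,
                          bool warmup, double tau, double sigma2,
                          const arma::vec& log_prior, double n_entries) {
  List enc_l = params["enc"], dec_l = params["dec"];
  Mlp emb = read_mlp(enc_l["emb"]);
  Mlp e1 = read_mlp(enc_l["e1"]);
  Mlp node = read_mlp(enc_l["node"]);
  Mlp eout = read_mlp(enc_l["out"]);
  List msg_l = dec_l["msg"];
  const int n_msg = msg_l.size();
  std::vector<Mlp> msg(n_msg);
  for (int k = 0; k < n_msg; ++k) msg[k] = read_mlp(msg_l[k]);
  Mlp dout = read_mlp(dec_l["out"]);

  const arma::uword n = X.n_rows;
  const arma::uword P = send0.n_elem;
  const int K = n_msg + 1;
  const int M = targets.size();

  // ---- encoder forward -----------------------------------------------
  mat logits, q, z;
  MlpCache c_emb, c_e1, c_node, c_out;
  mat ein, agg, oin_e;
  if (warmup) {
    z = z_clamp;
    q = z;
  } else {
    mlp_fwd(emb, X, true, c_emb);
    ein = gather2(c_emb.out, send0, recv0);
    mlp_fwd(e1, ein, true, c_e1);
    agg = arma::zeros<mat>(n, c_e1.out.n_cols);
    scatter_add(agg, c_e1.out, recv0);
    agg /= static_cast<double>(n - 1);
    mlp_fwd(node, agg, true, c_node);
    oin_e = gather2(c_node.out, send0, recv0);
    logits = mlp_fwd(eout, oin_e, false, c_out);
    if (!logits.is_finite()) {
      return List::create(_["diverged"] = true);
    }
    q = softmax_rows(logits);
    z = softmax_rows((logits + gumbel) / tau);
  }

  // ---- decoder rollout -----------------------------------------------
  const arma::uword BP = send_b0.n_elem;
  const arma::uword BN = S0.n_rows;
  const int C = S0.n_cols;
  mat z_rep(BP, K);
  for (arma::uword r = 0; r < BP; ++r) z_rep.row(r) = z.row(pair_rep0[r]);

  std::vector<MlpCache> c_pair(M * n_msg), c_dout(M);
  std::vector<mat> preds(M), tgts(M), pins(M), oins(M);
  mat S = S0;
  double sse = 0.0;
  for (int m = 0; m < M; ++m) {
    pins[m] = gather2(S, send_b0, recv_b0);
    mat msg_sum = arma::zeros<mat>(BP, msg[0].l2.W.n_cols);
    for (int k = 0; k < n_msg; ++k) {
      mat mk = mlp_fwd(msg[k], pins[m], true, c_pair[m * n_msg + k]);
      mk.each_col() %= z_rep.col(k + 1);
      msg_sum += mk;
    }
    mat agg_d = arma::zeros<mat>(BN, msg_sum.n_cols);
    scatter_add(agg_d, msg_sum, recv_b0);
    oins[m] = arma::join_rows(S, agg_d);
    mat delta = mlp_fwd(dout, oins[m], false, c_dout[m]);
    preds[m] = S + delta;
    tgts[m] = as<mat>(targets[m]);
    sse += arma::accu(arma::square(preds[m] - tgts[m]));
    S = preds[m];
  }
  double recon = sse / (2.0 * sigma2 * n_entries);

  double kl = 0.0;
  vec kl_row;
  if (!warmup) {
    mat qs = arma::clamp(q, 1e-16, 1.0);
    mat lq = arma::log(qs);
    lq.each_row() -= log_prior.t();
    kl_row = arma::sum(qs % lq, 1);
    kl = arma::mean(kl_row);
  }
  if (!std::isfinite(recon + kl)) {
    return List::create(_["diverged"] = true);
  }

  // ---- decoder backward ----------------------------------------------
  Mlp g_dout = zero_like(dout);
  std::vector<Mlp> g_msg(n_msg);
  for (int k = 0; k < n_msg; ++k) g_msg[k] = zero_like(msg[k]);
  mat dz = arma::zeros<mat>(P, K);
  mat dS = arma::zeros<mat>(BN, C);
  const int H = dout.l1.W.n_rows - C;
  for (int m = M - 1; m >= 0; --m) {
    mat dS_next = (preds[m] - tgts[m]) / (sigma2 * n_entries) + dS;
    mat doin = mlp_bwd(dout, c_dout[m], oins[m], dS_next, g_dout);
    dS = dS_next + doin.cols(0, C - 1);
    mat dagg = doin.cols(C, C + H - 1);
    mat dmsg = dagg.rows(recv_b0);
    mat dpin;
    for (int k = 0; k < n_msg; ++k) {
      const MlpCache& mk = c_pair[m * n_msg + k];
      // gradient to z: rowsum over chunks of <dmsg, msg_out>
      vec per_row = arma::sum(dmsg % mk.out, 1);
      for (arma::uword r = 0; r < BP; ++r) {
        dz(pair_rep0[r], k + 1) += per_row[r];
      }
      mat dmk = dmsg;
      dmk.each_col() %= z_rep.col(k + 1);
      mat dp = mlp_bwd(msg[k], mk, pins[m], dmk, g_msg[k]);
      if (k == 0) dpin = dp; else dpin += dp;
    }
    scatter_add(dS, dpin.cols(0, C - 1), send_b0);
    scatter_add(dS, dpin.cols(C, 2 * C - 1), recv_b0);
  }

  // ---- encoder backward ----------------------------------------------
  Mlp g_emb = zero_like(emb), g_e1 = zero_like(e1), g_node = zero_like(node),
      g_eout = zero_like(eout);
  if (!warmup) {
    // gumbel-softmax chain
    vec zdz = arma::sum(z % dz, 1);
    mat tmp = dz;
    tmp.each_col() -= zdz;
    mat dlog = (z % tmp) / tau;
    // KL chain
    mat qs = arma::clamp(q, 1e-16, 1.0);
    mat lq = arma::log(qs);
    lq.each_row() -= log_prior.t();
    lq.each_col() -= kl_row;
    mat dkl = (q % lq) / static_cast<double>(P);
    dlog += dkl;

    const int He = node.l2.W.n_cols;
    mat d_oin = mlp_bwd(eout, c_out, oin_e, dlog, g_eout);
    mat d_node_out = arma::zeros<mat>(n, He);
    scatter_add(d_node_out, d_oin.cols(0, He - 1), send0);
    scatter_add(d_node_out, d_oin.cols(He, 2 * He - 1), recv0);
    mat d_agg = mlp_bwd(node, c_node, agg, d_node_out, g_node);
    mat d_e1 = d_agg.rows(recv0) / static_cast<double>(n - 1);
    mat d_ein = mlp_bwd(e1, c_e1, ein, d_e1, g_e1);
    mat d_emb = arma::zeros<mat>(n, He);
    scatter_add(d_emb, d_ein.cols(0, He - 1), send0);
    scatter_add(d_emb, d_ein.cols(He, 2 * He - 1), recv0);
    mlp_bwd(emb, c_emb, X, d_emb, g_emb);
  }

  List msg_grads(n_msg);
  for (int k = 0; k < n_msg; ++k) msg_grads[k] = mlp_grad_list(g_msg[k]);
  List grads = List::create(
      _["enc"] = List::create(
          _["emb"] = mlp_grad_list(g_emb), _["e1"] = mlp_grad_list(g_e1),
          _["node"] = mlp_grad_list(g_node), _["out"] = mlp_grad_list(g_eout)),
      _["dec"] = List::create(_["msg"] = msg_grads,
                              _["out"] = mlp_grad_list(g_dout)));
  return List::create(_["diverged"] = false, _["grads"] = grads,
                      _["recon"] = recon, _["kl"] = kl,
                      _["total"] = recon + kl, _["q"] = q);
}
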