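// Small densely connected CNN: initial 3x3 conv, 2x2 average-pool
// downsampling, dense blocks (BN -> ReLU -> 3x3 conv, concatenated),
// compression transitions (BN -> ReLU -> 1x1 conv -> 2x2 average pool),
// final BN -> ReLU -> global average pool -> softmax classifier.
//
// Activations are stored as cubes with dims (channels, H*W, batch); pixels
// are column-major over (row, col), matching R matrix layout. Convolutions
// run as GEMMs over im2col matrices with zero padding of one pixel.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using arma::cube;
using arma::mat;
using arma::vec;

static const double BN_EPS = 1e-5;
static const double BN_MOMENTUM = 0.9;

// im2col for a 3x3 window, zero padding 1: output rows are ordered in nine
// blocks of C rows, one per window offset (dr, dc) scanned row-major.
static mat im2col3(const mat& X, int H, int W) {
  const int C = X.n_rows, HW = H * W;
  mat out(9 * C, HW, arma::fill::zeros);
  for (int t = 0; t < 9; ++t) {
    const int dr = t / 3 - 1, dc = t % 3 - 1;
    const int r0 = std::max(0, -dr), r1 = std::min(H, H - dr);
    const int c0 = std::max(0, -dc), c1 = std::min(W, W - dc);
    for (int c = c0; c < c1; ++c) {
      for (int r = r0; r < r1; ++r) {
        out.submat(t * C, r + c * H, (t + 1) * C - 1, r + c * H) =
          X.col((r + dr) + (c + dc) * H);
      }
    }
  }
  return out;
}

// adjoint of im2col3: scatter column gradients back onto pixels
static mat col2im3(const mat& cols, int C, int H, int W) {
  mat out(C, H * W, arma::fill::zeros);
  for (int t = 0; t < 9; ++t) {
    const int dr = t / 3 - 1, dc = t % 3 - 1;
    const int r0 = std::max(0, -dr), r1 = std::min(H, H - dr);
    const int c0 = std::max(0, -dc), c1 = std::min(W, W - dc);
    for (int c = c0; c < c1; ++c) {
      for (int r = r0; r < r1; ++r) {
        out.col((r + dr) + (c + dc) * H) +=
          cols.submat(t * C, r + c * H, (t + 1) * C - 1, r + c * H);
      }
    }
  }
  return out;
}

static cube conv3_fwd(const cube& X, const mat& Wm, const vec& b, int H, int W) {
  const int N = X.n_slices, Cout = Wm.n_rows;
  cube Y(Cout, H * W, N);
  for (int s = 0; s < N; ++s) {
    Y.slice(s) = Wm * im2col3(X.slice(s), H, W);
    Y.slice(s).each_col() += b;
  }
  return Y;
}

static cube conv3_bwd(const cube& X, const cube& dY, const mat& Wm,
                      int H, int W, mat& dW, vec& db) {
  const int N = X.n_slices, C = X.n_rows;
  dW.zeros(Wm.n_rows, Wm.n_cols);
  db.zeros(Wm.n_rows);
  cube dX(C, H * W, N);
  for (int s = 0; s < N; ++s) {
    mat cols = im2col3(X.slice(s), H, W);
    dW += dY.slice(s) * cols.t();
    db += arma::sum(dY.slice(s), 1);
    dX.slice(s) = col2im3(Wm.t() * dY.slice(s), C, H, W);
  }
  return dX;
}

// 2x2 average pooling (stride 2); H and W must be even
static cube pool2_fwd(const cube& X, int H, int W) {
  const int N = X.n_slices, C = X.n_rows, H2 = H / 2, W2 = W / 2;
  cube Y(C, H2 * W2, N, arma::fill::zeros);
  for (int s = 0; s < N; ++s) {
    for (int c = 0; c < W2; ++c) {
      for (int r = 0; r < H2; ++r) {
        const int q = r + c * H2;
        Y.slice(s).col(q) =
          (X.slice(s).col(2 * r + 2 * c * H) +
           X.slice(s).col(2 * r + 1 + 2 * c * H) +
           X.slice(s).col(2 * r + (2 * c + 1) * H) +
           X.slice(s).col(2 * r + 1 + (2 * c + 1) * H)) * 0.25;
      }
    }
  }
  return Y;
}

static cube pool2_bwd(const cube& dY, int H, int W) {
  const int N = dY.n_slices, C = dY.n_rows, H2 = H / 2, W2 = W / 2;
  cube dX(C, H * W, N, arma::fill::zeros);
  for (int s = 0; s < N; ++s) {
    for (int c = 0; c < W2; ++c) {
      for (int r = 0; r < H2; ++r) {
        const vec g = dY.slice(s).col(r + c * H2) * 0.25;
        dX.slice(s).col(2 * r + 2 * c * H) = g;
        dX.slice(s).col(2 * r + 1 + 2 * c * H) = g;
        dX.slice(s).col(2 * r + (2 * c + 1) * H) = g;
        dX.slice(s).col(2 * r + 1 + (2 * c + 1) * H) = g;
      }
    }
  }
  return dX;
}

struct BNCache {
  cube xhat;
  vec invstd;
  vec gamma;
};

// batch normalization over (pixels x batch) per channel
static cube bn_fwd(const cube& X, const vec& gamma, const vec& beta,
                   bool training, vec& rmean, vec& rvar, BNCache& cache) {
  const int C = X.n_rows, HW = X.n_cols, N = X.n_slices;
  const double M = double(HW) * N;
  vec mean(C), variance(C);
  if (training) {
    for (int ch = 0; ch < C; ++ch) {
      double s = 0, s2 = 0;
      for (int n = 0; n < N; ++n) {
        const arma::rowvec r = X.slice(n).row(ch);
        s += arma::accu(r);
        s2 += arma::dot(r, r);
      }
      mean(ch) = s / M;
      variance(ch) = s2 / M - mean(ch) * mean(ch);
      if (variance(ch) < 0) variance(ch) = 0;
    }
    rmean = BN_MOMENTUM * rmean + (1 - BN_MOMENTUM) * mean;
    rvar = BN_MOMENTUM * rvar + (1 - BN_MOMENTUM) * variance;
  } else {
    mean = rmean;
    variance = rvar;
  }
  vec invstd = 1.0 / arma::sqrt(variance + BN_EPS);
  cube Y(C, HW, N);
  cache.xhat.set_size(C, HW, N);
  for (int n = 0; n < N; ++n) {
    for (int ch = 0; ch < C; ++ch) {
      cache.xhat.slice(n).row(ch) =
        (X.slice(n).row(ch) - mean(ch)) * invstd(ch);
      Y.slice(n).row(ch) =
        cache.xhat.slice(n).row(ch) * gamma(ch) + beta(ch);
    }
  }
  cache.invstd = invstd;
  cache.gamma = gamma;
  return Y;
}

static cube bn_bwd(const cube& dY, const BNCache& cache,
                   vec& dgamma, vec& dbeta) {
  const int C = dY.n_rows, HW = dY.n_cols, N = dY.n_slices;
  const double M = double(HW) * N;
  dgamma.zeros(C);
  dbeta.zeros(C);
  for (int n = 0; n < N; ++n) {
    for (int ch = 0; ch < C; ++ch) {
      dgamma(ch) += arma::dot(dY.slice(n).row(ch), cache.xhat.slice(n).row(ch));
      dbeta(ch) += arma::accu(dY.slice(n).row(ch));
    }
  }
  cube dX(C, HW, N);
  for (int n = 0; n < N; ++n) {
    for (int ch = 0; ch < C; ++ch) {
      dX.slice(n).row(ch) = (cache.gamma(ch) * cache.invstd(ch)) *
        (dY.slice(n).row(ch) - dbeta(ch) / M -
         cache.xhat.slice(n).row(ch) * (dgamma(ch) / M));
    }
  }
  return dX;
}

static cube relu_fwd(const cube& X) {
  cube Y = X;
  Y.for_each([](double& v) { if (v < 0) v = 0; });
  return Y;
}

static cube relu_bwd(const cube& dY, const cube& Ypost) {
  cube dX = dY;
  const arma::uvec zero = arma::find(Ypost <= 0);
  dX.elem(zero).zeros();
  return dX;
}

// caches collected on the forward pass (training mode)
struct ForwardState {
  cube x0;                      // input as cube (1, HW, N)
  cube conv0_out;               // pre-pool conv output
  std::vector<cube> block_out;  // final concatenated cube per block
  std::vector<cube> layer_in;   // BN input (prefix copy) per dense layer
  std::vector<cube> layer_relu; // post-ReLU per dense layer
  std::vector<BNCache> bn;      // all BN caches in network order
  std::vector<cube> trans_relu; // post-ReLU per transition
  std::vector<cube> trans_conv; // 1x1 conv output per transition (pre-pool)
  cube final_relu;
  mat feat;                     // global-average-pooled features (C x N)
  mat probs;                    // softmax outputs (K x N)
};

// [[Rcpp::export]]
List dn_run(const arma::mat& X, const arma::ivec& y, const List& params,
            const List& rstats, const List& cfg, bool training,
            bool want_grads) {
  const int S = as<int>(cfg["input_size"]);
  const int k0 = as<int>(cfg["initial_channels"]);
  const int B = as<int>(cfg["num_blocks"]);
  const int Lb = as<int>(cfg["layers_per_block"]);
  const int g = as<int>(cfg["growth_rate"]);
  const double theta = as<double>(cfg["compression"]);
  const int K = as<int>(cfg["num_classes"]);
  const int N = X.n_cols;
  if ((int)X.n_rows != S * S) stop("input geometry mismatch");

  // unpack params in canonical flat order
  std::vector<mat> Wp;
  std::vector<vec> vp;  // parallel vectors (b, gamma, beta, ...)
  std::vector<bool> is_mat;
  for (int i = 0; i < params.size(); ++i) {
    SEXP p = params[i];
    NumericVector nv(p);
    if (Rf_isMatrix(p)) {
      Wp.push_back(as<mat>(p));
      vp.push_back(vec());
      is_mat.push_back(true);
    } else {
      Wp.push_back(mat());
      vp.push_back(as<vec>(p));
      is_mat.push_back(false);
    }
  }
  std::vector<vec> rs;
  for (int i = 0; i < rstats.size(); ++i) rs.push_back(as<vec>(rstats[i]));

  ForwardState st;
  st.x0.set_size(1, S * S, N);
  for (int s = 0; s < N; ++s) st.x0.slice(s).row(0) = X.col(s).t();

  int pi = 0;   // param cursor
  int bi = 0;   // BN (running-stat pair) cursor
  st.bn.resize(B * Lb + (B - 1) + 1);

  // initial conv + downsampling pool
  const mat& W0 = Wp[pi]; const vec& b0 = vp[pi + 1];
  st.conv0_out = conv3_fwd(st.x0, W0, b0, S, S);
  pi += 2;
  int H = S / 2;
  cube act = pool2_fwd(st.conv0_out, S, S);
  int C = k0;

  st.block_out.resize(B);
  st.layer_in.resize(B * Lb);
  st.layer_relu.resize(B * Lb);
  st.trans_relu.resize(B - 1);
  st.trans_conv.resize(B - 1);
  std::vector<int> block_H(B), block_Cin(B);
  std::vector<int> trans_Cin(std::max(B - 1, 0));

  for (int b = 0; b < B; ++b) {
    block_H[b] = H;
    block_Cin[b] = C;
    cube blk(C + Lb * g, H * H, N, arma::fill::zeros);
    blk.rows(0, C - 1) = act;
    int Cin = C;
    for (int l = 0; l < Lb; ++l) {
      const int li = b * Lb + l;
      st.layer_in[li] = blk.rows(0, Cin - 1);
      cube bn_out = bn_fwd(st.layer_in[li], vp[pi], vp[pi + 1], training,
                           rs[2 * bi], rs[2 * bi + 1], st.bn[bi]);
      st.layer_relu[li] = relu_fwd(bn_out);
      cube conv_out = conv3_fwd(st.layer_relu[li], Wp[pi + 2], vp[pi + 3], H, H);
      blk.rows(Cin, Cin + g - 1) = conv_out;
      Cin += g;
      pi += 4;
      ++bi;
    }
    st.block_out[b] = blk;
    C = Cin;
    if (b < B - 1) {
      trans_Cin[b] = C;
      cube bn_out = bn_fwd(st.block_out[b], vp[pi], vp[pi + 1], training,
                           rs[2 * bi], rs[2 * bi + 1], st.bn[bi]);
      st.trans_relu[b] = relu_fwd(bn_out);
      const mat& Wt = Wp[pi + 2]; const vec& bt = vp[pi + 3];
      const int Ct = Wt.n_rows;
      st.trans_conv[b].set_size(Ct, H * H, N);
      for (int s = 0; s < N; ++s) {
        st.trans_conv[b].slice(s) = Wt * st.trans_relu[b].slice(s);
        st.trans_conv[b].slice(s).each_col() += bt;
      }
      act = pool2_fwd(st.trans_conv[b], H, H);
      H /= 2;
      C = Ct;
      pi += 4;
      ++bi;
    }
  }

  // classification head
  cube bn_out = bn_fwd(st.block_out[B - 1], vp[pi], vp[pi + 1], training,
                       rs[2 * bi], rs[2 * bi + 1], st.bn[bi]);
  st.final_relu = relu_fwd(bn_out);
  const int Cf = st.final_relu.n_rows, HWf = st.final_relu.n_cols;
  st.feat.set_size(Cf, N);
  for (int s = 0; s < N; ++s) st.feat.col(s) = arma::mean(st.final_relu.slice(s), 1);
  const mat& Wfc = Wp[pi + 2]; const vec& bfc = vp[pi + 3];
  mat logits = Wfc * st.feat;
  logits.each_col() += bfc;
  st.probs.set_size(K, N);
  for (int s = 0; s < N; ++s) {
    vec z = logits.col(s) - logits.col(s).max();
    vec e = arma::exp(z);
    st.probs.col(s) = e / arma::accu(e);
  }

  double loss = NA_REAL;
  const bool have_y = (int)y.n_elem == N;
  if (have_y) {
    loss = 0.0;
    for (int s = 0; s < N; ++s) {
      loss -= std::log(std::max(st.probs(y(s), s), 1e-12));
    }
    loss /= N;
  }

  List out = List::create(
    Named("probs") = st.probs,
    Named("loss") = loss,
    Named("rstats") = wrap(rs)
  );
  if (!want_grads) return out;
  if (!have_y) stop("gradients require labels");

  // ---- backward pass ----
  std::vector<mat> gW(params.size());
  std::vector<vec> gv(params.size());

  mat dlogits = st.probs;
  for (int s = 0; s < N; ++s) dlogits(y(s), s) -= 1.0;
  dlogits /= N;

  const int fc_i = pi + 2;
  gW[fc_i] = dlogits * st.feat.t();
  gv[pi + 3] = arma::sum(dlogits, 1);
  mat dfeat = Wfc.t() * dlogits;

  cube dZ(Cf, HWf, N);
  for (int s = 0; s < N; ++s) {
    dZ.slice(s) = arma::repmat(dfeat.col(s) / double(HWf), 1, HWf);
  }
  dZ = relu_bwd(dZ, st.final_relu);
  {
    vec dgamma, dbeta;
    dZ = bn_bwd(dZ, st.bn[bi], dgamma, dbeta);
    gv[pi] = dgamma;
    gv[pi + 1] = dbeta;
  }
  cube d_act = dZ;   // gradient wrt last block's concatenated output

  // walk blocks in reverse
  for (int b = B - 1; b >= 0; --b) {
    const int Hb = block_H[b];
    if (b < B - 1) {
      // d_act currently holds gradient wrt this transition's pooled output
      --bi;
      pi -= 4;
      cube d_conv = pool2_bwd(d_act, Hb, Hb);
      const mat& Wt = Wp[pi + 2];
      gW[pi + 2].zeros(Wt.n_rows, Wt.n_cols);
      gv[pi + 3].zeros(Wt.n_rows);
      cube d_relu(trans_Cin[b], Hb * Hb, N);
      for (int s = 0; s < N; ++s) {
        gW[pi + 2] += d_conv.slice(s) * st.trans_relu[b].slice(s).t();
        gv[pi + 3] += arma::sum(d_conv.slice(s), 1);
        d_relu.slice(s) = Wt.t() * d_conv.slice(s);
      }
      d_relu = relu_bwd(d_relu, st.trans_relu[b]);
      vec dgamma, dbeta;
      d_act = bn_bwd(d_relu, st.bn[bi], dgamma, dbeta);
      gv[pi] = dgamma;
      gv[pi + 1] = dbeta;
    }
    // d_act: gradient wrt the block's full concatenated cube
    for (int l = Lb - 1; l >= 0; --l) {
      const int li = b * Lb + l;
      --bi;
      pi -= 4;
      const int Cin = block_Cin[b] + l * g;
      cube dY = d_act.rows(Cin, Cin + g - 1);
      mat dW; vec db;
      cube d_relu = conv3_bwd(st.layer_relu[li], dY, Wp[pi + 2], Hb, Hb, dW, db);
      gW[pi + 2] = dW;
      gv[pi + 3] = db;
      d_relu = relu_bwd(d_relu, st.layer_relu[li]);
      vec dgamma, dbeta;
      cube dXin = bn_bwd(d_relu, st.bn[bi], dgamma, dbeta);
      gv[pi] = dgamma;
      gv[pi + 1] = dbeta;
      d_act.rows(0, Cin - 1) += dXin;
    }
    d_act = cube(d_act.rows(0, block_Cin[b] - 1));
    if (b > 0) {
      // propagate through the previous transition's pool on the next loop
      // iteration; nothing else to do here
    }
  }

  // initial pool + conv
  pi -= 2;
  cube d_conv0 = pool2_bwd(d_act, S, S);
  mat dW0; vec db0;
  conv3_bwd(st.x0, d_conv0, Wp[pi], S, S, dW0, db0);
  gW[pi] = dW0;
  gv[pi + 1] = db0;

  List grads(params.size());
  for (int i = 0; i < (int)params.size(); ++i) {
    if (is_mat[i]) {
      grads[i] = wrap(gW[i]);
    } else {
      grads[i] = NumericVector(gv[i].begin(), gv[i].end());
    }
  }
  out["grads"] = grads;
  return out;
}
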