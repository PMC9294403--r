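// Forward and backward passes for the Conv-6 3D feature extractor.
//
// Layout conventions:
//  * a batch of activations is an arma::mat of size C x (N*V), where V = E^3
//    voxels per sample; sample n occupies columns [n*V, (n+1)*V).
//  * voxel v = x + E*(y + E*z), 0-based, matching the flattening of an R
//    array with dim c(E, E, E).
//  * conv weights W are C_out x (C_in*27); column index c_in*27 + k where
//    k = (dz+1)*9 + (dy+1)*3 + (dx+1) enumerates the 3x3x3 neighbourhood.
//
// Each block is conv(3x3x3, pad 1) -> batchnorm -> ReLU -> optional 2x2x2
// max-pool (stride 2, floor on odd edges); the final activations are
// globally average-pooled into one feature vector per sample.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Gather the 3x3x3 neighbourhood patches of one sample into columns of P.
// A points at the first element of the sample's block (C x V, col-major).
static void vol2col(const double* A, int C, int E, arma::mat& P, int pcol0) {
  const int V = E * E * E;
  (void)V;
  for (int z = 0; z < E; ++z)
    for (int y = 0; y < E; ++y)
      for (int x = 0; x < E; ++x) {
        const int v = x + E * (y + E * z);
        double* pc = P.colptr(pcol0 + v);
        int k = 0;
        for (int dz = -1; dz <= 1; ++dz)
          for (int dy = -1; dy <= 1; ++dy)
            for (int dx = -1; dx <= 1; ++dx) {
              const int xx = x + dx, yy = y + dy, zz = z + dz;
              if (xx < 0 || yy < 0 || zz < 0 || xx >= E || yy >= E || zz >= E) {
                for (int c = 0; c < C; ++c) pc[(size_t)c * 27 + k] = 0.0;
              } else {
                const double* ac = A + (size_t)(xx + E * (yy + E * zz)) * C;
                for (int c = 0; c < C; ++c) pc[(size_t)c * 27 + k] = ac[c];
              }
              ++k;
            }
      }
}

// Scatter-add the adjoint of vol2col: dP columns back onto dA (one sample).
static void col2vol(const arma::mat& dP, int pcol0, int C, int E, double* dA) {
  for (int z = 0; z < E; ++z)
    for (int y = 0; y < E; ++y)
      for (int x = 0; x < E; ++x) {
        const int v = x + E * (y + E * z);
        const double* pc = dP.colptr(pcol0 + v);
        int k = 0;
        for (int dz = -1; dz <= 1; ++dz)
          for (int dy = -1; dy <= 1; ++dy)
            for (int dx = -1; dx <= 1; ++dx) {
              const int xx = x + dx, yy = y + dy, zz = z + dz;
              if (!(xx < 0 || yy < 0 || zz < 0 || xx >= E || yy >= E || zz >= E)) {
                double* ac = dA + (size_t)(xx + E * (yy + E * zz)) * C;
                for (int c = 0; c < C; ++c) ac[c] += pc[(size_t)c * 27 + k];
              }
              ++k;
            }
      }
}

static arma::mat maxpool_fwd(const arma::mat& A, int C, int E, int N,
                             arma::ivec& argmax) {
  const int Ep = E / 2;
  const int V = E * E * E, Vp = Ep * Ep * Ep;
  arma::mat out(C, (size_t)N * Vp);
  argmax.set_size((size_t)C * N * Vp);
  for (int n = 0; n < N; ++n)
    for (int zo = 0; zo < Ep; ++zo)
      for (int yo = 0; yo < Ep; ++yo)
        for (int xo = 0; xo < Ep; ++xo) {
          const int vo = xo + Ep * (yo + Ep * zo);
          const size_t ocol = (size_t)n * Vp + vo;
          for (int c = 0; c < C; ++c) {
            double best = -arma::datum::inf;
            int bestv = -1;
            for (int dz = 0; dz < 2; ++dz)
              for (int dy = 0; dy < 2; ++dy)
                for (int dx = 0; dx < 2; ++dx) {
                  const int v = (2 * xo + dx) + E * ((2 * yo + dy) + E * (2 * zo + dz));
                  const double val = A(c, (size_t)n * V + v);
                  if (val > best) { best = val; bestv = v; }
                }
            out(c, ocol) = best;
            argmax((size_t)c + (size_t)C * ocol) = bestv;
          }
        }
  return out;
}

// [[Rcpp::export]]
List cnn_forward_cpp(const arma::mat& x, List params, IntegerVector widths,
                     LogicalVector pool, int in_edge, bool train,
                     double bn_momentum, double bn_eps, bool want_cache) {
  const int nb = widths.size();
  const int N = x.n_cols;
  int E = in_edge;
  int Cin = 1;
  // input as 1 x (N*V)
  arma::mat A(1, x.n_elem);
  {
    const int V = E * E * E;
    for (int n = 0; n < N; ++n)
      for (int v = 0; v < V; ++v) A(0, (size_t)n * V + v) = x(v, n);
  }
  List cache(nb);
  List new_running(nb);
  for (int b = 0; b < nb; ++b) {
    List pb = params[b];
    arma::mat W = as<arma::mat>(pb["W"]);
    arma::vec bias = as<arma::vec>(pb["b"]);
    arma::vec gamma = as<arma::vec>(pb["gamma"]);
    arma::vec beta = as<arma::vec>(pb["beta"]);
    arma::vec rmean = as<arma::vec>(pb["rmean"]);
    arma::vec rvar = as<arma::vec>(pb["rvar"]);
    const int Cout = widths[b];
    const int V = E * E * E;
    arma::mat P((size_t)Cin * 27, (size_t)N * V);
    for (int n = 0; n < N; ++n)
      vol2col(A.colptr((size_t)n * V), Cin, E, P, n * V);
    arma::mat Z = W * P;
    Z.each_col() += bias;
    arma::vec mu, var, invstd;
    if (train) {
      mu = arma::mean(Z, 1);
      arma::mat xc = Z.each_col() - mu;
      var = arma::mean(arma::square(xc), 1);
      invstd = 1.0 / arma::sqrt(var + bn_eps);
      Z = xc.each_col() % invstd;  // Z now holds xhat
      rmean = (1.0 - bn_momentum) * rmean + bn_momentum * mu;
      rvar = (1.0 - bn_momentum) * rvar + bn_momentum * var;
    } else {
      invstd = 1.0 / arma::sqrt(rvar + bn_eps);
      Z.each_col() -= rmean;
      Z.each_col() %= invstd;
    }
    arma::mat xhat;  // kept only when caching
    if (want_cache) xhat = Z;
    arma::mat Y = Z.each_col() % gamma;
    Y.each_col() += beta;
    Y.transform([](double u) { return u > 0.0 ? u : 0.0; });
    arma::ivec argmax;
    arma::mat Anext;
    int Enext = E;
    if (pool[b]) {
      Anext = maxpool_fwd(Y, Cout, E, N, argmax);
      Enext = E / 2;
    } else {
      Anext = Y;
    }
    if (want_cache) {
      cache[b] = List::create(_["Ain"] = A, _["xhat"] = xhat,
                              _["invstd"] = invstd,
                              _["argmax"] = pool[b] ? wrap(argmax) : R_NilValue);
    }
    new_running[b] = List::create(_["rmean"] = rmean, _["rvar"] = rvar);
    A = Anext;
    E = Enext;
    Cin = Cout;
  }
  // global average pool: features N x C
  const int Vf = E * E * E;
  arma::mat feats(N, Cin);
  for (int n = 0; n < N; ++n)
    feats.row(n) = arma::mean(A.cols((size_t)n * Vf, (size_t)(n + 1) * Vf - 1), 1).t();
  return List::create(_["features"] = feats, _["cache"] = cache,
                      _["running"] = new_running, _["final_edge"] = E);
}

// [[Rcpp::export]]
List cnn_backward_cpp(const arma::mat& dfeat, List cache, List params,
                      IntegerVector widths, LogicalVector pool,
                      int in_edge, double bn_eps) {
  const int nb = widths.size();
  const int N = dfeat.n_rows;
  // edge sizes entering each block
  std::vector<int> ein(nb + 1);
  ein[0] = in_edge;
  for (int b = 0; b < nb; ++b) ein[b + 1] = pool[b] ? ein[b] / 2 : ein[b];
  const int Ef = ein[nb];
  const int Vf = Ef * Ef * Ef;
  const int Cf = widths[nb - 1];
  arma::mat dA(Cf, (size_t)N * Vf);
  for (int n = 0; n < N; ++n)
    for (int v = 0; v < Vf; ++v)
      for (int c = 0; c < Cf; ++c)
        dA(c, (size_t)n * Vf + v) = dfeat(n, c) / Vf;
  List grads(nb);
  for (int b = nb - 1; b >= 0; --b) {
    List cb = cache[b];
    List pb = params[b];
    arma::mat W = as<arma::mat>(pb["W"]);
    arma::vec gamma = as<arma::vec>(pb["gamma"]);
    arma::vec beta = as<arma::vec>(pb["beta"]);
    arma::mat Ain = as<arma::mat>(cb["Ain"]);
    arma::mat xhat = as<arma::mat>(cb["xhat"]);
    arma::vec invstd = as<arma::vec>(cb["invstd"]);
    const int E = ein[b];
    const int V = E * E * E;
    const int Cout = widths[b];
    const int Cin = b == 0 ? 1 : widths[b - 1];
    arma::mat dY;
    if (pool[b]) {
      const int Ep = E / 2;
      const int Vp = Ep * Ep * Ep;
      arma::ivec argmax = as<arma::ivec>(cb["argmax"]);
      dY.zeros(Cout, (size_t)N * V);
      for (int n = 0; n < N; ++n)
        for (int vo = 0; vo < Vp; ++vo) {
          const size_t ocol = (size_t)n * Vp + vo;
          for (int c = 0; c < Cout; ++c) {
            const int v = argmax((size_t)c + (size_t)Cout * ocol);
            dY(c, (size_t)n * V + v) += dA(c, ocol);
          }
        }
    } else {
      dY = dA;
    }
    // ReLU mask from the batchnorm output gamma*xhat + beta
    for (size_t j = 0; j < dY.n_cols; ++j)
      for (int c = 0; c < Cout; ++c)
        if (gamma(c) * xhat(c, j) + beta(c) <= 0.0) dY(c, j) = 0.0;
    // batchnorm backward
    const double m = (double)dY.n_cols;
    arma::vec dgamma = arma::sum(dY % xhat, 1);
    arma::vec dbeta = arma::sum(dY, 1);
    arma::mat dxhat = dY.each_col() % gamma;
    arma::vec s1 = arma::sum(dxhat, 1);
    arma::vec s2 = arma::sum(dxhat % xhat, 1);
    arma::mat dZ = dxhat * m;
    dZ.each_col() -= s1;
    dZ -= xhat.each_col() % s2;
    dZ.each_col() %= invstd / m;
    // conv backward
    arma::vec db = arma::sum(dZ, 1);
    arma::mat dW(arma::size(W), arma::fill::zeros);
    arma::mat dAin(Cin, (size_t)N * V, arma::fill::zeros);
    arma::mat Pn((size_t)Cin * 27, V);
    for (int n = 0; n < N; ++n) {
      vol2col(Ain.colptr((size_t)n * V), Cin, E, Pn, 0);
      arma::mat dZn = dZ.cols((size_t)n * V, (size_t)(n + 1) * V - 1);
      dW += dZn * Pn.t();
      arma::mat dPn = W.t() * dZn;
      col2vol(dPn, 0, Cin, E, dAin.colptr((size_t)n * V));
    }
    grads[b] = List::create(_["W"] = dW, _["b"] = db, _["gamma"] = dgamma,
                            _["beta"] = dbeta);
    dA = dAin;
  }
  return grads;
}
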