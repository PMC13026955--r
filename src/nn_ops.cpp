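// Numerical kernels for the dual-branch network.
//
// Layout conventions (match R arrays, column-major):
//   activations : dim (H, W, C, N), double on the R side
//   conv weight : dim (3, 3, Cin, Cout)  -> viewed as (9*Cin) x Cout matrix
//   im2col      : (H*W*N) x (9*Cin), float; column (ci,kx,ky) is contiguous
//
// A conv "block" is conv(3x3, pad 1, stride 1) -> batchnorm -> ReLU ->
// maxpool(2x2).  Forward caches (im2col matrix, pre-BN conv output, BN
// statistics, argmax indices) live in float inside an external pointer, so
// the backward pass never rebuilds them and the R side never materialises
// full-resolution intermediates in double precision.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

struct BlockCache {
  int H = 0, W = 0, Cin = 0, Cout = 0, N = 0;
  arma::fmat K;      // (H*W*N) x (9*Cin)
  arma::fmat conv;   // (H*W*N) x Cout, conv output + bias, pre-BN
  arma::fmat Wm;     // (9*Cin) x Cout
  arma::fvec mu, invstd, gamma;
  std::vector<long long> poolidx; // per pooled cell: row into conv, -1 if ReLU-dead
  arma::fmat gy, gconv, gK;       // backward workspaces, reused across batches
};

static void check_dim4(const NumericVector& x, const char* what) {
  SEXP d = x.attr("dim");
  if (Rf_isNull(d) || LENGTH(d) != 4)
    stop("'%s' must be a 4-d array (H, W, C, N)", what);
}

// Fill the im2col matrix for a zero-padded 3x3, stride-1 convolution.
static void im2col3x3(const double* x, int H, int W, int Cin, int N, arma::fmat& K) {
  const long long HW = (long long)H * W;
  K.set_size(HW * N, 9 * (long long)Cin);
  for (int ci = 0; ci < Cin; ++ci) {
    for (int kx = 0; kx < 3; ++kx) {
      for (int ky = 0; ky < 3; ++ky) {
        float* col = K.colptr((long long)ci * 9 + kx * 3 + ky);
        for (int n = 0; n < N; ++n) {
          const double* plane = x + ((long long)n * Cin + ci) * HW;
          float* dst = col + (long long)n * HW;
          for (int cx = 0; cx < W; ++cx) {
            const int sx = cx + kx - 1;
            float* d2 = dst + (long long)cx * H;
            if (sx < 0 || sx >= W) {
              std::memset(d2, 0, sizeof(float) * H);
              continue;
            }
            const double* src = plane + (long long)sx * H;
            // rows y: source y + ky - 1 must lie in [0, H)
            const int y0 = std::max(0, 1 - ky);          // first valid y
            const int y1 = std::min(H, H + 1 - ky);      // one past last valid
            for (int y = 0; y < y0; ++y) d2[y] = 0.0f;
            for (int y = y0; y < y1; ++y) d2[y] = (float)src[y + ky - 1];
            for (int y = y1; y < H; ++y) d2[y] = 0.0f;
          }
        }
      }
    }
  }
}

// Scatter-accumulate the im2col-shaped gradient back to the input array.
static void col2im3x3(const arma::fmat& G, int H, int W, int Cin, int N, double* gx) {
  const long long HW = (long long)H * W;
  std::memset(gx, 0, sizeof(double) * HW * Cin * N);
  for (int ci = 0; ci < Cin; ++ci) {
    for (int kx = 0; kx < 3; ++kx) {
      for (int ky = 0; ky < 3; ++ky) {
        const float* col = G.colptr((long long)ci * 9 + kx * 3 + ky);
        for (int n = 0; n < N; ++n) {
          double* plane = gx + ((long long)n * Cin + ci) * HW;
          const float* s0 = col + (long long)n * HW;
          for (int cx = 0; cx < W; ++cx) {
            const int sx = cx + kx - 1;
            if (sx < 0 || sx >= W) continue;
            const float* s2 = s0 + (long long)cx * H;
            double* dst = plane + (long long)sx * H;
            const int y0 = std::max(0, 1 - ky);
            const int y1 = std::min(H, H + 1 - ky);
            for (int y = y0; y < y1; ++y) dst[y + ky - 1] += (double)s2[y];
          }
        }
      }
    }
  }
}

static List block_fw_core(BlockCache& cache, NumericVector x, NumericVector w,
                          NumericVector b, NumericVector gamma, NumericVector beta,
                          bool train, NumericVector run_mean, NumericVector run_var,
                          double eps, bool want_cache) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], Cin = xd[2], N = xd[3];
  IntegerVector wd = w.attr("dim");
  if (wd.size() != 4 || wd[0] != 3 || wd[1] != 3 || wd[2] != Cin)
    stop("conv weight must have dim (3, 3, %d, Cout)", Cin);
  const int Cout = wd[3];
  if (H % 2 != 0 || W % 2 != 0) stop("conv block expects even spatial dims, got %dx%d", H, W);
  const long long HW = (long long)H * W;
  const long long M = HW * N;

  cache.H = H; cache.W = W; cache.Cin = Cin; cache.Cout = Cout; cache.N = N;

  im2col3x3(REAL(x), H, W, Cin, N, cache.K);

  arma::fmat Wm(9 * (long long)Cin, Cout);
  for (long long i = 0; i < (long long)Wm.n_elem; ++i) Wm(i) = (float)w[i];

  cache.conv = cache.K * Wm;                         // M x Cout
  if (want_cache) cache.Wm = std::move(Wm);
  if (!want_cache) { cache.K.reset(); }

  arma::fvec mu(Cout), var(Cout), invstd(Cout);
  for (int co = 0; co < Cout; ++co) cache.conv.col(co) += (float)b[co];
  if (train) {
    for (int co = 0; co < Cout; ++co) {
      const float* cv = cache.conv.colptr(co);
      double s = 0.0;
      for (long long j = 0; j < M; ++j) s += cv[j];
      const float m0 = (float)(s / (double)M);
      double v = 0.0;
      for (long long j = 0; j < M; ++j) { const float d = cv[j] - m0; v += (double)d * d; }
      mu[co] = m0;
      var[co] = (float)(v / (double)M);              // biased, as used for normalisation
    }
  } else {
    for (int co = 0; co < Cout; ++co) {
      mu[co] = (float)run_mean[co];
      var[co] = (float)run_var[co];
    }
  }
  for (int co = 0; co < Cout; ++co) invstd[co] = 1.0f / std::sqrt(var[co] + (float)eps);
  cache.mu = mu; cache.invstd = invstd;
  cache.gamma.set_size(Cout);
  for (int co = 0; co < Cout; ++co) cache.gamma[co] = (float)gamma[co];

  const int Hp = H / 2, Wp = W / 2;
  const long long HWp = (long long)Hp * Wp;
  NumericVector out(HWp * Cout * (long long)N);
  out.attr("dim") = IntegerVector::create(Hp, Wp, Cout, N);
  if (want_cache) cache.poolidx.assign((size_t)(HWp * Cout * N), -1);

  for (int n = 0; n < N; ++n) {
    for (int co = 0; co < Cout; ++co) {
      const float g = (float)gamma[co], be = (float)beta[co];
      const float m0 = mu[co], is = invstd[co];
      const float* cv = cache.conv.colptr(co) + (long long)n * HW;
      double* op = REAL(out) + ((long long)n * Cout + co) * HWp;
      long long* pidx = want_cache ? cache.poolidx.data() + ((long long)n * Cout + co) * HWp : nullptr;
      for (int px = 0; px < Wp; ++px) {
        const float* c0 = cv + (long long)(2 * px) * H;
        const float* c1 = cv + (long long)(2 * px + 1) * H;
        for (int py = 0; py < Hp; ++py) {
          float best = 0.0f; long long besti = -1;
          const float v00 = g * (c0[2 * py] - m0) * is + be;
          const float v01 = g * (c0[2 * py + 1] - m0) * is + be;
          const float v10 = g * (c1[2 * py] - m0) * is + be;
          const float v11 = g * (c1[2 * py + 1] - m0) * is + be;
          if (v00 > best) { best = v00; besti = (long long)(2 * px) * H + 2 * py; }
          if (v01 > best) { best = v01; besti = (long long)(2 * px) * H + 2 * py + 1; }
          if (v10 > best) { best = v10; besti = (long long)(2 * px + 1) * H + 2 * py; }
          if (v11 > best) { best = v11; besti = (long long)(2 * px + 1) * H + 2 * py + 1; }
          op[(long long)px * Hp + py] = (double)best;
          if (pidx) pidx[(long long)px * Hp + py] = besti; // -1 when all ReLU-dead
        }
      }
    }
  }

  List res = List::create(_["out"] = out);
  if (train) {
    NumericVector bm(Cout), bv(Cout);
    const double corr = M > 1 ? (double)M / (double)(M - 1) : 1.0;
    for (int co = 0; co < Cout; ++co) { bm[co] = mu[co]; bv[co] = var[co] * corr; }
    res["batch_mean"] = bm;   // for the running-statistics update
    res["batch_var"] = bv;    // unbiased
  }
  return res;
}

// [[Rcpp::export(name = ".conv_block_fw")]]
List conv_block_fw(NumericVector x, NumericVector w, NumericVector b,
                   NumericVector gamma, NumericVector beta,
                   bool train, NumericVector run_mean, NumericVector run_var,
                   double eps, bool want_cache, SEXP prev_cache = R_NilValue) {
  check_dim4(x, "x");
  if (want_cache) {
    // reuse the previous batch's buffers when offered (same shapes -> no
    // reallocation); otherwise allocate fresh
    XPtr<BlockCache> cache = Rf_isNull(prev_cache)
      ? XPtr<BlockCache>(new BlockCache(), true)
      : XPtr<BlockCache>(prev_cache);
    List res = block_fw_core(*cache, x, w, b, gamma, beta, train,
                             run_mean, run_var, eps, true);
    res["cache"] = cache;
    return res;
  }
  BlockCache cache;   // freed on return: no stale memory waiting for GC
  List res = block_fw_core(cache, x, w, b, gamma, beta, train,
                           run_mean, run_var, eps, false);
  res["cache"] = R_NilValue;
  return res;
}

// [[Rcpp::export(name = ".conv_block_bw")]]
List conv_block_bw(SEXP cache_xp, NumericVector gout, bool need_gx) {
  XPtr<BlockCache> cache(cache_xp);
  if (cache->poolidx.empty()) stop("backward called on a cache built without want_cache");
  const int H = cache->H, W = cache->W, Cin = cache->Cin, Cout = cache->Cout, N = cache->N;
  const long long HW = (long long)H * W;
  const long long M = HW * N;
  const int Hp = H / 2, Wp = W / 2;
  const long long HWp = (long long)Hp * Wp;
  if ((long long)gout.size() != HWp * Cout * N) stop("gradient size mismatch in conv block backward");

  // Un-pool + ReLU mask: gradient w.r.t. the BN output y
  arma::fmat& gy = cache->gy;
  gy.zeros(M, Cout);
  for (int n = 0; n < N; ++n) {
    for (int co = 0; co < Cout; ++co) {
      const double* gp = REAL(gout) + ((long long)n * Cout + co) * HWp;
      const long long* pidx = cache->poolidx.data() + ((long long)n * Cout + co) * HWp;
      float* gc = gy.colptr(co) + (long long)n * HW;
      for (long long t = 0; t < HWp; ++t)
        if (pidx[t] >= 0) gc[pidx[t]] += (float)gp[t];
    }
  }

  // BatchNorm backward (batch statistics)
  NumericVector ggamma(Cout), gbeta(Cout), gb(Cout);
  arma::fmat& gconv = cache->gconv;
  gconv.set_size(M, Cout);
  for (int co = 0; co < Cout; ++co) {
    const float m0 = cache->mu[co], is = cache->invstd[co], g = cache->gamma[co];
    const float* cv = cache->conv.colptr(co);
    const float* gyc = gy.colptr(co);
    double sgy = 0.0, sgyx = 0.0;
    for (long long j = 0; j < M; ++j) {
      const double xh = (double)(cv[j] - m0) * is;
      sgy += gyc[j];
      sgyx += gyc[j] * xh;
    }
    gbeta[co] = sgy;
    ggamma[co] = sgyx;
    const float mg = (float)(sgy / (double)M);
    const float mgx = (float)(sgyx / (double)M);
    float* gcv = gconv.colptr(co);
    double sb = 0.0;
    for (long long j = 0; j < M; ++j) {
      const float xh = (cv[j] - m0) * is;
      gcv[j] = g * is * (gyc[j] - mg - xh * mgx);
      sb += gcv[j];
    }
    gb[co] = sb;
  }

  arma::fmat gw = cache->K.t() * gconv;              // (9*Cin) x Cout
  NumericVector gwr(9 * (long long)Cin * Cout);
  gwr.attr("dim") = IntegerVector::create(3, 3, Cin, Cout);
  for (long long i = 0; i < (long long)gw.n_elem; ++i) gwr[i] = gw(i);

  SEXP gxr = R_NilValue;
  if (need_gx) {
    arma::fmat& gK = cache->gK;
    gK = gconv * cache->Wm.t();                      // M x (9*Cin)
    NumericVector gx(HW * Cin * (long long)N);
    gx.attr("dim") = IntegerVector::create(H, W, Cin, N);
    col2im3x3(gK, H, W, Cin, N, REAL(gx));
    gxr = gx;
  }

  return List::create(_["gx"] = gxr, _["gw"] = gwr, _["gb"] = gb,
                      _["ggamma"] = ggamma, _["gbeta"] = gbeta);
}

// Adaptive average pooling to k x k (floor/ceil bin edges).
// [[Rcpp::export(name = ".adpool_fw")]]
NumericVector adpool_fw(NumericVector x, int k) {
  check_dim4(x, "x");
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  if (k < 1 || k > H || k > W) stop("adaptive pool size %d invalid for %dx%d input", k, H, W);
  NumericVector out((long long)k * k * C * N);
  out.attr("dim") = IntegerVector::create(k, k, C, N);
  const long long HW = (long long)H * W, KK = (long long)k * k;
  for (long long cn = 0; cn < (long long)C * N; ++cn) {
    const double* plane = REAL(x) + cn * HW;
    double* op = REAL(out) + cn * KK;
    for (int px = 0; px < k; ++px) {
      const int x0 = (int)std::floor((double)px * W / k);
      const int x1 = (int)std::ceil((double)(px + 1) * W / k);
      for (int py = 0; py < k; ++py) {
        const int y0 = (int)std::floor((double)py * H / k);
        const int y1 = (int)std::ceil((double)(py + 1) * H / k);
        double s = 0.0;
        for (int cx = x0; cx < x1; ++cx)
          for (int y = y0; y < y1; ++y) s += plane[(long long)cx * H + y];
        op[(long long)px * k + py] = s / ((double)(x1 - x0) * (y1 - y0));
      }
    }
  }
  return out;
}

// [[Rcpp::export(name = ".adpool_bw")]]
NumericVector adpool_bw(NumericVector gout, int H, int W) {
  check_dim4(gout, "gout");
  IntegerVector gd = gout.attr("dim");
  const int k = gd[0], C = gd[2], N = gd[3];
  if (gd[1] != k) stop("adaptive pool gradient must be square");
  NumericVector gx((long long)H * W * C * N);
  gx.attr("dim") = IntegerVector::create(H, W, C, N);
  const long long HW = (long long)H * W, KK = (long long)k * k;
  for (long long cn = 0; cn < (long long)C * N; ++cn) {
    double* plane = REAL(gx) + cn * HW;
    const double* gp = REAL(gout) + cn * KK;
    for (int px = 0; px < k; ++px) {
      const int x0 = (int)std::floor((double)px * W / k);
      const int x1 = (int)std::ceil((double)(px + 1) * W / k);
      for (int py = 0; py < k; ++py) {
        const int y0 = (int)std::floor((double)py * H / k);
        const int y1 = (int)std::ceil((double)(py + 1) * H / k);
        const double g = gp[(long long)px * k + py] / ((double)(x1 - x0) * (y1 - y0));
        for (int cx = x0; cx < x1; ++cx)
          for (int y = y0; y < y1; ++y) plane[(long long)cx * H + y] += g;
      }
    }
  }
  return gx;
}
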