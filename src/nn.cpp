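// Minimal dense/convolutional network engine used by the CNN and FCN
// builders.  A model is an R list of layer lists; this file provides one
// batched forward (+ optional backward) pass.  Layout conventions:
//   * batch input: numeric array (H, W, C, N)
//   * conv weights: array (k, k, C_in, C_out); dense weights: matrix (in, out)
//   * spatial activations travel as one arma::cube (H, W, C) per sample,
//     which shares memory layout with the R array slice.
// Binary cross-entropy is fused with the final sigmoid, so the first
// backward gradient is (p - y) / n_elements and never touches log() twice.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

using namespace Rcpp;

typedef std::vector<arma::cube> Batch;

// -- im2col / col2im for same-padded k x k convolution ----------------------

static void im2col(const arma::cube &A, int k, arma::mat &cols) {
  const int H = A.n_rows, W = A.n_cols, C = A.n_slices, p = (k - 1) / 2;
  cols.zeros(k * k * C, H * W);
  for (int c = 0; c < C; ++c) {
    for (int dx = 0; dx < k; ++dx) {
      for (int dy = 0; dy < k; ++dy) {
        const int r = dy + k * dx + k * k * c;
        for (int w = 0; w < W; ++w) {
          const int iw = w + dx - p;
          if (iw < 0 || iw >= W) continue;
          const int h0 = std::max(0, p - dy), h1 = std::min(H, H + p - dy);
          for (int h = h0; h < h1; ++h)
            cols(r, h + H * w) = A(h + dy - p, iw, c);
        }
      }
    }
  }
}

static void col2im_acc(const arma::mat &cols, int k, arma::cube &dA) {
  const int H = dA.n_rows, W = dA.n_cols, C = dA.n_slices, p = (k - 1) / 2;
  for (int c = 0; c < C; ++c) {
    for (int dx = 0; dx < k; ++dx) {
      for (int dy = 0; dy < k; ++dy) {
        const int r = dy + k * dx + k * k * c;
        for (int w = 0; w < W; ++w) {
          const int iw = w + dx - p;
          if (iw < 0 || iw >= W) continue;
          const int h0 = std::max(0, p - dy), h1 = std::min(H, H + p - dy);
          for (int h = h0; h < h1; ++h)
            dA(h + dy - p, iw, c) += cols(r, h + H * w);
        }
      }
    }
  }
}

// -- per-layer cache --------------------------------------------------------

struct Cache {
  Batch in_sp;              // spatial input (conv, pool, bnorm, dropout, flatten)
  arma::mat in_flat;        // flat input (dense, dropout)
  Batch out_sp;             // spatial output (relu mask / fused sigmoid)
  arma::mat out_flat;       // flat output
  std::vector<arma::ucube> pool_idx;
  Batch drop_mask_sp;
  arma::mat drop_mask_flat;
  Batch xhat;               // batchnorm normalized input
  arma::vec invstd;
};

static arma::cube cube_from(const double *src, int H, int W, int C) {
  arma::cube out(H, W, C);
  std::memcpy(out.memptr(), src, sizeof(double) * H * W * C);
  return out;
}

// [[Rcpp::export(name = ".nn_batch")]]
List nn_batch(List layers, NumericVector x, Nullable<NumericVector> y_,
              bool training, bool compute_grad) {
  IntegerVector xd = x.attr("dim");
  if (xd.size() != 4) stop("input batch must be a 4-d array (H, W, C, N)");
  const int H0 = xd[0], W0 = xd[1], C0 = xd[2], N = xd[3];
  const int L = layers.size();
  if (compute_grad && y_.isNull()) stop("targets required to compute gradients");

  RNGScope rng;  // dropout masks use R's RNG -> seedable from R

  Batch A(N);
  for (int n = 0; n < N; ++n)
    A[n] = cube_from(x.begin() + (size_t)n * H0 * W0 * C0, H0, W0, C0);
  arma::mat Aflat;
  bool spatial = true;

  std::vector<Cache> caches(L);

  // ---------------- forward ----------------
  for (int li = 0; li < L; ++li) {
    List ly = layers[li];
    std::string type = as<std::string>(ly["type"]);
    Cache &cc = caches[li];

    if (type == "conv") {
      NumericVector Wv = ly["W"];
      IntegerVector wd = Wv.attr("dim");
      const int k = wd[0], Cin = wd[2], Cout = wd[3];
      const bool relu = as<bool>(ly["relu"]);
      const bool sigm = as<bool>(ly["sigmoid"]);
      if ((int)A[0].n_slices != Cin) stop("conv: channel mismatch");
      arma::mat Wm(Wv.begin(), k * k * Cin, Cout, false);
      arma::vec b = as<arma::vec>(ly["b"]);
      if (compute_grad) cc.in_sp = A;
      const int H = A[0].n_rows, W = A[0].n_cols;
      arma::mat cols;
      Batch out(N);
      for (int n = 0; n < N; ++n) {
        im2col(A[n], k, cols);
        arma::mat O = cols.t() * Wm;          // (H*W) x Cout
        O.each_row() += b.t();
        if (relu) O.transform([](double v) { return v > 0 ? v : 0.0; });
        if (sigm) O.transform([](double v) { return 1.0 / (1.0 + std::exp(-v)); });
        out[n] = cube_from(O.memptr(), H, W, Cout);
      }
      if (compute_grad) cc.out_sp = out;
      A = out;

    } else if (type == "pool") {
      const int H = A[0].n_rows, W = A[0].n_cols, C = A[0].n_slices;
      if (H % 2 || W % 2) stop("pool: odd spatial size");
      const int Ho = H / 2, Wo = W / 2;
      Batch out(N);
      if (compute_grad) {
        cc.pool_idx.resize(N);
        cc.in_sp = A;  // only shape needed, but cheap
      }
      for (int n = 0; n < N; ++n) {
        arma::cube O(Ho, Wo, C);
        arma::ucube idx(Ho, Wo, C);
        for (int c = 0; c < C; ++c)
          for (int w = 0; w < Wo; ++w)
            for (int h = 0; h < Ho; ++h) {
              double best = -1e300; arma::uword bi = 0;
              for (int dw = 0; dw < 2; ++dw)
                for (int dh = 0; dh < 2; ++dh) {
                  const int hh = 2 * h + dh, ww = 2 * w + dw;
                  const double v = A[n](hh, ww, c);
                  if (v > best) { best = v; bi = hh + H * ww + (arma::uword)H * W * c; }
                }
              O(h, w, c) = best; idx(h, w, c) = bi;
            }
        out[n] = O;
        if (compute_grad) cc.pool_idx[n] = idx;
      }
      A = out;

    } else if (type == "bnorm") {
      arma::vec gamma = as<arma::vec>(ly["gamma"]);
      arma::vec beta  = as<arma::vec>(ly["beta"]);
      arma::vec rmean = as<arma::vec>(ly["running_mean"]);
      arma::vec rvar  = as<arma::vec>(ly["running_var"]);
      const double mom = as<double>(ly["momentum"]);
      const double eps = as<double>(ly["eps"]);
      const int C = A[0].n_slices;
      const arma::uword m = (arma::uword)A[0].n_rows * A[0].n_cols * N;
      arma::vec mu(C), var(C);
      if (training) {
        for (int c = 0; c < C; ++c) {
          double s = 0, s2 = 0;
          for (int n = 0; n < N; ++n) {
            const arma::mat &sl = A[n].slice(c);
            s += arma::accu(sl); s2 += arma::accu(sl % sl);
          }
          mu(c) = s / m;
          var(c) = s2 / m - mu(c) * mu(c);
          if (var(c) < 0) var(c) = 0;
        }
      } else { mu = rmean; var = rvar; }
      arma::vec invstd = 1.0 / arma::sqrt(var + eps);
      if (compute_grad) { cc.xhat.resize(N); cc.invstd = invstd; }
      for (int n = 0; n < N; ++n) {
        arma::cube xh = A[n];
        for (int c = 0; c < C; ++c) {
          xh.slice(c) = (xh.slice(c) - mu(c)) * invstd(c);
          A[n].slice(c) = gamma(c) * xh.slice(c) + beta(c);
        }
        if (compute_grad) cc.xhat[n] = xh;
      }
      if (training && compute_grad) {
        // updated running stats travel back to R inside the grads list
        cc.out_flat = arma::join_rows(arma::vec(mom * rmean + (1 - mom) * mu),
                                      arma::vec(mom * rvar  + (1 - mom) * var));
      }

    } else if (type == "flatten") {
      const int d = A[0].n_elem;
      if (compute_grad) cc.in_sp = A;
      Aflat.set_size(d, N);
      for (int n = 0; n < N; ++n)
        std::memcpy(Aflat.colptr(n), A[n].memptr(), sizeof(double) * d);
      spatial = false;
      A.clear();

    } else if (type == "dense") {
      arma::mat Wm = as<arma::mat>(ly["W"]);  // in x out
      arma::vec b = as<arma::vec>(ly["b"]);
      const bool relu = as<bool>(ly["relu"]);
      const bool sigm = as<bool>(ly["sigmoid"]);
      if ((int)Aflat.n_rows != (int)Wm.n_rows) stop("dense: input size mismatch");
      if (compute_grad) cc.in_flat = Aflat;
      arma::mat O = Wm.t() * Aflat;           // out x N
      O.each_col() += b;
      if (relu) O.transform([](double v) { return v > 0 ? v : 0.0; });
      if (sigm) O.transform([](double v) { return 1.0 / (1.0 + std::exp(-v)); });
      if (compute_grad) cc.out_flat = O;
      Aflat = O;

    } else if (type == "dropout") {
      const double rate = as<double>(ly["rate"]);
      if (training && rate > 0) {
        const double keep = 1.0 - rate;
        if (spatial) {
          if (compute_grad) cc.drop_mask_sp.resize(N);
          for (int n = 0; n < N; ++n) {
            arma::cube msk(A[n].n_rows, A[n].n_cols, A[n].n_slices);
            for (arma::uword i = 0; i < msk.n_elem; ++i)
              msk(i) = (R::unif_rand() < keep) ? 1.0 / keep : 0.0;
            A[n] %= msk;
            if (compute_grad) cc.drop_mask_sp[n] = msk;
          }
        } else {
          arma::mat msk(Aflat.n_rows, Aflat.n_cols);
          for (arma::uword i = 0; i < msk.n_elem; ++i)
            msk(i) = (R::unif_rand() < keep) ? 1.0 / keep : 0.0;
          Aflat %= msk;
          if (compute_grad) cc.drop_mask_flat = msk;
        }
      }

    } else stop("unknown layer type '%s'", type.c_str());
  }

  // ---------------- loss ----------------
  double loss = NA_REAL;
  size_t n_out = 0;
  const double eps_clip = 1e-7;
  if (y_.isNotNull()) {
    NumericVector y(y_);
    if (spatial) {
      n_out = (size_t)A[0].n_elem * N;
      if ((size_t)y.size() != n_out) stop("target shape mismatch");
      double s = 0;
      for (int n = 0; n < N; ++n) {
        const double *yp = y.begin() + (size_t)n * A[0].n_elem;
        const double *pp = A[n].memptr();
        for (arma::uword i = 0; i < A[0].n_elem; ++i) {
          double p = std::min(1.0 - eps_clip, std::max(eps_clip, pp[i]));
          s -= yp[i] * std::log(p) + (1 - yp[i]) * std::log1p(-p);
        }
      }
      loss = s / n_out;
    } else {
      n_out = Aflat.n_elem;
      if ((size_t)y.size() != n_out) stop("target shape mismatch");
      arma::mat Y(y.begin(), Aflat.n_rows, Aflat.n_cols, false);
      arma::mat P = arma::clamp(Aflat, eps_clip, 1 - eps_clip);
      loss = -arma::accu(Y % arma::log(P) + (1 - Y) % arma::log1p(-P)) / n_out;
    }
  }

  // ---------------- output for R ----------------
  RObject out_r;  // RObject keeps the result protected across later
                  // allocations in the backward pass
  if (spatial) {
    const int H = A[0].n_rows, W = A[0].n_cols, C = A[0].n_slices;
    NumericVector arr((size_t)H * W * C * N);
    for (int n = 0; n < N; ++n)
      std::memcpy(arr.begin() + (size_t)n * H * W * C, A[n].memptr(),
                  sizeof(double) * H * W * C);
    arr.attr("dim") = IntegerVector::create(H, W, C, N);
    out_r = arr;
  } else {
    out_r = wrap(Aflat);
  }

  if (!compute_grad) {
    return List::create(_["output"] = out_r, _["loss"] = loss,
                        _["grads"] = R_NilValue);
  }

  // ---------------- backward ----------------
  NumericVector y(y_);
  Batch dA;
  arma::mat dAflat;
  bool dspatial = spatial;
  // fused sigmoid + BCE: d(pre-activation) = (p - y) / n_out
  if (spatial) {
    dA.resize(N);
    for (int n = 0; n < N; ++n) {
      arma::cube d = A[n];
      const double *yp = y.begin() + (size_t)n * d.n_elem;
      for (arma::uword i = 0; i < d.n_elem; ++i)
        d(i) = (d(i) - yp[i]) / n_out;
      dA[n] = d;
    }
  } else {
    arma::mat Y(y.begin(), Aflat.n_rows, Aflat.n_cols, false);
    dAflat = (Aflat - Y) / (double)n_out;
  }

  List grads(L);
  bool fused_done = false;  // first sigmoid layer from the top is fused

  for (int li = L - 1; li >= 0; --li) {
    List ly = layers[li];
    std::string type = as<std::string>(ly["type"]);
    Cache &cc = caches[li];

    if (type == "conv") {
      NumericVector Wv = ly["W"];
      IntegerVector wd = Wv.attr("dim");
      const int k = wd[0], Cin = wd[2], Cout = wd[3];
      const bool relu = as<bool>(ly["relu"]);
      const bool sigm = as<bool>(ly["sigmoid"]);
      arma::mat Wm(Wv.begin(), k * k * Cin, Cout, false);
      const int H = cc.out_sp[0].n_rows, W = cc.out_sp[0].n_cols;
      arma::mat dW(k * k * Cin, Cout, arma::fill::zeros);
      arma::vec db(Cout, arma::fill::zeros);
      Batch dIn(N);
      arma::mat cols;
      for (int n = 0; n < N; ++n) {
        arma::mat dO(dA[n].memptr(), (size_t)H * W, Cout);  // copy
        if (sigm && !fused_done) {
          /* gradient already wrt pre-activation (fused) */
        } else if (sigm) {
          const arma::mat Om(cc.out_sp[n].memptr(), (size_t)H * W, Cout);
          dO %= Om % (1 - Om);
        } else if (relu) {
          const arma::mat Om(cc.out_sp[n].memptr(), (size_t)H * W, Cout);
          for (arma::uword i = 0; i < dO.n_elem; ++i)
            if (Om(i) <= 0) dO(i) = 0;
        }
        im2col(cc.in_sp[n], k, cols);
        dW += cols * dO;
        db += arma::sum(dO, 0).t();
        arma::mat dcols = Wm * dO.t();
        dIn[n].zeros(cc.in_sp[n].n_rows, cc.in_sp[n].n_cols, Cin);
        col2im_acc(dcols, k, dIn[n]);
      }
      if (sigm && !fused_done) fused_done = true;
      NumericVector dWr(wrap(arma::vectorise(dW)));
      dWr.attr("dim") = wd;
      grads[li] = List::create(_["W"] = dWr, _["b"] = wrap(db));
      dA = dIn;

    } else if (type == "pool") {
      const int Hi = cc.in_sp[0].n_rows, Wi = cc.in_sp[0].n_cols,
                C = cc.in_sp[0].n_slices;
      Batch dIn(N);
      for (int n = 0; n < N; ++n) {
        dIn[n].zeros(Hi, Wi, C);
        const arma::ucube &idx = cc.pool_idx[n];
        for (arma::uword i = 0; i < idx.n_elem; ++i)
          dIn[n](idx(i)) += dA[n](i);
      }
      dA = dIn;

    } else if (type == "bnorm") {
      arma::vec gamma = as<arma::vec>(ly["gamma"]);
      const int C = cc.xhat[0].n_slices;
      const double m = (double)cc.xhat[0].n_rows * cc.xhat[0].n_cols * N;
      arma::vec dgamma(C, arma::fill::zeros), dbeta(C, arma::fill::zeros);
      for (int c = 0; c < C; ++c)
        for (int n = 0; n < N; ++n) {
          dgamma(c) += arma::accu(dA[n].slice(c) % cc.xhat[n].slice(c));
          dbeta(c)  += arma::accu(dA[n].slice(c));
        }
      for (int n = 0; n < N; ++n)
        for (int c = 0; c < C; ++c)
          dA[n].slice(c) = gamma(c) * cc.invstd(c) / m *
            (m * dA[n].slice(c) - cc.xhat[n].slice(c) * dgamma(c) - dbeta(c));
      List g = List::create(_["gamma"] = wrap(dgamma), _["beta"] = wrap(dbeta));
      if (cc.out_flat.n_elem > 0) {  // training-mode running-stat update
        g["running_mean"] = wrap(arma::vec(cc.out_flat.col(0)));
        g["running_var"]  = wrap(arma::vec(cc.out_flat.col(1)));
      }
      grads[li] = g;

    } else if (type == "flatten") {
      const int H = cc.in_sp[0].n_rows, W = cc.in_sp[0].n_cols,
                C = cc.in_sp[0].n_slices;
      dA.resize(N);
      for (int n = 0; n < N; ++n) {
        dA[n].set_size(H, W, C);
        std::memcpy(dA[n].memptr(), dAflat.colptr(n), sizeof(double) * H * W * C);
      }
      dspatial = true;
      dAflat.reset();

    } else if (type == "dense") {
      arma::mat Wm = as<arma::mat>(ly["W"]);
      const bool relu = as<bool>(ly["relu"]);
      const bool sigm = as<bool>(ly["sigmoid"]);
      arma::mat dO = dAflat;
      if (sigm && !fused_done) {
        fused_done = true;
      } else if (sigm) {
        dO %= cc.out_flat % (1 - cc.out_flat);
      } else if (relu) {
        for (arma::uword i = 0; i < dO.n_elem; ++i)
          if (cc.out_flat(i) <= 0) dO(i) = 0;
      }
      arma::mat dW = cc.in_flat * dO.t();     // in x out
      arma::vec db = arma::sum(dO, 1);
      grads[li] = List::create(_["W"] = wrap(dW), _["b"] = wrap(db));
      dAflat = Wm * dO;

    } else if (type == "dropout") {
      if (dspatial) {
        if (!cc.drop_mask_sp.empty())
          for (int n = 0; n < N; ++n) dA[n] %= cc.drop_mask_sp[n];
      } else {
        if (cc.drop_mask_flat.n_elem > 0) dAflat %= cc.drop_mask_flat;
      }
    }
  }

  return List::create(_["output"] = out_r, _["loss"] = loss, _["grads"] = grads);
}
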