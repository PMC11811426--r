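// 3-D convolution and max-pooling kernels for the video backbone.
// Tensor layout follows the R arrays: dim = (N, C, T, H, W), column-major,
// so element (n,c,t,h,w) sits at n + N*(c + C*(t + T*(h + H*w))).
// Convolution is implemented as per-sample im2col + GEMM (Armadillo/BLAS).

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

static inline int out_size(int n, int k, int s, int p) {
  return (n + 2 * p - k) / s + 1;
}

static inline long xidx(long n, long c, long t, long h, long w,
                        long N, long C, long T, long H) {
  return n + N * (c + C * (t + T * (h + H * w)));
}

// Fill the im2col matrix (K x L) for sample n. Out-of-range taps (zero
// padding) are left at zero, so the caller must zero `col` first.
static void im2col_sample(const double* xp, arma::mat& col, int n,
                          int N, int C, int T, int H, int W,
                          int kt, int kh, int kw,
                          int st, int sh, int sw,
                          int pt, int ph, int pw,
                          int To, int Ho, int Wo) {
  for (int wo = 0; wo < Wo; ++wo) {
    for (int ho = 0; ho < Ho; ++ho) {
      for (int to = 0; to < To; ++to) {
        const int l = to + To * (ho + Ho * wo);
        const int t0 = to * st - pt;
        const int h0 = ho * sh - ph;
        const int w0 = wo * sw - pw;
        for (int dw = 0; dw < kw; ++dw) {
          const int wi = w0 + dw;
          if (wi < 0 || wi >= W) continue;
          for (int dh = 0; dh < kh; ++dh) {
            const int hi = h0 + dh;
            if (hi < 0 || hi >= H) continue;
            for (int dt = 0; dt < kt; ++dt) {
              const int ti = t0 + dt;
              if (ti < 0 || ti >= T) continue;
              const int krow0 = C * (dt + kt * (dh + kh * dw));
              for (int c = 0; c < C; ++c) {
                col(krow0 + c, l) = xp[xidx(n, c, ti, hi, wi, N, C, T, H)];
              }
            }
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector conv3d_fwd_cpp(NumericVector x, NumericVector w, NumericVector b,
                             IntegerVector stride, IntegerVector pad) {
  IntegerVector xd = x.attr("dim");
  IntegerVector wd = w.attr("dim");
  const int N = xd[0], C = xd[1], T = xd[2], H = xd[3], W = xd[4];
  const int Co = wd[0], Ci = wd[1], kt = wd[2], kh = wd[3], kw = wd[4];
  if (Ci != C) stop("channel mismatch between input and kernel");
  const int st = stride[0], sh = stride[1], sw = stride[2];
  const int pt = pad[0], ph = pad[1], pw = pad[2];
  const int To = out_size(T, kt, st, pt);
  const int Ho = out_size(H, kh, sh, ph);
  const int Wo = out_size(W, kw, sw, pw);
  if (To < 1 || Ho < 1 || Wo < 1) stop("input too small for kernel/stride/padding");
  const int K = Ci * kt * kh * kw, L = To * Ho * Wo;

  // Weight array (Co, Ci, kt, kh, kw) viewed column-major is exactly the
  // Co x K matrix whose column index matches the im2col row ordering above.
  arma::mat Wm(const_cast<double*>(w.begin()), Co, K, false, true);
  arma::mat col(K, L);
  NumericVector out((R_xlen_t)N * Co * To * Ho * Wo);
  out.attr("dim") = IntegerVector::create(N, Co, To, Ho, Wo);
  const double* xp = x.begin();
  double* op = out.begin();

  for (int n = 0; n < N; ++n) {
    col.zeros();
    im2col_sample(xp, col, n, N, C, T, H, W, kt, kh, kw, st, sh, sw,
                  pt, ph, pw, To, Ho, Wo);
    arma::mat o = Wm * col;  // Co x L
    for (int l = 0; l < L; ++l) {
      const int to = l % To, r = l / To, ho = r % Ho, wo = r / Ho;
      for (int oc = 0; oc < Co; ++oc) {
        op[xidx(n, oc, to, ho, wo, N, Co, To, Ho)] = o(oc, l) + b[oc];
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
List conv3d_bwd_cpp(NumericVector x, NumericVector w, NumericVector dout,
                    IntegerVector stride, IntegerVector pad, bool need_dx) {
  IntegerVector xd = x.attr("dim");
  IntegerVector wd = w.attr("dim");
  const int N = xd[0], C = xd[1], T = xd[2], H = xd[3], W = xd[4];
  const int Co = wd[0], Ci = wd[1], kt = wd[2], kh = wd[3], kw = wd[4];
  const int st = stride[0], sh = stride[1], sw = stride[2];
  const int pt = pad[0], ph = pad[1], pw = pad[2];
  const int To = out_size(T, kt, st, pt);
  const int Ho = out_size(H, kh, sh, ph);
  const int Wo = out_size(W, kw, sw, pw);
  const int K = Ci * kt * kh * kw, L = To * Ho * Wo;

  arma::mat Wm(const_cast<double*>(w.begin()), Co, K, false, true);
  arma::mat col(K, L), dOn(Co, L);
  arma::mat dW(Co, K, arma::fill::zeros);
  arma::vec db(Co, arma::fill::zeros);
  NumericVector dx(need_dx ? x.size() : 0);
  if (need_dx) dx.attr("dim") = xd;
  const double* xp = x.begin();
  const double* dp = dout.begin();
  double* dxp = dx.begin();

  for (int n = 0; n < N; ++n) {
    col.zeros();
    im2col_sample(xp, col, n, N, C, T, H, W, kt, kh, kw, st, sh, sw,
                  pt, ph, pw, To, Ho, Wo);
    for (int l = 0; l < L; ++l) {
      const int to = l % To, r = l / To, ho = r % Ho, wo = r / Ho;
      for (int oc = 0; oc < Co; ++oc) {
        dOn(oc, l) = dp[xidx(n, oc, to, ho, wo, N, Co, To, Ho)];
      }
    }
    db += arma::sum(dOn, 1);
    dW += dOn * col.t();
    if (need_dx) {
      arma::mat dcol = Wm.t() * dOn;  // K x L, scatter-add back (col2im)
      for (int wo = 0; wo < Wo; ++wo) {
        for (int ho = 0; ho < Ho; ++ho) {
          for (int to = 0; to < To; ++to) {
            const int l = to + To * (ho + Ho * wo);
            const int t0 = to * st - pt, h0 = ho * sh - ph, w0 = wo * sw - pw;
            for (int dw_ = 0; dw_ < kw; ++dw_) {
              const int wi = w0 + dw_;
              if (wi < 0 || wi >= W) continue;
              for (int dh = 0; dh < kh; ++dh) {
                const int hi = h0 + dh;
                if (hi < 0 || hi >= H) continue;
                for (int dt = 0; dt < kt; ++dt) {
                  const int ti = t0 + dt;
                  if (ti < 0 || ti >= T) continue;
                  const int krow0 = C * (dt + kt * (dh + kh * dw_));
                  for (int c = 0; c < C; ++c) {
                    dxp[xidx(n, c, ti, hi, wi, N, C, T, H)] += dcol(krow0 + c, l);
                  }
                }
              }
            }
          }
        }
      }
    }
  }

  NumericVector dWout(w.size());
  dWout.attr("dim") = wd;
  std::copy(dW.begin(), dW.end(), dWout.begin());
  NumericVector dbout(Co);
  std::copy(db.begin(), db.end(), dbout.begin());
  return List::create(_["dw"] = dWout, _["db"] = dbout, _["dx"] = dx);
}

// Max pooling. Window positions follow the same arithmetic as the
// convolution; padding taps act as -Inf (the window is clipped to the valid
// range). Returns the pooled tensor and 1-based linear argmax indices into
// the input, for the backward scatter.
// [[Rcpp::export]]
List maxpool3d_fwd_cpp(NumericVector x, IntegerVector ksize,
                       IntegerVector stride, IntegerVector pad) {
  IntegerVector xd = x.attr("dim");
  const int N = xd[0], C = xd[1], T = xd[2], H = xd[3], W = xd[4];
  const int kt = ksize[0], kh = ksize[1], kw = ksize[2];
  const int st = stride[0], sh = stride[1], sw = stride[2];
  const int pt = pad[0], ph = pad[1], pw = pad[2];
  const int To = out_size(T, kt, st, pt);
  const int Ho = out_size(H, kh, sh, ph);
  const int Wo = out_size(W, kw, sw, pw);
  if (To < 1 || Ho < 1 || Wo < 1) stop("input too small for pooling window");

  NumericVector out((R_xlen_t)N * C * To * Ho * Wo);
  out.attr("dim") = IntegerVector::create(N, C, To, Ho, Wo);
  IntegerVector arg(out.size());
  const double* xp = x.begin();
  double* op = out.begin();
  int* ap = INTEGER(arg);

  for (int wo = 0; wo < Wo; ++wo) {
    for (int ho = 0; ho < Ho; ++ho) {
      for (int to = 0; to < To; ++to) {
        const int t0 = to * st - pt, h0 = ho * sh - ph, w0 = wo * sw - pw;
        for (int c = 0; c < C; ++c) {
          for (int n = 0; n < N; ++n) {
            double best = -std::numeric_limits<double>::infinity();
            long besti = -1;
            for (int dw_ = 0; dw_ < kw; ++dw_) {
              const int wi = w0 + dw_;
              if (wi < 0 || wi >= W) continue;
              for (int dh = 0; dh < kh; ++dh) {
                const int hi = h0 + dh;
                if (hi < 0 || hi >= H) continue;
                for (int dt = 0; dt < kt; ++dt) {
                  const int ti = t0 + dt;
                  if (ti < 0 || ti >= T) continue;
                  const long ii = xidx(n, c, ti, hi, wi, N, C, T, H);
                  if (xp[ii] > best) { best = xp[ii]; besti = ii; }
                }
              }
            }
            const long oi = xidx(n, c, to, ho, wo, N, C, To, Ho);
            op[oi] = best;
            ap[oi] = (int)(besti + 1);
          }
        }
      }
    }
  }
  return List::create(_["out"] = out, _["argmax"] = arg);
}

// [[Rcpp::export]]
NumericVector maxpool3d_bwd_cpp(NumericVector dout, IntegerVector argmax,
                                IntegerVector xdim) {
  R_xlen_t n = 1;
  for (int i = 0; i < xdim.size(); ++i) n *= xdim[i];
  NumericVector dx(n);
  dx.attr("dim") = xdim;
  double* dxp = dx.begin();
  const double* dp = dout.begin();
  const int* ap = INTEGER(argmax);
  for (R_xlen_t i = 0; i < dout.size(); ++i) dxp[ap[i] - 1] += dp[i];
  return dx;
}
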