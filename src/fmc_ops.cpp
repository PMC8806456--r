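// Low-level tensor kernels for the network engine.
// Layout convention: activations are (H, W, C, N) column-major arrays,
// convolution kernels are (kh, kw, C_in, C_out).  Convolutions are
// evaluated as im2col + GEMM so the heavy lifting goes through BLAS.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static void im2col_fill(const double* x, int H, int W, int C, int N,
                        int kh, int kw, int stride, int pad,
                        int Ho, int Wo, arma::mat& col) {
    // col: (kh*kw*C) x (Ho*Wo*N); row index = i + kh*(j + kw*c)
    // matches the column-major flattening of a (kh, kw, C) kernel block.
    const size_t plane = (size_t)H * W;
    for (int n = 0; n < N; ++n) {
        const double* xn = x + plane * C * n;
        for (int wo = 0; wo < Wo; ++wo) {
            for (int ho = 0; ho < Ho; ++ho) {
                double* cp = col.colptr((size_t)ho + (size_t)Ho * wo +
                                        (size_t)Ho * Wo * n);
                int r = 0;
                for (int c = 0; c < C; ++c) {
                    const double* xc = xn + plane * c;
                    for (int j = 0; j < kw; ++j) {
                        const int inw = wo * stride - pad + j;
                        const bool wok = (inw >= 0 && inw < W);
                        for (int i = 0; i < kh; ++i, ++r) {
                            const int inh = ho * stride - pad + i;
                            cp[r] = (wok && inh >= 0 && inh < H)
                                ? xc[(size_t)inh + (size_t)H * inw] : 0.0;
                        }
                    }
                }
            }
        }
    }
}

// [[Rcpp::export]]
NumericVector conv2d_forward_cpp(NumericVector x, NumericVector w,
                                 NumericVector b, int stride, int pad) {
    IntegerVector xd = x.attr("dim");
    IntegerVector wd = w.attr("dim");
    if (xd.size() != 4 || wd.size() != 4)
        stop("conv2d expects a (H,W,C,N) input and a (kh,kw,Cin,Cout) kernel");
    const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
    const int kh = wd[0], kw = wd[1], F = wd[3];
    if (wd[2] != C) stop("conv2d: input has %d channels, kernel expects %d", C, wd[2]);
    const int Ho = (H + 2 * pad - kh) / stride + 1;
    const int Wo = (W + 2 * pad - kw) / stride + 1;
    if (Ho < 1 || Wo < 1) stop("conv2d: kernel larger than padded input");

    arma::mat Wm(const_cast<double*>(&w[0]), (size_t)kh * kw * C, F, false, true);
    arma::mat col((size_t)kh * kw * C, (size_t)Ho * Wo * N);
    im2col_fill(&x[0], H, W, C, N, kh, kw, stride, pad, Ho, Wo, col);
    arma::mat out = Wm.t() * col;   // F x (Ho*Wo*N)

    NumericVector res((size_t)Ho * Wo * F * N);
    double* rp = &res[0];
    for (int n = 0; n < N; ++n) {
        for (int f = 0; f < F; ++f) {
            const double bf = b[f];
            for (int wo = 0; wo < Wo; ++wo)
                for (int ho = 0; ho < Ho; ++ho)
                    rp[(size_t)ho + (size_t)Ho * (wo + (size_t)Wo * (f + (size_t)F * n))] =
                        out(f, (size_t)ho + (size_t)Ho * wo + (size_t)Ho * Wo * n) + bf;
        }
    }
    res.attr("dim") = IntegerVector::create(Ho, Wo, F, N);
    return res;
}

// [[Rcpp::export]]
List conv2d_backward_cpp(NumericVector x, NumericVector w, NumericVector dout,
                         int stride, int pad, bool want_dx, bool want_dw) {
    IntegerVector xd = x.attr("dim");
    IntegerVector wd = w.attr("dim");
    IntegerVector dd = dout.attr("dim");
    const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
    const int kh = wd[0], kw = wd[1], F = wd[3];
    const int Ho = dd[0], Wo = dd[1];
    if (dd[2] != F || dd[3] != N) stop("conv2d backward: dout shape mismatch");

    // dout rearranged to (F, Ho*Wo*N) with the same column order as im2col
    arma::mat dm(F, (size_t)Ho * Wo * N);
    const double* dp = &dout[0];
    for (int n = 0; n < N; ++n)
        for (int f = 0; f < F; ++f)
            for (int wo = 0; wo < Wo; ++wo)
                for (int ho = 0; ho < Ho; ++ho)
                    dm(f, (size_t)ho + (size_t)Ho * wo + (size_t)Ho * Wo * n) =
                        dp[(size_t)ho + (size_t)Ho * (wo + (size_t)Wo * (f + (size_t)F * n))];

    List res;
    if (want_dw) {
        arma::mat col((size_t)kh * kw * C, (size_t)Ho * Wo * N);
        im2col_fill(&x[0], H, W, C, N, kh, kw, stride, pad, Ho, Wo, col);
        arma::mat dWm = col * dm.t();           // (kh*kw*C) x F
        NumericVector dw(dWm.begin(), dWm.end());
        dw.attr("dim") = IntegerVector::create(kh, kw, C, F);
        arma::vec dbv = arma::sum(dm, 1);
        NumericVector db(dbv.begin(), dbv.end());
        res["dw"] = dw;
        res["db"] = db;
    }
    if (want_dx) {
        arma::mat Wm(const_cast<double*>(&w[0]), (size_t)kh * kw * C, F, false, true);
        arma::mat dcol = Wm * dm;               // (kh*kw*C) x (Ho*Wo*N)
        NumericVector dx((size_t)H * W * C * N);
        double* dxp = &dx[0];
        const size_t plane = (size_t)H * W;
        for (int n = 0; n < N; ++n) {
            double* dxn = dxp + plane * C * n;
            for (int wo = 0; wo < Wo; ++wo) {
                for (int ho = 0; ho < Ho; ++ho) {
                    const double* cp = dcol.colptr((size_t)ho + (size_t)Ho * wo +
                                                   (size_t)Ho * Wo * n);
                    int r = 0;
                    for (int c = 0; c < C; ++c) {
                        double* dxc = dxn + plane * c;
                        for (int j = 0; j < kw; ++j) {
                            const int inw = wo * stride - pad + j;
                            const bool wok = (inw >= 0 && inw < W);
                            for (int i = 0; i < kh; ++i, ++r) {
                                const int inh = ho * stride - pad + i;
                                if (wok && inh >= 0 && inh < H)
                                    dxc[(size_t)inh + (size_t)H * inw] += cp[r];
                            }
                        }
                    }
                }
            }
        }
        dx.attr("dim") = IntegerVector::create(H, W, C, N);
        res["dx"] = dx;
    }
    return res;
}

// [[Rcpp::export]]
List maxpool_forward_cpp(NumericVector x, int size, int stride) {
    IntegerVector xd = x.attr("dim");
    const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
    const int Ho = (H - size) / stride + 1;
    const int Wo = (W - size) / stride + 1;
    if (Ho < 1 || Wo < 1) stop("maxpool: window larger than input");
    NumericVector out((size_t)Ho * Wo * C * N);
    IntegerVector idx((size_t)Ho * Wo * C * N);   // 1-based linear index into x
    const double* xp = &x[0];
    double* op = &out[0];
    int* ip = &idx[0];
    size_t o = 0;
    for (int n = 0; n < N; ++n) {
        for (int c = 0; c < C; ++c) {
            const size_t base = (size_t)H * W * (c + (size_t)C * n);
            for (int wo = 0; wo < Wo; ++wo) {
                for (int ho = 0; ho < Ho; ++ho) {
                    double best = R_NegInf;
                    size_t besti = 0;
                    for (int j = 0; j < size; ++j) {
                        const int inw = wo * stride + j;
                        for (int i = 0; i < size; ++i) {
                            const int inh = ho * stride + i;
                            const size_t li = base + (size_t)inh + (size_t)H * inw;
                            if (xp[li] > best) { best = xp[li]; besti = li; }
                        }
                    }
                    // column order of out is (ho, wo) within (c, n); write via o
                    const size_t oi = (size_t)ho + (size_t)Ho * (wo + (size_t)Wo * (c + (size_t)C * n));
                    op[oi] = best;
                    ip[oi] = (int)(besti + 1);
                    (void)o;
                }
            }
        }
    }
    out.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
    idx.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
    return List::create(_["out"] = out, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector maxpool_backward_cpp(NumericVector dout, IntegerVector idx,
                                   IntegerVector xdim) {
    const size_t nx = (size_t)xdim[0] * xdim[1] * xdim[2] * xdim[3];
    NumericVector dx(nx);
    const double* dp = &dout[0];
    const int* ip = &idx[0];
    double* dxp = &dx[0];
    const size_t no = (size_t)dout.size();
    for (size_t k = 0; k < no; ++k) dxp[(size_t)ip[k] - 1] += dp[k];
    dx.attr("dim") = xdim;
    return dx;
}
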