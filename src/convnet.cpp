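#include <Rcpp.h>
using namespace Rcpp;

// Tight-loop kernels for the 3x1 convolution and 3x1 max-pool stages.
// Arrays are column-major with dims (N, H, W, C): index
// n + N*(h + H*(w + W*c)). All loops keep the N axis innermost so memory
// access is contiguous.

// [[Rcpp::export(name = ".conv3_forward")]]
NumericVector conv3_forward(NumericVector x, IntegerVector xdim,
                            NumericVector w, NumericVector b) {
  const int N = xdim[0], H = xdim[1], W = xdim[2], C = xdim[3];
  const int F = b.size();
  const int Ho = H - 2;
  NumericVector out(static_cast<R_xlen_t>(N) * Ho * W * F);
  double *po = out.begin();
  const double *px = x.begin();
  const double *pw = w.begin(); // dims (3, C, F)
  for (int f = 0; f < F; ++f) {
    const double bf = b[f];
    double *of = po + static_cast<R_xlen_t>(f) * N * Ho * W;
    for (R_xlen_t i = 0; i < static_cast<R_xlen_t>(N) * Ho * W; ++i)
      of[i] = bf;
    for (int c = 0; c < C; ++c) {
      const double *xc = px + static_cast<R_xlen_t>(c) * N * H * W;
      for (int k = 0; k < 3; ++k) {
        const double wk = pw[k + 3 * (c + C * f)];
        if (wk == 0.0) continue;
        for (int col = 0; col < W; ++col) {
          const double *xcol = xc + static_cast<R_xlen_t>(col) * N * H;
          double *ocol = of + static_cast<R_xlen_t>(col) * N * Ho;
          for (int h = 0; h < Ho; ++h) {
            const double *xrow = xcol + static_cast<R_xlen_t>(h + k) * N;
            double *orow = ocol + static_cast<R_xlen_t>(h) * N;
            for (int n = 0; n < N; ++n) orow[n] += wk * xrow[n];
          }
        }
      }
    }
  }
  out.attr("dim") = IntegerVector::create(N, Ho, W, F);
  return out;
}

// [[Rcpp::export(name = ".conv3_backward")]]
List conv3_backward(NumericVector x, IntegerVector xdim, NumericVector w,
                    NumericVector dy) {
  const int N = xdim[0], H = xdim[1], W = xdim[2], C = xdim[3];
  const int F = static_cast<int>(w.size() / (3 * C));
  const int Ho = H - 2;
  NumericVector dW(3 * C * F), db(F), dx(x.size());
  const double *px = x.begin();
  const double *pdy = dy.begin();
  const double *pw = w.begin();
  double *pdx = dx.begin();
  for (int f = 0; f < F; ++f) {
    const double *dyf = pdy + static_cast<R_xlen_t>(f) * N * Ho * W;
    double acc_b = 0.0;
    for (R_xlen_t i = 0; i < static_cast<R_xlen_t>(N) * Ho * W; ++i)
      acc_b += dyf[i];
    db[f] = acc_b;
    for (int c = 0; c < C; ++c) {
      const double *xc = px + static_cast<R_xlen_t>(c) * N * H * W;
      double *dxc = pdx + static_cast<R_xlen_t>(c) * N * H * W;
      for (int k = 0; k < 3; ++k) {
        const double wk = pw[k + 3 * (c + C * f)];
        double acc_w = 0.0;
        for (int col = 0; col < W; ++col) {
          const double *xcol = xc + static_cast<R_xlen_t>(col) * N * H;
          double *dxcol = dxc + static_cast<R_xlen_t>(col) * N * H;
          const double *dycol = dyf + static_cast<R_xlen_t>(col) * N * Ho;
          for (int h = 0; h < Ho; ++h) {
            const double *xrow = xcol + static_cast<R_xlen_t>(h + k) * N;
            double *dxrow = dxcol + static_cast<R_xlen_t>(h + k) * N;
            const double *dyrow = dycol + static_cast<R_xlen_t>(h) * N;
            for (int n = 0; n < N; ++n) {
              acc_w += xrow[n] * dyrow[n];
              dxrow[n] += wk * dyrow[n];
            }
          }
        }
        dW[k + 3 * (c + C * f)] = acc_w;
      }
    }
  }
  dW.attr("dim") = IntegerVector::create(3, C, F);
  dx.attr("dim") = xdim;
  return List::create(Named("dW") = dW, Named("db") = db, Named("dx") = dx);
}

// [[Rcpp::export(name = ".pool3_forward")]]
List pool3_forward(NumericVector x, IntegerVector xdim) {
  const int N = xdim[0], H = xdim[1], W = xdim[2], C = xdim[3];
  const int Hp = H / 3;
  NumericVector out(static_cast<R_xlen_t>(N) * Hp * W * C);
  IntegerVector which(out.size()); // winning row offset 0/1/2, first wins
  const double *px = x.begin();
  double *po = out.begin();
  int *pwh = which.begin();
  for (int c = 0; c < C; ++c)
    for (int col = 0; col < W; ++col) {
      const double *xcol = px +
        static_cast<R_xlen_t>(c) * N * H * W +
        static_cast<R_xlen_t>(col) * N * H;
      R_xlen_t obase = static_cast<R_xlen_t>(c) * N * Hp * W +
        static_cast<R_xlen_t>(col) * N * Hp;
      for (int p = 0; p < Hp; ++p) {
        const double *r0 = xcol + static_cast<R_xlen_t>(3 * p) * N;
        const double *r1 = r0 + N;
        const double *r2 = r1 + N;
        double *orow = po + obase + static_cast<R_xlen_t>(p) * N;
        int *wrow = pwh + obase + static_cast<R_xlen_t>(p) * N;
        for (int n = 0; n < N; ++n) {
          double v = r0[n];
          int idx = 0;
          if (r1[n] > v) { v = r1[n]; idx = 1; }
          if (r2[n] > v) { v = r2[n]; idx = 2; }
          orow[n] = v;
          wrow[n] = idx;
        }
      }
    }
  IntegerVector odim = IntegerVector::create(N, Hp, W, C);
  out.attr("dim") = odim;
  which.attr("dim") = odim;
  return List::create(Named("out") = out, Named("which") = which,
                      Named("H") = H);
}

// [[Rcpp::export(name = ".pool3_backward")]]
NumericVector pool3_backward(IntegerVector which, NumericVector dy, int H) {
  IntegerVector ydim = dy.attr("dim");
  const int N = ydim[0], Hp = ydim[1], W = ydim[2], C = ydim[3];
  NumericVector dx(static_cast<R_xlen_t>(N) * H * W * C);
  const double *pdy = dy.begin();
  const int *pwh = which.begin();
  double *pdx = dx.begin();
  for (int c = 0; c < C; ++c)
    for (int col = 0; col < W; ++col) {
      R_xlen_t ybase = static_cast<R_xlen_t>(c) * N * Hp * W +
        static_cast<R_xlen_t>(col) * N * Hp;
      double *dxcol = pdx + static_cast<R_xlen_t>(c) * N * H * W +
        static_cast<R_xlen_t>(col) * N * H;
      for (int p = 0; p < Hp; ++p) {
        const double *dyrow = pdy + ybase + static_cast<R_xlen_t>(p) * N;
        const int *wrow = pwh + ybase + static_cast<R_xlen_t>(p) * N;
        double *dx0 = dxcol + static_cast<R_xlen_t>(3 * p) * N;
        for (int n = 0; n < N; ++n)
          dx0[n + static_cast<R_xlen_t>(wrow[n]) * N] = dyrow[n];
      }
    }
  dx.attr("dim") = IntegerVector::create(N, H, W, C);
  return dx;
}
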