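// Dense kernels for the U-Net forward/backward passes.
//
// Feature maps are arma::cube with layout (H, W, C): slice c is the c-th
// channel image.  A cube's memory is exactly an (H*W) x C column-major
// matrix, which lets every convolution reduce to BLAS GEMMs over kernel
// offsets without materialising an im2col buffer.
//
// Weight layouts (passed as R arrays, column-major):
//   conv:            dim (k, k, c_in, c_out)
//   transposed conv: dim (2, 2, c_in, c_out)

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static arma::cube as_cube(const NumericVector& x) {
  IntegerVector d = x.attr("dim");
  if (d.size() != 3) stop("expected a 3-d array (H, W, C)");
  // copy: the cube outlives the R object in intermediate arithmetic
  arma::cube out(x.begin(), d[0], d[1], d[2]);
  return out;
}

static NumericVector wrap_cube(const arma::cube& c) {
  NumericVector out(c.begin(), c.end());
  out.attr("dim") = IntegerVector::create(c.n_rows, c.n_cols, c.n_slices);
  return out;
}

// weight slice W_o(c_in x c_out) for kernel offset (a, b)
static arma::mat offset_weights(const NumericVector& w, int k, int cin,
                                int cout, int a, int b) {
  arma::mat wo(cin, cout);
  const double* wp = w.begin();
  for (int co = 0; co < cout; ++co)
    for (int ci = 0; ci < cin; ++ci)
      wo(ci, co) = wp[a + k * b + k * k * ci + (R_xlen_t)k * k * cin * co];
  return wo;
}

static arma::cube zero_pad(const arma::cube& x, int p) {
  arma::cube xp(x.n_rows + 2 * p, x.n_cols + 2 * p, x.n_slices,
                arma::fill::zeros);
  xp.subcube(p, p, 0, p + x.n_rows - 1, p + x.n_cols - 1, x.n_slices - 1) = x;
  return xp;
}

// same-padding stride-1 2-d convolution
// [[Rcpp::export]]
NumericVector cpp_conv2d_fwd(NumericVector x_, NumericVector w,
                             NumericVector bias) {
  arma::cube x = as_cube(x_);
  IntegerVector wd = w.attr("dim");
  if (wd.size() != 4) stop("conv weights must be a 4-d array");
  const int k = wd[0], cin = wd[2], cout = wd[3];
  if (wd[1] != k) stop("conv kernel must be square");
  if (k % 2 == 0) stop("conv kernel size must be odd for same padding");
  if ((int)x.n_slices != cin) stop("input channel mismatch");
  const int H = x.n_rows, W = x.n_cols, p = k / 2;

  arma::cube xp = zero_pad(x, p);
  arma::mat O(H * (R_xlen_t)W, cout);
  O.each_row() = arma::rowvec(bias.begin(), cout);

  arma::mat S(H * (R_xlen_t)W, cin);
  for (int a = 0; a < k; ++a) {
    for (int b = 0; b < k; ++b) {
      for (int c = 0; c < cin; ++c)
        S.col(c) = arma::vectorise(
            xp.slice(c).submat(a, b, a + H - 1, b + W - 1));
      O += S * offset_weights(w, k, cin, cout, a, b);
    }
  }
  arma::cube oc(O.memptr(), H, W, cout);
  return wrap_cube(oc);
}

// gradients of the same-padding convolution
// [[Rcpp::export]]
List cpp_conv2d_bwd(NumericVector x_, NumericVector w, NumericVector gout_) {
  arma::cube x = as_cube(x_);
  arma::cube go = as_cube(gout_);
  IntegerVector wd = w.attr("dim");
  const int k = wd[0], cin = wd[2], cout = wd[3];
  const int H = x.n_rows, W = x.n_cols, p = k / 2;
  if ((int)go.n_slices != cout || (int)go.n_rows != H || (int)go.n_cols != W)
    stop("gradient shape mismatch");

  arma::cube xp = zero_pad(x, p);
  arma::mat G(go.memptr(), H * (R_xlen_t)W, cout, false);

  NumericVector gw(w.size());
  gw.attr("dim") = wd;
  NumericVector gb(cout);
  for (int co = 0; co < cout; ++co) gb[co] = arma::accu(G.col(co));

  arma::cube gxp(H + 2 * p, W + 2 * p, cin, arma::fill::zeros);
  arma::mat S(H * (R_xlen_t)W, cin);
  for (int a = 0; a < k; ++a) {
    for (int b = 0; b < k; ++b) {
      for (int c = 0; c < cin; ++c)
        S.col(c) = arma::vectorise(
            xp.slice(c).submat(a, b, a + H - 1, b + W - 1));
      arma::mat gWo = S.t() * G;  // cin x cout
      double* gwp = gw.begin();
      for (int co = 0; co < cout; ++co)
        for (int ci = 0; ci < cin; ++ci)
          gwp[a + k * b + k * k * ci + (R_xlen_t)k * k * cin * co] +=
              gWo(ci, co);
      arma::mat GX = G * offset_weights(w, k, cin, cout, a, b).t();
      for (int c = 0; c < cin; ++c)
        gxp.slice(c).submat(a, b, a + H - 1, b + W - 1) +=
            arma::reshape(GX.col(c), H, W);
    }
  }
  arma::cube gx =
      gxp.subcube(p, p, 0, p + H - 1, p + W - 1, cin - 1);
  return List::create(_["gx"] = wrap_cube(gx), _["gw"] = gw, _["gb"] = gb);
}

// 2x2 stride-2 transposed convolution (exact doubling, no overlap)
// [[Rcpp::export]]
NumericVector cpp_convt2_fwd(NumericVector x_, NumericVector w,
                             NumericVector bias) {
  arma::cube x = as_cube(x_);
  IntegerVector wd = w.attr("dim");
  if (wd.size() != 4 || wd[0] != 2 || wd[1] != 2)
    stop("transposed-conv weights must have dim (2, 2, c_in, c_out)");
  const int cin = wd[2], cout = wd[3];
  if ((int)x.n_slices != cin) stop("input channel mismatch");
  const int H = x.n_rows, W = x.n_cols;

  arma::mat Xm(x.memptr(), H * (R_xlen_t)W, cin, false);
  arma::mat Wm(cin, 4 * cout);
  const double* wp = w.begin();
  for (int co = 0; co < cout; ++co)
    for (int ci = 0; ci < cin; ++ci)
      for (int b = 0; b < 2; ++b)
        for (int a = 0; a < 2; ++a)
          Wm(ci, a + 2 * b + 4 * co) =
              wp[a + 2 * b + 4 * ci + (R_xlen_t)4 * cin * co];
  arma::mat P = Xm * Wm;  // (H*W) x (4*cout)

  arma::cube out(2 * H, 2 * W, cout);
  for (int co = 0; co < cout; ++co) out.slice(co).fill(bias[co]);
  for (int co = 0; co < cout; ++co)
    for (int b = 0; b < 2; ++b)
      for (int a = 0; a < 2; ++a) {
        arma::mat Pij(P.colptr(a + 2 * b + 4 * co), H, W, false);
        // strided scatter: rows a, a+2, ..., cols b, b+2, ...
        arma::mat& os = out.slice(co);
        for (int j = 0; j < W; ++j)
          for (int i = 0; i < H; ++i) os(2 * i + a, 2 * j + b) += Pij(i, j);
      }
  return wrap_cube(out);
}

// [[Rcpp::export]]
List cpp_convt2_bwd(NumericVector x_, NumericVector w, NumericVector gout_) {
  arma::cube x = as_cube(x_);
  arma::cube go = as_cube(gout_);
  IntegerVector wd = w.attr("dim");
  const int cin = wd[2], cout = wd[3];
  const int H = x.n_rows, W = x.n_cols;
  if ((int)go.n_rows != 2 * H || (int)go.n_cols != 2 * W ||
      (int)go.n_slices != cout)
    stop("gradient shape mismatch");

  // gather strided gradient back into patch matrix
  arma::mat Pg(H * (R_xlen_t)W, 4 * cout);
  for (int co = 0; co < cout; ++co)
    for (int b = 0; b < 2; ++b)
      for (int a = 0; a < 2; ++a) {
        arma::mat block(H, W);
        const arma::mat& gs = go.slice(co);
        for (int j = 0; j < W; ++j)
          for (int i = 0; i < H; ++i) block(i, j) = gs(2 * i + a, 2 * j + b);
        Pg.col(a + 2 * b + 4 * co) = arma::vectorise(block);
      }

  arma::mat Xm(x.memptr(), H * (R_xlen_t)W, cin, false);
  arma::mat gWm = Xm.t() * Pg;  // cin x 4cout

  NumericVector gw(w.size());
  gw.attr("dim") = wd;
  double* gwp = gw.begin();
  for (int co = 0; co < cout; ++co)
    for (int ci = 0; ci < cin; ++ci)
      for (int b = 0; b < 2; ++b)
        for (int a = 0; a < 2; ++a)
          gwp[a + 2 * b + 4 * ci + (R_xlen_t)4 * cin * co] =
              gWm(ci, a + 2 * b + 4 * co);

  NumericVector gb(cout);
  for (int co = 0; co < cout; ++co) gb[co] = arma::accu(go.slice(co));

  arma::mat Wm(cin, 4 * cout);
  const double* wp = w.begin();
  for (int co = 0; co < cout; ++co)
    for (int ci = 0; ci < cin; ++ci)
      for (int b = 0; b < 2; ++b)
        for (int a = 0; a < 2; ++a)
          Wm(ci, a + 2 * b + 4 * co) =
              wp[a + 2 * b + 4 * ci + (R_xlen_t)4 * cin * co];
  arma::mat GX = Pg * Wm.t();  // (H*W) x cin
  arma::cube gx(GX.memptr(), H, W, cin);
  return List::create(_["gx"] = wrap_cube(gx), _["gw"] = gw, _["gb"] = gb);
}

// 2x2 stride-2 max pooling; argmax returned as 0-based linear index into
// the input cube so the backward pass is a pure scatter
// [[Rcpp::export]]
List cpp_maxpool2_fwd(NumericVector x_) {
  arma::cube x = as_cube(x_);
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  if (H % 2 || W % 2) stop("spatial size must be even for 2x2 pooling");
  const int Ho = H / 2, Wo = W / 2;
  arma::cube out(Ho, Wo, C);
  IntegerVector arg((R_xlen_t)Ho * Wo * C);
  R_xlen_t q = 0;
  for (int c = 0; c < C; ++c) {
    const arma::mat& xs = x.slice(c);
    for (int j = 0; j < Wo; ++j)
      for (int i = 0; i < Ho; ++i) {
        int bi = 2 * i, bj = 2 * j;
        double best = xs(bi, bj);
        int ba = bi, bb = bj;
        if (xs(bi + 1, bj) > best) { best = xs(bi + 1, bj); ba = bi + 1; }
        if (xs(bi, bj + 1) > best) { best = xs(bi, bj + 1); ba = bi; bb = bj + 1; }
        if (xs(bi + 1, bj + 1) > best) { best = xs(bi + 1, bj + 1); ba = bi + 1; bb = bj + 1; }
        out(i, j, c) = best;
        arg[(R_xlen_t)c * Ho * Wo + (R_xlen_t)j * Ho + i] =
            c * H * W + bb * H + ba;
        ++q;
      }
  }
  (void)q;
  return List::create(_["out"] = wrap_cube(out), _["argmax"] = arg);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool2_bwd(NumericVector gout_, IntegerVector argmax,
                               int H, int W) {
  arma::cube go = as_cube(gout_);
  const int C = go.n_slices;
  arma::cube gx(H, W, C, arma::fill::zeros);
  double* gp = gx.memptr();
  const double* gop = go.memptr();
  for (R_xlen_t q = 0; q < argmax.size(); ++q) gp[argmax[q]] += gop[q];
  return wrap_cube(gx);
}
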