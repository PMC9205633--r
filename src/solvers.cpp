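#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// reflect index into [0, n-1] (symmetric padding without edge repeat for n > 1)
static inline int reflect_idx(int i, int n) {
  if (n == 1) return 0;
  while (i < 0 || i >= n) {
    if (i < 0) i = -i - 1;
    if (i >= n) i = 2 * n - i - 1;
  }
  return i;
}

// 2-D median filter, square window of odd side `wnd`, reflected boundaries.
// [[Rcpp::export]]
arma::mat cpp_median_filter(const arma::mat& x, int wnd) {
  int h = x.n_rows, w = x.n_cols;
  if (wnd <= 1) return x;
  int r = (wnd - 1) / 2;
  arma::mat out(h, w);
  std::vector<double> buf(wnd * wnd);
  for (int j = 0; j < w; ++j) {
    for (int i = 0; i < h; ++i) {
      int k = 0;
      for (int dj = -r; dj <= r; ++dj) {
        int jj = reflect_idx(j + dj, w);
        for (int di = -r; di <= r; ++di) {
          buf[k++] = x(reflect_idx(i + di, h), jj);
        }
      }
      std::nth_element(buf.begin(), buf.begin() + k / 2, buf.begin() + k);
      out(i, j) = buf[k / 2];
    }
  }
  return out;
}

// Pearson correlation of `frame` against `templ` displaced by (dy, dx),
// computed over the overlap restricted to a `margin`-px interior of the
// template (a margin >= the search radius keeps the overlap constant
// across candidate shifts and ignores border bands left by earlier
// integer translations).
static double ncc_at_shift(const arma::mat& frame, const arma::mat& templ,
                           int dy, int dx, int margin) {
  int h = frame.n_rows, w = frame.n_cols;
  int i0 = std::max(margin, dy), i1 = std::min(h - margin, h + dy);
  int j0 = std::max(margin, dx), j1 = std::min(w - margin, w + dx);
  long n = (long)(i1 - i0) * (j1 - j0);
  if (n < 2) return -2.0;
  double sf = 0, st = 0, sff = 0, stt = 0, sft = 0;
  for (int j = j0; j < j1; ++j) {
    for (int i = i0; i < i1; ++i) {
      double a = frame(i, j), b = templ(i - dy, j - dx);
      sf += a; st += b; sff += a * a; stt += b * b; sft += a * b;
    }
  }
  double vf = sff - sf * sf / n, vt = stt - st * st / n;
  if (vf <= 0 || vt <= 0) return -2.0;
  return (sft - sf * st / n) / std::sqrt(vf * vt);
}

// Exhaustive integer-shift normalized cross-correlation.
// Returns (shift_row, shift_col) maximizing NCC; ties broken by smallest
// L-infinity norm, then |row|, then |col|, then signed row, then signed col.
// When margin >= max_shift the template window is constant across shifts,
// so its moments are hoisted and the frame-window sums come from integral
// images; only the cross term is accumulated per shift.
// [[Rcpp::export]]
IntegerVector cpp_match_template(const arma::mat& frame, const arma::mat& templ,
                                 int max_shift, int margin = 0) {
  if (frame.n_rows != templ.n_rows || frame.n_cols != templ.n_cols)
    stop("frame and template must have the same shape");
  int h = frame.n_rows, w = frame.n_cols;
  int hw = std::min(h, w);
  if (2 * margin + 2 > hw) margin = std::max(0, (hw - 2) / 2);
  bool fast = margin >= max_shift && 2 * margin + 2 <= hw;
  double st = 0, stt = 0;
  long nwin = 0;
  arma::mat I1, I2;
  if (fast) {
    for (int j = margin; j < w - margin; ++j)
      for (int i = margin; i < h - margin; ++i) {
        double b = templ(i, j);
        st += b; stt += b * b;
      }
    nwin = (long)(h - 2 * margin) * (w - 2 * margin);
    // integral images of frame and frame^2 (I(i+1, j+1) = sum over [0..i]x[0..j])
    I1.zeros(h + 1, w + 1); I2.zeros(h + 1, w + 1);
    for (int j = 0; j < w; ++j)
      for (int i = 0; i < h; ++i) {
        double a = frame(i, j);
        I1(i + 1, j + 1) = a + I1(i, j + 1) + I1(i + 1, j) - I1(i, j);
        I2(i + 1, j + 1) = a * a + I2(i, j + 1) + I2(i + 1, j) - I2(i, j);
      }
  }
  double vt = fast ? (stt - st * st / nwin) : 0.0;
  double best = -3.0;
  int bdy = 0, bdx = 0;
  bool any = false;
  for (int dy = -max_shift; dy <= max_shift; ++dy) {
    for (int dx = -max_shift; dx <= max_shift; ++dx) {
      double r;
      if (fast) {
        if (vt <= 0) { r = -2.0; }
        else {
          int i0 = margin + dy, j0 = margin + dx;        // frame window start
          int i1 = h - margin + dy, j1 = w - margin + dx; // one past end
          double sf = I1(i1, j1) - I1(i0, j1) - I1(i1, j0) + I1(i0, j0);
          double sff = I2(i1, j1) - I2(i0, j1) - I2(i1, j0) + I2(i0, j0);
          double sft = 0;
          for (int j = margin; j < w - margin; ++j) {
            const double* fc = frame.colptr(j + dx) + dy;
            const double* tc = templ.colptr(j);
            for (int i = margin; i < h - margin; ++i) sft += fc[i] * tc[i];
          }
          double vf = sff - sf * sf / nwin;
          r = (vf <= 0) ? -2.0 : (sft - sf * st / nwin) / std::sqrt(vf * vt);
        }
      } else {
        r = ncc_at_shift(frame, templ, dy, dx, margin);
      }
      if (r <= -2.0) continue;
      any = true;
      bool take = false;
      if (r > best) {
        take = true;
      } else if (r == best) {
        int li = std::max(std::abs(dy), std::abs(dx));
        int lb = std::max(std::abs(bdy), std::abs(bdx));
        if (li < lb) take = true;
        else if (li == lb) {
          if (std::abs(dy) < std::abs(bdy)) take = true;
          else if (std::abs(dy) == std::abs(bdy)) {
            if (std::abs(dx) < std::abs(bdx)) take = true;
            else if (std::abs(dx) == std::abs(bdx)) {
              if (dy < bdy || (dy == bdy && dx < bdx)) take = true;
            }
          }
        }
      }
      if (take) { best = r; bdy = dy; bdx = dx; }
    }
  }
  if (!any) stop("flat image: normalized cross-correlation undefined");
  return IntegerVector::create(bdy, bdx);
}

// Per-pixel non-negative lasso for the spatial update, by cyclic coordinate
// descent on the Gram form.  X = [C f] (T x (K+1)), M = X'X, V = X'Y.
// cand: list of integer vectors (1-based component indices allowed at each
// pixel; the background component K+1 carries no l1 penalty).
// lambda: per-pixel l1 weight.  Returns (K+1) x P coefficient matrix.
// [[Rcpp::export]]
arma::mat cpp_spatial_lasso(const arma::mat& M, const arma::mat& V,
                            const List& cand, const arma::vec& lambda,
                            int n_unit, double tol, int max_sweep) {
  int K1 = M.n_rows;
  int P = V.n_cols;
  arma::mat A(K1, P, arma::fill::zeros);
  for (int p = 0; p < P; ++p) {
    IntegerVector cj = cand[p];
    int nc = cj.size();
    if (nc == 0) continue;
    std::vector<int> idx(nc);
    for (int q = 0; q < nc; ++q) idx[q] = cj[q] - 1;
    std::vector<double> a(nc, 0.0);
    double lam2 = lambda[p] / 2.0;
    for (int sweep = 0; sweep < max_sweep; ++sweep) {
      double delta = 0.0;
      for (int q = 0; q < nc; ++q) {
        int j = idx[q];
        double mjj = M(j, j);
        if (mjj <= 0) continue;
        double g = V(j, p);
        for (int q2 = 0; q2 < nc; ++q2) {
          if (q2 == q) continue;
          g -= M(j, idx[q2]) * a[q2];
        }
        if (j < n_unit) g -= lam2;  // background component unpenalized
        double anew = g / mjj;
        if (anew < 0) anew = 0;
        delta = std::max(delta, std::fabs(anew - a[q]));
        a[q] = anew;
      }
      if (delta < tol) break;
    }
    for (int q = 0; q < nc; ++q) A(idx[q], p) = a[q];
  }
  return A;
}

// Temporal deconvolution by coordinate descent on the spike parametrization.
// minimize ||y - D s - b0 - c0 d||^2 + lambda * sum(s)
//   s.t. s >= 0, b0 >= 0, c0 >= 0
// where D is lower-triangular Toeplitz with first column d (the AR impulse
// response, truncated to length L for speed).  c = D s.
// [[Rcpp::export]]
List cpp_temporal_cd(const arma::vec& y, const arma::vec& d, double lambda,
                     double tol, int max_sweep, bool fit_b0, bool fit_c0) {
  int T = y.n_elem;
  int L = d.n_elem;
  if (L > T) L = T;
  // cumulative squared norms of (possibly truncated) columns
  arma::vec d2cum(L + 1, arma::fill::zeros);
  for (int k = 0; k < L; ++k) d2cum[k + 1] = d2cum[k] + d[k] * d[k];
  arma::vec dfull(T, arma::fill::zeros);
  for (int k = 0; k < std::min<int>(T, L); ++k) dfull[k] = d[k];
  double dd_full = arma::dot(dfull, dfull);

  arma::vec s(T, arma::fill::zeros);
  double b0 = 0.0, c0 = 0.0;
  arma::vec r = y;  // residual
  double lam2 = lambda / 2.0;
  double yscale = arma::norm(y, "inf");
  if (yscale <= 0) yscale = 1.0;
  for (int sweep = 0; sweep < max_sweep; ++sweep) {
    double delta = 0.0;
    for (int t = 0; t < T; ++t) {
      int len = std::min(L, T - t);
      double dd = d2cum[len];
      if (dd <= 0) continue;
      double g = 0.0;
      for (int k = 0; k < len; ++k) g += d[k] * r[t + k];
      double snew = s[t] + (g - lam2) / dd;
      if (snew < 0) snew = 0;
      double ds = snew - s[t];
      if (ds != 0.0) {
        for (int k = 0; k < len; ++k) r[t + k] -= ds * d[k];
        s[t] = snew;
        delta = std::max(delta, std::fabs(ds));
      }
    }
    if (fit_b0) {
      double g = arma::mean(r);
      double bnew = b0 + g;
      if (bnew < 0) bnew = 0;
      double db = bnew - b0;
      if (db != 0.0) { r -= db; b0 = bnew; delta = std::max(delta, std::fabs(db)); }
    }
    if (fit_c0 && dd_full > 0) {
      double g = arma::dot(dfull, r) / dd_full;
      double cnew = c0 + g;
      if (cnew < 0) cnew = 0;
      double dc = cnew - c0;
      if (dc != 0.0) { r -= dc * dfull; c0 = cnew; delta = std::max(delta, std::fabs(dc)); }
    }
    if (delta < tol * yscale) break;
  }
  // calcium trace c = D s (truncated kernel)
  arma::vec c(T, arma::fill::zeros);
  for (int t = 0; t < T; ++t) {
    if (s[t] == 0.0) continue;
    int len = std::min(L, T - t);
    for (int k = 0; k < len; ++k) c[t + k] += s[t] * d[k];
  }
  return List::create(_["c"] = c, _["s"] = s, _["b0"] = b0, _["c0"] = c0);
}

// Integer translation of a frame by (-dy, -dx) (undoing an estimated shift),
// vacated borders filled with `fill`.
// [[Rcpp::export]]
arma::mat cpp_shift_frame(const arma::mat& x, int dy, int dx, double fill) {
  int h = x.n_rows, w = x.n_cols;
  arma::mat out(h, w);
  out.fill(fill);
  // out(i, j) = x(i + dy, j + dx) when in bounds
  int i0 = std::max(0, -dy), i1 = std::min(h, h - dy);
  int j0 = std::max(0, -dx), j1 = std::min(w, w - dx);
  for (int j = j0; j < j1; ++j)
    for (int i = i0; i < i1; ++i)
      out(i, j) = x(i + dy, j + dx);
  return out;
}
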