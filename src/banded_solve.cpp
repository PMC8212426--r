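#include <Rcpp.h>
using namespace Rcpp;

// Solve (I + alpha * D1' W1 D1 + beta * D3' W3 D3) x = y where D1 and D3
// are the first- and third-order difference operators and W1, W3 are
// diagonal weight matrices (vectors w1 of length n-1, w3 of length n-3).
//
// The weights span a dynamic range up to 1/epsilon ~ 1e10, so instead of a
// Cholesky factorization of the squared-condition normal equations, the
// update is computed as the banded least-squares problem
//
//     min_x || [ I; sqrt(alpha W1) D1; sqrt(beta W3) D3 ] x - [y; 0; 0] ||_2
//
// by Givens QR with all rows spanning at most 4 adjacent columns, keeping
// R upper banded with bandwidth 3. Cost is O(n); forward error scales with
// the square root of the normal-equation condition number.

// [[Rcpp::export]]
NumericVector gtv_banded_solve(NumericVector y, NumericVector w1,
                               NumericVector w3, double alpha, double beta) {
  const int n = y.size();
  if (n < 4)
    stop("series too short for the third-difference penalty (need n >= 4)");
  if (w1.size() != n - 1 || w3.size() != n - 3)
    stop("weight vectors have wrong length");

  // R bands: r0[i] = R[i,i], rd[i] = R[i,i+d]; q = Q'b
  std::vector<double> r0(n, 0.0), r1(n, 0.0), r2(n, 0.0), r3(n, 0.0), q(n, 0.0);

  // eliminate one row (cols c..c+3 in w[0..3], rhs brow) into R
  auto add_row = [&](int c, double w0, double w1v, double w2v, double w3v,
                     double brow) {
    double w[4] = {w0, w1v, w2v, w3v};
    while (c < n) {
      if (w[0] == 0.0) {
        w[0] = w[1]; w[1] = w[2]; w[2] = w[3]; w[3] = 0.0;
        ++c;
        if (w[0] == 0.0 && w[1] == 0.0 && w[2] == 0.0 && w[3] == 0.0) return;
        continue;
      }
      if (r0[c] == 0.0) {            // column slot empty: row becomes R row c
        r0[c] = w[0]; r1[c] = w[1]; r2[c] = w[2]; r3[c] = w[3];
        q[c] = brow;
        return;
      }
      const double a = r0[c], b = w[0];
      const double g = std::hypot(a, b);
      const double cs = a / g, sn = b / g;
      double rr[4] = {r0[c], r1[c], r2[c], r3[c]};
      for (int t = 0; t < 4; ++t) {
        const double tmp = cs * rr[t] + sn * w[t];
        w[t] = -sn * rr[t] + cs * w[t];
        rr[t] = tmp;
      }
      r0[c] = rr[0]; r1[c] = rr[1]; r2[c] = rr[2]; r3[c] = rr[3];
      const double tq = cs * q[c] + sn * brow;
      brow = -sn * q[c] + cs * brow;
      q[c] = tq;
      // w[0] is now exactly representable as 0
      w[0] = w[1]; w[1] = w[2]; w[2] = w[3]; w[3] = 0.0;
      ++c;
      if (w[0] == 0.0 && w[1] == 0.0 && w[2] == 0.0 && w[3] == 0.0) return;
    }
  };

  const double sa = (alpha > 0.0) ? std::sqrt(alpha) : 0.0;
  const double sb = (beta > 0.0) ? std::sqrt(beta) : 0.0;
  for (int k = 0; k < n; ++k) {
    add_row(k, 1.0, 0.0, 0.0, 0.0, y[k]);                    // fidelity row
    if (sa > 0.0 && k < n - 1) {
      const double s = sa * std::sqrt(w1[k]);
      if (s > 0.0) add_row(k, -s, s, 0.0, 0.0, 0.0);          // D1 row
    }
    if (sb > 0.0 && k < n - 3) {
      const double s = sb * std::sqrt(w3[k]);
      if (s > 0.0) add_row(k, -s, 3.0 * s, -3.0 * s, s, 0.0); // D3 row
    }
  }

  NumericVector x(n);
  for (int i = n - 1; i >= 0; --i) {
    if (r0[i] == 0.0) stop("rank-deficient system");
    double s = q[i];
    if (i + 1 < n) s -= r1[i] * x[i + 1];
    if (i + 2 < n) s -= r2[i] * x[i + 2];
    if (i + 3 < n) s -= r3[i] * x[i + 3];
    x[i] = s / r0[i];
  }
  return x;
}
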