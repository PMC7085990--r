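#include <Rcpp.h>
using namespace Rcpp;

// Exact convolution of a piecewise-linear curve c(t) (knots t, values c)
// with exp(-theta * t), together with the running time-integral of the
// convolution:
//
//   y(t) = int_0^t exp(-theta (t - s)) c(s) ds
//   S(t) = int_0^t y(u) du
//
// evaluated at the knots. Per segment of width h with c(s) = cj + m*(s-tj),
// the update uses the closed-form moments
//   F = (1 - e^{-theta h}) / theta
//   G = (h - F) / theta
//   H = (h^2/2 - G) / theta
// which are computed by series expansion when theta*h is small so that the
// theta -> 0 limit (y = running integral of c, S = its double integral) is
// reached without cancellation.
// [[Rcpp::export]]
List conv_exp_cpp(NumericVector t, NumericVector c, double theta) {
  const int n = t.size();
  NumericVector y(n), S(n);
  if (n < 2) return List::create(_["y"] = y, _["S"] = S);
  for (int j = 0; j + 1 < n; ++j) {
    const double h  = t[j + 1] - t[j];
    const double cj = c[j];
    const double m  = (h > 0.0) ? (c[j + 1] - c[j]) / h : 0.0;
    const double a  = theta * h;
    double E, F, G, H;
    if (a < 1e-4) {
      E = std::exp(-a);
      F = h * (1.0 - a / 2.0 + a * a / 6.0 - a * a * a / 24.0);
      G = h * h * (0.5 - a / 6.0 + a * a / 24.0 - a * a * a / 120.0);
      H = h * h * h * (1.0 / 6.0 - a / 24.0 + a * a / 120.0 - a * a * a / 720.0);
    } else {
      E = std::exp(-a);
      F = (1.0 - E) / theta;
      G = (h - F) / theta;
      H = (h * h / 2.0 - G) / theta;
    }
    y[j + 1] = y[j] * E + cj * F + m * G;
    S[j + 1] = S[j] + y[j] * F + cj * G + m * H;
  }
  return List::create(_["y"] = y, _["S"] = S);
}
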