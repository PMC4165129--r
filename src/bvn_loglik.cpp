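#include <Rcpp.h>
#include <cmath>
#include <limits>

using namespace Rcpp;

// Bivariate-normal machinery for the interval-censored ripening likelihood.
// The hot path (one likelihood evaluation) needs ~1e4-1e5 rectangle
// probabilities, so the standard-normal rectangle and the quadrature sum
// live here rather than in R.

static inline double phid(double x) {
  return 0.5 * erfc(-x * M_SQRT1_2);
}

// Gauss-Legendre abscissae/weights used by the Genz BVND algorithm
static const double GL_W1[3] = {0.1713244923791704, 0.3607615730481384,
                                0.4679139345726904};
static const double GL_X1[3] = {0.9324695142031521, 0.6612093864662645,
                                0.2386191860831969};
static const double GL_W2[6] = {0.04717533638651183, 0.1069393259953184,
                                0.1600783285433462,  0.2031674267230659,
                                0.2334925365383548,  0.2491470458134028};
static const double GL_X2[6] = {0.9815606342467192, 0.9041172563704749,
                                0.7699026741943047, 0.5873179542866175,
                                0.3678314989981802, 0.1252334085114689};
static const double GL_W3[10] = {0.01761400713915212, 0.04060142980038694,
                                 0.06267204833410906, 0.08327674157670475,
                                 0.1019301198172404,  0.1181945319615184,
                                 0.1316886384491766,  0.1420961093183821,
                                 0.1491729864726037,  0.1527533871307259};
static const double GL_X3[10] = {0.9931285991850949,  0.9639719272779138,
                                 0.9122344282513259,  0.8391169718222188,
                                 0.7463319064601508,  0.6360536807265150,
                                 0.5108670019508271,  0.3737060887154196,
                                 0.2277858511416451,  0.07652652113349733};

// P(X > dh, Y > dk) for standard bivariate normal with correlation r.
// Genz's adaptation of the Drezner-Wesolowsky algorithm (double precision,
// absolute accuracy ~5e-16). Handles infinite bounds.
static double bvnu(double dh, double dk, double r) {
  if (dh == R_PosInf || dk == R_PosInf) return 0.0;
  if (dh == R_NegInf) return (dk == R_NegInf) ? 1.0 : phid(-dk);
  if (dk == R_NegInf) return phid(-dh);
  if (r == 0.0) return phid(-dh) * phid(-dk);

  const double tp = 2.0 * M_PI;
  double h = dh, k = dk, hk = h * k, bvn = 0.0;
  const double *w, *x;
  int lg;
  double ar = std::fabs(r);
  if (ar < 0.3)      { lg = 3;  w = GL_W1; x = GL_X1; }
  else if (ar < 0.75){ lg = 6;  w = GL_W2; x = GL_X2; }
  else               { lg = 10; w = GL_W3; x = GL_X3; }

  if (ar < 0.925) {
    double hs = (h * h + k * k) / 2.0;
    double asr = std::asin(r);
    for (int i = 0; i < lg; i++) {
      for (int is = -1; is <= 1; is += 2) {
        double sn = std::sin(asr * (is * x[i] + 1.0) / 2.0);
        bvn += w[i] * std::exp((sn * hk - hs) / (1.0 - sn * sn));
      }
    }
    bvn = bvn * asr / (2.0 * tp) + phid(-h) * phid(-k);
  } else {
    if (r < 0.0) { k = -k; hk = -hk; }
    if (ar < 1.0) {
      double as = (1.0 - r) * (1.0 + r);
      double a = std::sqrt(as);
      double bs = (h - k) * (h - k);
      double c = (4.0 - hk) / 8.0;
      double d = (12.0 - hk) / 16.0;
      double asr = -(bs / as + hk) / 2.0;
      if (asr > -100.0)
        bvn = a * std::exp(asr) *
              (1.0 - c * (bs - as) * (1.0 - d * bs / 5.0) / 3.0 +
               c * d * as * as / 5.0);
      if (-hk < 100.0) {
        double b = std::sqrt(bs);
        bvn -= std::exp(-hk / 2.0) * std::sqrt(tp) * phid(-b / a) * b *
               (1.0 - c * bs * (1.0 - d * bs / 5.0) / 3.0);
      }
      a /= 2.0;
      for (int i = 0; i < lg; i++) {
        for (int is = -1; is <= 1; is += 2) {
          double xs = a * (is * x[i] + 1.0);
          xs = xs * xs;
          double rs = std::sqrt(1.0 - xs);
          double asr2 = -(bs / xs + hk) / 2.0;
          if (asr2 > -100.0) {
            bvn += a * w[i] * std::exp(asr2) *
                   (std::exp(-hk * (1.0 - rs) / (2.0 * (1.0 + rs))) / rs -
                    (1.0 + c * xs * (1.0 + d * xs)));
          }
        }
      }
      bvn = -bvn / tp;
    }
    if (r > 0.0) {
      bvn += phid(-std::max(h, k));
    } else {
      bvn = -bvn;
      if (k > h) {
        if (h < 0.0) bvn += phid(k) - phid(h);
        else         bvn += phid(-h) - phid(-k);
      }
    }
  }
  if (bvn < 0.0) bvn = 0.0;
  if (bvn > 1.0) bvn = 1.0;
  return bvn;
}

// Standard bivariate normal CDF P(X <= x, Y <= y)
static inline double bvn_cdf(double x, double y, double rho) {
  double mx = (x == R_PosInf) ? R_NegInf : (x == R_NegInf ? R_PosInf : -x);
  double my = (y == R_PosInf) ? R_NegInf : (y == R_NegInf ? R_PosInf : -y);
  return bvnu(mx, my, rho);
}

// Rectangle probability for standardized bounds, by inclusion-exclusion;
// clipped to [0,1] to absorb CDF round-off.
static inline double rect_prob_std(double a1, double b1, double a2, double b2,
                                   double rho) {
  double p = bvn_cdf(b1, b2, rho) - bvn_cdf(a1, b2, rho) -
             bvn_cdf(b1, a2, rho) + bvn_cdf(a1, a2, rho);
  if (p < 0.0) p = 0.0;
  if (p > 1.0) p = 1.0;
  return p;
}

// [[Rcpp::export(name = ".bvn_cdf_cpp")]]
NumericVector bvn_cdf_cpp(NumericVector x, NumericVector y, double rho) {
  R_xlen_t n = x.size();
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; i++) out[i] = bvn_cdf(x[i], y[i], rho);
  return out;
}

// Vectorised standardized rectangle probability (used by the Monte-Carlo
// oracle in tests as well as by mvn_rectangle_probability()).
// [[Rcpp::export(name = ".rect_prob_cpp")]]
NumericVector rect_prob_cpp(NumericVector a1, NumericVector b1,
                            NumericVector a2, NumericVector b2, double rho) {
  R_xlen_t n = a1.size();
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; i++)
    out[i] = rect_prob_std(a1[i], b1[i], a2[i], b2[i], rho);
  return out;
}

// Marginal log-likelihood of all plants.
//
// For plant p with fruits f and quadrature nodes z_pk (placed by the R
// layer, which also folds the prior density and any importance correction
// into the log-weights logw_pk):
//   ll_p = logsumexp_k [ logw_pk + sum_f log P_Sigma( Y in [L,R] - shift_f - z_pk ) ]
// nodes holds nplant blocks of K rows (plant-major). plant is a 1-based
// contiguous group index over the fruit rows.
// [[Rcpp::export(name = ".total_loglik_cpp")]]
List total_loglik_cpp(NumericVector L1, NumericVector R1, NumericVector L2,
                      NumericVector R2, NumericVector shift1,
                      NumericVector shift2, IntegerVector plant, int nplant,
                      NumericMatrix nodes, NumericVector logw, int K,
                      double s1, double s2, double rho) {
  const R_xlen_t n = L1.size();
  const double neg_inf = -std::numeric_limits<double>::infinity();

  // per-fruit bounds after removing the fixed-effect shift
  std::vector<double> a1(n), b1(n), a2(n), b2(n);
  for (R_xlen_t i = 0; i < n; i++) {
    a1[i] = (L1[i] == R_NegInf) ? R_NegInf : (L1[i] - shift1[i]);
    b1[i] = (R1[i] == R_PosInf) ? R_PosInf : (R1[i] - shift1[i]);
    a2[i] = (L2[i] == R_NegInf) ? R_NegInf : (L2[i] - shift2[i]);
    b2[i] = (R2[i] == R_PosInf) ? R_PosInf : (R2[i] - shift2[i]);
  }

  NumericVector plant_ll(nplant);
  std::vector<double> node_sum(K);

  R_xlen_t i0 = 0;
  for (int p = 1; p <= nplant; p++) {
    R_xlen_t i1 = i0;
    while (i1 < n && plant[i1] == p) i1++;
    const int base = (p - 1) * K;
    for (int k = 0; k < K; k++) node_sum[k] = logw[base + k];
    for (int k = 0; k < K; k++) {
      double z1 = nodes(base + k, 0), z2 = nodes(base + k, 1);
      double acc = 0.0;
      for (R_xlen_t i = i0; i < i1; i++) {
        double lo1 = (a1[i] == R_NegInf) ? R_NegInf : (a1[i] - z1) / s1;
        double hi1 = (b1[i] == R_PosInf) ? R_PosInf : (b1[i] - z1) / s1;
        double lo2 = (a2[i] == R_NegInf) ? R_NegInf : (a2[i] - z2) / s2;
        double hi2 = (b2[i] == R_PosInf) ? R_PosInf : (b2[i] - z2) / s2;
        double pr = rect_prob_std(lo1, hi1, lo2, hi2, rho);
        if (pr <= 0.0) { acc = neg_inf; break; }
        acc += std::log(pr);
      }
      node_sum[k] += acc;
    }
    // log-sum-exp over nodes
    double m = neg_inf;
    for (int k = 0; k < K; k++)
      if (node_sum[k] > m) m = node_sum[k];
    double ll;
    if (m == neg_inf) {
      ll = neg_inf;
    } else {
      double s = 0.0;
      for (int k = 0; k < K; k++) s += std::exp(node_sum[k] - m);
      ll = m + std::log(s);
    }
    plant_ll[p - 1] = ll;
    i0 = i1;
  }

  double total = 0.0;
  for (int p = 0; p < nplant; p++) total += plant_ll[p];
  return List::create(_["total"] = total, _["per_plant"] = plant_ll);
}
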