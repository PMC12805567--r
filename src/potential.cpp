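// Hot kernel: smoothed mean-field membrane potential of a rigid CG body.
//
// The caller precomputes, in the protein's local frame, the kept probe
// positions (bead position + Fibonacci-shell offset, interior probes already
// dropped) and the three zone plateau depths for each probe's bead type.
// Each evaluation applies the placement (R, z) and sums the smoothed field,
// optionally accumulating the analytic gradient: dP/dz, the 3x3 matrix
// A = sum_k grad M'(y_k) u_k^T (so dP/dtheta_p = <dR/dtheta_p, A>), and the
// analytic dP/dD and dP/dc.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline double sigmoid(double x) { return 1.0 / (1.0 + std::exp(-x)); }

// zone mixing profile of a single membrane as a function of the signed
// midplane distance d: g1 leaves the core, g2 leaves the head zone
struct FieldEval {
  double value, dvalue_dd;
};

static inline FieldEval field_profile(double d, double eps_w, double eps_h,
                                      double eps_t, double a, double b,
                                      double inv_sw) {
  double s1p = sigmoid((d - a) * inv_sw), s1m = sigmoid((-d - a) * inv_sw);
  double s2p = sigmoid((d - b) * inv_sw), s2m = sigmoid((-d - b) * inv_sw);
  double g1 = s1p + s1m, g2 = s2p + s2m;
  double dg1 = (s1p * (1 - s1p) - s1m * (1 - s1m)) * inv_sw;
  double dg2 = (s2p * (1 - s2p) - s2m * (1 - s2m)) * inv_sw;
  FieldEval out;
  out.value = -eps_t + (eps_t - eps_h) * g1 + (eps_h - eps_w) * g2;
  out.dvalue_dd = (eps_t - eps_h) * dg1 + (eps_h - eps_w) * dg2;
  return out;
}

// [[Rcpp::export]]
List cpp_total_field(const arma::mat& U, const arma::vec& eps_w,
                     const arma::vec& eps_h, const arma::vec& eps_t,
                     const arma::mat& R, double z, double core_half,
                     double head_w, double smooth_w, int n_mem, double D,
                     double curv, bool want_grad) {
  const arma::uword m = U.n_rows;
  const double a = core_half, b = core_half + head_w, inv_sw = 1.0 / smooth_w;
  double P = 0.0, dPdz = 0.0, dPdD = 0.0, dPdc = 0.0;
  arma::mat A(3, 3, arma::fill::zeros);

  const bool curved = std::abs(curv) > 1e-7;
  const double sgn = curv >= 0 ? 1.0 : -1.0;
  const double z0 = curved ? 1.0 / curv : 0.0;

  for (arma::uword k = 0; k < m; ++k) {
    // world position y = R u + (0, 0, z)
    double ux = U(k, 0), uy = U(k, 1), uz = U(k, 2);
    double yx = R(0, 0) * ux + R(0, 1) * uy + R(0, 2) * uz;
    double yy = R(1, 0) * ux + R(1, 1) * uy + R(1, 2) * uz;
    double yz = R(2, 0) * ux + R(2, 1) * uy + R(2, 2) * uz + z;

    double val = 0.0, gx = 0.0, gy = 0.0, gz = 0.0;

    if (n_mem == 2) {
      double d1 = yz + D / 2.0, d2 = yz - D / 2.0;
      FieldEval f1 = field_profile(d1, eps_w[k], eps_h[k], eps_t[k], a, b, inv_sw);
      FieldEval f2 = field_profile(d2, eps_w[k], eps_h[k], eps_t[k], a, b, inv_sw);
      val = f1.value + f2.value + eps_w[k];
      gz = f1.dvalue_dd + f2.dvalue_dd;
      dPdD += 0.5 * (f1.dvalue_dd - f2.dvalue_dd);
    } else if (!curved) {
      FieldEval f = field_profile(yz, eps_w[k], eps_h[k], eps_t[k], a, b, inv_sw);
      val = f.value;
      gz = f.dvalue_dd;
    } else {
      double wx = yx, wy = yy, wz = yz - z0;
      double r = std::sqrt(wx * wx + wy * wy + wz * wz);
      double d = 1.0 / curv - sgn * r;      // == sign(c) (1/|c| - r)
      FieldEval f = field_profile(d, eps_w[k], eps_h[k], eps_t[k], a, b, inv_sw);
      val = f.value;
      double inv_r = 1.0 / r;
      gx = f.dvalue_dd * (-sgn * wx * inv_r);
      gy = f.dvalue_dd * (-sgn * wy * inv_r);
      gz = f.dvalue_dd * (-sgn * wz * inv_r);
      // d = 1/c - sign(c) r with dr/dc = (yz - 1/c) / (r c^2)
      double inv_c2 = 1.0 / (curv * curv);
      dPdc += f.dvalue_dd * (-inv_c2 * (1.0 + sgn * wz * inv_r));
    }

    P += val;
    if (want_grad) {
      dPdz += gz;
      A(0, 0) += gx * ux; A(0, 1) += gx * uy; A(0, 2) += gx * uz;
      A(1, 0) += gy * ux; A(1, 1) += gy * uy; A(1, 2) += gy * uz;
      A(2, 0) += gz * ux; A(2, 1) += gz * uy; A(2, 2) += gz * uz;
    }
  }

  if (!want_grad) return List::create(_["value"] = P);
  return List::create(_["value"] = P, _["dz"] = dPdz, _["A"] = A,
                      _["dD"] = dPdD, _["dc"] = dPdc);
}

// minimum distance from each probe to any bead centre (used once per
// protein to drop interior probes)
// [[Rcpp::export]]
arma::vec cpp_min_dist(const arma::mat& probes, const arma::mat& beads) {
  arma::vec out(probes.n_rows);
  for (arma::uword i = 0; i < probes.n_rows; ++i) {
    double best = arma::datum::inf;
    for (arma::uword j = 0; j < beads.n_rows; ++j) {
      double dx = probes(i, 0) - beads(j, 0);
      double dy = probes(i, 1) - beads(j, 1);
      double dz = probes(i, 2) - beads(j, 2);
      double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < best) best = d2;
    }
    out[i] = std::sqrt(best);
  }
  return out;
}

// first-hit ray casting for the surface finder: for each ray (origin o,
// unit direction v) return the 1-based index of the first bead whose centre
// lies within `radius` of the ray (smallest positive t), or 0
// [[Rcpp::export]]
IntegerVector cpp_ray_first_hit(const arma::mat& origins, const arma::mat& dirs,
                                const arma::mat& beads, double radius) {
  const double r2 = radius * radius;
  IntegerVector out(origins.n_rows);
  for (arma::uword i = 0; i < origins.n_rows; ++i) {
    double best_t = arma::datum::inf;
    int best_j = 0;
    for (arma::uword j = 0; j < beads.n_rows; ++j) {
      double px = beads(j, 0) - origins(i, 0);
      double py = beads(j, 1) - origins(i, 1);
      double pz = beads(j, 2) - origins(i, 2);
      double t = px * dirs(i, 0) + py * dirs(i, 1) + pz * dirs(i, 2);
      if (t <= 0 || t >= best_t) continue;
      double dx = px - t * dirs(i, 0);
      double dy = py - t * dirs(i, 1);
      double dz = pz - t * dirs(i, 2);
      if (dx * dx + dy * dy + dz * dz <= r2) {
        best_t = t;
        best_j = (int)j + 1;
      }
    }
    out[i] = best_j;
  }
  return out;
}
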