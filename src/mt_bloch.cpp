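// Two-pool Bloch integration of off-resonance saturation pulse trains.
//
// State x = (MxF, MyF, MzF, MzB): full 3D Bloch for the free (water) pool,
// longitudinal-only bound (macromolecular) pool whose RF response enters as
// a saturation rate W = pi * omega1(t)^2 * G(delta_f). The RF envelope is
// discretised into piecewise-constant segments; each segment is an affine
// ODE dx/dt = B x + b solved exactly via the matrix exponential pair
//   E = exp(B t),  J = integral_0^t exp(B s) ds
// computed by Taylor series with scaling and doubling (the doubling
// recurrence for the pair is E_2t = E E, J_2t = J E + J), so the only
// discretisation error is the envelope staircase itself.
//
// The pulses of a train are identical, so one pulse propagator and one
// inter-pulse gap propagator are built per (voxel, pulse-shape) pair and
// the train is their alternating product; the post-train delays reuse the
// same train state, making the four repetition delays nearly free.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// exact affine propagator over dt: x(dt) = E x(0) + J b
static void affine_propagator(const mat44& B, double dt, mat44& E, mat44& J) {
  double nrm = norm(B * dt, "inf");
  int s = 0;
  while (nrm > 0.5 && s < 40) { nrm *= 0.5; ++s; }
  double h = dt / std::ldexp(1.0, s);
  mat44 A = B * h;
  // Taylor with term_n = A^n/n!: E = sum term_n, J = h * sum term_n/(n+1)
  mat44 term; term.eye();
  E = term;
  J = term;
  for (int n = 1; n <= 18; ++n) {
    term = (term * A) / n;
    E += term;
    J += term / (n + 1);
    if (norm(term, "inf") < 1e-17) break;
  }
  J *= h;
  for (int i = 0; i < s; ++i) {
    J = J * E + J;
    E = E * E;
  }
}

// generator of a constant-RF segment (homogeneous part B, drift b).
// omega1 [rad/s], domega [rad/s], W [1/s]; relaxation/exchange in 1/s.
static void segment_generator(double omega1, double domega, double W,
                              double R1, double R2f, double kf, double kb,
                              double F, mat44& B, vec4& b) {
  B.zeros();
  B(0, 0) = -R2f;   B(0, 1) = domega;
  B(1, 0) = -domega; B(1, 1) = -R2f; B(1, 2) = omega1;
  B(2, 1) = -omega1; B(2, 2) = -(R1 + kf); B(2, 3) = kb;
  B(3, 2) = kf;      B(3, 3) = -(R1 + kb + W);
  b.zeros();
  b(2) = R1;       // R1 * M0F with M0F = 1
  b(3) = R1 * F;   // R1 * M0B with M0B = F
}

// [[Rcpp::export]]
arma::mat mt_weighting_batch_cpp(const arma::mat& omega1_seg,   // nseg x npairs
                                 const arma::vec& delta_omega,  // npairs, rad/s
                                 const arma::mat& G,            // nvox x npairs, seconds
                                 double seg_dt,                 // seconds
                                 int n_pulses,
                                 double gap_s,                  // inter-pulse delay
                                 const arma::vec& delays_s,     // post-train delays
                                 const arma::vec& R1,           // 1/s, per voxel
                                 const arma::vec& R2f,          // 1/s, per voxel
                                 const arma::vec& kf,           // 1/s, per voxel
                                 const arma::vec& kb,           // 1/s, per voxel
                                 const arma::vec& F) {          // pool ratio, per voxel
  const uword nseg = omega1_seg.n_rows;
  const uword npairs = omega1_seg.n_cols;
  const uword nvox = R1.n_elem;
  const uword ndel = delays_s.n_elem;
  mat out(nvox, npairs * ndel);
  mat44 B, E, J, Eseg, Jseg;
  vec4 b, bgap;

  for (uword v = 0; v < nvox; ++v) {
    // RF-free generator: relaxation + exchange only (no precession kept
    // between pulses; transverse magnetisation simply decays)
    segment_generator(0.0, 0.0, 0.0, R1(v), R2f(v), kf(v), kb(v), F(v),
                      B, bgap);
    mat44 Egap, Jgap;
    affine_propagator(B, gap_s, Egap, Jgap);
    vec4 fgap = Jgap * bgap;
    std::vector<mat44> Edel(ndel);
    std::vector<vec4> fdel(ndel);
    for (uword d = 0; d < ndel; ++d) {
      affine_propagator(B, delays_s(d), Edel[d], J);
      fdel[d] = J * bgap;
    }
    vec4 eq = {0.0, 0.0, 1.0, F(v)};

    for (uword p = 0; p < npairs; ++p) {
      // one-pulse propagator: composition of exact segment propagators
      mat44 Ep; Ep.eye();
      vec4 fp; fp.zeros();
      for (uword sseg = 0; sseg < nseg; ++sseg) {
        double w1 = omega1_seg(sseg, p);
        double W = M_PI * w1 * w1 * G(v, p);
        segment_generator(w1, delta_omega(p), W, R1(v), R2f(v), kf(v),
                          kb(v), F(v), B, b);
        affine_propagator(B, seg_dt, Eseg, Jseg);
        Ep = Eseg * Ep;
        fp = Eseg * fp + Jseg * b;
      }
      vec4 x = eq;
      for (int k = 0; k < n_pulses; ++k) {
        x = Ep * x + fp;
        if (k < n_pulses - 1) x = Egap * x + fgap;
      }
      for (uword d = 0; d < ndel; ++d) {
        vec4 xd = Edel[d] * x + fdel[d];
        out(v, p * ndel + d) = xd(2); // MzF / MzF_eq with MzF_eq = 1
      }
    }
  }
  return out;
}
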