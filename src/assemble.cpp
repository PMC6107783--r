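// Element assembly for the stabilized equal-order (P1-P1) finite-element
// discretization of the steady incompressible Navier-Stokes equations.
// Picard linearization: the advection field is the previous velocity
// iterate. Stabilization: SUPG on momentum, PSPG on continuity with
// tau = ((2|a|/h_a)^2 + (4 nu/h^2)^2)^-1/2, plus optional grad-div (LSIC)
// to control element-level mass error. An optional pseudo-time diagonal
// damping term globalizes the iteration; it cancels from the steady
// residual at convergence.
//
// DOF layout (1-based, interleaved per node to keep the matrix banded for
// the station-major node ordering of the tube mesh): node i owns velocity
// dofs 4(i-1)+1..4(i-1)+3 and pressure dof 4(i-1)+4.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// [[Rcpp::export]]
List assemble_ns_system(const NumericMatrix& nodes,   // N x 3 (metres)
                        const IntegerMatrix& cells,   // M x 4 (1-based)
                        const NumericMatrix& uvel,    // N x 3 current velocity
                        const NumericVector& pres,    // N current pressure
                        const double mu, const double rho,
                        const double pseudo_cfl,
                        const double lsic_scale,
                        const double dc_scale,
                        const int newton,
                        const NumericVector& mu_frozen) {
  const int N = nodes.nrow();
  const int M = cells.nrow();
  const double nu = mu / rho;
  const bool use_pseudo = R_finite(pseudo_cfl) && pseudo_cfl > 0.0;
  const bool use_lsic = lsic_scale > 0.0;

  const std::size_t per_elem = 16 * 3 * 3 + 16 +
    ((use_lsic || newton) ? 16 * 9 : 0);
  std::vector<int> ti; ti.reserve(per_elem * (std::size_t)M);
  std::vector<int> tj; tj.reserve(per_elem * (std::size_t)M);
  std::vector<double> tx; tx.reserve(per_elem * (std::size_t)M);
  NumericVector rhs_pseudo(4 * N);
  // compensation so that A x - (b + rhs_newton) stays the true steady
  // residual when the Newton cross term is assembled into A
  NumericVector rhs_newton(4 * N);
  // per-element effective viscosity actually used (molecular + capturing);
  // can be fed back in via mu_frozen to freeze the capturing field
  NumericVector mu_el(M);
  const bool frozen = mu_frozen.size() == M;

  for (int e = 0; e < M; ++e) {
    int n[4];
    for (int k = 0; k < 4; ++k) n[k] = cells(e, k) - 1;

    double J[3][3];
    for (int c = 0; c < 3; ++c)
      for (int d = 0; d < 3; ++d)
        J[d][c] = nodes(n[c + 1], d) - nodes(n[0], d);
    const double det =
      J[0][0] * (J[1][1] * J[2][2] - J[1][2] * J[2][1]) -
      J[0][1] * (J[1][0] * J[2][2] - J[1][2] * J[2][0]) +
      J[0][2] * (J[1][0] * J[2][1] - J[1][1] * J[2][0]);
    const double V = det / 6.0;
    if (V <= 0.0) stop("inverted cell encountered during assembly (cell %d)",
                       e + 1);
    double inv[3][3];
    const double id = 1.0 / det;
    inv[0][0] = (J[1][1] * J[2][2] - J[1][2] * J[2][1]) * id;
    inv[0][1] = (J[0][2] * J[2][1] - J[0][1] * J[2][2]) * id;
    inv[0][2] = (J[0][1] * J[1][2] - J[0][2] * J[1][1]) * id;
    inv[1][0] = (J[1][2] * J[2][0] - J[1][0] * J[2][2]) * id;
    inv[1][1] = (J[0][0] * J[2][2] - J[0][2] * J[2][0]) * id;
    inv[1][2] = (J[0][2] * J[1][0] - J[0][0] * J[1][2]) * id;
    inv[2][0] = (J[1][0] * J[2][1] - J[1][1] * J[2][0]) * id;
    inv[2][1] = (J[0][1] * J[2][0] - J[0][0] * J[2][1]) * id;
    inv[2][2] = (J[0][0] * J[1][1] - J[0][1] * J[1][0]) * id;
    double g[4][3];  // shape-function gradients (constant on the tet)
    for (int k = 1; k < 4; ++k)
      for (int d = 0; d < 3; ++d) g[k][d] = inv[k - 1][d];
    for (int d = 0; d < 3; ++d)
      g[0][d] = -(g[1][d] + g[2][d] + g[3][d]);

    double a[4][3], abar[3] = {0, 0, 0}, asum[3] = {0, 0, 0};
    for (int k = 0; k < 4; ++k)
      for (int d = 0; d < 3; ++d) {
        a[k][d] = uvel(n[k], d);
        asum[d] += a[k][d];
      }
    for (int d = 0; d < 3; ++d) abar[d] = asum[d] / 4.0;
    const double amag = std::sqrt(abar[0] * abar[0] + abar[1] * abar[1] +
                                  abar[2] * abar[2]);

    const double h_iso = std::cbrt(6.0 * std::sqrt(2.0) * V);
    double h_a = h_iso;
    if (amag > 1e-12) {
      double s = 0.0;
      for (int k = 0; k < 4; ++k)
        s += std::fabs(abar[0] * g[k][0] + abar[1] * g[k][1] +
                       abar[2] * g[k][2]);
      if (s > 1e-12) h_a = 2.0 * amag / s;
    }
    const double inv_t_conv = 2.0 * amag / h_a;
    double inv_t_diff = 4.0 * nu / (h_iso * h_iso);
    const double inv_t = std::sqrt(inv_t_conv * inv_t_conv +
                                   inv_t_diff * inv_t_diff);
    const double tau = 1.0 / inv_t;
    const double inv_dtau = use_pseudo ? inv_t / pseudo_cfl : 0.0;
    // grad-div parameter, viscosity-like units
    const double gamma = use_lsic
      ? lsic_scale * (rho * amag * h_a / 2.0 + mu)
      : 0.0;

    double ag[4];
    for (int k = 0; k < 4; ++k)
      ag[k] = abar[0] * g[k][0] + abar[1] * g[k][1] + abar[2] * g[k][2];
    // velocity gradient of the current iterate (constant on the tet),
    // grad_a[d][e] = d a_d / d x_e
    double grad_a[3][3] = {{0, 0, 0}, {0, 0, 0}, {0, 0, 0}};
    for (int k = 0; k < 4; ++k)
      for (int d = 0; d < 3; ++d)
        for (int e2 = 0; e2 < 3; ++e2)
          grad_a[d][e2] += a[k][d] * g[k][e2];

    // residual-based discontinuity capturing (Codina-type): an isotropic
    // artificial viscosity proportional to the element momentum residual,
    // which vanishes as the smooth solution is approached but damps
    // under-resolved shear layers (stenotic jets). Capped at the
    // first-order upwind level.
    double mu_e = mu;
    if (frozen) {
      mu_e = mu_frozen[e];
    } else if (dc_scale > 0.0) {
      double gp[3] = {0, 0, 0};
      for (int k = 0; k < 4; ++k)
        for (int d = 0; d < 3; ++d) gp[d] += pres[n[k]] * g[k][d];
      double Rm = 0.0, Gn = 0.0;
      for (int d = 0; d < 3; ++d) {
        double rd = gp[d];
        for (int e2 = 0; e2 < 3; ++e2) rd += rho * grad_a[d][e2] * abar[e2];
        Rm += rd * rd;
        for (int e2 = 0; e2 < 3; ++e2) Gn += grad_a[d][e2] * grad_a[d][e2];
      }
      Rm = std::sqrt(Rm);
      Gn = std::sqrt(Gn) + 1e-10 * (amag + 1e-9) / h_iso;
      double nu_dc = dc_scale * 0.5 * h_iso * Rm / (rho * Gn);
      const double nu_cap = 0.5 * amag * h_iso;
      if (nu_dc > nu_cap) nu_dc = nu_cap;
      // act only in convection-dominated cells: ramp in over element
      // Reynolds 20..60 so resolved viscous benchmarks are untouched
      const double re_h = amag * h_iso / (2.0 * nu);
      double ramp = (re_h - 20.0) / 40.0;
      if (ramp < 0.0) ramp = 0.0;
      if (ramp > 1.0) ramp = 1.0;
      mu_e = mu + rho * nu_dc * ramp;
    }
    mu_el[e] = mu_e;

    for (int i = 0; i < 4; ++i) {
      double w[3];  // int(phi_i * a) = V/20 (sum_k a_k + a_i)
      for (int d = 0; d < 3; ++d) w[d] = V / 20.0 * (asum[d] + a[i][d]);
      const int rowu = 4 * n[i];      // 0-based base of velocity dofs
      const int rowp = 4 * n[i] + 3;  // 0-based pressure dof
      for (int j = 0; j < 4; ++j) {
        const int colu = 4 * n[j];
        const int colp = 4 * n[j] + 3;
        const double diff = mu_e * V *
          (g[i][0] * g[j][0] + g[i][1] * g[j][1] + g[i][2] * g[j][2]);
        const double conv = rho *
          (w[0] * g[j][0] + w[1] * g[j][1] + w[2] * g[j][2]);
        const double supg_vv = tau * V * rho * ag[i] * ag[j];
        const double mass = V / 20.0 * (i == j ? 2.0 : 1.0);
        const double vv = diff + conv + supg_vv + rho * inv_dtau * mass;
        for (int d = 0; d < 3; ++d) {
          ti.push_back(rowu + d + 1);
          tj.push_back(colu + d + 1);
          tx.push_back(vv);
          // momentum row, pressure column: Galerkin + SUPG
          ti.push_back(rowu + d + 1);
          tj.push_back(colp + 1);
          tx.push_back(-V / 4.0 * g[i][d] + tau * V * ag[i] * g[j][d]);
          // continuity row, velocity column: Galerkin + PSPG
          ti.push_back(rowp + 1);
          tj.push_back(colu + d + 1);
          tx.push_back(V / 4.0 * g[j][d] + tau * V * g[i][d] * ag[j]);
          if (use_lsic || newton) {
            for (int d2 = 0; d2 < 3; ++d2) {
              double val = 0.0;
              if (use_lsic) val += gamma * V * g[i][d] * g[j][d2];
              // Newton: rho * int(phi_i phi_j) * (grad a)_{d,d2}
              if (newton) {
                val += rho * mass * grad_a[d][d2];
                rhs_newton[rowu + d] +=
                  rho * mass * grad_a[d][d2] * a[j][d2];
              }
              if (val != 0.0) {
                ti.push_back(rowu + d + 1);
                tj.push_back(colu + d2 + 1);
                tx.push_back(val);
              }
            }
          }
        }
        // PSPG pressure-pressure
        ti.push_back(rowp + 1);
        tj.push_back(colp + 1);
        tx.push_back(tau / rho * V *
          (g[i][0] * g[j][0] + g[i][1] * g[j][1] + g[i][2] * g[j][2]));
        if (use_pseudo) {
          for (int d = 0; d < 3; ++d)
            rhs_pseudo[rowu + d] += rho * inv_dtau * mass * a[j][d];
        }
      }
    }
  }

  return List::create(_["i"] = wrap(ti), _["j"] = wrap(tj),
                      _["x"] = wrap(tx), _["rhs_pseudo"] = rhs_pseudo,
                      _["rhs_newton"] = rhs_newton, _["mu_el"] = mu_el);
}
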