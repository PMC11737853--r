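#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Closed-loop stepper: supraspinal commands -> delayed afferents ->
// spinal network -> activation dynamics -> Hill muscles -> two-link arm.
// Mirrors the R reference primitives exactly (exponential neuron and
// activation updates, semi-implicit Euler arm integration) so that the
// compiled and interpreted routes can be cross-checked.

static inline double sigmoid(double x, double D, double x0) {
  return 1.0 / (1.0 + std::exp(-D * (x - x0)));
}

static inline double clamp01(double x) {
  return x < 0.0 ? 0.0 : (x > 1.0 ? 1.0 : x);
}

// [[Rcpp::export]]
List run_engine_cpp(int n_steps, double dt,
                    NumericVector q0, NumericVector qd0,
                    List arm, List muscles, List afferents,
                    List neuron, List network,
                    NumericMatrix command,
                    NumericVector gravity,
                    bool perturb_on, NumericVector perturb_force,
                    int perturb_i_on, int perturb_i_off) {
  const int M = 7;
  // arm parameters
  const double L1 = arm["upper_arm_length_m"], L2 = arm["forearm_length_m"];
  const double m1 = arm["upper_arm_mass_kg"], m2 = arm["forearm_mass_kg"];
  const double cf = arm["com_fraction"];
  const double I1 = arm["upper_arm_inertia_kgm2"];
  const double I2 = arm["forearm_inertia_kgm2"];
  const double damp = arm["joint_damping_nms"];
  NumericVector shl = arm["shoulder_limits_rad"];
  NumericVector ell = arm["elbow_limits_rad"];
  const double klim = arm["limit_stiffness_nm_rad"];
  const double r1 = cf * L1, r2 = cf * L2;
  const double gx = gravity[0], gy = gravity[1];

  // muscle parameters
  NumericVector fmax = muscles["f_max_n"];
  NumericVector l0 = muscles["optimal_fiber_length_mm"];
  NumericVector penn = muscles["pennation_rad"];
  NumericVector maS = muscles["moment_arm_shoulder_mm"];
  NumericVector maE = muscles["moment_arm_elbow_mm"];
  NumericVector tact = muscles["tau_act_s"];
  NumericVector tdeact = muscles["tau_deact_s"];
  NumericVector lref = muscles["reference_length_mm"];
  NumericVector refpost = muscles["reference_posture_rad"];

  // afferent parameters
  const double ia_vg = afferents["ia_velocity_gain"];
  const double ia_ve = afferents["ia_velocity_exponent"];
  const double ia_lg = afferents["ia_length_gain"];
  const double ii_lg = afferents["ii_length_gain"];
  const double base = afferents["baseline_rate_hz"];
  const double vfloor = afferents["velocity_floor_mm_s"];
  const double norm_ia = afferents["norm_ia_hz"];
  const double norm_ii = afferents["norm_ii_hz"];
  const int delay_steps = afferents["delay_steps"];

  // neuron parameters
  const double tau = neuron["tau_s"];
  const double D = neuron["sigmoid_slope"];
  const double x0 = neuron["sigmoid_offset"];
  const double ndecay = std::exp(-dt / tau);
  const double r_rest = sigmoid(0.0, D, x0);

  // network wiring
  NumericVector w_iamn = network["w_iamn"], w_ii = network["w_ii"];
  NumericVector w_ib = network["w_ib"], w_rn = network["w_rn"];
  NumericMatrix m_iamns = network["m_iamns"], m_iaina = network["m_iaina"];

  // state
  double q[2] = {q0[0], q0[1]};
  double qd[2] = {qd0[0], qd0[1]};
  std::vector<double> a(M, 0.0), u(M, r_rest);
  std::vector<double> r_mn(M, r_rest), r_inia(M, r_rest),
      r_inii(M, r_rest), r_inib(M, r_rest), r_rn(M, r_rest);

  // delay ring buffers (per muscle, per fiber type)
  const int depth = delay_steps > 0 ? delay_steps : 1;
  std::vector<double> buf_ia(M * depth), buf_ii(M * depth),
      buf_ib(M * depth);
  int pos = 0;

  auto fiber_signals = [&](double* lm, double* vm) {
    const double dsh = q[0] - refpost[0], del = q[1] - refpost[1];
    for (int m = 0; m < M; ++m) {
      double l = lref[m] - maS[m] * dsh - maE[m] * del;
      double lmin = 0.5 * l0[m];
      lm[m] = l < lmin ? lmin : l;
      vm[m] = -maS[m] * qd[0] - maE[m] * qd[1];
    }
  };
  auto norm_rates = [&](const double* lm, const double* vm,
                        const double* F, double* nia, double* nii,
                        double* nib) {
    for (int m = 0; m < M; ++m) {
      double v = vm[m];
      double sg = (v > 0) - (v < 0);
      double av = std::fabs(v);
      if (av < vfloor) av = vfloor;
      double ia = sg * ia_vg * std::pow(av, ia_ve) +
                  ia_lg * (lm[m] - l0[m]) + base;
      double ii = ii_lg * (lm[m] - l0[m]) + base;
      nia[m] = clamp01(ia / norm_ia);
      nii[m] = clamp01(ii / norm_ii);
      nib[m] = clamp01(F[m] / fmax[m]);
    }
  };
  auto hill = [&](const double* lm, const double* vm, double* F) {
    for (int m = 0; m < M; ++m) {
      double lt = lm[m] / l0[m];
      double vt = vm[m] / (10.0 * l0[m]);
      double fl = std::exp(-std::pow((lt - 1.0) / 0.45, 2.0));
      double fv = vt < 0 ? std::max(0.0, (1.0 + vt) / (1.0 - 4.0 * vt))
                         : 1.0 + 0.4 * vt / (vt + 0.075);
      double fp = lt <= 1.0 ? 0.0
                            : (std::exp(5.0 * (lt - 1.0)) - 1.0) /
                                  (std::exp(2.5) - 1.0);
      double f = fmax[m] * (a[m] * fl * fv + fp) * std::cos(penn[m]);
      F[m] = f > 0 ? f : 0.0;
    }
  };

  // prefill delay lines with t = 0 rates (a = 0, passive forces)
  {
    double lm[7], vm[7], F[7], nia[7], nii[7], nib[7];
    fiber_signals(lm, vm);
    hill(lm, vm, F);
    norm_rates(lm, vm, F, nia, nii, nib);
    for (int k = 0; k < depth; ++k)
      for (int m = 0; m < M; ++m) {
        buf_ia[k * M + m] = nia[m];
        buf_ii[k * M + m] = nii[m];
        buf_ib[k * M + m] = nib[m];
      }
  }

  const int n_out = n_steps + 1;
  NumericMatrix theta(n_out, 2), thetadot(n_out, 2);
  NumericMatrix Uout(n_out, M), Aout(n_out, M), Fout(n_out, M);
  NumericMatrix IAout(n_out, M), IIout(n_out, M), IBout(n_out, M);

  double lm[7], vm[7], F[7], nia[7], nii[7], nib[7];
  double dia[7], dii[7], dib[7];

  for (int i = 0; i < n_steps; ++i) {
    if (!std::isfinite(q[0]) || !std::isfinite(q[1]) ||
        !std::isfinite(qd[0]) || !std::isfinite(qd[1]))
      stop("numerical blow-up at t = %f s", i * dt);
    theta(i, 0) = q[0]; theta(i, 1) = q[1];
    thetadot(i, 0) = qd[0]; thetadot(i, 1) = qd[1];

    // (2) read delayed afferents (sample pushed delay_steps ago)
    for (int m = 0; m < M; ++m) {
      if (delay_steps == 0) { // filled after push below; use current
        dia[m] = buf_ia[m]; dii[m] = buf_ii[m]; dib[m] = buf_ib[m];
      } else {
        dia[m] = buf_ia[pos * M + m];
        dii[m] = buf_ii[pos * M + m];
        dib[m] = buf_ib[pos * M + m];
      }
    }

    // (3) spinal network step -> u
    double mn_in[7];
    for (int m = 0; m < M; ++m) {
      double s = command(i, m) + w_iamn[m] * dia[m] +
                 w_ii[m] * r_inii[m] - w_ib[m] * r_inib[m] -
                 w_rn[m] * r_rn[m];
      for (int k = 0; k < M; ++k) {
        s += m_iamns(m, k) * dia[k];
        s -= m_iaina(m, k) * r_inia[k];
      }
      mn_in[m] = s;
    }
    double new_mn[7], new_inia[7], new_inii[7], new_inib[7], new_rn[7];
    for (int m = 0; m < M; ++m) {
      double tgt = sigmoid(mn_in[m], D, x0);
      new_mn[m] = clamp01(tgt + (r_mn[m] - tgt) * ndecay);
      tgt = sigmoid(dia[m], D, x0);
      new_inia[m] = clamp01(tgt + (r_inia[m] - tgt) * ndecay);
      tgt = sigmoid(dii[m], D, x0);
      new_inii[m] = clamp01(tgt + (r_inii[m] - tgt) * ndecay);
      tgt = sigmoid(dib[m], D, x0);
      new_inib[m] = clamp01(tgt + (r_inib[m] - tgt) * ndecay);
      tgt = sigmoid(r_mn[m], D, x0);
      new_rn[m] = clamp01(tgt + (r_rn[m] - tgt) * ndecay);
    }
    for (int m = 0; m < M; ++m) {
      r_mn[m] = new_mn[m]; r_inia[m] = new_inia[m];
      r_inii[m] = new_inii[m]; r_inib[m] = new_inib[m];
      r_rn[m] = new_rn[m];
      u[m] = r_mn[m];
    }

    // (4) activation dynamics
    for (int m = 0; m < M; ++m) {
      double tc = u[m] > a[m] ? tact[m] : tdeact[m];
      a[m] = clamp01(u[m] + (a[m] - u[m]) * std::exp(-dt / tc));
    }

    // (5) muscle geometry and forces at time t_i (with updated activation)
    fiber_signals(lm, vm);
    hill(lm, vm, F);
    norm_rates(lm, vm, F, nia, nii, nib);
    for (int m = 0; m < M; ++m) {
      Uout(i, m) = u[m]; Aout(i, m) = a[m]; Fout(i, m) = F[m];
      IAout(i, m) = nia[m]; IIout(i, m) = nii[m]; IBout(i, m) = nib[m];
    }

    // (6) arm dynamics: semi-implicit Euler
    {
      double c2 = std::cos(q[1]), s2 = std::sin(q[1]);
      double M11 = m1 * r1 * r1 + I1 +
                   m2 * (L1 * L1 + r2 * r2 + 2.0 * L1 * r2 * c2) + I2;
      double M12 = m2 * (r2 * r2 + L1 * r2 * c2) + I2;
      double M22 = m2 * r2 * r2 + I2;
      double h = -m2 * L1 * r2 * s2;
      double C1 = h * qd[1] * (2.0 * qd[0] + qd[1]);
      double C2 = -h * qd[0] * qd[0];
      double phi1 = q[0], phi2 = q[0] + q[1];
      double cp1 = std::cos(phi1), sp1 = std::sin(phi1);
      double cp2 = std::cos(phi2), sp2 = std::sin(phi2);
      double G1 = -(gx * (m1 * r1 * cp1 + m2 * (L1 * cp1 + r2 * cp2)) +
                    gy * (m1 * r1 * sp1 + m2 * (L1 * sp1 + r2 * sp2)));
      double G2 = -(gx * m2 * r2 * cp2 + gy * m2 * r2 * sp2);
      double tau1 = 0.0, tau2 = 0.0;
      for (int m = 0; m < M; ++m) {
        tau1 += maS[m] * 1e-3 * F[m];
        tau2 += maE[m] * 1e-3 * F[m];
      }
      if (perturb_on && i >= perturb_i_on && i < perturb_i_off) {
        double fx = perturb_force[0], fy = perturb_force[1];
        tau1 += (L1 * cp1 + L2 * cp2) * fx + (L1 * sp1 + L2 * sp2) * fy;
        tau2 += L2 * cp2 * fx + L2 * sp2 * fy;
      }
      // soft joint limits and damping
      if (q[0] > shl[1]) tau1 -= klim * (q[0] - shl[1]);
      if (q[0] < shl[0]) tau1 += klim * (shl[0] - q[0]);
      if (q[1] > ell[1]) tau2 -= klim * (q[1] - ell[1]);
      if (q[1] < ell[0]) tau2 += klim * (ell[0] - q[1]);
      tau1 -= damp * qd[0];
      tau2 -= damp * qd[1];
      double b1 = tau1 - C1 - G1, b2 = tau2 - C2 - G2;
      double det = M11 * M22 - M12 * M12;
      double qdd1 = (M22 * b1 - M12 * b2) / det;
      double qdd2 = (-M12 * b1 + M11 * b2) / det;
      qd[0] += dt * qdd1; qd[1] += dt * qdd2;
      q[0] += dt * qd[0]; q[1] += dt * qd[1];
    }

    // (7) push the time-t_i afferent samples into the delay lines, so a
    // read at step i + delay_steps returns exactly this sample
    for (int m = 0; m < M; ++m) {
      if (delay_steps > 0) {
        buf_ia[pos * M + m] = nia[m];
        buf_ii[pos * M + m] = nii[m];
        buf_ib[pos * M + m] = nib[m];
      } else {
        buf_ia[m] = nia[m]; buf_ii[m] = nii[m]; buf_ib[m] = nib[m];
      }
    }
    if (delay_steps > 0) pos = (pos + 1) % depth;
  }
  theta(n_steps, 0) = q[0]; theta(n_steps, 1) = q[1];
  thetadot(n_steps, 0) = qd[0]; thetadot(n_steps, 1) = qd[1];
  for (int m = 0; m < M; ++m) {
    Uout(n_steps, m) = u[m]; Aout(n_steps, m) = a[m];
    Fout(n_steps, m) = Fout(n_steps - 1, m);
    IAout(n_steps, m) = IAout(n_steps - 1, m);
    IIout(n_steps, m) = IIout(n_steps - 1, m);
    IBout(n_steps, m) = IBout(n_steps - 1, m);
  }
  return List::create(_["theta"] = theta, _["thetadot"] = thetadot,
                      _["u"] = Uout, _["a"] = Aout, _["force"] = Fout,
                      _["ia"] = IAout, _["ii"] = IIout, _["ib"] = IBout);
}
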