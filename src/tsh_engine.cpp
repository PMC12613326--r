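// Fewest-switches surface-hopping trajectory propagator.
//
// One call propagates a single trajectory: Velocity-Verlet nuclei on the
// active adiabatic surface, local-diabatization electronic propagation with
// RK4 substeps, density-flux (or classic fewest-switches) hopping with
// isotropic velocity rescaling, and the configured decoherence correction
// (EDC / FM / FMi / PFM / PFMi) driven by trajectory-velocity-projected
// auxiliary forces and momenta.  Randomness comes from R's RNG stream, so a
// set.seed() on the R side makes runs exactly reproducible; exactly one
// uniform draw is consumed per electronic substep.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

namespace {

struct ModelC {
  int ns = 0, ndof = 0, kind = 1;   // 1 = terms1d, 2 = lvc
  arma::vec masses;
  arma::mat terms;                  // rows: i j type p1 p2 p3
  arma::vec omega;
  arma::mat v0m;
  arma::cube wc;

  void init(const List& m) {
    ns = as<int>(m["n_states"]);
    ndof = as<int>(m["n_dof"]);
    masses = as<arma::vec>(m["masses"]);
    std::string k = as<std::string>(m["kind"]);
    List cs = m["cspec"];
    if (k == "terms1d") {
      kind = 1;
      terms = as<arma::mat>(cs["terms"]);
    } else {
      kind = 2;
      omega = as<arma::vec>(cs["omega"]);
      v0m = as<arma::mat>(cs["v0"]);
      NumericVector wv = cs["w"];
      IntegerVector dims = wv.attr("dim");
      wc = arma::cube(wv.begin(), dims[0], dims[1], dims[2]);
    }
  }

  static double term_val(int type, double p1, double p2, double p3,
                         double x) {
    switch (type) {
      case 1: return p1;
      case 2: return p1 * (x - p2);
      case 3: return 0.5 * p1 * (x - p2) * (x - p2);
      case 4: { double e = std::exp(-p2 * (x - p3));
                return p1 * (1 - e) * (1 - e); }
      case 5: return p1 * std::exp(-p2 * (x - p3));
      case 6: return p1 * std::exp(-p2 * (x - p3) * (x - p3));
      case 7: return p1 * std::tanh(p2 * (x - p3));
    }
    return 0.0;
  }

  static double term_der(int type, double p1, double p2, double p3,
                         double x) {
    switch (type) {
      case 1: return 0.0;
      case 2: return p1;
      case 3: return p1 * (x - p2);
      case 4: { double e = std::exp(-p2 * (x - p3));
                return 2 * p1 * (1 - e) * p2 * e; }
      case 5: return -p2 * p1 * std::exp(-p2 * (x - p3));
      case 6: return -2 * p2 * (x - p3) * p1 *
                     std::exp(-p2 * (x - p3) * (x - p3));
      case 7: { double c = std::cosh(p2 * (x - p3));
                return p1 * p2 / (c * c); }
    }
    return 0.0;
  }

  arma::mat V(const arma::vec& R) const {
    arma::mat out(ns, ns, arma::fill::zeros);
    if (kind == 1) {
      double x = R(0);
      for (arma::uword r = 0; r < terms.n_rows; ++r) {
        int i = (int)terms(r, 0) - 1, j = (int)terms(r, 1) - 1;
        double v = term_val((int)terms(r, 2), terms(r, 3), terms(r, 4),
                            terms(r, 5), x);
        out(i, j) += v;
        if (i != j) out(j, i) += v;
      }
    } else {
      out = v0m;
      double harm = 0.0;
      for (int a = 0; a < ndof; ++a) {
        harm += 0.5 * omega(a) * omega(a) * R(a) * R(a);
        out += wc.slice(a) * R(a);
      }
      out.diag() += harm;
    }
    return out;
  }

  arma::cube dV(const arma::vec& R) const {
    arma::cube out(ns, ns, ndof, arma::fill::zeros);
    if (kind == 1) {
      double x = R(0);
      for (arma::uword r = 0; r < terms.n_rows; ++r) {
        int i = (int)terms(r, 0) - 1, j = (int)terms(r, 1) - 1;
        double g = term_der((int)terms(r, 2), terms(r, 3), terms(r, 4),
                            terms(r, 5), x);
        out(i, j, 0) += g;
        if (i != j) out(j, i, 0) += g;
      }
    } else {
      for (int a = 0; a < ndof; ++a) {
        out.slice(a) = wc.slice(a);
        out.slice(a).diag() += omega(a) * omega(a) * R(a);
      }
    }
    return out;
  }
};

// eigendecomposition with ascending energies and largest-component-positive
// column gauge
void adiabatize_pt(const arma::mat& V, arma::vec& E, arma::mat& W) {
  arma::eig_sym(E, W, arma::symmatu(V));
  for (arma::uword k = 0; k < W.n_cols; ++k) {
    arma::uword pk = arma::abs(W.col(k)).index_max();
    if (W(pk, k) < 0) W.col(k) *= -1.0;
  }
}

arma::vec active_gradient(const ModelC& mod, const arma::vec& R,
                          const arma::mat& W, int a) {
  arma::cube G = mod.dV(R);
  arma::vec g(mod.ndof);
  for (int d = 0; d < mod.ndof; ++d) {
    g(d) = arma::as_scalar(W.col(a).t() * G.slice(d) * W.col(a));
  }
  return g;
}

// polar factor (closest orthogonal matrix) of S via SVD
arma::mat polar_factor(const arma::mat& S) {
  arma::mat Us, Vs;
  arma::vec sv;
  if (!arma::svd(Us, sv, Vs, S) || sv.min() < 1e-12) {
    stop("local diabatization: singular overlap matrix");
  }
  return Us * Vs.t();
}

// per-step local diabatization matrix: polar factor with columns flipped so
// the diagonal is non-negative
arma::mat polar_orthogonal(const arma::mat& S) {
  arma::mat U = polar_factor(S);
  for (arma::uword k = 0; k < U.n_cols; ++k) {
    if (U(k, k) < 0) U.col(k) *= -1.0;
  }
  return U;
}

double kinetic(const arma::vec& m, const arma::vec& v) {
  return 0.5 * arma::dot(m, v % v);
}

struct DecoPars {
  int variant = 0;   // 0 nd, 1 edc, 2 fm, 3 fmi, 4 pfm, 5 pfmi
  double C = 0.1, sigma = 0, mu = 0, omega = 0, eta = 1e-4, kappa = 1e-9;
  int n_d = 1;
  bool injection() const { return variant == 3 || variant == 5; }
};

arma::vec deco_rates(const DecoPars& dp, int a, const arma::vec& paux,
                     const arma::vec& faux, const arma::vec& E, double T) {
  int ns = E.n_elem;
  arma::vec k(ns, arma::fill::zeros);
  if (dp.variant == 0) return k;
  for (int i = 0; i < ns; ++i) {
    if (i == a) continue;
    if (dp.variant == 1) {
      k(i) = std::abs(E(i) - E(a)) * T / (T + dp.C);
    } else if (dp.variant == 2 || dp.variant == 3) {
      double p = paux(i) - paux(a), f = faux(i) - faux(a);
      k(i) = dp.sigma * dp.sigma / 2.0 *
             (p * f + std::abs(p) *
                        std::sqrt(f * f + 1.0 / (dp.mu * dp.mu *
                                                 std::pow(dp.sigma, 6))));
    } else {
      double P = std::abs(paux(i) - paux(a));
      double F = std::abs(faux(i) - faux(a));
      k(i) = M_PI * M_PI / (8.0 * dp.omega) * P * F +
             P * std::sqrt(M_PI * M_PI * dp.n_d * dp.omega / 8.0);
    }
  }
  return k;
}

double slave_factor(double eia, double T) {
  if (T <= 0) return (eia <= 0) ? 1.0 : 0.0;
  double r = 1.0 - eia / T;
  return (r > 0) ? std::sqrt(r) : 0.0;
}

}  // namespace

// [[Rcpp::export(name = ".tsh_trajectory_cpp")]]
List tsh_trajectory_cpp(List model, arma::vec R0, arma::vec v0,
                        arma::vec c0_re, arma::vec c0_im, int active0,
                        List pars) {
  arma::cx_vec c0(c0_re, c0_im);
  ModelC mod;
  mod.init(model);
  const int ns = mod.ns, ndof = mod.ndof;

  const double dt = as<double>(pars["dt"]);
  const int n_steps = as<int>(pars["n_steps"]);
  const int n_sub = as<int>(pars["n_substeps"]);
  const int hop_scheme = as<int>(pars["hop_scheme"]);  // 0 flux, 1 fssh
  const int record_every = as<int>(pars["record_every"]);
  DecoPars dp;
  dp.variant = as<int>(pars["variant"]);
  dp.C = as<double>(pars["C"]);
  dp.sigma = as<double>(pars["sigma"]);
  dp.mu = as<double>(pars["mu"]);
  dp.omega = as<double>(pars["omega"]);
  dp.n_d = as<int>(pars["n_d"]);
  dp.eta = as<double>(pars["eta"]);
  dp.kappa = as<double>(pars["kappa"]);
  const double dsub = dt / n_sub;

  // state
  arma::vec R = R0, v = v0, m = mod.masses, sqm = arma::sqrt(m);
  int a = active0 - 1;
  arma::vec E_old(ns);
  arma::mat W_old(ns, ns);
  adiabatize_pt(mod.V(R), E_old, W_old);
  arma::cx_vec cad = c0 / arma::norm(c0);
  arma::cx_vec ctil = cad;                 // U(0,0) = I
  arma::mat U_cum(ns, ns, arma::fill::eye);
  arma::mat Vt0 = arma::diagmat(E_old);    // diabatized potential at t0
  arma::mat Kt0(ns, ns, arma::fill::zeros);   // diabatized residual NAC
  arma::mat Kad0(ns, ns, arma::fill::zeros);  // adiabatic finite-diff NAC
  arma::vec F = -active_gradient(mod, R, W_old, a);

  // auxiliary bundle
  double T0 = kinetic(m, v);
  double pa0 = (ndof == 1) ? m(0) * v(0) : arma::norm(sqm % v);
  arma::vec paux(ns), faux(ns, arma::fill::zeros);
  for (int j = 0; j < ns; ++j) {
    double pop = std::norm(cad(j));
    paux(j) = (pop >= dp.eta || j == a)
                  ? pa0
                  : pa0 * slave_factor(E_old(j) - E_old(a), T0);
  }

  // records
  const int n_rec = n_steps / record_every + 2;
  arma::vec rec_t(n_rec);
  arma::mat rec_R(n_rec, ndof), rec_v(n_rec, ndof), rec_paux(n_rec, ns);
  arma::ivec rec_a(n_rec);
  arma::cx_mat rec_c(n_rec, ns);
  arma::vec rec_E(n_rec);
  std::vector<double> hop_t, hop_from, hop_to, hop_frus;
  int ir = 0;
  bool failed = false;
  std::string fail_reason = "";

  auto record = [&](double t) {
    rec_t(ir) = t;
    rec_R.row(ir) = R.t();
    rec_v.row(ir) = v.t();
    rec_a(ir) = a + 1;
    rec_c.row(ir) = cad.st();
    rec_E(ir) = E_old(a) + kinetic(m, v);
    rec_paux.row(ir) = paux.t();
    ++ir;
  };
  record(0.0);

  for (int step = 0; step < n_steps && !failed; ++step) {
    const double t0 = step * dt;
    const int a_start = a;
    arma::vec pop_old(ns);
    for (int j = 0; j < ns; ++j) pop_old(j) = std::norm(cad(j));
    const double Tstart = kinetic(m, v);

    // i. first Velocity-Verlet half-step
    arma::vec v_half = v + 0.5 * dt * (F / m);
    arma::vec R_new = R + dt * v_half;
    if (!R_new.is_finite()) { failed = true; fail_reason = "non-finite position"; break; }

    // ii. adiabatic states at the new geometry, sign continuity
    arma::vec E_new(ns);
    arma::mat W_new(ns, ns);
    adiabatize_pt(mod.V(R_new), E_new, W_new);
    arma::mat S = W_new.t() * W_old;
    for (int k = 0; k < ns; ++k) {
      if (S(k, k) < 0) { W_new.col(k) *= -1.0; S.row(k) *= -1.0; }
    }

    // iii. auxiliary forces from the forward energy difference, midpoint
    // velocity as reference
    double vref = (ndof == 1) ? v_half(0) : arma::norm(sqm % v_half);
    if (std::abs(vref) < dp.kappa) {
      faux.zeros();
    } else {
      faux = -(E_new - E_old) / (vref * dt);
    }

    // iv-v. local diabatization and diabatized potential / residual NAC
    arma::mat U_step = polar_orthogonal(S);
    arma::mat U_new = U_step * U_cum;
    arma::mat Vt1 = U_new.t() * arma::diagmat(E_new) * U_new;
    arma::mat Kt1 = (arma::eye(ns, ns) - U_new.t() * S * U_cum) / dt;
    arma::mat Kad1 = (arma::eye(ns, ns) - S) / dt;

    // large per-step electronic rotation (sharp avoided crossing): the
    // interpolated cumulative U needs re-orthogonalization per substep
    const bool need_polar =
        arma::abs(U_step - arma::eye(ns, ns)).max() > 0.02;

    // decoherence rates for this step, from step-start quantities
    double Tmid = kinetic(m, v_half);
    arma::vec kdec = deco_rates(dp, a, paux, faux, E_old, Tstart);

    // vi-vii. electronic substeps with linear interpolants; the step-mean
    // diagonal energy is subtracted (global-phase gauge) to reduce the RK4
    // phase error -- populations and coherences are invariant under it
    double eshift = (arma::trace(Vt0) + arma::trace(Vt1)) / (2.0 * ns);
    arma::mat Vs0 = Vt0, Vs1 = Vt1;
    Vs0.diag() -= eshift;
    Vs1.diag() -= eshift;
    arma::cx_mat H0(Vs0, -Kt0), H1(Vs1, -Kt1);
    arma::cx_mat Hd = H1 - H0;                    // interpolation slope
    arma::mat Ud = U_new - U_cum;
    arma::vec rho_prev(ns), rho_now(ns), g(ns, arma::fill::zeros);
    arma::cx_vec k1(ns), k2(ns), k3(ns), k4(ns), ctmp(ns);
    arma::mat U_s(ns, ns);
    const std::complex<double> mi(0.0, -1.0);
    // hand-rolled small-matrix kernels: the 51-substep loop dominates the
    // trajectory runtime and generic matrix calls carry too much per-call
    // overhead at these dimensions
    const std::complex<double>* h0 = H0.memptr();
    const std::complex<double>* hd = Hd.memptr();
    auto deriv = [&](const std::complex<double>* c, double s,
                     std::complex<double>* out) {
      for (int i = 0; i < ns; ++i) {
        std::complex<double> acc(0.0, 0.0);
        for (int j = 0; j < ns; ++j) {
          acc += (h0[i + j * ns] + s * hd[i + j * ns]) * c[j];
        }
        out[i] = mi * acc;
      }
    };
    auto renorm = [&](std::complex<double>* c) {
      double n2 = 0;
      for (int i = 0; i < ns; ++i) n2 += std::norm(c[i]);
      double inv = 1.0 / std::sqrt(n2);
      for (int i = 0; i < ns; ++i) c[i] *= inv;
    };
    for (int j = 0; j < ns; ++j) rho_prev(j) = std::norm(cad(j));
    for (int ssub = 1; ssub <= n_sub; ++ssub) {
      double s0 = (double)(ssub - 1) / n_sub;
      double s1 = (double)ssub / n_sub;
      double sm = 0.5 * (s0 + s1);
      std::complex<double>* ct = ctil.memptr();
      deriv(ct, s0, k1.memptr());
      for (int i = 0; i < ns; ++i) ctmp(i) = ct[i] + 0.5 * dsub * k1(i);
      deriv(ctmp.memptr(), sm, k2.memptr());
      for (int i = 0; i < ns; ++i) ctmp(i) = ct[i] + 0.5 * dsub * k2(i);
      deriv(ctmp.memptr(), sm, k3.memptr());
      for (int i = 0; i < ns; ++i) ctmp(i) = ct[i] + dsub * k3(i);
      deriv(ctmp.memptr(), s1, k4.memptr());
      for (int i = 0; i < ns; ++i) {
        ct[i] += dsub / 6.0 * (k1(i) + 2.0 * k2(i) + 2.0 * k3(i) + k4(i));
      }
      renorm(ct);

      // transform to the adiabatic basis with the interpolated U,
      // re-orthogonalized (when the per-step rotation is large) so that
      // damping in the adiabatic frame and the back-transform stay exactly
      // norm-consistent across sharp avoided crossings
      {
        double* us = U_s.memptr();
        const double* uc = U_cum.memptr();
        const double* ud = Ud.memptr();
        for (int i = 0; i < ns * ns; ++i) us[i] = uc[i] + s1 * ud[i];
      }
      if (need_polar) U_s = polar_factor(U_s);
      {
        const double* us = U_s.memptr();
        for (int i = 0; i < ns; ++i) {
          std::complex<double> acc(0.0, 0.0);
          for (int j = 0; j < ns; ++j) acc += us[i + j * ns] * ctil(j);
          cad(i) = acc;
        }
      }
      renorm(cad.memptr());
      for (int j = 0; j < ns; ++j) rho_now(j) = std::norm(cad(j));

      // hopping probabilities
      g.zeros();
      if (hop_scheme == 0) {
        if (rho_prev(a) > 0 && rho_now(a) < rho_prev(a)) {
          double loss = (rho_prev(a) - rho_now(a)) / rho_prev(a);
          double gain_sum = 0;
          for (int l = 0; l < ns; ++l) {
            if (l == a) continue;
            double gl = rho_now(l) - rho_prev(l);
            if (gl > 0) { g(l) = gl; gain_sum += gl; }
          }
          if (gain_sum > 0) g *= loss / gain_sum; else g.zeros();
        }
      } else {
        arma::mat Kad = Kad0 + s1 * (Kad1 - Kad0);
        if (rho_now(a) > 0) {
          for (int k = 0; k < ns; ++k) {
            if (k == a) continue;
            double flux =
                2.0 * std::real(Kad(a, k) * cad(k) * std::conj(cad(a)));
            double gk = dsub * flux / rho_now(a);
            if (gk > 0) g(k) = gk;
          }
        }
      }

      // one uniform draw per substep (fixed schedule)
      double r = unif_rand();
      double cum = 0;
      int target = -1;
      for (int k = 0; k < ns; ++k) {
        if (k == a) continue;
        cum += g(k);
        if (r <= cum) { target = k; break; }
      }
      if (target >= 0) {
        double Ea_s = E_old(a) + s1 * (E_new(a) - E_old(a));
        double Ek_s = E_old(target) + s1 * (E_new(target) - E_old(target));
        bool ok = (Ea_s + Tmid >= Ek_s);
        hop_t.push_back(t0 + s1 * dt);
        hop_from.push_back(a + 1);
        hop_to.push_back(target + 1);
        hop_frus.push_back(ok ? 0.0 : 1.0);
        if (ok) {
          a = target;
          kdec = deco_rates(dp, a, paux, faux, E_old, Tstart);
        }
      }

      // decoherence damping of the adiabatic coefficients
      if (dp.variant != 0) {
        double inact = 0;
        for (int i = 0; i < ns; ++i) {
          if (i == a) continue;
          cad(i) *= std::exp(-kdec(i) * dsub);
          inact += std::norm(cad(i));
        }
        double ca = std::abs(cad(a));
        if (ca < 1e-200) {
          failed = true;
          fail_reason = "zero active coefficient during decoherence";
          break;
        }
        cad(a) *= std::sqrt(std::max(0.0, 1.0 - inact)) / ca;
        const double* us = U_s.memptr();
        for (int i = 0; i < ns; ++i) {
          std::complex<double> acc(0.0, 0.0);
          for (int j = 0; j < ns; ++j) acc += us[j + i * ns] * cad(j);
          ctil(i) = acc;
        }
        renorm(ctil.memptr());
        renorm(cad.memptr());
      }
      for (int j = 0; j < ns; ++j) rho_prev(j) = std::norm(cad(j));
    }
    if (failed) break;

    // end of substeps: exact adiabatic coefficients
    cad = U_new * ctil;
    cad /= arma::norm(cad);

    // viii. second Velocity-Verlet half-step with the (new) active force
    arma::vec F_new = -active_gradient(mod, R_new, W_new, a);
    arma::vec v_new = v_half + 0.5 * dt * (F_new / m);
    if (!v_new.is_finite()) { failed = true; fail_reason = "non-finite velocity"; break; }

    // ix. isotropic velocity rescaling if the active surface changed
    double hop_factor = 1.0;
    if (a != a_start) {
      double T_end = kinetic(m, v_new);
      double dE = E_new(a) + T_end - (E_old(a_start) + Tstart);
      double rad = (T_end > 0) ? 1.0 - dE / T_end : -1.0;
      if (rad < 0) {
        // interpolation edge: not enough kinetic energy after all; treat as
        // frustrated and stay on the original surface
        a = a_start;
        F_new = -active_gradient(mod, R_new, W_new, a);
        v_new = v_half + 0.5 * dt * (F_new / m);
        if (!hop_frus.empty()) hop_frus.back() = 1.0;
      } else {
        hop_factor = std::sqrt(rad);
        v_new *= hop_factor;
      }
    }

    // x-xi. auxiliary momentum propagation
    arma::vec pop_new(ns);
    for (int j = 0; j < ns; ++j) pop_new(j) = std::norm(cad(j));
    double T_post = kinetic(m, v_new);
    arma::vec paux_new = paux;
    double pa = paux(a_start) + faux(a) * dt;
    if (a != a_start) pa *= hop_factor;
    paux_new(a) = pa;
    for (int i = 0; i < ns; ++i) {
      if (i == a) continue;
      double slave = pa * slave_factor(E_new(i) - E_new(a), T_post);
      if (pop_old(i) >= dp.eta && pop_new(i) >= dp.eta) {
        double pi_new = paux(i) + faux(i) * dt;
        double drho = pop_new(i) - pop_old(i);
        if (dp.injection() && drho > 0) {
          double frac = drho / pop_new(i);
          pi_new = pi_new * (1 - frac) + frac * slave;
        }
        paux_new(i) = pi_new;
      } else {
        paux_new(i) = slave;
      }
    }
    paux = paux_new;

    // xii. collapse of populations that fell below the threshold
    bool collapsed = false;
    for (int i = 0; i < ns; ++i) {
      if (i == a) continue;
      if (pop_old(i) >= dp.eta && pop_new(i) < dp.eta &&
          pop_new(i) > 0) {
        double ca2 = std::norm(cad(a));
        if (ca2 > 0) {
          cad(a) *= std::sqrt(1.0 + pop_new(i) / ca2);
          cad(i) = 0;
          collapsed = true;
        }
      }
    }
    if (collapsed) {
      cad /= arma::norm(cad);
      ctil = U_new.t() * cad;
      ctil /= arma::norm(ctil);
    }

    // shift caches
    R = R_new; v = v_new; F = F_new;
    E_old = E_new; W_old = W_new; U_cum = U_new;
    Vt0 = Vt1; Kt0 = Kt1; Kad0 = Kad1;

    if ((step + 1) % record_every == 0 || step + 1 == n_steps) {
      record((step + 1) * dt);
    }
  }

  arma::mat hops(hop_t.size(), 4);
  for (size_t h = 0; h < hop_t.size(); ++h) {
    hops(h, 0) = hop_t[h];
    hops(h, 1) = hop_from[h];
    hops(h, 2) = hop_to[h];
    hops(h, 3) = hop_frus[h];
  }

  arma::cx_mat cfin = rec_c.head_rows(ir);
  return List::create(
      _["times"] = rec_t.head(ir), _["positions"] = rec_R.head_rows(ir),
      _["velocities"] = rec_v.head_rows(ir),
      _["active"] = rec_a.head(ir),
      _["coefficients_re"] = arma::mat(arma::real(cfin)),
      _["coefficients_im"] = arma::mat(arma::imag(cfin)),
      _["energy"] = rec_E.head(ir), _["p_aux"] = rec_paux.head_rows(ir),
      _["hops"] = hops, _["failed"] = failed,
      _["fail_reason"] = fail_reason);
}
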