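// Fewest-switches surface-hopping integration loop on LVC surfaces.
// The per-step physics mirrors the documented R-level operations
// (evaluate_adiabatic, hst_tdc/nac_tdc, propagate_electronic,
// hop_probabilities, attempt_hop); it is compiled because a trajectory
// swarm takes millions of small steps.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// diabatic LVC Hamiltonian at Q
static mat diabatic_V(const vec& omega, const vec& eps, const mat& kappa,
                      const cube& lambda, const mat& eta, const vec& Q) {
  const uword ns = eps.n_elem, nm = omega.n_elem;
  mat V = eta;
  double base = 0.5 * dot(omega, Q % Q);
  for (uword a = 0; a < nm; ++a) V += lambda.slice(a) * Q(a);
  for (uword i = 0; i < ns; ++i) V(i, i) = eps(i) + dot(kappa.row(i), Q) + base;
  return V;
}

// deterministic eigenvector sign convention: largest-|component| positive
static void fix_signs(mat& U) {
  for (uword j = 0; j < U.n_cols; ++j) {
    uword imax = index_max(abs(U.col(j)));
    if (U(imax, j) < 0) U.col(j) *= -1.0;
  }
}

struct AdiPoint {
  vec E;        // ascending adiabatic energies
  mat U;        // diabatic -> adiabatic eigenvectors (columns)
  mat grad;     // ns x nm state gradients
  cube nac;     // ns x ns x nm couplings (antisymmetric)
};

static AdiPoint eval_point(const vec& omega, const vec& eps, const mat& kappa,
                           const cube& lambda, const mat& eta, const vec& Q,
                           double deg_floor) {
  const uword ns = eps.n_elem, nm = omega.n_elem;
  AdiPoint pt;
  mat V = diabatic_V(omega, eps, kappa, lambda, eta, Q);
  eig_sym(pt.E, pt.U, V);          // ascending
  fix_signs(pt.U);
  pt.grad.set_size(ns, nm);
  pt.nac.zeros(ns, ns, nm);
  for (uword a = 0; a < nm; ++a) {
    mat G = lambda.slice(a);
    for (uword i = 0; i < ns; ++i) G(i, i) = kappa(i, a) + omega(a) * Q(a);
    mat W = pt.U.t() * G * pt.U;
    pt.grad.col(a) = W.diag();
    for (uword i = 0; i < ns; ++i)
      for (uword k = i + 1; k < ns; ++k) {
        double gap = pt.E(k) - pt.E(i);
        double den = (std::abs(gap) < deg_floor)
                         ? (gap >= 0 ? deg_floor : -deg_floor)
                         : gap;
        double d = W(i, k) / den;
        pt.nac(i, k, a) = d;
        pt.nac(k, i, a) = -d;
      }
  }
  return pt;
}

// phase correction: flip signs of U_curr columns so diag(U_prev^T U_curr) >= 0;
// returns the (corrected) overlap matrix
static mat align_phase(const mat& U_prev, mat& U_curr, AdiPoint* pt) {
  mat S = U_prev.t() * U_curr;
  for (uword j = 0; j < S.n_cols; ++j) {
    if (S(j, j) < 0) {
      S.col(j) *= -1.0;
      U_curr.col(j) *= -1.0;
      if (pt) {
        // flipping column j of U flips row/col j of every U^T G U product
        for (uword a = 0; a < pt->nac.n_slices; ++a) {
          pt->nac.slice(a).row(j) *= -1.0;
          pt->nac.slice(a).col(j) *= -1.0;
        }
      }
    }
  }
  return S;
}

// one exponential-midpoint substep: c <- exp(-i h H) c, H = diag(E) - i T
static cx_vec expstep(const vec& E, const mat& T, double h, const cx_vec& c) {
  const uword ns = E.n_elem;
  const std::complex<double> I(0.0, 1.0);
  if (ns == 1) return std::exp(-I * E(0) * h) * c;
  if (ns == 2) {
    // closed form for a Hermitian 2x2: H = m I + {{d, z},{conj(z), -d}}
    double m = 0.5 * (E(0) + E(1));
    double d = 0.5 * (E(0) - E(1));
    std::complex<double> z = -I * T(0, 1);
    double Delta = std::sqrt(d * d + std::norm(z));
    std::complex<double> phase = std::exp(-I * m * h);
    cx_vec out(2);
    if (Delta < 1e-300) return phase * c;
    double ch = std::cos(Delta * h), sh = std::sin(Delta * h) / Delta;
    std::complex<double> a00 = ch - I * sh * d;
    std::complex<double> a01 = -I * sh * z;
    std::complex<double> a10 = -I * sh * std::conj(z);
    std::complex<double> a11 = ch + I * sh * d;
    out(0) = phase * (a00 * c(0) + a01 * c(1));
    out(1) = phase * (a10 * c(0) + a11 * c(1));
    return out;
  }
  cx_mat H(ns, ns, fill::zeros);
  H.set_real(diagmat(E));
  H += cx_mat(zeros(ns, ns), -T);
  vec w;
  cx_mat Vv;
  eig_sym(w, Vv, H);
  cx_vec ph = exp(-I * h * conv_to<cx_vec>::from(w));
  return Vv * (ph % (Vv.t() * c));
}

// [[Rcpp::export]]
Rcpp::List elec_propagate_cpp(const arma::vec& c_re, const arma::vec& c_im,
                              const arma::vec& E0, const arma::vec& E1,
                              const arma::mat& T0, const arma::mat& T1,
                              double dt, int n_sub) {
  cx_vec c = cx_vec(c_re, c_im);
  double h = dt / n_sub;
  for (int j = 0; j < n_sub; ++j) {
    double f = (j + 0.5) / n_sub;      // midpoint interpolation fraction
    vec E = (1.0 - f) * E0 + f * E1;
    mat T = (1.0 - f) * T0 + f * T1;
    c = expstep(E, T, h, c);
  }
  return Rcpp::List::create(Rcpp::Named("re") = vec(real(c)),
                            Rcpp::Named("im") = vec(imag(c)));
}

// [[Rcpp::export]]
Rcpp::List fssh_run_cpp(const arma::vec& omega, const arma::vec& eps,
                        const arma::mat& kappa, const arma::cube& lambda,
                        const arma::mat& eta, const arma::vec& Q0,
                        const arma::vec& P0, int active0,
                        const arma::vec& c0_re, const arma::vec& c0_im,
                        double dt, int n_steps,
                        int n_sub, std::string tdc_source, int stride,
                        double deg_floor) {
  const uword ns = eps.n_elem, nm = omega.n_elem;
  const bool use_hst = (tdc_source == "hst");

  vec Q = Q0, P = P0;
  int active = active0 - 1;            // 0-based internally
  cx_vec c = cx_vec(c0_re, c0_im);

  AdiPoint pt = eval_point(omega, eps, kappa, lambda, eta, Q, deg_floor);

  const int n_rec = n_steps / stride + 1;
  vec rec_t(n_rec), rec_E(n_rec);
  mat rec_Q(n_rec, nm), rec_P(n_rec, nm);
  ivec rec_act(n_rec);
  mat rec_cre(n_rec, ns), rec_cim(n_rec, ns);
  std::vector<int> hop_step, hop_from, hop_to;
  int n_frustrated = 0;
  std::string termination = "completed";

  auto record = [&](int slot, double t) {
    rec_t(slot) = t;
    rec_Q.row(slot) = Q.t();
    rec_P.row(slot) = P.t();
    rec_act(slot) = active + 1;
    rec_cre.row(slot) = vec(real(c)).t();
    rec_cim.row(slot) = vec(imag(c)).t();
    rec_E(slot) = 0.5 * dot(omega, P % P) + pt.E(active);
  };
  record(0, 0.0);

  auto tdc_from_nac = [&](const AdiPoint& p, const vec& mom) {
    mat T(ns, ns, fill::zeros);
    vec qdot = omega % mom;
    for (uword a = 0; a < nm; ++a) T += p.nac.slice(a) * qdot(a);
    return T;
  };

  mat T_prev;
  if (!use_hst) T_prev = tdc_from_nac(pt, P);

  int slot = 1;
  int step = 0;
  for (step = 1; step <= n_steps; ++step) {
    // velocity Verlet on the active surface
    vec F = -pt.grad.row(active).t();
    vec Phalf = P + 0.5 * dt * F;
    vec Qnew = Q + dt * (omega % Phalf);
    AdiPoint ptnew = eval_point(omega, eps, kappa, lambda, eta, Qnew, deg_floor);
    mat S = align_phase(pt.U, ptnew.U, &ptnew);
    vec Fnew = -ptnew.grad.row(active).t();
    vec Pnew = Phalf + 0.5 * dt * Fnew;

    // time-derivative couplings across the step
    mat T0, T1;
    if (use_hst) {
      T0 = (S - S.t()) / (2.0 * dt);
      T1 = T0;
    } else {
      T0 = T_prev;
      T1 = tdc_from_nac(ptnew, Pnew);
    }

    // electronic propagation with linear interpolation of E and T
    double h = dt / n_sub;
    for (int j = 0; j < n_sub; ++j) {
      double f = (j + 0.5) / n_sub;
      vec Em = (1.0 - f) * pt.E + f * ptnew.E;
      mat Tm = (1.0 - f) * T0 + f * T1;
      c = expstep(Em, Tm, h, c);
    }

    // fewest-switches hop attempt with midpoint couplings
    mat Tmid = 0.5 * (T0 + T1);
    double pa = std::norm(c(active));
    if (pa > 1e-12) {
      vec g(ns, fill::zeros);
      for (uword k = 0; k < ns; ++k) {
        if ((int)k == active) continue;
        double gg = 2.0 * dt * Tmid(active, k) *
                    std::real(std::conj(c(active)) * c(k)) / pa;
        g(k) = gg > 0 ? gg : 0.0;
      }
      double tot = accu(g);
      if (tot > 1.0) g /= tot;
      double u = R::runif(0.0, 1.0);
      double cum = 0.0;
      int target = -1;
      for (uword k = 0; k < ns; ++k) {
        cum += g(k);
        if (u < cum) { target = k; break; }
      }
      if (target >= 0 && target != active) {
        double dE = ptnew.E(target) - ptnew.E(active);
        vec d = ptnew.nac.tube(active, target);
        double nd = norm(d);
        bool done = false, frustrated = false;
        if (std::isfinite(nd) && nd > 1e-12) {
          vec dir = d / nd;
          double aa = 0.5 * dot(omega, dir % dir);
          double bb = dot(omega, Pnew % dir);
          double disc = bb * bb - 4.0 * aa * dE;
          if (disc < 0) {
            frustrated = true;
          } else {
            double r1 = (-bb + std::sqrt(disc)) / (2.0 * aa);
            double r2 = (-bb - std::sqrt(disc)) / (2.0 * aa);
            double gam = (std::abs(r1) < std::abs(r2)) ? r1 : r2;
            Pnew += gam * dir;
            done = true;
          }
        } else {
          double ekin = 0.5 * dot(omega, Pnew % Pnew);
          if (dE > ekin) {
            frustrated = true;
          } else {
            Pnew *= std::sqrt(1.0 - dE / ekin);
            done = true;
          }
        }
        if (done) {
          hop_step.push_back(step);
          hop_from.push_back(active + 1);
          hop_to.push_back(target + 1);
          active = target;
        } else if (frustrated) {
          ++n_frustrated;
        }
      }
    }

    Q = Qnew;
    P = Pnew;
    pt = ptnew;
    if (!use_hst) T_prev = tdc_from_nac(pt, P);

    double Etot = 0.5 * dot(omega, P % P) + pt.E(active);
    if (!std::isfinite(Etot) || !Q.is_finite() || !c.is_finite()) {
      termination = "nonfinite_energy";
      break;
    }
    if (step % stride == 0) {
      record(slot, step * dt);
      ++slot;
    }
  }

  Rcpp::List hops = Rcpp::List::create(
      Rcpp::Named("step") = hop_step, Rcpp::Named("from") = hop_from,
      Rcpp::Named("to") = hop_to);

  return Rcpp::List::create(
      Rcpp::Named("time") = rec_t.head(slot),
      Rcpp::Named("Q") = rec_Q.head_rows(slot),
      Rcpp::Named("P") = rec_P.head_rows(slot),
      Rcpp::Named("active") = rec_act.head(slot),
      Rcpp::Named("coeff_re") = rec_cre.head_rows(slot),
      Rcpp::Named("coeff_im") = rec_cim.head_rows(slot),
      Rcpp::Named("energy") = rec_E.head(slot),
      Rcpp::Named("hops") = hops,
      Rcpp::Named("n_frustrated") = n_frustrated,
      Rcpp::Named("termination") = termination);
}
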