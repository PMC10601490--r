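# Synthetic model systems: every other module is exercisable with no
# external data.  All generators are deterministic given their arguments
# (and seed, where one is taken).

#' Diatomic molecule with a single stretching force constant
#'
#' Two atoms on the x axis at 1.4 bohr separation; the Hessian holds the
#' single stretch block \eqn{k \,[[1,-1],[-1,1]]} in the x coordinates.
#' The lone vibration has \eqn{\omega = \sqrt{k/\mu}} with reduced mass
#' \eqn{\mu = m_1 m_2/(m_1 + m_2)}.
#'
#' @param masses_amu two atomic masses (amu).
#' @param k stretching force constant (E_h/bohr^2, > 0).
#' @return list with \code{molecule} and \code{hessian}.
#' @export
make_diatomic <- function(masses_amu = c(1, 1), k = 0.1) {
  if (k <= 0) stop(vib_error("bad_force_constant", "k must be positive"))
  mol <- molecule(c("H", "H"), rbind(c(0, 0, 0), c(1.4, 0, 0)),
                  units_in = "bohr", masses_amu = masses_amu)
  H <- matrix(0, 6, 6)
  H[1, 1] <- H[4, 4] <- k
  H[1, 4] <- H[4, 1] <- -k
  list(molecule = mol, hessian = H)
}

#' Bent triatomic with three known vibrational frequencies
#'
#' A water-like bent molecule whose Hessian is constructed by reverse mass
#' weighting from three chosen frequencies (1595.0, 3657.0, 3756.0
#' cm\eqn{^{-1}}) and a seeded random orthonormal completion of the
#' external-mode basis: \eqn{H = M^{1/2} L\, \omega^2 L^T M^{1/2}}.  The
#' frequencies are therefore recovered exactly by
#' \code{\link{compute_modes}}.
#'
#' @param seed integer seed for the vibrational eigenvector choice.
#' @return list with \code{molecule}, \code{hessian}, \code{omega}
#'   (a.u.), \code{freq_cm}, \code{L} (the generating eigenvectors).
#' @export
make_bent_triatomic <- function(seed = 1L) {
  # O at origin, two H at the water geometry (bohr)
  mol <- molecule(c("O", "H", "H"),
                  rbind(c(0, 0, 0),
                        c(1.431, 1.108, 0),
                        c(-1.431, 1.108, 0)),
                  units_in = "bohr")
  freq_cm <- c(1595.0, 3657.0, 3756.0)
  omega <- freq_cm * au_constants$cm1_to_hartree
  B <- external_mode_basis(mol)            # 9 x 6
  set.seed(seed)
  L <- matrix(stats::rnorm(9 * 3), 9, 3)
  L <- L - B %*% crossprod(B, L)           # orthogonal to external modes
  L <- qr.Q(qr(L))[, 1:3, drop = FALSE]
  L <- fix_eigvec_signs(L)
  sqm <- rep(sqrt(mol$masses), each = 3L)
  Hmw <- L %*% diag(omega^2) %*% t(L)
  H <- Hmw * outer(sqm, sqm)
  H <- (H + t(H)) / 2
  list(molecule = mol, hessian = H, omega = omega, freq_cm = freq_cm, L = L)
}

#' Two-state one-mode avoided-crossing model
#'
#' LVC model with \eqn{\epsilon = (0, gap)}, opposite intrastate slopes
#' \eqn{\kappa = (+slope, -slope)}, a constant interstate coupling
#' \eqn{\eta_{12}} and optionally a linear one \eqn{\lambda_{12}}.  The
#' adiabatic gap at Q = 0 is \eqn{\sqrt{gap^2 + 4\eta^2}}.  The
#' Landau-Zener test bed used throughout the surface-hopping suite.
#'
#' @param gap vertical gap at Q = 0 (E_h).
#' @param slope intrastate gradient magnitude (E_h per unit Q).
#' @param coupling_const constant coupling \eqn{\eta_{12}} (E_h).
#' @param coupling_linear linear coupling \eqn{\lambda_{12}} (E_h per unit Q).
#' @param omega mode frequency (a.u.).
#' @param dipole01 transition dipole vector between the states (a.u.).
#' @return an \code{\link{lvc_model}}.
#' @export
make_two_state_crossing <- function(gap = 0, slope = 0.01,
                                    coupling_const = 0.003,
                                    coupling_linear = 0,
                                    omega = 0.002,
                                    dipole01 = c(1, 0, 0)) {
  lambda <- array(0, c(2, 2, 1))
  lambda[1, 2, 1] <- lambda[2, 1, 1] <- coupling_linear
  eta <- matrix(c(0, coupling_const, coupling_const, 0), 2, 2)
  dip <- array(0, c(2, 2, 3))
  dip[1, 2, ] <- dip[2, 1, ] <- dipole01
  lvc_model(omega = omega, epsilon = c(0, gap),
            kappa = matrix(c(slope, -slope), 2, 1),
            lambda = lambda, eta = eta, dipoles = dip)
}

#' Random multi-mode multi-state vibronic model
#'
#' Frequencies log-uniform between \code{omega_band} (cm\eqn{^{-1}}),
#' intrastate gradients and interstate linear couplings normal with the
#' given scales, vertical shifts spread over \code{epsilon_span}, random
#' unit-scale transition dipoles from the ground state.  Reproducible by
#' seed.
#'
#' @param n_modes,n_states model size.
#' @param kappa_scale,lambda_scale normal scales (E_h per unit Q).
#' @param epsilon_span upper edge of the vertical-shift range (E_h).
#' @param omega_band frequency band (cm^-1).
#' @param seed integer seed.
#' @return an \code{\link{lvc_model}}.
#' @export
make_multimode_lvc <- function(n_modes = 3L, n_states = 3L,
                               kappa_scale = 0.002, lambda_scale = 0.001,
                               epsilon_span = 0.2,
                               omega_band = c(500, 3000), seed = 1L) {
  set.seed(seed)
  omega <- exp(stats::runif(n_modes, log(omega_band[1]), log(omega_band[2]))) *
    au_constants$cm1_to_hartree
  epsilon <- c(0, sort(stats::runif(n_states - 1L, epsilon_span / 4, epsilon_span)))
  kappa <- matrix(stats::rnorm(n_states * n_modes, 0, kappa_scale),
                  n_states, n_modes)
  lambda <- array(0, c(n_states, n_states, n_modes))
  for (a in seq_len(n_modes)) {
    la <- matrix(0, n_states, n_states)
    up <- upper.tri(la)
    la[up] <- stats::rnorm(sum(up), 0, lambda_scale)
    lambda[, , a] <- la + t(la)
  }
  dip <- array(0, c(n_states, n_states, 3))
  for (j in 2:n_states) {
    v <- stats::rnorm(3)
    dip[1, j, ] <- dip[j, 1, ] <- v / sqrt(sum(v^2))
  }
  lvc_model(omega, epsilon, kappa = kappa, lambda = lambda, dipoles = dip)
}

#' Piecewise flux / cross-section / quantum-yield curves
#'
#' Two-column curves for the photolysis-rate integrator:
#' \code{"constant"} (params: \code{value}, \code{from}, \code{to},
#' \code{n}) and \code{"gaussian"} (params: \code{area}, \code{center},
#' \code{fwhm}, \code{from}, \code{to}, \code{n}).
#'
#' @param kind curve family.
#' @param params named list of family parameters (see above).
#' @return data.frame with \code{x} (nm) and \code{y}.
#' @export
make_flux_table <- function(kind = c("constant", "gaussian"), params = list()) {
  kind <- match.arg(kind)
  p <- utils::modifyList(switch(kind,
    constant = list(value = 1, from = 300, to = 400, n = 101L),
    gaussian = list(area = 1, center = 350, fwhm = 30, from = 250,
                    to = 450, n = 401L)
  ), params)
  if (!(p$to > p$from)) stop(vib_error("empty_window", "need to > from"))
  x <- seq(p$from, p$to, length.out = p$n)
  y <- switch(kind,
    constant = rep(p$value, p$n),
    gaussian = {
      sd <- p$fwhm / (2 * sqrt(2 * log(2)))
      p$area * stats::dnorm(x, p$center, sd)
    })
  data.frame(x = x, y = y)
}
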