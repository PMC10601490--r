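# Initial-condition generation: classical normal-mode sampling (NMS) with
# Boltzmann mode energies and random phases, and ground-state / thermal
# Wigner sampling.  All phase-space coordinates here are mass-weighted
# normal coordinates Q (bohr sqrt(m_e)) with conjugate momenta P, so each
# mode's energy is (P^2 + omega^2 Q^2)/2.

#' Sample per-mode vibrational energies from a classical Boltzmann law
#'
#' Each mode's energy is drawn independently as \eqn{E_i = -k_B T \ln u}
#' with \eqn{u} uniform on (0, 1]; at T = 0 all energies are zero.
#'
#' @param modes a \code{\link{compute_modes}} result.
#' @param temperature temperature in kelvin (>= 0).
#' @param n number of samples.
#' @return n x n_modes matrix of energies (E_h).
#' @export
sample_boltzmann_energies <- function(modes, temperature, n) {
  if (temperature < 0) stop(vib_error("negative_temperature", "temperature must be >= 0"))
  k <- n_modes(modes)
  if (temperature == 0) return(matrix(0, n, k))
  u <- matrix(stats::runif(n * k), n, k)
  -au_constants$kB * temperature * log1p(-u)  # log of uniform on (0,1]
}

#' Position and momentum of one classical mode at a given phase
#'
#' \eqn{A = \sqrt{2E}/\omega}, \eqn{Q = A\cos\phi},
#' \eqn{P = -A\omega\sin\phi}; the mode energy
#' \eqn{(P^2 + \omega^2 Q^2)/2} equals \eqn{E} for every phase.
#'
#' @param E mode energy (E_h).
#' @param omega mode frequency (a.u.).
#' @param phase phase angle in radians.
#' @return list with \code{Q}, \code{P} (recycled elementwise).
#' @export
nms_mode_sample <- function(E, omega, phase) {
  A <- sqrt(2 * E) / omega
  list(Q = A * cos(phase), P = -A * omega * sin(phase))
}

#' Classical normal-mode sampling of initial conditions
#'
#' Draws per-mode Boltzmann energies and uniform phases, builds normal-mode
#' positions and momenta, transforms to Cartesian coordinates, removes
#' center-of-mass momentum, and (by default) rescales each sample by a
#' single common factor so its total harmonic energy equals the sum of the
#' sampled mode energies.
#'
#' @param modes a \code{\link{compute_modes}} result (imaginary modes are
#'   excluded automatically).
#' @param temperature temperature in kelvin.
#' @param n ensemble size.
#' @param rescale rescale to the summed sampled energies (default TRUE).
#' @param seed optional integer seed (calls \code{set.seed}).
#' @return an \code{ic_ensemble} object; see Details.
#' @details The returned object carries matrices \code{Q}, \code{P}
#'   (n x n_modes), \code{x}, \code{p} (n x 3N), the sampled per-mode
#'   energies \code{E_modes}, phases, per-sample rescale factors, and
#'   provenance (method tag, temperature, seed, the mode set).
#' @export
sample_nms <- function(modes, temperature, n, rescale = TRUE, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  vib <- vibrational_modes(modes)
  k <- n_modes(vib)
  if (k < 1L) stop(vib_error("no_modes", "mode set has no vibrational modes"))
  if (any(vib$omega == 0)) stop(vib_error("zero_frequency",
    "zero-frequency mode in the sampled set; filter upstream"))
  E <- sample_boltzmann_energies(vib, temperature, n)
  phase <- matrix(stats::runif(n * k, 0, 2 * pi), n, k)
  A <- sweep(sqrt(2 * E), 2, vib$omega, "/")
  Q <- A * cos(phase)
  P <- -sweep(A, 2, vib$omega, "*") * sin(phase)
  scale <- rep(1, n)
  if (rescale && temperature > 0) {
    fin <- .finalize_qp(vib, Q, P, rowSums(E))
    Q <- fin$Q; P <- fin$P; scale <- fin$scale
  }
  cart <- to_cartesian(vib, Q, P)
  .new_ensemble(vib, Q, P, cart$x, cart$p,
                E_modes = E, phase = phase, W = NULL,
                method = "nms", temperature = temperature, seed = seed,
                scheme = NULL, scale = scale)
}

#' Wigner-distribution sampling of initial conditions
#'
#' Samples each mode's (Q, P) from the harmonic Wigner density
#' \deqn{W_i \propto \exp(-\alpha_i \omega_i Q_i^2/\hbar)\,
#'       \exp(-\alpha_i P_i^2/(\hbar\omega_i)),}
#' with \eqn{\alpha_i(T) = \tanh(\hbar\omega_i / 2 k_B T)} supplying the
#' thermal dependence (\eqn{\alpha = 1} in the ground state, i.e. T = 0).
#' Scheme \code{"reject"} draws (Q, P) uniformly on \eqn{\pm 5\sigma} boxes
#' and accepts when \eqn{W/W_{max}} exceeds a uniform cutoff; scheme
#' \code{"direct"} draws from the equivalent Gaussians.  Samples are
#' transformed to Cartesian coordinates and the center-of-mass momentum is
#' removed; no energy rescaling is applied (it would destroy the quantum
#' distribution).
#'
#' @inheritParams sample_nms
#' @param scheme \code{"reject"} or \code{"direct"}.
#' @return an \code{ic_ensemble}; method tag \code{"wigner0"} at T = 0,
#'   else \code{"wignerT"}.
#' @export
sample_wigner <- function(modes, temperature, n, scheme = c("reject", "direct"),
                          seed = NULL) {
  scheme <- match.arg(scheme)
  if (temperature < 0) stop(vib_error("negative_temperature", "temperature must be >= 0"))
  if (!is.null(seed)) set.seed(seed)
  vib <- vibrational_modes(modes)
  k <- n_modes(vib)
  if (k < 1L) stop(vib_error("no_modes", "mode set has no vibrational modes"))
  alpha <- thermal_alpha(vib$omega, temperature)
  Q <- matrix(0, n, k); P <- matrix(0, n, k); W <- matrix(0, n, k)
  for (j in seq_len(k)) {
    w <- vib$omega[j]; a <- alpha[j]
    sigQ <- sqrt(1 / (2 * a * w))
    sigP <- sqrt(w / (2 * a))
    if (scheme == "direct") {
      Q[, j] <- stats::rnorm(n, 0, sigQ)
      P[, j] <- stats::rnorm(n, 0, sigP)
    } else {
      got <- 0L
      while (got < n) {
        m <- max(1000L, ceiling((n - got) / 0.05))
        q <- stats::runif(m, -5 * sigQ, 5 * sigQ)
        p <- stats::runif(m, -5 * sigP, 5 * sigP)
        w_rel <- exp(-a * (w * q^2 + p^2 / w))   # W / W_max, W_max at (0,0)
        acc <- w_rel > stats::runif(m)
        take <- min(n - got, sum(acc))
        if (take > 0L) {
          idx <- which(acc)[seq_len(take)]
          Q[(got + 1L):(got + take), j] <- q[idx]
          P[(got + 1L):(got + take), j] <- p[idx]
          got <- got + take
        }
      }
    }
    W[, j] <- exp(-alpha[j] * (w * Q[, j]^2 + P[, j]^2 / w))
  }
  cart <- to_cartesian(vib, Q, P)
  E <- .mode_energies(vib, Q, P)
  .new_ensemble(vib, Q, P, cart$x, cart$p,
                E_modes = E, phase = NULL, W = W,
                method = if (temperature == 0) "wigner0" else "wignerT",
                temperature = temperature, seed = seed, scheme = scheme,
                scale = rep(1, n))
}

#' Thermal Wigner sharpening factor
#'
#' \eqn{\alpha_i(T) = \tanh(\hbar\omega_i / 2 k_B T)}; in (0, 1], and
#' \eqn{\alpha \to 1} as \eqn{T \to 0}.
#'
#' @param omega mode frequencies (a.u.).
#' @param temperature kelvin.
#' @return numeric vector of the same length as \code{omega}.
#' @export
thermal_alpha <- function(omega, temperature) {
  if (temperature <= 0) return(rep(1, length(omega)))
  tanh(omega / (2 * au_constants$kB * temperature))
}

#' Transform between normal-mode and Cartesian phase space
#'
#' Displacements \eqn{x - x_{eq} = M^{-1/2} L Q} and momenta
#' \eqn{p = M^{1/2} L P}.  \code{from_cartesian} is the exact inverse
#' (projection onto the vibrational subspace).
#'
#' @param modes a \code{\link{compute_modes}} result.
#' @param Q,P normal-mode coordinates/momenta: vectors of length n_modes
#'   or n x n_modes matrices.
#' @return \code{to_cartesian}: list with \code{x} (positions, bohr) and
#'   \code{p} (momenta, a.u.), matching the input shape (rows = samples).
#' @export
to_cartesian <- function(modes, Q, P) {
  k <- n_modes(modes)
  Q <- .as_row_matrix(Q, k, "Q"); P <- .as_row_matrix(P, k, "P")
  m3 <- rep(modes$molecule$masses, each = 3L)
  Tx <- modes$L / sqrt(m3)       # columns: Cartesian displacement per unit Q
  Tp <- modes$L * sqrt(m3)
  x0 <- as.vector(t(modes$molecule$coords))
  x <- sweep(Q %*% t(Tx), 2, x0, "+")
  p <- P %*% t(Tp)
  list(x = drop_if_vector(x, Q), p = drop_if_vector(p, P))
}

#' @rdname to_cartesian
#' @param x,p Cartesian positions (bohr) and momenta (a.u.): vectors of
#'   length 3N or n x 3N matrices.
#' @return \code{from_cartesian}: list with \code{Q}, \code{P}.
#' @export
from_cartesian <- function(modes, x, p) {
  d3 <- nrow(modes$L)
  x <- .as_row_matrix(x, d3, "x"); p <- .as_row_matrix(p, d3, "p")
  m3 <- rep(modes$molecule$masses, each = 3L)
  x0 <- as.vector(t(modes$molecule$coords))
  dx <- sweep(x, 2, x0)
  Q <- sweep(dx, 2, sqrt(m3), "*") %*% modes$L
  P <- sweep(p, 2, sqrt(m3), "/") %*% modes$L
  list(Q = drop_if_vector(Q, x), P = drop_if_vector(P, p))
}

#' Center-of-mass cleanup and total-energy rescaling
#'
#' Subtracts the center-of-mass momentum (optionally also the rigid-body
#' angular momentum), projects the cleaned phase-space point back onto the
#' vibrational modes, and scales positions and momenta by one common factor
#' \eqn{s = \sqrt{E_{target}/E_{current}}} so the total harmonic energy
#' \eqn{\sum_i (P_i^2 + \omega_i^2 Q_i^2)/2} matches the target.
#'
#' @param modes a \code{\link{compute_modes}} result.
#' @param x,p Cartesian positions/momenta (vector or matrix, rows = samples).
#' @param target_energy per-sample target total energy (E_h); \code{NULL}
#'   skips rescaling (cleanup only).
#' @param zero_rotation also remove rigid-body angular momentum
#'   (default FALSE: only center-of-mass translation is removed).
#' @return list with cleaned/rescaled \code{x}, \code{p}, \code{Q},
#'   \code{P} and the applied \code{scale} factor(s).
#' @export
finalize_sample <- function(modes, x, p, target_energy = NULL,
                            zero_rotation = FALSE) {
  d3 <- nrow(modes$L)
  was_matrix <- is.matrix(x)
  xm <- .as_row_matrix(x, d3, "x"); pm <- .as_row_matrix(p, d3, "p")
  mol <- modes$molecule
  m <- mol$masses
  mtot <- sum(m)
  n <- nrow(pm)
  for (ax in 1:3) {
    cols <- seq(ax, d3, by = 3L)
    pcom <- rowSums(pm[, cols, drop = FALSE]) / mtot     # COM velocity
    pm[, cols] <- pm[, cols, drop = FALSE] - outer(pcom, m)
  }
  if (zero_rotation) {
    for (i in seq_len(n)) pm[i, ] <- .remove_angular_momentum(mol, xm[i, ], pm[i, ])
  }
  qp <- from_cartesian(modes, xm, pm)
  Q <- .as_row_matrix(qp$Q, n_modes(modes), "Q")
  P <- .as_row_matrix(qp$P, n_modes(modes), "P")
  scale <- rep(1, n)
  if (!is.null(target_energy)) {
    fin <- .finalize_qp(modes, Q, P, rep_len(target_energy, n))
    Q <- fin$Q; P <- fin$P; scale <- fin$scale
  }
  cart <- to_cartesian(modes, Q, P)
  dv <- function(mat) if (was_matrix || nrow(xm) > 1L) mat else drop(mat)
  list(x = dv(.as_row_matrix(cart$x, d3, "x")), p = dv(.as_row_matrix(cart$p, d3, "p")),
       Q = dv(Q), P = dv(P), scale = scale)
}

# common-factor rescale in mode space (rows = samples)
.finalize_qp <- function(modes, Q, P, target) {
  E_cur <- rowSums(.mode_energies(modes, Q, P))
  if (any(E_cur == 0 & target > 0)) {
    stop(vib_error("zero_energy", "cannot rescale a zero-energy sample to a finite target"))
  }
  scale <- ifelse(E_cur > 0, sqrt(target / E_cur), 1)
  list(Q = Q * scale, P = P * scale, scale = scale)
}

.mode_energies <- function(modes, Q, P) {
  Q <- .as_row_matrix(Q, n_modes(modes), "Q")
  P <- .as_row_matrix(P, n_modes(modes), "P")
  (P^2 + sweep(Q, 2, modes$omega, "*")^2) / 2
}

#' Per-mode harmonic energies of an ensemble
#'
#' \eqn{E_i = (P_i^2 + \omega_i^2 Q_i^2)/2} for every sample and mode.
#'
#' @param ens an \code{ic_ensemble}.
#' @return n x n_modes matrix (E_h).
#' @export
mode_energies <- function(ens) .mode_energies(ens$modes, ens$Q, ens$P)

.remove_angular_momentum <- function(mol, x, p) {
  n <- length(mol$masses)
  xm <- matrix(x, n, 3, byrow = TRUE)
  pm <- matrix(p, n, 3, byrow = TRUE)
  m <- mol$masses
  com <- colSums(xm * m) / sum(m)
  r <- sweep(xm, 2, com)
  Lang <- colSums(cbind(r[, 2] * pm[, 3] - r[, 3] * pm[, 2],
                        r[, 3] * pm[, 1] - r[, 1] * pm[, 3],
                        r[, 1] * pm[, 2] - r[, 2] * pm[, 1]))
  r2 <- rowSums(r^2)
  I <- diag(sum(m * r2), 3) - t(r * m) %*% r
  wrot <- tryCatch(solve(I, Lang), error = function(e) rep(0, 3))
  vrot <- cbind(wrot[2] * r[, 3] - wrot[3] * r[, 2],
                wrot[3] * r[, 1] - wrot[1] * r[, 3],
                wrot[1] * r[, 2] - wrot[2] * r[, 1])
  as.vector(t(pm - vrot * m))
}

.new_ensemble <- function(modes, Q, P, x, p, E_modes, phase, W, method,
                          temperature, seed, scheme, scale) {
  n <- nrow(.as_row_matrix(Q, n_modes(modes), "Q"))
  structure(list(
    modes = modes,
    Q = .as_row_matrix(Q, n_modes(modes), "Q"),
    P = .as_row_matrix(P, n_modes(modes), "P"),
    x = .as_row_matrix(x, nrow(modes$L), "x"),
    p = .as_row_matrix(p, nrow(modes$L), "p"),
    E_modes = E_modes, phase = phase, W = W,
    method = method, temperature = temperature,
    seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
    scheme = if (is.null(scheme)) NA_character_ else scheme,
    scale = scale, n = n
  ), class = "ic_ensemble")
}

#' @export
print.ic_ensemble <- function(x, ...) {
  cat(sprintf("<ic_ensemble> %d samples, method %s, T = %g K, %d mode(s)\n",
              x$n, x$method, x$temperature, ncol(x$Q)))
  invisible(x)
}

.as_row_matrix <- function(v, width, what) {
  if (is.matrix(v)) {
    if (ncol(v) != width) {
      stop(vib_error("dimension_mismatch",
        sprintf("%s has %d columns, expected %d", what, ncol(v), width)))
    }
    return(v)
  }
  if (length(v) != width) {
    stop(vib_error("dimension_mismatch",
      sprintf("%s has length %d, expected %d", what, length(v), width)))
  }
  matrix(v, 1L, width)
}

drop_if_vector <- function(mat, template) {
  if (is.matrix(template) && nrow(template) > 1L) mat else drop(mat)
}
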