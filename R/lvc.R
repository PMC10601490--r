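# Linear vibronic coupling (LVC) models.  The diabatic Hamiltonian in
# dimensionless mass-frequency-scaled coordinates Q_a:
#   V_ii(Q) = eps_i + sum_a kappa_{i,a} Q_a + sum_a (omega_a/2) Q_a^2
#   V_ij(Q) = eta_ij + sum_a lambda_{ij,a} Q_a          (i != j)
# with constant (transition) dipoles.  The conjugate kinetic energy is
# sum_a (omega_a/2) P_a^2, so a mass-weighted normal-mode point (q, p)
# maps to Q = sqrt(omega) q, P = p / sqrt(omega).

#' Construct a linear vibronic coupling model
#'
#' @param omega mode frequencies (a.u.), length n_modes.
#' @param epsilon vertical shifts per state (E_h), length n_states.
#' @param kappa n_states x n_modes intrastate gradients (E_h per unit
#'   dimensionless coordinate); default zero.
#' @param lambda n_states x n_states x n_modes array of linear interstate
#'   couplings, symmetric in (i, j) with zero diagonal; default zero.
#' @param eta n_states x n_states constant couplings (E_h, e.g.
#'   spin-orbit-like), symmetric; default zero.
#' @param dipoles n_states x n_states x 3 array of constant state and
#'   transition dipole components (a.u.); default zero.
#' @return an object of class \code{"lvc_model"}.
#' @export
lvc_model <- function(omega, epsilon, kappa = NULL, lambda = NULL,
                      eta = NULL, dipoles = NULL) {
  nm <- length(omega); ns <- length(epsilon)
  if (nm < 1L || ns < 1L) stop(vib_error("lvc_shape", "need >= 1 mode and state"))
  if (is.null(kappa)) kappa <- matrix(0, ns, nm)
  kappa <- matrix(kappa, ns, nm)
  if (is.null(lambda)) lambda <- array(0, c(ns, ns, nm))
  if (is.null(eta)) eta <- matrix(0, ns, ns)
  if (is.null(dipoles)) dipoles <- array(0, c(ns, ns, 3))
  stopifnot(all(dim(lambda) == c(ns, ns, nm)), all(dim(eta) == c(ns, ns)),
            all(dim(dipoles) == c(ns, ns, 3)))
  for (a in seq_len(nm)) {
    la <- lambda[, , a]
    if (max(abs(la - t(la))) > 0 || any(diag(matrix(la, ns, ns)) != 0)) {
      stop(vib_error("lvc_lambda", "lambda must be (i,j)-symmetric with zero diagonal"))
    }
  }
  if (max(abs(eta - t(eta))) > 0) stop(vib_error("lvc_eta", "eta must be symmetric"))
  if (!all(is.finite(c(omega, epsilon, kappa, lambda, eta, dipoles)))) {
    stop(vib_error("lvc_finite", "all model arrays must be finite"))
  }
  structure(list(omega = as.numeric(omega), epsilon = as.numeric(epsilon),
                 kappa = kappa, lambda = lambda, eta = eta, dipoles = dipoles,
                 n_states = ns, n_modes = nm),
            class = "lvc_model")
}

#' @export
print.lvc_model <- function(x, ...) {
  cat(sprintf("<lvc_model> %d state(s), %d mode(s)\n", x$n_states, x$n_modes))
  cat(sprintf("  omega (cm-1): %s\n",
              paste(sprintf("%.1f", x$omega / au_constants$cm1_to_hartree),
                    collapse = " ")))
  invisible(x)
}

#' Diabatic LVC Hamiltonian at a nuclear configuration
#'
#' @param model an \code{\link{lvc_model}}.
#' @param Q dimensionless coordinates, length n_modes.
#' @return n_states x n_states real symmetric matrix (E_h).
#' @export
diabatic_hamiltonian <- function(model, Q) {
  if (length(Q) != model$n_modes) {
    stop(vib_error("dimension_mismatch", "Q length must equal the mode count"))
  }
  ns <- model$n_states
  base <- sum(model$omega / 2 * Q^2)
  V <- model$eta + matrix(0, ns, ns)
  for (a in seq_len(model$n_modes)) V <- V + model$lambda[, , a] * Q[a]
  diag(V) <- model$epsilon + as.vector(model$kappa %*% Q) + base
  V
}

# dV/dQ_a as an ns x ns matrix
diabatic_gradient <- function(model, Q, a) {
  G <- model$lambda[, , a] + 0
  diag(G) <- model$kappa[, a] + model$omega[a] * Q[a]
  matrix(G, model$n_states, model$n_states)
}

#' Adiabatic energies, gradients, couplings and dipoles at a point
#'
#' Diagonalizes the diabatic Hamiltonian (ascending energies, deterministic
#' eigenvector signs), and applies Hellmann-Feynman:
#' \eqn{\partial E_a/\partial Q_\alpha = [U^T (\partial V/\partial
#' Q_\alpha) U]_{aa}}, couplings \eqn{d_{ab,\alpha} = [U^T \partial V/
#' \partial Q_\alpha U]_{ab} / (E_b - E_a)}, adiabatic dipoles
#' \eqn{U^T \mu U}, and oscillator strengths \eqn{f_{0a} = (2/3) \Delta E
#' |\mu_{0a}|^2}.  Energy gaps below \code{deg_floor} have their couplings
#' capped (denominator floored) and flagged rather than raising mid-run.
#'
#' @param model an \code{\link{lvc_model}}.
#' @param Q dimensionless coordinates.
#' @param deg_floor degeneracy floor for coupling denominators (E_h).
#' @return list with \code{Q}, \code{E} (ascending), \code{U} (columns:
#'   diabatic -> adiabatic), \code{grad} (n_states x n_modes),
#'   \code{nac} (n_states x n_states x n_modes, antisymmetric),
#'   \code{dip} (adiabatic dipoles, n_states x n_states x 3),
#'   \code{f} (oscillator strengths from the lowest state),
#'   \code{degenerate} (logical).
#' @export
evaluate_adiabatic <- function(model, Q, deg_floor = 1e-10) {
  V <- diabatic_hamiltonian(model, Q)
  ns <- model$n_states; nm <- model$n_modes
  es <- eigen(V, symmetric = TRUE)
  ord <- rev(seq_len(ns))                # eigen() returns descending
  E <- es$values[ord]
  U <- fix_eigvec_signs(es$vectors[, ord, drop = FALSE])
  grad <- matrix(0, ns, nm)
  nac <- array(0, c(ns, ns, nm))
  degenerate <- FALSE
  gap <- outer(E, E, function(a, b) b - a)     # gap[a,b] = E_b - E_a
  small <- abs(gap) < deg_floor
  denom <- ifelse(small, sign(gap) * deg_floor + (gap == 0) * deg_floor, gap)
  for (a in seq_len(nm)) {
    W <- crossprod(U, diabatic_gradient(model, Q, a) %*% U)
    grad[, a] <- diag(W)
    D <- W / denom
    diag(D) <- 0
    if (any(small & upper.tri(small) & abs(W) > 0)) degenerate <- TRUE
    nac[, , a] <- (D - t(D)) / 2     # exact antisymmetry (W is symmetric)
  }
  if (degenerate) {
    vib_warn("degenerate_point",
             "near-degenerate adiabatic states: couplings capped at the degeneracy floor")
  }
  dip <- array(0, c(ns, ns, 3))
  for (cc in 1:3) dip[, , cc] <- crossprod(U, model$dipoles[, , cc] %*% U)
  dE <- E - E[1]
  f <- (2 / 3) * dE * (dip[1, , 1]^2 + dip[1, , 2]^2 + dip[1, , 3]^2)
  f[1] <- 0
  list(Q = Q, E = E, U = U, grad = grad, nac = nac, dip = dip, f = f,
       degenerate = degenerate)
}

#' Overlap between consecutive eigenvector frames, with phase tracking
#'
#' \eqn{S = U_{prev}^T U_{curr}}.  When a diagonal overlap magnitude drops
#' below \eqn{1/\sqrt 2}, states are re-ordered by maximal-overlap
#' assignment (trivially-avoided-crossing tracking); afterwards per-column
#' sign flips are applied to the current frame so every diagonal entry of
#' S is non-negative.  The corrected frame is returned so callers can
#' propagate the fixed global phase.
#'
#' @param U_prev,U_curr eigenvector matrices (columns = states).
#' @param dt time step between the frames (a.u.), stored on the result.
#' @return list with \code{S} (corrected overlap), \code{U} (corrected
#'   current frame), \code{signs}, \code{perm}, \code{dt}.
#' @export
frame_overlap <- function(U_prev, U_curr, dt = NA_real_) {
  if (!all(dim(U_prev) == dim(U_curr))) {
    stop(vib_error("dimension_mismatch", "frames must have matching dimensions"))
  }
  S <- crossprod(U_prev, U_curr)
  ns <- ncol(S)
  perm <- seq_len(ns)
  if (any(abs(diag(S)) < 1 / sqrt(2))) {
    A <- abs(S)
    perm <- rep(NA_integer_, ns)
    for (step in seq_len(ns)) {             # greedy maximal-overlap assignment
      idx <- which(A == max(A), arr.ind = TRUE)[1, ]
      perm[idx[1]] <- idx[2]
      A[idx[1], ] <- -1; A[, idx[2]] <- -1
    }
    S <- S[, perm, drop = FALSE]
    U_curr <- U_curr[, perm, drop = FALSE]
  }
  signs <- ifelse(diag(S) < 0, -1, 1)
  S <- sweep(S, 2, signs, "*")
  U_curr <- sweep(U_curr, 2, signs, "*")
  list(S = S, U = U_curr, signs = signs, perm = perm, dt = dt)
}

#' Parameterize an LVC model from reference-point electronic data
#'
#' One reference geometry supplies state energies, Cartesian gradients,
#' and interstate coupling data; everything is projected onto the
#' dimensionless normal-mode coordinates through \eqn{M^{-1/2} L} and the
#' \eqn{\omega^{-1/2}} scaling.  Vertical shifts are \eqn{\epsilon_i = E_i
#' - E_0}; \eqn{\kappa_{i,\alpha}} is the state gradient projected on mode
#' \eqn{\alpha}; \eqn{\lambda_{ij,\alpha}} is the energy gap times the
#' projected nonadiabatic coupling vector (or the projected raw
#' coupling-gradient vector, which stays finite near degeneracies).
#'
#' @param modes a \code{\link{compute_modes}} result.
#' @param energies reference state energies (E_h), length n_states.
#' @param gradients 3N x n_states matrix of Cartesian state gradients
#'   (E_h/bohr).
#' @param nac optional n_states x n_states x 3N array of nonadiabatic
#'   coupling vectors (1/bohr), antisymmetric in (i, j).
#' @param coupling_gradients optional n_states x n_states x 3N array of
#'   raw interstate coupling gradients (E_h/bohr), used directly as the
#'   linear coupling; mutually exclusive alternative to \code{nac}.
#' @param eta,dipoles passed through to \code{\link{lvc_model}}.
#' @param degeneracy_tol gap below which NAC-based extraction refuses to
#'   divide (E_h).
#' @return an \code{\link{lvc_model}}.
#' @export
build_lvc <- function(modes, energies, gradients, nac = NULL,
                      coupling_gradients = NULL, eta = NULL, dipoles = NULL,
                      degeneracy_tol = 1e-8) {
  ns <- length(energies)
  nm <- n_modes(modes)
  d3 <- nrow(modes$L)
  gradients <- matrix(gradients, d3, ns)
  m3 <- rep(modes$molecule$masses, each = 3L)
  # projection of a Cartesian derivative vector onto dimensionless modes:
  # dE/dQ_a = g . dx/dQ_a = (L_a^T M^{-1/2} g) / sqrt(omega_a)
  proj <- function(v) as.vector(crossprod(modes$L, v / sqrt(m3))) / sqrt(modes$omega)
  kappa <- t(apply(gradients, 2, proj))          # ns x nm
  kappa <- matrix(kappa, ns, nm)
  lambda <- array(0, c(ns, ns, nm))
  if (!is.null(nac) && !is.null(coupling_gradients)) {
    stop(vib_error("lvc_input", "give either nac or coupling_gradients, not both"))
  }
  if (!is.null(nac)) {
    stopifnot(all(dim(nac) == c(ns, ns, d3)))
    for (i in seq_len(ns)) for (j in seq_len(ns)) if (i < j) {
      v <- nac[i, j, ]
      if (all(v == 0)) next
      gap <- energies[j] - energies[i]
      if (abs(gap) < degeneracy_tol) {
        stop(vib_error("lvc_degenerate_reference",
          sprintf(paste("states %d and %d are degenerate at the reference;",
                        "NAC-based extraction diverges - supply coupling_gradients"),
                  i, j)))
      }
      lam <- gap * proj(v)
      lambda[i, j, ] <- lam
      lambda[j, i, ] <- lam
    }
  }
  if (!is.null(coupling_gradients)) {
    stopifnot(all(dim(coupling_gradients) == c(ns, ns, d3)))
    for (i in seq_len(ns)) for (j in seq_len(ns)) if (i < j) {
      lam <- proj(coupling_gradients[i, j, ])
      lambda[i, j, ] <- lam
      lambda[j, i, ] <- lam
    }
  }
  lvc_model(omega = modes$omega, epsilon = energies - energies[1],
            kappa = kappa, lambda = lambda, eta = eta, dipoles = dipoles)
}

#' Map an ensemble's mass-weighted phase space to model coordinates
#'
#' \eqn{Q_\alpha = \sqrt{\omega_\alpha}\, q_\alpha}, \eqn{P_\alpha =
#' p_\alpha / \sqrt{\omega_\alpha}} (dimensionless coordinates and
#' conjugate momenta of the LVC Hamiltonian).
#'
#' @param ens an \code{ic_ensemble}.
#' @return list with matrices \code{Q}, \code{P} (n x n_modes).
#' @export
model_coordinates <- function(ens) {
  sw <- sqrt(ens$modes$omega)
  list(Q = sweep(ens$Q, 2, sw, "*"), P = sweep(ens$P, 2, sw, "/"))
}

#' Read / write the LVC model text format
#'
#' Plain-text exchange format: a header with state and mode counts, then
#' blocks \code{OMEGA}, \code{EPSILON}, \code{KAPPA} (one row per state),
#' \code{LAMBDA} and \code{DIPOLES} (one line per (i, j) pair), and
#' \code{ETA} (full matrix).  All values in Hartree atomic units; lines
#' starting with \code{#} are comments.
#'
#' @param model an \code{\link{lvc_model}}.
#' @param path file path.
#' @export
write_lvc <- function(model, path) {
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  num <- function(v) paste(sprintf("%22.15e", v), collapse = " ")
  w("# LVC model (atomic units)")
  w("NSTATES %d", model$n_states)
  w("NMODES %d", model$n_modes)
  w("OMEGA"); w("%s", num(model$omega))
  w("EPSILON"); w("%s", num(model$epsilon))
  w("KAPPA")
  for (i in seq_len(model$n_states)) w("%s", num(model$kappa[i, ]))
  w("LAMBDA")
  for (i in seq_len(model$n_states)) for (j in seq_len(model$n_states)) {
    if (i < j && any(model$lambda[i, j, ] != 0)) {
      w("%d %d %s", i, j, num(model$lambda[i, j, ]))
    }
  }
  w("ETA")
  for (i in seq_len(model$n_states)) w("%s", num(model$eta[i, ]))
  w("DIPOLES")
  for (i in seq_len(model$n_states)) for (j in seq_len(model$n_states)) {
    if (i <= j && any(model$dipoles[i, j, ] != 0)) {
      w("%d %d %s", i, j, num(model$dipoles[i, j, ]))
    }
  }
  w("END")
  invisible(path)
}

#' @rdname write_lvc
#' @export
read_lvc <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  get_int <- function(key) {
    hit <- grep(paste0("^", key, "\\b"), lines)
    if (!length(hit)) stop(vib_error("lvc_format", sprintf("missing %s header", key)))
    as.integer(strsplit(lines[hit[1]], "\\s+")[[1]][2])
  }
  ns <- get_int("NSTATES"); nm <- get_int("NMODES")
  block <- function(key) {
    hit <- grep(paste0("^", key, "$"), lines)
    if (!length(hit)) stop(vib_error("lvc_format", sprintf("missing %s block", key)))
    start <- hit[1] + 1L
    keys <- grep("^[A-Z]+$|^NSTATES|^NMODES|^END$", lines)
    nxt <- keys[keys >= start]
    end <- if (length(nxt)) nxt[1] - 1L else length(lines)
    if (end < start) return(character(0))
    lines[start:end]
  }
  nums <- function(l) as.numeric(strsplit(l, "\\s+")[[1]])
  omega <- nums(block("OMEGA")[1])
  epsilon <- nums(block("EPSILON")[1])
  kap <- do.call(rbind, lapply(block("KAPPA")[seq_len(ns)], nums))
  lambda <- array(0, c(ns, ns, nm))
  for (l in block("LAMBDA")) {
    v <- nums(l)
    i <- as.integer(v[1]); j <- as.integer(v[2])
    lambda[i, j, ] <- v[-(1:2)]; lambda[j, i, ] <- v[-(1:2)]
  }
  eta <- do.call(rbind, lapply(block("ETA")[seq_len(ns)], nums))
  dipoles <- array(0, c(ns, ns, 3))
  for (l in block("DIPOLES")) {
    v <- nums(l)
    i <- as.integer(v[1]); j <- as.integer(v[2])
    dipoles[i, j, ] <- v[3:5]; dipoles[j, i, ] <- v[3:5]
  }
  lvc_model(omega, epsilon, kappa = kap, lambda = lambda, eta = eta,
            dipoles = dipoles)
}
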