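# Normal-mode analysis: mass weighting, projection of translations and
# rotations, and the validated mode set used by all sampling and model
# building.

#' Mass-weight a Cartesian Hessian
#'
#' \eqn{\tilde H = M^{-1/2} H M^{-1/2}} with the diagonal mass matrix in
#' electron masses.  The input must be symmetric within tolerance.
#'
#' @param hessian 3N x 3N symmetric matrix (E_h/bohr^2).
#' @param masses per-atom masses in electron masses (length N).
#' @param tol asymmetry tolerance relative to the largest element.
#' @return mass-weighted Hessian (symmetric, atomic units).
#' @export
mass_weight <- function(hessian, masses, tol = 1e-8) {
  hessian <- as.matrix(hessian)
  if (nrow(hessian) != ncol(hessian) || nrow(hessian) != 3L * length(masses)) {
    stop(vib_error("hessian_shape", "Hessian must be 3N x 3N for N masses"))
  }
  if (any(masses <= 0)) stop(vib_error("bad_masses", "masses must be positive"))
  if (max(abs(hessian - t(hessian))) > tol * max(1, max(abs(hessian)))) {
    stop(vib_error("hessian_asymmetric", "Hessian not symmetric within tolerance"))
  }
  invsqrtm <- rep(1 / sqrt(masses), each = 3L)
  mw <- hessian * outer(invsqrtm, invsqrtm)
  (mw + t(mw)) / 2
}

# Orthonormal basis of the external (translation + rotation) subspace in
# mass-weighted coordinates.  3 translations always; 3 rotations (2 for
# linear molecules, 0 for a single atom), detected by dropping generators
# whose norm after Gram-Schmidt is negligible.
external_mode_basis <- function(mol) {
  n <- n_atoms(mol)
  m <- mol$masses
  sqm <- sqrt(m)
  com <- colSums(mol$coords * m) / sum(m)
  r <- sweep(mol$coords, 2, com)
  gens <- matrix(0, 3 * n, 6)
  for (k in 1:3) gens[seq(k, 3 * n, by = 3), k] <- sqm       # translations
  # rotations: sqrt(m_a) * (e_k x r_a)
  ex <- cbind(rep(0, n), -r[, 3], r[, 2])
  ey <- cbind(r[, 3], rep(0, n), -r[, 1])
  ez <- cbind(-r[, 2], r[, 1], rep(0, n))
  gens[, 4] <- as.vector(t(ex * sqm))
  gens[, 5] <- as.vector(t(ey * sqm))
  gens[, 6] <- as.vector(t(ez * sqm))
  # Gram-Schmidt, dropping null generators (linear molecule, single atom)
  basis <- NULL
  for (j in 1:6) {
    v <- gens[, j]
    if (!is.null(basis)) v <- v - basis %*% crossprod(basis, v)
    nv <- sqrt(sum(v^2))
    if (nv > 1e-8 * sqrt(sum(gens[, j]^2) + 1)) {
      basis <- cbind(basis, v / nv)
    }
  }
  if (is.null(basis)) basis <- matrix(0, 3 * n, 0)
  basis
}

#' Project translations and rotations out of a mass-weighted Hessian
#'
#' Builds the 6 (5 for linear molecules, 3 for a free atom) external
#' generator vectors explicitly, orthonormalizes them, and applies the
#' orthogonal-complement projector \eqn{P = I - BB^T} from both sides.
#'
#' @param mw_hessian mass-weighted Hessian from \code{\link{mass_weight}}.
#' @param mol the \code{\link{molecule}} providing geometry and masses.
#' @return list with \code{hessian} (projected, symmetric) and
#'   \code{n_external} (number of projected generators).
#' @export
project_external <- function(mw_hessian, mol) {
  B <- external_mode_basis(mol)
  P <- diag(nrow(mw_hessian)) - tcrossprod(B)
  H <- P %*% mw_hessian %*% P
  list(hessian = (H + t(H)) / 2, n_external = ncol(B))
}

#' Compute normal modes from a Cartesian Hessian
#'
#' Mass-weights the Hessian, projects out center-of-mass translation and
#' rigid rotation, diagonalizes, and returns the vibrational mode set.
#' Eigenvalues \eqn{\lambda_i} give \eqn{\omega_i = \sqrt{\lambda_i}};
#' negative eigenvalues are flagged imaginary with \eqn{|\omega|} stored.
#' Near-zero modes left over from the projection (|omega| below
#' \code{threshold_cm}) are discarded.  Modes are sorted ascending by
#' eigenvalue (imaginary first), and each eigenvector's sign is fixed so
#' its largest-magnitude component is positive (first index on ties).
#'
#' @param hessian 3N x 3N Cartesian Hessian (E_h/bohr^2).
#' @param mol the reference \code{\link{molecule}}.
#' @param project project external modes first (default TRUE).
#' @param threshold_cm discard threshold for residual external modes, cm^-1.
#' @return object of class \code{"normal_modes"}: \code{molecule},
#'   \code{omega} (|omega|, a.u.), \code{freq_cm} (cm^-1 view),
#'   \code{L} (3N x n_vib orthonormal mass-weighted eigenvectors),
#'   \code{imaginary} (logical), \code{n_external}.
#' @export
compute_modes <- function(hessian, mol, project = TRUE, threshold_cm = 10) {
  mw <- mass_weight(hessian, mol$masses)
  n_ext <- 0L
  if (project) {
    pr <- project_external(mw, mol)
    mw <- pr$hessian
    n_ext <- pr$n_external
  }
  if (max(abs(mw)) == 0) {
    vib_warn("zero_hessian", "all-zero Hessian: no vibrational modes")
    return(structure(list(
      molecule = mol, omega = numeric(0), freq_cm = numeric(0),
      L = matrix(0, nrow(mw), 0), imaginary = logical(0),
      n_external = n_ext
    ), class = "normal_modes"))
  }
  es <- eigen(mw, symmetric = TRUE)
  ev <- rev(es$values)                       # ascending
  V <- es$vectors[, rev(seq_along(es$values)), drop = FALSE]
  thr <- (threshold_cm * au_constants$cm1_to_hartree)^2
  keep <- abs(ev) >= thr
  ev <- ev[keep]
  V <- V[, keep, drop = FALSE]
  omega <- sqrt(abs(ev))
  imaginary <- ev < 0
  if (any(imaginary)) {
    vib_warn("imaginary_modes",
             sprintf("%d imaginary mode(s) present; they will not be sampled",
                     sum(imaginary)))
  }
  V <- fix_eigvec_signs(V)
  structure(list(
    molecule = mol,
    omega = omega,
    freq_cm = sign(ev) * omega / au_constants$cm1_to_hartree,
    L = V,
    imaginary = imaginary,
    n_external = n_ext
  ), class = "normal_modes")
}

# deterministic sign convention: largest-|component| entry positive,
# ties resolved to the first index (which.max semantics)
fix_eigvec_signs <- function(V) {
  if (ncol(V) == 0L) return(V)
  for (j in seq_len(ncol(V))) {
    i <- which.max(abs(V[, j]))
    if (V[i, j] < 0) V[, j] <- -V[, j]
  }
  V
}

#' @export
print.normal_modes <- function(x, ...) {
  cat(sprintf("<normal_modes> %d vibrational mode(s), %d external projected\n",
              length(x$omega), x$n_external))
  if (length(x$omega)) {
    tag <- ifelse(x$imaginary, "i", " ")
    cat(sprintf("  %8.1f%s cm-1\n", abs(x$freq_cm), tag), sep = "")
  }
  invisible(x)
}

# number of vibrational (sampleable) modes
n_modes <- function(modes) length(modes$omega)

# modes actually usable for sampling (real frequencies only)
vibrational_modes <- function(modes) {
  if (!any(modes$imaginary)) return(modes)
  keep <- !modes$imaginary
  modes$omega <- modes$omega[keep]
  modes$freq_cm <- modes$freq_cm[keep]
  modes$L <- modes$L[, keep, drop = FALSE]
  modes$imaginary <- modes$imaginary[keep]
  modes
}
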