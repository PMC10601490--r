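# Nuclear-ensemble-approach spectra, trajectory-resolved transient maps,
# photolysis-rate integration, and rate-equation population kinetics.

# Absolute oscillator-strength -> cross-section prefactor,
# C = e^2 h / (4 eps0 m_e c), expressed in cm^2 eV: a transition of unit
# oscillator strength has integrated cross section C over photon energy.
.sigma_prefactor_cm2_ev <- local({
  e <- 1.602176634e-19; h <- 6.62607015e-34
  eps0 <- 8.8541878128e-12; me <- 9.1093837015e-31; c <- 2.99792458e8
  (e^2 * h / (4 * eps0 * me * c)) / e * 1e4
})

#' Oscillator-strength-to-cross-section prefactor
#'
#' The standard constant \eqn{C = e^2 h / (4 \varepsilon_0 m_e c)}
#' converted to cm\eqn{^2} eV: a unit-oscillator-strength transition has
#' integrated absorption cross section C over photon energy.
#' @return numeric scalar (about 1.0977e-16 cm^2 eV).
#' @export
sigma_prefactor <- function() .sigma_prefactor_cm2_ev

#' Vertical transitions over a geometry ensemble
#'
#' For every sampled geometry, adiabatic excitation energies from the
#' lowest state and oscillator strengths \eqn{f = (2/3)\Delta E |\mu|^2}
#' via the LVC model.
#'
#' @param model an \code{\link{lvc_model}}.
#' @param samples an \code{ic_ensemble} (converted through
#'   \code{\link{model_coordinates}}) or an n x n_modes matrix of
#'   dimensionless coordinates.
#' @param n_states number of states to include (>= 2, <= model states).
#' @return data.frame of class \code{"transition_set"} with columns
#'   \code{geometry}, \code{state}, \code{dE} (E_h), \code{dE_ev},
#'   \code{f}; attribute \code{n_geom}.
#' @export
transitions_from_ensemble <- function(model, samples,
                                      n_states = model$n_states) {
  if (n_states > model$n_states) {
    stop(vib_error("bad_states",
      sprintf("requested %d states but the model has %d", n_states,
              model$n_states)))
  }
  Q <- if (inherits(samples, "ic_ensemble")) model_coordinates(samples)$Q
       else .as_row_matrix(samples, model$n_modes, "samples")
  n <- nrow(Q)
  nex <- n_states - 1L
  out <- data.frame(
    geometry = rep(seq_len(n), each = nex),
    state = rep(2:n_states, times = n),
    dE = numeric(n * nex), dE_ev = numeric(n * nex), f = numeric(n * nex)
  )
  row <- 1L
  for (i in seq_len(n)) {
    ev <- evaluate_adiabatic(model, Q[i, ])
    idx <- row:(row + nex - 1L)
    dE <- ev$E[2:n_states] - ev$E[1]
    out$dE[idx] <- dE
    out$dE_ev[idx] <- unit_convert(dE, "hartree", "ev")
    out$f[idx] <- ev$f[2:n_states]
    row <- row + nex
  }
  attr(out, "n_geom") <- n
  class(out) <- c("transition_set", class(out))
  out
}

.lineshape <- function(shape, E, center, fwhm) {
  if (shape == "gaussian") {
    sd <- fwhm / (2 * sqrt(2 * log(2)))
    stats::dnorm(E, center, sd)
  } else {
    hw <- fwhm / 2
    (hw / pi) / ((E - center)^2 + hw^2)
  }
}

#' Nuclear-ensemble-approach absorption spectrum
#'
#' Broadens every vertical transition with a unit-area Gaussian or
#' Lorentzian lineshape of empirical full width at half maximum
#' \eqn{\delta}, centered at \eqn{\Delta E} and weighted by its
#' oscillator strength; the spectrum is the geometry average scaled by the
#' absolute cross-section prefactor:
#' \deqn{\sigma(E) = \frac{C}{N} \sum_{geom} \sum_{states}
#'       f\, g_\delta(E - \Delta E).}
#'
#' @param transitions a \code{\link{transitions_from_ensemble}} result.
#' @param delta_ev full width at half maximum \eqn{\delta} (eV, > 0).
#' @param shape \code{"gaussian"} or \code{"lorentzian"}.
#' @param grid energy grid (eV); default
#'   \code{[min dE - 3 delta, max dE + 3 delta]} with \code{n_grid} points.
#' @param n_grid grid size for the default grid.
#' @param prefactor absolute scale C in cm^2 eV; defaults to
#'   \code{\link{sigma_prefactor}()}.
#' @return object of class \code{"ensemble_spectrum"}: \code{energy_ev},
#'   \code{sigma} (cm^2), \code{per_state} (columns = excited states),
#'   \code{n_geom}, \code{delta_ev}, \code{shape}, \code{prefactor}.
#' @export
nea_spectrum <- function(transitions, delta_ev, shape = c("gaussian", "lorentzian"),
                         grid = NULL, n_grid = 1000L, prefactor = NULL) {
  shape <- match.arg(shape)
  if (delta_ev <= 0) stop(vib_error("bad_width", "delta must be positive"))
  if (is.null(prefactor)) prefactor <- .sigma_prefactor_cm2_ev
  n_geom <- attr(transitions, "n_geom")
  if (is.null(n_geom)) n_geom <- length(unique(transitions$geometry))
  if (n_geom < 1L) stop(vib_error("empty_ensemble", "need at least one geometry"))
  if (is.null(grid)) {
    grid <- seq(min(transitions$dE_ev) - 3 * delta_ev,
                max(transitions$dE_ev) + 3 * delta_ev, length.out = n_grid)
  }
  states <- sort(unique(transitions$state))
  per_state <- matrix(0, length(grid), length(states),
                      dimnames = list(NULL, paste0("S", states - 1L)))
  for (si in seq_along(states)) {
    rows <- transitions[transitions$state == states[si], ]
    acc <- numeric(length(grid))
    for (r in seq_len(nrow(rows))) {
      if (rows$f[r] == 0) next
      acc <- acc + rows$f[r] * .lineshape(shape, grid, rows$dE_ev[r], delta_ev)
    }
    per_state[, si] <- prefactor * acc / n_geom
  }
  structure(list(energy_ev = grid, sigma = rowSums(per_state),
                 per_state = per_state, n_geom = n_geom,
                 delta_ev = delta_ev, shape = shape, prefactor = prefactor),
            class = "ensemble_spectrum")
}

#' @export
print.ensemble_spectrum <- function(x, ...) {
  cat(sprintf("<ensemble_spectrum> %d grid points, %d geometries, delta = %g eV (%s)\n",
              length(x$energy_ev), x$n_geom, x$delta_ev, x$shape))
  invisible(x)
}

#' Wavelength view of an ensemble spectrum
#'
#' Pointwise re-expression of the cross section on a wavelength axis,
#' \eqn{\lambda(nm) = 1239.841984 / E(eV)}; the cross-section value at a
#' given photon energy is axis-independent.
#'
#' @param spec an \code{\link{nea_spectrum}} result.
#' @return data.frame with \code{lambda_nm} (ascending) and \code{sigma}.
#' @export
spectrum_wavelength <- function(spec) {
  lam <- au_constants$nm_ev / spec$energy_ev
  ord <- order(lam)
  data.frame(lambda_nm = lam[ord], sigma = spec$sigma[ord])
}

#' Photolysis rate from cross section, quantum yield and actinic flux
#'
#' \deqn{J = \int \phi(\lambda)\,\sigma_{abs}(\lambda)\,F(\lambda)\,
#' d\lambda} by composite trapezoid on the merged grid of all inputs.
#' \eqn{\sigma} in cm\eqn{^2}, F in quanta s\eqn{^{-1}} cm\eqn{^{-2}}
#' nm\eqn{^{-1}}, wavelengths in nm, so J is in s\eqn{^{-1}}.
#'
#' @param sigma cross-section curve: a two-column data.frame
#'   (\code{lambda_nm}/\code{x}, value) or an \code{ensemble_spectrum}.
#' @param flux actinic-flux curve, same two-column form.
#' @param quantum_yield scalar in [0, 1] or a two-column curve.
#' @param window optional c(min, max) wavelength window (nm); defaults to
#'   the overlap of the curves' supports.
#' @return J in s^-1.
#' @export
photolysis_rate <- function(sigma, flux, quantum_yield = 1, window = NULL) {
  as_curve <- function(obj) {
    if (inherits(obj, "ensemble_spectrum")) obj <- spectrum_wavelength(obj)
    data.frame(x = obj[[1]], y = obj[[2]])
  }
  sg <- as_curve(sigma); fl <- as_curve(flux)
  lo <- max(min(sg$x), min(fl$x))
  hi <- min(max(sg$x), max(fl$x))
  qy_fun <- if (is.function(quantum_yield)) {
    quantum_yield
  } else if (is.data.frame(quantum_yield)) {
    qc <- as_curve(quantum_yield)
    lo <- max(lo, min(qc$x)); hi <- min(hi, max(qc$x))
    function(l) stats::approx(qc$x, qc$y, l, rule = 1)$y
  } else {
    if (quantum_yield < 0 || quantum_yield > 1) {
      stop(vib_error("bad_quantum_yield", "quantum yield must lie in [0, 1]"))
    }
    function(l) rep(quantum_yield, length(l))
  }
  if (!is.null(window)) {
    lo <- max(lo, window[1]); hi <- min(hi, window[2])
  }
  if (!(hi > lo)) {
    stop(vib_error("window_overlap", "wavelength windows do not overlap"))
  }
  grid <- sort(unique(c(lo, hi, sg$x[sg$x > lo & sg$x < hi],
                        fl$x[fl$x > lo & fl$x < hi])))
  s <- stats::approx(sg$x, sg$y, grid, rule = 2)$y
  fv <- stats::approx(fl$x, fl$y, grid, rule = 2)$y
  integrand <- qy_fun(grid) * s * fv
  sum(diff(grid) * (utils::head(integrand, -1) + utils::tail(integrand, -1)) / 2)
}

#' Transient spectrum from a surface-hopping swarm
#'
#' Implements the trajectory-resolved workflow: geometries are extracted
#' along the dynamics at a chosen stride, the manifold of higher-lying
#' states is evaluated at every snapshot, per-time slices are formed from
#' excited-state absorption (active state to higher states, positive) and
#' stimulated emission (active state to lower states, negative), and the
#' slices are broadened in energy (optionally convolved in time with a
#' Gaussian instrument response).
#'
#' @param trajectories list of \code{sh_trajectory} objects on a common
#'   model and a common record grid.
#' @param model the \code{\link{lvc_model}} the trajectories ran on.
#' @param delta_ev broadening full width at half maximum (eV).
#' @param stride take every stride-th stored record; must divide the
#'   record count evenly.
#' @param shape lineshape kind.
#' @param signs \code{"both"} (ESA positive, SE negative) or
#'   \code{"absorption"} (ESA only; map is everywhere >= 0).
#' @param grid energy grid (eV); defaults to covering all observed gaps.
#' @param n_grid default grid size.
#' @param instrument_fwhm_fs optional Gaussian instrument-response FWHM
#'   for temporal convolution (fs); NULL (default) applies none.
#' @param prefactor absolute scale; defaults to \code{\link{sigma_prefactor}()}.
#' @return object of class \code{"transient_map"}: \code{time_fs},
#'   \code{energy_ev}, \code{map} (time x energy, cm^2), plus metadata.
#' @export
transient_spectrum <- function(trajectories, model, delta_ev, stride = 1L,
                               shape = c("gaussian", "lorentzian"),
                               signs = c("both", "absorption"),
                               grid = NULL, n_grid = 400L,
                               instrument_fwhm_fs = NULL, prefactor = NULL) {
  shape <- match.arg(shape); signs <- match.arg(signs)
  if (length(trajectories) < 1L) {
    stop(vib_error("empty_ensemble", "need at least one trajectory"))
  }
  if (is.null(prefactor)) prefactor <- .sigma_prefactor_cm2_ev
  nrec <- length(trajectories[[1]]$time)
  for (tr in trajectories) {
    if (length(tr$time) != nrec ||
        max(abs(tr$time - trajectories[[1]]$time)) > 1e-9) {
      stop(vib_error("grid_mismatch", "trajectories must share one record grid"))
    }
  }
  stride <- as.integer(stride)
  if (stride < 1L || (nrec - 1L) %% stride != 0L) {
    stop(vib_error("bad_stride",
      sprintf("stride %d is not commensurate with %d stored steps", stride,
              nrec - 1L)))
  }
  sel <- seq(1L, nrec, by = stride)
  times <- trajectories[[1]]$time[sel]
  ns <- model$n_states
  # gather transitions per slice
  slices <- vector("list", length(sel))
  all_e <- numeric(0)
  for (ti in seq_along(sel)) {
    rec <- sel[ti]
    ee <- numeric(0); ff <- numeric(0); sg <- numeric(0)
    for (tr in trajectories) {
      ev <- evaluate_adiabatic(model, tr$Q[rec, ])
      a <- tr$active[rec]
      mu2 <- ev$dip[a, , 1]^2 + ev$dip[a, , 2]^2 + ev$dip[a, , 3]^2
      for (b in seq_len(ns)) {
        if (b == a) next
        dE <- abs(ev$E[b] - ev$E[a])
        f <- (2 / 3) * dE * mu2[b]
        if (f == 0) next
        if (b > a) {                      # excited-state absorption
          ee <- c(ee, dE); ff <- c(ff, f); sg <- c(sg, 1)
        } else if (signs == "both") {     # stimulated emission
          ee <- c(ee, dE); ff <- c(ff, f); sg <- c(sg, -1)
        }
      }
    }
    slices[[ti]] <- list(e = unit_convert(ee, "hartree", "ev"), f = ff, s = sg)
    all_e <- c(all_e, slices[[ti]]$e)
  }
  if (is.null(grid)) {
    if (!length(all_e)) all_e <- c(0, 1)
    grid <- seq(min(all_e) - 3 * delta_ev, max(all_e) + 3 * delta_ev,
                length.out = n_grid)
  }
  map <- matrix(0, length(times), length(grid))
  for (ti in seq_along(slices)) {
    sl <- slices[[ti]]
    acc <- numeric(length(grid))
    for (r in seq_along(sl$e)) {
      acc <- acc + sl$s[r] * sl$f[r] * .lineshape(shape, grid, sl$e[r], delta_ev)
    }
    map[ti, ] <- prefactor * acc / length(trajectories)
  }
  time_fs <- times / au_constants$fs_to_au
  if (!is.null(instrument_fwhm_fs) && length(times) > 2L) {
    sd <- instrument_fwhm_fs / (2 * sqrt(2 * log(2)))
    for (j in seq_along(grid)) {
      w <- outer(time_fs, time_fs, function(a, b) stats::dnorm(a - b, 0, sd))
      w <- w / rowSums(w)
      map[, j] <- as.vector(w %*% map[, j])
    }
  }
  structure(list(time_fs = time_fs, energy_ev = grid, map = map,
                 delta_ev = delta_ev, shape = shape, signs = signs,
                 n_traj = length(trajectories), prefactor = prefactor),
            class = "transient_map")
}

#' @export
print.transient_map <- function(x, ...) {
  cat(sprintf("<transient_map> %d time slices x %d energies, %d trajectories\n",
              length(x$time_fs), length(x$energy_ev), x$n_traj))
  invisible(x)
}

#' Propagate a first-order rate-equation kinetics model
#'
#' Populations follow \eqn{\dot p = K p} with a first-order rate matrix K
#' (off-diagonal entries are rates into a state, fs\eqn{^{-1}};
#' column sums of zero conserve total population).  Solved as
#' \eqn{p(t) = e^{Kt} p(0)} by eigendecomposition, with a
#' scaling-and-squaring fallback for defective K.
#'
#' @param K n x n rate matrix (fs^-1); off-diagonals must be >= 0.
#' @param p0 initial populations.
#' @param t_grid ascending times from 0 (fs).
#' @return data.frame with \code{time} and one population column per
#'   state.
#' @export
kinetics_propagate <- function(K, p0, t_grid) {
  K <- as.matrix(K)
  n <- nrow(K)
  off <- K - diag(diag(K), n)
  if (any(off < 0)) {
    stop(vib_error("negative_rate", "off-diagonal rates must be non-negative"))
  }
  if (is.unsorted(t_grid) || t_grid[1] < 0) {
    stop(vib_error("bad_grid", "t_grid must ascend from 0"))
  }
  es <- eigen(K)
  P <- matrix(NA_real_, length(t_grid), n)
  use_eigen <- rcondest(es$vectors) > 1e-10
  if (use_eigen) {
    V <- es$vectors + 0i
    Vi_p0 <- solve(V, p0 + 0i)
    for (i in seq_along(t_grid)) {
      P[i, ] <- Re(V %*% (exp(es$values * t_grid[i]) * Vi_p0))
    }
  } else {
    p <- p0
    prev_t <- 0
    for (i in seq_along(t_grid)) {
      p <- .expm_ss(K * (t_grid[i] - prev_t)) %*% p
      prev_t <- t_grid[i]
      P[i, ] <- p
    }
  }
  out <- data.frame(time = t_grid)
  for (k in seq_len(n)) out[[paste0("P", k)]] <- P[, k]
  out
}

rcondest <- function(V) {
  s <- svd(V, nu = 0, nv = 0)$d
  if (min(s) == 0) 0 else min(s) / max(s)
}

# matrix exponential by scaling and squaring with a Taylor core
.expm_ss <- function(M) {
  n <- nrow(M)
  s <- max(0L, ceiling(log2(max(1e-300, norm(M, "1")))))
  A <- M / 2^s
  E <- diag(n)
  term <- diag(n)
  for (k in 1:25) {
    term <- term %*% A / k
    E <- E + term
  }
  for (j in seq_len(s)) E <- E %*% E
  E
}
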