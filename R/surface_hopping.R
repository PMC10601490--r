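# Tully fewest-switches surface hopping on LVC surfaces.
#
# Nuclear propagation is velocity Verlet for H = sum_a (omega_a/2) P_a^2
# + E_act(Q); the electronic coefficients follow the adiabatic-basis TDSE
#   cdot_k = -i E_k c_k - sum_i T_ki c_i
# with time-derivative couplings T either from analytic coupling vectors
# (T_ik = sum_a d_ik,a dQ_a/dt) or from the wave-function-overlap
# (Hammes-Schiffer-Tully) formula.  The integration loop itself lives in
# compiled code (src/fssh.cpp); the functions here are the documented
# single-step operations and the user-facing drivers.

#' Time-derivative couplings from a frame overlap (Hammes-Schiffer-Tully)
#'
#' Midpoint antisymmetrized estimate
#' \eqn{T_{ik} = (S_{ik} - S_{ki}) / (2\Delta t)} of
#' \eqn{\langle\phi_i|\partial\phi_k/\partial t\rangle} built from the
#' phase-corrected wave-function overlap
#' \eqn{S_{ik} = \langle\phi_i(t)|\phi_k(t+\Delta t)\rangle}.
#'
#' @param S overlap result from \code{\link{frame_overlap}} (or a plain
#'   matrix, in which case \code{dt} must be given).
#' @param dt time step (a.u.); defaults to the one stored on \code{S}.
#' @return antisymmetric coupling matrix (a.u.^-1) with attribute
#'   \code{source = "hst"}.
#' @export
hst_tdc <- function(S, dt = NULL) {
  if (is.list(S)) {
    if (is.null(dt)) dt <- S$dt
    S <- S$S
  }
  if (is.null(dt) || is.na(dt) || dt <= 0) {
    stop(vib_error("bad_timestep", "dt must be positive"))
  }
  structure((S - t(S)) / (2 * dt), source = "hst")
}

#' Time-derivative couplings from analytic coupling vectors
#'
#' \eqn{T_{ik} = \sum_\alpha d_{ik,\alpha}\,\dot Q_\alpha} with
#' \eqn{\dot Q_\alpha = \omega_\alpha P_\alpha}.
#'
#' @param point an \code{\link{evaluate_adiabatic}} result.
#' @param P dimensionless momenta.
#' @param omega mode frequencies (a.u.).
#' @return antisymmetric coupling matrix with attribute \code{source = "nac"}.
#' @export
nac_tdc <- function(point, P, omega) {
  qdot <- omega * P
  ns <- nrow(point$U)
  T <- matrix(0, ns, ns)
  for (a in seq_along(qdot)) T <- T + point$nac[, , a] * qdot[a]
  structure(T, source = "nac")
}

#' Propagate electronic coefficients across one nuclear step
#'
#' Integrates the adiabatic-basis TDSE by \code{n_sub} exponential-midpoint
#' substeps; energies and couplings are interpolated linearly between the
#' step endpoints, and each substep applies the unitary
#' \eqn{\exp[-i(\mathrm{diag}(E) - iT)h]}, so the norm is preserved to
#' machine precision.
#'
#' @param coeff complex coefficient vector.
#' @param E0,E1 adiabatic energies at the step start/end.
#' @param T0,T1 coupling matrices (antisymmetric) at the step start/end.
#' @param dt nuclear time step (a.u.).
#' @param n_sub number of substeps (default 25).
#' @return the propagated complex coefficient vector.
#' @export
propagate_electronic <- function(coeff, E0, E1, T0, T1, dt, n_sub = 25L) {
  if (!all(is.finite(c(E0, E1, T0, T1, dt))) || !all(is.finite(Mod(coeff)))) {
    stop(vib_error("nonfinite", "non-finite input to electronic propagation"))
  }
  coeff <- as.complex(coeff)
  out <- elec_propagate_cpp(Re(coeff), Im(coeff), as.numeric(E0),
                            as.numeric(E1),
                            matrix(as.numeric(T0), length(E0)),
                            matrix(as.numeric(T1), length(E0)),
                            dt, as.integer(n_sub))
  complex(real = out$re, imaginary = out$im)
}

#' Fewest-switches hopping probabilities
#'
#' \eqn{g_{a\to k} = \max[0,\; 2\Delta t\, T_{ak} \mathrm{Re}(c_a^* c_k) /
#' |c_a|^2]} (zero toward the active state), clipped so the total never
#' exceeds one.  The sign convention follows from differentiating
#' \eqn{|c_a|^2} under the TDSE, so probability flows toward states that
#' are gaining population.
#'
#' @param coeff complex coefficients.
#' @param T antisymmetric coupling matrix (\eqn{T_{ik} \approx
#'   \langle i|\partial_t|k\rangle}).
#' @param active active state index (1-based).
#' @param dt nuclear time step (a.u.).
#' @return vector of hop probabilities (active entry 0).
#' @export
hop_probabilities <- function(coeff, T, active, dt) {
  pa <- Mod(coeff[active])^2
  ns <- length(coeff)
  if (pa < 1e-12) {
    vib_warn("vanishing_population",
             "active-state population below 1e-12: hop probabilities zeroed")
    return(numeric(ns))
  }
  g <- 2 * dt * T[active, ] * Re(Conj(coeff[active]) * coeff) / pa
  g[active] <- 0
  g <- pmax(g, 0)
  tot <- sum(g)
  if (tot > 1) g <- g / tot
  g
}

#' Attempt a stochastic surface hop
#'
#' Selects the target by comparing one uniform draw with the cumulative
#' hop probabilities.  On a hop the momentum is adjusted to conserve total
#' energy: along the nonadiabatic coupling direction when it is finite and
#' well-conditioned, otherwise by uniform rescaling.  If the kinetic
#' energy along the adjustment direction cannot cover an upward gap the
#' hop is frustrated: state and momentum are left unchanged (no velocity
#' reversal).
#'
#' @param g hop probabilities from \code{\link{hop_probabilities}}.
#' @param u uniform random draw on (0, 1).
#' @param active current active state.
#' @param P dimensionless momenta.
#' @param omega mode frequencies (a.u.).
#' @param E adiabatic energies at the hop geometry.
#' @param nac n_states x n_states x n_modes coupling array (optional;
#'   uniform rescaling is used when absent or ill-conditioned).
#' @return list with \code{active}, \code{P}, \code{hopped},
#'   \code{frustrated}, \code{target}.
#' @export
attempt_hop <- function(g, u, active, P, omega, E, nac = NULL) {
  cum <- cumsum(g)
  target <- which(u < cum)[1]
  if (is.na(target) || target == active) {
    return(list(active = active, P = P, hopped = FALSE, frustrated = FALSE,
                target = NA_integer_))
  }
  dE <- E[target] - E[active]
  ekin <- sum(omega * P^2) / 2
  dir <- NULL
  if (!is.null(nac)) {
    d <- nac[active, target, ]
    nd <- sqrt(sum(d^2))
    if (is.finite(nd) && nd > 1e-12) dir <- d / nd
  }
  if (!is.null(dir)) {
    a <- sum(omega * dir^2) / 2
    b <- sum(omega * P * dir)
    disc <- b^2 - 4 * a * dE
    if (disc < 0) {
      return(list(active = active, P = P, hopped = FALSE, frustrated = TRUE,
                  target = target))
    }
    roots <- c((-b + sqrt(disc)) / (2 * a), (-b - sqrt(disc)) / (2 * a))
    gam <- roots[which.min(abs(roots))]
    return(list(active = target, P = P + gam * dir, hopped = TRUE,
                frustrated = FALSE, target = target))
  }
  if (dE > ekin) {
    return(list(active = active, P = P, hopped = FALSE, frustrated = TRUE,
                target = target))
  }
  s <- sqrt(1 - dE / ekin)
  list(active = target, P = P * s, hopped = TRUE, frustrated = FALSE,
       target = target)
}

#' Run one fewest-switches surface-hopping trajectory
#'
#' Velocity-Verlet nuclear propagation on the active adiabatic surface of
#' an LVC model, with electronic propagation and a hop attempt after every
#' nuclear step (using midpoint couplings).  The time-derivative couplings
#' come either from analytic coupling vectors (\code{tdc = "nac"}) or from
#' inter-step eigenvector overlaps (\code{tdc = "hst"}).  Deterministic
#' for a fixed seed.  Non-finite energies terminate the trajectory with a
#' recorded reason instead of an error.
#'
#' @param model an \code{\link{lvc_model}}.
#' @param Q0,P0 initial dimensionless coordinates and momenta.
#' @param state initial active adiabatic state (1-based), or a complex
#'   coefficient vector whose largest-population state starts active.
#' @param dt nuclear time step (a.u.; \code{dt_fs} may be given instead).
#' @param n_steps number of nuclear steps.
#' @param tdc coupling source, \code{"hst"} or \code{"nac"}.
#' @param seed integer seed for the hopping RNG.
#' @param n_sub electronic substeps per nuclear step.
#' @param stride record every \code{stride}-th step (default 1).
#' @param dt_fs time step in femtoseconds (alternative to \code{dt}).
#' @param deg_floor degeneracy floor passed to the adiabatic evaluation.
#' @return object of class \code{"sh_trajectory"}: \code{time},
#'   \code{Q}, \code{P} (rows = records), \code{active}, \code{coeff}
#'   (complex matrix), \code{energy} (total, E_h), \code{hops}
#'   (data.frame), \code{n_frustrated}, \code{seed}, \code{dt},
#'   \code{tdc}, \code{termination}.
#' @export
run_trajectory <- function(model, Q0, P0, state = 1L, dt = NULL,
                           n_steps = 1000L, tdc = c("hst", "nac"),
                           seed = NULL, n_sub = 25L, stride = 1L,
                           dt_fs = NULL, deg_floor = 1e-10) {
  tdc <- match.arg(tdc)
  if (is.null(dt)) {
    if (is.null(dt_fs)) stop(vib_error("bad_timestep", "give dt or dt_fs"))
    dt <- unit_convert(dt_fs, "fs", "autime")
  }
  if (dt <= 0) stop(vib_error("bad_timestep", "dt must be positive"))
  ns <- model$n_states
  if (length(state) == 1L) {
    active0 <- as.integer(state)
    c0 <- complex(ns); c0[active0] <- 1 + 0i
  } else {
    c0 <- as.complex(state)
    c0 <- c0 / sqrt(sum(Mod(c0)^2))
    active0 <- which.max(Mod(c0)^2)
  }
  if (active0 < 1L || active0 > ns) {
    stop(vib_error("bad_state", "initial state index out of range"))
  }
  if (!is.null(seed)) set.seed(as.integer(seed))
  res <- fssh_run_cpp(model$omega, model$epsilon, model$kappa, model$lambda,
                      model$eta, as.numeric(Q0), as.numeric(P0), active0,
                      Re(c0), Im(c0),
                      dt, as.integer(n_steps), as.integer(n_sub),
                      tdc, as.integer(stride), deg_floor)
  res$coeff <- res$coeff_re + 1i * res$coeff_im
  res$coeff_re <- NULL
  res$coeff_im <- NULL
  res$seed <- if (is.null(seed)) NA_integer_ else as.integer(seed)
  res$dt <- dt
  res$tdc <- tdc
  res$hops <- as.data.frame(res$hops)
  class(res) <- "sh_trajectory"
  res
}

#' @export
print.sh_trajectory <- function(x, ...) {
  cat(sprintf(
    "<sh_trajectory> %d records, dt = %.4g fs, tdc = %s, %d hop(s), %s\n",
    length(x$time), x$dt / au_constants$fs_to_au, x$tdc, nrow(x$hops),
    x$termination))
  invisible(x)
}

#' Run a swarm of surface-hopping trajectories
#'
#' One trajectory per initial condition; each trajectory gets its own RNG
#' stream seeded as \code{seed + index}, so the ensemble is reproducible
#' and independent of execution order.
#'
#' @param model an \code{\link{lvc_model}}.
#' @param Q0,P0 matrices of initial conditions (rows = trajectories), e.g.
#'   from \code{\link{model_coordinates}}.
#' @param seed master integer seed.
#' @param ... passed to \code{\link{run_trajectory}}.
#' @inheritParams run_trajectory
#' @return list of \code{sh_trajectory} objects.
#' @export
run_ensemble <- function(model, Q0, P0, state = 1L, seed = 1L, ...) {
  Q0 <- .as_row_matrix(Q0, model$n_modes, "Q0")
  P0 <- .as_row_matrix(P0, model$n_modes, "P0")
  lapply(seq_len(nrow(Q0)), function(i) {
    run_trajectory(model, Q0[i, ], P0[i, ], state = state,
                   seed = seed + i, ...)
  })
}

#' Classical state populations of a trajectory ensemble
#'
#' Fraction of trajectories whose active state is k at each requested
#' time (nearest recorded time not after t).
#'
#' @param trajectories list of \code{sh_trajectory} objects on a common
#'   model.
#' @param t_grid times (a.u.) at which to evaluate; defaults to the first
#'   trajectory's record times.
#' @return data.frame with \code{time} and one column per state.
#' @export
ensemble_populations <- function(trajectories, t_grid = NULL) {
  if (length(trajectories) < 1L) {
    stop(vib_error("empty_ensemble", "need at least one trajectory"))
  }
  if (is.null(t_grid)) t_grid <- trajectories[[1]]$time
  ns <- ncol(trajectories[[1]]$coeff)
  counts <- matrix(0, length(t_grid), ns)
  for (tr in trajectories) {
    idx <- findInterval(t_grid, tr$time)
    idx[idx < 1L] <- 1L
    idx[idx > length(tr$active)] <- length(tr$active)
    st <- tr$active[idx]
    for (k in seq_len(ns)) counts[, k] <- counts[, k] + (st == k)
  }
  out <- data.frame(time = t_grid)
  pops <- counts / length(trajectories)
  for (k in seq_len(ns)) out[[paste0("S", k - 1L)]] <- pops[, k]
  out
}

#' Fit a single-exponential decay rate to a population trace
#'
#' Least-squares fit of \eqn{p(t) = p_0 e^{-kt}} (nonlinear, seeded by a
#' log-linear fit).
#'
#' @param time time points.
#' @param population population values.
#' @param window optional c(tmin, tmax) fitting window.
#' @param fix_p0 fix the amplitude at its initial value instead of
#'   fitting it (default FALSE).
#' @return list with \code{k}, \code{k_se}, \code{p0}, \code{fitted}.
#' @export
fit_decay <- function(time, population, window = NULL, fix_p0 = FALSE) {
  keep <- rep(TRUE, length(time))
  if (!is.null(window)) keep <- time >= window[1] & time <= window[2]
  t <- time[keep]; p <- population[keep]
  pos <- p > 0
  k0 <- -stats::coef(stats::lm(log(p[pos]) ~ t[pos]))[[2]]
  if (!is.finite(k0) || k0 <= 0) k0 <- 1 / max(t[t > 0], 1)
  df <- data.frame(t = t, p = p)
  fit <- if (fix_p0) {
    p00 <- p[1]
    stats::nls(p ~ p00 * exp(-k * t), data = df, start = list(k = k0))
  } else {
    stats::nls(p ~ p0 * exp(-k * t), data = df,
               start = list(p0 = max(p), k = k0))
  }
  sm <- summary(fit)$coefficients
  list(k = sm["k", "Estimate"], k_se = sm["k", "Std. Error"],
       p0 = if (fix_p0) p[1] else sm["p0", "Estimate"],
       fitted = stats::predict(fit))
}
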