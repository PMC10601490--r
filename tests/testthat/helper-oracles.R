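# Independent oracles used across the suite.  These deliberately avoid
# the code paths they check: dense series summation for matrix
# exponentials, central finite differences for gradients/couplings, and a
# step-by-step R transcription of the surface-hopping algorithm built only
# from the exported single-step operations.

# matrix exponential by scaled high-order Taylor series
expm_series <- function(M, terms = 60L) {
  n <- nrow(M)
  s <- max(0L, ceiling(log2(max(1, norm(M, "1")))))
  A <- M / 2^s
  E <- diag(n)
  term <- diag(n)
  for (k in seq_len(terms)) {
    term <- term %*% A / k
    E <- E + term
  }
  for (j in seq_len(s)) E <- E %*% E
  E
}

# align eigenvector column signs to a reference frame
align_to <- function(Uref, U) {
  s <- sign(colSums(Uref * U))
  sweep(U, 2, ifelse(s == 0, 1, s), "*")
}

# central finite-difference gradients and couplings of an LVC model
fd_point <- function(model, Q, h = 1e-5) {
  nm <- model$n_modes
  ns <- model$n_states
  ev0 <- evaluate_adiabatic(model, Q)
  grad <- matrix(0, ns, nm)
  nac <- array(0, c(ns, ns, nm))
  for (a in seq_len(nm)) {
    Qp <- Q; Qp[a] <- Q[a] + h
    Qm <- Q; Qm[a] <- Q[a] - h
    ep <- evaluate_adiabatic(model, Qp)
    em <- evaluate_adiabatic(model, Qm)
    grad[, a] <- (ep$E - em$E) / (2 * h)
    dU <- (align_to(ev0$U, ep$U) - align_to(ev0$U, em$U)) / (2 * h)
    nac[, , a] <- crossprod(ev0$U, dU)
  }
  list(grad = grad, nac = nac, E = ev0$E, U = ev0$U)
}

# pure-R transcription of one surface-hopping run, assembled from the
# exported per-step operations; mirrors the compiled engine's algorithm
# (analytic-coupling TDC source, phase alignment, midpoint-coupling hops)
reference_fssh <- function(model, Q0, P0, active, dt, n_steps, seed,
                           n_sub = 25L) {
  set.seed(seed)
  ns <- model$n_states
  ev <- evaluate_adiabatic(model, Q0)
  Q <- as.numeric(Q0); P <- as.numeric(P0)
  cc <- complex(length.out = ns); cc[active] <- 1 + 0i
  Tprev <- nac_tdc(ev, P, model$omega)
  recs <- vector("list", n_steps + 1L)
  recs[[1]] <- list(Q = Q, P = P, active = active, c = cc)
  for (step in seq_len(n_steps)) {
    F0 <- -ev$grad[active, ]
    Ph <- P + dt / 2 * F0
    Qn <- Q + dt * model$omega * Ph
    evn <- evaluate_adiabatic(model, Qn)
    fo <- frame_overlap(ev$U, evn$U, dt)
    evn$U <- fo$U
    flip <- which(fo$signs < 0)
    if (length(flip)) {
      for (a in seq_len(model$n_modes)) {
        na <- evn$nac[, , a]
        na[flip, ] <- -na[flip, ]
        na[, flip] <- -na[, flip]
        evn$nac[, , a] <- na
      }
    }
    Fn <- -evn$grad[active, ]
    Pn <- Ph + dt / 2 * Fn
    T1 <- nac_tdc(evn, Pn, model$omega)
    cc <- propagate_electronic(cc, ev$E, evn$E, Tprev, T1, dt, n_sub)
    Tmid <- (Tprev + T1) / 2
    if (Mod(cc[active])^2 > 1e-12) {
      g <- hop_probabilities(cc, Tmid, active, dt)
      u <- stats::runif(1)
      hop <- attempt_hop(g, u, active, Pn, model$omega, evn$E, evn$nac)
      active <- hop$active
      Pn <- hop$P
    }
    Q <- Qn; P <- Pn; ev <- evn
    Tprev <- nac_tdc(ev, P, model$omega)
    recs[[step + 1L]] <- list(Q = Q, P = P, active = active, c = cc)
  }
  recs
}

# rigid rotation of a molecule and its Hessian
rotate_system <- function(mol, H, angles = c(0.3, -0.7, 1.1)) {
  rx <- function(t) rbind(c(1, 0, 0), c(0, cos(t), -sin(t)), c(0, sin(t), cos(t)))
  ry <- function(t) rbind(c(cos(t), 0, sin(t)), c(0, 1, 0), c(-sin(t), 0, cos(t)))
  rz <- function(t) rbind(c(cos(t), -sin(t), 0), c(sin(t), cos(t), 0), c(0, 0, 1))
  R <- rz(angles[3]) %*% ry(angles[2]) %*% rx(angles[1])
  n <- length(mol$symbols)
  Rbig <- matrix(0, 3 * n, 3 * n)
  for (a in seq_len(n)) {
    idx <- (3 * a - 2):(3 * a)
    Rbig[idx, idx] <- R
  }
  mol2 <- mol
  mol2$coords <- mol$coords %*% t(R)
  list(molecule = mol2, hessian = Rbig %*% H %*% t(Rbig))
}

# trapezoid integral on a (possibly nonuniform) grid
trapz <- function(x, y) sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)

# Landau-Zener fixture shared by the hopping tests: single passage through
# an avoided crossing, measured as the active state the first time Q > 2
lz_setup <- function() {
  list(model = make_two_state_crossing(gap = 0, slope = 0.01,
                                       coupling_const = 0.005,
                                       omega = 0.002),
       Q0 = -8, P0 = 10, dt = 2, n_steps = 400)
}

lz_survival <- function(n_traj, tdc, seed0, dt = NULL) {
  lz <- lz_setup()
  if (is.null(dt)) dt <- lz$dt
  n_steps <- ceiling(lz$dt * lz$n_steps / dt)
  up <- 0L
  for (i in seq_len(n_traj)) {
    tr <- run_trajectory(lz$model, lz$Q0, lz$P0, state = 1, dt = dt,
                         n_steps = n_steps, tdc = tdc, seed = seed0 + i)
    j <- which(tr$Q[, 1] > 2)[1]
    stopifnot(!is.na(j))
    if (tr$active[j] == 2L) up <- up + 1L
  }
  up / n_traj
}

# closed-form Landau-Zener diabatic survival for lz_setup()
lz_theory <- function() {
  eta <- 0.005; s <- 0.01; w <- 0.002
  vlow <- function(Q) 0.5 * w * Q^2 - sqrt((s * Q)^2 + eta^2)
  etot <- 0.5 * w * 10^2 + vlow(-8)
  v_cross <- sqrt(2 * w * (etot - vlow(0)))
  exp(-2 * pi * eta^2 / (v_cross * 2 * s))
}
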