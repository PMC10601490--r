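# Fewest-switches surface hopping: couplings, electronic propagation,
# hop logic, trajectory integration.

test_that("overlap-based couplings are antisymmetric and match rotation algebra", {
  # symmetric overlap: antisymmetrization leaves nothing
  S <- matrix(c(1, 0.2, 0.2, 1), 2, 2)
  expect_true(all(hst_tdc(S, 0.5) == 0))

  # eigenframe rotating by theta over dt (S12 = +sin theta): T12 = sin(theta)/dt
  th <- 0.08; dt <- 0.4
  R <- rbind(c(cos(th), sin(th)), c(-sin(th), cos(th)))
  T <- hst_tdc(R, dt)
  expect_equal(T[1, 2], sin(th) / dt, tolerance = 1e-14)
  expect_lt(max(abs(T + t(T))), 1e-15)
  expect_identical(attr(T, "source"), "hst")
  expect_error(hst_tdc(S, -1), class = "vibronica_bad_timestep")
})

test_that("overlap couplings converge quadratically to the analytic ones", {
  mod <- make_two_state_crossing(gap = 0.08, slope = 0.004,
                                 coupling_const = 0.002, omega = 0.002)
  err_at <- function(dtau) {
    tr <- run_trajectory(mod, Q0 = -3, P0 = 4, state = 1, dt = dtau,
                         n_steps = round(800 / dtau), tdc = "nac", seed = 5)
    n <- nrow(tr$Q)
    U_prev <- evaluate_adiabatic(mod, tr$Q[1, ])$U
    worst <- 0
    for (i in seq_len(n - 1)) {
      evn <- evaluate_adiabatic(mod, tr$Q[i + 1, ])
      fo <- frame_overlap(U_prev, evn$U, dtau)
      Th <- hst_tdc(fo)
      Qm <- (tr$Q[i, ] + tr$Q[i + 1, ]) / 2
      Pm <- (tr$P[i, ] + tr$P[i + 1, ]) / 2
      Tex <- nac_tdc(evaluate_adiabatic(mod, Qm), Pm, mod$omega)
      worst <- max(worst, abs(Th[1, 2] - Tex[1, 2]))
      U_prev <- fo$U
    }
    worst
  }
  e_coarse <- err_at(2)
  e_fine <- err_at(1)
  expect_gt(e_coarse / e_fine, 3.5)        # O(dt^2): halving gains ~4x
})

test_that("electronic propagation is unitary, phase-exact and Rabi-exact", {
  # single state: pure phase, modulus untouched
  c1 <- propagate_electronic(1 + 0i, 0.3, 0.3, matrix(0, 1, 1),
                             matrix(0, 1, 1), dt = 2, n_sub = 10)
  expect_equal(c1, exp(-0.3i * 2), tolerance = 1e-12)

  # degenerate 2-state with constant coupling: population sin^2(|T12| t)
  T12 <- 0.02; tt <- 30
  Tm <- matrix(c(0, T12, -T12, 0), 2, 2, byrow = TRUE)
  c2 <- propagate_electronic(c(1 + 0i, 0i), c(0, 0), c(0, 0), Tm, Tm,
                             dt = tt, n_sub = 50)
  expect_equal(Mod(c2[2])^2, sin(T12 * tt)^2, tolerance = 1e-6)

  # random 3-state system: norm drift < 1e-10 over 1e4 steps
  set.seed(6)
  cc <- complex(real = rnorm(3), imaginary = rnorm(3))
  cc <- cc / sqrt(sum(Mod(cc)^2))
  E <- runif(3); A <- matrix(rnorm(9), 3); Tr <- (A - t(A)) / 50
  for (i in 1:100) {
    cc <- propagate_electronic(cc, E, E, Tr, Tr, dt = 0.5, n_sub = 100)
  }
  expect_lt(abs(sum(Mod(cc)^2) - 1), 1e-10)
  expect_error(propagate_electronic(cc, NaN, E, Tr, Tr, 0.5),
               class = "vibronica_nonfinite")
})

test_that("hop probabilities are non-negative, bounded, and mirror the population flux", {
  # zero couplings: no hopping flux anywhere
  cc <- c(sqrt(0.7) + 0i, sqrt(0.3) + 0i)
  expect_true(all(hop_probabilities(cc, matrix(0, 2, 2), 1, 0.5) == 0))

  # 2-state detailed balance: when the active population is draining, g
  # equals the negative population derivative times dt/|c_a|^2; the
  # derivative is measured by propagating the TDSE over a short interval
  set.seed(8)
  checked <- 0L
  for (i in 1:80) {
    cc <- complex(real = rnorm(2), imaginary = rnorm(2))
    cc <- cc / sqrt(sum(Mod(cc)^2))
    t12 <- rnorm(1, 0, 0.05)
    Tm <- matrix(c(0, t12, -t12, 0), 2, 2, byrow = TRUE)
    dt <- 1e-3
    g <- hop_probabilities(cc, Tm, 1, dt)
    c2 <- propagate_electronic(cc, c(0.1, 0.1), c(0.1, 0.1), Tm, Tm, dt,
                               n_sub = 200)
    dp <- (Mod(c2[1])^2 - Mod(cc[1])^2) / dt
    expected <- -dp * dt / Mod(cc[1])^2
    if (dp < -1e-6) {
      expect_lt(abs(g[2] - expected), 1e-3 * expected + 2e-8)
      checked <- checked + 1L
    } else if (dp > 1e-6) {
      expect_equal(g[2], 0)
    }
  }
  expect_gt(checked, 10L)

  # sum never exceeds one across a large random sweep
  set.seed(9)
  for (i in 1:2000) {
    ns <- sample(2:4, 1)
    cc <- complex(real = rnorm(ns), imaginary = rnorm(ns))
    cc <- cc / sqrt(sum(Mod(cc)^2))
    A <- matrix(rnorm(ns * ns, 0, 5), ns)
    Tm <- A - t(A)
    g <- hop_probabilities(cc, Tm, 1, runif(1, 0.01, 2))
    expect_true(all(g >= 0))
    expect_lte(sum(g), 1 + 1e-12)
  }

  cc0 <- c(1e-8 + 0i, 1 + 0i)
  expect_warning(g0 <- hop_probabilities(cc0, Tm[1:2, 1:2], 1, 0.5),
                 class = "vibronica_vanishing_population")
  expect_true(all(g0 == 0))
})

test_that("hop attempts conserve energy and frustrate correctly", {
  omega <- c(0.004, 0.01)
  E <- c(0, 0.002, 0.05)
  nac <- array(0, c(3, 3, 2))
  nac[1, 2, ] <- c(1, 0.5); nac[2, 1, ] <- -c(1, 0.5)

  # no probability: nothing happens
  h0 <- attempt_hop(rep(0, 3), 0.5, 2, c(1, 1), omega, E, nac)
  expect_false(h0$hopped)
  expect_equal(h0$P, c(1, 1))

  # downward hop: kinetic energy rises by exactly the gap
  P <- c(1, 1)
  ekin0 <- sum(omega * P^2) / 2
  h1 <- attempt_hop(c(1, 0, 0), 0.1, 2, P, omega, E, nac)
  expect_true(h1$hopped)
  expect_equal(h1$active, 1)
  expect_equal(sum(omega * h1$P^2) / 2, ekin0 + (E[2] - E[1]), tolerance = 1e-12)

  # upward hop without enough kinetic energy is frustrated, untouched
  Psmall <- c(0.1, 0.1)
  h2 <- attempt_hop(c(0, 0, 1), 0.1, 2, Psmall, omega, E, nac = NULL)
  expect_false(h2$hopped)
  expect_true(h2$frustrated)
  expect_equal(h2$P, Psmall)
})

test_that("single-surface trajectories keep the harmonic period and conserve energy", {
  w <- 0.002
  mod <- lvc_model(omega = w, epsilon = 0)
  dtau <- unit_convert(0.5, "fs", "autime")
  tr <- run_trajectory(mod, Q0 = 1, P0 = 0, state = 1, dt = dtau,
                       n_steps = 1000, tdc = "nac", seed = 1)
  expect_equal(nrow(tr$hops), 0L)
  expect_lt(max(abs(tr$energy - tr$energy[1])), 1e-6)

  # period from upward zero crossings of Q(t)
  q <- tr$Q[, 1]; t <- tr$time
  up <- which(q[-1] > 0 & q[-length(q)] <= 0)
  tcross <- t[up] + (t[up + 1] - t[up]) * (-q[up]) / (q[up + 1] - q[up])
  period <- mean(diff(tcross))
  expect_lt(abs(period - 2 * pi / w) / (2 * pi / w), 1e-3)

  # time reversal retraces the path
  nlast <- nrow(tr$Q)
  back <- run_trajectory(mod, Q0 = tr$Q[nlast, 1], P0 = -tr$P[nlast, 1],
                         state = 1, dt = dtau, n_steps = 1000, tdc = "nac",
                         seed = 2)
  expect_lt(max(abs(rev(back$Q[, 1]) - tr$Q[, 1])), 1e-6)
})

test_that("uncoupled multi-state models never transfer population", {
  mod <- make_two_state_crossing(gap = 0.05, slope = 0.003,
                                 coupling_const = 0, coupling_linear = 0)
  tr <- run_trajectory(mod, Q0 = -2, P0 = 3, state = 2, dt = 2,
                       n_steps = 500, tdc = "nac", seed = 3)
  expect_equal(nrow(tr$hops), 0L)
  expect_true(all(tr$active == 2L))
  pops <- Mod(tr$coeff)^2
  expect_lt(max(abs(pops[, 2] - 1)), 1e-10)
  # norm conservation at every step
  expect_lt(max(abs(rowSums(pops) - 1)), 1e-8)
})

test_that("the compiled engine reproduces the step-by-step R reference", {
  lz <- lz_setup()
  # start just before the coupling region so hops occur within few steps
  n_steps <- 60L
  tr <- run_trajectory(lz$model, Q0 = -2, P0 = 9.5, state = 1, dt = 2,
                       n_steps = n_steps, tdc = "nac", seed = 77)
  ref <- reference_fssh(lz$model, -2, 9.5, 1L, 2, n_steps, seed = 77)
  for (i in c(10, 30, 45, n_steps + 1)) {
    expect_equal(tr$Q[i, ], ref[[i]]$Q, tolerance = 1e-9)
    expect_equal(tr$P[i, ], ref[[i]]$P, tolerance = 1e-9)
    expect_equal(tr$active[i], ref[[i]]$active)
    expect_lt(max(Mod(tr$coeff[i, ] - ref[[i]]$c)), 1e-9)
  }
  # at least one stochastic branch was exercised somewhere in the swarm
  hopped <- any(vapply(1:20, function(s) {
    nrow(run_trajectory(lz$model, -2, 9.5, 1, dt = 2, n_steps = n_steps,
                        tdc = "nac", seed = s)$hops) > 0
  }, logical(1)))
  expect_true(hopped)
})

test_that("trajectories are deterministic per seed and record bookkeeping is coherent", {
  lz <- lz_setup()
  a <- run_trajectory(lz$model, lz$Q0, lz$P0, 1, dt = 2, n_steps = 200,
                      tdc = "hst", seed = 4)
  b <- run_trajectory(lz$model, lz$Q0, lz$P0, 1, dt = 2, n_steps = 200,
                      tdc = "hst", seed = 4)
  expect_identical(a$Q, b$Q)
  expect_identical(a$active, b$active)
  expect_true(all(diff(a$time) > 0))
  expect_length(a$energy, length(a$time))
  # energy is exactly bookkept across hops; the residual is the bounded
  # Verlet oscillation through the avoided-crossing curvature
  expect_lt(max(abs(a$energy - a$energy[1])), 1e-5)
})

test_that("ensemble populations and decay fitting behave", {
  mod <- make_two_state_crossing(gap = 0.05, slope = 0.003,
                                 coupling_const = 0)
  trs <- run_ensemble(mod, Q0 = matrix(c(-1, -1.1), 2, 1),
                      P0 = matrix(c(2, 2), 2, 1), state = 1, seed = 5,
                      dt = 2, n_steps = 50, tdc = "nac")
  pops <- ensemble_populations(trs)
  expect_equal(pops$S0, rep(1, nrow(pops)))
  expect_equal(pops$S1, rep(0, nrow(pops)))

  # duplicated trajectories change nothing (idempotent averaging)
  pops2 <- ensemble_populations(c(trs, trs))
  expect_equal(pops2$S0, pops$S0)

  expect_error(ensemble_populations(list()), class = "vibronica_empty_ensemble")

  # generate-and-refit: e^(-0.01 t) with 1% noise recovers k within 2 SE
  set.seed(10)
  t <- seq(0, 400, by = 2)
  p <- exp(-0.01 * t) * (1 + rnorm(length(t), 0, 0.01))
  fit <- fit_decay(t, p)
  expect_lt(abs(fit$k - 0.01), 2 * fit$k_se)
})

test_that("overlap and analytic coupling sources give the same hop statistics", {
  n <- 600
  s_nac <- lz_survival(n, "nac", seed0 = 2000, dt = 4.1341374)  # 0.1 fs
  s_hst <- lz_survival(n, "hst", seed0 = 4000, dt = 4.1341374)
  p <- (s_nac + s_hst) / 2
  se <- sqrt(2 * p * (1 - p) / n)
  expect_lt(abs(s_nac - s_hst), 3 * se)
})
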