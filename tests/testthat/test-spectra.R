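# Ensemble spectra, photolysis rates, transient maps, kinetics.

test_that("vertical transitions follow the model's gaps and dipoles", {
  mod <- make_two_state_crossing(gap = 0.1, slope = 0, coupling_const = 0,
                                 omega = 0.005)
  Q <- matrix(0, 10, 1)
  tr <- transitions_from_ensemble(mod, Q)
  expect_true(all(abs(tr$dE - 0.1) < 1e-14))
  expect_equal(attr(tr, "n_geom"), 10)

  # kappa difference without couplings: linear gap in Q
  mod2 <- lvc_model(omega = 0.005, epsilon = c(0, 0.1),
                    kappa = matrix(c(0, 0.01), 2, 1))
  Qs <- matrix(seq(-2, 2, length.out = 9), ncol = 1)
  tr2 <- transitions_from_ensemble(mod2, Qs)
  expect_equal(tr2$dE, 0.1 + 0.01 * Qs[, 1], tolerance = 1e-12)

  # zero transition dipole: all oscillator strengths vanish
  mod3 <- lvc_model(omega = 0.005, epsilon = c(0, 0.1))
  tr3 <- transitions_from_ensemble(mod3, Q)
  expect_true(all(tr3$f == 0))
  expect_error(transitions_from_ensemble(mod, Q, n_states = 5),
               class = "vibronica_bad_states")
})

test_that("a single broadened transition integrates to C * f", {
  mod <- make_two_state_crossing(gap = 0.1, slope = 0, coupling_const = 0,
                                 omega = 0.005, dipole01 = c(1, 0, 0))
  tr <- transitions_from_ensemble(mod, matrix(0, 1, 1))
  f_ref <- (2 / 3) * 0.1 * 1
  for (shape in c("gaussian", "lorentzian")) {
    delta <- 0.08
    center <- tr$dE_ev[1]
    grid <- if (shape == "gaussian") {
      seq(center - 10 * delta, center + 10 * delta, length.out = 4001)
    } else {
      sort(unique(c(seq(center - 10 * delta, center + 10 * delta,
                        length.out = 4001),
                    center + exp(seq(log(10 * delta), log(5e3 * delta),
                                     length.out = 4000)),
                    center - exp(seq(log(10 * delta), log(5e3 * delta),
                                     length.out = 4000)))))
    }
    spec <- nea_spectrum(tr, delta, shape = shape, grid = grid)
    area <- trapz(spec$energy_ev, spec$sigma)
    expect_equal(area, sigma_prefactor() * f_ref, tolerance = 2e-6,
                 info = shape)
  }
  expect_error(nea_spectrum(tr, -0.1), class = "vibronica_bad_width")
})

test_that("spectra are linear in f, idempotent under duplication, and obey the sum rule", {
  mod <- make_multimode_lvc(n_modes = 2, n_states = 3, seed = 19)
  modes_Q <- matrix(rnorm(40, 0, 0.7), 20, 2)
  tr <- transitions_from_ensemble(mod, modes_Q)
  grid <- seq(min(tr$dE_ev) - 2, max(tr$dE_ev) + 2, length.out = 3000)

  s1 <- nea_spectrum(tr, 0.1, grid = grid)
  tr2x <- tr; tr2x$f <- 2 * tr2x$f
  s2 <- nea_spectrum(tr2x, 0.1, grid = grid)
  expect_equal(s2$sigma, 2 * s1$sigma, tolerance = 1e-12)

  # duplicated geometries: identical spectrum
  trdup <- rbind(tr, tr)
  attr(trdup, "n_geom") <- 2 * attr(tr, "n_geom")
  class(trdup) <- class(tr)
  sdup <- nea_spectrum(trdup, 0.1, grid = grid)
  expect_equal(sdup$sigma, s1$sigma, tolerance = 1e-12)

  # sum rule: total area = C * mean total f, independent of delta (1e-4 rel)
  target <- sigma_prefactor() * sum(tr$f) / attr(tr, "n_geom")
  for (delta in c(0.05, 0.15, 0.3)) {
    sp <- nea_spectrum(tr, delta, grid = grid)
    expect_equal(trapz(sp$energy_ev, sp$sigma), target, tolerance = 1e-4)
  }
  # per-state decomposition sums to the total
  expect_equal(rowSums(s1$per_state), s1$sigma, tolerance = 1e-12)

  # as delta -> 0 the first moment approaches the f-weighted mean gap
  sp0 <- nea_spectrum(tr, 0.01, grid = grid)
  m1 <- trapz(sp0$energy_ev, sp0$energy_ev * sp0$sigma) /
    trapz(sp0$energy_ev, sp0$sigma)
  expect_equal(m1, sum(tr$f * tr$dE_ev) / sum(tr$f), tolerance = 1e-4)
})

test_that("photolysis rates integrate flux times cross section times yield", {
  # constant integrand toy: phi = 1, sigma = 1e-18 cm^2, F = 1e14 over 100 nm
  sig <- make_flux_table("constant", list(value = 1e-18, from = 300, to = 400))
  flux <- make_flux_table("constant", list(value = 1e14, from = 300, to = 400))
  J <- photolysis_rate(sig, flux, quantum_yield = 1)
  expect_equal(J, 1e-2, tolerance = 1e-12)
  expect_equal(photolysis_rate(sig, flux, quantum_yield = 0), 0)

  # Gaussian cross section against constant flux: analytic integral
  area <- 3.2e-17
  sigg <- make_flux_table("gaussian", list(area = area, center = 350,
                                           fwhm = 20, from = 200, to = 500,
                                           n = 4001))
  Jg <- photolysis_rate(sigg, make_flux_table("constant",
                                              list(value = 1e14, from = 200,
                                                   to = 500)))
  expect_equal(Jg, area * 1e14, tolerance = 1e-6)

  flux_far <- make_flux_table("constant", list(value = 1, from = 600, to = 700))
  expect_error(photolysis_rate(sig, flux_far), class = "vibronica_window_overlap")
})

test_that("rate-equation kinetics are exact and conservative", {
  # 0.01 fs^-1 decay: excited population e^-1 = 0.3679 at 100 fs
  K <- matrix(c(-0.01, 0.01, 0, 0), 2, 2)
  out <- kinetics_propagate(K, c(1, 0), c(0, 50, 100, 200))
  expect_equal(out$P1[out$time == 100], exp(-1), tolerance = 1e-12)
  expect_equal(out$P1[out$time == 100], 0.3679, tolerance = 1e-4)
  expect_lt(max(abs(rowSums(out[, -1]) - 1)), 1e-12)

  # K = 0: populations frozen
  out0 <- kinetics_propagate(matrix(0, 2, 2), c(0.4, 0.6), 0:10)
  expect_true(all(out0$P1 == 0.4) && all(out0$P2 == 0.6))

  # 3-state chain vs dense series-summation oracle, incl. a defective
  # equal-rate case that exercises the scaling-and-squaring fallback
  for (rates in list(c(0.02, 0.005), c(0.01, 0.01))) {
    K3 <- matrix(0, 3, 3)
    K3[1, 1] <- -rates[1]; K3[2, 1] <- rates[1]
    K3[2, 2] <- -rates[2]; K3[3, 2] <- rates[2]
    t_grid <- c(0, 10, 50, 120, 300)
    got <- kinetics_propagate(K3, c(1, 0, 0), t_grid)
    for (i in seq_along(t_grid)) {
      oracle <- expm_series(K3 * t_grid[i]) %*% c(1, 0, 0)
      expect_equal(as.numeric(got[i, -1]), as.numeric(oracle),
                   tolerance = 1e-10)
    }
    expect_lt(max(abs(rowSums(got[, -1]) - 1)), 1e-12)
  }

  Kbad <- matrix(c(-0.01, -0.01, 0.02, 0), 2, 2)
  expect_error(kinetics_propagate(Kbad, c(1, 0), 0:5),
               class = "vibronica_negative_rate")
})

make_frozen_trajectory <- function(times, active_trace, nm = 1, ns = 3) {
  structure(list(
    time = times,
    Q = matrix(0, length(times), nm),
    P = matrix(0, length(times), nm),
    active = active_trace,
    coeff = matrix(0 + 0i, length(times), ns),
    energy = rep(0, length(times)),
    hops = data.frame(), n_frustrated = 0L, seed = NA_integer_,
    dt = diff(times)[1], tdc = "nac", termination = "completed"
  ), class = "sh_trajectory")
}

test_that("transient maps reduce to the steady spectrum in the static limit", {
  dip <- array(0, c(3, 3, 3))
  dip[1, 2, 1] <- dip[2, 1, 1] <- 1        # one bright gap from the ground state
  mod <- lvc_model(omega = 0.005, epsilon = c(0, 0.1, 0.25), dipoles = dip)
  times <- seq(0, 400, by = 40)
  trs <- lapply(1:5, function(i)
    make_frozen_trajectory(times, rep(1L, length(times))))
  grid <- seq(1.5, 4, length.out = 500)
  tmap <- transient_spectrum(trs, mod, delta_ev = 0.15, grid = grid)
  # time-independent, positive, equal to the single-geometry NEA spectrum
  for (i in seq_along(times)) {
    expect_equal(tmap$map[i, ], tmap$map[1, ], tolerance = 1e-12)
  }
  ref <- nea_spectrum(transitions_from_ensemble(mod, matrix(0, 1, 1)),
                      0.15, grid = grid)
  expect_equal(tmap$map[1, ], ref$sigma, tolerance = 1e-10)
})

test_that("stimulated-emission bands decay with the population and signs behave", {
  # bright state (index 3) emits to the ground state at 0.1 E_h; decay
  # funnels into a spectroscopically dark intermediate (index 2) so the
  # emission band amplitude tracks the bright-state population alone
  dip <- array(0, c(3, 3, 3))
  dip[1, 3, 1] <- dip[3, 1, 1] <- 1
  dip[2, 3, 2] <- dip[3, 2, 2] <- 0.5
  mod <- lvc_model(omega = 0.005, epsilon = c(0, 0.05, 0.1), dipoles = dip)
  k <- 0.01                                  # fs^-1
  dt_fs <- 10
  times_au <- seq(0, 300, by = dt_fs) * au_constants$fs_to_au
  set.seed(33)
  n_traj <- 400
  trs <- lapply(seq_len(n_traj), function(i) {
    t_hop <- stats::rexp(1, k)               # fs
    active <- ifelse(seq(0, 300, by = dt_fs) < t_hop, 3L, 2L)
    make_frozen_trajectory(times_au, active, ns = 3)
  })
  grid <- seq(1.5, 4, length.out = 300)
  tmap <- transient_spectrum(trs, mod, delta_ev = 0.2, grid = grid)
  # SE amplitude at the band center decays as e^(-kt)
  centre <- which.min(abs(grid - unit_convert(0.1, "hartree", "ev")))
  se_amp <- -tmap$map[, centre]
  fit <- fit_decay(tmap$time_fs, se_amp / se_amp[1])
  expect_lt(abs(fit$k - k), 2 * max(fit$k_se, k * sqrt(1 / n_traj)))

  # absorption-only maps are non-negative everywhere
  tabs <- transient_spectrum(trs, mod, delta_ev = 0.2, grid = grid,
                             signs = "absorption")
  expect_true(all(tabs$map >= 0))

  # stride must divide the stored record count
  expect_error(transient_spectrum(trs, mod, delta_ev = 0.2, stride = 7),
               class = "vibronica_bad_stride")
})
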