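test_that("light equilibrium constants follow the radiation-temperature formulas", {
  lc <- light_equilibrium_constants(lambda_nm = 570, T_R = 1570)
  pe <- photon_energy(570)
  expect_equal(pe$hv_kBT, 84.66, tolerance = 1e-3)
  expect_equal(lc$K_D, exp(pe$hv_kBT), tolerance = 1e-10)
  expect_equal(lc$K_L, exp(pe$J / (physical_constants()$k_B * 1570)),
               tolerance = 1e-12)
  expect_lt(lc$K_L, lc$K_D)

  # K_L -> 1 as the radiation temperature diverges
  hot <- light_equilibrium_constants(lambda_nm = 570, T_R = 1e12)
  expect_equal(hot$K_L, 1, tolerance = 1e-6)

  expect_error(light_equilibrium_constants(lambda_nm = 570, T_R = 200),
               "T_R must exceed")

  # monotone: larger T_R, smaller K_L
  k1 <- light_equilibrium_constants(lambda_nm = 570, T_R = 1000)$K_L
  k2 <- light_equilibrium_constants(lambda_nm = 570, T_R = 2000)$K_L
  expect_gt(k1, k2)
})

test_that("cycle closure fixes K_1 and round-trips through the cycle affinity", {
  # all other K = 1 and X_sec = 0 (with a trivial K_D) gives K_1 = 1
  expect_equal(
    close_cycle_equilibrium_constant(rep(1, 6), 0, K_D = 1), 1
  )
  # doubling exp(X_sec / R T) doubles K_1
  RT <- 8.31446261815 * 298.16 / 1000
  k1a <- close_cycle_equilibrium_constant(rep(2, 6), -10, K_D = 5)
  k1b <- close_cycle_equilibrium_constant(rep(2, 6), -10 + RT * log(2), K_D = 5)
  expect_equal(k1b / k1a, 2, tolerance = 1e-10)
  expect_error(close_cycle_equilibrium_constant(c(1, 0), -5, K_D = 2),
               "positive")

  # full model round trip: the thermal productive cycle recovers X_sec
  for (xs in c(-18.84, -123)) {
    m <- synthetic_br_photocycle(X_sec_kJ_mol = xs)
    ca <- cycle_affinity(m, c("D", paste0("T", 1:7)))
    expect_equal(ca$X / 1000, xs, tolerance = 1e-9)
    # and the light-side cycle carries X_sec plus the photon force
    ca_l <- cycle_affinity(m, c("L", paste0("T", 1:7)))
    x_photon <- 8.31446261815 * m$temperature *
      log(m$light$K_D / m$light$K_L) / 1000
    expect_equal(ca_l$X / 1000, xs + x_photon, tolerance = 1e-9)
  }
})

test_that("the light-decay pair is a genuine parallel-edge cycle with the photon affinity", {
  m <- synthetic_br_photocycle()
  expect_identical(validate_scheme(m), character(0))
  tr <- m$transitions
  expect_equal(tr$from[tr$id %in% c("L", "D")], c("1", "1"))
  expect_equal(tr$to[tr$id %in% c("L", "D")], c("2", "2"))
  ca <- cycle_affinity(m, c("L", "D"), c(1, -1))
  expect_equal(ca$X_RT, log(m$light$K_D / m$light$K_L), tolerance = 1e-10)
  # the L-D cycle flux is the leak J_L - J
  fit <- steady_state(m)
  J <- fit$transitions$J
  names(J) <- fit$transitions$id
  expect_equal(J[["L"]] - J[["T7"]], -J[["D"]], tolerance = 1e-10)
})

test_that("solver invariants hold unchanged on the photocycle multigraph", {
  m <- synthetic_br_photocycle(X_sec_kJ_mol = -26.86)
  p <- stationary_probabilities(m)
  po <- steady_state_oracle(m)
  expect_lt(max(abs(p - po) / p), 1e-10)
  expect_lt(kirchhoff_residual(m), 1e-12)
  fit <- steady_state(m)
  expect_true(all(fit$transitions$sigma_kB >= -1e-15))
  cd <- cycle_decomposition(m)
  expect_equal(sum(cd$sigma_kB), fit$sigma_tot_kB,
               tolerance = 1e-10)
})

test_that("quantum yield reflects the branching between transport and decay", {
  m <- synthetic_br_photocycle()
  qy <- quantum_yield(m)
  expect_gt(qy$yield, 0)
  expect_lte(qy$yield, 1)
  # with k1 = 2.5e11 against k_d = 1e8 the yield is ~k1/(k1 + k_d) = 99.96%
  expect_equal(qy$yield, 0.9996, tolerance = 1e-3)

  # less non-radiative loss, higher yield; more, lower
  low_kd <- synthetic_br_photocycle(k_d = 1e4)
  high_kd <- synthetic_br_photocycle(k_d = 1e10)
  expect_gt(quantum_yield(low_kd)$yield, qy$yield)
  expect_lt(quantum_yield(high_kd)$yield, qy$yield)
  expect_gt(quantum_yield(low_kd)$yield, 0.99999)
})

test_that("the force scan reproduces the pump's characteristic curves", {
  m <- synthetic_br_photocycle()
  sc <- force_scan(m, c(0, -18.84, -26.86, -80, -123, -160))
  expect_equal(sc$eta[sc$X_sec == 0], 0)
  # efficiency ordering across the three reference forces
  eta <- function(x) sc$eta[sc$X_sec == x]
  expect_gt(eta(-26.86), eta(-18.84))
  expect_gt(eta(-123), eta(-26.86))
  # interior maximum: efficiency collapses beyond the stall force
  expect_lt(eta(-160), eta(-123))
  # flux nearly constant over the pumping regime, falling beyond it
  expect_equal(sc$J[sc$X_sec == -26.86], sc$J[sc$X_sec == 0], tolerance = 1e-6)
  expect_lt(sc$J[sc$X_sec == -160], 0.01 * sc$J[sc$X_sec == 0])
  # entropy production decreases as the efficiency rises
  expect_true(all(diff(sc$sigma_tot[1:5]) < 0))
})

test_that("efficiency obeys the photocycle energy balance", {
  m <- synthetic_br_photocycle(X_sec_kJ_mol = -60)
  fit <- steady_state(m)
  qy <- quantum_yield(m, fit)
  eta <- photocycle_efficiency(m, fit)
  x_photon <- 8.31446261815 * m$temperature * log(m$light$K_D / m$light$K_L)
  p_in <- x_photon * qy$J_L
  p_out <- 60e3 * qy$J
  expect_equal(eta, p_out / p_in, tolerance = 1e-12)
  expect_equal(fit$temperature * fit$sigma_tot * 1000, p_in - p_out,
               tolerance = 1e-8 * p_in)
})
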