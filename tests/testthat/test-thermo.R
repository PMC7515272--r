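test_that("transition affinities vanish at equilibrium and telescope to the cycle affinity", {
  db <- triangle_scheme(c(2, 6, 1), c(1, 3, 4))
  for (id in c("T1", "T2", "T3")) {
    expect_equal(transition_affinity(db, id)$X, 0, tolerance = 1e-10)
  }

  tri <- triangle_scheme(c(2, 2, 2), c(1, 1, 1))
  aff <- transition_affinity(tri, "T1")
  expect_equal(aff$X_RT, log(2), tolerance = 1e-12)
  expect_equal(aff$X / 1000, 1.718, tolerance = 1e-3)  # kJ/mol at 298.16 K

  # sum of transition affinities around a cycle = R T ln K, independent of p
  for (seed in c(3, 17, 99)) {
    sch <- generate_random_scheme(6, 2, seed = seed)
    p <- stationary_probabilities(sch)
    pc <- attr(sch, "prescribed_cycles")[[1]]
    xsum <- sum(vapply(seq_along(pc$transitions), function(i) {
      pc$orientation[i] * transition_affinity(sch, pc$transitions[i], p)$X_RT
    }, numeric(1)))
    expect_equal(xsum, pc$X_RT, tolerance = 1e-9)
  }
})

test_that("transitional entropy production is sigma = X J / T, zero at equilibrium, non-negative always", {
  db <- triangle_scheme(c(2, 6, 1), c(1, 3, 4))
  expect_equal(transition_entropy_production(db, "T2")$sigma, 0,
               tolerance = 1e-12)

  tri <- triangle_scheme(c(2, 2, 2), c(1, 1, 1))
  ep <- transition_entropy_production(tri, "T1")
  expect_equal(ep$sigma_kB, log(2) / 3, tolerance = 1e-12)

  for (case in random_case_grid(20)) {
    sch <- generate_random_scheme(case$n_states, case$n_extra, seed = case$seed)
    fit <- steady_state(sch)
    expect_true(all(fit$transitions$sigma_kB >= -1e-15),
                info = paste("seed", case$seed))
  }
})

test_that("total entropy production equals the cycle-basis decomposition", {
  tri <- triangle_scheme(c(2, 2, 2), c(1, 1, 1))
  tot <- total_entropy_production(tri)
  expect_equal(tot$sigma_tot_kB, log(2), tolerance = 1e-12)
  cd <- cycle_decomposition(tri)
  expect_equal(sum(cd$sigma_kB), tot$sigma_tot_kB, tolerance = 1e-12)

  for (case in random_case_grid(20, seed0 = 300)) {
    sch <- generate_random_scheme(case$n_states, case$n_extra, seed = case$seed)
    tot <- total_entropy_production(sch)
    cd <- cycle_decomposition(sch)
    expect_equal(sum(cd$sigma_kB), tot$sigma_tot_kB,
                 tolerance = 1e-10,
                 info = paste("seed", case$seed))
  }
})

test_that("Shannon entropy handles uniform, point-mass and published distributions", {
  expect_equal(shannon_entropy(rep(1 / 3, 3)), log(3), tolerance = 1e-14)
  expect_equal(shannon_entropy(rep(1 / 8, 8)), log(8), tolerance = 1e-14)
  expect_equal(shannon_entropy(c(1, 0, 0)), 0)
  # entropy of the published five-state occupancies brackets the printed 1.17
  p5 <- c(0.04, 0.3, 0.49, 0.01, 0.16)
  S <- shannon_entropy(p5)
  expect_gte(S, 1.17)
  expect_lte(S, 1.19)
})

test_that("catalytic constants: limiting step, hyperbola identification, and time rescaling", {
  # effectively irreversible, very fast catalysis makes release
  # rate-limiting: k_cat -> k3
  fast <- mm_3state_scheme(k_f = c(1000, 1e9, 50), k_b = c(100, 1e3, 1e-20))
  cp <- catalytic_parameters(fast, binding = "T1", release = "T3", k_on = 1e6)
  expect_equal(cp$k_cat, 50, tolerance = 1e-4)

  sch <- mm_3state_scheme(k_f = c(1000, 100, 50), k_b = c(100, 50, 1e-20))
  cp <- catalytic_parameters(sch, binding = "T1", release = "T3", k_on = 1e6)
  # numeric saturation limit agrees with the exact hyperbola identification
  expect_equal(cp$k_cat_numeric, cp$k_cat, tolerance = 1e-5)
  expect_equal(cp$specificity, cp$k_cat / cp$K_M, tolerance = 1e-12)
  # closed form for the irreversible-release 3-state cycle:
  # k_cat = k2 k3 / (k2 + k_-2 + k3)
  expect_equal(cp$k_cat, 100 * 50 / (100 + 50 + 50), tolerance = 1e-6)

  # doubling every rate constant doubles k_cat and leaves K_M unchanged
  sch2 <- sch
  sch2$transitions$k_forward <- sch$transitions$k_forward * 2
  sch2$transitions$k_backward <- sch$transitions$k_backward * 2
  cp2 <- catalytic_parameters(sch2, binding = "T1", release = "T3", k_on = 2e6)
  expect_equal(cp2$k_cat, 2 * cp$k_cat, tolerance = 1e-6)
  expect_equal(cp2$K_M, cp$K_M, tolerance = 1e-6)
})

test_that("transduction efficiency: static head, level flow, and exact power balance", {
  expect_equal(transduction_efficiency(1e4, 5, -2e3, 0), 0)   # static head
  expect_equal(transduction_efficiency(1e4, 5, 0, 3), 0)      # level flow
  expect_error(transduction_efficiency(1e4, 0, -2e3, 1), "zero input power")

  # two-force scheme with the forces concentrated on the IN and OUT edges:
  # T sigma_tot = X_in J_IN + X_out J_OUT exactly (the probability terms of
  # the edge affinities telescope away by current conservation), so
  # eta + dissipated fraction = 1
  sch <- two_force_scheme(K_in = 1e4, K_out = 1e-1)
  fit <- steady_state(sch)
  RT <- 8.31446261815 * fit$temperature
  J <- setNames(fit$transitions$J, fit$transitions$id)
  X_in <- RT * log(1e4)
  X_out <- RT * log(1e-1)
  eta <- transduction_efficiency(X_in, J[["IN"]], X_out, J[["OUT"]])
  dissipated <- fit$temperature * fit$sigma_tot * 1000 / (X_in * J[["IN"]])
  expect_gt(eta, 0)
  expect_lt(eta, 1)
  expect_equal(eta + dissipated, 1, tolerance = 1e-10)
})
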