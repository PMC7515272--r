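# shared scheme builders for the tests

# driven four-state cycle with a slip edge: the input force sits on IN and
# the output force on OUT of the same cycle (K = 1 everywhere else), so the
# net cycle force ln(K_in K_out) > 0 pumps the OUT step uphill while SL
# leaks part of the input flux.  With the forces concentrated on IN and
# OUT, T sigma_tot = X_in J_IN + X_out J_OUT exactly.
two_force_scheme <- function(K_in = 1e4, K_out = 1e-1) {
  kinetic_scheme(
    states = c("S1", "S2", "S3", "S4"),
    transitions = data.frame(
      id = c("IN", "A", "OUT", "C", "SL"),
      from = c("S1", "S2", "S3", "S4", "S1"),
      to = c("S2", "S3", "S4", "S1", "S3"),
      k_forward = c(50, 20, 10, 30, 0.05),
      k_backward = c(50 / K_in, 20, 10 / K_out, 30, 0.05)
    )
  )
}

# five-state ATP-synthase-like topology (two parallel two-step binding
# branches) with synthetic rates, for Kirchhoff branch checks
atpase_topology_scheme <- function() {
  fx <- load_fixture("atpase_5state")
  tr <- fx$topology[, c("id", "from", "to")]
  tr$k_forward <- c(500, 800, 300, 400, 40, 60)
  tr$k_backward <- c(0.5, 40, 30, 20, 10, 6)
  kinetic_scheme(fx$states, tr, temperature = fx$temperature_K)
}

random_case_grid <- function(n_cases, seed0 = 100) {
  lapply(seq_len(n_cases), function(i) {
    list(
      n_states = 3 + (i %% 6),
      n_extra = 1 + (i %% 3),
      seed = seed0 + i
    )
  })
}
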