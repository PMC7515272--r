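# Light-absorbing extension of the diagram formalism: a photocycle couples a
# light-activated excitation (L) and a non-radiative decay (D) as parallel
# edges between the ground and excited state, with the productive
# proton-transport pathway closing the cycle against a secondary force.

#' Photon energy
#'
#' @param lambda_nm Wavelength in nm.
#' @return List with `J` (energy per photon, J), `kJ_mol` (molar photon
#'   energy), and `hv_kBT` (`h nu / (k_B T)` at the given temperature).
#' @param temperature Temperature in kelvin for the dimensionless form.
#' @export
photon_energy <- function(lambda_nm, temperature = .DEFAULT_T) {
  cst <- physical_constants()
  hv <- cst$h * cst$c / (lambda_nm * 1e-9)
  list(
    J = hv,
    kJ_mol = hv * cst$N_A / 1000,
    hv_kBT = hv / (cst$k_B * temperature)
  )
}

#' Equilibrium constants of the light cycle
#'
#' For the excitation/decay pair between the ground and excited state the
#' relaxation-direction equilibrium constants are
#' `K_L = exp(h nu / (k_B T_R))` for the light transition (with `T_R` the
#' effective radiation temperature, `T_R > T`) and `K_D = exp(h nu /
#' (k_B T))` for the thermal (non-radiative) transition.  Because `T_R > T`,
#' `K_L < K_D`, and the light cycle carries the Carnot-like photon driving
#' force `R T ln(K_D / K_L) = N_A h nu (1 - T / T_R)` per mole.
#'
#' @param lambda_nm Photon wavelength, nm (alternative to `hv`).
#' @param hv Photon energy, J (used if `lambda_nm` missing).
#' @param temperature System temperature T, K.
#' @param T_R Effective radiation temperature, K; must exceed `temperature`.
#' @return List with `K_L`, `K_D`, `hv` (J) and `X_light_kJ_mol` (the molar
#'   photon driving force of the L-D cycle).
#' @examples
#' light_equilibrium_constants(lambda_nm = 570, T_R = 1570)
#' @export
light_equilibrium_constants <- function(lambda_nm = NULL, hv = NULL,
                                        temperature = .DEFAULT_T, T_R) {
  if (!(temperature > 0)) stop("temperature must be positive")
  if (!(T_R > temperature)) stop("T_R must exceed the system temperature")
  cst <- physical_constants()
  if (is.null(hv)) {
    if (is.null(lambda_nm)) stop("supply lambda_nm or hv")
    hv <- cst$h * cst$c / (lambda_nm * 1e-9)
  }
  K_L <- exp(hv / (cst$k_B * T_R))
  K_D <- exp(hv / (cst$k_B * temperature))
  list(
    K_L = K_L,
    K_D = K_D,
    hv = hv,
    X_light_kJ_mol = hv * cst$N_A * (1 - temperature / T_R) / 1000
  )
}

#' Close the productive cycle on the secondary force
#'
#' The product of equilibrium constants around the all-thermal charge
#' separation cycle (decay edge D traversed ground-to-excited, then the
#' productive transitions T1..T7) must equal `exp(X_sec / (R T))`, with
#' `X_sec` the secondary (output) force closing the cycle thermodynamically.
#' Given the other equilibrium constants this fixes the first productive
#' step's constant:
#' `K_1 = exp(X_sec / (R T)) * K_D / (K_2 ... K_7)`.
#'
#' The default orientation (`through = "decay"`) treats the charge
#' separation cycle as the thermal pathway; closure through the light edge
#' instead (`through = "light"`, using `K_L`) is exposed for completeness but
#' gives a pump that cannot run uphill at negative secondary force.
#'
#' @param K_rest Numeric vector of the other productive-cycle equilibrium
#'   constants (K_2 ... K_7).
#' @param X_sec_kJ_mol Secondary force, kJ/mol (negative when opposing).
#' @param K_D,K_L Relaxation-direction equilibrium constants of the D and L
#'   edges (see [light_equilibrium_constants()]).
#' @param temperature Temperature, K.
#' @param through `"decay"` (default) or `"light"`.
#' @return `K_1`, the equilibrium constant of the first productive
#'   transition.
#' @export
close_cycle_equilibrium_constant <- function(K_rest, X_sec_kJ_mol,
                                             K_D, K_L = NULL,
                                             temperature = .DEFAULT_T,
                                             through = c("decay", "light")) {
  through <- match.arg(through)
  if (any(!is.finite(K_rest) | K_rest <= 0)) stop("equilibrium constants must be positive")
  K_pair <- if (through == "decay") K_D else K_L
  if (is.null(K_pair) || !(K_pair > 0)) stop("need a positive K for the closing edge")
  target <- exp(X_sec_kJ_mol * 1000 / (.R_GAS * temperature))
  target * K_pair / prod(K_rest)
}

#' Assemble a photocycle kinetic scheme
#'
#' Builds the 8-state light-driven proton pump scheme: ground state (1),
#' excited state (2) connected to the ground state by the parallel light (L)
#' and non-radiative decay (D) edges, and productive transitions T1..T7
#' through the intermediates back to the ground state.  The L edge (declared
#' 1 -> 2) has forward rate `alpha01` (light absorption) and equilibrium
#' constant `1/K_L`; the D edge (declared 1 -> 2) has backward rate `k_d`
#' (decay) and equilibrium constant `1/K_D`.  `K_1` of the first productive
#' step is set by [close_cycle_equilibrium_constant()] so the thermal cycle
#' satisfies the secondary-force closure.
#'
#' @param alpha01 Light absorption rate, 1/s.
#' @param k_d Non-radiative decay rate, 1/s.
#' @param lambda_nm Photon wavelength, nm.
#' @param T_R Effective radiation temperature, K.
#' @param k1 Forward rate of the first productive transition, 1/s.
#' @param t_rates Data frame with columns `id`, `k_forward`, `K_eq` for the
#'   intermediate productive transitions T2..T6 (these are model inputs; no
#'   default is supplied).
#' @param k7,K7 Forward rate and equilibrium constant of the recovery
#'   transition T7.
#' @param X_sec_kJ_mol Secondary force, kJ/mol.
#' @param temperature Temperature, K.
#' @param closure_through Orientation flag passed to
#'   [close_cycle_equilibrium_constant()].
#' @return A `photocycle` object: a [kinetic_scheme()] with extra fields
#'   `light` (the light parameters) and transition roles.
#' @export
br_photocycle <- function(alpha01 = 100, k_d = 1e8, lambda_nm = 570,
                          T_R, k1 = 2.5e11, t_rates, k7 = 700, K7 = 2e7,
                          X_sec_kJ_mol, temperature = .DEFAULT_T,
                          closure_through = "decay") {
  t_rates <- as.data.frame(t_rates, stringsAsFactors = FALSE)
  if (!identical(t_rates$id, paste0("T", 2:6))) {
    stop("t_rates must supply transitions T2..T6 in order")
  }
  lc <- light_equilibrium_constants(
    lambda_nm = lambda_nm, temperature = temperature, T_R = T_R
  )
  K1 <- close_cycle_equilibrium_constant(
    K_rest = c(t_rates$K_eq, K7),
    X_sec_kJ_mol = X_sec_kJ_mol,
    K_D = lc$K_D, K_L = lc$K_L,
    temperature = temperature,
    through = closure_through
  )
  states <- data.frame(
    id = as.character(1:8),
    label = c("bR", "bR*", "K", "L", "M1", "M2", "N", "O"),
    stringsAsFactors = FALSE
  )
  transitions <- rbind(
    data.frame(
      id = "L", from = "1", to = "2", k_forward = alpha01,
      K_eq = 1 / lc$K_L, kind = "light", stringsAsFactors = FALSE
    ),
    data.frame(
      id = "D", from = "1", to = "2", k_forward = k_d / lc$K_D,
      K_eq = 1 / lc$K_D, kind = "nonradiative", stringsAsFactors = FALSE
    ),
    data.frame(
      id = "T1", from = "2", to = "3", k_forward = k1,
      K_eq = K1, kind = "chemical", stringsAsFactors = FALSE
    ),
    data.frame(
      id = t_rates$id, from = as.character(3:7), to = as.character(4:8),
      k_forward = t_rates$k_forward, K_eq = t_rates$K_eq, kind = "chemical",
      stringsAsFactors = FALSE
    ),
    data.frame(
      id = "T7", from = "8", to = "1", k_forward = k7,
      K_eq = K7, kind = "chemical", stringsAsFactors = FALSE
    )
  )
  sch <- kinetic_scheme(states, transitions, temperature = temperature,
                        x_sec = X_sec_kJ_mol)
  sch$light <- list(
    alpha01 = alpha01, k_d = k_d, lambda_nm = lambda_nm, T_R = T_R,
    K_L = lc$K_L, K_D = lc$K_D, hv = lc$hv,
    light_transition = "L", decay_transition = "D",
    output_transition = "T7", closure_through = closure_through
  )
  class(sch) <- c("photocycle", class(sch))
  sch
}

#' Synthetic photocycle parameterization
#'
#' A fully parameterized instance of [br_photocycle()] usable end-to-end in
#' examples and property tests.  The printed model parameters (`alpha01 =
#' 100`, `k_d = 1e8`, `k1 = 2.5e11`, `k7 = 700`, `K7 = 2e7`, 570 nm,
#' 298.16 K) are retained; the intermediate T2..T6 rate constants are *not*
#' published for this model, so the values here are synthetic stand-ins
#' chosen to give intermediate occupancies of a few percent each -- they do
#' not reproduce any published observable table, and are labelled
#' accordingly.
#'
#' @param X_sec_kJ_mol Secondary force, kJ/mol (default -18.84).
#' @param T_R Effective radiation temperature, K (default 1570).
#' @param ... Passed through to [br_photocycle()].
#' @return A `photocycle` object.
#' @export
synthetic_br_photocycle <- function(X_sec_kJ_mol = -18.84, T_R = 1570, ...) {
  t_rates <- data.frame(
    id = paste0("T", 2:6),
    k_forward = c(4600, 1550, 920, 710, 575),
    K_eq = c(6, 3.3, 2.6, 2.3, 1),
    stringsAsFactors = FALSE
  )
  br_photocycle(T_R = T_R, t_rates = t_rates,
                X_sec_kJ_mol = X_sec_kJ_mol, ...)
}

#' Photochemical quantum yield
#'
#' Ratio of the productive cycle flux (through the recovery transition) to
#' the photon absorption flux through the light transition, `J / J_L`.  The
#' difference `J_L - J` is the non-radiative leak through the decay edge.
#'
#' @param model A `photocycle` object.
#' @param fit Optional precomputed [steady_state()] of the model.
#' @return List with `yield` (dimensionless, in (0, 1] for a forward-running
#'   pump), `J` (output flux, 1/s) and `J_L` (light flux, 1/s).
#' @export
quantum_yield <- function(model, fit = NULL) {
  if (is.null(fit)) fit <- steady_state(model)
  tr <- fit$transitions
  J_L <- tr$J[tr$id == model$light$light_transition]
  J <- tr$J[tr$id == model$light$output_transition]
  if (J_L == 0) stop("zero light flux")
  list(yield = J / J_L, J = J, J_L = J_L)
}

#' Free-energy transduction efficiency of a photocycle
#'
#' Input power is the photon driving force of the light cycle times the
#' light flux, `X_photon J_L` with
#' `X_photon = R T ln(K_D / K_L) = N_A h nu (1 - T / T_R)` (the Carnot-like
#' exergy of the absorbed photons); output power is the secondary force
#' times the productive flux, `-X_sec J`.  With these conventions the
#' steady-state energy balance `T sigma_tot = X_photon J_L + X_sec J` holds
#' exactly, so `0 <= eta < 1` for any dissipative state.
#'
#' @param model A `photocycle` object.
#' @param fit Optional precomputed [steady_state()].
#' @return Efficiency `eta` (dimensionless).
#' @export
photocycle_efficiency <- function(model, fit = NULL) {
  if (is.null(fit)) fit <- steady_state(model)
  tr <- fit$transitions
  iL <- tr$id == model$light$light_transition
  iOut <- tr$id == model$light$output_transition
  X_sec <- model$forces$X_sec_kJ_per_mol * 1000
  X_photon <- .R_GAS * model$temperature *
    log(model$light$K_D / model$light$K_L)
  transduction_efficiency(
    X_in = X_photon, J_in = tr$J[iL],
    X_out = X_sec, J_out = tr$J[iOut]
  )
}

#' Scan the photocycle over the secondary force
#'
#' Rebuilds and re-solves the photocycle at each value of the secondary
#' force and reports the steady-state output flux, total entropy production,
#' transduction efficiency and quantum yield -- the three characteristic
#' curves of a light-driven pump: flux nearly constant over the pumping
#' regime, entropy production decreasing, efficiency rising from zero to an
#' interior maximum and collapsing beyond the stall force.
#'
#' @param model A `photocycle` object (template; its `X_sec` is replaced).
#' @param x_sec_grid Vector of secondary forces, kJ/mol.
#' @return An object of class `force_scan`: data frame with columns `X_sec`,
#'   `J`, `sigma_tot`, `eta`, `yield`.
#' @export
force_scan <- function(model, x_sec_grid) {
  li <- model$light
  rows <- lapply(x_sec_grid, function(xs) {
    m <- .rebuild_photocycle(model, xs)
    fit <- steady_state(m)
    qy <- quantum_yield(m, fit)
    data.frame(
      X_sec = xs,
      J = qy$J,
      sigma_tot = fit$sigma_tot,
      eta = photocycle_efficiency(m, fit),
      yield = qy$yield
    )
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  class(out) <- c("force_scan", class(out))
  out
}

# re-close the productive cycle for a new secondary force, keeping every
# other parameter of the template
.rebuild_photocycle <- function(model, x_sec) {
  li <- model$light
  tr <- model$transitions
  t_rates <- tr[tr$id %in% paste0("T", 2:6), c("id", "k_forward", "K_eq")]
  br_photocycle(
    alpha01 = li$alpha01, k_d = li$k_d, lambda_nm = li$lambda_nm,
    T_R = li$T_R, k1 = tr$k_forward[tr$id == "T1"], t_rates = t_rates,
    k7 = tr$k_forward[tr$id == "T7"], K7 = tr$K_eq[tr$id == "T7"],
    X_sec_kJ_mol = x_sec, temperature = model$temperature,
    closure_through = li$closure_through
  )
}
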