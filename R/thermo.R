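# Per-transition and aggregate thermodynamic observables at steady state.

#' Transition affinity
#'
#' `X_ij = R T ln(k_ij p_i / (k_ji p_j))`: the thermodynamic force felt
#' across a single transition at the stationary distribution.  Zero exactly
#' when the transition is equilibrated; summed around any cycle the state
#' probabilities telescope away, leaving the cycle affinity `R T ln K`.
#'
#' @param scheme A [kinetic_scheme()].
#' @param transition Transition id.
#' @param p Stationary distribution (computed if missing).
#' @return List with `X` (J/mol) and `X_RT` (dimensionless).
#' @export
transition_affinity <- function(scheme, transition, p = NULL) {
  if (is.null(p)) p <- stationary_probabilities(scheme)
  i <- .transition_row(scheme, transition)
  tr <- scheme$transitions[i, ]
  pi <- p[[tr$from]]; pj <- p[[tr$to]]
  if (!(pi > 0) || !(pj > 0)) stop("zero state probability")
  x_rt <- log(tr$k_forward * pi / (tr$k_backward * pj))
  list(X = .R_GAS * scheme$temperature * x_rt, X_RT = x_rt)
}

#' Transitional entropy production
#'
#' `sigma_ij = X_ij J_ij / T`, the entropy production density of one
#' transition at steady state; non-negative for every transition because the
#' affinity and the net flux always share sign.
#'
#' @param scheme A [kinetic_scheme()].
#' @param transition Transition id.
#' @param p Stationary distribution (computed if missing).
#' @return List with `sigma` (kJ mol^-1 K^-1 s^-1), `sigma_kB`
#'   (dimensionless form, 1/s), `X` (J/mol), `J` (1/s).
#' @export
transition_entropy_production <- function(scheme, transition, p = NULL) {
  if (is.null(p)) p <- stationary_probabilities(scheme)
  aff <- transition_affinity(scheme, transition, p)
  i <- .transition_row(scheme, transition)
  tr <- scheme$transitions[i, ]
  J <- tr$k_forward * p[[tr$from]] - tr$k_backward * p[[tr$to]]
  sigma_kB <- aff$X_RT * J
  list(
    sigma = .R_GAS * sigma_kB / 1000,
    sigma_kB = sigma_kB,
    X = aff$X,
    J = J
  )
}

#' Total entropy production
#'
#' Sum of the transitional entropy productions over all transitions.  At
#' steady state it equals the cycle decomposition
#' `sum_c J_c X_c / T` over any fundamental cycle basis (see
#' [cycle_decomposition()]), which serves as an independent identity check.
#'
#' @param scheme A [kinetic_scheme()].
#' @return List with `sigma_tot` (kJ mol^-1 K^-1 s^-1) and `sigma_tot_kB`
#'   (1/s).
#' @export
total_entropy_production <- function(scheme) {
  fit <- steady_state(scheme)
  list(sigma_tot = fit$sigma_tot, sigma_tot_kB = fit$sigma_tot_kB)
}

#' Cycle decomposition of the entropy production
#'
#' Chooses a spanning tree, treats every remaining transition as the chord of
#' a fundamental cycle, and returns per-cycle affinities
#' `X_c = R T ln(prod K)` and cycle fluxes (the chord's net flux).  At steady
#' state `T sigma_tot = sum_c J_c X_c` exactly.
#'
#' @param scheme A [kinetic_scheme()].
#' @return Data frame with one row per chord: `chord`, `X_RT`, `X_kJ_mol`,
#'   `J` and the implied `sigma_kB` contribution.
#' @export
cycle_decomposition <- function(scheme) {
  .assert_valid(scheme)
  g <- .graph(scheme)
  # greedy spanning tree
  parent <- seq_len(g$n)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  tree <- integer(0)
  chords <- integer(0)
  for (e in seq_along(g$from)) {
    a <- find(g$from[e]); b <- find(g$to[e])
    if (a == b) {
      chords <- c(chords, e)
    } else {
      parent[a] <- b
      tree <- c(tree, e)
    }
  }
  J_all <- transition_fluxes(scheme)  # stable diagram form
  rows <- lapply(chords, function(e) {
    cyc <- .fundamental_cycle(g, tree, e)
    x_rt <- sum(cyc$orientation * log(g$K[cyc$edges]))
    data.frame(
      chord = g$tid[e],
      X_RT = x_rt,
      X_kJ_mol = .R_GAS * scheme$temperature * x_rt / 1000,
      J = as.numeric(J_all[e]),
      sigma_kB = x_rt * as.numeric(J_all[e]),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

# cycle formed by chord e and the tree path joining its endpoints; the cycle
# is traversed in the chord's forward direction
.fundamental_cycle <- function(g, tree, e) {
  # path in the tree from g$to[e] back to g$from[e]
  target <- g$from[e]
  start <- g$to[e]
  # BFS over tree edges recording the incoming edge
  prev_e <- integer(g$n); prev_v <- integer(g$n)
  seen <- logical(g$n); seen[start] <- TRUE
  queue <- start
  while (length(queue)) {
    v <- queue[[1]]; queue <- queue[-1]
    if (v == target) break
    for (ed in tree) {
      u <- if (g$from[ed] == v) g$to[ed] else if (g$to[ed] == v) g$from[ed] else next
      if (!seen[u]) {
        seen[u] <- TRUE
        prev_e[u] <- ed; prev_v[u] <- v
        queue <- c(queue, u)
      }
    }
  }
  edges <- e
  orient <- 1L
  v <- target
  while (v != start) {
    ed <- prev_e[v]
    w <- prev_v[v]
    # cycle direction is chord-forward then start(=to) -> ... -> target(=from),
    # so the path edge between w (nearer start) and v is traversed w -> v
    orient <- c(orient, if (g$from[ed] == w) 1L else -1L)
    edges <- c(edges, ed)
    v <- w
  }
  list(edges = edges, orientation = orient)
}

#' Shannon entropy of a state distribution
#'
#' `S = -sum_i p_i ln p_i` in nats, with `0 ln 0 := 0`; bounded by `ln n`.
#'
#' @param p Numeric probability vector (normalized).
#' @return Entropy in nats.
#' @examples
#' shannon_entropy(rep(1 / 8, 8))  # log(8) = 2.079...
#' @export
shannon_entropy <- function(p) {
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Catalytic constants from the diagram solution
#'
#' For a single-cycle enzyme scheme with one substrate-binding step (whose
#' forward constant is `k_on * [S]`) and one product-release step (backward
#' constant held at the positive activity floor, i.e. the zero-product
#' limit), the diagram solution makes the per-enzyme cycle flux an exact
#' rectangular hyperbola in the substrate activity,
#' `J(S) = k_cat S / (K_M + S)`.  The hyperbola is identified exactly from
#' two substrate activities via the double-reciprocal (Lineweaver-Burk) line,
#' and the saturation limit is recomputed numerically at `S = 1e6 K_M` as a
#' mandatory cross-check.
#'
#' @param scheme A [kinetic_scheme()] whose binding step already carries an
#'   effective first-order constant `k_on * S0`.
#' @param binding Id of the substrate-binding transition.
#' @param release Id of the product-release transition (flux is measured
#'   through it).
#' @param k_on Second-order binding constant, 1/(M s).
#' @param saturation_factor Substrate excess over `K_M` used for the numeric
#'   saturation cross-check (default 1e6).
#' @return List with `k_cat` (1/s), `K_M` (M), `specificity`
#'   (`k_cat/K_M`, 1/(M s)), and `k_cat_numeric` (saturation-limit
#'   cross-check).
#' @export
catalytic_parameters <- function(scheme, binding, release, k_on,
                                 saturation_factor = 1e6) {
  ib <- .transition_row(scheme, binding)
  .transition_row(scheme, release)
  if (!is.finite(k_on) || k_on <= 0) stop("k_on must be positive")
  S0 <- scheme$transitions$k_forward[ib] / k_on

  flux_at <- function(S) {
    sch <- scheme
    tr <- sch$transitions
    tr$k_forward[ib] <- k_on * S
    tr$K_eq[ib] <- tr$k_forward[ib] / tr$k_backward[ib]
    sch$transitions <- tr
    fit <- steady_state(sch)
    fit$transitions$J[fit$transitions$id == release]
  }

  # exact double-reciprocal identification from two activities
  S1 <- S0; S2 <- 100 * S0
  r1 <- 1 / flux_at(S1); r2 <- 1 / flux_at(S2)
  slope <- (r1 - r2) / (1 / S1 - 1 / S2)
  intercept <- r1 - slope / S1
  k_cat <- 1 / intercept
  K_M <- slope / intercept
  k_cat_numeric <- flux_at(saturation_factor * K_M)
  list(
    k_cat = k_cat,
    K_M = K_M,
    specificity = k_cat / K_M,
    k_cat_numeric = k_cat_numeric
  )
}

#' Free-energy transduction efficiency
#'
#' `eta = (-X_out * J_out) / (X_in * J_in)` for a designated input
#' (driving) and output (driven) force-flux pair.  At static head
#' (`J_out = 0`) and at level flow (`X_out = 0`) the efficiency is zero; a
#' dissipative steady state has `0 <= eta < 1`.
#'
#' @param X_in,J_in Input force (J/mol) and conjugate flux (1/s).
#' @param X_out,J_out Output force (J/mol) and conjugate flux (1/s).
#' @return Efficiency (dimensionless, reported as 0 at static head / level
#'   flow).
#' @export
transduction_efficiency <- function(X_in, J_in, X_out, J_out) {
  power_in <- X_in * J_in
  if (!is.finite(power_in) || power_in == 0) stop("zero input power")
  eta <- (-X_out * J_out) / power_in
  if (J_out == 0 || X_out == 0) eta <- 0
  max(eta, 0)
}
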