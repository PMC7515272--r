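#' Nonequilibrium steady state of a kinetic scheme
#'
#' The central fitting function of the package: solves the stationary
#' distribution of a reversible kinetic scheme by Hill's diagram method and
#' assembles the full set of steady-state observables -- per-transition
#' affinities `X_ij = R T ln(k_ij p_i / (k_ji p_j))`, net fluxes
#' `J_ij = k_ij p_i - k_ji p_j`, transitional entropy productions
#' `sigma_ij = X_ij J_ij / T` (non-negative for every transition), the total
#' entropy production, and the Shannon entropy of the state occupancies.
#'
#' Quantities are reported in two unit systems: molar (`X` in kJ/mol,
#' `sigma` in kJ mol^-1 K^-1 s^-1, the convention of tabulated enzyme
#' observables) and dimensionless/per-molecule (`X_RT = X/(R T)`,
#' `sigma_kB = sigma/k_B` in 1/s).
#'
#' @param scheme A [kinetic_scheme()].
#' @param method `"diagram"` (spanning-tree solution, default) or `"oracle"`
#'   (GTH solve of the stationarity conditions, see
#'   [steady_state_oracle()]).
#' @return An object of class `steady_state`: list with `probabilities`,
#'   `transitions` (data frame: `id`, `from`, `to`, `J`, `X_RT`, `X_kJ_mol`,
#'   `sigma_kB`, `sigma`), `sigma_tot`, `sigma_tot_kB`, `shannon_entropy`,
#'   `temperature`, `scheme`.
#' @examples
#' fit <- steady_state(triangle_scheme(k_forward = c(2, 2, 2)))
#' coef(fit)             # stationary probabilities
#' fit$sigma_tot_kB      # log(2) for the symmetric triangle
#' @export
steady_state <- function(scheme, method = c("diagram", "oracle")) {
  method <- match.arg(method)
  .assert_valid(scheme)
  tr <- scheme$transitions
  TK <- scheme$temperature
  if (method == "diagram") {
    sol <- .diagram_solution(scheme)
    p <- sol$p
    J <- as.numeric(sol$J)
    X_RT <- as.numeric(sol$X_RT)
  } else {
    p <- steady_state_oracle(scheme)
    J <- as.numeric(tr$k_forward * p[tr$from] - tr$k_backward * p[tr$to])
    X_RT <- as.numeric(
      log(tr$k_forward) + log(p[tr$from]) -
        log(tr$k_backward) - log(p[tr$to])
    )
  }
  sigma_kB <- X_RT * J                      # 1/s
  sigma <- .R_GAS * sigma_kB / 1000         # kJ mol^-1 K^-1 s^-1
  obs <- data.frame(
    id = tr$id, from = tr$from, to = tr$to,
    J = J, X_RT = X_RT, X_kJ_mol = .R_GAS * TK * X_RT / 1000,
    sigma_kB = sigma_kB, sigma = sigma,
    stringsAsFactors = FALSE
  )
  structure(
    list(
      probabilities = p,
      transitions = obs,
      sigma_tot = sum(sigma),
      sigma_tot_kB = sum(sigma_kB),
      shannon_entropy = shannon_entropy(p),
      temperature = TK,
      method = method,
      scheme = scheme
    ),
    class = "steady_state"
  )
}

#' @export
print.steady_state <- function(x, ...) {
  cat(sprintf(
    "Steady state (%s method), %d states, T = %g K\n",
    x$method, length(x$probabilities), x$temperature
  ))
  cat(sprintf(
    "  sigma_tot = %.6g kJ mol^-1 K^-1 s^-1  (sigma_tot/k_B = %.6g 1/s)\n",
    x$sigma_tot, x$sigma_tot_kB
  ))
  cat(sprintf("  Shannon entropy S = %.4g nats\n", x$shannon_entropy))
  invisible(x)
}

#' @export
summary.steady_state <- function(object, digits = 4, ...) {
  x <- object
  cat(sprintf(
    "Nonequilibrium steady state (%s method), T = %g K\n\n",
    x$method, x$temperature
  ))
  cat("State probabilities:\n")
  print(round(x$probabilities, digits))
  cat("\nTransition observables:\n")
  obs <- x$transitions
  obs[, -(1:3)] <- signif(obs[, -(1:3)], digits)
  print(obs, row.names = FALSE)
  cat(sprintf(
    "\nsigma_tot = %.*g kJ mol^-1 K^-1 s^-1;  S = %.*g nats (max %.*g)\n",
    digits, x$sigma_tot, digits, x$shannon_entropy,
    digits, log(length(x$probabilities))
  ))
  invisible(x)
}

#' @export
coef.steady_state <- function(object, ...) object$probabilities

#' Serialize a steady-state report
#'
#' Writes the state probabilities and per-transition observables either as a
#' pair of TSV tables (`<path>_states.tsv`, `<path>_transitions.tsv`) or as a
#' single JSON document.
#'
#' @param fit A [steady_state()] object.
#' @param path Output path (without extension for TSV).
#' @param format `"tsv"` or `"json"`.
#' @return Invisibly, the path(s) written.
#' @export
write_report <- function(fit, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (format == "json") {
    doc <- list(
      temperature_K = fit$temperature,
      states = data.frame(
        state = names(fit$probabilities),
        p = as.numeric(fit$probabilities)
      ),
      transitions = data.frame(
        transition = fit$transitions$id,
        from = fit$transitions$from,
        to = fit$transitions$to,
        J_per_s = fit$transitions$J,
        X_kJ_mol = fit$transitions$X_kJ_mol,
        sigma = fit$transitions$sigma
      ),
      sigma_tot = fit$sigma_tot,
      shannon_entropy = fit$shannon_entropy
    )
    jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    return(invisible(path))
  }
  p1 <- paste0(path, "_states.tsv")
  p2 <- paste0(path, "_transitions.tsv")
  utils::write.table(
    data.frame(state = names(fit$probabilities), p = as.numeric(fit$probabilities)),
    p1, sep = "\t", quote = FALSE, row.names = FALSE
  )
  utils::write.table(
    data.frame(
      transition = fit$transitions$id, from = fit$transitions$from,
      to = fit$transitions$to, J_per_s = fit$transitions$J
    ),
    p2, sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(c(p1, p2))
}
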