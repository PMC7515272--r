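#' Kinetic cycle schemes
#'
#' A kinetic scheme is a multigraph of discrete enzyme functional states
#' connected by reversible first-order transitions.  Each transition `i -> j`
#' carries a forward rate constant `k_forward` (1/s), a backward rate constant
#' `k_backward` (1/s) and the equilibrium constant `K_eq = k_forward /
#' k_backward`.  Parallel transitions between the same pair of states are
#' allowed and remain distinct (a light and a thermal path between the same
#' two states, for example).  Rates are stored as effective first-order
#' constants; concentration scaling of pseudo-first-order steps is a
#' pre-processing step, see [with_concentrations()].
#'
#' @param states Either a character vector of state ids or a data frame with
#'   columns `id` and (optionally) `label`.
#' @param transitions A data frame with columns `id`, `from`, `to`,
#'   `k_forward` and at least one of `k_backward`, `K_eq` (the missing one is
#'   filled in from `K_eq = k_forward / k_backward`).  An optional `kind`
#'   column takes values `"chemical"` (default), `"light"` or
#'   `"nonradiative"`.
#' @param temperature Temperature in kelvin.  Default 298.16 K.
#' @param x_sec Optional secondary (output) force in kJ/mol, carried as
#'   metadata for free-energy transducing schemes.
#'
#' @return An object of class `kinetic_scheme`: a list with elements
#'   `states`, `transitions`, `temperature`, `forces`.
#' @seealso [validate_scheme()], [steady_state()], [read_scheme()]
#' @examples
#' sch <- triangle_scheme(k_forward = c(2, 2, 2), k_backward = c(1, 1, 1))
#' validate_scheme(sch)
#' @export
kinetic_scheme <- function(states, transitions, temperature = .DEFAULT_T,
                           x_sec = NULL) {
  if (is.character(states)) {
    states <- data.frame(id = states, label = states, stringsAsFactors = FALSE)
  }
  states <- as.data.frame(states, stringsAsFactors = FALSE)
  if (is.null(states$label)) states$label <- states$id
  states <- states[, c("id", "label")]

  transitions <- as.data.frame(transitions, stringsAsFactors = FALSE)
  if (is.null(transitions$kind)) transitions$kind <- "chemical"
  if (is.null(transitions$k_backward) && !is.null(transitions$K_eq)) {
    transitions$k_backward <- transitions$k_forward / transitions$K_eq
  }
  if (is.null(transitions$K_eq) && !is.null(transitions$k_backward)) {
    transitions$K_eq <- transitions$k_forward / transitions$k_backward
  }
  req <- c("id", "from", "to", "k_forward", "k_backward", "K_eq", "kind")
  missing_cols <- setdiff(req, names(transitions))
  if (length(missing_cols)) {
    stop("transitions lack column(s): ", paste(missing_cols, collapse = ", "))
  }
  transitions <- transitions[, req]

  obj <- structure(
    list(
      states = states,
      transitions = transitions,
      temperature = as.numeric(temperature),
      forces = list(X_sec_kJ_per_mol = x_sec),
      n_moles = 1
    ),
    class = "kinetic_scheme"
  )
  obj
}

#' @export
print.kinetic_scheme <- function(x, ...) {
  cat(sprintf(
    "Kinetic scheme: %d states, %d transitions, T = %g K\n",
    nrow(x$states), nrow(x$transitions), x$temperature
  ))
  tr <- x$transitions
  for (i in seq_len(nrow(tr))) {
    cat(sprintf(
      "  %-4s %s <-> %s  k+ = %.6g  k- = %.6g  K = %.6g  [%s]\n",
      tr$id[i], tr$from[i], tr$to[i],
      tr$k_forward[i], tr$k_backward[i], tr$K_eq[i], tr$kind[i]
    ))
  }
  if (!is.null(x$forces$X_sec_kJ_per_mol)) {
    cat(sprintf("  secondary force X_sec = %g kJ/mol\n", x$forces$X_sec_kJ_per_mol))
  }
  invisible(x)
}

#' Validate a kinetic scheme
#'
#' Checks every structural and thermodynamic invariant of a scheme and
#' reports all violations.  Validation never raises an error: a valid scheme
#' yields an empty character vector.
#'
#' Checked invariants: unique state and transition ids, transitions refer to
#' declared states, no self loops, strictly positive rate constants,
#' `K_eq == k_forward / k_backward` to 1e-12 relative, positive temperature,
#' and connectivity of the underlying graph.
#'
#' @param scheme A [kinetic_scheme()].
#' @return Character vector of violation messages, empty if the scheme is
#'   valid.
#' @export
validate_scheme <- function(scheme) {
  out <- character(0)
  st <- scheme$states
  tr <- scheme$transitions
  if (anyDuplicated(st$id)) {
    out <- c(out, sprintf(
      "duplicate state id(s): %s",
      paste(unique(st$id[duplicated(st$id)]), collapse = ", ")
    ))
  }
  if (anyDuplicated(tr$id)) {
    out <- c(out, sprintf(
      "duplicate transition id(s): %s",
      paste(unique(tr$id[duplicated(tr$id)]), collapse = ", ")
    ))
  }
  bad_ref <- !(tr$from %in% st$id) | !(tr$to %in% st$id)
  if (any(bad_ref)) {
    out <- c(out, sprintf(
      "transition(s) reference unknown states: %s",
      paste(tr$id[bad_ref], collapse = ", ")
    ))
  }
  loops <- tr$from == tr$to
  if (any(loops)) {
    out <- c(out, sprintf(
      "self-loop transition(s): %s", paste(tr$id[loops], collapse = ", ")
    ))
  }
  nonpos <- !(tr$k_forward > 0) | !(tr$k_backward > 0)
  if (any(nonpos)) {
    out <- c(out, sprintf(
      "non-positive rate constant(s) in transition(s): %s",
      paste(tr$id[nonpos], collapse = ", ")
    ))
  }
  keq_rel <- abs(tr$K_eq * tr$k_backward - tr$k_forward) /
    pmax(abs(tr$k_forward), .Machine$double.xmin)
  bad_k <- !is.finite(keq_rel) | keq_rel > 1e-12
  if (any(bad_k)) {
    out <- c(out, sprintf(
      "K_eq != k_forward/k_backward in transition(s): %s",
      paste(tr$id[bad_k], collapse = ", ")
    ))
  }
  if (!(scheme$temperature > 0)) {
    out <- c(out, "temperature must be > 0 K")
  }
  if (!isTRUE(all.equal(scheme$n_moles, 1))) {
    out <- c(out, "number of moles n must be 1")
  }
  # connectivity of the underlying (undirected) graph
  if (!any(bad_ref) && nrow(st) > 0) {
    if (!.is_connected(st$id, tr$from, tr$to)) {
      out <- c(out, "graph disconnected")
    }
  }
  out
}

.is_connected <- function(ids, from, to) {
  n <- length(ids)
  if (n <= 1) return(TRUE)
  idx <- seq_len(n)
  names(idx) <- ids
  adj <- vector("list", n)
  for (k in seq_along(from)) {
    i <- idx[[from[k]]]; j <- idx[[to[k]]]
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }
  seen <- logical(n)
  stack <- 1L
  seen[1L] <- TRUE
  while (length(stack)) {
    v <- stack[[length(stack)]]
    stack <- stack[-length(stack)]
    for (w in adj[[v]]) {
      if (!seen[w]) {
        seen[w] <- TRUE
        stack <- c(stack, w)
      }
    }
  }
  all(seen)
}

.assert_valid <- function(scheme) {
  v <- validate_scheme(scheme)
  if (length(v)) stop("invalid scheme: ", paste(v, collapse = "; "))
  invisible(scheme)
}

.transition_row <- function(scheme, transition) {
  i <- match(transition, scheme$transitions$id)
  if (is.na(i)) stop("unknown transition id: ", transition)
  i
}

#' Cycle affinity
#'
#' The thermodynamic force (affinity) of a closed walk through the scheme:
#' `X = R T sum_e orientation_e * ln K_e`, equivalently `R T ln K` with `K`
#' the product of equilibrium constants along the cycle.  `X = 0` exactly when
#' the cycle satisfies detailed balance (Wegscheider condition).
#'
#' @param scheme A [kinetic_scheme()].
#' @param transitions Character vector of transition ids forming a closed
#'   walk.
#' @param orientation Integer vector of +1 (traverse in the declared forward
#'   direction) / -1 (backward), recycled if length 1.
#' @return List with `X` (J/mol), `X_RT` (dimensionless `X/(R T)`), and `K`
#'   (overall equilibrium constant of the cycle).
#' @examples
#' sch <- triangle_scheme(k_forward = c(2, 2, 2), k_backward = c(1, 1, 1))
#' cycle_affinity(sch, c("T1", "T2", "T3"))$X_RT  # 3 * log(2)
#' @export
cycle_affinity <- function(scheme, transitions, orientation = 1L) {
  orientation <- rep_len(as.integer(orientation), length(transitions))
  idx <- vapply(transitions, .transition_row, integer(1), scheme = scheme)
  tr <- scheme$transitions[idx, ]
  # closed-walk check: traverse and make sure we return to the start
  at <- if (orientation[1] == 1L) tr$from[1] else tr$to[1]
  start <- at
  for (k in seq_along(idx)) {
    a <- if (orientation[k] == 1L) tr$from[k] else tr$to[k]
    b <- if (orientation[k] == 1L) tr$to[k] else tr$from[k]
    if (a != at) stop("not a cycle: walk breaks at transition ", tr$id[k])
    at <- b
  }
  if (at != start) stop("not a cycle: walk is open")
  x_rt <- sum(orientation * log(tr$K_eq))
  list(
    X = .R_GAS * scheme$temperature * x_rt,
    X_RT = x_rt,
    K = exp(x_rt)
  )
}

#' Apply concentrations to pseudo-first-order steps
#'
#' Binding and release steps of enzyme cycles are second-order: the effective
#' first-order rate constant is the product of the second-order constant and
#' the activity of the bound species (substrate on the forward side of a
#' binding step, product on the backward side of a release step).  This
#' replaces the designated rate by `rate2 * activity` and rescales `K_eq`
#' accordingly; the original scheme is not modified.
#'
#' Zero activities are disallowed: the diagram formalism assumes every
#' transition reversible, and the transition affinity diverges at a zero
#' backward rate.  Activities below `floor_activity` are raised to it.
#'
#' @param scheme A [kinetic_scheme()].
#' @param bindings A named list, one element per transition id, each a list
#'   with `rate2` (second-order constant, 1/(M s)), `activity` (M) and `side`
#'   (`"forward"` or `"backward"`, default `"forward"`).
#' @param floor_activity Positive floor applied to activities (default
#'   1e-30 M) so that reversibility is preserved.
#' @return A new `kinetic_scheme`.
#' @examples
#' sch <- mm_3state_scheme()
#' sch2 <- with_concentrations(sch, list(
#'   T1 = list(rate2 = 1e6, activity = 1e-3, side = "forward")
#' ))
#' sch2$transitions$k_forward[1]  # 1000 /s
#' @export
with_concentrations <- function(scheme, bindings, floor_activity = 1e-30) {
  tr <- scheme$transitions
  for (id in names(bindings)) {
    b <- bindings[[id]]
    i <- .transition_row(scheme, id)
    side <- if (is.null(b$side)) "forward" else b$side
    act <- b$activity
    if (is.na(act) || act < 0) stop("negative activity for transition ", id)
    act <- max(act, floor_activity)
    rate <- b$rate2 * act
    if (side == "forward") {
      tr$k_forward[i] <- rate
    } else if (side == "backward") {
      tr$k_backward[i] <- rate
    } else {
      stop("side must be 'forward' or 'backward'")
    }
    tr$K_eq[i] <- tr$k_forward[i] / tr$k_backward[i]
  }
  out <- scheme
  out$transitions <- tr
  out
}

#' Replace the forward rate constant of one transition
#'
#' Sets `k_forward` of the designated transition to `k`, keeping the
#' equilibrium constant fixed (so `k_backward = k / K_eq` co-varies), which is
#' the constraint under which transitional entropy production is maximized.
#'
#' @param scheme A [kinetic_scheme()].
#' @param transition Transition id.
#' @param k New forward rate constant, 1/s (> 0).
#' @return A new `kinetic_scheme`.
#' @export
set_forward_rate <- function(scheme, transition, k) {
  if (!is.finite(k) || k <= 0) stop("forward rate must be positive")
  i <- .transition_row(scheme, transition)
  tr <- scheme$transitions
  tr$k_forward[i] <- k
  tr$k_backward[i] <- k / tr$K_eq[i]
  scheme$transitions <- tr
  scheme
}

#' Read / write scheme definition files
#'
#' Scheme files are JSON with fields `states` (array of `{id, label}`),
#' `transitions` (array of `{id, from, to, k_forward, k_backward | K_eq,
#' kind}`), `temperature_K`, and optional `forces: {X_sec_kJ_per_mol}`.
#' Round-tripping a scheme through [write_scheme()] and [read_scheme()] is
#' lossless (rates serialized at full double precision).
#'
#' @param path File path.
#' @return `read_scheme` returns a [kinetic_scheme()]; `write_scheme`
#'   invisibly returns `path`.
#' @export
read_scheme <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  for (f in c("states", "transitions", "temperature_K")) {
    if (is.null(doc[[f]])) stop("scheme file missing field: ", f)
  }
  tr <- as.data.frame(doc$transitions, stringsAsFactors = FALSE)
  if (is.null(tr$k_forward)) stop("scheme file transitions lack field: k_forward")
  if (is.null(tr$k_backward) && is.null(tr$K_eq)) {
    stop("scheme file transitions need k_backward or K_eq")
  }
  x_sec <- if (!is.null(doc$forces)) doc$forces$X_sec_kJ_per_mol else NULL
  kinetic_scheme(
    states = as.data.frame(doc$states, stringsAsFactors = FALSE),
    transitions = tr,
    temperature = doc$temperature_K,
    x_sec = x_sec
  )
}

#' @param scheme A [kinetic_scheme()].
#' @rdname read_scheme
#' @export
write_scheme <- function(scheme, path) {
  doc <- list(
    states = scheme$states,
    transitions = scheme$transitions,
    temperature_K = scheme$temperature
  )
  if (!is.null(scheme$forces$X_sec_kJ_per_mol)) {
    doc$forces <- list(X_sec_kJ_per_mol = scheme$forces$X_sec_kJ_per_mol)
  }
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Export the scheme topology as an edge list
#'
#' Writes a TSV with columns `transition`, `from`, `to`, `k_forward`,
#' `k_backward`, `K_eq`, `kind`, suitable for external graph tools.
#'
#' @param scheme A [kinetic_scheme()].
#' @param path Output file path.
#' @export
write_edge_list <- function(scheme, path) {
  tr <- scheme$transitions
  names(tr)[1] <- "transition"
  utils::write.table(tr, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
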