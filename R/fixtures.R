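# Packaged kinetic scheme templates, published reference observables, and a
# seeded generator of thermodynamically consistent random schemes.

#' Small example schemes
#'
#' Constructors for the toy schemes used throughout examples and tests:
#' a two-state single-edge scheme, a three-state cycle (triangle), and a
#' reversible three-state Michaelis-Menten cycle (E -> ES -> EP -> E).
#'
#' @param k12,k21 Rates of the two-state scheme, 1/s.
#' @return A [kinetic_scheme()].
#' @export
two_state_scheme <- function(k12 = 2, k21 = 1) {
  kinetic_scheme(
    states = c("A", "B"),
    transitions = data.frame(
      id = "T1", from = "A", to = "B", k_forward = k12, k_backward = k21
    )
  )
}

#' @param k_forward,k_backward Length-3 rate vectors for the triangle's
#'   transitions T1: A->B, T2: B->C, T3: C->A.
#' @param temperature Temperature, K.
#' @rdname two_state_scheme
#' @export
triangle_scheme <- function(k_forward = c(2, 2, 2), k_backward = c(1, 1, 1),
                            temperature = .DEFAULT_T) {
  kinetic_scheme(
    states = c("A", "B", "C"),
    transitions = data.frame(
      id = c("T1", "T2", "T3"),
      from = c("A", "B", "C"),
      to = c("B", "C", "A"),
      k_forward = k_forward,
      k_backward = k_backward
    ),
    temperature = temperature
  )
}

#' @param k_f,k_b Length-3 rate vectors for binding (E->ES), catalysis
#'   (ES->EP) and release (EP->E).
#' @rdname two_state_scheme
#' @export
mm_3state_scheme <- function(k_f = c(1000, 100, 50),
                             k_b = c(100, 50, 0.01)) {
  kinetic_scheme(
    states = data.frame(
      id = c("E", "ES", "EP"),
      label = c("free enzyme", "enzyme-substrate", "enzyme-product")
    ),
    transitions = data.frame(
      id = c("T1", "T2", "T3"),
      from = c("E", "ES", "EP"),
      to = c("ES", "EP", "E"),
      k_forward = k_f,
      k_backward = k_b
    )
  )
}

.FIXTURE_IDS <- c("lactamase_3state", "tim_4state", "atpase_5state", "br_8state")

#' Load a packaged scheme fixture
#'
#' Returns the packaged template for one of the four enzyme models shipped
#' with the package: the three-state beta-lactamase cycle, the four-state
#' triosephosphate isomerase cycle, the five-state ATP synthase model and
#' the eight-state bacteriorhodopsin photocycle.  Each bundle carries the
#' scheme topology, the published model parameters that are available
#' (unavailable rate constants are `NA` and must be supplied by the user),
#' and tables of published reference observables used for regression
#' checks.  Loading never requires network access.
#'
#' @param id One of `"lactamase_3state"`, `"tim_4state"`, `"atpase_5state"`,
#'   `"br_8state"`.
#' @return A list with elements `id`, `topology` (data frame of transitions
#'   with possibly-`NA` rate slots), `states`, `parameters` (named list,
#'   `NA` marks required user input), and `regression` (list of data
#'   frames of published observables, when available).
#' @export
load_fixture <- function(id) {
  if (!id %in% .FIXTURE_IDS) {
    stop("unknown fixture id: ", id, " (known: ",
         paste(.FIXTURE_IDS, collapse = ", "), ")")
  }
  path <- system.file("extdata", paste0(id, ".json"), package = "mtepkin")
  doc <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  reg <- list()
  for (tab in c("observables")) {
    tsv <- system.file("extdata", paste0(id, "_", tab, ".tsv"),
                       package = "mtepkin")
    if (nzchar(tsv)) {
      reg[[tab]] <- utils::read.table(tsv, sep = "\t", header = TRUE,
                                      stringsAsFactors = FALSE)
    }
  }
  list(
    id = id,
    states = as.data.frame(doc$states, stringsAsFactors = FALSE),
    topology = as.data.frame(doc$transitions, stringsAsFactors = FALSE),
    parameters = doc$parameters,
    temperature_K = doc$temperature_K,
    regression = reg
  )
}

#' List the packaged fixtures
#' @return Character vector of fixture ids.
#' @export
list_fixtures <- function() .FIXTURE_IDS

#' Generate a seeded random kinetic scheme
#'
#' Draws a connected random scheme that is thermodynamically consistent by
#' construction: a random spanning tree with log-uniform rate constants
#' (every tree is detailed-balanced), plus `n_extra_edges` chord transitions
#' whose backward rates are closed so that each chord's fundamental cycle
#' realizes a prescribed dimensionless affinity `X/(R T)`.  Deterministic
#' given `seed`; the generator state of the session is restored on exit.
#'
#' @param n_states Number of states (3 to 8).
#' @param n_extra_edges Number of chord transitions (0 to 3); each creates
#'   one independent cycle.
#' @param seed Integer seed.
#' @param cycle_forces Dimensionless cycle affinities `X/(R T)` for the
#'   chords; recycled, or drawn uniformly from `force_range` when `NULL`.
#' @param force_range Range for drawn cycle affinities (default
#'   `c(-20, 20)`).
#' @param rate_range Log-uniform range of rate constants, 1/s (default
#'   `c(1e-3, 1e6)`).
#' @param temperature Temperature, K.
#' @return A [kinetic_scheme()] with attribute `prescribed_cycles`: a list
#'   with, per chord, the cycle's transitions, orientations and target
#'   `X/(R T)`.
#' @export
generate_random_scheme <- function(n_states, n_extra_edges = 1, seed = 21,
                                   cycle_forces = NULL,
                                   force_range = c(-20, 20),
                                   rate_range = c(1e-3, 1e6),
                                   temperature = .DEFAULT_T) {
  if (n_states < 3 || n_states > 8) stop("n_states must be in 3..8")
  if (n_extra_edges < 0 || n_extra_edges > 3) {
    stop("infeasible spec: n_extra_edges must be in 0..3")
  }
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(seed)

  ids <- paste0("S", seq_len(n_states))
  runif_log <- function(n) {
    exp(stats::runif(n, log(rate_range[1]), log(rate_range[2])))
  }
  # random spanning tree: attach each new vertex to a random earlier one
  from <- character(0); to <- character(0)
  for (v in 2:n_states) {
    u <- sample.int(v - 1, 1)
    from <- c(from, ids[u]); to <- c(to, ids[v])
  }
  m_tree <- length(from)
  kf <- runif_log(m_tree)
  kb <- runif_log(m_tree)
  tid <- paste0("E", seq_len(m_tree))
  transitions <- data.frame(
    id = tid, from = from, to = to, k_forward = kf, k_backward = kb,
    stringsAsFactors = FALSE
  )
  sch <- kinetic_scheme(ids, transitions, temperature = temperature)

  if (is.null(cycle_forces) && n_extra_edges > 0) {
    cycle_forces <- stats::runif(n_extra_edges, force_range[1], force_range[2])
  }
  prescribed <- list()
  if (n_extra_edges > 0) {
    cycle_forces <- rep_len(cycle_forces, n_extra_edges)
    for (c_i in seq_len(n_extra_edges)) {
      uv <- sample.int(n_states, 2)
      chord_id <- paste0("X", c_i)
      k_fwd <- runif_log(1)
      # tree path from uv[2] back to uv[1]; realize the prescribed force on
      # the fundamental cycle chord + path
      path <- .tree_path(sch, ids[uv[2]], ids[uv[1]])
      x_path <- sum(path$orientation * log(sch$transitions$K_eq[path$rows]))
      K_chord <- exp(cycle_forces[c_i] - x_path)
      sch$transitions <- rbind(sch$transitions, data.frame(
        id = chord_id, from = ids[uv[1]], to = ids[uv[2]],
        k_forward = k_fwd, k_backward = k_fwd / K_chord, K_eq = K_chord,
        kind = "chemical", stringsAsFactors = FALSE
      ))
      prescribed[[c_i]] <- list(
        transitions = c(chord_id, sch$transitions$id[path$rows]),
        orientation = c(1L, path$orientation),
        X_RT = cycle_forces[c_i]
      )
    }
  }
  attr(sch, "prescribed_cycles") <- prescribed
  sch
}

# walk the original tree (transitions E*) from state `a` to state `b`;
# returns transition row indices and traversal orientations
.tree_path <- function(scheme, a, b) {
  tr <- scheme$transitions
  tree_rows <- grep("^E", tr$id)
  # BFS
  prev <- list()
  seen <- a
  queue <- a
  while (length(queue)) {
    v <- queue[[1]]; queue <- queue[-1]
    if (v == b) break
    for (r in tree_rows) {
      u <- if (tr$from[r] == v) tr$to[r] else if (tr$to[r] == v) tr$from[r] else next
      if (!(u %in% seen)) {
        seen <- c(seen, u)
        prev[[u]] <- list(v = v, r = r)
        queue <- c(queue, u)
      }
    }
  }
  rows <- integer(0); orient <- integer(0)
  v <- b
  while (v != a) {
    st <- prev[[v]]
    # traversal direction along the path a -> b is st$v -> v
    orient <- c(if (tr$from[st$r] == st$v) 1L else -1L, orient)
    rows <- c(st$r, rows)
    v <- st$v
  }
  list(rows = rows, orientation = orient)
}
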