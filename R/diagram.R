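# Hill directional-diagram (King-Altman spanning tree) machinery.
#
# Internally a scheme is flattened to parallel integer/double vectors; all
# tree weights are accumulated on rates scaled by their geometric mean so
# that products stay O(1) even when rate constants span many orders of
# magnitude, and are rescaled at the end.

.graph <- function(scheme) {
  ids <- scheme$states$id
  tr <- scheme$transitions
  list(
    n = length(ids),
    ids = ids,
    tid = tr$id,
    from = match(tr$from, ids),
    to = match(tr$to, ids),
    kf = tr$k_forward,
    kb = tr$k_backward,
    K = tr$K_eq
  )
}

# union-find based spanning test for an edge subset
.is_spanning_forestless <- function(n, from, to) {
  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  for (k in seq_along(from)) {
    a <- find(from[k]); b <- find(to[k])
    if (a == b) return(FALSE) # cycle
    parent[a] <- b
  }
  TRUE # n-1 acyclic edges on n vertices => spanning tree
}

#' Spanning trees of the scheme multigraph
#'
#' Enumerates every spanning tree of the undirected multigraph underlying a
#' kinetic scheme.  Parallel transitions between the same pair of states are
#' distinct edges, so trees that differ only in which parallel edge they use
#' are counted separately.  These trees are the skeletons of Hill's
#' directional diagrams.  Exhaustive enumeration is exact and cheap for the
#' cycle sizes that occur in enzyme kinetics (at most ~10 states).
#'
#' @param scheme A [kinetic_scheme()].
#' @return A list of character vectors, each the set of transition ids of one
#'   spanning tree.
#' @examples
#' length(spanning_structures(triangle_scheme()))  # 3
#' @export
spanning_structures <- function(scheme) {
  .assert_valid(scheme)
  g <- .graph(scheme)
  idx <- .spanning_tree_indices(g)
  lapply(idx, function(e) g$tid[e])
}

.spanning_tree_indices <- function(g) {
  m <- length(g$from)
  k <- g$n - 1L
  if (k == 0L) return(list(integer(0)))
  combos <- utils::combn(m, k, simplify = FALSE)
  Filter(function(e) .is_spanning_forestless(g$n, g$from[e], g$to[e]), combos)
}

#' Spanning-tree count by the matrix-tree theorem
#'
#' Independent determinant-based count of spanning trees (Kirchhoff's
#' matrix-tree theorem on the multigraph Laplacian), used to cross-check the
#' exhaustive enumeration.
#'
#' @param scheme A [kinetic_scheme()].
#' @return Number of spanning trees (numeric).
#' @export
matrix_tree_count <- function(scheme) {
  g <- .graph(scheme)
  L <- matrix(0, g$n, g$n)
  for (k in seq_along(g$from)) {
    i <- g$from[k]; j <- g$to[k]
    L[i, j] <- L[i, j] - 1
    L[j, i] <- L[j, i] - 1
    L[i, i] <- L[i, i] + 1
    L[j, j] <- L[j, j] + 1
  }
  if (g$n == 1) return(1)
  round(det(L[-1, -1, drop = FALSE]))
}

# For one tree (edge index vector) return, for every root state, the product
# of scaled rate constants with all tree edges directed toward the root.
# Returns an n-vector of weights. kf, kb are pre-scaled rates.
.tree_root_weights <- function(g, tree, kf, kb) {
  n <- g$n
  # adjacency among tree edges
  adj_v <- vector("list", n)  # neighbour vertex
  adj_e <- vector("list", n)  # via which edge
  for (e in tree) {
    i <- g$from[e]; j <- g$to[e]
    adj_v[[i]] <- c(adj_v[[i]], j); adj_e[[i]] <- c(adj_e[[i]], e)
    adj_v[[j]] <- c(adj_v[[j]], i); adj_e[[j]] <- c(adj_e[[j]], e)
  }
  w <- numeric(n)
  for (root in seq_len(n)) {
    prod_w <- 1
    seen <- logical(n)
    seen[root] <- TRUE
    queue <- root
    while (length(queue)) {
      v <- queue[[1]]
      queue <- queue[-1]
      nb <- adj_v[[v]]; ed <- adj_e[[v]]
      for (q in seq_along(nb)) {
        u <- nb[q]
        if (!seen[u]) {
          seen[u] <- TRUE
          e <- ed[q]
          # edge directed u -> v (toward the root side)
          prod_w <- prod_w * if (g$from[e] == u) kf[e] else kb[e]
          queue <- c(queue, u)
        }
      }
    }
    w[root] <- prod_w
  }
  w
}

# Directional-diagram weight matrix: rows = trees, cols = states.
# Rates are scaled by their geometric mean; attr "scale" carries it.
.diagram_weights <- function(scheme) {
  g <- .graph(scheme)
  s <- exp(mean(log(c(g$kf, g$kb))))
  kf <- g$kf / s
  kb <- g$kb / s
  trees <- .spanning_tree_indices(g)
  W <- matrix(0, length(trees), g$n)
  for (t in seq_along(trees)) {
    W[t, ] <- .tree_root_weights(g, trees[[t]], kf, kb)
  }
  structure(W, scale = s, trees = trees)
}

#' Stationary probabilities by the diagram method
#'
#' The stationary probability of state `i` is proportional to the sum over
#' all spanning trees of the product of rate constants with the tree's edges
#' directed toward `i` (Hill's directional diagrams / the King-Altman
#' method).  Exact combinatorics: no linear solve is involved.
#'
#' @param scheme A [kinetic_scheme()].
#' @return Named numeric vector of probabilities summing to 1.
#' @examples
#' stationary_probabilities(two_state_scheme(k12 = 2, k21 = 1))  # 1/3, 2/3
#' @export
stationary_probabilities <- function(scheme) {
  .assert_valid(scheme)
  W <- .diagram_weights(scheme)
  p <- colSums(W)
  p <- p / sum(p)
  names(p) <- scheme$states$id
  p
}

#' Stationary probabilities from the master-equation null space
#'
#' Independent verification path for [stationary_probabilities()]: solves the
#' linear stationarity conditions (zero net probability flow into every
#' state, probabilities normalized) by GTH (Grassmann-Taksar-Heyman) state
#' reduction.  GTH is a subtraction-free elimination, so every stationary
#' probability is obtained with small *componentwise* relative error even
#' when the probabilities span tens of orders of magnitude -- which a plain
#' LU null-space solve cannot guarantee.
#'
#' @param scheme A [kinetic_scheme()].
#' @return Named numeric vector of probabilities summing to 1.
#' @export
steady_state_oracle <- function(scheme) {
  .assert_valid(scheme)
  g <- .graph(scheme)
  n <- g$n
  Q <- matrix(0, n, n) # Q[i, j] = total rate i -> j
  for (k in seq_along(g$from)) {
    Q[g$from[k], g$to[k]] <- Q[g$from[k], g$to[k]] + g$kf[k]
    Q[g$to[k], g$from[k]] <- Q[g$to[k], g$from[k]] + g$kb[k]
  }
  p <- .gth(Q)
  names(p) <- g$ids
  p
}

# GTH elimination on an off-diagonal rate matrix.
.gth <- function(Q) {
  n <- nrow(Q)
  if (n == 1) return(1)
  A <- Q
  for (k in n:2) {
    below <- seq_len(k - 1L)
    S <- sum(A[k, below])
    if (!(S > 0) || !is.finite(S)) stop("non-ergodic scheme")
    A[below, k] <- A[below, k] / S
    # rank-one positive update; diagonal is never used afterwards
    A[below, below] <- A[below, below] + A[below, k] %o% A[k, below]
  }
  p <- numeric(n)
  p[1] <- 1
  for (k in 2:n) {
    below <- seq_len(k - 1L)
    p[k] <- sum(p[below] * A[below, k])
  }
  p / sum(p)
}

#' Directional-diagram sums for one transition
#'
#' Decomposes the diagram solution with respect to a single transition
#' `e = (i, j)` with forward constant `k_ij` and equilibrium constant
#' `K_ij`.  Spanning trees either contain the edge `e` or not:
#'
#' * `b_ij`, `b_ji`: sums of directional-diagram weights for states `i`, `j`
#'   over the trees *excluding* `e`;
#' * `a`: the common reduced weight of the trees *containing* `e` (product of
#'   the other edges' rates directed toward `e`; directing toward `i` or
#'   toward `j` gives the same product, which is why a single `a` serves both
#'   states -- `a_ij = a_ji = a`);
#' * `Sigma_a`, `Sigma_b`: the decomposition of the normalization
#'   `Sigma = k_ij * Sigma_a + Sigma_b` over all states.
#'
#' These sums do not depend on `k_ij` or `k_ji`, so the steady state can be
#' reconstructed for any value of the forward constant at fixed `K_ij`:
#' `p_i = (b_ij + (k/K) a) / Sigma(k)`, `p_j = (b_ji + k a) / Sigma(k)`,
#' the net flux is `J = k (b_ij - b_ji / K) / Sigma(k)` and the affinity is
#' `X = R T ln((K b_ij + k a) / (b_ji + k a))`.  This reduction is what makes
#' the transitional entropy production a closed-form function of `k_ij`.
#'
#' For a bridge (cut) edge every spanning tree contains it, so
#' `b_ij = b_ji = 0`: the transition carries no cycle, its flux vanishes for
#' every `k`, and the result is flagged `degenerate`.
#'
#' @param scheme A [kinetic_scheme()].
#' @param transition Transition id.
#' @return An object of class `diagram_sums`: list with `transition`, `K`,
#'   `k_forward`, `a`, `b_ij`, `b_ji`, `Sigma_a`, `Sigma_b`, `degenerate`.
#'   Sums are in unscaled rate units (products of rate constants).
#' @export
diagram_sums <- function(scheme, transition) {
  .assert_valid(scheme)
  g <- .graph(scheme)
  e <- .transition_row(scheme, transition)
  i <- g$from[e]; j <- g$to[e]
  s <- exp(mean(log(c(g$kf, g$kb))))
  kf <- g$kf / s
  kb <- g$kb / s
  K <- g$K[e]
  trees <- .spanning_tree_indices(g)
  n <- g$n

  b_i <- 0; b_j <- 0; Sigma_b <- 0; a <- 0; Sigma_a <- 0
  for (t in trees) {
    if (e %in% t) {
      # remove e; remaining edges split the tree into the i-side and j-side
      rest <- setdiff(t, e)
      # reduced product: other edges directed toward the e endpoints
      side <- .component_of(g, rest, n)
      # direct every remaining edge toward its side's endpoint of e
      prod_w <- 1
      for (ed in rest) {
        u <- g$from[ed]; v <- g$to[ed]
        root <- if (side[u] == side[i]) i else j
        # orientation: which endpoint is nearer the root within this side
        prod_w <- prod_w * .edge_factor_toward(g, rest, ed, root, kf, kb)
      }
      a <- a + prod_w
      # contribution to Sigma of k-bearing trees: states on the j side see
      # the edge directed i -> j (factor k), states on the i side see j -> i
      # (factor k / K)
      w_rest <- .forest_root_weights(g, rest, kf, kb, side, i, j)
      Sigma_a <- Sigma_a +
        sum(w_rest[side == side[j]]) + sum(w_rest[side == side[i]]) / K
    } else {
      w <- .tree_root_weights(g, t, kf, kb)
      b_i <- b_i + w[i]
      b_j <- b_j + w[j]
      Sigma_b <- Sigma_b + sum(w)
    }
  }
  scale_full <- s^(n - 1)   # trees have n-1 edges
  scale_red <- s^(n - 2)    # reduced diagrams have n-2 edges
  structure(
    list(
      transition = scheme$transitions$id[e],
      K = K,
      k_forward = g$kf[e],
      a = a * scale_red,
      b_ij = b_i * scale_full,
      b_ji = b_j * scale_full,
      Sigma_a = Sigma_a * scale_red,
      Sigma_b = Sigma_b * scale_full,
      degenerate = (b_i == 0 && b_j == 0)
    ),
    class = "diagram_sums"
  )
}

# connected-component labels of vertices under an edge subset
.component_of <- function(g, edges, n) {
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (e in edges) {
      i <- g$from[e]; j <- g$to[e]
      m <- min(comp[i], comp[j])
      if (comp[i] != m || comp[j] != m) {
        comp[i] <- m; comp[j] <- m
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  comp
}

# factor contributed by edge `ed` when the forest `edges` is directed toward
# `root` within its component
.edge_factor_toward <- function(g, edges, ed, root, kf, kb) {
  # find which endpoint of ed is closer to root along the forest
  u <- g$from[ed]; v <- g$to[ed]
  # walk from u toward root without crossing ed; if reachable, v is the child
  if (.reachable(g, setdiff(edges, ed), u, root)) {
    # u on the root side: edge directed v -> u
    if (g$from[ed] == v) kf[ed] else kb[ed]
  } else {
    if (g$from[ed] == u) kf[ed] else kb[ed]
  }
}

.reachable <- function(g, edges, from, to, n = g$n) {
  if (from == to) return(TRUE)
  seen <- logical(n)
  seen[from] <- TRUE
  stack <- from
  while (length(stack)) {
    v <- stack[[length(stack)]]
    stack <- stack[-length(stack)]
    for (e in edges) {
      u <- if (g$from[e] == v) g$to[e] else if (g$to[e] == v) g$from[e] else next
      if (!seen[u]) {
        if (u == to) return(TRUE)
        seen[u] <- TRUE
        stack <- c(stack, u)
      }
    }
  }
  FALSE
}

# weights of the two-component forest (tree minus edge e) with each state s
# as root of its own component and the other component directed toward its
# endpoint of e
.forest_root_weights <- function(g, edges, kf, kb, side, i, j) {
  n <- g$n
  w <- numeric(n)
  for (s in seq_len(n)) {
    anchor <- if (side[s] == side[i]) j else i  # far-side endpoint of e
    own_root <- s
    prod_w <- 1
    for (ed in edges) {
      u <- g$from[ed]
      root <- if (side[u] == side[s]) own_root else anchor
      prod_w <- prod_w * .edge_factor_toward(g, edges, ed, root, kf, kb)
    }
    w[s] <- prod_w
  }
  w
}

#' Net transition fluxes at steady state
#'
#' `J_ij = k_ij p_i - k_ji p_j` for every transition.  When no distribution
#' is supplied the fluxes are evaluated in the numerically stable diagram
#' form `J_ij = (k_ij b_ij - k_ji b_ji) / Sigma`, where `b_ij`, `b_ji` sum
#' only the spanning trees *not* containing the edge: the contributions of
#' the trees containing it cancel identically in the flux and dropping them
#' analytically avoids catastrophic cancellation (a bridge edge yields an
#' exact zero).  At steady state the fluxes obey the Kirchhoff current law
#' at every state.
#'
#' @param scheme A [kinetic_scheme()].
#' @param p Optional stationary distribution (named as the states); when
#'   supplied, the plain `k_ij p_i - k_ji p_j` form is used.
#' @return Named numeric vector of net fluxes (1/s) per transition id.
#' @export
transition_fluxes <- function(scheme, p = NULL) {
  if (!is.null(p)) {
    tr <- scheme$transitions
    J <- tr$k_forward * p[tr$from] - tr$k_backward * p[tr$to]
    names(J) <- tr$id
    return(J)
  }
  .assert_valid(scheme)
  .diagram_fluxes(scheme)
}

# Stable per-edge steady-state observables from one pass over the trees.
#
# Fluxes: for each spanning tree t not containing edge e, the two
# directional diagrams differ only along the tree path between the edge's
# endpoints, so
#   kf w_i(t) - kb w_j(t) = kb w_j(t) * expm1(ln K_cycle(e, t))
# with K_cycle the equilibrium-constant product around the cycle formed by
# e and the tree path.  expm1 removes the exactly cancelling parts, so a
# detailed-balance cycle gives an exact zero and near-equilibrium edges do
# not lose precision to subtraction.
#
# Affinities: in kf N_i - kb N_j the contributions of the trees containing
# e cancel identically, leaving the same numerator, so
#   X_e / (R T) = ln(kf p_i / (kb p_j)) = log1p(num_e / (kb N_j))
# which is accurate in absolute terms even for nearly equilibrated edges.
.diagram_solution <- function(scheme) {
  g <- .graph(scheme)
  s <- exp(mean(log(c(g$kf, g$kb))))
  W <- .diagram_weights(scheme)
  trees <- attr(W, "trees")
  N <- colSums(W)
  Sigma <- sum(N)
  m <- length(g$from)
  lnK <- log(g$K)
  num <- numeric(m)
  abs_num <- numeric(m)   # accumulated magnitude: rounding bound of `num`
  for (t in seq_along(trees)) {
    out <- setdiff(seq_len(m), trees[[t]])
    for (e in out) {
      path <- .tree_path_edges(g, trees[[t]], g$to[e], g$from[e])
      x_cycle <- lnK[e] + sum(path$orientation * lnK[path$edges])
      term <- (g$kb[e] / s) * W[t, g$to[e]] * expm1(x_cycle)
      num[e] <- num[e] + term
      abs_num[e] <- abs_num[e] + abs(term)
    }
  }
  # the expm1 form is exact where the plain difference cancels (bridges,
  # near-equilibrium edges); but when a single cycle term dwarfs the net
  # flux its own rounding dominates and the plain difference kf N_i - kb N_j
  # is the better-conditioned expression.  Choose per edge by error bound.
  fwd <- (g$kf / s) * N[g$from]
  bwd <- (g$kb / s) * N[g$to]
  plain_bound <- pmax(fwd, bwd)
  use_plain <- abs_num > plain_bound
  num[use_plain] <- fwd[use_plain] - bwd[use_plain]
  p <- N / Sigma
  names(p) <- g$ids
  J <- num / Sigma * s
  names(J) <- g$tid
  # affinity: log1p on the stable numerator near equilibrium; when the
  # one-way flows differ by more than a factor ~2 the plain log ratio is
  # exact and immune to the numerator's rounding
  r <- num / bwd
  X_RT <- ifelse(!use_plain & abs(r) < 0.5, log1p(r), log(fwd) - log(bwd))
  names(X_RT) <- g$tid
  list(p = p, J = J, X_RT = X_RT)
}

.diagram_fluxes <- function(scheme) .diagram_solution(scheme)$J

# path from state a to state b along the given tree edges, with traversal
# orientation relative to each edge's declared direction
.tree_path_edges <- function(g, tree, a, b) {
  prev_e <- integer(g$n)
  prev_v <- integer(g$n)
  seen <- logical(g$n)
  seen[a] <- TRUE
  queue <- a
  while (length(queue)) {
    v <- queue[[1]]
    queue <- queue[-1]
    if (v == b) break
    for (ed in tree) {
      u <- if (g$from[ed] == v) g$to[ed] else if (g$to[ed] == v) g$from[ed] else next
      if (!seen[u]) {
        seen[u] <- TRUE
        prev_e[u] <- ed
        prev_v[u] <- v
        queue <- c(queue, u)
      }
    }
  }
  edges <- integer(0)
  orient <- integer(0)
  v <- b
  while (v != a) {
    ed <- prev_e[v]
    w <- prev_v[v]
    # the path runs a -> ... -> w -> v, so this edge is traversed w -> v
    orient <- c(if (g$from[ed] == w) 1L else -1L, orient)
    edges <- c(ed, edges)
    v <- w
  }
  list(edges = edges, orientation = orient)
}

#' Kirchhoff current-law residual
#'
#' Maximum over states of the net probability inflow, relative to the largest
#' flux magnitude; zero (to rounding) at any steady state.
#'
#' @param scheme A [kinetic_scheme()].
#' @param J Optional flux vector from [transition_fluxes()].
#' @return Scalar residual.
#' @export
kirchhoff_residual <- function(scheme, J = NULL) {
  if (is.null(J)) J <- transition_fluxes(scheme)
  tr <- scheme$transitions
  net <- numeric(nrow(scheme$states))
  names(net) <- scheme$states$id
  for (k in seq_len(nrow(tr))) {
    net[tr$from[k]] <- net[tr$from[k]] - J[k]
    net[tr$to[k]] <- net[tr$to[k]] + J[k]
  }
  jmax <- max(abs(J), .Machine$double.xmin)
  max(abs(net)) / jmax
}
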