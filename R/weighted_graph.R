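#' Weighted clustering coefficient (Onnela)
#'
#' Average over nodes of the Onnela per-node coefficient
#' \deqn{c_i = \frac{1}{k_i (k_i - 1)} \sum_{j \ne h}
#'   (\hat w_{ij}\, \hat w_{ih}\, \hat w_{jh})^{1/3},}
#' where \eqn{\hat w = w / \max(w)} and \eqn{k_i} is the number of
#' neighbours of node i.  Nodes with fewer than two neighbours contribute 0.
#' This is the geometric-mean triangle-intensity generalisation of the
#' binary clustering coefficient, the standard choice for coherence-weighted
#' brain graphs.
#'
#' @param W Symmetric non-negative weight matrix with zero diagonal.
#' @return Mean clustering coefficient, a scalar in [0, 1].
#' @export
weighted_clustering <- function(W) {
  W <- as_weight_matrix(W)
  check_weight_matrix(W, min_n = 3L)
  mx <- max(W)
  if (mx == 0) {
    warning("all-zero graph: clustering is 0")
    return(0)
  }
  W13 <- (W / mx)^(1 / 3)
  k <- rowSums(W > 0)
  cyc <- diag(W13 %*% W13 %*% W13)      # ordered closed triples per node
  denom <- k * (k - 1)
  ci <- ifelse(denom > 0, cyc / denom, 0)
  mean(ci)
}

#' Weighted characteristic path length
#'
#' Mean over unordered node pairs of the shortest weighted path length,
#' with edge length the inverse weight (`d = 1/w`): strong coherence means
#' a short functional distance.  On the dense coherence matrices this
#' package targets, values are close to 1.
#'
#' @param W Symmetric non-negative weight matrix with zero diagonal.
#' @return Mean shortest-path length (dimensionless).
#' @export
characteristic_path <- function(W) {
  W <- as_weight_matrix(W)
  check_weight_matrix(W, min_n = 2L)
  comp <- weight_components(W)
  if (max(comp) > 1L) {
    sizes <- tabulate(comp)
    small <- which(comp == which.min(sizes))
    stop(sprintf(
      "graph is disconnected: smallest isolated component has %d node(s) {%s}",
      min(sizes), paste(small, collapse = ", ")), call. = FALSE)
  }
  D <- shortest_distances(W)
  mean(D[upper.tri(D)])
}

# all-pairs shortest weighted distances under d = 1/w (igraph Dijkstra)
shortest_distances <- function(W) {
  g <- igraph::graph_from_adjacency_matrix(W, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  igraph::E(g)$weight <- 1 / igraph::E(g)$weight
  igraph::distances(g, algorithm = "dijkstra")
}

# connected components over positive weights, without igraph overhead
weight_components <- function(W) {
  n <- nrow(W)
  comp <- integer(n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] > 0L) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue)) {
      v <- queue[[1]]
      queue <- queue[-1]
      nb <- which(W[v, ] > 0 & comp == 0L)
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  comp
}

check_weight_matrix <- function(W, min_n = 2L, tol = 1e-10) {
  if (!is.matrix(W) || nrow(W) != ncol(W))
    stop("expected a square weight matrix", call. = FALSE)
  if (nrow(W) < min_n)
    stop(sprintf("graph must have at least %d nodes", min_n), call. = FALSE)
  if (anyNA(W) || any(!is.finite(W)))
    stop("weight matrix contains non-finite entries", call. = FALSE)
  if (max(abs(W - t(W))) > tol)
    stop("weight matrix must be symmetric", call. = FALSE)
  if (min(W) < 0)
    stop("weights must be non-negative", call. = FALSE)
  if (any(diag(W) != 0))
    stop("self-loops (non-zero diagonal) are not allowed", call. = FALSE)
  invisible(TRUE)
}

# upper-triangle pairs ordered by distance from the diagonal, then row
band_order <- function(n) {
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  ord <- order(idx[, 2] - idx[, 1], idx[, 1])
  idx[ord, , drop = FALSE]
}

#' Lattice null graph
#'
#' Deterministic weight-preserving rearrangement used as the segregation
#' reference in the Small-World Propensity: the multiset of off-diagonal
#' weights is kept exactly, but weights are reassigned so that the largest
#' weights sit nearest the matrix diagonal, filling it band by band.  This
#' concentrates weight in local neighbourhoods, maximising clustering for
#' the given weight distribution.
#'
#' @param W Symmetric non-negative weight matrix with zero diagonal.
#' @return A weight matrix of the same size with the same weight multiset.
#' @export
lattice_null <- function(W) {
  W <- as_weight_matrix(W)
  check_weight_matrix(W, min_n = 4L)
  n <- nrow(W)
  w <- sort(W[upper.tri(W)], decreasing = TRUE)
  pos <- band_order(n)
  L <- matrix(0, n, n)
  L[pos] <- w
  L + t(L)
}

#' Random null graph
#'
#' Weight-preserving randomisation used as the integration reference in the
#' Small-World Propensity: the off-diagonal weight multiset is placed on a
#' uniformly random permutation of the node pairs.  Symmetric and seeded.
#'
#' @param W Symmetric non-negative weight matrix with zero diagonal.
#' @param seed Integer seed (local to this call; the caller's RNG state is
#'   untouched).  `NULL` uses the current RNG stream.
#' @return A weight matrix of the same size with the same weight multiset.
#' @export
random_null <- function(W, seed = NULL) {
  W <- as_weight_matrix(W)
  check_weight_matrix(W, min_n = 4L)
  n <- nrow(W)
  w <- W[upper.tri(W)]
  perm <- with_local_seed(seed, sample.int(length(w)))
  R <- matrix(0, n, n)
  R[upper.tri(R)] <- w[perm]
  R + t(R)
}

# evaluate expr under a temporary seed without disturbing the global stream
with_local_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Small-World Propensity of a weighted graph
#'
#' Quantifies how far a weighted graph lies between a matched lattice
#' (maximally segregated) and a matched random graph (maximally integrated)
#' in terms of its clustering coefficient C and characteristic path length
#' L:
#' \deqn{\phi = 1 - \sqrt{\frac{\Delta_C^2 + \Delta_L^2}{2}},}
#' with \eqn{\Delta_C = (C_{latt} - C_{given}) / (C_{latt} - C_{rand})} and
#' \eqn{\Delta_L = (L_{given} - L_{rand}) / (L_{latt} - L_{rand})}, each
#' clamped to [0, 1] so that \eqn{\phi \in [0, 1]}.  Both null models
#' preserve the graph's weight multiset exactly; the random reference uses
#' the mean C and L over `n_null` independent weight permutations.  Values
#' above 0.6 are conventionally read as small-world topology.
#'
#' @param W Symmetric non-negative weight matrix with zero diagonal;
#'   must be connected.
#' @param n_null Number of random null graphs averaged (default 50).
#' @param seed Integer seed for the null ensemble.
#' @return A list of class `swp_result`: `phi`, `delta_C`, `delta_L`,
#'   `C_given`, `C_lattice`, `C_random`, `L_given`, `L_lattice`,
#'   `L_random`.
#' @export
small_world_propensity <- function(W, n_null = 50L, seed = NULL) {
  W <- as_weight_matrix(W)
  check_weight_matrix(W, min_n = 4L)
  stopifnot(n_null >= 1L)
  C_given <- weighted_clustering(W)
  L_given <- characteristic_path(W)
  Wl <- lattice_null(W)
  C_latt <- weighted_clustering(Wl)
  L_latt <- characteristic_path(Wl)
  nulls <- with_local_seed(seed, {
    vapply(seq_len(n_null), function(i) {
      R <- random_null(W, seed = NULL)
      # a permutation can in principle disconnect a sparse graph; resample
      tries <- 0L
      while (max(weight_components(R)) > 1L && tries < 20L) {
        R <- random_null(R, seed = NULL)
        tries <- tries + 1L
      }
      c(weighted_clustering(R), characteristic_path(R))
    }, numeric(2))
  })
  C_rand <- mean(nulls[1, ])
  L_rand <- mean(nulls[2, ])
  delta_C <- if (abs(C_latt - C_rand) < .Machine$double.eps^0.5) {
    warning("degenerate clustering nulls (C_lattice == C_random); delta_C = 0")
    0
  } else (C_latt - C_given) / (C_latt - C_rand)
  delta_L <- if (abs(L_latt - L_rand) < .Machine$double.eps^0.5) {
    warning("degenerate path nulls (L_lattice == L_random); delta_L = 0")
    0
  } else (L_given - L_rand) / (L_latt - L_rand)
  delta_C <- min(max(delta_C, 0), 1)
  delta_L <- min(max(delta_L, 0), 1)
  structure(list(
    phi = 1 - sqrt((delta_C^2 + delta_L^2) / 2),
    delta_C = delta_C, delta_L = delta_L,
    C_given = C_given, C_lattice = C_latt, C_random = C_rand,
    L_given = L_given, L_lattice = L_latt, L_random = L_rand
  ), class = "swp_result")
}

#' @export
print.swp_result <- function(x, ...) {
  cat(sprintf("<swp_result> phi = %.3f (delta_C = %.3f, delta_L = %.3f)\n",
              x$phi, x$delta_C, x$delta_L))
  cat(sprintf("  C: given %.4f, lattice %.4f, random %.4f\n",
              x$C_given, x$C_lattice, x$C_random))
  cat(sprintf("  L: given %.4f, lattice %.4f, random %.4f\n",
              x$L_given, x$L_lattice, x$L_random))
  invisible(x)
}
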