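#' Minimum spanning tree of a coherence graph
#'
#' The MST is the acyclic subgraph connecting all nodes at minimum total
#' functional distance, with distance the inverse coherence (`d = 1/w`);
#' equivalently, the maximum spanning tree of the coherence weights (any
#' strictly monotone decreasing transform of w yields the same tree).  It
#' is the loop-free backbone of the strongest couplings and avoids the
#' arbitrary-threshold problem of binarised graph analysis.
#'
#' Kruskal's algorithm with ties broken by lexicographic edge index
#' `(i, j)`, so the tree is unique and reproducible even when weights tie.
#'
#' @param W Symmetric positive-weight matrix with zero diagonal; the graph
#'   over the positive weights must be connected.
#' @return A list of class `spanning_tree`: `n`, `edges` (an `(n-1) x 2`
#'   matrix of node indices, `i < j`), `labels`.
#' @export
minimum_spanning_tree <- function(W) {
  labels <- rownames(W)
  W <- as_weight_matrix(W)
  check_weight_matrix(W, min_n = 2L)
  if (max(weight_components(W)) > 1L)
    stop("cannot span a disconnected graph", call. = FALSE)
  n <- nrow(W)
  idx <- which(upper.tri(W) & W > 0, arr.ind = TRUE)
  d <- 1 / W[idx]
  ord <- order(d, idx[, 1], idx[, 2])          # deterministic tie-break
  idx <- idx[ord, , drop = FALSE]
  # union-find
  parent <- seq_len(n)
  find <- function(v) {
    while (parent[v] != v) {
      parent[v] <<- parent[parent[v]]
      v <- parent[v]
    }
    v
  }
  edges <- matrix(0L, n - 1L, 2L)
  m <- 0L
  for (e in seq_len(nrow(idx))) {
    ri <- find(idx[e, 1])
    rj <- find(idx[e, 2])
    if (ri != rj) {
      parent[ri] <- rj
      m <- m + 1L
      edges[m, ] <- idx[e, ]
      if (m == n - 1L) break
    }
  }
  structure(list(n = n, edges = edges, labels = labels),
            class = "spanning_tree")
}

#' Construct a spanning tree from an explicit edge list
#'
#' @param n Node count.
#' @param edges `(n-1) x 2` matrix (or two-column data frame) of node
#'   indices.
#' @param labels Optional node labels.
#' @return A `spanning_tree`; errors if the edges do not form a tree.
#' @export
spanning_tree <- function(n, edges, labels = NULL) {
  edges <- as.matrix(edges)
  storage.mode(edges) <- "integer"
  if (nrow(edges) != n - 1L)
    stop(sprintf("a tree on %d nodes needs exactly %d edges", n, n - 1L),
         call. = FALSE)
  edges <- cbind(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
  t <- structure(list(n = n, edges = edges, labels = labels),
                 class = "spanning_tree")
  if (any(edges < 1L) || any(edges > n) || any(edges[, 1] == edges[, 2]))
    stop("edge indices out of range or self-loop", call. = FALSE)
  if (max(weight_components(tree_adjacency(t))) > 1L)
    stop("edges do not connect all nodes (not a tree)", call. = FALSE)
  t
}

#' @export
print.spanning_tree <- function(x, ...) {
  cat(sprintf("<spanning_tree> %d nodes, %d edges\n", x$n, nrow(x$edges)))
  invisible(x)
}

tree_adjacency <- function(t) {
  A <- matrix(0, t$n, t$n)
  A[t$edges] <- 1
  A[t$edges[, 2:1, drop = FALSE]] <- 1
  A
}

tree_neighbours <- function(t) {
  nb <- vector("list", t$n)
  for (e in seq_len(nrow(t$edges))) {
    i <- t$edges[e, 1]; j <- t$edges[e, 2]
    nb[[i]] <- c(nb[[i]], j)
    nb[[j]] <- c(nb[[j]], i)
  }
  nb
}

# BFS over the tree from root; returns list(order, parent, dist)
tree_bfs <- function(nb, n, root) {
  parent <- integer(n)
  dist <- rep(NA_integer_, n)
  ord <- integer(n)
  dist[root] <- 0L
  ord[1] <- root
  head <- 1L; tail <- 1L
  while (head <= tail) {
    v <- ord[head]
    for (u in nb[[v]]) {
      if (is.na(dist[u])) {
        dist[u] <- dist[v] + 1L
        parent[u] <- v
        tail <- tail + 1L
        ord[tail] <- u
      }
    }
    head <- head + 1L
  }
  list(order = ord, parent = parent, dist = dist)
}

#' Tree betweenness centrality (ordered-pair counts)
#'
#' For each node v, the number of ordered pairs of other nodes whose unique
#' tree path passes through v.  On a tree this equals
#' \eqn{(\sum_a s_a)^2 - \sum_a s_a^2} where \eqn{s_a} are the component
#' sizes left after deleting v.  The ordered-pair (unnormalised) convention
#' is used throughout: a leaf scores 0 and the centre of an n-node star
#' scores \eqn{(n-1)(n-2)}.
#'
#' @param t A `spanning_tree`.
#' @return Integer vector of per-node betweenness counts.
#' @export
tree_betweenness <- function(t) {
  nb <- tree_neighbours(t)
  bfs <- tree_bfs(nb, t$n, 1L)
  # subtree sizes under a rooting at node 1, in reverse BFS order
  size <- rep(1L, t$n)
  for (v in rev(bfs$order)) {
    if (v != 1L) size[bfs$parent[v]] <- size[bfs$parent[v]] + size[v]
  }
  bc <- numeric(t$n)
  for (v in seq_len(t$n)) {
    kids <- nb[[v]][nb[[v]] != bfs$parent[v] | v == 1L]
    s <- size[kids]
    if (v != 1L) s <- c(s, t$n - size[v])   # the component containing the root
    bc[v] <- sum(s)^2 - sum(s^2)
  }
  bc
}

#' Tree leaf fraction
#'
#' Number of degree-1 nodes divided by `n - 1`.  A star attains the maximum
#' of 1 (maximal integration); a path attains the minimum `2/(n-1)`.
#'
#' @param t A `spanning_tree`.
#' @return Scalar in (0, 1].
#' @export
leaf_fraction <- function(t) {
  stopifnot(t$n >= 2L)
  sum(tree_degree(t) == 1L) / (t$n - 1L)
}

#' Per-node tree degree
#' @param t A `spanning_tree`.
#' @return Integer vector of edge counts per node.
#' @export
tree_degree <- function(t) {
  tabulate(c(t$edges), nbins = t$n)
}

#' Tree eccentricity and diameter
#'
#' The eccentricity of a node is its maximal tree distance (in edges) to
#' any other node; the diameter is the maximal eccentricity.  High average
#' eccentricity marks a stretched, poorly integrated tree.
#'
#' @param t A `spanning_tree`.
#' @return A list with `eccentricity` (per node, in edges),
#'   `avg_eccentricity` and `diameter`.
#' @export
eccentricity_and_diameter <- function(t) {
  nb <- tree_neighbours(t)
  ecc <- vapply(seq_len(t$n),
                function(v) max(tree_bfs(nb, t$n, v)$dist), integer(1))
  list(eccentricity = ecc,
       avg_eccentricity = mean(ecc),
       diameter = max(ecc))
}

#' All tree integration metrics for one spanning tree
#'
#' Aggregates betweenness centrality, degree, leaf fraction, eccentricity
#' and diameter into one record.
#'
#' @param t A `spanning_tree`.
#' @return A list of class `tree_metrics`: `bc`, `max_bc`, `degree`,
#'   `leaf_fraction`, `eccentricity`, `avg_eccentricity`, `diameter`.
#' @export
tree_metrics <- function(t) {
  bc <- tree_betweenness(t)
  ed <- eccentricity_and_diameter(t)
  structure(list(
    bc = bc, max_bc = max(bc),
    degree = tree_degree(t),
    leaf_fraction = leaf_fraction(t),
    eccentricity = ed$eccentricity,
    avg_eccentricity = ed$avg_eccentricity,
    diameter = ed$diameter,
    labels = t$labels
  ), class = "tree_metrics")
}

#' @export
print.tree_metrics <- function(x, ...) {
  cat(sprintf(
    "<tree_metrics> max BC %g, leaf fraction %.3f, diameter %d, avg ecc %.2f\n",
    x$max_bc, x$leaf_fraction, x$diameter, x$avg_eccentricity))
  invisible(x)
}
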