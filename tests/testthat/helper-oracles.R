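# Independent brute-force oracles used to validate the graph and tree
# operations on small inputs.  They enumerate rather than optimise and share
# no code with the implementations they check.

# Onnela clustering by explicit loop over all node triples
oracle_clustering <- function(W) {
  n <- nrow(W)
  mx <- max(W)
  if (mx == 0) return(0)
  Wn <- W / mx
  ci <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(W[i, ] > 0)
    k <- length(nb)
    if (k < 2) next
    s <- 0
    for (j in nb) for (h in nb) {
      if (j != h) s <- s + (Wn[i, j] * Wn[i, h] * Wn[j, h])^(1 / 3)
    }
    ci[i] <- s / (k * (k - 1))
  }
  mean(ci)
}

# all-pairs shortest paths on d = 1/w by repeated full relaxation
oracle_path <- function(W) {
  n <- nrow(W)
  d <- ifelse(W > 0, 1 / W, Inf)
  diag(d) <- 0
  for (rep in seq_len(n)) {
    for (i in seq_len(n)) for (j in seq_len(n)) {
      through <- min(d[i, ] + d[, j])
      if (through < d[i, j]) d[i, j] <- through
    }
  }
  mean(d[upper.tri(d)])
}

# minimum spanning tree by enumerating all spanning edge subsets (small n)
oracle_mst_edges <- function(W) {
  n <- nrow(W)
  pairs <- which(upper.tri(W) & W > 0, arr.ind = TRUE)
  combos <- utils::combn(nrow(pairs), n - 1)
  best <- NULL
  best_cost <- Inf
  for (c in seq_len(ncol(combos))) {
    es <- pairs[combos[, c], , drop = FALSE]
    A <- matrix(0, n, n)
    A[es] <- 1
    A[es[, 2:1, drop = FALSE]] <- 1
    reach <- (diag(n) + A)
    for (s in seq_len(n)) reach <- pmin(reach %*% (diag(n) + A), 1)
    if (all(reach > 0)) {
      cost <- sum(1 / W[es])
      if (cost < best_cost - 1e-12) {
        best_cost <- cost
        best <- es
      }
    }
  }
  best[order(best[, 1], best[, 2]), , drop = FALSE]
}

# ordered-pair betweenness by enumerating every source-target path
oracle_tree_bc <- function(tree) {
  n <- tree$n
  A <- matrix(FALSE, n, n)
  A[tree$edges] <- TRUE
  A[tree$edges[, 2:1, drop = FALSE]] <- TRUE
  path_between <- function(s, u) {
    # depth-first search for the unique path
    stack <- list(s)
    seen <- rep(FALSE, n)
    parent <- integer(n)
    seen[s] <- TRUE
    while (length(stack)) {
      v <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      if (v == u) break
      for (w in which(A[v, ] & !seen)) {
        seen[w] <- TRUE
        parent[w] <- v
        stack[[length(stack) + 1L]] <- w
      }
    }
    path <- u
    while (path[1] != s) path <- c(parent[path[1]], path)
    path
  }
  bc <- numeric(n)
  for (s in seq_len(n)) for (u in seq_len(n)) {
    if (s == u) next
    inner <- setdiff(path_between(s, u), c(s, u))
    bc[inner] <- bc[inner] + 1
  }
  bc
}

# eccentricities from the tree's unweighted distance matrix via powers
oracle_tree_ecc <- function(tree) {
  n <- tree$n
  A <- matrix(0, n, n)
  A[tree$edges] <- 1
  A[tree$edges[, 2:1, drop = FALSE]] <- 1
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  reach <- diag(n)
  for (step in seq_len(n)) {
    reach <- pmin(reach %*% (A + diag(n)), 1)
    newly <- reach > 0 & !is.finite(D)
    D[newly] <- step
    if (all(is.finite(D))) break
  }
  apply(D, 1, max)
}

# random connected weighted graph with distinct weights
random_weighted_graph <- function(n, density = 0.7) {
  repeat {
    W <- matrix(0, n, n)
    m <- n * (n - 1) / 2
    w <- stats::runif(m)
    w[stats::runif(m) > density] <- 0
    W[upper.tri(W)] <- w
    W <- W + t(W)
    comp <- coherenet:::weight_components(W)
    if (max(comp) == 1L) return(W)
  }
}

# random labelled tree by sequential random attachment
random_tree <- function(n) {
  edges <- cbind(2:n, vapply(2:n, function(v) sample.int(v - 1L, 1L),
                             integer(1)))
  spanning_tree(n, edges)
}
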