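#' Welch two-sample t statistic
#'
#' Unequal-variance t statistic \eqn{(\bar x - \bar y) / \sqrt{s_x^2/n_x +
#' s_y^2/n_y}}, the robust default for comparing groups of unequal size.
#' Used as the observed and permuted statistic in [permutation_test()].
#'
#' @param x,y Numeric sample vectors.
#' @return The t statistic (NaN if both variances are zero).
#' @export
welch_t <- function(x, y) {
  nx <- length(x); ny <- length(y)
  se2 <- stats::var(x) / nx + stats::var(y) / ny
  (mean(x) - mean(y)) / sqrt(se2)
}

#' Two-sample permutation test
#'
#' Nonparametric two-sided test of a group difference: the observed Welch t
#' is referred to its permutation null, built by shuffling the pooled group
#' labels `n_perm` times.  The p-value uses the add-one convention
#' \eqn{p = (1 + \#\{|t^*| \ge |t_{obs}|\}) / (n_{perm} + 1)}, so the
#' smallest attainable p is `1/(n_perm + 1)` and p = 0 is impossible.
#'
#' @param x,y Numeric sample vectors (each of length >= 2).
#' @param n_perm Number of label shuffles (default 5000).
#' @param seed Integer seed; `NULL` uses the current RNG stream.
#' @return A list of class `group_test`: `t_obs`, `p`, `n_perm`,
#'   `mean_x`, `sd_x`, `mean_y`, `sd_y`, `n_x`, `n_y`.
#' @export
permutation_test <- function(x, y, n_perm = 5000L, seed = NULL) {
  stopifnot(length(x) >= 2L, length(y) >= 2L, n_perm >= 1L)
  if (anyNA(c(x, y))) stop("samples contain missing values", call. = FALSE)
  pooled <- c(x, y)
  nx <- length(x); n <- length(pooled)
  res <- list(t_obs = NA_real_, p = 1, n_perm = as.integer(n_perm),
              mean_x = mean(x), sd_x = stats::sd(x), n_x = nx,
              mean_y = mean(y), sd_y = stats::sd(y), n_y = length(y))
  if (stats::var(pooled) < .Machine$double.eps) {
    warning("zero pooled variance; p = 1")
    res$t_obs <- 0
    class(res) <- "group_test"
    return(res)
  }
  t_obs <- welch_t(x, y)
  # vectorised permutation null: draw all label shuffles as an index matrix
  t_perm <- with_local_seed(seed, {
    perm_stats <- numeric(n_perm)
    for (b in seq_len(n_perm)) {
      idx <- sample.int(n, nx)
      perm_stats[b] <- welch_t(pooled[idx], pooled[-idx])
    }
    perm_stats
  })
  t_perm[!is.finite(t_perm)] <- 0   # degenerate shuffles (tied halves)
  res$t_obs <- t_obs
  res$p <- (1 + sum(abs(t_perm) >= abs(t_obs))) / (n_perm + 1)
  class(res) <- "group_test"
  res
}

#' @export
print.group_test <- function(x, ...) {
  cat(sprintf("<group_test> t = %.3f, p = %.4g (%d permutations)\n",
              x$t_obs, x$p, x$n_perm))
  invisible(x)
}

#' Benjamini-Hochberg adjusted p-values (q-values)
#'
#' Step-up false discovery rate adjustment: with the p-values sorted
#' ascending, \eqn{q_{(i)} = \min_{j \ge i} p_{(j)} m / j}, capped at 1 and
#' returned in the input order.
#'
#' @param p Numeric vector of p-values in [0, 1].
#' @return Vector of q-values, same length and order as `p`.
#' @export
fdr_bh <- function(p) {
  if (anyNA(p) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  stats::p.adjust(p, method = "BH")
}

metric_columns <- c("swp", "L", "C", "max_bc", "leaf_fraction",
                    "diameter", "avg_eccentricity")

#' Compare the seven global graph indices between groups
#'
#' Runs one permutation test per index x band cell of a subject-level
#' metrics table (7 indices x 4 bands = 28 tests with the defaults) and
#' applies Benjamini-Hochberg FDR jointly across all cells.  Cases are the
#' `x` sample and controls the `y` sample, so `t_obs > 0` means a larger
#' value in cases.
#'
#' @param metrics A data frame as returned by [compute_metrics_table()]:
#'   columns `subject`, `group` (`"case"`/`"control"`), `band`, and the
#'   seven index columns `swp`, `L`, `C`, `max_bc`, `leaf_fraction`,
#'   `diameter`, `avg_eccentricity`.
#' @param n_perm Shuffles per test (default 5000).
#' @param seed Integer seed; each cell receives an independent substream.
#' @param alpha Significance level on the q-values (default 0.05).
#' @return A data frame with one row per cell: `index`, `band`, `t`, `p`,
#'   `q`, `significant`, group means and SDs.
#' @export
compare_global <- function(metrics, n_perm = 5000L, seed = NULL,
                           alpha = 0.05) {
  stopifnot(is.data.frame(metrics),
            all(c("subject", "group", "band", metric_columns) %in%
                  names(metrics)))
  groups <- sort(unique(metrics$group))
  if (length(groups) != 2L)
    stop("metrics table must contain exactly two groups", call. = FALSE)
  if (anyNA(metrics[metric_columns])) {
    bad <- unique(metrics$subject[rowSums(is.na(metrics[metric_columns])) > 0])
    stop("missing metric cells for subjects: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  bands <- unique(metrics$band)
  cells <- expand.grid(index = metric_columns, band = bands,
                       stringsAsFactors = FALSE)
  out <- lapply(seq_len(nrow(cells)), function(i) {
    idx <- cells$index[i]; bd <- cells$band[i]
    rows <- metrics[metrics$band == bd, ]
    x <- rows[[idx]][rows$group == "case"]
    y <- rows[[idx]][rows$group == "control"]
    tst <- permutation_test(x, y, n_perm = n_perm,
                            seed = if (is.null(seed)) NULL
                                   else substream_seed(seed, i))
    data.frame(index = idx, band = bd, t = tst$t_obs, p = tst$p,
               mean_case = tst$mean_x, sd_case = tst$sd_x,
               mean_control = tst$mean_y, sd_control = tst$sd_y,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out$q <- fdr_bh(out$p)
  out$significant <- out$q < alpha
  out
}

#' Compare nodal betweenness or eccentricity between groups
#'
#' Follow-up localisation analysis, gated on the global results: nodal
#' tests are run only in bands where the corresponding global summary
#' (`max_bc` for betweenness, `avg_eccentricity` for eccentricity) was
#' significant.  One permutation test per ROI, with Benjamini-Hochberg FDR
#' applied across the ROIs within each metric/band family.
#'
#' @param nodal A data frame with columns `subject`, `group`, `band`,
#'   `metric` (`"bc"` or `"eccentricity"`), and one column per ROI label
#'   (or a `node`/`value` long pair; see Details).
#' @param global Result of [compare_global()], used for gating.
#' @param n_perm,seed,alpha As in [compare_global()].
#' @param override Set `TRUE` to run for all bands regardless of gating.
#' @return A data frame with one row per ROI x metric x band tested.
#' @details `nodal` is expected in long format: columns `subject`, `group`,
#'   `band`, `metric`, `node`, `value` (one row per subject/band/ROI).
#' @export
compare_nodal <- function(nodal, global, n_perm = 5000L, seed = NULL,
                          alpha = 0.05, override = FALSE) {
  stopifnot(is.data.frame(nodal),
            all(c("subject", "group", "band", "metric", "node", "value") %in%
                  names(nodal)))
  gate <- list(
    bc = global$band[global$index == "max_bc" & global$significant],
    eccentricity = global$band[global$index == "avg_eccentricity" &
                                 global$significant]
  )
  req <- unique(nodal[, c("metric", "band")])
  out <- list()
  for (i in seq_len(nrow(req))) {
    met <- req$metric[i]; bd <- req$band[i]
    if (!override && !(bd %in% gate[[met]]))
      stop(sprintf(
        "nodal %s tests in band '%s' are gated: the global %s comparison was not significant (set override = TRUE to force)",
        met, bd, if (met == "bc") "max_bc" else "avg_eccentricity"),
        call. = FALSE)
    rows <- nodal[nodal$metric == met & nodal$band == bd, ]
    nodes <- unique(rows$node)
    fam <- lapply(seq_along(nodes), function(k) {
      nd <- rows[rows$node == nodes[k], ]
      tst <- permutation_test(
        nd$value[nd$group == "case"], nd$value[nd$group == "control"],
        n_perm = n_perm,
        seed = if (is.null(seed)) NULL
               else substream_seed(seed, i * 1000L + k))
      data.frame(metric = met, band = bd, node = nodes[k],
                 t = tst$t_obs, p = tst$p,
                 mean_case = tst$mean_x, mean_control = tst$mean_y,
                 stringsAsFactors = FALSE)
    })
    fam <- do.call(rbind, fam)
    fam$q <- fdr_bh(fam$p)        # FDR within the metric/band family
    fam$significant <- fam$q < alpha
    out[[length(out) + 1L]] <- fam
  }
  do.call(rbind, out)
}

# deterministic independent substream seeds below 2^31
substream_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + 7919 * as.numeric(k)) %% 2147483647)
}
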