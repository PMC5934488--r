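#' Construct and validate a connectivity matrix
#'
#' A connectivity matrix is a symmetric weighted adjacency matrix of
#' band-averaged lagged coherences: entries in [0, 1], zero diagonal, with
#' row/column names taken from the ROI atlas.
#'
#' @param W Square numeric matrix.
#' @param band A `band_spec` (or band name) the matrix belongs to, optional.
#' @param subject_id Subject label, optional.
#' @param labels Node labels; defaults to existing dimnames, else
#'   `build_roi_atlas()$label` when `nrow(W) == 84`.
#' @param tol Symmetry tolerance.
#' @return `W` with class `connectivity_matrix` and `band` / `subject_id`
#'   attributes.
#' @export
connectivity_matrix <- function(W, band = NULL, subject_id = NULL,
                                labels = NULL, tol = 1e-8) {
  if (!is.matrix(W) || !is.numeric(W) || nrow(W) != ncol(W))
    stop("W must be a square numeric matrix", call. = FALSE)
  if (anyNA(W) || any(!is.finite(W)))
    stop("W contains missing or non-finite entries", call. = FALSE)
  if (max(abs(W - t(W))) > tol)
    stop(sprintf("W is asymmetric beyond tolerance %g", tol), call. = FALSE)
  if (min(W) < -tol || max(W) > 1 + tol)
    stop("coherence entries must lie in [0, 1]", call. = FALSE)
  W <- (W + t(W)) / 2
  W[W < 0] <- 0
  W[W > 1] <- 1
  diag(W) <- 0
  if (is.null(labels)) {
    labels <- rownames(W)
    if (is.null(labels) && nrow(W) == 84L) labels <- build_roi_atlas()$label
  }
  if (!is.null(labels)) {
    if (length(labels) != nrow(W))
      stop("label count does not match matrix dimension", call. = FALSE)
    dimnames(W) <- list(labels, labels)
  }
  structure(W,
            band = if (inherits(band, "band_spec")) band$name else band,
            subject_id = subject_id,
            class = c("connectivity_matrix", "matrix", "array"))
}

#' @export
print.connectivity_matrix <- function(x, ...) {
  cat(sprintf("<connectivity_matrix> %d x %d", nrow(x), ncol(x)))
  if (!is.null(attr(x, "band"))) cat(", band:", attr(x, "band"))
  if (!is.null(attr(x, "subject_id"))) cat(", subject:", attr(x, "subject_id"))
  cat(sprintf("\n  mean off-diagonal weight %.4f\n",
              mean(x[upper.tri(x)])))
  invisible(x)
}

# strip class/attributes down to a plain base matrix
as_weight_matrix <- function(W) {
  W <- unclass(W)
  attr(W, "band") <- NULL
  attr(W, "subject_id") <- NULL
  W
}
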