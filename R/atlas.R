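#' Canonical 84-node Brodmann-area ROI atlas
#'
#' The network nodes are the cytoarchitectonic Brodmann areas (BA) that
#' standard EEG source-localisation software can resolve: BA 1-47 excluding
#' areas 12, 14, 15, 16 and 26, in both hemispheres, giving 42 areas per
#' hemisphere and 84 nodes in total.  Node order is fixed: left hemisphere
#' in ascending BA number, then right hemisphere in ascending BA number.
#' All adjacency matrices handled by this package use this ordering.
#'
#' @return A data frame with 84 rows and columns `label` (e.g. `"BA20 R"`),
#'   `ba` (integer Brodmann number) and `hemisphere` (`"L"` or `"R"`).
#' @examples
#' atlas <- build_roi_atlas()
#' nrow(atlas)                       # 84
#' table(atlas$hemisphere)           # 42 L, 42 R
#' @export
build_roi_atlas <- function() {
  excluded <- c(12L, 14L, 15L, 16L, 26L)
  ba <- setdiff(1:47, excluded)
  atlas <- data.frame(
    label = c(paste0("BA", ba, " L"), paste0("BA", ba, " R")),
    ba = rep(ba, 2L),
    hemisphere = rep(c("L", "R"), each = length(ba)),
    stringsAsFactors = FALSE
  )
  class(atlas) <- c("roi_atlas", "data.frame")
  atlas
}

#' Frequency-band definitions
#'
#' Default analysis bands: theta [4, 8), alpha [8, 12), beta1 [12, 20) and
#' beta2 [20, 30) Hz.  Band intervals are half-open on the right so the four
#' bands tile [4, 30) Hz without double-counting the shared edges.
#'
#' @param name Band label.
#' @param f_lo,f_hi Band edges in Hz, `0 < f_lo < f_hi`.
#' @return `band_spec()`: a list of class `band_spec`; `default_bands()`:
#'   a named list of the four default `band_spec` objects.
#' @examples
#' default_bands()$theta
#' @export
band_spec <- function(name, f_lo, f_hi) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!(is.finite(f_lo) && is.finite(f_hi) && f_lo > 0 && f_hi > f_lo))
    stop("band edges must satisfy 0 < f_lo < f_hi", call. = FALSE)
  structure(list(name = name, f_lo = f_lo, f_hi = f_hi),
            class = "band_spec")
}

#' @rdname band_spec
#' @export
default_bands <- function() {
  list(
    theta = band_spec("theta", 4, 8),
    alpha = band_spec("alpha", 8, 12),
    beta1 = band_spec("beta1", 12, 20),
    beta2 = band_spec("beta2", 20, 30)
  )
}

#' @export
print.band_spec <- function(x, ...) {
  cat(sprintf("<band_spec> %s: [%g, %g) Hz\n", x$name, x$f_lo, x$f_hi))
  invisible(x)
}
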