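#' Bundle segmented multichannel time series into an epoch set
#'
#' Resting EEG source time courses are analysed as a set of artifact-free
#' epochs of equal length.  The defaults mirror a standard quantitative-EEG
#' protocol: 250 Hz sampling, 25 epochs, 1024 samples (about 4.1 s) each.
#'
#' @param epochs List of numeric matrices, samples x channels, all the same
#'   shape.  Epochs of 1000-1250 samples are accepted and zero-padded to the
#'   next power of two (1024 or 2048) before the Fourier transform.
#' @param fs Sampling rate in Hz.
#' @param channel_labels Optional channel labels; defaults to the column
#'   names of the first epoch.
#' @return A list of class `epoch_set` with elements `epochs`, `fs`,
#'   `epoch_len`, `n_channels`, `channel_labels`.
#' @export
epoch_set <- function(epochs, fs = 250, channel_labels = NULL) {
  if (!is.list(epochs) || length(epochs) < 1L)
    stop("epochs must be a non-empty list of matrices", call. = FALSE)
  epochs <- lapply(epochs, function(e) {
    e <- as.matrix(e)
    storage.mode(e) <- "double"
    e
  })
  dims <- vapply(epochs, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("all epochs must have the same shape", call. = FALSE)
  if (dims[1, 1] < 2L)
    stop("epochs must contain at least 2 samples", call. = FALSE)
  if (any(!vapply(epochs, function(e) all(is.finite(e)), logical(1))))
    stop("epochs contain non-finite values", call. = FALSE)
  if (is.null(channel_labels)) channel_labels <- colnames(epochs[[1]])
  structure(list(epochs = epochs, fs = fs,
                 epoch_len = dims[1, 1], n_channels = dims[2, 1],
                 channel_labels = channel_labels),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  cat(sprintf("<epoch_set> %d epochs of %d samples x %d channels @ %g Hz\n",
              length(x$epochs), x$epoch_len, x$n_channels, x$fs))
  invisible(x)
}

#' Averaged-periodogram cross-spectral matrices
#'
#' Estimates the cross-spectral density between every pair of channels by
#' the mean tapered periodogram over epochs: each epoch is demeaned, Hann
#' tapered, zero-padded to a power of two, Fourier transformed, and the
#' per-bin outer products are averaged.  The result at every frequency bin
#' is Hermitian with a real non-negative diagonal.
#'
#' @param x An `epoch_set`.
#' @param taper `"hann"` (default) or `"none"`.
#' @return A list of class `cross_spectrum`: `S`, a complex array of
#'   dimension `n_channels x n_channels x n_bins`; `freqs`, bin centres in
#'   Hz (spacing `fs / nfft`); `n_epochs`; `fs`.
#' @export
estimate_cross_spectra <- function(x, taper = c("hann", "none")) {
  stopifnot(inherits(x, "epoch_set"))
  taper <- match.arg(taper)
  n <- x$epoch_len
  nfft <- max(2^ceiling(log2(n)), 2L)
  w <- if (taper == "hann") 0.5 - 0.5 * cos(2 * pi * seq_len(n) / (n + 1))
       else rep(1, n)
  nc <- x$n_channels
  n_bins <- nfft %/% 2L + 1L
  S <- array(0 + 0i, dim = c(nc, nc, n_bins))
  # accumulate per-bin outer products X(f) X(f)^H across epochs
  F_all <- vector("list", length(x$epochs))
  for (e in seq_along(x$epochs)) {
    ep <- x$epochs[[e]]
    ep <- sweep(ep, 2L, colMeans(ep)) * w
    if (nfft > n) ep <- rbind(ep, matrix(0, nfft - n, nc))
    F_all[[e]] <- stats::mvfft(ep)[seq_len(n_bins), , drop = FALSE]
  }
  for (b in seq_len(n_bins)) {
    Fb <- matrix(vapply(F_all, function(Fe) Fe[b, ], complex(nc)),
                 nrow = nc)                       # channels x epochs
    S[, , b] <- Fb %*% Conj(t(Fb)) / length(F_all)
  }
  structure(list(S = S, freqs = (seq_len(n_bins) - 1L) * x$fs / nfft,
                 n_epochs = length(x$epochs), fs = x$fs,
                 channel_labels = x$channel_labels),
            class = "cross_spectrum")
}

band_bins <- function(cs, band) {
  which(cs$freqs >= band$f_lo & cs$freqs < band$f_hi)
}

#' Band-averaged lagged coherence
#'
#' Lagged coherence quantifies the non-instantaneous component of the
#' coupling between two signals, suppressing the spurious zero-lag
#' connectivity produced by volume conduction (a static mixing of sources
#' contributes only to the real part of the cross-spectrum).  Per frequency
#' bin it is
#' \deqn{\lambda_{xy}(f) = \frac{\mathrm{Im}[S_{xy}(f)]^2}
#'   {S_{xx}(f)\,S_{yy}(f) - \mathrm{Re}[S_{xy}(f)]^2},}
#' clamped to [0, 1]; bins with a non-positive denominator (degenerate
#' spectra) contribute 0.  The band value is the mean over all bins whose
#' centres fall in `[f_lo, f_hi)`.
#'
#' @param cs A `cross_spectrum`.
#' @param band A `band_spec`.
#' @param subject_id Optional subject label attached to the result.
#' @return A `connectivity_matrix` (symmetric, zero diagonal, entries in
#'   [0, 1]).
#' @seealso [msc()] for the ordinary magnitude-squared coherence.
#' @export
lagged_coherence <- function(cs, band, subject_id = NULL) {
  stopifnot(inherits(cs, "cross_spectrum"), inherits(band, "band_spec"))
  bins <- band_bins(cs, band)
  if (length(bins) == 0L)
    stop(sprintf("band %s [%g, %g) contains no frequency bins",
                 band$name, band$f_lo, band$f_hi), call. = FALSE)
  nc <- dim(cs$S)[1]
  acc <- matrix(0, nc, nc)
  n_degenerate <- 0L
  for (b in bins) {
    Sb <- cs$S[, , b]
    P <- Re(diag(Sb))
    den <- outer(P, P) - Re(Sb)^2
    lam <- Im(Sb)^2 / den
    bad <- den <= 0 | !is.finite(lam)
    n_degenerate <- n_degenerate + sum(bad[upper.tri(bad)])
    lam[bad] <- 0
    lam[lam > 1] <- 1
    lam[lam < 0] <- 0
    acc <- acc + lam
  }
  if (n_degenerate > 0L)
    message(sprintf("lagged_coherence: %d degenerate pair-bins set to 0",
                    n_degenerate))
  W <- acc / length(bins)
  diag(W) <- 0
  connectivity_matrix(W, band = band, subject_id = subject_id,
                      labels = cs$channel_labels)
}

#' Band-averaged magnitude-squared coherence
#'
#' Ordinary coherence, `|S_xy|^2 / (S_xx S_yy)`, averaged over the band's
#' bins.  It does not discount zero-lag (volume-conducted) coupling and is
#' provided as the reference against which the lagged measure's mixing
#' suppression can be demonstrated.
#'
#' @inheritParams lagged_coherence
#' @return A `connectivity_matrix`.
#' @export
msc <- function(cs, band, subject_id = NULL) {
  stopifnot(inherits(cs, "cross_spectrum"), inherits(band, "band_spec"))
  bins <- band_bins(cs, band)
  if (length(bins) == 0L)
    stop(sprintf("band %s [%g, %g) contains no frequency bins",
                 band$name, band$f_lo, band$f_hi), call. = FALSE)
  nc <- dim(cs$S)[1]
  acc <- matrix(0, nc, nc)
  for (b in bins) {
    Sb <- cs$S[, , b]
    P <- Re(diag(Sb))
    den <- outer(P, P)
    coh <- Mod(Sb)^2 / den
    coh[den <= 0 | !is.finite(coh)] <- 0
    coh[coh > 1] <- 1
    acc <- acc + coh
  }
  W <- acc / length(bins)
  diag(W) <- 0
  connectivity_matrix(W, band = band, subject_id = subject_id,
                      labels = cs$channel_labels)
}
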