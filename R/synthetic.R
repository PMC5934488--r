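#' Truncated-normal draws on [0, 1]
#'
#' Coherence weights are bounded, so the generator draws weights from a
#' normal distribution truncated to the unit interval (by inverse-CDF
#' sampling, exact, no rejection).
#'
#' @param n Number of draws.
#' @param mean,sd Location and scale of the parent normal (recycled).
#' @return Numeric vector in [0, 1].
#' @keywords internal
rtruncnorm01 <- function(n, mean, sd) {
  if (all(sd <= 0)) return(pmin(pmax(rep_len(mean, n), 0), 1))
  sd <- pmax(sd, 1e-12)
  lo <- stats::pnorm(0, mean, sd)
  hi <- stats::pnorm(1, mean, sd)
  stats::qnorm(lo + stats::runif(n) * (hi - lo), mean, sd)
}

#' Generate one small-world coherence matrix
#'
#' Builds an 84-node (by default) weighted graph with the structure the
#' analysis assumes of band-limited resting-state coherence: strong
#' coherence within a lattice neighbourhood of the `k` nearest nodes in
#' the atlas ordering, background coherence that decays with node distance
#' towards a weak
#' noise floor (functional coupling falls off with cortical distance), and
#' per-pair noise.  A fraction `p_rewire` of the weights is then relocated
#' by a random permutation among a random subset of node pairs, sending
#' some strong local weights to distant pairs (long-range shortcuts).
#'
#' With a small rewiring fraction this yields small-world structure
#' (clustering near the lattice null, path length near the random null,
#' Small-World Propensity above 0.6); `p_rewire = 1` is exactly a uniform
#' permutation of all off-diagonal weights, i.e. the random null.
#'
#' @param n Node count (default 84, the ROI atlas size).
#' @param k Lattice neighbourhood size: each node is strongly coupled to
#'   its `k` nearest neighbours in node order (`k/2` on each side;
#'   default 6).
#' @param p_rewire Fraction of off-diagonal weights relocated by random
#'   permutation (default 0.1).
#' @param weight_mean,weight_sd Truncated-normal mean and sd of the strong
#'   within-neighbourhood coherences (defaults 0.85, 0.04).
#' @param noise_mean,noise_sd Mean and sd of the distant-pair noise floor
#'   (defaults 0.05, 0.015).
#' @param decay Node-distance e-folding (in index spans beyond `k/2`) of the
#'   background coherence profile between `weight_mean` and `noise_mean`
#'   (default 4).
#' @param seed Integer seed; `NULL` uses the current RNG stream.
#' @param labels Node labels; defaults to the ROI atlas when `n == 84`.
#' @param band,subject_id Passed to [connectivity_matrix()].
#' @return A `connectivity_matrix`.
#' @export
generate_sw_matrix <- function(n = 84L, k = 6L, p_rewire = 0.1,
                               weight_mean = 0.85, weight_sd = 0.04,
                               noise_mean = 0.05, noise_sd = 0.015,
                               decay = 4, seed = NULL, labels = NULL,
                               band = NULL, subject_id = NULL) {
  stopifnot(n >= 4L, k >= 2L, k < n, p_rewire >= 0, p_rewire <= 1,
            decay > 0)
  with_local_seed(seed, {
    idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    span <- idx[, 2] - idx[, 1]
    excess <- pmax(span - k %/% 2L, 0)
    prof <- noise_mean + (weight_mean - noise_mean) * exp(-excess / decay)
    sdv <- ifelse(excess == 0, weight_sd, noise_sd)
    w <- rtruncnorm01(nrow(idx), prof, sdv)
    # relocate a fraction of the weights by permutation over random pairs;
    # p_rewire = 1 permutes the whole weight multiset uniformly
    sel <- which(stats::runif(nrow(idx)) < p_rewire)
    if (length(sel) > 1L) w[sel] <- w[sel][sample.int(length(sel))]
    W <- matrix(0, n, n)
    W[idx] <- w
    W <- W + t(W)
    if (stats::sd(W[upper.tri(W)]) < 1e-12)
      warning("all weights (near-)equal: the spanning tree will be tie-broken")
    if (is.null(labels) && n == 84L) labels <- build_roi_atlas()$label
    connectivity_matrix(W, labels = labels, band = band,
                        subject_id = subject_id)
  })
}

#' Specify a group effect for the cohort generator
#'
#' An effect perturbs the case-group generator in one band:
#' \describe{
#'   \item{`clustering`}{scales the node-distance `decay` of the coherence
#'     profile by `1 + direction * magnitude`, widening (positive) or
#'     shrinking (negative) the strongly clustered neighbourhood and with
#'     it the weighted clustering coefficient.}
#'   \item{`path`}{scales all off-diagonal weights by
#'     `1 / (1 + direction * magnitude)` so the inverse-weight path length
#'     moves by the stated relative amount while normalised clustering is
#'     untouched.}
#'   \item{`diameter`}{scales the rewiring fraction by
#'     `1 - direction * magnitude`: fewer long-range shortcuts stretch the
#'     spanning tree (positive direction = larger diameter).}
#'   \item{`hub_bc` / `nodal_bc:<label>`}{scales one ROI's couplings to all
#'     others by `1 + direction * magnitude`, pulling the spanning tree's
#'     shortest paths through it (`hub_bc` uses the default hub
#'     `"BA20 R"`).}
#' }
#'
#' @param band Band name the effect applies to (e.g. `"theta"`).
#' @param target One of `"clustering"`, `"path"`, `"diameter"`,
#'   `"hub_bc"`, or `"nodal_bc:<ROI label>"`.
#' @param magnitude Non-negative relative effect size.
#' @param direction `+1` (cases higher) or `-1` (cases lower).
#' @return A list of class `effect_spec`.
#' @export
effect_spec <- function(band, target, magnitude, direction = 1) {
  stopifnot(magnitude >= 0, direction %in% c(-1, 1))
  base <- sub(":.*$", "", target)
  if (!base %in% c("clustering", "path", "diameter", "hub_bc", "nodal_bc"))
    stop("unknown effect target: ", target, call. = FALSE)
  if (base == "nodal_bc" && !grepl(":", target, fixed = TRUE))
    stop("nodal_bc target must name an ROI, e.g. 'nodal_bc:BA20 R'",
         call. = FALSE)
  structure(list(band = band, target = target, magnitude = magnitude,
                 direction = direction), class = "effect_spec")
}

default_generator_params <- function() {
  list(n = 84L, k = 6L, p_rewire = 0.1,
       weight_mean = 0.85, weight_sd = 0.04,
       noise_mean = 0.05, noise_sd = 0.015,
       decay = 4, subject_jitter = 0.03)
}

apply_effects_to_params <- function(params, effects, band) {
  hub_scale <- NULL
  for (ef in effects) {
    if (ef$band != band) next
    delta <- ef$direction * ef$magnitude
    base <- sub(":.*$", "", ef$target)
    if (base == "clustering") {
      params$decay <- (params$decay %||% 4) * (1 + delta)
    } else if (base == "path") {
      params$global_scale <- (params$global_scale %||% 1) / (1 + delta)
    } else if (base == "diameter") {
      params$p_rewire <- min(max(params$p_rewire * (1 - delta), 0), 1)
    } else {
      node <- if (base == "hub_bc") "BA20 R" else sub("^nodal_bc:", "", ef$target)
      hub_scale <- rbind(hub_scale,
                         data.frame(node = node, scale = 1 + delta))
    }
  }
  params$hub_scale <- hub_scale
  params
}

`%||%` <- function(a, b) if (is.null(a)) b else a

generate_subject_matrix <- function(params, band, subject_id, seed) {
  W <- generate_sw_matrix(
    n = params$n, k = params$k, p_rewire = params$p_rewire,
    weight_mean = min(params$weight_mean, 0.98),
    weight_sd = params$weight_sd,
    noise_mean = params$noise_mean, noise_sd = params$noise_sd,
    decay = params$decay %||% 4,
    seed = seed, band = band, subject_id = subject_id)
  M <- as_weight_matrix(W)
  if (!is.null(params$hub_scale)) {
    for (r in seq_len(nrow(params$hub_scale))) {
      i <- match(params$hub_scale$node[r], rownames(W))
      if (is.na(i))
        stop("effect targets unknown ROI: ", params$hub_scale$node[r],
             call. = FALSE)
      M[i, ] <- M[i, ] * params$hub_scale$scale[r]
      M[, i] <- M[i, ]
    }
  }
  M <- M * (params$global_scale %||% 1)
  M[M > 1] <- 1
  M[M < 0] <- 0
  diag(M) <- 0
  connectivity_matrix(M, labels = rownames(W), band = band,
                      subject_id = subject_id)
}

#' Generate a synthetic two-group cohort of coherence matrices
#'
#' Emulates the study design the analysis targets: 19 cases and 52
#' controls, each with one 84-node coherence matrix per band (theta, alpha,
#' beta1, beta2).  Controls are drawn from the base small-world generator;
#' cases from the same generator with the listed [effect_spec()] effects
#' applied.  Between-subject variability enters through per-subject jitter
#' of the strong-weight mean and the rewiring fraction.  Fully seeded and
#' reproducible.
#'
#' @param n_case,n_ctrl Group sizes (defaults 19 and 52).
#' @param effects List of [effect_spec()] objects (default none).
#' @param params Base generator parameters; see
#'   `default_generator_params()`.
#' @param bands Character vector of band names (default the four standard
#'   bands).
#' @param seed Integer seed.
#' @return A list of class `synthetic_cohort`: `subjects` (data frame with
#'   `subject`, `group`), `matrices` (nested list,
#'   `matrices[[subject]][[band]]`), `bands`, `params`, `effects`, `seed`.
#' @export
generate_cohort <- function(n_case = 19L, n_ctrl = 52L, effects = list(),
                            params = default_generator_params(),
                            bands = names(default_bands()), seed = NULL) {
  stopifnot(n_case >= 2L, n_ctrl >= 2L)
  if (inherits(effects, "effect_spec")) effects <- list(effects)
  tgt <- vapply(effects, function(e) paste(e$band, e$target), character(1))
  if (anyDuplicated(tgt))
    stop("duplicate effect targets: ", paste(tgt[duplicated(tgt)],
                                             collapse = ", "), call. = FALSE)
  subjects <- data.frame(
    subject = c(sprintf("case%02d", seq_len(n_case)),
                sprintf("ctrl%02d", seq_len(n_ctrl))),
    group = rep(c("case", "control"), c(n_case, n_ctrl)),
    stringsAsFactors = FALSE)
  matrices <- with_local_seed(seed, {
    lapply(seq_len(nrow(subjects)), function(s) {
      is_case <- subjects$group[s] == "case"
      jit_mean <- stats::rnorm(1, 0, params$subject_jitter)
      jit_rewire <- stats::rnorm(1, 0, params$subject_jitter / 2)
      out <- lapply(bands, function(bd) {
        p <- params
        p$weight_mean <- p$weight_mean + jit_mean
        p$p_rewire <- min(max(p$p_rewire + jit_rewire, 0), 1)
        if (is_case) p <- apply_effects_to_params(p, effects, bd)
        generate_subject_matrix(
          p, band = bd, subject_id = subjects$subject[s],
          seed = NULL)
      })
      names(out) <- bands
      out
    })
  })
  names(matrices) <- subjects$subject
  structure(list(subjects = subjects, matrices = matrices, bands = bands,
                 params = params, effects = effects, seed = seed),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> %d cases + %d controls, bands: %s\n",
              sum(x$subjects$group == "case"),
              sum(x$subjects$group == "control"),
              paste(x$bands, collapse = ", ")))
  invisible(x)
}

#' Generate coupled band-limited ROI time series
#'
#' Produces an [epoch_set()] of stochastic narrowband oscillations for
#' end-to-end tests of the spectral connectivity path.  Every channel
#' receives independent broadband noise; each coupling shares one
#' band-limited source between a channel pair with the second channel
#' delayed by `lag` samples, so the pair exhibits genuine time-lagged
#' coupling in that band.  An optional zero-lag common source mixed into
#' all channels emulates volume conduction: it inflates ordinary coherence
#' but, having no lag, is suppressed by lagged coherence.
#'
#' @param n_channels Number of channels (use 84 for atlas-sized runs).
#' @param couplings List of lists with elements `pair` (two channel
#'   indices), `band` (a `band_spec`), `lag` (samples, non-zero) and
#'   `strength` (amplitude of the shared source relative to the noise).
#' @param fs Sampling rate in Hz (default 250).
#' @param n_epochs Number of epochs (default 25).
#' @param epoch_len Samples per epoch (default 1024).
#' @param zero_lag_mixing Amplitude of a common broadband source added to
#'   all channels at lag 0 (default 0, none).
#' @param noise_sd Independent noise standard deviation (default 1).
#' @param seed Integer seed.
#' @param labels Optional channel labels.
#' @return An `epoch_set`.
#' @export
generate_coupled_timeseries <- function(n_channels, couplings = list(),
                                        fs = 250, n_epochs = 25L,
                                        epoch_len = 1024L,
                                        zero_lag_mixing = 0, noise_sd = 1,
                                        seed = NULL, labels = NULL) {
  for (cp in couplings) {
    stopifnot(length(cp$pair) == 2L, cp$lag != 0,
              inherits(cp$band, "band_spec"))
    if (cp$band$f_hi >= fs / 2)
      stop("coupling band exceeds the Nyquist frequency", call. = FALSE)
  }
  with_local_seed(seed, {
    pad <- 200L   # absorb filter transients and lags
    epochs <- lapply(seq_len(n_epochs), function(e) {
      X <- matrix(stats::rnorm(epoch_len * n_channels, 0, noise_sd),
                  epoch_len, n_channels)
      for (cp in couplings) {
        src <- narrowband_noise(epoch_len + pad, fs, cp$band)
        a <- cp$strength %||% 2
        i <- cp$pair[1]; j <- cp$pair[2]
        X[, i] <- X[, i] + a * src[pad + seq_len(epoch_len)]
        X[, j] <- X[, j] + a * src[pad + seq_len(epoch_len) - cp$lag]
      }
      if (zero_lag_mixing > 0) {
        common <- stats::rnorm(epoch_len)
        X <- X + zero_lag_mixing * common   # same source, lag 0, all channels
      }
      colnames(X) <- labels
      X
    })
    epoch_set(epochs, fs = fs, channel_labels = labels)
  })
}

# unit-variance Gaussian noise band-limited by frequency-domain masking
narrowband_noise <- function(n, fs, band) {
  nfft <- 2^ceiling(log2(n))
  f <- (seq_len(nfft) - 1) * fs / nfft
  f <- pmin(f, fs - f)                      # two-sided frequency axis
  mask <- as.numeric(f >= band$f_lo & f < band$f_hi)
  z <- stats::fft(stats::rnorm(nfft))
  x <- Re(stats::fft(z * mask, inverse = TRUE)) / nfft
  x <- x[seq_len(n)]
  x / stats::sd(x)
}
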