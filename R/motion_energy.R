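#' Frame stacks
#'
#' An ordered sequence of 2D grayscale frames with a frame rate, the input
#' of the motion-energy model. Color input is reduced to grayscale by
#' channel averaging.
#'
#' @param frames numeric array: `height x width x n_frames`, or
#'   `height x width x channels x n_frames` (averaged over channels).
#' @param rate frame rate in Hz.
#' @return object of class `frame_stack` with fields `frames` and `rate`.
#' @export
frame_stack <- function(frames, rate = 10) {
  if (length(dim(frames)) == 4L) {
    frames <- apply(frames, c(1, 2, 4), mean)
  }
  if (length(dim(frames)) != 3L) stopf("frames must be a h x w x t array")
  if (dim(frames)[3L] < 2L) stopf("a frame stack needs at least 2 frames")
  if (rate <= 0) stopf("frame rate must be positive")
  structure(list(frames = frames, rate = rate), class = "frame_stack")
}

#' Motion-energy filter-bank configuration
#'
#' Defines a small, documented bank of quadrature-pair spatiotemporal Gabor
#' filters: each channel is one (spatial frequency, motion direction,
#' temporal frequency) triple, plus one static (temporally low-pass,
#' non-oriented) channel. Orientations encode preferred motion direction in
#' degrees; spatial frequencies are in cycles per image width; temporal
#' frequencies in Hz. The PCA fields configure [pca_reduce_and_pool()]:
#' either a fixed component count or the smallest count reaching a variance
#' target.
#'
#' @param spatial_freqs cycles per image width.
#' @param temporal_freqs temporal frequencies in Hz (all > 0; direction
#'   coverage comes from the orientation set).
#' @param orientations preferred motion directions in degrees.
#' @param temporal_window temporal filter length in frames (odd).
#' @param pca_components fixed number of retained components (default mode).
#' @param pca_variance variance target in (0, 1]; used when
#'   `pca_components` is `NULL`.
#' @param log_energy log-transform (log(1 + x)) energies before PCA.
#' @return object of class `motion_energy_config`.
#' @export
motion_energy_config <- function(spatial_freqs = c(2, 4, 8),
                                 temporal_freqs = c(1, 2),
                                 orientations = c(0, 90, 180, 270),
                                 temporal_window = 9,
                                 pca_components = 128,
                                 pca_variance = NULL,
                                 log_energy = FALSE) {
  if (length(spatial_freqs) < 1L || any(spatial_freqs <= 0)) {
    stopf("need at least one positive spatial frequency")
  }
  if (any(temporal_freqs <= 0)) stopf("temporal frequencies must be > 0 (the static channel is added automatically)")
  temporal_window <- as.integer(temporal_window)
  if (temporal_window < 3L || temporal_window %% 2L == 0L) {
    stopf("temporal_window must be an odd integer >= 3")
  }
  if (is.null(pca_components)) {
    if (is.null(pca_variance) || pca_variance <= 0 || pca_variance > 1) {
      stopf("pca_variance must lie in (0, 1] when no fixed component count is given")
    }
  } else if (pca_components < 1L) {
    stopf("pca_components must be >= 1")
  }
  structure(list(spatial_freqs = spatial_freqs,
                 temporal_freqs = temporal_freqs,
                 orientations = orientations,
                 temporal_window = temporal_window,
                 pca_components = pca_components,
                 pca_variance = pca_variance,
                 log_energy = isTRUE(log_energy)),
            class = "motion_energy_config")
}

# Complex spatial Gabor kernels for one spatial frequency: an isotropic
# Gaussian envelope carrying plane waves along each motion direction.
# Returns kernel matrix (pixels x orientations), the support radius, and the
# tiling stride.
spatial_gabor_bank <- function(sf, orientations, img_dim) {
  lambda <- min(img_dim) / sf            # wavelength in pixels
  sigma <- lambda / 2
  rs <- min(ceiling(2 * sigma), floor((min(img_dim) - 1) / 2))
  ax <- (-rs):rs
  gx <- matrix(rep(ax, each = length(ax)), ncol = length(ax))   # column offset
  gy <- matrix(rep(ax, times = length(ax)), ncol = length(ax))  # row offset
  env <- exp(-(gx^2 + gy^2) / (2 * sigma^2))
  kernels <- vapply(orientations, function(th) {
    a <- th * pi / 180
    phase <- 2 * pi * (gx * cos(a) + gy * sin(a)) / lambda
    as.vector(env * exp(1i * phase))
  }, complex(length(ax)^2))
  list(kernels = kernels, radius = rs, stride = max(1L, floor(sigma)))
}

# Complex temporal kernel: Gaussian envelope times e^{-2 pi i f t / rate},
# mean-subtracted for f > 0 so constant input yields exactly zero energy.
temporal_kernel <- function(tf, window, rate) {
  hw <- (window - 1L) / 2L
  tau <- (-hw):hw
  env <- exp(-tau^2 / (2 * (window / 4)^2))
  if (tf == 0) return(env / sum(env))
  w <- env * exp(-2i * pi * tf * tau / rate)
  w - mean(w)
}

#' Motion-energy features of a frame stack
#'
#' Convolves the stack with a bank of quadrature-pair spatiotemporal Gabor
#' filters. For each channel, per-frame energy is the squared modulus of
#' the complex (sine/cosine quadrature) filter response, pooled over a
#' spatial tiling of the image. Channels with nonzero temporal frequency
#' use zero-mean temporal kernels, so static input produces exactly zero
#' energy in them; a drifting pattern excites most the channel matched to
#' its direction and spatiotemporal frequency.
#'
#' @param frames a [frame_stack()] or `h x w x t` array.
#' @param cfg a [motion_energy_config()].
#' @return numeric matrix: one row per valid frame position (frames with a
#'   full temporal window), one column per channel; columns named
#'   `sf<…>_dir<…>_tf<…>` plus `static`. The covered frame indices are in
#'   attribute `frame_index`.
#' @export
motion_energy <- function(frames, cfg = motion_energy_config()) {
  if (!inherits(frames, "frame_stack")) frames <- frame_stack(frames)
  stack <- frames$frames
  rate <- frames$rate
  dims <- dim(stack)
  n_t <- dims[3L]
  wt <- cfg$temporal_window
  if (n_t < wt) {
    stopf("insufficient frames: %d frames but temporal window is %d", n_t, wt)
  }
  hw <- (wt - 1L) / 2L
  t_out <- (hw + 1L):(n_t - hw)

  channel_names <- character(0)
  energies <- list()

  pool_positions <- function(rs, stride) {
    centers_r <- seq(rs + 1L, dims[1L] - rs, by = stride)
    centers_c <- seq(rs + 1L, dims[2L] - rs, by = stride)
    as.matrix(expand.grid(r = centers_r, c = centers_c))
  }
  # linear pixel indices of every patch (positions x support pixels)
  patch_index <- function(pos, rs) {
    ax <- (-rs):rs
    off <- as.matrix(expand.grid(dr = ax, dc = ax))  # row-major within kernel? matches kernel vectorization below
    # kernel was vectorized with row offset varying fastest (gy within column)
    idx <- matrix(0L, nrow(pos), nrow(off))
    for (p in seq_len(nrow(pos))) {
      idx[p, ] <- (pos[p, "c"] + off[, "dc"] - 1L) * dims[1L] + (pos[p, "r"] + off[, "dr"])
    }
    idx
  }

  # responses S[p, ori, t] per spatial frequency, then temporal filtering
  for (sf in cfg$spatial_freqs) {
    bank <- spatial_gabor_bank(sf, cfg$orientations, dims[1:2])
    pos <- pool_positions(bank$radius, bank$stride)
    idx <- patch_index(pos, bank$radius)
    S <- array(0i, c(nrow(pos), length(cfg$orientations), n_t))
    for (t in seq_len(n_t)) {
      fv <- as.vector(stack[, , t])
      S[, , t] <- matrix(fv[idx], nrow(pos)) %*% bank$kernels
    }
    for (tf in cfg$temporal_freqs) {
      w <- temporal_kernel(tf, wt, rate)
      for (o in seq_along(cfg$orientations)) {
        e <- vapply(t_out, function(t0) {
          resp <- S[, o, (t0 - hw):(t0 + hw), drop = FALSE]
          resp <- matrix(resp, nrow(pos), wt)
          sum(Mod(resp %*% w)^2)
        }, numeric(1))
        energies[[length(energies) + 1L]] <- e
        channel_names <- c(channel_names,
                           sprintf("sf%g_dir%g_tf%g", sf, cfg$orientations[o], tf))
      }
    }
  }

  # static channel: coarsest-scale Gaussian low-pass, temporal Gaussian
  sf0 <- min(cfg$spatial_freqs)
  lambda <- min(dims[1:2]) / sf0
  sigma <- lambda / 2
  rs <- min(ceiling(2 * sigma), floor((min(dims[1:2]) - 1) / 2))
  ax <- (-rs):rs
  gx <- matrix(rep(ax, each = length(ax)), ncol = length(ax))
  gy <- matrix(rep(ax, times = length(ax)), ncol = length(ax))
  kern <- as.vector(exp(-(gx^2 + gy^2) / (2 * sigma^2)))
  pos <- pool_positions(rs, max(1L, floor(sigma)))
  idx <- patch_index(pos, rs)
  S0 <- matrix(0, nrow(pos), n_t)
  for (t in seq_len(n_t)) {
    fv <- as.vector(stack[, , t])
    S0[, t] <- matrix(fv[idx], nrow(pos)) %*% kern
  }
  w0 <- temporal_kernel(0, wt, rate)
  e0 <- vapply(t_out, function(t0) {
    sum((S0[, (t0 - hw):(t0 + hw), drop = FALSE] %*% w0)^2)
  }, numeric(1))
  energies[[length(energies) + 1L]] <- e0
  channel_names <- c(channel_names, "static")

  out <- do.call(cbind, energies)
  colnames(out) <- channel_names
  attr(out, "frame_index") <- t_out
  out
}

#' PCA reduction and frame pooling of motion-energy features
#'
#' Principal components are fitted across the frames of the full stimulus
#' set pooled together (a per-video fit would make representations
#' non-comparable across videos); per-frame projections are then averaged
#' across frames within each video, yielding one feature vector per video.
#' The retained dimension is the fixed component count, or the smallest
#' count whose cumulative explained variance reaches the target.
#'
#' @param features named list of per-video feature matrices (frames x
#'   channels, as from [motion_energy()]), or a single matrix (one video).
#' @param cfg a [motion_energy_config()] (its `pca_*` and `log_energy`
#'   fields are used).
#' @return a [representation_set()] with one pooled vector per video; the
#'   number of retained components and their explained variance fraction
#'   are in attributes `n_components` and `explained_variance`.
#' @export
pca_reduce_and_pool <- function(features, cfg = motion_energy_config()) {
  if (is.matrix(features)) features <- list(video_1 = features)
  if (is.null(names(features))) names(features) <- paste0("video_", seq_along(features))
  mats <- lapply(features, function(m) {
    m <- as.matrix(m)
    if (cfg$log_energy) m <- log1p(m)
    m
  })
  pooled <- do.call(rbind, mats)
  fit <- stats::prcomp(pooled, center = TRUE, scale. = FALSE)
  var_frac <- fit$sdev^2 / sum(fit$sdev^2)
  if (!is.null(cfg$pca_components)) {
    k <- as.integer(cfg$pca_components)
    k_avail <- min(k, length(fit$sdev))
  } else {
    k_avail <- k <- which(cumsum(var_frac) >= cfg$pca_variance - 1e-12)[1L]
    if (is.na(k)) stopf("variance target %.3f unreachable", cfg$pca_variance)
    if (nrow(pooled) <= k) {
      stopf("variance-target mode needs more frames (%d) than retained components (%d)",
            nrow(pooled), k)
    }
  }
  vecs <- do.call(rbind, lapply(mats, function(m) {
    sc <- scale(m, center = fit$center, scale = FALSE) %*% fit$rotation[, seq_len(k_avail), drop = FALSE]
    v <- colMeans(sc)
    # fixed-count mode may request more components than the data's rank;
    # missing dimensions carry zero variance and are padded with zeros
    if (k_avail < k) v <- c(v, numeric(k - k_avail))
    v
  }))
  out <- representation_set(names(mats), vecs)
  attr(out, "n_components") <- k
  attr(out, "explained_variance") <- sum(var_frac[seq_len(k_avail)])
  out
}
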