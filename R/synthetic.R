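#' Synthetic rating-count tables
#'
#' Multinomial draws emulating per-video category rating counts (e.g. 10-19
#' raters per video choosing friendly / neutral / adversarial).
#'
#' @param n_videos number of videos.
#' @param n_raters raters per video (scalar or length `n_videos`).
#' @param profiles category probability profile: numeric vector of 3
#'   (recycled) or `n_videos x 3` matrix, rows summing to 1 in the fixed
#'   category order (friendly, neutral, adversarial).
#' @param seed RNG seed.
#' @return data frame with columns `video`, `friendly`, `neutral`,
#'   `adversarial`; feed to [rating_representation_set()].
#' @export
gen_rating_counts <- function(n_videos, n_raters = 10L,
                              profiles = c(1, 1, 1) / 3, seed = 1L) {
  if (is.null(dim(profiles))) {
    profiles <- matrix(profiles, n_videos, 3L, byrow = TRUE)
  }
  if (!all(dim(profiles) == c(n_videos, 3L))) stopf("profiles must be n_videos x 3")
  if (any(abs(rowSums(profiles) - 1) > 1e-8) || any(profiles < 0)) {
    stopf("each probability profile must be non-negative and sum to 1")
  }
  n_raters <- rep_len(as.integer(n_raters), n_videos)
  counts <- with_seed(seed, {
    t(vapply(seq_len(n_videos), function(i) {
      as.integer(stats::rmultinom(1L, n_raters[i], profiles[i, ]))
    }, integer(3)))
  })
  data.frame(video = paste0("video_", seq_len(n_videos)),
             friendly = counts[, 1L], neutral = counts[, 2L],
             adversarial = counts[, 3L], stringsAsFactors = FALSE)
}

# Spearman correlation between the RDMs of two representation matrices.
rdm_cor <- function(xa, xb) {
  spearman_rsa(rdm_vector(representation_rdm(xa)),
               rdm_vector(representation_rdm(xb)))$rho
}

#' Model representations with controlled inter-RDM correlations
#'
#' Generates three representation sets (`modelA`, `modelB`, `behavior`)
#' whose pairwise RDM Spearman correlations match the requested targets
#' within tolerance — e.g. the (0.27, 0.50, 0.46) structure of a
#' decorrelated two-model stimulus set. Construction: a latent condition
#' embedding is drawn; each set is the latent embedding plus independent
#' Gaussian distortion whose scale is tuned by bisection so the set's RDM
#' couples to the latent RDM at the strength implied by the targets (under
#' independent distortions, the pairwise RDM correlation factorizes into
#' the product of the two latent couplings). Attempts are repeated with
#' fresh draws until all three measured correlations are within tolerance.
#'
#' @param n_conditions number of conditions (default 50).
#' @param targets named numeric: `ab`, `a_beh`, `b_beh`, each in (-1, 1);
#'   a target of exactly 1 duplicates the corresponding representations.
#' @param dims latent dimensionality (default 16).
#' @param seed RNG seed.
#' @param tolerance maximum absolute deviation per target (default 0.05).
#' @param max_iter maximum regeneration attempts (default 25).
#' @return list with `sets` (named list of [representation_set()]),
#'   `achieved` (measured correlations), `targets`, and `attempts`.
#' @export
gen_model_representations <- function(n_conditions = 50L,
                                      targets = c(ab = 0.27, a_beh = 0.50, b_beh = 0.46),
                                      dims = 16L, seed = 1L,
                                      tolerance = 0.05, max_iter = 25L) {
  targets <- targets[c("ab", "a_beh", "b_beh")]
  if (anyNA(targets)) stopf("targets must be named ab, a_beh, b_beh")
  if (any(targets >= 1 | targets <= -1)) {
    if (identical(unname(targets["ab"]), 1)) {
      # duplicated models: requires the two behavior couplings to agree
      if (abs(targets["a_beh"] - targets["b_beh"]) > 1e-12) {
        stopf("with r(A,B) = 1 the two behavior couplings must be equal")
      }
      sub <- gen_model_representations(
        n_conditions, c(ab = 0.999, a_beh = unname(targets["a_beh"]),
                        b_beh = unname(targets["b_beh"])),
        dims, seed, tolerance, max_iter)
      sub$sets$modelB <- sub$sets$modelA
      sub$achieved["ab"] <- 1
      return(sub)
    }
    stopf("targets must lie in (-1, 1)")
  }
  if (any(targets <= 0)) {
    # near-zero or negative targets: independent constructions; only |r| <=
    # tolerance around 0 is supported (negative RDM couplings are not
    # constructible from shared-latent mixing)
    if (any(targets < -tolerance)) stopf("negative targets are not supported")
  }
  # latent couplings implied by a single-common-factor structure
  couple <- function(t_ab, t_a, t_b) {
    if (t_ab <= 0) return(NULL)  # handled by independent draws below
    c(A = sqrt(t_ab * t_a / t_b), B = sqrt(t_ab * t_b / t_a),
      beh = sqrt(t_a * t_b / t_ab))
  }
  cpl <- couple(targets[["ab"]], targets[["a_beh"]], targets[["b_beh"]])
  if (is.null(cpl)) {
    cpl <- c(A = max(targets[["a_beh"]], 0), B = max(targets[["b_beh"]], 0), beh = 1)
  }
  if (any(cpl > 0.999)) cpl <- pmin(cpl, 0.999)

  best <- NULL; best_err <- Inf
  for (attempt in seq_len(max_iter)) {
    res <- with_seed(derive_seed(seed, attempt), {
      Z <- matrix(stats::rnorm(n_conditions * dims), n_conditions, dims)
      make_set <- function(cc) {
        E <- matrix(stats::rnorm(n_conditions * dims), n_conditions, dims)
        if (cc <= 0) return(E)             # independent of the latent
        measure <- function(sig) rdm_cor(Z + sig * E, Z)
        lo <- 0; hi <- 1
        while (measure(hi) > cc && hi < 64) hi <- hi * 2
        for (it in seq_len(30L)) {
          mid <- (lo + hi) / 2
          if (measure(mid) > cc) lo <- mid else hi <- mid
        }
        Z + ((lo + hi) / 2) * E
      }
      list(A = make_set(cpl[["A"]]), B = make_set(cpl[["B"]]),
           beh = make_set(cpl[["beh"]]))
    })
    achieved <- c(ab = rdm_cor(res$A, res$B),
                  a_beh = rdm_cor(res$A, res$beh),
                  b_beh = rdm_cor(res$B, res$beh))
    err <- max(abs(achieved - targets))
    if (err < best_err) {
      best_err <- err
      best <- list(res = res, achieved = achieved, attempts = attempt)
    }
    if (err <= tolerance) break
  }
  if (best_err > tolerance) {
    stopf("could not reach targets (%s) within +/- %.3f after %d attempts; best achieved: %s",
          paste(sprintf("%s=%.2f", names(targets), targets), collapse = ", "),
          tolerance, max_iter,
          paste(sprintf("%s=%.3f", names(best$achieved), best$achieved), collapse = ", "))
  }
  labels <- paste0("video_", seq_len(n_conditions))
  list(sets = list(modelA = representation_set(labels, best$res$A),
                   modelB = representation_set(labels, best$res$B),
                   behavior = representation_set(labels, best$res$beh)),
       achieved = best$achieved, targets = targets, attempts = best$attempts)
}

#' Planted-mixture specification for synthetic pattern datasets
#'
#' Describes the generative assumption behind model-brain RSA inference:
#' within each planted region, the neural representational geometry is a
#' weighted blend of named component (model) RDMs; everywhere else, and on
#' top of the signal, voxels carry independent Gaussian noise.
#'
#' @param components named list of [rdm()]s sharing condition labels.
#' @param regions named list; each element a list with `mask` (a
#'   [voxel_mask()]) and `weights` — either a named numeric vector over the
#'   components, or a windows x components matrix of per-window weight
#'   schedules (5 windows for the time-resolved design).
#' @param sigma noise standard deviation relative to a unit-variance
#'   signal (>= 0).
#' @param n_subjects,n_repeats dataset dimensions.
#' @param subject_jitter idiosyncratic fraction of each subject's regional
#'   geometry, in `[0, 1)`: subject Gram = `(1 - jitter) * blend + jitter *
#'   subject-specific random geometry`. The default 0.7 yields
#'   subject-to-group RDM correlations around 0.3-0.4, in the range of
#'   empirical inter-subject consistency of representational geometries;
#'   0 makes every subject's noiseless geometry identical to the blend.
#' @return object of class `mixture_spec`.
#' @export
mixture_spec <- function(components, regions, sigma = 1,
                         n_subjects = 25L, n_repeats = 5L,
                         subject_jitter = 0.7) {
  if (!length(components) || is.null(names(components))) {
    stopf("components must be a named list of RDMs")
  }
  labs <- rownames(components[[1L]])
  for (cm in components) {
    if (!is_rdm(cm)) stopf("each component must be an rdm")
    if (!identical(rownames(cm), labs)) stopf("component RDMs must share condition labels")
  }
  if (!length(regions) || is.null(names(regions))) {
    stopf("regions must be a named list")
  }
  for (rg in regions) {
    if (!inherits(rg$mask, "voxel_mask")) stopf("each region needs a voxel_mask")
    w <- rg$weights
    if (is.matrix(w)) {
      if (ncol(w) != length(components)) stopf("weight schedule columns must match components")
    } else if (length(w) != length(components)) {
      stopf("region weights must match the number of components")
    }
    if (any(!is.finite(w)) || any(w < 0)) stopf("weights must be finite and >= 0")
  }
  if (sigma < 0) stopf("sigma must be >= 0")
  if (subject_jitter < 0 || subject_jitter >= 1) {
    stopf("subject_jitter must lie in [0, 1)")
  }
  structure(list(components = components, regions = regions, sigma = sigma,
                 n_subjects = as.integer(n_subjects),
                 n_repeats = as.integer(n_repeats),
                 subject_jitter = subject_jitter, labels = labs),
            class = "mixture_spec")
}

# Ground-truth consistency correction for zero-weight components. The
# measurable geometry is the centered, correlation-normalized version of
# the planted blend, and that version generically carries a small nonzero
# semi-partial rank correlation with components declared absent (weight
# 0). Declaring "component z contributes nothing" while planting geometry
# with nonzero z-unique rank variance would make the generator's ground
# truth false under its own measurement model, so the blend is iteratively
# adjusted: each zero-weight component's residual direction (its ranks
# residualized on the other components' ranks) is removed from the
# dissimilarity vector by root-finding until the semi-partial is zero,
# alternating with re-projection onto the centered-compatible manifold.
correct_zero_components <- function(D, components, weights) {
  zero <- which(weights == 0)
  if (length(zero) == 0L || all(weights == 0)) return(D)
  n <- nrow(D)
  Cm <- diag(n) - 1 / n
  vecs <- lapply(components, function(cm) unclass(cm)[lower.tri(cm)])
  normalize_centered <- function(R) {
    Gc <- Cm %*% R %*% Cm
    s <- sqrt(pmax(diag(Gc), 1e-12))
    Gc / outer(s, s)
  }
  R <- normalize_centered(1 - D)
  for (outer in seq_len(8L)) {
    dv <- 1 - R[lower.tri(R)]
    worst <- 0
    for (z in zero) {
      ctrl <- vecs[-z]
      u <- stats::lm.fit(cbind(1, vapply(ctrl, rank, numeric(length(dv)))),
                         rank(vecs[[z]]))$residuals
      u <- u / stats::sd(u) * stats::sd(dv)
      f <- function(g) semipartial_spearman(dv - g * u, vecs[[z]], ctrl)$rho
      s0 <- f(0)
      worst <- max(worst, abs(s0))
      if (abs(s0) < 1e-5) next
      lo <- -0.5; hi <- 0.5
      if (f(lo) * f(hi) < 0) {
        g <- stats::uniroot(f, c(lo, hi), tol = 1e-8)$root
        dv <- dv - g * u
      }
    }
    Rnew <- matrix(0, n, n)
    Rnew[lower.tri(Rnew)] <- 1 - dv
    Rnew <- Rnew + t(Rnew)
    diag(Rnew) <- 1
    R <- normalize_centered(Rnew)
    if (worst < 1e-5) break
  }
  Dc <- 1 - R
  diag(Dc) <- 0
  Dc
}

# Zero-mean orthonormal voxel basis balanced so that every voxel carries
# the same share of the embedding energy (lambda-weighted row norms all
# equal, by alternating orthonormalization and row rescaling). With such a
# basis the planted patterns have exactly zero mean and equal variance
# across conditions at every voxel, so the pipeline's voxelwise z-scoring
# is transparent to the planted geometry.
balanced_basis <- function(n_voxels, lam, seed, iters = 40L) {
  with_seed(seed, {
    M <- matrix(stats::rnorm(n_voxels * length(lam)), n_voxels, length(lam))
    for (it in seq_len(iters)) {
      M <- sweep(M, 2L, colMeans(M))
      M <- qr.Q(qr(M))
      m_v <- as.numeric(M^2 %*% lam)
      M <- M * sqrt(mean(m_v) / pmax(m_v, 1e-12))
    }
    M <- sweep(M, 2L, colMeans(M))
    qr.Q(qr(M))
  })
}

# Noise-free per-subject region patterns realizing a blended
# correlation-distance RDM. Each subject's geometry is a mixture of the
# group blend and a subject-specific random geometry (inter-subject
# representational variability; `subject_jitter` is the idiosyncratic
# fraction). The subject Gram is double-centered (voxelwise normalization
# confines measurable geometry to the centered subspace), clipped to PSD,
# factorized, and expressed on a balanced zero-mean orthonormal voxel
# basis. Returns one pattern matrix per subject plus the clipped-eigenvalue
# distortion fraction of the group blend.
plant_region_patterns <- function(components, weights, n_voxels, n_subjects,
                                  subject_jitter, seed, jitter_dims = 16L) {
  wsum <- sum(weights)
  if (wsum == 0) return(NULL)
  D <- Reduce(`+`, Map(function(cm, w) w * unclass(cm), components,
                       as.list(weights))) / wsum
  G <- 1 - correct_zero_components(D, components, weights)
  n <- nrow(G)
  Cm <- diag(n) - 1 / n
  embed <- function(Gs, sub_seed) {
    Gc <- Cm %*% Gs %*% Cm
    eg <- eigen(Gc, symmetric = TRUE)
    vals <- pmax(eg$values, 0)
    q <- min(sum(vals > 1e-10), n_voxels - 1L)
    if (q < 2L) stopf("region too small to embed the blended geometry")
    ord <- order(vals, decreasing = TRUE)[seq_len(q)]
    lam <- vals[ord]
    L <- eg$vectors[, ord, drop = FALSE] %*% diag(sqrt(lam), q)
    Q <- balanced_basis(n_voxels, lam, sub_seed)
    P <- L %*% t(Q)
    P / mean(apply(P, 2L, stats::sd))
  }
  eg0 <- eigen(Cm %*% G %*% Cm, symmetric = TRUE)
  distortion <- sum(abs(pmin(eg0$values, 0))) / sum(abs(eg0$values))
  patterns <- lapply(seq_len(n_subjects), function(s) {
    Gs <- if (subject_jitter > 0) {
      Zs <- with_seed(derive_seed(seed, 31L * s), {
        matrix(stats::rnorm(n * jitter_dims), n, jitter_dims)
      })
      (1 - subject_jitter) * G + subject_jitter * stats::cor(t(Zs))
    } else G
    embed(Gs, derive_seed(seed, 97L * s))
  })
  list(patterns = patterns, distortion = distortion)
}

#' Generate a multi-subject synthetic pattern dataset
#'
#' Builds per-subject, per-repeat condition x voxel response matrices on a
#' volume grid. Within each planted region the noiseless patterns realize
#' the weighted blend of the component RDMs (correlation-distance
#' geometry, exact up to clipping of non-embeddable negative eigenvalues,
#' whose fraction is logged per region); voxels outside planted regions
#' receive pure noise; independent Gaussian noise of standard deviation
#' `sigma` is added per subject and repeat. Bit-reproducible under `seed`.
#'
#' @param spec a [mixture_spec()] with vector weights per region.
#' @param grid a [volume_grid()].
#' @param seed RNG seed.
#' @param analysis_mask optional [voxel_mask()]; defaults to the whole
#'   grid. All planted regions must lie inside it.
#' @param window for internal use by [gen_windowed_dataset()]: selects a
#'   row of matrix-valued weight schedules.
#' @return object of class `synthetic_dataset` (also `pattern_dataset`):
#'   list with `patterns` (subjects -> repeats -> condition x voxel
#'   matrix), `labels`, `grid`, `mask`, `regions` (per region: `mask`,
#'   `columns` into the mask, `weights`, `distortion`), `spec`, `seed`.
#' @export
gen_pattern_dataset <- function(spec, grid, seed = 1L, analysis_mask = NULL,
                                window = NULL) {
  stopifnot(inherits(spec, "mixture_spec"), inherits(grid, "volume_grid"))
  mask <- analysis_mask %||% voxel_mask(grid, array(1L, grid$shape))
  mask_lin <- mask_linear(mask)
  n_vox <- length(mask_lin)
  n_cond <- length(spec$labels)
  # per-subject noiseless signal; subject geometry (jitter and basis) is
  # derived from region-specific seeds only, so windowed datasets share
  # each subject's idiosyncratic geometry across windows
  signal <- lapply(seq_len(spec$n_subjects), function(s) {
    m <- matrix(0, n_cond, n_vox)
    rownames(m) <- spec$labels
    m
  })
  regions_out <- list()
  for (rn in names(spec$regions)) {
    rg <- spec$regions[[rn]]
    if (!same_grid(rg$mask, mask)) stopf("region '%s' lives on a different grid", rn)
    cols <- match(mask_linear(rg$mask), mask_lin)
    if (anyNA(cols)) stopf("region '%s' extends outside the analysis mask", rn)
    w <- rg$weights
    if (is.matrix(w)) {
      if (is.null(window)) stopf("region '%s' has windowed weights; use gen_windowed_dataset", rn)
      w <- w[window, ]
    }
    planted <- plant_region_patterns(spec$components, w, length(cols),
                                     n_subjects = spec$n_subjects,
                                     subject_jitter = spec$subject_jitter,
                                     seed = derive_seed(seed, match(rn, names(spec$regions))))
    if (!is.null(planted)) {
      for (s in seq_len(spec$n_subjects)) {
        signal[[s]][, cols] <- planted$patterns[[s]]
      }
    }
    regions_out[[rn]] <- list(mask = rg$mask, columns = cols, weights = w,
                              distortion = if (is.null(planted)) NA_real_ else planted$distortion)
  }
  patterns <- with_seed(derive_seed(seed, 1000L + (window %||% 0L)), {
    lapply(seq_len(spec$n_subjects), function(s) {
      lapply(seq_len(spec$n_repeats), function(r) {
        signal[[s]] + spec$sigma * matrix(stats::rnorm(n_cond * n_vox), n_cond, n_vox)
      })
    })
  })
  names(patterns) <- paste0("subject_", seq_len(spec$n_subjects))
  structure(list(patterns = patterns, labels = spec$labels, grid = grid,
                 mask = mask, regions = regions_out, spec = spec, seed = seed),
            class = c("synthetic_dataset", "pattern_dataset"))
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf("synthetic_dataset: %d subjects x %d repeats, %d conditions, %d voxels\n",
              length(x$patterns), length(x$patterns[[1L]]),
              length(x$labels), nrow(x$mask$members)))
  for (rn in names(x$regions)) {
    rg <- x$regions[[rn]]
    cat(sprintf("  region %s: %d voxels, weights (%s)\n", rn, length(rg$columns),
                paste(sprintf("%.2f", rg$weights), collapse = ", ")))
  }
  invisible(x)
}

#' Generate a time-resolved (windowed) dataset family
#'
#' One pattern dataset per time window, with window-specific mixture
#' weights taken from each region's windows x components weight-schedule
#' matrix. Planted projection bases are shared across windows (the same
#' "voxels" carry the evolving geometry); noise is drawn independently per
#' window. The default schedules emulate an early rise-and-fall component
#' against a gradually increasing one.
#'
#' @param spec a [mixture_spec()] whose regions carry matrix weight
#'   schedules (rows = windows).
#' @param grid a [volume_grid()].
#' @param seed RNG seed.
#' @param analysis_mask optional [voxel_mask()].
#' @return list of `synthetic_dataset`s, one per window, sharing subjects,
#'   conditions, and grid.
#' @export
gen_windowed_dataset <- function(spec, grid, seed = 1L, analysis_mask = NULL) {
  n_win <- unique(vapply(spec$regions, function(rg) {
    if (!is.matrix(rg$weights)) stopf("gen_windowed_dataset needs matrix weight schedules")
    nrow(rg$weights)
  }, integer(1)))
  if (length(n_win) != 1L) stopf("all regions must share the same number of windows")
  out <- lapply(seq_len(n_win), function(w) {
    gen_pattern_dataset(spec, grid, seed = seed, analysis_mask = analysis_mask,
                        window = w)
  })
  names(out) <- paste0("window_", seq_len(n_win))
  out
}

#' Default rise-and-fall / monotone window weight schedules
#'
#' @param n_windows number of windows (default 5).
#' @param peak peak weight of the rise-and-fall component.
#' @return 2-column matrix (`rise_fall`, `monotone`) of weights per window.
#' @export
window_schedules <- function(n_windows = 5L, peak = 1) {
  stopifnot(n_windows >= 2L)
  x <- seq(0, 1, length.out = n_windows)
  rise_fall <- peak * exp(-((x - 0.45) / 0.28)^2)
  monotone <- seq(0.1, 1, length.out = n_windows)
  cbind(rise_fall = rise_fall, monotone = monotone)
}

#' Moving-blob frame stacks
#'
#' Deterministic test fixture for the motion-energy model: a Gaussian
#' intensity blob translated along a trajectory, with an optional static
#' distractor blob.
#'
#' @param trajectory `n_frames x 2` matrix of blob centers (row, col), or a
#'   single (row, col) pair for a static blob.
#' @param size frame dimensions `c(height, width)`.
#' @param n_frames number of frames (required when `trajectory` is a single
#'   point).
#' @param blob_sigma blob standard deviation in pixels.
#' @param amplitude peak intensity.
#' @param distractor optional static (row, col) center of a second blob.
#' @param rate frame rate in Hz.
#' @return a [frame_stack()].
#' @export
gen_frame_stack <- function(trajectory, size = c(32L, 32L), n_frames = NULL,
                            blob_sigma = 2, amplitude = 1, distractor = NULL,
                            rate = 10) {
  if (is.null(dim(trajectory))) trajectory <- matrix(trajectory, 1L, 2L)
  if (nrow(trajectory) == 1L) {
    if (is.null(n_frames)) stopf("n_frames required for a static trajectory")
    trajectory <- trajectory[rep(1L, n_frames), , drop = FALSE]
  }
  n_frames <- nrow(trajectory)
  if (any(trajectory[, 1L] < 1 | trajectory[, 1L] > size[1L] |
          trajectory[, 2L] < 1 | trajectory[, 2L] > size[2L])) {
    stopf("trajectory leaves the frame bounds")
  }
  rr <- matrix(seq_len(size[1L]), size[1L], size[2L])
  cc <- matrix(rep(seq_len(size[2L]), each = size[1L]), size[1L], size[2L])
  blob <- function(center) {
    amplitude * exp(-((rr - center[1L])^2 + (cc - center[2L])^2) / (2 * blob_sigma^2))
  }
  frames <- array(0, c(size[1L], size[2L], n_frames))
  for (t in seq_len(n_frames)) {
    f <- blob(trajectory[t, ])
    if (!is.null(distractor)) f <- f + blob(distractor)
    frames[, , t] <- f
  }
  frame_stack(frames, rate = rate)
}
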