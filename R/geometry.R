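#' Volume grids and voxel masks
#'
#' A `volume_grid` records the 3D voxel extents, voxel size in mm, and an
#' optional affine mapping to world coordinates (carried for NIfTI
#' round-trips; all geometry is computed in voxel units). A `voxel_mask` is
#' a set of voxel indices on a grid; indices are 1-based integer triples.
#'
#' @param shape integer vector of 3 positive extents (voxels).
#' @param voxel_size voxel edge lengths in mm (scalar or length 3).
#' @param affine optional 4x4 voxel-to-world affine.
#' @return a `volume_grid`.
#' @export
volume_grid <- function(shape, voxel_size = 3, affine = NULL) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 1L)) stopf("shape must be 3 positive extents")
  voxel_size <- rep_len(as.numeric(voxel_size), 3L)
  if (any(voxel_size <= 0)) stopf("voxel size must be positive")
  structure(list(shape = shape, voxel_size = voxel_size, affine = affine),
            class = "volume_grid")
}

#' @rdname volume_grid
#' @param grid a `volume_grid`.
#' @param members integer matrix (n x 3) of 1-based voxel indices, or a
#'   logical/numeric 3D array on the grid (nonzero = member).
#' @export
voxel_mask <- function(grid, members) {
  stopifnot(inherits(grid, "volume_grid"))
  if (is.array(members) && length(dim(members)) == 3L) {
    if (!all(dim(members) == grid$shape)) stopf("mask array does not match grid shape")
    members <- which(members != 0, arr.ind = TRUE)
  }
  members <- matrix(as.integer(members), ncol = 3L,
                    dimnames = list(NULL, c("x", "y", "z")))
  if (nrow(members)) {
    if (any(members < 1L) || any(t(members) > grid$shape)) {
      stopf("mask members fall outside the grid")
    }
    members <- unique(members)
    members <- members[order(members[, 1L], members[, 2L], members[, 3L]), , drop = FALSE]
  }
  structure(list(grid = grid, members = members), class = "voxel_mask")
}

#' @export
print.voxel_mask <- function(x, ...) {
  cat(sprintf("voxel_mask: %d voxels on a %s grid\n", nrow(x$members),
              paste(x$grid$shape, collapse = "x")))
  invisible(x)
}

mask_size <- function(mask) nrow(mask$members)

# linear (column-major) voxel indices of a member matrix
mask_linear <- function(mask) {
  m <- mask$members
  s <- mask$grid$shape
  (m[, 3L] - 1L) * (s[1L] * s[2L]) + (m[, 2L] - 1L) * s[1L] + m[, 1L]
}

#' @rdname volume_grid
#' @export
mask_to_array <- function(mask) {
  a <- array(0L, mask$grid$shape)
  a[mask$members] <- 1L
  a
}

same_grid <- function(a, b) all(a$grid$shape == b$grid$shape)

#' Spherical voxel mask
#'
#' Convenience builder for ball-shaped masks (e.g. a brain-like analysis
#' mask inside a bounding grid, or a spherical ROI).
#'
#' @param grid a [volume_grid()].
#' @param center sphere center in voxel coordinates (length 3; may be
#'   fractional).
#' @param radius radius in voxel units (inclusive boundary).
#' @return a [voxel_mask()].
#' @export
spherical_mask <- function(grid, center, radius) {
  stopifnot(inherits(grid, "volume_grid"))
  idx <- as.matrix(expand.grid(x = seq_len(grid$shape[1L]),
                               y = seq_len(grid$shape[2L]),
                               z = seq_len(grid$shape[3L])))
  d2 <- (idx[, 1L] - center[1L])^2 + (idx[, 2L] - center[2L])^2 +
    (idx[, 3L] - center[3L])^2
  voxel_mask(grid, idx[d2 <= radius^2 + 1e-12, , drop = FALSE])
}

#' Spherical searchlights over a voxel mask
#'
#' One searchlight per in-mask voxel: the center plus every in-mask voxel
#' within Euclidean distance `radius` (in voxel units, inclusive boundary).
#' Searchlights at mask edges keep whatever members fall in-mask.
#' Searchlights with fewer than `min_voxels` members are kept but flagged
#' so users can filter them.
#'
#' @param mask a [voxel_mask()] (analysis mask; both centers and members
#'   are restricted to it).
#' @param radius sphere radius in voxels (> 0); the radius-3 sphere deep
#'   inside a solid mask has 123 members.
#' @param min_voxels flag threshold (default 10).
#' @return object of class `searchlight_set`: list with `centers` (n x 3),
#'   `members` (list of integer vectors indexing into the mask's member
#'   rows), `flagged` (logical), `radius`, and the `mask`.
#' @export
define_searchlights <- function(mask, radius = 3, min_voxels = 10L) {
  stopifnot(inherits(mask, "voxel_mask"))
  if (radius <= 0) stopf("searchlight radius must be > 0")
  m <- mask$members
  if (nrow(m) == 0L) {
    warnf("empty mask: no searchlights defined")
    return(structure(list(centers = m, members = list(), flagged = logical(),
                          radius = radius, mask = mask),
                     class = "searchlight_set"))
  }
  r_int <- floor(radius)
  ax <- (-r_int):r_int
  off <- as.matrix(expand.grid(dx = ax, dy = ax, dz = ax))
  off <- off[rowSums(off^2) <= radius^2 + 1e-12, , drop = FALSE]
  s <- mask$grid$shape
  lookup <- array(NA_integer_, s)
  lookup[m] <- seq_len(nrow(m))
  hits <- matrix(NA_integer_, nrow(m), nrow(off))
  for (k in seq_len(nrow(off))) {
    p <- sweep(m, 2L, -off[k, ])  # m + offset
    ok <- p[, 1L] >= 1L & p[, 1L] <= s[1L] &
          p[, 2L] >= 1L & p[, 2L] <= s[2L] &
          p[, 3L] >= 1L & p[, 3L] <= s[3L]
    idx <- rep(NA_integer_, nrow(m))
    idx[ok] <- lookup[p[ok, , drop = FALSE]]
    hits[, k] <- idx
  }
  members <- lapply(seq_len(nrow(m)), function(i) {
    v <- hits[i, ]
    sort(v[!is.na(v)])
  })
  flagged <- lengths(members) < min_voxels
  structure(list(centers = m, members = members, flagged = flagged,
                 radius = radius, mask = mask),
            class = "searchlight_set")
}

#' @export
print.searchlight_set <- function(x, ...) {
  cat(sprintf("searchlight_set: %d searchlights, radius %g voxels (%d flagged < min size)\n",
              length(x$members), x$radius, sum(x$flagged)))
  invisible(x)
}

#' Voxelwise normalization and repeat averaging
#'
#' Standardizes each voxel's responses to zero mean and unit variance
#' across all conditions and repeats (within subject and task), then
#' averages across repeats per condition. Voxels with zero variance are
#' excluded (their indices are recorded in attribute `excluded`).
#'
#' @param repeats list of condition x voxel beta matrices, one per repeat,
#'   identical shapes.
#' @return condition x voxel matrix of normalized, repeat-averaged
#'   responses.
#' @export
normalize_and_average <- function(repeats) {
  if (!is.list(repeats) || length(repeats) < 1L) stopf("need at least one repeat")
  dims <- dim(repeats[[1L]])
  if (!all(vapply(repeats, function(m) all(dim(m) == dims), logical(1)))) {
    stopf("repeat matrices differ in shape")
  }
  # accumulate column moments across repeats without materializing the
  # stacked matrix (the voxel count dominates memory traffic)
  nr <- dims[1L] * length(repeats)
  csum <- 0; csum2 <- 0; acc <- 0
  for (r in repeats) {
    csum <- csum + colSums(r)
    csum2 <- csum2 + colSums(r^2)
    acc <- acc + r
  }
  mu <- csum / nr
  sdv <- sqrt(pmax(csum2 - nr * mu^2, 0) / (nr - 1L))
  sdv[abs(sdv) < 1e-300] <- 0
  keep <- sdv > 0
  if (!all(keep)) {
    warnf("excluding %d zero-variance voxel(s) from normalization", sum(!keep))
  }
  avg <- acc[, keep, drop = FALSE] / length(repeats)
  # mean over repeats of (x - mu)/sd equals (mean x - mu)/sd
  out <- sweep(sweep(avg, 2L, mu[keep]), 2L, sdv[keep], "/")
  rownames(out) <- rownames(repeats[[1L]])
  attr(out, "excluded") <- which(!keep)
  out
}

#' Neural RDM within a voxel subset
#'
#' Correlation-distance RDM over condition patterns restricted to the given
#' voxels (a searchlight's members or an ROI).
#'
#' @param patterns condition x voxel response matrix.
#' @param voxels integer column indices to restrict to (default all).
#' @return an [rdm()].
#' @export
neural_rdm <- function(patterns, voxels = seq_len(ncol(patterns))) {
  x <- patterns[, voxels, drop = FALSE]
  if (ncol(x) < 2L) stopf("insufficient voxels: need >= 2, got %d", ncol(x))
  if (nrow(x) < 3L) stopf("need at least 3 conditions")
  v <- apply(x, 1L, stats::var)
  if (any(v == 0)) {
    lab <- rownames(x) %||% as.character(seq_len(nrow(x)))
    stopf("degenerate pattern: zero variance for condition(s) %s",
          paste(lab[v == 0], collapse = ", "))
  }
  rdm(1 - stats::cor(t(x)), labels = rownames(x))
}

# First/second split of repeat indices: odd positions (1, 3, 5, ...) vs even
# positions; with an odd repeat count the extra repeat stays in the first
# split. Deterministic rendering of the even/odd-repetition convention.
split_half_indices <- function(n_repeats) {
  idx <- seq_len(n_repeats)
  list(a = idx[idx %% 2L == 1L], b = idx[idx %% 2L == 0L])
}

#' Split-half voxel reliability
#'
#' Splits the repeats into two halves, averages each half per condition,
#' and correlates the two averages across conditions for each voxel. The
#' liberal reliability mask keeps voxels with r > 0; voxels with an
#' undefined correlation (zero-variance half) are excluded from the mask.
#'
#' @param repeats list of condition x voxel matrices (>= 2 repeats).
#' @return list with `r` (per-voxel correlations, `NA` where undefined)
#'   and `mask` (logical, `r > 0`).
#' @export
split_half_voxel_reliability <- function(repeats) {
  if (length(repeats) < 2L) stopf("split-half reliability needs >= 2 repeats")
  sp <- split_half_indices(length(repeats))
  avg <- function(ix) Reduce(`+`, repeats[ix]) / length(ix)
  a <- avg(sp$a); b <- avg(sp$b)
  # vectorized per-voxel Pearson correlation across conditions
  n <- nrow(a)
  ma <- colMeans(a); mb <- colMeans(b)
  va <- colSums(a^2) - n * ma^2
  vb <- colSums(b^2) - n * mb^2
  cross <- colSums(a * b) - n * ma * mb
  denom <- sqrt(pmax(va, 0) * pmax(vb, 0))
  r <- ifelse(denom > 1e-12 * n, cross / denom, NA_real_)
  r <- pmin(pmax(r, -1), 1)
  list(r = r, mask = !is.na(r) & r > 0)
}

#' Spearman-Brown corrected split-half RSA reliability
#'
#' The ROI-level noise ceiling: repeats are split into halves, each half is
#' normalized and averaged, the split-half reliability mask (r > 0 on the
#' full data) is applied to both halves, RDMs are built per half and
#' compared with Spearman's rank correlation, and the result is corrected
#' to full length with the Spearman-Brown formula `2r / (1 + r)`.
#'
#' @param repeats list of condition x voxel matrices (>= 2 repeats).
#' @param voxels integer voxel indices of the ROI (columns of the repeat
#'   matrices); default all.
#' @return list with `rho_split` (uncorrected split-half Spearman rho) and
#'   `ceiling` (Spearman-Brown corrected value; `NA` with a warning when
#'   rho_split = -1 makes the correction undefined).
#' @export
split_half_rsa_reliability <- function(repeats, voxels = seq_len(ncol(repeats[[1L]]))) {
  if (length(repeats) < 2L) stopf("split-half RSA needs >= 2 repeats")
  repeats <- lapply(repeats, function(m) m[, voxels, drop = FALSE])
  rel <- split_half_voxel_reliability(repeats)
  keep <- which(rel$mask)
  if (length(keep) < 2L) {
    warnf("fewer than 2 reliable voxels; split-half RSA undefined")
    return(list(rho_split = NA_real_, ceiling = NA_real_))
  }
  sp <- split_half_indices(length(repeats))
  pat_a <- normalize_and_average(lapply(repeats[sp$a], function(m) m[, keep, drop = FALSE]))
  pat_b <- normalize_and_average(lapply(repeats[sp$b], function(m) m[, keep, drop = FALSE]))
  rho <- spearman_rsa(rdm_vector(neural_rdm(pat_a)), rdm_vector(neural_rdm(pat_b)))$rho
  list(rho_split = rho, ceiling = spearman_brown(rho))
}

#' Spearman-Brown prophecy correction
#'
#' Projects a split-half correlation to the reliability of the full-length
#' measurement: `2r / (1 + r)`.
#'
#' @param r split-half correlation.
#' @return corrected reliability; `NA` (with a warning) at r = -1 where the
#'   correction is undefined.
#' @export
spearman_brown <- function(r) {
  out <- ifelse(abs(1 + r) < 1e-12, NA_real_, 2 * r / (1 + r))
  if (anyNA(out)) warnf("Spearman-Brown correction undefined at r = -1")
  out
}

#' Functional ROI from the top fraction of a contrast map within a parcel
#'
#' Selects the `ceiling(pct * parcel size)` parcel voxels with the largest
#' contrast values. Ties at the threshold are broken by lexicographic voxel
#' index order, making the ROI deterministic.
#'
#' @param contrast 3D array of per-voxel contrast values on the parcel's
#'   grid (must be defined, non-NA, on every parcel voxel).
#' @param parcel a [voxel_mask()].
#' @param pct fraction of parcel voxels to keep, in (0, 1].
#' @return a [voxel_mask()], subset of the parcel.
#' @export
define_roi_top_percent <- function(contrast, parcel, pct = 0.10) {
  stopifnot(inherits(parcel, "voxel_mask"))
  if (pct <= 0 || pct > 1) stopf("pct must lie in (0, 1]")
  m <- parcel$members
  if (nrow(m) == 0L) stopf("empty parcel")
  if (!all(dim(contrast) == parcel$grid$shape)) {
    stopf("contrast map does not match the parcel's grid")
  }
  vals <- contrast[m]
  if (anyNA(vals)) stopf("contrast undefined for %d parcel voxel(s)", sum(is.na(vals)))
  k <- ceiling(pct * nrow(m))
  # members are stored in lexicographic order, so row order breaks ties
  ord <- order(-vals, seq_len(nrow(m)))
  voxel_mask(parcel$grid, m[ord[seq_len(k)], , drop = FALSE])
}

#' DICE overlap coefficient between two voxel masks
#'
#' `2|A ∩ B| / (|A| + |B|)`; symmetric, 1 iff the masks are identical.
#'
#' @param a,b [voxel_mask()] objects on the same grid.
#' @return overlap coefficient in `[0, 1]`.
#' @export
dice <- function(a, b) {
  stopifnot(inherits(a, "voxel_mask"), inherits(b, "voxel_mask"))
  if (!same_grid(a, b)) stopf("masks live on different grids")
  na <- mask_size(a); nb <- mask_size(b)
  if (na + nb == 0L) stopf("undefined overlap: both masks are empty")
  inter <- length(intersect(mask_linear(a), mask_linear(b)))
  2 * inter / (na + nb)
}

#' Remove mutually overlapping voxels from two ROIs
#'
#' @param a,b [voxel_mask()] objects on the same grid.
#' @return list of the two masks with the intersection removed from both
#'   (`a` minus `b`, `b` minus `a`); a warning is raised if either becomes
#'   empty.
#' @export
remove_overlap <- function(a, b) {
  stopifnot(inherits(a, "voxel_mask"), inherits(b, "voxel_mask"))
  if (!same_grid(a, b)) stopf("masks live on different grids")
  la <- mask_linear(a); lb <- mask_linear(b)
  keep_a <- !(la %in% lb); keep_b <- !(lb %in% la)
  out <- list(a = voxel_mask(a$grid, a$members[keep_a, , drop = FALSE]),
              b = voxel_mask(b$grid, b$members[keep_b, , drop = FALSE]))
  if (mask_size(out$a) == 0L || mask_size(out$b) == 0L) {
    warnf("overlap removal emptied a mask; downstream analyses will reject it")
  }
  out
}

#' NIfTI volume I/O
#'
#' Thin wrappers for reading and writing masks and statistic maps as
#' NIfTI-1 volumes, preserving voxel size and affine metadata on the
#' `volume_grid`.
#'
#' @param path NIfTI file path (`.nii` / `.nii.gz`).
#' @return `read_volume` returns a list with `data` (3D array) and `grid`;
#'   `read_mask_nifti` returns a [voxel_mask()].
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) != 3L) stopf("expected a 3D volume, got %dD", length(dim(arr)))
  grid <- volume_grid(dim(arr), voxel_size = RNifti::pixdim(img)[1:3],
                      affine = RNifti::xform(img))
  list(data = arr, grid = grid)
}

#' @rdname read_volume
#' @export
read_mask_nifti <- function(path) {
  v <- read_volume(path)
  voxel_mask(v$grid, v$data != 0)
}

#' @rdname read_volume
#' @param data 3D numeric array on `grid` (for masks use 0/1).
#' @param grid a [volume_grid()].
#' @export
write_volume <- function(data, grid, path) {
  stopifnot(inherits(grid, "volume_grid"))
  if (!all(dim(data) == grid$shape)) stopf("data does not match grid shape")
  img <- RNifti::asNifti(data)
  RNifti::pixdim(img) <- grid$voxel_size
  if (!is.null(grid$affine)) {
    RNifti::qform(img) <- structure(grid$affine, code = 2L)
    RNifti::sform(img) <- structure(grid$affine, code = 2L)
  }
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname read_volume
#' @param mask a [voxel_mask()].
#' @export
write_mask_nifti <- function(mask, path) {
  write_volume(mask_to_array(mask), mask$grid, path)
}
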