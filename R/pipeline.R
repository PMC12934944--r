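#' Pattern datasets
#'
#' Container binding per-subject, per-repeat condition x voxel response
#' matrices to a volume grid and analysis mask. Voxel columns correspond to
#' the mask's member rows (lexicographic order). [gen_pattern_dataset()]
#' produces this structure; real beta images read from NIfTI can be
#' assembled with this constructor.
#'
#' @param patterns list over subjects; each element a list over repeats of
#'   condition x voxel matrices (identical shapes within a subject; repeat
#'   counts may differ between subjects).
#' @param labels condition labels (shared by all subjects and repeats).
#' @param grid a [volume_grid()].
#' @param mask a [voxel_mask()]; its size must equal the voxel count.
#' @return object of class `pattern_dataset`.
#' @export
pattern_dataset <- function(patterns, labels, grid, mask) {
  stopifnot(inherits(grid, "volume_grid"), inherits(mask, "voxel_mask"))
  n_vox <- mask_size(mask)
  for (s in seq_along(patterns)) {
    for (r in seq_along(patterns[[s]])) {
      m <- patterns[[s]][[r]]
      if (nrow(m) != length(labels) || ncol(m) != n_vox) {
        stopf("subject %d repeat %d: expected %d x %d, got %d x %d",
              s, r, length(labels), n_vox, nrow(m), ncol(m))
      }
    }
  }
  if (is.null(names(patterns))) names(patterns) <- paste0("subject_", seq_along(patterns))
  structure(list(patterns = patterns, labels = labels, grid = grid, mask = mask),
            class = "pattern_dataset")
}

# Column indices of an ROI within a dataset's analysis mask.
roi_columns <- function(dataset, roi) {
  if (inherits(roi, "voxel_mask")) {
    cols <- match(mask_linear(roi), mask_linear(dataset$mask))
    if (anyNA(cols)) stopf("ROI extends outside the dataset's analysis mask")
    return(cols)
  }
  as.integer(roi)
}

# Model RDMs as plain numeric vectors of the expected pair length.
model_vectors <- function(models, n_cond) {
  if (!is.list(models) || is.null(names(models)) || any(names(models) == "")) {
    stopf("models must be a named list of RDMs or RDM vectors")
  }
  npair <- n_cond * (n_cond - 1L) / 2L
  out <- lapply(models, function(m) {
    v <- as_rdm_entries(m)
    if (length(v) != npair) {
      stopf("model RDM has %d pairs, dataset implies %d", length(v), npair)
    }
    v
  })
  out
}

# Fast correlation-distance RDM vector (canonical row-major upper order).
fast_rdm_vec <- function(x) {
  C <- stats::cor(t(x))
  1 - C[lower.tri(C)]
}

# Normalized, repeat-averaged patterns for one subject plus the mapping
# from original voxel columns to columns of the returned matrix (NA for
# voxels excluded as zero-variance).
subject_average <- function(repeats) {
  avg <- normalize_and_average(repeats)
  excluded <- attr(avg, "excluded")
  n_vox <- ncol(repeats[[1L]])
  colmap <- rep(NA_integer_, n_vox)
  kept <- setdiff(seq_len(n_vox), excluded)
  colmap[kept] <- seq_along(kept)
  list(avg = avg, colmap = colmap)
}

# Group-level test of per-subject rhos, optionally Fisher-z transforming
# the values before the sign-flip test (reported mean stays on the rho
# scale).
group_cell <- function(rhos, tail, n_perm, seed, fisher_z = FALSE) {
  vals <- rhos[!is.na(rhos)]
  if (length(vals) < 2L) {
    return(list(mean = mean(vals), p = NA_real_, n = length(vals)))
  }
  tv <- if (fisher_z) atanh(pmin(pmax(vals, -1 + 1e-12), 1 - 1e-12)) else vals
  gr <- signed_permutation_test(tv, tail = tail, n_perm = n_perm, seed = seed)
  list(mean = mean(vals), p = gr$p, n = length(vals))
}

#' ROI-based RSA with variance partitioning and noise ceilings
#'
#' For every subject and ROI: applies the subject-specific split-half
#' reliability mask (voxels with r > 0), builds the neural RDM from
#' normalized repeat-averaged patterns, and computes the full Spearman
#' correlation with every model RDM plus (when >= 2 models) each model's
#' semi-partial correlation controlling for the others. Group-level
#' one-tailed sign-flip permutation tests are FDR-corrected across the
#' (ROI x model) family within each statistic kind. Spearman-Brown
#' split-half RSA ceilings are attached per ROI; ROIs whose ceiling is not
#' significantly above zero are flagged (`ceiling_ok = FALSE`) and should
#' not be interpreted.
#'
#' @param dataset a [pattern_dataset()].
#' @param rois named list of [voxel_mask()]s (or integer voxel-column
#'   vectors).
#' @param models named list of model RDMs / RDM vectors.
#' @param n_perm permutations for the group tests (default 5000).
#' @param alpha FDR level (default 0.05).
#' @param semipartial also compute unique-variance statistics (default
#'   TRUE when >= 2 models).
#' @param fisher_z Fisher-z transform per-subject rhos before the group
#'   test (default off).
#' @param seed seed for the Monte-Carlo permutation draws.
#' @return list with `table` (tidy data frame: roi, model, kind, n,
#'   mean_rho, p, p_adj, z, significant, ceiling, ceiling_ok), `per_subject`
#'   (long data frame of subject-level statistics), `ceilings`, and
#'   `manifest`.
#' @export
run_roi_analysis <- function(dataset, rois, models, n_perm = 5000L,
                             alpha = 0.05, semipartial = TRUE,
                             fisher_z = FALSE, seed = 1L) {
  stopifnot(inherits(dataset, "pattern_dataset"))
  if (length(dataset$patterns) < 2L) stopf("group analysis needs >= 2 subjects")
  mv <- model_vectors(models, length(dataset$labels))
  model_ranks <- vapply(mv, rank, numeric(length(mv[[1L]])))
  do_sp <- semipartial && length(mv) >= 2L
  roi_cols <- lapply(rois, roi_columns, dataset = dataset)
  if (is.null(names(roi_cols))) names(roi_cols) <- paste0("roi_", seq_along(roi_cols))

  subjects <- names(dataset$patterns)
  per_subject <- list()
  ceil_rows <- list()
  for (s in subjects) {
    repeats <- dataset$patterns[[s]]
    rel <- split_half_voxel_reliability(repeats)
    sa <- subject_average(repeats)
    for (rn in names(roi_cols)) {
      vox <- roi_cols[[rn]]
      keep <- vox[rel$mask[vox] & !is.na(sa$colmap[vox])]
      ceil <- split_half_rsa_reliability(repeats, voxels = vox)
      ceil_rows[[length(ceil_rows) + 1L]] <-
        data.frame(subject = s, roi = rn, ceiling = ceil$ceiling,
                   stringsAsFactors = FALSE)
      if (length(keep) < 2L) {
        per_subject[[length(per_subject) + 1L]] <-
          data.frame(subject = s, roi = rn, model = names(mv), kind = "full",
                     rho = NA_real_, stringsAsFactors = FALSE)
        next
      }
      dvec <- fast_rdm_vec(sa$avg[, sa$colmap[keep], drop = FALSE])
      dr <- rank(dvec)
      full <- as.numeric(stats::cor(dr, model_ranks))
      rows <- data.frame(subject = s, roi = rn, model = names(mv),
                         kind = "full", rho = full, stringsAsFactors = FALSE)
      if (do_sp) {
        sp <- vapply(seq_along(mv), function(k) {
          semipartial_spearman(dvec, mv[[k]], controls = mv[-k])$rho
        }, numeric(1))
        rows <- rbind(rows, data.frame(subject = s, roi = rn, model = names(mv),
                                       kind = "semipartial", rho = sp,
                                       stringsAsFactors = FALSE))
      }
      per_subject[[length(per_subject) + 1L]] <- rows
    }
  }
  per_subject <- do.call(rbind, per_subject)
  ceilings <- do.call(rbind, ceil_rows)

  # group inference per (roi, model, kind), FDR per kind across roi x model
  kinds <- unique(per_subject$kind)
  table_rows <- list()
  cell_id <- 0L
  for (kd in kinds) {
    sub <- per_subject[per_subject$kind == kd, ]
    cells <- unique(sub[c("roi", "model")])
    res <- lapply(seq_len(nrow(cells)), function(i) {
      cell_id <<- cell_id + 1L
      rhos <- sub$rho[sub$roi == cells$roi[i] & sub$model == cells$model[i]]
      group_cell(rhos, tail = "one", n_perm = n_perm,
                 seed = derive_seed(seed, cell_id), fisher_z = fisher_z)
    })
    p <- vapply(res, `[[`, numeric(1), "p")
    fdr <- fdr_bh(p, alpha)
    table_rows[[kd]] <- data.frame(
      roi = cells$roi, model = cells$model, kind = kd,
      n = vapply(res, `[[`, numeric(1), "n"),
      mean_rho = vapply(res, `[[`, numeric(1), "mean"),
      p = p, p_adj = fdr$adjusted,
      z = p_to_z(fdr$adjusted, tail = "one"),
      significant = fdr$rejected, stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, table_rows)

  # noise ceilings: group test per ROI that the ceiling is above zero
  ceil_group <- lapply(names(roi_cols), function(rn) {
    vals <- ceilings$ceiling[ceilings$roi == rn]
    g <- group_cell(vals, tail = "one", n_perm = n_perm,
                    seed = derive_seed(seed, 90000L + match(rn, names(roi_cols))))
    data.frame(roi = rn, ceiling = g$mean, ceiling_p = g$p,
               ceiling_ok = !is.na(g$p) && g$p <= alpha,
               stringsAsFactors = FALSE)
  })
  ceil_group <- do.call(rbind, ceil_group)
  tab <- merge(tab, ceil_group, by = "roi", sort = FALSE)
  tab <- tab[order(tab$kind, tab$roi, tab$model), ]
  rownames(tab) <- NULL

  list(table = tab, per_subject = per_subject, ceilings = ceilings,
       manifest = list(analysis = "roi", n_perm = n_perm, alpha = alpha,
                       tail = "one", fdr_family = "roi x model cells per statistic kind",
                       fisher_z = fisher_z, seed = seed,
                       n_subjects = length(subjects),
                       models = names(mv), rois = names(roi_cols)))
}

#' Whole-volume searchlight RSA with group permutation maps
#'
#' Defines spherical searchlights over the group reliability mask (voxels
#' whose mean split-half reliability across subjects exceeds zero),
#' computes per-subject Spearman correlations between each searchlight's
#' neural RDM and every model RDM (optionally semi-partial, controlling
#' for the other models), then runs a voxelwise group sign-flip
#' permutation test with FDR correction across voxels. Z-maps are derived
#' from the FDR-adjusted p-values, signed by the group mean, and
#' additionally thresholded at |z| >= `z_thresh`.
#'
#' @inheritParams run_roi_analysis
#' @param radius searchlight radius in voxels (default 3).
#' @param tail `"two"` (default) or `"one"`.
#' @param min_voxels searchlights smaller than this are skipped (NA in the
#'   maps).
#' @param z_thresh threshold for the thresholded map (default 1.96).
#' @param semipartial also produce unique-variance maps (default FALSE).
#' @return list with `maps` (per model, per kind: 3D arrays `mean_rho`,
#'   `p`, `p_adj`, `z`, `z_thresh`, NA outside the analyzed voxels),
#'   `searchlights`, `reliability_mask`, and `manifest`.
#' @export
run_searchlight_analysis <- function(dataset, models, radius = 3,
                                     n_perm = 5000L, alpha = 0.05,
                                     tail = "two", min_voxels = 10L,
                                     z_thresh = 1.96, semipartial = FALSE,
                                     fisher_z = FALSE, seed = 1L) {
  stopifnot(inherits(dataset, "pattern_dataset"))
  subjects <- names(dataset$patterns)
  if (length(subjects) < 2L) stopf("group analysis needs >= 2 subjects")
  mv <- model_vectors(models, length(dataset$labels))
  model_ranks <- vapply(mv, rank, numeric(length(mv[[1L]])))
  do_sp <- semipartial && length(mv) >= 2L

  # group reliability mask: mean per-voxel split-half r across subjects > 0
  rel_sum <- 0
  averages <- vector("list", length(subjects)); names(averages) <- subjects
  for (s in subjects) {
    rel <- split_half_voxel_reliability(dataset$patterns[[s]])
    rel_sum <- rel_sum + ifelse(is.na(rel$r), 0, rel$r)
    averages[[s]] <- subject_average(dataset$patterns[[s]])
  }
  rel_mean <- rel_sum / length(subjects)
  keep_vox <- which(rel_mean > 0)
  if (length(keep_vox) < 2L) stopf("group reliability mask is (nearly) empty")
  rel_mask <- voxel_mask(dataset$grid,
                         dataset$mask$members[keep_vox, , drop = FALSE])
  sls <- define_searchlights(rel_mask, radius = radius, min_voxels = min_voxels)
  n_sl <- length(sls$members)

  kinds <- c("full", if (do_sp) "semipartial")
  # rho[subject, searchlight] per model and kind
  rho <- lapply(kinds, function(kd) {
    lapply(names(mv), function(m) matrix(NA_real_, length(subjects), n_sl))
  })
  names(rho) <- kinds
  for (kd in kinds) names(rho[[kd]]) <- names(mv)

  for (si in seq_along(subjects)) {
    sa <- averages[[subjects[si]]]
    for (li in seq_len(n_sl)) {
      if (sls$flagged[li]) next
      vox <- keep_vox[sls$members[[li]]]
      cols <- sa$colmap[vox]
      cols <- cols[!is.na(cols)]
      if (length(cols) < 2L) next
      dvec <- fast_rdm_vec(sa$avg[, cols, drop = FALSE])
      rfull <- as.numeric(stats::cor(rank(dvec), model_ranks))
      for (k in seq_along(mv)) rho$full[[k]][si, li] <- rfull[k]
      if (do_sp) {
        for (k in seq_along(mv)) {
          rho$semipartial[[k]][si, li] <-
            semipartial_spearman(dvec, mv[[k]], controls = mv[-k])$rho
        }
      }
    }
  }

  shape <- dataset$grid$shape
  centers_lin <- mask_linear(rel_mask)
  blank <- array(NA_real_, shape)
  maps <- list()
  cell_id <- 0L
  for (kd in kinds) {
    maps[[kd]] <- list()
    for (m in names(mv)) {
      R <- rho[[kd]][[m]]
      ok <- which(colSums(!is.na(R)) >= 2L)
      cell_id <- cell_id + 1L
      stats_list <- lapply(seq_along(ok), function(j) {
        group_cell(R[, ok[j]], tail = tail, n_perm = n_perm,
                   seed = derive_seed(seed, cell_id * 100000L + j),
                   fisher_z = fisher_z)
      })
      p <- vapply(stats_list, `[[`, numeric(1), "p")
      mu <- vapply(stats_list, `[[`, numeric(1), "mean")
      fdr <- fdr_bh(p, alpha)
      z <- p_to_z(fdr$adjusted, effect_sign = sign(mu), tail = tail)
      zt <- ifelse(abs(z) >= z_thresh, z, NA_real_)
      mk <- function(vals) { a <- blank; a[centers_lin[ok]] <- vals; a }
      maps[[kd]][[m]] <- list(mean_rho = mk(mu), p = mk(p),
                              p_adj = mk(fdr$adjusted), z = mk(z),
                              z_thresh = mk(zt))
    }
  }
  list(maps = maps, searchlights = sls, reliability_mask = rel_mask,
       manifest = list(analysis = "searchlight", radius = radius,
                       n_perm = n_perm, alpha = alpha, tail = tail,
                       fdr_family = "across voxels per model map",
                       z_thresh = z_thresh, z_from = "fdr-adjusted p",
                       fisher_z = fisher_z, seed = seed,
                       min_voxels = min_voxels, models = names(mv)))
}

#' Time-resolved ROI RSA with model-by-window ANOVA
#'
#' Runs the unique-variance (semi-partial) ROI analysis separately in each
#' time-window dataset, tests each (window, model) cell at the group level
#' (one-tailed sign-flip permutation, FDR across the window x model
#' family), and assesses model-by-time interaction with a two-way
#' repeated-measures ANOVA on the subject x model x window grid of
#' semi-partial correlations.
#'
#' @param windows list of [pattern_dataset()]s, one per time window,
#'   sharing subjects and conditions (5 windows expected; other counts
#'   produce a warning).
#' @param roi a [voxel_mask()] or integer voxel-column vector.
#' @inheritParams run_roi_analysis
#' @return list with `profile` (data frame: window, model, n, mean_rho, p,
#'   p_adj, significant), `anova` (an `anova_table`), `per_subject` (3D
#'   array subjects x models x windows), and `manifest`.
#' @export
run_time_resolved <- function(windows, roi, models, n_perm = 5000L,
                              alpha = 0.05, fisher_z = FALSE, seed = 1L) {
  if (length(windows) != 5L) {
    warnf("time-resolved analysis usually uses 5 windows; got %d", length(windows))
  }
  if (is.null(names(windows))) names(windows) <- paste0("window_", seq_along(windows))
  mv <- model_vectors(models, length(windows[[1L]]$labels))
  if (length(mv) < 2L) stopf("time-resolved variance partitioning needs >= 2 models")
  subjects <- names(windows[[1L]]$patterns)
  for (w in windows) {
    if (!identical(names(w$patterns), subjects)) {
      stopf("all windows must share the same subjects")
    }
  }
  vox_by_window <- lapply(windows, roi_columns, roi = roi)
  vals <- array(NA_real_, c(length(subjects), length(mv), length(windows)),
                dimnames = list(subjects, names(mv), names(windows)))
  for (wi in seq_along(windows)) {
    ds <- windows[[wi]]
    vox <- vox_by_window[[wi]]
    for (si in seq_along(subjects)) {
      repeats <- ds$patterns[[si]]
      rel <- split_half_voxel_reliability(repeats)
      sa <- subject_average(repeats)
      keep <- vox[rel$mask[vox] & !is.na(sa$colmap[vox])]
      if (length(keep) < 2L) next
      dvec <- fast_rdm_vec(sa$avg[, sa$colmap[keep], drop = FALSE])
      for (k in seq_along(mv)) {
        vals[si, k, wi] <- semipartial_spearman(dvec, mv[[k]], controls = mv[-k])$rho
      }
    }
  }
  cells <- expand.grid(model = names(mv), window = names(windows),
                       stringsAsFactors = FALSE)
  res <- lapply(seq_len(nrow(cells)), function(i) {
    group_cell(vals[, cells$model[i], cells$window[i]], tail = "one",
               n_perm = n_perm, seed = derive_seed(seed, i),
               fisher_z = fisher_z)
  })
  p <- vapply(res, `[[`, numeric(1), "p")
  fdr <- fdr_bh(p, alpha)
  profile <- data.frame(window = cells$window, model = cells$model,
                        n = vapply(res, `[[`, numeric(1), "n"),
                        mean_rho = vapply(res, `[[`, numeric(1), "mean"),
                        p = p, p_adj = fdr$adjusted,
                        significant = fdr$rejected, stringsAsFactors = FALSE)
  anova <- if (length(mv) == 2L && !anyNA(vals)) {
    rm_anova_2way(vals, factor_names = c("model", "window"))
  } else NULL
  list(profile = profile, anova = anova, per_subject = vals,
       manifest = list(analysis = "time_resolved", n_perm = n_perm,
                       alpha = alpha, tail = "one",
                       fdr_family = "window x model cells",
                       fisher_z = fisher_z, seed = seed,
                       n_windows = length(windows), models = names(mv),
                       sphericity_correction = "none"))
}

#' Write pipeline outputs
#'
#' `write_roi_table` writes the tidy ROI results as TSV;
#' `write_searchlight_maps` writes each model's z-maps (unthresholded and
#' thresholded) as NIfTI volumes named `<kind>_<model>_z.nii.gz` /
#' `<kind>_<model>_z_thresh.nii.gz`.
#'
#' @param result output of [run_roi_analysis()] /
#'   [run_searchlight_analysis()].
#' @param path,dir output file / directory.
#' @param grid the dataset's [volume_grid()].
#' @return the written path(s), invisibly.
#' @export
write_roi_table <- function(result, path) {
  utils::write.table(result$table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_roi_table
#' @export
write_manifest <- function(result, path) {
  if (is.null(result$manifest)) stopf("result carries no manifest")
  jsonlite::write_json(result$manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_roi_table
#' @export
write_searchlight_maps <- function(result, grid, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  for (kd in names(result$maps)) {
    for (m in names(result$maps[[kd]])) {
      for (which_map in c("z", "z_thresh")) {
        arr <- result$maps[[kd]][[m]][[which_map]]
        arr[is.na(arr)] <- 0
        p <- file.path(dir, sprintf("%s_%s_%s.nii.gz", kd, m, which_map))
        write_volume(arr, grid, p)
        paths <- c(paths, p)
      }
    }
  }
  invisible(paths)
}
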