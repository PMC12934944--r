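# Volumetric geometry: searchlights, normalization, neural RDMs,
# reliability, ROI definition, overlap.

test_that("searchlight spheres enumerate the expected lattice", {
  grid <- volume_grid(c(13, 13, 13))
  solid <- voxel_mask(grid, array(1L, grid$shape))
  sl3 <- define_searchlights(solid, radius = 3)
  deep <- which(apply(sl3$centers, 1, function(v) all(v == 7)))
  expect_length(sl3$members[[deep]], 123)  # |{x^2+y^2+z^2 <= 9}|
  # exhaustive lattice oracle
  off <- expand.grid(-3:3, -3:3, -3:3)
  expect_equal(sum(rowSums(off^2) <= 9), 123)
  sl1 <- define_searchlights(solid, radius = 1)
  expect_length(sl1$members[[deep]], 7)    # center + 6 face neighbors
  single <- voxel_mask(grid, matrix(c(5L, 5L, 5L), 1))
  s <- define_searchlights(single, radius = 3)
  expect_length(s$members, 1)
  expect_length(s$members[[1]], 1)
  expect_true(all(s$flagged))
})

test_that("searchlight membership is mask-restricted and monotone in radius", {
  grid <- volume_grid(c(9, 9, 9))
  set.seed(5)
  arr <- array(rbinom(9^3, 1, 0.5), grid$shape)
  mask <- voxel_mask(grid, arr)
  sl2 <- define_searchlights(mask, radius = 2)
  sl3 <- define_searchlights(mask, radius = 3)
  n <- nrow(mask$members)
  for (i in seq_len(n)) {
    expect_true(all(sl2$members[[i]] %in% seq_len(n)))
    expect_true(all(sl2$members[[i]] %in% sl3$members[[i]]))
    expect_true(i %in% sl2$members[[i]])  # center belongs to its sphere
  }
  expect_warning(define_searchlights(voxel_mask(grid, matrix(0L, 0, 3)), 2),
                 "empty mask")
})

test_that("normalization standardizes voxelwise then averages repeats", {
  set.seed(31)
  x <- matrix(rnorm(40), 8, 5)
  xs <- scale(x); attributes(xs) <- attributes(xs)["dim"]
  expect_equal(normalize_and_average(list(xs)), xs,
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(max(abs(normalize_and_average(list(x, -x)))), 0)
  # two-pass oracle on a random 2-repeat input
  r1 <- matrix(rnorm(40), 8, 5); r2 <- matrix(rnorm(40), 8, 5)
  got <- normalize_and_average(list(r1, r2))
  stacked <- rbind(r1, r2)
  oracle <- (scale(r1, colMeans(stacked), apply(stacked, 2, sd)) +
             scale(r2, colMeans(stacked), apply(stacked, 2, sd))) / 2
  expect_equal(got, oracle, tolerance = 1e-12, ignore_attr = TRUE)
  # zero-variance voxel excluded with a warning
  r1[, 3] <- 1; r2[, 3] <- 1
  expect_warning(out <- normalize_and_average(list(r1, r2)), "zero-variance")
  expect_equal(ncol(out), 4)
  expect_equal(attr(out, "excluded"), 3L)
})

test_that("neural RDMs are correlation distances over voxel subsets", {
  set.seed(17)
  p <- matrix(rnorm(40), 4, 10)
  p[2, ] <- p[1, ]          # identical patterns
  p[3, ] <- -p[1, ]         # sign-flipped
  r <- neural_rdm(p)
  expect_equal(unname(r[1, 2]), 0)
  expect_equal(unname(r[1, 3]), 2)
  q <- matrix(rnorm(40), 4, 10)
  oracle <- 1 - cor(t(q))
  expect_equal(unclass(neural_rdm(q)), oracle, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_error(neural_rdm(q, voxels = 1), "insufficient voxels")
  q2 <- q; q2[2, ] <- 3
  rownames(q2) <- paste0("c", 1:4)
  expect_error(neural_rdm(q2), "zero variance.*c2")
  # voxelwise affine rescaling is absorbed by the normalization stage, so
  # the normalize -> RDM pipeline is invariant to it
  slope <- runif(10, 0.5, 2); offset <- rnorm(10)
  reps <- list(matrix(rnorm(40), 4, 10), matrix(rnorm(40), 4, 10))
  reps_aff <- lapply(reps, function(m) sweep(sweep(m, 2, slope, "*"), 2, offset, "+"))
  r_raw <- neural_rdm(normalize_and_average(reps))
  r_aff <- neural_rdm(normalize_and_average(reps_aff))
  expect_equal(unclass(r_aff), unclass(r_raw), tolerance = 1e-12)
})

test_that("split-half voxel reliability matches the attenuation expectation", {
  reps <- list(matrix(1:20, 5, 4), matrix(1:20, 5, 4))
  out <- split_half_voxel_reliability(reps)
  expect_equal(out$r, rep(1, 4))
  out2 <- split_half_voxel_reliability(list(matrix(1:20, 5, 4), -matrix(1:20, 5, 4)))
  expect_equal(out2$r, rep(-1, 4))
  expect_false(any(out2$mask))
  # signal + noise with known variance ratio: with k repeats per half,
  # E[r] ~ s2 / (s2 + n2/k); here k = 2, s2 = 1, n2 = 1 -> 2/3
  set.seed(71)
  n_vox <- 1000; n_cond <- 60
  signal <- matrix(rnorm(n_cond * n_vox), n_cond, n_vox)
  reps <- lapply(1:4, function(i) signal + matrix(rnorm(n_cond * n_vox), n_cond, n_vox))
  r <- split_half_voxel_reliability(reps)$r
  expect_equal(mean(r), 2 / 3, tolerance = 0.02)
})

test_that("split-half RSA ceiling applies Spearman-Brown", {
  expect_equal(spearman_brown(1), 1)
  expect_equal(spearman_brown(0), 0)
  expect_equal(spearman_brown(0.5), 2 * 0.5 / 1.5)
  expect_warning(nd <- spearman_brown(-1), "undefined")
  expect_true(is.na(nd))
  set.seed(3)
  sig <- matrix(rnorm(30 * 20), 30, 20)
  perfect <- split_half_rsa_reliability(list(sig, sig))
  expect_equal(perfect$rho_split, 1)
  expect_equal(perfect$ceiling, 1)
})

test_that("top-percent ROIs respect count, ties, and containment", {
  grid <- volume_grid(c(5, 5, 5))
  parcel <- cube_mask(grid, c(1, 1, 1), c(5, 4, 1))  # 20 voxels
  contrast <- array(0, grid$shape)
  contrast[parcel$members] <- 1:20
  roi <- define_roi_top_percent(contrast, parcel, 0.10)
  expect_equal(sort(contrast[roi$members]), c(19, 20))
  # all-equal contrast: ties broken by lexicographic member order
  ceq <- array(1, grid$shape)
  roi_eq <- define_roi_top_percent(ceq, parcel, 0.10)
  expect_equal(roi_eq$members, parcel$members[1:2, ])
  expect_equal(define_roi_top_percent(contrast, parcel, 1)$members, parcel$members)
  # always ceil(pct * n) voxels, always inside the parcel
  for (pct in c(0.07, 0.33, 0.5)) {
    r <- define_roi_top_percent(contrast, parcel, pct)
    expect_equal(nrow(r$members), ceiling(pct * 20))
    expect_true(all(mask_linear(r) %in% mask_linear(parcel)))
  }
  cna <- contrast; cna[parcel$members[1, , drop = FALSE]] <- NA
  expect_error(define_roi_top_percent(cna, parcel, 0.1), "undefined")
})

test_that("DICE and overlap removal obey set arithmetic", {
  grid <- volume_grid(c(10, 10, 10))
  a10 <- voxel_mask(grid, rbind(cbind(1:5, 1, 1), cbind(1:5, 2, 1)))  # 10 voxels
  b10 <- voxel_mask(grid, rbind(a10$members[1:2, ], cbind(1:8, 4, 4)))
  expect_equal(dice(a10, a10), 1)
  expect_equal(dice(a10, b10), 2 * 2 / 20)  # |a|=|b|=10, overlap 2
  expect_equal(dice(a10, b10), dice(b10, a10))
  disj <- voxel_mask(grid, cbind(6, 6, 1:4))
  expect_equal(dice(a10, disj), 0)
  expect_error(dice(voxel_mask(grid, matrix(0L, 0, 3)),
                    voxel_mask(grid, matrix(0L, 0, 3))), "undefined overlap")

  out <- remove_overlap(a10, b10)
  expect_equal(mask_size(out$a), 8)
  expect_equal(mask_size(out$b), 8)
  expect_equal(length(intersect(mask_linear(out$a), mask_linear(out$b))), 0)
  out2 <- remove_overlap(a10, disj)
  expect_equal(out2$a$members, a10$members)
  expect_warning(remove_overlap(a10, a10), "emptied")
})

test_that("masks and volumes round-trip through NIfTI", {
  grid <- volume_grid(c(7, 6, 5), voxel_size = 3)
  mask <- cube_mask(grid, c(2, 2, 2), c(4, 4, 3))
  f <- tempfile(fileext = ".nii.gz")
  write_mask_nifti(mask, f)
  back <- read_mask_nifti(f)
  expect_equal(back$members, mask$members)
  expect_equal(back$grid$shape, grid$shape)
  expect_equal(back$grid$voxel_size, c(3, 3, 3))
  vol <- array(rnorm(7 * 6 * 5), grid$shape)
  f2 <- tempfile(fileext = ".nii.gz")
  write_volume(vol, grid, f2)
  expect_equal(read_volume(f2)$data, vol, tolerance = 1e-6, ignore_attr = TRUE)
  unlink(c(f, f2))
})
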