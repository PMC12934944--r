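# Shared fixture builders. Everything is generated in code under fixed
# seeds; no data files.

# Random representation set with labelled conditions.
toy_reps <- function(n = 6L, d = 4L, seed = 1L, labels = paste0("v", seq_len(n))) {
  set.seed(seed)
  representation_set(labels, matrix(rnorm(n * d), n, d))
}

# Small solid cubic region mask inside a grid.
cube_mask <- function(grid, from, to) {
  a <- array(0L, grid$shape)
  a[from[1]:to[1], from[2]:to[2], from[3]:to[3]] <- 1L
  voxel_mask(grid, a)
}

# Planted-mixture dataset on a small grid: two component RDMs from the
# generator's default correlation structure, one cubic region.
planted_dataset <- function(weights = c(A = 1, B = 1), sigma = 1,
                            n_subjects = 10L, n_repeats = 4L,
                            n_conditions = 30L, grid_dim = c(8L, 8L, 8L),
                            region_from = c(3L, 3L, 3L), region_to = c(6L, 6L, 6L),
                            seed = 1L, rep_seed = 42L, subject_jitter = 0.7) {
  reps <- gen_model_representations(n_conditions = n_conditions, seed = rep_seed)
  rdA <- representation_rdm(reps$sets$modelA)
  rdB <- representation_rdm(reps$sets$modelB)
  grid <- volume_grid(grid_dim)
  region <- cube_mask(grid, region_from, region_to)
  spec <- mixture_spec(list(A = rdA, B = rdB),
                       list(planted = list(mask = region, weights = weights)),
                       sigma = sigma, n_subjects = n_subjects,
                       n_repeats = n_repeats, subject_jitter = subject_jitter)
  ds <- gen_pattern_dataset(spec, grid, seed = seed)
  list(dataset = ds, region = region, grid = grid, rdA = rdA, rdB = rdB)
}

# Independent brute-force oracle for the semi-partial Spearman statistic:
# explicit rank transform, normal-equations residualization, Pearson.
oracle_semipartial <- function(target, predictor, controls) {
  rt <- rank(target); rp <- rank(predictor)
  X <- cbind(1, vapply(controls, rank, numeric(length(rp))))
  beta <- solve(t(X) %*% X, t(X) %*% rp)
  res <- as.numeric(rp - X %*% beta)
  sum((rt - mean(rt)) * (res - mean(res))) /
    sqrt(sum((rt - mean(rt))^2) * sum((res - mean(res))^2))
}

# Manual cell-means sums-of-squares oracle for the two-way within-subject
# ANOVA (independent of aov).
oracle_rm_anova <- function(arr) {
  n <- dim(arr)[1]; a <- dim(arr)[2]; b <- dim(arr)[3]
  m <- mean(arr)
  ms <- apply(arr, 1, mean); mi <- apply(arr, 2, mean); mj <- apply(arr, 3, mean)
  msi <- apply(arr, c(1, 2), mean); msj <- apply(arr, c(1, 3), mean)
  mij <- apply(arr, c(2, 3), mean)
  ss_a <- b * n * sum((mi - m)^2)
  ss_as <- b * sum((msi - outer(ms, rep(1, a)) - outer(rep(1, n), mi) + m)^2)
  ss_b <- a * n * sum((mj - m)^2)
  ss_bs <- a * sum((msj - outer(ms, rep(1, b)) - outer(rep(1, n), mj) + m)^2)
  ss_ab <- n * sum((mij - outer(mi, rep(1, b)) - outer(rep(1, a), mj) + m)^2)
  resid <- arr
  for (s in 1:n) for (i in 1:a) for (j in 1:b) {
    resid[s, i, j] <- arr[s, i, j] - msi[s, i] - msj[s, j] - mij[i, j] +
      ms[s] + mi[i] + mj[j] - m
  }
  ss_abs <- sum(resid^2)
  data.frame(
    effect = c("A", "B", "A:B"),
    ss = c(ss_a, ss_b, ss_ab),
    df1 = c(a - 1, b - 1, (a - 1) * (b - 1)),
    df2 = c((a - 1) * (n - 1), (b - 1) * (n - 1), (a - 1) * (b - 1) * (n - 1)),
    F = c((ss_a / (a - 1)) / (ss_as / ((a - 1) * (n - 1))),
          (ss_b / (b - 1)) / (ss_bs / ((b - 1) * (n - 1))),
          (ss_ab / ((a - 1) * (b - 1))) / (ss_abs / ((a - 1) * (b - 1) * (n - 1)))))
}
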