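# Synthetic-data generators: rating counts, controlled representations,
# planted pattern datasets, windowed datasets, frame stacks.

test_that("rating-count generation follows the multinomial law", {
  det <- gen_rating_counts(5, n_raters = 10, profiles = c(1, 0, 0), seed = 1)
  expect_true(all(det$friendly == 10))
  expect_true(all(det$neutral == 0 & det$adversarial == 0))
  a <- gen_rating_counts(20, 12, c(0.8, 0, 0.2), seed = 9)
  b <- gen_rating_counts(20, 12, c(0.8, 0, 0.2), seed = 9)
  expect_identical(a, b)
  big <- gen_rating_counts(10000, 10, c(0.5, 0.3, 0.2), seed = 3)
  freq <- colSums(big[, 2:4]) / (10000 * 10)
  se <- sqrt(c(0.5, 0.3, 0.2) * c(0.5, 0.7, 0.8) / (10000 * 10))
  expect_true(all(abs(freq - c(0.5, 0.3, 0.2)) < 3 * se))
  expect_error(gen_rating_counts(3, 10, c(0.5, 0.2, 0.2)), "sum to 1")
})

test_that("representation generation hits its target inter-RDM correlations", {
  out <- gen_model_representations(n_conditions = 50, seed = 7, tolerance = 0.05)
  expect_true(all(abs(out$achieved - c(0.27, 0.50, 0.46)) <= 0.05))
  # target of exactly 1 duplicates the representations
  dup <- gen_model_representations(30, c(ab = 1, a_beh = 0.5, b_beh = 0.5), seed = 2)
  expect_equal(dup$sets$modelA$vectors, dup$sets$modelB$vectors)
  expect_equal(unname(dup$achieved["ab"]), 1)
  # near-zero target: independent construction keeps |r| small
  z <- gen_model_representations(40, c(ab = 0, a_beh = 0.5, b_beh = 0), seed = 3,
                                 tolerance = 0.1)
  expect_lte(abs(z$achieved[["ab"]]), 0.1)
  expect_lte(abs(z$achieved[["b_beh"]]), 0.1)
})

test_that("planted datasets realize the blended geometry and are reproducible", {
  # subject_jitter = 0: checks the embedding distortion alone
  fx <- planted_dataset(weights = c(A = 1, B = 0), sigma = 0, n_subjects = 1,
                        n_repeats = 1, seed = 5, subject_jitter = 0)
  cols <- fx$dataset$regions$planted$columns
  nr <- neural_rdm(fx$dataset$patterns[[1]][[1]], cols)
  rho <- spearman_rsa(rdm_vector(nr), rdm_vector(fx$rdA))$rho
  expect_gte(rho, 0.95)
  expect_lte(fx$dataset$regions$planted$distortion, 0.05)
  # determinism: bit-identical under the same seed
  fx2 <- planted_dataset(weights = c(A = 1, B = 0), sigma = 0, n_subjects = 1,
                         n_repeats = 1, seed = 5, subject_jitter = 0)
  expect_identical(fx$dataset$patterns, fx2$dataset$patterns)
})

test_that("pure-noise regions carry no model geometry", {
  # subject-level RSA statistics against the models center on zero
  fx <- planted_dataset(weights = c(A = 0, B = 0), sigma = 1, n_subjects = 20,
                        n_repeats = 2, seed = 8)
  cols <- fx$dataset$regions$planted$columns
  va <- rdm_vector(fx$rdA)
  rhos <- vapply(fx$dataset$patterns, function(reps) {
    spearman_rsa(rdm_vector(neural_rdm(normalize_and_average(reps), cols)), va)$rho
  }, numeric(1))
  expect_lt(abs(mean(rhos)), 2 * sd(rhos) / sqrt(length(rhos)) + 0.02)
})

test_that("noise monotonically erodes the split-half RSA ceiling", {
  ceilings <- vapply(c(0.5, 1.5, 4), function(sg) {
    fx <- planted_dataset(weights = c(A = 1, B = 1), sigma = sg, n_subjects = 4,
                          n_repeats = 4, seed = 21)
    cols <- fx$dataset$regions$planted$columns
    mean(vapply(fx$dataset$patterns, function(reps) {
      split_half_rsa_reliability(reps, voxels = cols)$ceiling
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(ceilings) < 0))
})

test_that("windowed datasets follow their weight schedules", {
  reps <- gen_model_representations(n_conditions = 20, seed = 31)
  rdA <- representation_rdm(reps$sets$modelA)
  rdB <- representation_rdm(reps$sets$modelB)
  grid <- volume_grid(c(6, 6, 6))
  region <- cube_mask(grid, c(2, 2, 2), c(5, 5, 4))
  sch <- window_schedules(5)
  # component B absent in every window: its semi-partial stays at zero
  spec <- mixture_spec(list(A = rdA, B = rdB),
                       list(r = list(mask = region,
                                     weights = cbind(A = sch[, 1], B = rep(0, 5)))),
                       sigma = 1, n_subjects = 12, n_repeats = 2)
  wins <- gen_windowed_dataset(spec, grid, seed = 6)
  expect_length(wins, 5)
  va <- rdm_vector(rdA); vb <- rdm_vector(rdB)
  for (w in c(1, 3, 5)) {
    cols <- wins[[w]]$regions$r$columns
    sp_b <- vapply(wins[[w]]$patterns, function(rp) {
      d <- rdm_vector(neural_rdm(normalize_and_average(rp), cols))
      semipartial_spearman(d, vb, list(A = va))$rho
    }, numeric(1))
    expect_lt(abs(mean(sp_b)), 2 * sd(sp_b) / sqrt(length(sp_b)) + 0.03)
  }
  # same seed reproduces the whole window family
  wins2 <- gen_windowed_dataset(spec, grid, seed = 6)
  expect_identical(lapply(wins, `[[`, "patterns"), lapply(wins2, `[[`, "patterns"))
})

test_that("frame stacks are deterministic and respect bounds", {
  tr <- cbind(seq(5, 25, length.out = 10), rep(16, 10))
  s1 <- gen_frame_stack(tr, size = c(32, 32))
  s2 <- gen_frame_stack(tr, size = c(32, 32))
  expect_identical(s1$frames, s2$frames)
  static <- gen_frame_stack(c(16, 16), size = c(32, 32), n_frames = 8)
  expect_equal(max(abs(sweep(static$frames, c(1, 2), static$frames[, , 1]))), 0)
  expect_error(gen_frame_stack(cbind(c(1, 40), c(1, 1)), size = c(32, 32)),
               "bounds")
  # distractor adds a second, static blob
  d <- gen_frame_stack(tr, size = c(32, 32), distractor = c(8, 8))
  expect_gt(d$frames[8, 8, 1], s1$frames[8, 8, 1])
})
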