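# Group permutation inference, FDR, z-conversion, repeated-measures ANOVA.

test_that("sign-flip test is exact under full enumeration", {
  g <- signed_permutation_test(c(1, 2, 3), tail = "one", n_perm = 5000)
  expect_equal(g$p, 1 / 8)  # only (+,+,+) attains mean >= 2
  expect_identical(g$method, "exhaustive")
  # exhaustive p ignores the seed
  g2 <- signed_permutation_test(c(1, 2, 3), tail = "one", n_perm = 5000, seed = 99)
  expect_equal(g2$p, g$p)
  # two-tailed doubles the extreme set for symmetric values
  gt <- signed_permutation_test(c(1, 2, 3), tail = "two", n_perm = 5000)
  expect_equal(gt$p, 2 / 8)
  expect_warning(gz <- signed_permutation_test(c(0, 0, 0)), "zero")
  expect_equal(gz$p, 1)
})

test_that("Monte-Carlo p-values converge to the exhaustive value", {
  set.seed(12)
  vals <- rnorm(10) + 0.6
  exact <- signed_permutation_test(vals, tail = "one", n_perm = 2^10)
  expect_identical(exact$method, "exhaustive")
  mc <- signed_permutation_test(vals, tail = "one", n_perm = 999, seed = 4)
  expect_identical(mc$method, "monte-carlo")
  expect_lt(abs(mc$p - exact$p), 0.05)
  set.seed(13)
  vals16 <- rnorm(16) + 0.4
  exact16 <- signed_permutation_test(vals16, tail = "one", n_perm = 2^16)
  mc16 <- signed_permutation_test(vals16, tail = "one", n_perm = 20000, seed = 7)
  expect_lt(abs(mc16$p - exact16$p), 0.02)
  # determinism under the seed
  mc16b <- signed_permutation_test(vals16, tail = "one", n_perm = 20000, seed = 7)
  expect_equal(mc16$p, mc16b$p)
})

test_that("paired model comparisons test the difference distribution", {
  a <- c(0.2, 0.3, 0.1, 0.4)
  expect_warning(same <- paired_model_comparison(a, a), "zero")
  expect_equal(same$p, 1)
  b <- rep(0, 10)
  g <- paired_model_comparison(b + 1, b, n_perm = 2^10)
  expect_equal(g$p, 2 / 2^10)  # all-same-sign differences, two-tailed
})

test_that("BH step-up rejects the documented set", {
  out <- fdr_bh(c(0.01, 0.02, 0.03, 0.2), alpha = 0.05)
  expect_equal(out$rejected, c(TRUE, TRUE, TRUE, FALSE))
  expect_equal(out$adjusted, c(0.04, 0.04, 0.04, 0.2))
  expect_true(fdr_bh(0.04, 0.05)$rejected)
  all1 <- fdr_bh(rep(1, 5), 0.05)
  expect_false(any(all1$rejected))
  expect_equal(all1$adjusted, rep(1, 5))
  expect_length(fdr_bh(numeric(0))$rejected, 0)
  # monotone: lowering alpha never adds rejections
  set.seed(20)
  p <- runif(50)^2
  r05 <- fdr_bh(p, 0.05)$rejected
  r01 <- fdr_bh(p, 0.01)$rejected
  expect_true(all(which(r01) %in% which(r05)))
  expect_error(fdr_bh(c(0.5, 0)), "0, 1")
})

test_that("p-to-z conversion matches the normal quantiles", {
  expect_equal(p_to_z(0.05, 1, "two"), qnorm(0.975))
  expect_equal(p_to_z(0.05, -1, "two"), -qnorm(0.975))
  expect_equal(p_to_z(0.5, tail = "one"), 0)
  expect_equal(p_to_z(1, 1, "two"), 0)
  expect_equal(p_to_z(1, tail = "one"), qnorm(0))  # -Inf at the lower tail
  # resolution cap at the permutation floor
  expect_equal(p_to_z(1e-12, tail = "one", n_perm = 999), qnorm(1 - 1 / 1000))
  expect_error(p_to_z(0), "0, 1")
})

test_that("permutation p-values are valid under an exchangeable-sign null", {
  # quick calibration check (the full 1000-simulation version lives in the
  # acceptance suite): upper bound P(p <= alpha) <= alpha + MC tolerance
  set.seed(30)
  n_sim <- 300
  p <- vapply(seq_len(n_sim), function(i) {
    signed_permutation_test(rnorm(12), tail = "one", n_perm = 400, seed = i)$p
  }, numeric(1))
  for (alpha in c(0.01, 0.05, 0.1)) {
    rate <- mean(p <= alpha)
    expect_lt(rate, alpha + 3 * sqrt(alpha * (1 - alpha) / n_sim) + 1e-9)
  }
})

test_that("repeated-measures ANOVA matches the sums-of-squares oracle", {
  set.seed(40)
  arr <- array(rnorm(12 * 3 * 4), c(12, 3, 4))
  got <- rm_anova_2way(arr)
  want <- oracle_rm_anova(arr)
  expect_equal(got$ss, want$ss, tolerance = 1e-10)
  expect_equal(got$df1, want$df1)
  expect_equal(got$df2, want$df2)
  expect_equal(got$F, want$F, tolerance = 1e-10)
  # interaction df for the study design: 25 subjects, 2 models, 5 windows
  arr2 <- array(rnorm(25 * 2 * 5), c(25, 2, 5))
  tab <- rm_anova_2way(arr2, c("model", "window"))
  inter <- tab[tab$effect == "model:window", ]
  expect_equal(c(inter$df1, inter$df2), c(4, 96))
})

test_that("ANOVA degenerates correctly on additive and shifted data", {
  # remove the A x B interaction component from random data: cell means
  # become exactly additive while subject-level residual variance remains,
  # so the interaction F collapses to zero
  set.seed(44)
  n <- 8; a <- 2; b <- 5
  arr <- array(rnorm(n * a * b), c(n, a, b))
  mij <- apply(arr, c(2, 3), mean)
  inter <- mij - outer(rowMeans(mij), rep(1, b)) -
    outer(rep(1, a), colMeans(mij)) + mean(mij)
  for (s in 1:n) arr[s, , ] <- arr[s, , ] - inter
  tab <- rm_anova_2way(arr)
  expect_lt(tab$F[tab$effect == "A:B"], 1e-12)
  # adding a per-subject constant leaves every F unchanged
  set.seed(41)
  arr2 <- array(rnorm(10 * 2 * 3), c(10, 2, 3))
  arr3 <- arr2 + rnorm(10)  # recycles over the subject dimension
  expect_equal(rm_anova_2way(arr3)$F, rm_anova_2way(arr2)$F, tolerance = 1e-8)
  # missing cells are rejected
  df <- expand.grid(subject = 1:3, A = 1:2, B = 1:2)
  df$value <- rnorm(12)
  expect_error(rm_anova_2way(df[-1, ]), "incomplete design")
})
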