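# RDM construction, vectorization, and rank-correlation statistics.

test_that("representation RDMs realize correlation distance", {
  # identical vectors -> 0; anticorrelated (c - v) -> 2; one-hot pair -> 1.5
  x <- rbind(a = c(0.8, 0, 0.2), b = c(0.8, 0, 0.2), c = c(1, 1, 1) - c(0.8, 0, 0.2))
  r <- representation_rdm(x)
  expect_equal(r["a", "b"], 0)
  expect_equal(r["a", "c"], 2)
  oh <- representation_rdm(rbind(f = c(1, 0, 0), n = c(0, 1, 0), a = c(0, 0, 1)))
  expect_equal(unname(oh["f", "n"]), 1.5)  # Pearson of distinct one-hots = -0.5
  expect_true(all(diag(r) == 0))
  expect_equal(unclass(r), t(unclass(r)))
})

test_that("representation RDMs are invariant to shift and positive rescale", {
  reps <- toy_reps(n = 8, d = 5, seed = 3)
  base <- representation_rdm(reps)
  shifted <- representation_set(reps$labels, reps$vectors + 7.5)
  scaled <- representation_set(reps$labels, reps$vectors * rep(c(2, 0.3), 4))
  expect_equal(unclass(representation_rdm(shifted)), unclass(base), tolerance = 1e-12)
  expect_equal(unclass(representation_rdm(scaled)), unclass(base), tolerance = 1e-12)
})

test_that("degenerate representations are rejected with the condition named", {
  x <- rbind(a = c(1, 2, 3), b = c(5, 5, 5), c = c(2, 1, 0))
  expect_error(representation_rdm(x), "zero variance.*b")
  expect_error(representation_rdm(x[1:2, ]), "at least 3 conditions")
  expect_error(rdm(matrix(c(0, 1, 2, 0), 2, 2)), "square|labels|asymmetric")
})

test_that("RDM validation catches asymmetry, bad diagonal, out-of-range values", {
  m <- matrix(0, 3, 3); m[1, 2] <- 0.5; m[2, 1] <- 0.7
  expect_error(rdm(m), "asymmetric")
  m2 <- diag(0.1, 3)
  expect_error(rdm(m2), "diagonal")
  m3 <- matrix(0, 3, 3); m3[1, 2] <- m3[2, 1] <- 2.5
  expect_error(rdm(m3), "outside \\[0, 2\\]")
})

test_that("vectorization uses row-major upper-triangle order and round-trips", {
  m <- matrix(0, 3, 3)
  m[1, 2] <- m[2, 1] <- 0.1; m[1, 3] <- m[3, 1] <- 0.2; m[2, 3] <- m[3, 2] <- 0.3
  v <- rdm_vector(rdm(m, labels = c("x", "y", "z")))
  expect_equal(as.numeric(v), c(0.1, 0.2, 0.3))
  expect_equal(rdm_pair_index(3), cbind(i = c(1L, 1L, 2L), j = c(2L, 3L, 3L)))

  big <- representation_rdm(toy_reps(n = 50, d = 6, seed = 9))
  vb <- rdm_vector(big)
  expect_length(vb, 1225)  # n(n-1)/2 at n = 50
  back <- rdm_from_vector(vb)
  expect_equal(unclass(back), unclass(big))
  expect_equal(as.numeric(rdm_vector(back)), as.numeric(vb))
})

test_that("Spearman RSA handles self, reversal, and a closed-form case", {
  v <- rdm_vector(representation_rdm(toy_reps(n = 5, seed = 2)))
  expect_equal(spearman_rsa(v, v)$rho, 1)
  expect_equal(spearman_rsa(v, -(as.numeric(v)) + 3)$rho, -1)
  # untied ranks 1..6 vs (2,1,3,4,6,5): rho = 1 - 6*4/(6*35)
  expect_equal(spearman_rsa(1:6, c(2, 1, 3, 4, 6, 5))$rho, 1 - 24 / 210)
  expect_error(spearman_rsa(c(1, 1, 1), c(1, 2, 3)), "constant")
  expect_error(spearman_rsa(1:4, 1:5), "length")
})

test_that("semi-partial Spearman matches the brute-force oracle on random instances", {
  set.seed(101)
  for (i in 1:100) {
    n_ctrl <- sample(1:3, 1)
    target <- rnorm(20); predictor <- rnorm(20)
    controls <- replicate(n_ctrl, rnorm(20), simplify = FALSE)
    got <- semipartial_spearman(target, predictor, controls)
    expect_equal(got$rho, oracle_semipartial(target, predictor, controls),
                 tolerance = 1e-12)
    expect_identical(got$kind, "semipartial")
  }
})

test_that("semi-partial edge cases: empty controls, self-control, orthogonal control", {
  set.seed(7)
  t <- rnorm(15); p <- rnorm(15)
  expect_equal(semipartial_spearman(t, p, list())$rho,
               spearman_rsa(t, p)$rho, tolerance = 1e-12)
  # residual of a variable on itself is zero -> no unique variance
  expect_equal(semipartial_spearman(t, p, list(p))$rho, 0)
  # a control whose ranks are orthogonal to the predictor's centered ranks
  # leaves the semi-partial equal to the full Spearman
  found <- NULL
  perms <- combinat_perms <- NULL
  p5 <- rank(p[1:5])
  all_perms <- as.matrix(expand.grid(rep(list(1:5), 5)))
  all_perms <- all_perms[apply(all_perms, 1, function(r) length(unique(r)) == 5), ]
  cp <- p5 - mean(p5)
  for (k in seq_len(nrow(all_perms))) {
    cand <- all_perms[k, ]
    if (abs(sum(cp * (cand - mean(cand)))) < 1e-12) { found <- cand; break }
  }
  expect_false(is.null(found))
  t5 <- t[1:5]
  expect_equal(semipartial_spearman(t5, p[1:5], list(as.numeric(found)))$rho,
               spearman_rsa(t5, p[1:5])$rho, tolerance = 1e-12)
})

test_that("variance partitioning assigns unique variance per model", {
  set.seed(11)
  neural <- rnorm(21)
  a <- neural + 0.01 * rnorm(21)  # target's geometry
  b <- rnorm(21)                  # unrelated
  vp <- variance_partition(neural, list(A = a, B = b))
  expect_named(vp, c("A", "B"))
  expect_gt(vp$A$rho, 0.5)
  expect_lt(abs(vp$B$rho), 0.25)
  # order swap returns the same statistics, reordered
  vp2 <- variance_partition(neural, list(B = b, A = a))
  expect_equal(vp2$A$rho, vp$A$rho)
  expect_equal(vp2$B$rho, vp$B$rho)
  expect_named(vp2, c("B", "A"))
  expect_error(variance_partition(neural, list(A = a)), "at least 2")
  expect_error(variance_partition(neural, stats::setNames(list(a, b), c("A", "A"))),
               "unique")
})

test_that("RDMs serialize to square and long delimited text", {
  r <- representation_rdm(toy_reps(n = 6, seed = 13))
  f <- tempfile(fileext = ".tsv")
  write_rdm(r, f)
  back <- read_rdm(f)
  expect_equal(unclass(back), unclass(r), tolerance = 1e-12)
  lg <- rdm_long(r)
  expect_equal(nrow(lg), 15)
  expect_equal(lg$dissimilarity, as.numeric(rdm_vector(r)))
  expect_equal(lg$cond_i[1], "v1")
  unlink(f)
})
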