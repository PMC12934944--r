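#' Group-level sign-flip permutation test
#'
#' Tests whether the group mean of per-subject statistics (e.g. RSA
#' correlations) differs from zero, assuming only sign symmetry of the
#' subject values under the null. The null distribution is built by
#' randomly flipping each subject's sign; when the full enumeration
#' (`2^n` patterns) fits within `n_perm`, it is used and the p-value is
#' exact. The observed statistic is always included in the null count, so
#' p > 0 and the test is valid.
#'
#' @param values per-subject statistic values (length >= 2).
#' @param tail `"two"` (default; uses |mean|) or `"one"` (greater).
#' @param n_perm requested number of permutations (default 5000).
#' @param seed RNG seed for the Monte-Carlo branch (ignored under full
#'   enumeration, which is deterministic).
#' @return object of class `group_result`: list with `values`, `mean`,
#'   `p`, `z`, `tail`, `n_perm` (permutations actually used), `method`
#'   (`"exhaustive"` or `"monte-carlo"`), and `seed`.
#' @export
signed_permutation_test <- function(values, tail = c("two", "one"),
                                    n_perm = 5000L, seed = NULL) {
  tail <- match.arg(tail)
  values <- as.numeric(values)
  n <- length(values)
  if (n < 2L) stopf("need at least 2 subjects")
  if (n_perm < 1L) stopf("n_perm must be >= 1")
  obs <- mean(values)
  if (all(values == 0)) {
    warnf("all subject values are zero; degenerate null (p = 1)")
    return(structure(list(values = values, mean = 0, p = 1,
                          z = p_to_z(1, effect_sign = 1, tail = tail),
                          tail = tail, n_perm = 0L, method = "degenerate",
                          seed = seed),
                     class = "group_result"))
  }
  exhaustive <- n <= 30 && 2^n <= n_perm
  if (exhaustive) {
    signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
    null_means <- as.numeric(signs %*% values) / n
    total <- nrow(signs)  # observed all-ones pattern is among them
    extreme <- if (tail == "one") sum(null_means >= obs - 1e-12)
               else sum(abs(null_means) >= abs(obs) - 1e-12)
    p <- extreme / total
    method <- "exhaustive"; used <- total
  } else {
    null_means <- with_seed(seed, {
      signs <- matrix(sample(c(-1, 1), n_perm * n, replace = TRUE), n_perm, n)
      as.numeric(signs %*% values) / n
    })
    extreme <- if (tail == "one") sum(null_means >= obs - 1e-12)
               else sum(abs(null_means) >= abs(obs) - 1e-12)
    p <- (1 + extreme) / (n_perm + 1)  # observed pattern included
    method <- "monte-carlo"; used <- as.integer(n_perm)
  }
  structure(list(values = values, mean = obs, p = p,
                 z = p_to_z(p, effect_sign = sign(obs), tail = tail),
                 tail = tail, n_perm = used, method = method, seed = seed),
            class = "group_result")
}

#' @export
print.group_result <- function(x, ...) {
  cat(sprintf("sign-flip permutation test (%s, %s-tailed): mean = %.4f, p = %.4g, z = %.3f\n",
              x$method, x$tail, x$mean, x$p, x$z))
  invisible(x)
}

#' Benjamini-Hochberg FDR correction
#'
#' Step-up procedure controlling the false discovery rate: reject all
#' hypotheses up to the largest rank i with `p(i) <= i * alpha / m`.
#'
#' @param pvalues vector of p-values in (0, 1].
#' @param alpha FDR level (default 0.05).
#' @return list with `adjusted` (BH-adjusted p-values, capped at 1) and
#'   `rejected` (logical), in input order.
#' @export
fdr_bh <- function(pvalues, alpha = 0.05) {
  if (length(pvalues) == 0L) return(list(adjusted = numeric(0), rejected = logical(0)))
  if (any(is.na(pvalues)) || any(pvalues <= 0) || any(pvalues > 1)) {
    stopf("p-values must lie in (0, 1]")
  }
  adjusted <- stats::p.adjust(pvalues, method = "BH")
  list(adjusted = adjusted, rejected = adjusted <= alpha)
}

#' Convert a permutation p-value to a signed z-statistic
#'
#' One-tailed: `z = qnorm(1 - p)`. Two-tailed: `z = qnorm(1 - p/2) *
#' sign(effect)`. Used to render group maps in z units (thresholding, e.g.
#' at |z| >= 1.96, is applied by the pipeline, not here). P-values at the
#' permutation resolution floor are capped at the quantile of
#' `1 - 1/(n_perm + 1)` when `n_perm` is supplied.
#'
#' @param p p-value in (0, 1].
#' @param effect_sign sign of the observed effect (two-tailed only).
#' @param tail `"two"` or `"one"`.
#' @param n_perm optional permutation count used to cap infinitesimal p.
#' @return z-statistic.
#' @export
p_to_z <- function(p, effect_sign = 1, tail = c("two", "one"), n_perm = NULL) {
  tail <- match.arg(tail)
  if (any(p <= 0 | p > 1)) stopf("p must lie in (0, 1]")
  if (!is.null(n_perm)) p <- pmax(p, 1 / (n_perm + 1))
  if (tail == "one") stats::qnorm(1 - p)
  else stats::qnorm(1 - p / 2) * ifelse(effect_sign == 0, 1, sign(effect_sign))
}

#' Paired comparison of two models' per-subject statistics
#'
#' Two-tailed sign-flip permutation test on the per-subject differences
#' `valuesA - valuesB` — used to ask whether two model RDMs differ in how
#' well they match a region's representational geometry.
#'
#' @param valuesA,valuesB equal-length paired per-subject statistics.
#' @param n_perm,seed as in [signed_permutation_test()].
#' @return a `group_result` for the differences.
#' @export
paired_model_comparison <- function(valuesA, valuesB, n_perm = 5000L, seed = NULL) {
  if (length(valuesA) != length(valuesB)) stopf("paired values differ in length")
  signed_permutation_test(valuesA - valuesB, tail = "two",
                          n_perm = n_perm, seed = seed)
}

#' Two-way repeated-measures ANOVA
#'
#' Within-subject ANOVA with two crossed factors (e.g. model and time
#' window) on a complete balanced subject x factorA x factorB grid. Each
#' effect is tested against its own subject-by-effect interaction error
#' term; no sphericity correction is applied. For n subjects, a levels of
#' factor A and b levels of factor B the A:B interaction has df
#' `((a-1)(b-1), (a-1)(b-1)(n-1))` — e.g. (4, 96) for 25 subjects, 2
#' models, 5 windows.
#'
#' @param values 3D numeric array `subjects x levelsA x levelsB` (dimnames
#'   used as factor labels when present), or a data frame with columns
#'   `subject`, `A`, `B`, `value`.
#' @param factor_names names for the two within-subject factors.
#' @return data frame (class `anova_table`) with one row per effect (`A`,
#'   `B`, `A:B`): sum of squares, numerator/denominator df, F, and p.
#' @export
rm_anova_2way <- function(values, factor_names = c("A", "B")) {
  if (is.data.frame(values)) {
    df <- values
    names(df) <- c("subject", "A", "B", "value")
  } else {
    d <- dim(values)
    if (length(d) != 3L) stopf("expected a subjects x A x B array")
    dn <- dimnames(values) %||% list(NULL, NULL, NULL)
    df <- expand.grid(subject = dn[[1L]] %||% paste0("s", seq_len(d[1L])),
                      A = dn[[2L]] %||% paste0("a", seq_len(d[2L])),
                      B = dn[[3L]] %||% paste0("b", seq_len(d[3L])),
                      stringsAsFactors = TRUE)
    df$value <- as.numeric(values)
  }
  if (anyNA(df$value)) stopf("incomplete design: missing cell values")
  df$subject <- factor(df$subject); df$A <- factor(df$A); df$B <- factor(df$B)
  n <- nlevels(df$subject); a <- nlevels(df$A); b <- nlevels(df$B)
  if (n < 2L) stopf("need at least 2 subjects")
  if (nrow(df) != n * a * b || anyDuplicated(df[c("subject", "A", "B")])) {
    stopf("incomplete design: need exactly one value per subject x A x B cell")
  }
  fit <- stats::aov(value ~ A * B + Error(subject / (A * B)), data = df)
  sm <- summary(fit)
  pick <- function(stratum, effect) {
    tab <- sm[[stratum]][[1L]]
    rn <- trimws(rownames(tab))
    eff <- tab[match(effect, rn), ]
    err <- tab[match("Residuals", rn), ]
    data.frame(effect = effect, ss = eff[["Sum Sq"]],
               df1 = eff[["Df"]], df2 = err[["Df"]],
               F = eff[["F value"]], p = eff[["Pr(>F)"]],
               stringsAsFactors = FALSE)
  }
  out <- rbind(pick("Error: subject:A", "A"),
               pick("Error: subject:B", "B"),
               pick("Error: subject:A:B", "A:B"))
  out$effect <- c(factor_names, paste(factor_names, collapse = ":"))
  class(out) <- c("anova_table", "data.frame")
  out
}
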