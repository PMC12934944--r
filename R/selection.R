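#' Stimulus subset-selection criteria
#'
#' Parameters of the decorrelation-driven subset search: the subset size,
#' the number of random samples, the weights of the three correlation
#' criteria, and the category-balance constraint. The composite score of a
#' subset is
#' `w_a_beh * r(A, behavior) + w_b_beh * r(B, behavior) - w_ab * r(A, B)`,
#' rewarding subsets on which the two candidate models agree with behavior
#' but disagree with each other; balance is a hard constraint (max minus
#' min category count must not exceed `balance_tol`).
#'
#' @param n_select subset size (default 50).
#' @param n_iter number of random samples (default 1000).
#' @param weights named numeric vector `c(ab =, a_beh =, b_beh =)`, all
#'   >= 0, not all zero.
#' @param balance_tol maximum allowed spread of category counts (default 4,
#'   consistent with a 16/19/15 split of 50).
#' @param seed RNG seed for the sampling.
#' @return object of class `selection_criteria`.
#' @export
selection_criteria <- function(n_select = 50L, n_iter = 1000L,
                               weights = c(ab = 1, a_beh = 1, b_beh = 1),
                               balance_tol = 4L, seed = 1L) {
  if (n_select < 4L) stopf("n_select must be >= 4 for non-degenerate RDMs")
  if (n_iter < 1L) stopf("n_iter must be >= 1")
  if (!all(c("ab", "a_beh", "b_beh") %in% names(weights))) {
    stopf("weights must be named ab, a_beh, b_beh")
  }
  weights <- weights[c("ab", "a_beh", "b_beh")]
  if (any(weights < 0) || all(weights == 0)) {
    stopf("weights must be >= 0 and not all zero")
  }
  structure(list(n_select = as.integer(n_select), n_iter = as.integer(n_iter),
                 weights = weights, balance_tol = as.integer(balance_tol),
                 seed = as.integer(seed)),
            class = "selection_criteria")
}

#' Score one candidate stimulus subset
#'
#' Restricts the three representation sets to the subset, builds their
#' RDMs, computes the three pairwise Spearman correlations between RDM
#' vectors, and combines them into the composite score defined by the
#' criteria. Subsets violating the category-balance constraint are marked
#' infeasible regardless of their correlations.
#'
#' @param subset integer indices of the candidate conditions.
#' @param reps named list of three [representation_set()]s: `modelA`,
#'   `modelB`, `behavior`.
#' @param categories character vector of category labels, one per pool
#'   condition.
#' @param criteria a [selection_criteria()].
#' @return list with `score`, `r_ab`, `r_a_beh`, `r_b_beh`, `counts`
#'   (category counts), and `feasible`.
#' @export
subset_score <- function(subset, reps, categories, criteria) {
  subset <- as.integer(subset)
  if (anyDuplicated(subset)) stopf("subset indices must be unique")
  if (length(subset) < 4L) stopf("subset too small for non-degenerate RDMs")
  counts <- table(factor(categories[subset], levels = unique(categories)))
  feasible <- (max(counts) - min(counts)) <= criteria$balance_tol
  sub_rdm <- function(rs) {
    rdm_vector(representation_rdm(representation_set(
      rs$labels[subset], rs$vectors[subset, , drop = FALSE])))
  }
  va <- sub_rdm(reps$modelA); vb <- sub_rdm(reps$modelB); vh <- sub_rdm(reps$behavior)
  r_ab <- spearman_rsa(va, vb)$rho
  r_a_beh <- spearman_rsa(va, vh)$rho
  r_b_beh <- spearman_rsa(vb, vh)$rho
  w <- criteria$weights
  list(score = w[["a_beh"]] * r_a_beh + w[["b_beh"]] * r_b_beh - w[["ab"]] * r_ab,
       r_ab = r_ab, r_a_beh = r_a_beh, r_b_beh = r_b_beh,
       counts = counts, feasible = feasible)
}

#' Select a decorrelated, behavior-aligned stimulus subset
#'
#' Draws `n_iter` random subsets of size `n_select` without replacement
#' from the candidate pool, scores each with [subset_score()], and returns
#' the feasible subset with the maximal composite score, along with an
#' audit table of every sampled subset's component correlations.
#'
#' @inheritParams subset_score
#' @param reps named list of three [representation_set()]s over the full
#'   pool: `modelA`, `modelB`, `behavior` (identical label order).
#' @return object of class `subset_result`: `selected` (indices),
#'   `r_ab`, `r_a_beh`, `r_b_beh`, `counts`, `score`, and `audit` (data
#'   frame over all iterations).
#' @export
select_subset <- function(reps, categories, criteria = selection_criteria()) {
  pool <- length(reps$modelA$labels)
  if (!all(vapply(reps[c("modelB", "behavior")],
                  function(r) identical(r$labels, reps$modelA$labels), logical(1)))) {
    stopf("the three representation sets must share identical label order")
  }
  if (length(categories) != pool) stopf("need one category label per pool condition")
  if (criteria$n_select > pool) stopf("n_select exceeds the candidate pool size")
  draws <- with_seed(criteria$seed, {
    lapply(seq_len(criteria$n_iter), function(i) {
      sort(sample.int(pool, criteria$n_select))
    })
  })
  audit <- vector("list", criteria$n_iter)
  best <- NULL
  for (i in seq_len(criteria$n_iter)) {
    sc <- subset_score(draws[[i]], reps, categories, criteria)
    audit[[i]] <- data.frame(iteration = i, score = sc$score, r_ab = sc$r_ab,
                             r_a_beh = sc$r_a_beh, r_b_beh = sc$r_b_beh,
                             feasible = sc$feasible,
                             indices = paste(draws[[i]], collapse = ","),
                             stringsAsFactors = FALSE)
    if (sc$feasible && (is.null(best) || sc$score > best$score)) {
      best <- c(sc, list(selected = draws[[i]]))
    }
  }
  audit <- do.call(rbind, audit)
  if (is.null(best)) {
    stopf("no feasible subset in %d draws: every sample violated the balance constraint (tolerance %d)",
          criteria$n_iter, criteria$balance_tol)
  }
  structure(list(selected = best$selected, r_ab = best$r_ab,
                 r_a_beh = best$r_a_beh, r_b_beh = best$r_b_beh,
                 counts = best$counts, score = best$score, audit = audit,
                 criteria = criteria),
            class = "subset_result")
}

#' @export
print.subset_result <- function(x, ...) {
  cat(sprintf("subset_result: %d conditions selected (score %.3f)\n",
              length(x$selected), x$score))
  cat(sprintf("  r(A,B) = %.3f, r(A,behavior) = %.3f, r(B,behavior) = %.3f\n",
              x$r_ab, x$r_a_beh, x$r_b_beh))
  cat("  category counts:", paste(sprintf("%s=%d", names(x$counts), x$counts),
                                  collapse = ", "), "\n")
  invisible(x)
}
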