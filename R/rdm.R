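#' Representational dissimilarity matrices
#'
#' An RDM is a symmetric condition-by-condition matrix of dissimilarities
#' with an exactly-zero diagonal. Throughout this package dissimilarities are
#' correlation distances, `1 - Pearson r`, and therefore live in `[0, 2]`.
#' The `rdm` constructor validates these invariants and is the single entry
#' point through which every analysis stage builds its RDMs.
#'
#' @param values square numeric matrix of dissimilarities.
#' @param labels optional character vector of condition identifiers; defaults
#'   to the matrix dimnames or `cond_1 ... cond_n`.
#' @param tol numerical tolerance for the symmetry and zero-diagonal checks.
#' @return an object of class `rdm`: the validated matrix with condition
#'   labels as dimnames.
#' @export
rdm <- function(values, labels = NULL, tol = 1e-8) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stopf("an RDM must be a numeric matrix")
  }
  n <- nrow(values)
  if (ncol(values) != n) stopf("an RDM must be square (got %d x %d)", n, ncol(values))
  if (anyNA(values)) stopf("RDM contains missing entries")
  if (is.null(labels)) labels <- rownames(values) %||% paste0("cond_", seq_len(n))
  if (length(labels) != n) stopf("need %d labels, got %d", n, length(labels))
  if (anyDuplicated(labels)) stopf("condition labels must be unique")
  asym <- max(abs(values - t(values)))
  if (asym > tol) stopf("RDM asymmetric beyond tolerance (max |d - t(d)| = %.3g)", asym)
  if (max(abs(diag(values))) > tol) stopf("RDM diagonal must be zero")
  # correlation distances live in [0, 2]; anything clearly outside is a sign
  # that a non-correlation-distance matrix was passed in
  if (min(values) < -1e-9 || max(values) > 2 + 1e-9) {
    stopf("dissimilarities outside [0, 2] (range %.3g .. %.3g)",
          min(values), max(values))
  }
  values <- (values + t(values)) / 2
  values[values < 0] <- 0
  diag(values) <- 0
  dimnames(values) <- list(labels, labels)
  class(values) <- c("rdm", "matrix", "array")
  values
}

#' @export
print.rdm <- function(x, ...) {
  cat(sprintf("RDM over %d conditions (correlation distance)\n", nrow(x)))
  print(unclass(x)[seq_len(min(6L, nrow(x))), seq_len(min(6L, ncol(x)))])
  if (nrow(x) > 6L) cat(sprintf("... %d more conditions\n", nrow(x) - 6L))
  invisible(x)
}

is_rdm <- function(x) inherits(x, "rdm")

#' Build an RDM from a set of condition representations
#'
#' Computes entry `(i, j) = 1 - Pearson(vec_i, vec_j)` over the feature
#' vectors of a [representation_set()] (or a plain numeric matrix with one
#' row per condition).
#'
#' @param reps a `representation_set`, or a numeric matrix (conditions in
#'   rows, features in columns) with optional rownames as labels.
#' @return an [rdm()].
#' @export
representation_rdm <- function(reps) {
  x <- as_representation_matrix(reps)
  n <- nrow(x)
  if (n < 3L) stopf("need at least 3 conditions to build an RDM, got %d", n)
  if (ncol(x) < 2L) stopf("feature vectors need at least 2 entries")
  v <- apply(x, 1L, stats::var)
  if (any(v == 0)) {
    stopf("degenerate representation: zero variance for condition(s) %s",
          paste(rownames(x)[v == 0], collapse = ", "))
  }
  d <- 1 - stats::cor(t(x))
  rdm(d, labels = rownames(x))
}

# Accepts representation_set or labelled matrix.
as_representation_matrix <- function(reps) {
  if (inherits(reps, "representation_set")) {
    x <- reps$vectors
  } else if (is.matrix(reps) && is.numeric(reps)) {
    x <- reps
    if (is.null(rownames(x))) rownames(x) <- paste0("cond_", seq_len(nrow(x)))
  } else {
    stopf("expected a representation_set or a numeric matrix")
  }
  x
}

#' Vectorize an RDM (strictly upper triangle, row-major)
#'
#' Extracts the strictly-upper-triangle entries in row-major pair order:
#' (1,2), (1,3), ..., (1,n), (2,3), ..., (n-1,n). This fixed order is the
#' canonical form on which all RDM comparisons operate; the round trip
#' through [rdm_from_vector()] is lossless.
#'
#' @param x an [rdm()] (or symmetric numeric matrix).
#' @param tol symmetry tolerance when a plain matrix is given.
#' @return numeric vector of length `n(n-1)/2` of class `rdm_vector`, with
#'   attributes `n` and `labels`.
#' @export
rdm_vector <- function(x, tol = 1e-8) {
  if (!is_rdm(x)) x <- rdm(as.matrix(x), tol = tol)
  n <- nrow(x)
  # for a symmetric matrix, column-major traversal of the strict lower
  # triangle yields exactly the row-major strict upper triangle
  v <- unclass(x)[lower.tri(x)]
  structure(v, n = n, labels = rownames(x), class = "rdm_vector")
}

#' Pair index of the canonical RDM vectorization
#'
#' @param n number of conditions.
#' @return integer matrix with columns `i`, `j` (`i < j`), one row per
#'   vector entry, in the order used by [rdm_vector()].
#' @export
rdm_pair_index <- function(n) {
  i <- rep.int(seq_len(n - 1L), times = (n - 1L):1L)
  j <- unlist(lapply(seq_len(n - 1L), function(k) (k + 1L):n))
  cbind(i = i, j = j)
}

#' Rebuild an RDM from its canonical vector form
#'
#' @param v numeric vector of length `n(n-1)/2` (an `rdm_vector` or plain).
#' @param n number of conditions; inferred from the `n` attribute or the
#'   vector length when omitted.
#' @param labels optional condition labels.
#' @return an [rdm()].
#' @export
rdm_from_vector <- function(v, n = NULL, labels = NULL) {
  n <- n %||% attr(v, "n")
  if (is.null(n)) {
    n <- as.integer(round((1 + sqrt(1 + 8 * length(v))) / 2))
  }
  if (length(v) != n * (n - 1L) / 2L) {
    stopf("vector length %d does not match n = %d conditions", length(v), n)
  }
  labels <- labels %||% attr(v, "labels")
  m <- matrix(0, n, n)
  m[lower.tri(m)] <- as.numeric(v)
  m <- m + t(m)
  rdm(m, labels = labels)
}

#' @export
print.rdm_vector <- function(x, ...) {
  cat(sprintf("RDM vector: %d pairs over %d conditions\n", length(x), attr(x, "n")))
  print(as.numeric(utils::head(x, 10)))
  invisible(x)
}

as_rdm_entries <- function(x) {
  if (is_rdm(x)) return(as.numeric(rdm_vector(x)))
  as.numeric(x)
}

#' RSA statistic container
#'
#' Light-weight record of one RDM comparison: the rank-correlation
#' coefficient, whether it is a full or semi-partial correlation, and which
#' model RDMs were controlled for.
#'
#' @param rho rank correlation coefficient in `[-1, 1]`.
#' @param kind `"full"` or `"semipartial"`.
#' @param controlled character vector of controlled-model identifiers
#'   (empty iff `kind = "full"`).
#' @return object of class `rsa_stat`.
#' @export
rsa_stat <- function(rho, kind = c("full", "semipartial"), controlled = character()) {
  kind <- match.arg(kind)
  if (abs(rho) > 1 + 1e-12) stopf("|rho| must be <= 1, got %.6f", rho)
  if (kind == "full" && length(controlled)) stopf("full correlations control for nothing")
  structure(list(rho = as.numeric(rho), kind = kind,
                 controlled = as.character(controlled)),
            class = "rsa_stat")
}

#' @export
print.rsa_stat <- function(x, ...) {
  if (x$kind == "full") {
    cat(sprintf("RSA: Spearman rho = %.4f (full)\n", x$rho))
  } else {
    cat(sprintf("RSA: semi-partial Spearman rho = %.4f (controlling for %s)\n",
                x$rho, paste(x$controlled, collapse = ", ")))
  }
  invisible(x)
}

#' Spearman rank correlation between two RDM vectors
#'
#' Average ranks are used for ties (required because, e.g., one-hot RDMs
#' contain only two distinct values).
#'
#' @param a,b RDM vectors (or RDMs) of equal length, at least 3 entries.
#' @return an [rsa_stat()] with `kind = "full"`.
#' @export
spearman_rsa <- function(a, b) {
  a <- as_rdm_entries(a); b <- as_rdm_entries(b)
  if (length(a) != length(b)) stopf("RDM vectors differ in length (%d vs %d)",
                                    length(a), length(b))
  if (length(a) < 3L) stopf("need at least 3 dissimilarity pairs")
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    stopf("undefined correlation: constant RDM vector")
  }
  rsa_stat(stats::cor(a, b, method = "spearman"), kind = "full")
}

#' Semi-partial (part) Spearman correlation
#'
#' The unique-variance statistic of the variance-partitioning analyses: all
#' vectors are rank-transformed (average ranks), the predictor's ranks are
#' residualized on an intercept plus the ranks of every control by least
#' squares, and the returned rho is the Pearson correlation between the
#' target's ranks and the predictor residuals. The target is *not*
#' residualized (semi-partial, not partial). With no controls this reduces
#' exactly to the full Spearman correlation.
#'
#' A predictor that is numerically collinear with its controls has no unique
#' variance left; its semi-partial correlation is reported as 0.
#'
#' @param target neural (or other target) RDM vector.
#' @param predictor model RDM vector whose unique contribution is assessed.
#' @param controls list of RDM vectors to partial out of the predictor; may
#'   be named (names recorded in the result).
#' @return an [rsa_stat()].
#' @export
semipartial_spearman <- function(target, predictor, controls = list()) {
  target <- as_rdm_entries(target); predictor <- as_rdm_entries(predictor)
  if (!is.list(controls)) controls <- list(controls)
  m <- length(target)
  if (length(predictor) != m) stopf("target and predictor differ in length")
  if (m < 3L) stopf("need at least 3 dissimilarity pairs")
  if (length(controls) == 0L) {
    s <- spearman_rsa(target, predictor)
    return(rsa_stat(s$rho, kind = "semipartial", controlled = character()))
  }
  ctrl_names <- names(controls) %||% paste0("control_", seq_along(controls))
  ctrl_names[ctrl_names == ""] <- paste0("control_", which(ctrl_names == ""))
  rt <- rank(target)
  rp <- rank(predictor)
  cm <- vapply(controls, function(v) {
    v <- as_rdm_entries(v)
    if (length(v) != m) stopf("control vector length mismatch")
    rank(v)
  }, numeric(m))
  fit <- stats::lm.fit(cbind(1, cm), rp)
  res <- fit$residuals
  scale <- sqrt(sum((rp - mean(rp))^2))
  if (sqrt(sum(res^2)) < 1e-10 * max(scale, 1)) {
    # predictor fully explained by controls: no unique variance
    return(rsa_stat(0, kind = "semipartial", controlled = ctrl_names))
  }
  if (stats::sd(rt) == 0) stopf("undefined correlation: constant target ranks")
  rsa_stat(stats::cor(rt, res), kind = "semipartial", controlled = ctrl_names)
}

#' Variance partitioning across a set of model RDMs
#'
#' For each named model, computes the semi-partial Spearman correlation of
#' the neural RDM with that model while controlling for all the others —
#' the model's unique contribution to the neural representational geometry.
#'
#' @param neural neural RDM vector (target).
#' @param models named list (>= 2) of model RDM vectors.
#' @return named list of [rsa_stat()], in input order.
#' @export
variance_partition <- function(neural, models) {
  if (!is.list(models) || length(models) < 2L) {
    stopf("variance partitioning needs at least 2 named model RDMs")
  }
  nm <- names(models)
  if (is.null(nm) || any(nm == "") || anyDuplicated(nm)) {
    stopf("model RDMs must carry unique non-empty names")
  }
  out <- lapply(seq_along(models), function(k) {
    semipartial_spearman(neural, models[[k]], controls = models[-k])
  })
  names(out) <- nm
  out
}

#' Read / write RDMs as delimited text
#'
#' The square format is a tab-delimited matrix with condition labels as the
#' header row and first column; [rdm_long()] gives the three-column long
#' form (`cond_i`, `cond_j`, `dissimilarity`) over the canonical pair order.
#'
#' @param x an [rdm()].
#' @param path file path.
#' @return `read_rdm` returns an [rdm()]; `write_rdm` returns `path`
#'   invisibly.
#' @export
write_rdm <- function(x, path) {
  stopifnot(is_rdm(x))
  utils::write.table(as.data.frame(unclass(x)), path, sep = "\t",
                     quote = FALSE, col.names = NA)
  invisible(path)
}

#' @rdname write_rdm
#' @export
read_rdm <- function(path) {
  m <- as.matrix(utils::read.table(path, sep = "\t", header = TRUE,
                                   row.names = 1, check.names = FALSE))
  rdm(m, labels = rownames(m))
}

#' @rdname write_rdm
#' @export
rdm_long <- function(x) {
  stopifnot(is_rdm(x))
  idx <- rdm_pair_index(nrow(x))
  data.frame(cond_i = rownames(x)[idx[, "i"]],
             cond_j = rownames(x)[idx[, "j"]],
             dissimilarity = as.numeric(rdm_vector(x)),
             stringsAsFactors = FALSE)
}
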