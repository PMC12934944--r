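#' Ordered condition representations
#'
#' A representation set binds ordered condition labels to one real-valued
#' feature vector per condition (model embeddings, rating proportions,
#' motion-energy summaries, ...). It is the input of [representation_rdm()].
#'
#' @param labels character vector of unique condition identifiers.
#' @param vectors numeric matrix, one row per condition, uniform length.
#' @return object of class `representation_set` with fields `labels` and
#'   `vectors` (rownames set to the labels).
#' @export
representation_set <- function(labels, vectors) {
  labels <- as.character(labels)
  if (!is.matrix(vectors)) vectors <- as.matrix(vectors)
  storage.mode(vectors) <- "double"
  if (nrow(vectors) != length(labels)) {
    stopf("got %d labels for %d feature vectors", length(labels), nrow(vectors))
  }
  if (anyDuplicated(labels)) {
    stopf("duplicate condition label(s): %s",
          paste(unique(labels[duplicated(labels)]), collapse = ", "))
  }
  if (anyNA(vectors)) stopf("feature vectors contain missing values")
  rownames(vectors) <- labels
  structure(list(labels = labels, vectors = vectors),
            class = "representation_set")
}

#' @export
print.representation_set <- function(x, ...) {
  cat(sprintf("representation_set: %d conditions x %d features\n",
              length(x$labels), ncol(x$vectors)))
  invisible(x)
}

# Fixed category vocabulary of the social-relationship judgments.
RATING_CATEGORIES <- c("friendly", "neutral", "adversarial")

#' Rating-count representation of a condition
#'
#' Converts counts of "friendly", "neutral", and "adversarial" judgments
#' into a proportion vector summing to 1. Keeping the proportions (rather
#' than the modal category) preserves the ambiguity in human ratings: a
#' video rated friendly by 8 raters, neutral by 0, and adversarial by 2
#' maps to (0.8, 0, 0.2).
#'
#' @param counts numeric vector of 3 non-negative integers in category order
#'   (friendly, neutral, adversarial); a named vector is reordered to that
#'   fixed order.
#' @return numeric proportion vector of length 3, named by category.
#' @export
rating_representation <- function(counts) {
  if (!is.null(names(counts))) {
    if (!setequal(names(counts), RATING_CATEGORIES)) {
      stopf("named counts must cover exactly: %s",
            paste(RATING_CATEGORIES, collapse = ", "))
    }
    counts <- counts[RATING_CATEGORIES]
  }
  if (length(counts) != 3L) stopf("expected 3 category counts, got %d", length(counts))
  if (any(counts < 0) || any(counts != round(counts))) {
    stopf("rating counts must be non-negative integers")
  }
  total <- sum(counts)
  if (total < 1) stopf("empty ratings: all category counts are zero")
  stats::setNames(as.numeric(counts) / total, RATING_CATEGORIES)
}

#' One-hot representation of a categorical judgment
#'
#' @param label one of `"friendly"`, `"neutral"`, `"adversarial"`.
#' @return unit vector of length 3 in the fixed category order.
#' @export
onehot_representation <- function(label) {
  if (length(label) != 1L || !label %in% RATING_CATEGORIES) {
    stopf("unknown rating category '%s'; expected one of: %s",
          paste(label, collapse = "/"), paste(RATING_CATEGORIES, collapse = ", "))
  }
  stats::setNames(as.numeric(RATING_CATEGORIES == label), RATING_CATEGORIES)
}

#' Behavioral representation set from a rating-count table
#'
#' @param counts data frame with a label column plus `friendly`, `neutral`,
#'   `adversarial` count columns (one row per video).
#' @param label_col name of the label column (default first column).
#' @return a [representation_set()] of per-video rating proportions.
#' @export
rating_representation_set <- function(counts, label_col = names(counts)[1]) {
  missing_cols <- setdiff(RATING_CATEGORIES, names(counts))
  if (length(missing_cols)) {
    stopf("count table lacks column(s): %s", paste(missing_cols, collapse = ", "))
  }
  vecs <- t(apply(counts[RATING_CATEGORIES], 1L, rating_representation))
  representation_set(counts[[label_col]], vecs)
}

#' Read / write representation tables
#'
#' Delimited text, one row per condition, first column the condition label,
#' remaining columns the feature vector. Tab- or comma-separated by file
#' extension (`.tsv`/`.txt` vs `.csv`).
#'
#' @param path file path.
#' @param sep field separator; inferred from the extension when `NULL`.
#' @param header whether the file carries a header row (written files do).
#' @return `read_representations` returns a [representation_set()].
#' @export
read_representations <- function(path, sep = NULL, header = TRUE) {
  sep <- sep %||% (if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t")
  df <- utils::read.table(path, sep = sep, header = header,
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (ncol(df) < 2L) stopf("representation table needs a label plus >= 1 feature column")
  labels <- as.character(df[[1L]])
  if (anyDuplicated(labels)) {
    line <- which(duplicated(labels))[1L] + as.integer(header)
    stopf("duplicate condition label '%s' at line %d of %s",
          labels[duplicated(labels)][1L], line, path)
  }
  vecs <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(vecs)) {
    bad <- which(!apply(df[, -1L, drop = FALSE], 1L,
                        function(r) all(!is.na(suppressWarnings(as.numeric(r))))))[1L]
    stopf("non-numeric feature value at line %d of %s",
          (bad %||% 1L) + as.integer(header), path)
  }
  representation_set(labels, vecs)
}

#' @rdname read_representations
#' @param x a [representation_set()].
#' @export
write_representations <- function(x, path, sep = NULL) {
  stopifnot(inherits(x, "representation_set"))
  sep <- sep %||% (if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t")
  df <- data.frame(label = x$labels, x$vectors, check.names = FALSE,
                   row.names = NULL)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}
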